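# Propensity-score analysis: correlation with physicochemical property
# scales, composition reports, positional score profiles, histograms, and
# the 20 x 20 heat-map matrix.

#' Pearson product-moment correlation with explicit degenerate handling
#'
#' A thin wrapper around [stats::cor()] that errors informatively when
#' either vector has zero variance (where the correlation is undefined)
#' instead of returning `NA` silently.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return The correlation coefficient in \eqn{[-1, 1]}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("`x` and `y` must have equal length >= 2", class = "scmseq_eval_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("correlation inputs must not contain NA", class = "scmseq_eval_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: input has zero variance", class = "scmseq_undefined_cor")
  }
  cor(x, y)
}

#' Read a per-amino-acid property table
#'
#' Reads a TSV with a `residue` column (single letters) and one numeric
#' column per property scale — the 20-vector format in which AAindex-style
#' physicochemical scales are consumed here. Lines starting with `#` are
#' comments. Rows are returned in the alphabetical residue order of
#' [AA_ALPHABET].
#'
#' @param path Path to the TSV file.
#' @return A tibble with `residue` plus one column per property.
#' @export
#' @examples
#' props <- read_property_table(
#'   system.file("extdata", "aa_properties.tsv", package = "scmseq")
#' )
#' names(props)
read_property_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("property table not found: ", path), class = "scmseq_io_error")
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"residue" %in% names(tab)) {
    abort("property table needs a `residue` column", class = "scmseq_io_error")
  }
  if (!setequal(tab$residue, AA_ALPHABET) || nrow(tab) != 20L) {
    abort("property table must have exactly one row per standard amino acid",
      class = "scmseq_io_error"
    )
  }
  as_tibble(tab[match(AA_ALPHABET, tab$residue), ])
}

#' Correlate amino-acid propensity scores with property scales
#'
#' Computes the Pearson correlation between the 20 amino-acid propensity
#' scores and every property column of the table, ranked by absolute
#' correlation (ties broken by name). This is the scan used to identify
#' physicochemical properties that characterize the positive class, e.g.
#' transfer free energy and membrane preference for bioluminescent
#' proteins.
#'
#' @param properties A property tibble from [read_property_table()] (or any
#'   tibble with `residue` plus numeric columns).
#' @param scores A scoring card, or a named 20-vector of amino-acid scores.
#' @return A tibble with columns `property`, `r`, `rank` sorted by
#'   `abs(r)` descending. Constant property columns have `r` and `rank`
#'   `NA` and are excluded from ranking with a warning.
#' @export
property_scan <- function(properties, scores) {
  if (!is.data.frame(properties) || !"residue" %in% names(properties)) {
    abort("`properties` must be a data frame with a `residue` column",
      class = "scmseq_type_error"
    )
  }
  aa <- if (is_scoring_card(scores)) scores$aa_scores else {
    as_composition_vector(scores, AA_ALPHABET, "scores")
  }
  prop_names <- setdiff(names(properties), "residue")
  if (length(prop_names) == 0L) {
    abort("property table has no property columns", class = "scmseq_type_error")
  }
  ord <- match(AA_ALPHABET, properties$residue)
  r <- purrr::map_dbl(prop_names, function(p) {
    v <- properties[[p]][ord]
    if (sd(v) == 0) NA_real_ else pearson(aa, v)
  })
  if (anyNA(r)) {
    warn(paste0(
      "constant property column(s) excluded from ranking: ",
      paste(prop_names[is.na(r)], collapse = ", ")
    ))
  }
  out <- tibble(property = prop_names, r = r) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$property)
  out$rank <- ifelse(is.na(out$r), NA_integer_, seq_len(nrow(out)))
  out
}

#' Amino-acid score and composition report for two classes
#'
#' Builds the 20-row characterization table pairing a card's amino-acid
#' propensity scores with the percent amino-acid composition of the
#' positive and negative sequence sets and their difference, plus the
#' summary correlations between score and each composition column.
#'
#' @param data A labeled dataset tibble.
#' @param card A scoring card.
#' @param weighting Passed to [class_mean_composition()].
#' @return A tibble with columns `residue`, `score`, `rank` (by descending
#'   score), `comp_pos`, `comp_neg` (percent, each summing to 100) and
#'   `diff`. The correlations of score with the three columns are attached
#'   as the `"correlations"` attribute (named vector; entries are `NA`
#'   where undefined, e.g. a zero-variance difference column).
#' @export
composition_report <- function(data, card, weighting = c("sequence", "pooled")) {
  weighting <- rlang::arg_match(weighting)
  check_labeled(data)
  check_card(card)
  pos <- class_mean_composition(data[data$label == "positive", ], "amino_acid", weighting)
  neg <- class_mean_composition(data[data$label == "negative", ], "amino_acid", weighting)
  out <- tibble(
    residue = AA_ALPHABET,
    score = unname(card$aa_scores),
    rank = rank(-card$aa_scores, ties.method = "min"),
    comp_pos = 100 * pos$value,
    comp_neg = 100 * neg$value,
    diff = 100 * (pos$value - neg$value)
  )
  safe_r <- function(x) if (sd(x) == 0) NA_real_ else pearson(out$score, x)
  attr(out, "correlations") <- c(
    score_vs_pos = safe_r(out$comp_pos),
    score_vs_neg = safe_r(out$comp_neg),
    score_vs_diff = safe_r(out$diff)
  )
  out
}

#' Positional dipeptide-score profile of a sequence
#'
#' Returns the card score of the dipeptide starting at each position of the
#' sequence (a track of \eqn{L - 1} values), optionally smoothed with a
#' centered moving average (window truncated at the sequence ends). Used to
#' ask whether high-scoring dipeptides cluster in segments or are spread
#' along the whole sequence.
#'
#' @param seq A single-row tibble with `id`/`residues`, or a residue string.
#' @param card A scoring card.
#' @param window Odd integer \eqn{\ge 1}; 1 (default) returns the raw track.
#' @return A tibble with columns `position`, `dipeptide`, `score`, and
#'   `smoothed` when `window > 1`.
#' @export
positional_profile <- function(seq, card, window = 1L) {
  check_card(card)
  residues <- if (is.data.frame(seq)) {
    check_sequences(seq, "seq")
    if (nrow(seq) != 1L) abort("`seq` must hold exactly one sequence", class = "scmseq_type_error")
    seq$residues
  } else {
    as.character(seq)
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 1", class = "scmseq_config_error")
  }
  codes <- seq_codes(residues)
  if (length(codes) < 2L) {
    abort("sequence too short for a dipeptide profile", class = "scmseq_feature_error")
  }
  idx <- (codes[-length(codes)] - 1L) * 20L + codes[-1L]
  track <- unname(card$dipeptide_scores[idx])
  out <- tibble(
    position = seq_along(track),
    dipeptide = DIPEPTIDES[idx],
    score = track
  )
  if (window > 1L) {
    half <- window %/% 2L
    out$smoothed <- vapply(seq_along(track), function(i) {
      mean(track[max(1L, i - half):min(length(track), i + half)])
    }, numeric(1))
  }
  out
}

#' Histogram of sequence scores on the card scale
#'
#' Bins scores into half-open intervals `[lo, lo + width)` covering
#' \eqn{[0, 1000]} (the last bin is closed at 1000); counts sum to the
#' number of scores.
#'
#' @param scores Numeric scores in \eqn{[0, 1000]} (e.g. the `score` column
#'   from [score_sequences()]).
#' @param bin_width Positive bin width in score units.
#' @return A tibble with columns `bin_lo`, `bin_hi`, `count`.
#' @export
score_histogram <- function(scores, bin_width = 50) {
  if (length(scores) == 0L) {
    abort("`scores` must be non-empty", class = "scmseq_eval_error")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be positive", class = "scmseq_config_error")
  }
  if (any(scores < 0 | scores > 1000)) {
    abort("scores must lie in [0, 1000]", class = "scmseq_eval_error")
  }
  n_bins <- ceiling(1000 / bin_width)
  bin <- pmin(floor(scores / bin_width), n_bins - 1L) + 1L
  tibble(
    bin_lo = (seq_len(n_bins) - 1L) * bin_width,
    bin_hi = pmin(seq_len(n_bins) * bin_width, 1000),
    count = tabulate(bin, nbins = n_bins)
  )
}

#' Scoring card as a 20 x 20 matrix
#'
#' Rows index the first residue of each dipeptide and columns the second,
#' both in alphabetical order; flattening the matrix row-major recovers the
#' 400-score vector. This is the matrix drawn as the card heat map (see
#' [autoplot.scoring_card()]).
#'
#' @param card A scoring card.
#' @return A 20 x 20 numeric matrix with residue dimnames.
#' @export
card_heatmap_matrix <- function(card) {
  check_card(card)
  matrix(card$dipeptide_scores, 20L, 20L,
    byrow = TRUE,
    dimnames = list(first = AA_ALPHABET, second = AA_ALPHABET)
  )
}
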