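# The scoring card: 400 dipeptide propensity scores in [0, 1000], the 20
# derived amino-acid scores, and an optional decision threshold.

new_scoring_card <- function(dipeptide_scores, threshold = NA_real_, metadata = list()) {
  dipeptide_scores <- as_composition_vector(dipeptide_scores, DIPEPTIDES, "dipeptide_scores")
  if (any(!is.finite(dipeptide_scores))) {
    abort("dipeptide scores must be finite", class = "scmseq_card_error")
  }
  if (any(dipeptide_scores < 0 | dipeptide_scores > 1000)) {
    abort("dipeptide scores must lie in [0, 1000]", class = "scmseq_card_error")
  }
  if (!is.na(threshold) && (threshold < 0 || threshold > 1000)) {
    abort("threshold must lie in [0, 1000]", class = "scmseq_card_error")
  }
  structure(
    list(
      dipeptide_scores = dipeptide_scores,
      aa_scores = derive_aa_scores(dipeptide_scores),
      threshold = threshold,
      metadata = metadata
    ),
    class = "scoring_card"
  )
}

#' Is an object a scoring card?
#' @param x An object.
#' @return `TRUE` for objects created by [initial_card()],
#'   [card_from_compositions()], [ga_optimize()] or [load_card()].
#' @export
is_scoring_card <- function(x) inherits(x, "scoring_card")

check_card <- function(card, need_threshold = FALSE) {
  if (!is_scoring_card(card)) {
    abort("`card` must be a scoring_card object", class = "scmseq_type_error")
  }
  if (need_threshold && is.na(card$threshold)) {
    abort("card has no threshold; set one with `calibrate_threshold()` or `set_threshold()`",
      class = "scmseq_usage_error"
    )
  }
  invisible(card)
}

#' @export
print.scoring_card <- function(x, ...) {
  s <- x$dipeptide_scores
  cat("<scoring_card>\n")
  cat(sprintf(
    "  400 dipeptide scores in [%.1f, %.1f]; threshold %s\n",
    min(s), max(s),
    if (is.na(x$threshold)) "unset" else sprintf("%.2f", x$threshold)
  ))
  top <- sort(x$aa_scores, decreasing = TRUE)[1:3]
  cat(
    "  top amino acids:",
    paste(sprintf("%s=%.1f", names(top), top), collapse = ", "), "\n"
  )
  if (!is.null(x$metadata$dataset)) cat("  trained on:", x$metadata$dataset, "\n")
  invisible(x)
}

#' Build the initial scoring card from class composition differences
#'
#' The raw propensity of dipeptide \eqn{i} is the difference between its mean
#' composition in the positive class and in the negative class,
#' \eqn{d_i = p_i - n_i}. The 400 differences are mapped affinely onto
#' \eqn{[0, 1000]}: \eqn{s_i = 1000 (d_i - \min d) / (\max d - \min d)}, so
#' the most positive-class-enriched dipeptide scores exactly 1000 and the
#' most depleted exactly 0. If all differences are equal (degenerate input)
#' every score is set to 500 with a warning.
#'
#' `initial_card()` is the data-first interface: it computes the two class
#' mean compositions from a labeled dataset. `card_from_compositions()`
#' accepts precomputed 400-entry composition vectors.
#'
#' @param data A labeled dataset tibble (see [load_dataset()]).
#' @param weighting Passed to [class_mean_composition()].
#' @return A [scoring_card][is_scoring_card] with threshold unset.
#' @seealso [ga_optimize()] to refine the card, [calibrate_threshold()] to
#'   set its decision threshold.
#' @export
initial_card <- function(data, weighting = c("sequence", "pooled")) {
  weighting <- rlang::arg_match(weighting)
  check_labeled(data)
  pos <- class_mean_composition(data[data$label == "positive", ], "dipeptide", weighting)
  neg <- class_mean_composition(data[data$label == "negative", ], "dipeptide", weighting)
  card <- card_from_compositions(pos, neg)
  card$metadata$dataset <- attr(data, "dataset_name")
  card$metadata$weighting <- weighting
  card
}

#' @rdname initial_card
#' @param pos_comp,neg_comp Dipeptide compositions of the positive and
#'   negative classes: named 400-vectors or `feature`/`value` tibbles as
#'   returned by [class_mean_composition()].
#' @export
card_from_compositions <- function(pos_comp, neg_comp) {
  p <- as_composition_vector(pos_comp, DIPEPTIDES, "pos_comp")
  n <- as_composition_vector(neg_comp, DIPEPTIDES, "neg_comp")
  d <- p - n
  rng <- range(d)
  if (rng[1] == rng[2]) {
    warn("all composition differences are equal; every dipeptide score set to 500")
    s <- rep(500, 400L)
  } else {
    # guard the box constraint against floating-point overshoot at the ends
    s <- pmin(pmax(1000 * (d - rng[1]) / (rng[2] - rng[1]), 0), 1000)
  }
  new_scoring_card(setNames(s, DIPEPTIDES), metadata = list(normalization = "minmax [0,1000]"))
}

#' Derive the 20 amino-acid propensity scores from a card
#'
#' The score of residue `O` is the mean of the 40 dipeptide scores
#' \eqn{\{s(O,X)\} \cup \{s(X,O)\}} with `X` ranging over all 20 residues;
#' the homo-dipeptide \eqn{(O,O)} appears in both lists and therefore
#' contributes twice (the divisor is 40).
#'
#' @param card A scoring card, or a named 400-vector of dipeptide scores.
#' @return A named numeric vector of 20 amino-acid scores.
#' @export
derive_aa_scores <- function(card) {
  s <- if (is_scoring_card(card)) card$dipeptide_scores else {
    as_composition_vector(card, DIPEPTIDES, "card")
  }
  drop(aa_matrix() %*% s)
}

#' Score sequences with a card
#'
#' The score of a sequence is the composition-weighted mean of dipeptide
#' propensity scores, \eqn{S(P) = \sum_{i=1}^{400} w_i s_i}, where
#' \eqn{w_i} is the sequence's dipeptide composition ([dipeptide_composition()])
#' and \eqn{s_i} the card's propensity scores. Because the weights sum to 1,
#' \eqn{S(P)} always lies between the smallest and largest card score.
#'
#' @param seqs A tibble with columns `id` and `residues` (extra columns such
#'   as `label` are carried through).
#' @param card A scoring card.
#' @return The input tibble with a `score` column appended.
#' @export
score_sequences <- function(seqs, card) {
  check_sequences(seqs)
  check_card(card)
  w <- dpc_matrix(seqs$residues, seqs$id)
  dplyr::mutate(as_tibble(seqs), score = unname(drop(w %*% card$dipeptide_scores)))
}

#' Choose the decision threshold maximizing training accuracy
#'
#' Scans candidate thresholds and returns the one maximizing
#' \eqn{(TP + TN) / N} under the classification rule "positive iff
#' \eqn{S(P) >} threshold". Candidates are the midpoints between adjacent
#' distinct values of the pooled sorted scores, plus one candidate below the
#' minimum and one above the maximum, so every achievable confusion table is
#' realized. Ties are broken toward the smallest qualifying threshold
#' (favoring sensitivity).
#'
#' @param pos_scores,neg_scores Numeric score vectors for the two classes.
#' @return The chosen threshold, with the achieved training accuracy in the
#'   `"accuracy"` attribute.
#' @export
choose_threshold <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    abort("both score vectors must be non-empty", class = "scmseq_eval_error")
  }
  u <- sort(unique(c(pos_scores, neg_scores)))
  candidates <- c(u[1] - 1, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sp <- sort(pos_scores)
  sn <- sort(neg_scores)
  # positive iff score > t:  TP = #pos above t, TN = #neg at or below t
  tp <- length(sp) - findInterval(candidates, sp)
  tn <- findInterval(candidates, sn)
  acc <- (tp + tn) / (length(sp) + length(sn))
  best <- which.max(acc) # which.max returns the first (smallest) maximizer
  structure(candidates[best], accuracy = acc[best])
}

#' Set or calibrate a card's decision threshold
#'
#' `calibrate_threshold()` scores a labeled training set with the card and
#' stores the accuracy-maximizing threshold (see [choose_threshold()]);
#' `set_threshold()` stores an explicit value.
#'
#' @param card A scoring card.
#' @param data A labeled dataset tibble.
#' @return The card with its `threshold` set (and, for
#'   `calibrate_threshold()`, the training accuracy recorded in
#'   `metadata$training_accuracy`).
#' @export
calibrate_threshold <- function(card, data) {
  check_card(card)
  check_labeled(data)
  scored <- score_sequences(data, card)
  thr <- choose_threshold(
    scored$score[scored$label == "positive"],
    scored$score[scored$label == "negative"]
  )
  card$threshold <- clamp_threshold(as.numeric(thr))
  card$metadata$training_accuracy <- attr(thr, "accuracy")
  card
}

# Candidate thresholds one unit outside the observed scores can leave
# [0, 1000]; the decision rule is unchanged by clamping back to the scale.
clamp_threshold <- function(x) min(max(x, 0), 1000)

#' @rdname calibrate_threshold
#' @param threshold A value in \eqn{[0, 1000]}.
#' @export
set_threshold <- function(card, threshold) {
  check_card(card)
  new_scoring_card(card$dipeptide_scores, threshold = threshold, metadata = card$metadata)
}

#' Classify sequences with a thresholded card
#'
#' A sequence is labeled `positive` when its score is strictly greater than
#' the card's threshold; a score exactly equal to the threshold is labeled
#' `negative`.
#'
#' @inheritParams score_sequences
#' @param card A scoring card with its threshold set.
#' @return The input tibble with `score` and `predicted` (factor
#'   `positive`/`negative`) columns appended.
#' @export
classify <- function(seqs, card) {
  check_card(card, need_threshold = TRUE)
  scored <- score_sequences(seqs, card)
  dplyr::mutate(
    scored,
    predicted = factor(
      ifelse(.data$score > card$threshold, "positive", "negative"),
      levels = c("positive", "negative")
    )
  )
}

#' Save or load a scoring card
#'
#' Cards are stored as plain TSV: `#`-prefixed header lines carrying the
#' threshold and a JSON metadata blob, then 400 `dipeptide<TAB>score` rows in
#' the row-major alphabetical pair order of [DIPEPTIDES]. Scores round-trip
#' at full double precision by default; `digits` writes a rounded copy for
#' presentation.
#'
#' @param card A scoring card.
#' @param path File path.
#' @param digits Optional number of decimal places for the exported scores.
#' @return `save_card()` returns `card` invisibly; `load_card()` returns the
#'   scoring card read from `path`.
#' @export
save_card <- function(card, path, digits = NULL) {
  check_card(card)
  s <- card$dipeptide_scores
  fmt <- if (is.null(digits)) {
    function(x) sprintf("%.17g", x)
  } else {
    function(x) sprintf(paste0("%.", digits, "f"), x)
  }
  header <- c(
    "# scmseq scoring card",
    paste0("# threshold: ", if (is.na(card$threshold)) "NA" else sprintf("%.17g", card$threshold)),
    paste0("# metadata: ", jsonlite::toJSON(card$metadata, auto_unbox = TRUE))
  )
  writeLines(c(header, paste(names(s), fmt(s), sep = "\t")), path)
  invisible(card)
}

#' @rdname save_card
#' @export
load_card <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("card file not found: ", path), class = "scmseq_io_error")
  }
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  threshold <- NA_real_
  thr_line <- grep("^# threshold:", header, value = TRUE)
  if (length(thr_line) == 1L) {
    raw <- trimws(sub("^# threshold:", "", thr_line))
    if (raw != "NA") threshold <- as.numeric(raw)
  }
  metadata <- list()
  meta_line <- grep("^# metadata:", header, value = TRUE)
  if (length(meta_line) == 1L) {
    metadata <- jsonlite::fromJSON(trimws(sub("^# metadata:", "", meta_line)))
  }
  parts <- stringr::str_split_fixed(body, "\t", 2L)
  pairs <- parts[, 1]
  scores <- suppressWarnings(as.numeric(parts[, 2]))
  bad <- which(!pairs %in% DIPEPTIDES | is.na(scores))
  if (length(bad) > 0L) {
    abort(paste0("malformed card row ", bad[1], ": \"", body[bad[1]], "\""),
      class = "scmseq_io_error"
    )
  }
  missing <- setdiff(DIPEPTIDES, pairs)
  if (length(missing) > 0L) {
    abort(paste0("card file is missing dipeptide(s): ", paste(head(missing, 5L), collapse = ", ")),
      class = "scmseq_io_error"
    )
  }
  if (anyDuplicated(pairs)) {
    abort(paste0("duplicated dipeptide row: ", pairs[anyDuplicated(pairs)]),
      class = "scmseq_io_error"
    )
  }
  out_of_range <- which(scores < 0 | scores > 1000)
  if (length(out_of_range) > 0L) {
    abort(
      paste0(
        "score out of [0, 1000] at row for ", pairs[out_of_range[1]],
        ": ", scores[out_of_range[1]]
      ),
      class = "scmseq_io_error"
    )
  }
  new_scoring_card(setNames(scores, pairs), threshold = threshold, metadata = metadata)
}

#' Tidy a scoring card into a tibble of dipeptide scores
#'
#' @param x A scoring card.
#' @param ... Unused.
#' @return A 400-row tibble with columns `first`, `second`, `dipeptide`,
#'   `score`.
#' @method tidy scoring_card
#' @export
tidy.scoring_card <- function(x, ...) {
  tibble(
    first = substr(DIPEPTIDES, 1L, 1L),
    second = substr(DIPEPTIDES, 2L, 2L),
    dipeptide = DIPEPTIDES,
    score = unname(x$dipeptide_scores)
  )
}

#' One-row summary of a scoring card
#'
#' @param x A scoring card.
#' @param ... Unused.
#' @return A one-row tibble: score range, mean, threshold, top-scoring
#'   residue.
#' @method glance scoring_card
#' @export
glance.scoring_card <- function(x, ...) {
  tibble(
    n_dipeptides = 400L,
    min_score = min(x$dipeptide_scores),
    max_score = max(x$dipeptide_scores),
    mean_score = mean(x$dipeptide_scores),
    threshold = x$threshold,
    top_residue = names(which.max(x$aa_scores))
  )
}
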