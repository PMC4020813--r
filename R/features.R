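# Composition features: per-sequence dipeptide (400) and amino-acid (20)
# fractions, and class-level means. Internal matrix versions feed the
# scorer and optimizer; user-facing functions return tidy tibbles.

seq_codes <- function(residues, id = "?") {
  codes <- match(strsplit(residues, "")[[1]], AA_ALPHABET)
  if (anyNA(codes)) {
    abort(paste0("sequence ", id, " contains non-standard residues"),
      class = "scmseq_feature_error"
    )
  }
  codes
}

# n x 400 matrix of dipeptide fractions, rows in input order
dpc_matrix <- function(residues, ids = NULL) {
  ids <- ids %||% as.character(seq_along(residues))
  out <- matrix(0, length(residues), 400L, dimnames = list(ids, DIPEPTIDES))
  for (i in seq_along(residues)) {
    codes <- seq_codes(residues[i], ids[i])
    L <- length(codes)
    if (L < 2L) {
      abort(paste0("sequence ", ids[i], " is too short for dipeptide composition (length ", L, ")"),
        class = "scmseq_feature_error"
      )
    }
    idx <- (codes[-L] - 1L) * 20L + codes[-1L]
    out[i, ] <- tabulate(idx, nbins = 400L) / (L - 1L)
  }
  out
}

# n x 20 matrix of amino-acid fractions
aac_matrix <- function(residues, ids = NULL) {
  ids <- ids %||% as.character(seq_along(residues))
  out <- matrix(0, length(residues), 20L, dimnames = list(ids, AA_ALPHABET))
  for (i in seq_along(residues)) {
    codes <- seq_codes(residues[i], ids[i])
    if (length(codes) < 1L) {
      abort(paste0("sequence ", ids[i], " is empty"), class = "scmseq_feature_error")
    }
    out[i, ] <- tabulate(codes, nbins = 20L) / length(codes)
  }
  out
}

#' Dipeptide composition of protein sequences
#'
#' Computes, for each sequence, the fractions of the 400 ordered adjacent
#' residue pairs (overlapping windows): entry \eqn{(a,b)} is the number of
#' positions where `a` is immediately followed by `b`, divided by
#' \eqn{L - 1}. These fractions are the weights \eqn{w_i} of the scoring
#' function used by [score_sequences()].
#'
#' @param seqs A tibble with columns `id` and `residues`.
#' @param format `"long"` (default) for a tidy `id`/`dipeptide`/`frequency`
#'   tibble, `"wide"` for one row per sequence with 400 columns.
#' @return A tibble; in long format `dipeptide` follows the row-major
#'   alphabetical order of [DIPEPTIDES].
#' @export
#' @examples
#' seqs <- tibble::tibble(id = "x", residues = "ACA")
#' dipeptide_composition(seqs) |> dplyr::filter(frequency > 0)
dipeptide_composition <- function(seqs, format = c("long", "wide")) {
  format <- rlang::arg_match(format)
  check_sequences(seqs)
  m <- dpc_matrix(seqs$residues, seqs$id)
  composition_output(m, seqs$id, "dipeptide", format)
}

#' Amino-acid composition of protein sequences
#'
#' Entry for residue `r` is `count(r) / L` (fraction mode) or
#' `100 * count(r) / L` (percent mode).
#'
#' @inheritParams dipeptide_composition
#' @param mode `"fraction"` (sums to 1) or `"percent"` (sums to 100).
#' @return A tibble; in long format columns `id`, `residue`, `frequency`.
#' @export
amino_acid_composition <- function(seqs, mode = c("fraction", "percent"),
                                   format = c("long", "wide")) {
  mode <- rlang::arg_match(mode)
  format <- rlang::arg_match(format)
  check_sequences(seqs)
  m <- aac_matrix(seqs$residues, seqs$id)
  if (mode == "percent") m <- m * 100
  composition_output(m, seqs$id, "residue", format)
}

composition_output <- function(m, ids, feature_name, format) {
  if (format == "wide") {
    return(dplyr::bind_cols(tibble(id = ids), as_tibble(m)))
  }
  tibble(
    id = rep(ids, each = ncol(m)),
    "{feature_name}" := rep(colnames(m), times = nrow(m)),
    frequency = as.vector(t(m))
  )
}

#' Class-level mean composition
#'
#' Averages per-sequence composition vectors over a set of sequences. The
#' default gives every sequence equal weight, so long sequences do not
#' dominate the class profile; `weighting = "pooled"` instead pools residue
#' (or pair) counts over the whole class, which weights sequences by length.
#' Either way the result is itself a composition (sums to 1).
#'
#' @inheritParams dipeptide_composition
#' @param kind `"dipeptide"` (400 entries) or `"amino_acid"` (20 entries).
#' @param weighting `"sequence"` (equal weight per sequence, default) or
#'   `"pooled"` (length-weighted pooled counts).
#' @return A tibble with columns `feature` and `value`.
#' @export
class_mean_composition <- function(seqs, kind = c("dipeptide", "amino_acid"),
                                   weighting = c("sequence", "pooled")) {
  kind <- rlang::arg_match(kind)
  weighting <- rlang::arg_match(weighting)
  check_sequences(seqs)
  if (nrow(seqs) == 0L) {
    abort("no sequences supplied", class = "scmseq_feature_error")
  }
  m <- if (kind == "dipeptide") {
    dpc_matrix(seqs$residues, seqs$id)
  } else {
    aac_matrix(seqs$residues, seqs$id)
  }
  v <- if (weighting == "sequence") {
    colMeans(m)
  } else {
    lens <- nchar(seqs$residues)
    w <- if (kind == "dipeptide") lens - 1L else lens
    drop(w %*% m) / sum(w)
  }
  tibble(feature = colnames(m), value = unname(v))
}

# Coerce a composition given as named vector, tibble(feature, value), or
# matrix row into a plain numeric vector in canonical order.
as_composition_vector <- function(x, features = DIPEPTIDES, arg = "composition") {
  if (is.data.frame(x)) {
    if (!all(c("feature", "value") %in% names(x))) {
      abort(paste0("`", arg, "` data frame needs columns `feature` and `value`"),
        class = "scmseq_type_error"
      )
    }
    x <- setNames(x$value, x$feature)
  }
  x <- drop(x)
  if (!is.numeric(x) || length(x) != length(features)) {
    abort(paste0("`", arg, "` must hold ", length(features), " values"),
      class = "scmseq_type_error"
    )
  }
  if (!is.null(names(x))) {
    missing <- setdiff(features, names(x))
    if (length(missing) > 0L) {
      abort(paste0("`", arg, "` is missing entries: ", paste(head(missing, 5L), collapse = ", ")),
        class = "scmseq_type_error"
      )
    }
    x <- x[features]
  } else {
    names(x) <- features
  }
  x
}
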