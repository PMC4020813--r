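#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a tibble of
#' identifiers and residue strings. Residues are upper-cased and internal
#' whitespace is stripped. Characters outside the 20-letter standard
#' amino-acid alphabet (see [AA_ALPHABET]) are handled according to the
#' sanitization policy: by default the offending positions are dropped with a
#' warning; in strict mode any non-standard character is an error.
#'
#' Records whose residue string becomes empty after sanitization are skipped
#' with a warning (an error in strict mode). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param strict Logical; if `TRUE`, reject records containing non-standard
#'   residues instead of dropping the offending positions.
#' @return A tibble with columns `id` (character) and `residues` (character,
#'   over the 20 standard letters).
#' @seealso [write_fasta()], [load_dataset()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKVL", ">p2", "ACDEFG"), f)
#' read_fasta(f)
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "scmseq_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("could not read FASTA file ", path, ": ", conditionMessage(e)),
        class = "scmseq_io_error"
      )
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  residues <- as.character(set)
  sanitize_residues(ids, residues, strict = strict)
}

sanitize_residues <- function(ids, residues, strict = FALSE) {
  res <- toupper(gsub("[\\s*]", "", residues, perl = TRUE))
  clean <- stringr::str_remove_all(res, paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"))
  touched <- clean != res
  if (strict && any(touched)) {
    abort(
      paste0(
        "non-standard residues in record(s): ",
        paste(ids[touched], collapse = ", ")
      ),
      class = "scmseq_alphabet_error"
    )
  }
  if (any(touched)) {
    warn(paste0(
      "dropped non-standard residues from ", sum(touched), " record(s): ",
      paste(head(ids[touched], 5L), collapse = ", "),
      if (sum(touched) > 5L) ", ..." else ""
    ))
  }
  emptied <- !nzchar(clean)
  if (strict && any(emptied)) {
    abort(paste0("record(s) empty after sanitization: ", paste(ids[emptied], collapse = ", ")),
      class = "scmseq_alphabet_error"
    )
  }
  if (any(emptied)) {
    warn(paste0(
      "skipped ", sum(emptied), " record(s) emptied by sanitization: ",
      paste(ids[emptied], collapse = ", ")
    ))
  }
  tibble(id = ids[!emptied], residues = clean[!emptied])
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `residues`, as returned by
#'   [read_fasta()].
#' @param path Output file path.
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  check_sequences(seqs)
  set <- Biostrings::BStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(seqs)
}

#' Load a labeled two-class sequence dataset from FASTA files
#'
#' Reads a positive-class and a negative-class FASTA file (for example a set
#' of bioluminescent proteins and a set of non-bioluminescent proteins) into
#' a single labeled tibble suitable for [initial_card()], [ga_optimize()]
#' and [cross_validate()].
#'
#' @param pos_path FASTA file of positive-class sequences.
#' @param neg_path FASTA file of negative-class sequences.
#' @param name Optional dataset name stored in the `"dataset_name"` attribute.
#' @param strict Passed to [read_fasta()].
#' @return A tibble with columns `id`, `residues` and `label` (factor with
#'   levels `positive`, `negative`).
#' @export
load_dataset <- function(pos_path, neg_path, name = NULL, strict = FALSE) {
  pos <- read_fasta(pos_path, strict = strict)
  neg <- read_fasta(neg_path, strict = strict)
  if (nrow(pos) == 0L) {
    abort(paste0("positive class is empty: ", pos_path), class = "scmseq_config_error")
  }
  if (nrow(neg) == 0L) {
    abort(paste0("negative class is empty: ", neg_path), class = "scmseq_config_error")
  }
  label_dataset(pos, neg, name = name)
}

#' Combine positive and negative sequence tibbles into a labeled dataset
#'
#' @param pos,neg Tibbles with columns `id` and `residues`.
#' @inheritParams load_dataset
#' @return A labeled tibble; see [load_dataset()].
#' @export
label_dataset <- function(pos, neg, name = NULL) {
  check_sequences(pos)
  check_sequences(neg)
  shared <- intersect(pos$id, neg$id)
  if (length(shared) > 0L) {
    abort(
      paste0(
        "sequence id(s) present in both classes: ",
        paste(head(shared, 5L), collapse = ", ")
      ),
      class = "scmseq_config_error"
    )
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(pos, label = "positive"),
    dplyr::mutate(neg, label = "negative")
  )
  out$label <- factor(out$label, levels = c("positive", "negative"))
  if (!is.null(name)) attr(out, "dataset_name") <- name
  out
}

check_sequences <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("id", "residues") %in% names(seqs))) {
    abort(paste0("`", arg, "` must be a data frame with columns `id` and `residues`"),
      class = "scmseq_type_error"
    )
  }
  invisible(seqs)
}

check_labeled <- function(data, arg = "data") {
  check_sequences(data, arg)
  if (!"label" %in% names(data)) {
    abort(paste0("`", arg, "` must have a `label` column (see `load_dataset()`)"),
      class = "scmseq_type_error"
    )
  }
  lab <- as.character(data$label)
  if (!all(lab %in% c("positive", "negative"))) {
    abort("`label` must only contain \"positive\" and \"negative\"",
      class = "scmseq_type_error"
    )
  }
  invisible(data)
}
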