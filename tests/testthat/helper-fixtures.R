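# Shared fixture builders; all fixtures are generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_residues <- function(n, len, seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    }, character(1))
  })
}

make_seqs <- function(residues, ids = NULL) {
  tibble::tibble(
    id = ids %||% paste0("s", seq_along(residues)),
    residues = residues
  )
}

make_card <- function(scores, threshold = NA_real_) {
  scmseq:::new_scoring_card(stats::setNames(scores, DIPEPTIDES), threshold = threshold)
}

random_card <- function(seed = 1L, threshold = NA_real_) {
  make_card(withr::with_seed(seed, stats::runif(400, 0, 1000)), threshold)
}

constant_card <- function(value, threshold = NA_real_) {
  make_card(rep(value, 400L), threshold)
}

# tiny labeled dataset of random sequences
tiny_dataset <- function(n_per_class = 4L, len = 30L, seed = 1L) {
  label_dataset(
    make_seqs(random_residues(n_per_class, len, seed), paste0("p", seq_len(n_per_class))),
    make_seqs(random_residues(n_per_class, len, seed + 1000L), paste0("n", seq_len(n_per_class)))
  )
}

write_fasta_file <- function(residues, ids = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(
    as.vector(rbind(paste0(">", ids %||% paste0("s", seq_along(residues))), residues)),
    path
  )
  path
}

extdata <- function(name) system.file("extdata", name, package = "scmseq")
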