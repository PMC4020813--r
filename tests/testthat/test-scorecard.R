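
uniform_comp <- function() stats::setNames(rep(1 / 400, 400), DIPEPTIDES)

test_that("initial card maps composition differences affinely onto [0, 1000]", {
  pos <- uniform_comp()
  neg <- uniform_comp()
  delta <- 1e-3
  pos["AC"] <- pos["AC"] + delta
  pos["CA"] <- pos["CA"] - delta
  card <- card_from_compositions(pos, neg)
  expect_equal(unname(card$dipeptide_scores["AC"]), 1000)
  expect_equal(unname(card$dipeptide_scores["CA"]), 0)
  expect_equal(unname(card$dipeptide_scores["GG"]), 500)

  expect_warning(
    flat <- card_from_compositions(uniform_comp(), uniform_comp()),
    "equal"
  )
  expect_true(all(flat$dipeptide_scores == 500))
})

test_that("initial card matches an independent affine-map oracle entry-wise", {
  p <- withr::with_seed(5, {
    x <- stats::runif(400)
    x / sum(x)
  })
  n <- withr::with_seed(6, {
    x <- stats::runif(400)
    x / sum(x)
  })
  card <- card_from_compositions(
    stats::setNames(p, DIPEPTIDES), stats::setNames(n, DIPEPTIDES)
  )
  d <- p - n
  oracle <- 1000 * (d - min(d)) / (max(d) - min(d))
  expect_equal(unname(card$dipeptide_scores), oracle, tolerance = 1e-12)
  expect_equal(min(card$dipeptide_scores), 0)
  expect_equal(max(card$dipeptide_scores), 1000)

  # affine invariance: percent-scale compositions give the same card
  scaled <- card_from_compositions(
    stats::setNames(100 * p, DIPEPTIDES), stats::setNames(100 * n, DIPEPTIDES)
  )
  expect_equal(scaled$dipeptide_scores, card$dipeptide_scores, tolerance = 1e-9)
})

test_that("amino-acid scores average the 40 pair scores, homo-pair counted twice", {
  expect_equal(unname(constant_card(321)$aa_scores), rep(321, 20), tolerance = 1e-12)

  one_hot <- rep(0, 400)
  names(one_hot) <- DIPEPTIDES
  one_hot["GC"] <- 1000
  aa <- derive_aa_scores(one_hot)
  expect_equal(unname(aa["G"]), 25)
  expect_equal(unname(aa["C"]), 25)
  expect_equal(sum(aa), 50)

  # brute-force 40-term sum per residue on a random card
  card <- random_card(seed = 7)
  s <- card$dipeptide_scores
  for (o in c("A", "M", "Y")) {
    terms <- c(s[paste0(o, AA_ALPHABET)], s[paste0(AA_ALPHABET, o)])
    expect_equal(unname(card$aa_scores[o]), sum(terms) / 40, tolerance = 1e-12)
  }
})

test_that("sequence scores are the composition-weighted mean of card scores", {
  expect_equal(
    score_sequences(make_seqs("MKVLYACDE"), constant_card(500))$score, 500
  )

  card <- constant_card(0)
  card$dipeptide_scores["AC"] <- 900
  card$dipeptide_scores["CA"] <- 300
  card$aa_scores <- derive_aa_scores(card$dipeptide_scores)
  expect_equal(
    score_sequences(make_seqs("ACAC"), card)$score,
    (2 / 3) * 900 + (1 / 3) * 300
  )

  # brute-force dot product oracle; bounds; composition-identity invariance
  rc <- random_card(seed = 3)
  for (seed in 1:3) {
    res <- random_residues(1, 70, seed = seed)
    chars <- strsplit(res, "")[[1]]
    pairs <- paste0(chars[-length(chars)], chars[-1])
    oracle <- sum(vapply(
      DIPEPTIDES,
      function(p) sum(pairs == p) * rc$dipeptide_scores[p],
      numeric(1)
    )) / (length(chars) - 1)
    got <- score_sequences(make_seqs(res), rc)$score
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_gte(got, min(rc$dipeptide_scores))
    expect_lte(got, max(rc$dipeptide_scores))
  }
  # two sequences with identical dipeptide composition score identically
  expect_equal(
    score_sequences(make_seqs("ACACA"), rc)$score,
    score_sequences(make_seqs("CACAC"), rc)$score,
    tolerance = 1e-9
  )
})

test_that("threshold choice maximizes training accuracy, smallest tie wins", {
  thr <- choose_threshold(c(700, 700), c(300, 300))
  expect_equal(as.numeric(thr), 500)
  expect_equal(attr(thr, "accuracy"), 1)

  tie <- choose_threshold(c(400, 400), c(400, 400))
  expect_equal(as.numeric(tie), 399) # one unit below the minimum
  expect_equal(attr(tie, "accuracy"), 0.5)

  # brute-force scan oracle on interleaved scores
  pos <- c(9.1, 7.3, 6.2, 5.8, 3.4)
  neg <- c(8.0, 6.5, 5.1, 2.2, 1.7)
  grid <- sort(c(seq(0, 11, by = 0.01), pos, neg))
  acc <- vapply(grid, function(t) (sum(pos > t) + sum(neg <= t)) / 10, numeric(1))
  got <- choose_threshold(pos, neg)
  expect_equal(attr(got, "accuracy"), max(acc))
  expect_equal(
    (sum(pos > as.numeric(got)) + sum(neg <= as.numeric(got))) / 10,
    max(acc)
  )
  expect_error(choose_threshold(numeric(0), neg), class = "scmseq_eval_error")
})

test_that("classification is strict: scores equal to the threshold are negative", {
  card <- constant_card(500, threshold = 500)
  pred <- classify(make_seqs(c("MKVL", "ACDE")), card)
  expect_true(all(pred$predicted == "negative"))

  card2 <- random_card(seed = 2, threshold = 200)
  pred2 <- classify(make_seqs(random_residues(6, 40, 8)), card2)
  expect_equal(as.character(pred2$predicted), ifelse(pred2$score > 200, "positive", "negative"))

  expect_error(classify(make_seqs("MKVL"), random_card()), class = "scmseq_usage_error")
})

test_that("cards round-trip through TSV at full precision", {
  card <- random_card(seed = 10, threshold = 439.6271234)
  card$metadata <- list(dataset = "toy", note = "unit test")
  path <- withr::local_tempfile(fileext = ".tsv")
  save_card(card, path)
  back <- load_card(path)
  expect_identical(back$dipeptide_scores, card$dipeptide_scores)
  expect_identical(back$threshold, card$threshold)
  expect_equal(back$metadata$dataset, "toy")
  expect_equal(back$aa_scores, card$aa_scores)
})

test_that("card loading rejects missing pairs, bad rows, and out-of-range scores", {
  card <- random_card(seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  save_card(card, path)
  lines <- readLines(path)

  drop_one <- withr::local_tempfile()
  writeLines(lines[-grep("^GC\t", lines)], drop_one)
  expect_error(load_card(drop_one), "GC", class = "scmseq_io_error")

  out_of_range <- withr::local_tempfile()
  bad <- sub("^AC\t.*$", "AC\t1001", lines)
  writeLines(bad, out_of_range)
  expect_error(load_card(out_of_range), "out of", class = "scmseq_io_error")

  malformed <- withr::local_tempfile()
  writeLines(sub("^AD\t.*$", "AD\tnot-a-number", lines), malformed)
  expect_error(load_card(malformed), "malformed", class = "scmseq_io_error")
})

test_that("tidy and glance expose card scores and summary", {
  card <- random_card(seed = 1, threshold = 400)
  td <- tidy(card)
  expect_equal(nrow(td), 400L)
  expect_equal(td$dipeptide, DIPEPTIDES)
  expect_equal(paste0(td$first, td$second), td$dipeptide)
  gl <- glance(card)
  expect_equal(gl$threshold, 400)
  expect_equal(gl$n_dipeptides, 400L)
})
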