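
test_that("pearson handles exact and degenerate cases", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson(x, x), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  expect_equal(pearson(x, 3 + 2 * x), 1.0)
  expect_error(pearson(x, rep(1, 5)), class = "scmseq_undefined_cor")
  expect_error(pearson(x, x[1:3]), class = "scmseq_eval_error")
})

test_that("bioluminescent-protein composition correlates with membrane proteins", {
  sub <- read_property_table(extdata("subcellular_composition.tsv"))
  expect_equal(pearson(sub$comp_blp, sub$comp_membrane), 0.921, tolerance = 0.005)
  expect_equal(pearson(sub$comp_blp, sub$comp_nuclear), 0.766, tolerance = 0.005)
})

test_that("property scan ranks by absolute correlation and matches a direct oracle", {
  props <- read_property_table(extdata("aa_properties.tsv"))
  blp <- read_property_table(extdata("blp_aa_reference.tsv"))
  scores <- stats::setNames(blp$score, blp$residue)

  scan <- property_scan(props, scores)
  expect_equal(scan$rank, seq_len(nrow(scan)))
  expect_false(is.unsorted(rev(abs(scan$r))))
  for (p in scan$property) {
    expect_equal(
      scan$r[scan$property == p],
      stats::cor(scores, stats::setNames(props[[p]], props$residue)[names(scores)]),
      tolerance = 1e-12
    )
  }

  # a property equal to the scores ranks first with r = 1
  props$self <- blp$score
  scan2 <- property_scan(props, scores)
  expect_equal(scan2$property[1], "self")
  expect_equal(scan2$r[1], 1.0)

  # constant columns are excluded from ranking with a warning
  props$flat <- 1
  expect_warning(scan3 <- property_scan(props, scores), "flat")
  expect_true(is.na(scan3$r[scan3$property == "flat"]))
  expect_true(is.na(scan3$rank[scan3$property == "flat"]))
})

test_that("composition report pairs scores with percent compositions", {
  spec <- synthetic_spec(n_pos = 10, n_neg = 10, length_range = c(60, 60), seed = 2)
  data <- generate_dataset(spec)
  card <- initial_card(data)
  rep <- composition_report(data, card)
  expect_equal(nrow(rep), 20L)
  expect_equal(sum(rep$comp_pos), 100, tolerance = 1e-9)
  expect_equal(sum(rep$comp_neg), 100, tolerance = 1e-9)
  expect_equal(rep$diff, rep$comp_pos - rep$comp_neg, tolerance = 1e-9)
  expect_equal(unname(rep$rank[which.max(rep$score)]), 1L)
  r <- attr(rep, "correlations")
  expect_true(all(c("score_vs_pos", "score_vs_neg", "score_vs_diff") %in% names(r)))

  # identical classes: zero differences, undefined score-vs-diff correlation
  pos <- data[data$label == "positive", c("id", "residues")]
  mirrored <- label_dataset(
    pos, dplyr::mutate(pos, id = paste0("m_", .data$id))
  )
  rep0 <- composition_report(mirrored, card)
  expect_true(all(abs(rep0$diff) < 1e-12))
  expect_true(is.na(attr(rep0, "correlations")["score_vs_diff"]))
})

test_that("positional profiles track dipeptide scores along the sequence", {
  card <- random_card(seed = 12)
  p2 <- positional_profile(make_seqs("GC"), card)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$score, unname(card$dipeptide_scores["GC"]))

  flat <- positional_profile(make_seqs("MKVLYACDE"), constant_card(777))
  expect_true(all(flat$score == 777))

  res <- random_residues(1, 40, seed = 13)
  prof <- positional_profile(make_seqs(res), card, window = 5)
  raw <- prof$score
  manual <- vapply(seq_along(raw), function(i) {
    mean(raw[max(1, i - 2):min(length(raw), i + 2)])
  }, numeric(1))
  expect_equal(prof$smoothed, manual, tolerance = 1e-12)

  expect_error(positional_profile(make_seqs("A"), card), class = "scmseq_feature_error")
  expect_error(positional_profile(make_seqs("ACDE"), card, window = 2), class = "scmseq_config_error")
})

test_that("score histograms conserve counts over half-open bins", {
  one <- score_histogram(500, bin_width = 100)
  expect_equal(one$count[one$bin_lo == 500], 1L)
  expect_equal(sum(one$count), 1L)

  withr::with_seed(3, scores <- stats::runif(250, 0, 1000))
  h <- score_histogram(scores, bin_width = 50)
  expect_equal(sum(h$count), 250L)

  grid <- seq(0, 1000, by = 10) # 1000 lands in the final closed bin
  hg <- score_histogram(grid, bin_width = 100)
  oracle <- vapply(hg$bin_lo, function(lo) {
    hi <- lo + 100
    sum(grid >= lo & (grid < hi | (hi >= 1000 & grid == 1000)))
  }, numeric(1))
  expect_equal(hg$count, as.integer(oracle))
  expect_error(score_histogram(numeric(0)), class = "scmseq_eval_error")
  expect_error(score_histogram(500, bin_width = 0), class = "scmseq_config_error")
})

test_that("the heat-map matrix indexes first residue by row and flattens row-major", {
  card <- random_card(seed = 14)
  m <- card_heatmap_matrix(card)
  expect_equal(dim(m), c(20L, 20L))
  expect_equal(m["G", "C"], unname(card$dipeptide_scores["GC"]))
  expect_equal(as.vector(t(m)), unname(card$dipeptide_scores))
  expect_true(all(card_heatmap_matrix(constant_card(5)) == 5))
})

test_that("plot builders return ggplot objects", {
  card <- random_card(seed = 15, threshold = 500)
  expect_s3_class(autoplot(card), "ggplot")
  data <- tiny_dataset(3, len = 30)
  expect_s3_class(plot_score_distribution(score_sequences(data, card), card), "ggplot")
  expect_s3_class(plot_positional_profile(positional_profile(make_seqs("MKVLYACDE"), card, 3)), "ggplot")
})
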