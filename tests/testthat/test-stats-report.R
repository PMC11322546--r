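test_that("normalization divides by the per-experiment reference median", {
  rec <- data.frame(
    genotype = rep(c("wt", "mut"), each = 3, times = 2),
    timepoint_d = 14,
    height_um = c(90, 100, 110, 75, 80, 85,     # experiment A
                  45, 50, 55, 40, 41, 42),      # experiment B (half scale)
    experiment_id = rep(c("A", "B"), each = 6))
  out <- normalizeByReference(rec, "wt", "height_um")
  # hand-computed: medians 100 (A) and 50 (B)
  expect_equal(out$reference_median[out$experiment_id == "A"][1L], 100)
  expect_equal(out$reference_median[out$experiment_id == "B"][1L], 50)
  expect_equal(out$normalized[out$genotype == "mut" &
                                out$experiment_id == "A"],
               c(75, 80, 85) / 100)
  expect_equal(out$normalized[out$genotype == "mut" &
                                out$experiment_id == "B"],
               c(40, 41, 42) / 50)
  # the reference genotype always normalises to median 1 per experiment
  for (e in c("A", "B"))
    expect_equal(median(out$normalized[out$genotype == "wt" &
                                         out$experiment_id == e]), 1)
  expect_error(normalizeByReference(rec, "absent", "height_um"),
               "lacks records")
})

test_that("the rank-sum test matches the exact enumeration oracle", {
  res <- compareGenotypes(mkRecords(c(1, 2, 3), c(10, 11, 12)),
                          "height_um", 14)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$p_value, enumRankSumP(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)
  expect_false(res$significant)
  # a few random small-sample cases against the oracle
  set.seed(7)
  for (i in 1:5) {
    x <- round(rnorm(3, 10), 2); y <- round(rnorm(3, 11), 2)
    res <- compareGenotypes(mkRecords(x, y), "height_um", 14)
    expect_equal(res$p_value, enumRankSumP(x, y), tolerance = 1e-12)
  }
})

test_that("identical samples give the maximal attainable p", {
  res <- compareGenotypes(mkRecords(c(5, 6, 7), c(5, 6, 7)),
                          "height_um", 14)
  expect_gte(res$p_value, 0.95)
})

test_that("rank-test p-values are invariant to monotone transforms", {
  set.seed(12)
  x <- rlnorm(8); y <- rlnorm(8, meanlog = 0.6)
  p0 <- compareGenotypes(mkRecords(x, y), "height_um", 14)$p_value
  for (f in list(log, sqrt, function(v) v^3 + 1)) {
    pf <- compareGenotypes(mkRecords(f(x), f(y)), "height_um", 14)$p_value
    expect_equal(pf, p0, tolerance = 1e-12)
  }
})

test_that("compact letters obey the Tukey p matrix invariants", {
  mkTc <- function(shift, seed) {
    set.seed(seed)
    data.frame(
      genotype = "wt",
      timepoint_d = rep(c(10, 12, 14), each = 8),
      height_um = c(rnorm(8, 50, 3), rnorm(8, 50 + shift, 3),
                    rnorm(8, 50, 3)),
      experiment_id = "e1")
  }
  # strongly shifted middle timepoint gets a unique letter
  ld <- compareTimepoints(mkTc(30, 5), "height_um", "wt")
  l10 <- strsplit(ld$letters[["10"]], "")[[1L]]
  l12 <- strsplit(ld$letters[["12"]], "")[[1L]]
  expect_length(intersect(l10, l12), 0L)
  expect_lt(ld$anova$p_value, 1e-6)
  # letter/shared-p consistency over random null and shifted cases
  for (s in 1:6) {
    ld <- compareTimepoints(mkTc(sample(c(0, 4, 30), 1L), 100 + s),
                            "height_um", "wt")
    ltr <- lapply(ld$letters, function(x) strsplit(x, "")[[1L]])
    tps <- names(ld$letters)
    for (a in seq_along(tps)) for (b in seq_along(tps)) {
      if (a >= b) next
      shared <- length(intersect(ltr[[a]], ltr[[b]])) > 0L
      expect_equal(shared, ld$tukey_p[tps[a], tps[b]] >= 0.05)
    }
  }
})

test_that("two-timepoint letters agree with the pairwise Tukey test", {
  set.seed(3)
  rec <- data.frame(
    genotype = "wt", timepoint_d = rep(c(10, 14), each = 10),
    height_um = c(rnorm(10, 50, 4), rnorm(10, 70, 4)),
    experiment_id = "e1")
  ld <- compareTimepoints(rec, "height_um", "wt")
  distinct <- ld$tukey_p["10", "14"] < 0.05
  shared <- length(intersect(strsplit(ld$letters[["10"]], "")[[1L]],
                             strsplit(ld$letters[["14"]], "")[[1L]])) > 0L
  expect_equal(shared, !distinct)
})

test_that("letters match multcomp's display on a worked case", {
  skip_if_not_installed("multcomp")
  set.seed(21)
  rec <- data.frame(
    genotype = "wt",
    timepoint_d = rep(c(10, 12, 14, 17), each = 8),
    height_um = c(rnorm(8, 50, 4), rnorm(8, 55, 4), rnorm(8, 80, 4),
                  rnorm(8, 82, 4)),
    experiment_id = "e1")
  ld <- compareTimepoints(rec, "height_um", "wt")
  rec$tp <- factor(rec$timepoint_d)
  glt <- multcomp::glht(stats::aov(height_um ~ tp, data = rec),
                        linfct = multcomp::mcp(tp = "Tukey"))
  cl <- multcomp::cld(glt)$mcletters$Letters
  # same partition: pairs share a letter in ours iff they do in multcomp
  tps <- names(ld$letters)
  for (a in seq_along(tps)) for (b in seq_along(tps)) {
    if (a >= b) next
    oursShared <- length(intersect(
      strsplit(ld$letters[[a]], "")[[1L]],
      strsplit(ld$letters[[b]], "")[[1L]])) > 0L
    theirShared <- length(intersect(
      strsplit(cl[[tps[a]]], "")[[1L]],
      strsplit(cl[[tps[b]]], "")[[1L]])) > 0L
    expect_equal(oursShared, theirShared)
  }
})

test_that("ANOVA preconditions are enforced", {
  rec <- data.frame(genotype = "wt", timepoint_d = c(10, 10, 12),
                    height_um = c(50, 51, 60), experiment_id = "e1")
  expect_error(compareTimepoints(rec, "height_um", "wt"), "n >= 2")
  one <- rec[rec$timepoint_d == 10, ]
  expect_error(compareTimepoints(one, "height_um", "wt"),
               "at least two timepoints")
})

test_that("fold changes are ratios of timepoint medians", {
  rec <- data.frame(
    genotype = "wt", timepoint_d = rep(c(10, 14), each = 3),
    height_um = c(55, 60, 65, 110, 120, 130), experiment_id = "e1")
  expect_equal(foldChange(rec, "height_um", 10, 14), 2)
  expect_equal(foldChange(rec, "height_um", 10, 10), 1)
  z <- rec; z$height_um[z$timepoint_d == 10] <- 0
  expect_error(foldChange(z, "height_um", 10, 14), "zero median")
  expect_error(foldChange(rec, "height_um", 10, 99), "populated")
})
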