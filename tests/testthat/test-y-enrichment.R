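test_that("expected focal proportion follows chromosome lengths", {
  p <- expected_proportion()
  expect_equal(p, 57200 / 3088200)
  expect_equal(sprintf("%.2f%%", 100 * p), "1.85%")
  expect_equal(expected_proportion(default_chrom_lengths(), "X"),
               156040 / 3088200)
  toy <- list(lengths = c(only = 500), total = 500)
  expect_equal(expected_proportion(toy, "only"), 1)
  expect_error(expected_proportion(default_chrom_lengths(), "Z"),
               "no length")
})

test_that("exact binomial focal test matches closed forms", {
  p0 <- 57200 / 3088200
  copies <- toy_copies("Y", seq(0, 900, by = 100), seq(50, 950, by = 100))
  rec <- binomial_focal_test(copies, "SF1", expected = p0, focal = "Y")
  expect_equal(rec$n_total, 10L)
  expect_equal(rec$n_focal, 10L)
  expect_equal(rec$p, p0^10, tolerance = 1e-9)

  none <- toy_copies("chr1", seq(0, 9900, by = 100), seq(50, 9950, by = 100))
  rec0 <- binomial_focal_test(none, "SF1", expected = p0, focal = "Y")
  expect_equal(rec0$n_focal, 0L)
  expect_equal(rec0$p, oracle_minlike(0, 100, p0), tolerance = 1e-12)

  # observed proportion exactly at the expectation sits at the mode
  mode_copies <- toy_copies(c("Y", rep("chr1", 53)),
                            seq(0, 5300, by = 100), seq(50, 5350, by = 100))
  recm <- binomial_focal_test(mode_copies, "SF1", expected = 1 / 54,
                              focal = "Y")
  expect_equal(recm$p, 1)
  expect_error(binomial_focal_test(copies, "SFX"), "no copies")
})

test_that("minlike p equals enumeration oracle on sampled (k, n) pairs", {
  set.seed(61)
  p0 <- 0.0185
  for (i in 1:40) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    expect_equal(binomial_focal_test(
      toy_copies(c(rep("Y", k), rep("chr1", n - k)),
                 seq(0, by = 100, length.out = n),
                 seq(50, by = 100, length.out = n)),
      "SF1", expected = p0, focal = "Y")$p,
      oracle_minlike(k, n, p0), tolerance = 1e-9)
  }
})

test_that("doubling alternative is available and bounded by 1", {
  p_min <- binomial_focal_test(
    toy_copies(c("Y", rep("chr1", 9)), 1:10 * 100, 1:10 * 100 + 50),
    "SF1", expected = 0.5, focal = "Y", method = "doubling")$p
  lo <- pbinom(1, 10, 0.5); hi <- pbinom(0, 10, 0.5, lower.tail = FALSE)
  expect_equal(p_min, min(1, 2 * min(lo, hi)))
})

test_that("classification recovers a planted enrichment and partitions cleanly", {
  set.seed(62)
  lens <- list(lengths = c(chr1 = 9800, Y = 200, X = 1000), total = 11000)
  mk <- function(subfam, chroms) {
    df <- toy_copies(chroms, seq(0, by = 10, length.out = length(chroms)),
                     seq(5, by = 10, length.out = length(chroms)))
    df$copy_id <- paste0(subfam, "_", seq_along(chroms))
    df$subfamily <- subfam
    df
  }
  planted <- mk("HOT", sample(c(rep("Y", 50), rep("chr1", 50))))
  cold <- mk("COLD", rep("chr1", 200))           # no Y, no X copies
  xonly <- mk("XONLY", c(rep("X", 5), rep("chr1", 95)))
  copies <- rbind(planted, cold, xonly)
  rec <- classify_y_enrichment(copies, lens, focal = "Y", other = "X")
  groups <- attr(rec, "groups")
  expect_equal(rec$status[rec$subfamily == "HOT"], "enriched")
  expect_true("COLD" %in% groups$no_focal_copies)
  expect_true("COLD" %in% groups$no_focal_no_other)
  expect_true("XONLY" %in% groups$no_focal_copies)
  expect_false("XONLY" %in% groups$no_other_copies)
  # the three test-based groups are a disjoint cover of all tested
  expect_setequal(c(groups$enriched, groups$depleted, groups$neither),
                  rec$subfamily)
  expect_length(intersect(groups$enriched, groups$neither), 0L)
})

test_that("copies proportional to length give no calls (null calibration)", {
  set.seed(63)
  lens <- list(lengths = c(chr1 = 9800, Y = 200), total = 10000)
  chroms <- replicate(30, sample(c("chr1", "Y"), 100, replace = TRUE,
                                 prob = c(0.98, 0.02)), simplify = FALSE)
  copies <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    df <- toy_copies(chroms[[i]], seq(0, by = 10, length.out = 100),
                     seq(5, by = 10, length.out = 100))
    df$copy_id <- sprintf("n%02d_%03d", i, 1:100)
    df$subfamily <- sprintf("N%02d", i)
    df
  }))
  rec <- classify_y_enrichment(copies, lens, focal = "Y", other = "X")
  expect_lte(sum(rec$status != "neither"), 1L)
})

test_that("upper-tail mass shrinks as observed k grows on the enriched side", {
  p0 <- 0.02
  tails <- vapply(5:15, function(k)
    pbinom(k - 1, 100, p0, lower.tail = FALSE), numeric(1))
  rec_p <- vapply(5:15, function(k) oracle_minlike(k, 100, p0), numeric(1))
  expect_true(all(diff(tails) < 0))
  expect_true(all(diff(rec_p) < 1e-12))
})

test_that("enriched-share test reproduces the reported top-subfamily excess", {
  rec <- data.frame(subfamily = sprintf("S%03d", 1:200),
                    status = c(rep("enriched", 18), rep("neither", 182)))
  sel <- c(sprintf("S%03d", 1:8), sprintf("S%03d", 101:107))  # 8 of 15
  res <- enriched_share_test(sel, rec, background_share = 0.0907)
  expect_equal(res$n_enriched, 8L)
  expect_lt(res$p, 1e-3)
  # closed-form one-sided upper tail for 3 of 7
  res37 <- enriched_share_test(
    c(sprintf("S%03d", 1:3), sprintf("S%03d", 120:123)), rec,
    background_share = 0.0907)
  expect_equal(res37$p,
               sum(dbinom(3:7, 7, 0.0907)), tolerance = 1e-12)
  # share equal to background is unremarkable
  even <- enriched_share_test(c("S001", sprintf("S%03d", 110:118)), rec,
                              background_share = 0.10)
  expect_gt(even$p, 0.5)
  expect_error(enriched_share_test(character(), rec), "empty")
})
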