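de_sheet <- function(n_per = 6L, batch = TRUE) {
  n <- 2L * n_per
  df <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                   karyotype = rep(c("XX", "XY"), each = n_per),
                   stringsAsFactors = FALSE)
  if (batch) df$batch <- rep(c("b1", "b2"), n_per)
  df
}

unit_sf <- function(sheet) setNames(rep(1, nrow(sheet)), sheet$sample_id)

test_that("planted two-fold change is recovered with honest error bars", {
  set.seed(51)
  sheet <- de_sheet()
  mu <- ifelse(sheet$karyotype == "XY", 200, 100)
  m <- rbind(
    t(sapply(1:20, function(i) rnbinom(12, mu = mu, size = 100))),
    t(sapply(1:40, function(i) rnbinom(12, mu = 100, size = 100))))
  dimnames(m) <- list(sprintf("f%02d", 1:60), sheet$sample_id)
  res <- suppressMessages(fit_nb_de(make_cm(m, "te_subfamily"),
                                    unit_sf(sheet), sheet,
                                    design_spec("karyotype", "batch")))
  w <- res[res$test == "wald", ]
  expect_equal(mean(w$log2fc[1:20]), 1.0, tolerance = 0.15)
  expect_gt(mean(w$padj[1:20] < 0.05), 0.8)        # sensitivity
  expect_lt(mean(w$padj[21:60] < 0.05), 0.1)       # null false positives
  lr <- res[res$test == "lr", ]
  expect_gt(mean(lr$padj[1:20] < 0.05), 0.8)
})

test_that("contrasts are antisymmetric under reference swap", {
  set.seed(52)
  sheet <- de_sheet(4L, batch = FALSE)
  m <- matrix(rnbinom(10 * 8, mu = 100, size = 20), 10, 8,
              dimnames = list(sprintf("f%d", 1:10), sheet$sample_id))
  cm <- make_cm(m, "te_subfamily")
  a <- suppressMessages(fit_nb_de(cm, unit_sf(sheet), sheet,
                                  design_spec("karyotype", character(), "XX")))
  b <- suppressMessages(fit_nb_de(cm, unit_sf(sheet), sheet,
                                  design_spec("karyotype", character(), "XY")))
  wa <- a[a$test == "wald", ]; wb <- b[b$test == "wald", ]
  expect_equal(wa$contrast[1], "XY vs XX")
  expect_equal(wb$contrast[1], "XX vs XY")
  expect_equal(wa$log2fc, -wb$log2fc, tolerance = 1e-6)
  expect_equal(wa$p, wb$p, tolerance = 1e-6)
})

test_that("a constant feature gives log2fc 0 and p near 1", {
  sheet <- de_sheet(3L, batch = FALSE)
  m <- matrix(100L, 1, 6, dimnames = list("flat", sheet$sample_id))
  res <- suppressMessages(fit_nb_de(make_cm(m, "te_subfamily"),
                                    unit_sf(sheet), sheet,
                                    design_spec("karyotype", character())))
  w <- res[res$test == "wald", ]
  expect_equal(w$log2fc, 0, tolerance = 1e-8)
  expect_gt(w$p, 0.99)
})

test_that("low-count features are excluded from testing", {
  sheet <- de_sheet(3L, batch = FALSE)
  m <- rbind(lo = rep(1L, 6), hi = rep(50L, 6))
  colnames(m) <- sheet$sample_id
  res <- suppressMessages(fit_nb_de(make_cm(m, "te_subfamily"),
                                    unit_sf(sheet), sheet,
                                    design_spec("karyotype", character())))
  expect_false("lo" %in% res$feature_id)
  expect_true("hi" %in% res$feature_id)
})

test_that("size-factor offsets remove pure depth differences", {
  set.seed(53)
  sheet <- de_sheet(4L, batch = FALSE)
  base <- matrix(rnbinom(30 * 8, mu = 100, size = 50), 30, 8,
                 dimnames = list(sprintf("f%d", 1:30), sheet$sample_id))
  depth <- ifelse(sheet$karyotype == "XY", 3, 1)  # depth confounded w/ group
  m <- round(sweep(base, 2, depth, "*"))
  sf <- setNames(depth, sheet$sample_id)
  res <- suppressMessages(fit_nb_de(make_cm(m, "te_subfamily"), sf, sheet,
                                    design_spec("karyotype", character())))
  w <- res[res$test == "wald", ]
  expect_equal(mean(w$log2fc), 0, tolerance = 0.1)
  expect_lt(mean(w$p < 0.05), 0.2)
})

test_that("BH adjustment: hand example, passthrough, oracle equivalence", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(54)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("median log2FC test: symmetry null, one-sided mass, short input", {
  sym <- rep(c(-0.1, 0.1), 10)
  res <- median_log2fc_test(sym)
  expect_equal(res$median, 0)
  expect_equal(res$p, 1)

  shift <- rep(0.05, 20)
  res2 <- median_log2fc_test(shift)
  expect_equal(res2$median, 0.05)
  # all 20 signs positive: exact two-sided signed-rank tail 2 * 2^-20
  expect_lt(res2$p, 1e-3)

  expect_error(median_log2fc_test(c(0.1, 0.2, 0.3, 0.4)), "at least 5")
})

test_that("top-feature ranking is deterministic with documented tie rules", {
  res <- data.frame(
    feature_id = c("b", "a", "c", "d"),
    contrast = "omnibus",
    log2fc = NA_real_,
    p = c(0.001, 0.001, 0.002, 0.5),
    padj = c(0.01, 0.01, 0.01, 0.5),
    test = "lr")
  top <- rank_top_features(res, 3)
  expect_equal(top$feature_id, c("a", "b", "c"))
  expect_equal(nrow(rank_top_features(res, 99)), 4L)

  set.seed(55)
  sheet <- de_sheet()
  mu <- ifelse(sheet$karyotype == "XY", 400, 100)
  m <- rbind(
    t(sapply(1:3, function(i) rnbinom(12, mu = mu, size = 100))),
    t(sapply(1:30, function(i) rnbinom(12, mu = 100, size = 100))))
  dimnames(m) <- list(c(sprintf("planted%d", 1:3), sprintf("null%02d", 1:30)),
                      sheet$sample_id)
  fit <- suppressMessages(fit_nb_de(make_cm(m, "te_subfamily"),
                                    unit_sf(sheet), sheet,
                                    design_spec("karyotype", "batch")))
  top3 <- rank_top_features(fit, 3, "lr")
  expect_setequal(top3$feature_id, sprintf("planted%d", 1:3))
})
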