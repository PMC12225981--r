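norm_toy <- function() {
  # 2 genes + 5 subfamilies x 3 samples, already "normalized"
  m <- rbind(g1 = c(500, 400, 300), g2 = c(400, 500, 600),
             A = c(40, 10, 20), B = c(30, 20, 10),
             C = c(10, 30, 30), D = c(15, 25, 20), E = c(5, 15, 20))
  colnames(m) <- c("s1", "s2", "s3")
  count_matrix(m, feature_kind = c("gene", "gene", rep("te_subfamily", 5)),
               normalized = TRUE)
}

test_that("global TE proportion: arithmetic, subsets, shared denominator", {
  nm <- norm_toy()
  all_prop <- global_te_proportion(nm)
  expect_equal(unname(all_prop["s1"]), 100 / 1000)
  expect_equal(unname(global_te_proportion(nm, character())), rep(0, 3),
               ignore_attr = TRUE)
  # LTR = {A, B}; denominator still genes + all TE subfamilies
  ltr <- global_te_proportion(nm, c("A", "B"))
  expect_equal(unname(ltr), c(70 / 1000, 30 / 1000, 30 / 1000))
})

test_that("singleton-subset proportions sum to the ALL proportion", {
  nm <- norm_toy()
  singles <- sapply(c("A", "B", "C", "D", "E"), function(s)
    global_te_proportion(nm, s))
  expect_equal(rowSums(singles), global_te_proportion(nm))
})

test_that("TE subsets are built from lineage plus name-prefix rules", {
  lineage <- data.frame(
    subfamily = c("HERVK9-int", "AluSx", "AluYb8", "L1HS", "SVA_D", "MER1"),
    class = c("LTR", "SINE", "SINE", "LINE", "SVA", "DNA"))
  subsets <- build_te_subsets(lineage)
  expect_setequal(subsets$ALL, lineage$subfamily)
  expect_equal(subsets$SINE, c("AluSx", "AluYb8"))
  expect_equal(subsets$HERVK, "HERVK9-int")
  expect_equal(subsets$AluY, "AluYb8")
  expect_equal(subsets$L1, "L1HS")
})

test_that("pairwise rank-sum test: exact small-sample branch and symmetry", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  res <- pairwise_group_test(v, g)
  expect_equal(res$p, 0.1)           # 2/20 labelings as extreme
  expect_equal(res$method, "exact")

  same <- pairwise_group_test(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(same$p, 1)

  three <- pairwise_group_test(c(v, 7, 8), c(g, "c", "c"))
  expect_equal(nrow(three), 3L)

  flip <- pairwise_group_test(v, rep(c("b", "a"), each = 3))
  expect_equal(flip$p, res$p)
})

test_that("exact rank-sum branch equals complete labeling enumeration (n+m <= 10)", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(seq_len(50), n + m)   # distinct values: no ties
    g <- rep(c("a", "b"), c(n, m))
    res <- pairwise_group_test(v, g)
    expect_equal(res$p, oracle_ranksum(v[g == "a"], v[g == "b"]),
                 tolerance = 1e-12)
  }
})

test_that("omnibus Kruskal-Wallis: degenerate, power, null calibration", {
  expect_message(p_deg <- multi_group_test(rep(1, 9), rep(c("a", "b", "c"), 3)),
                 "degenerate")
  expect_equal(p_deg, 1)

  set.seed(42)
  shifted <- c(rnorm(20), rnorm(20) + 3)
  expect_lt(multi_group_test(shifted, rep(c("a", "b"), each = 20)), 1e-3)

  reps <- 500
  hits <- vapply(seq_len(reps), function(i) {
    v <- rnorm(24)
    multi_group_test(v, rep(c("a", "b", "c"), each = 8)) < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.08)
})

test_that("sex effect adjusted on age group: recovery and design collapse", {
  set.seed(43)
  n <- 80
  sheet <- data.frame(sex = rep(c("female", "male"), each = n / 2),
                      age_group = sample(c("[20-30]", "]30-40]", "]40-50]"),
                                         n, replace = TRUE))
  age_eff <- c("[20-30]" = 0, "]30-40]" = 0.3, "]40-50]" = 0.6)
  v <- age_eff[sheet$age_group] + (sheet$sex == "male") * 1.0 +
    rnorm(n, 0, 0.1)
  fit <- adjusted_sex_effect_test(v, sheet)
  expect_equal(fit$estimate, 1.0, tolerance = 0.05)
  expect_lt(fit$p, 1e-6)

  flat <- sheet; flat$age_group <- "[20-30]"
  v2 <- (flat$sex == "male") * 0.5 + rnorm(n, 0, 0.3)
  fit2 <- adjusted_sex_effect_test(v2, flat)
  tt <- t.test(v2[flat$sex == "male"], v2[flat$sex == "female"],
               var.equal = TRUE)
  expect_equal(fit2$p, tt$p.value, tolerance = 1e-12)
})

test_that("sex-effect test is calibrated under the null", {
  set.seed(44)
  reps <- 400
  sheet <- data.frame(sex = rep(c("female", "male"), each = 40),
                      age_group = rep(c("[20-30]", "]30-40]"), 40))
  hits <- vapply(seq_len(reps), function(i)
    adjusted_sex_effect_test(rnorm(80), sheet)$p < 0.05, TRUE)
  expect_gt(mean(hits), 0.025)
  expect_lt(mean(hits), 0.08)
})

test_that("aneuploidy suspects: XXY-like males flagged, females never", {
  m <- rbind(XIST = c(100, 120, 1, 110, 0),
             USP9Y = c(0, 0, 50, 40, 45),
             g1 = c(10, 10, 10, 10, 10))
  colnames(m) <- sprintf("s%d", 1:5)
  cm <- count_matrix(m, "gene", normalized = TRUE)
  sheet <- data.frame(sample_id = colnames(m),
                      karyotype = c("XX", "XX", "XY", "XY", "XY"),
                      sex = c("female", "female", "male", "male", "male"))
  flags <- flag_aneuploidy_suspects(cm, sheet)
  expect_equal(unname(flags), c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_error(flag_aneuploidy_suspects(cm, sheet, marker_x = "NOPE"),
               "marker gene absent")
})
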