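# FPKM, expressed filter, Z-scores, JS specificity, DE, KS, Pfaffl.

mini_design <- function(tissues) {
  sample_design(data.frame(
    sample = paste0(rep(tissues, each = 2), "_r", 1:2),
    tissue = rep(tissues, each = 2),
    replicate = rep(1:2, length(tissues)), stringsAsFactors = FALSE))
}

test_that("fpkm implements the unit-scale formula", {
  counts <- matrix(c(50, 0), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  counts["b", 1] <- 1e6 - 50   # library size exactly 1e6
  fk <- fpkm(counts, c(a = 1000, b = 2000))
  expect_equal(fk["a", 1], 50)
  expect_equal(fpkm(matrix(c(0, 10), 2, 1,
                           dimnames = list(c("a", "b"), "s")),
                    c(a = 500, b = 500))["a", 1], 0)
  expect_error(fpkm(matrix(0, 1, 1, dimnames = list("a", "s")),
                    c(a = 100)), "library size")
})

test_that("the FPKM conservation identity holds on random matrices", {
  set.seed(61)
  for (k in 1:10) {
    counts <- matrix(rpois(200, 50), 20, 10,
                     dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
    len <- stats::setNames(sample(200:3000, 20), rownames(counts))
    fk <- fpkm(counts, len)
    lib <- colSums(counts)
    recon <- colSums(fk * len) * lib / 1e9
    expect_equal(recon, lib, tolerance = 1e-9)
  }
})

test_that("expressed filter needs > 2 FPKM in both replicates somewhere", {
  d <- mini_design(c("t1", "t2"))
  mk <- function(vals) matrix(vals, 1, 4,
                              dimnames = list("f", d$sample))
  expect_true(expressed_filter(mk(c(2.5, 2.1, 0, 0)), d)[["f"]])
  expect_false(expressed_filter(mk(c(2.5, 1.9, 2.5, 1.9)), d)[["f"]])
  expect_false(expressed_filter(mk(c(2.0, 2.0, 2.0, 2.0)), d)[["f"]])
})

test_that("tissue Z-scores standardise averaged profiles", {
  d <- mini_design(paste0("t", 1:4))
  m <- matrix(rep(c(0, 0, 10, 0), each = 2), 1, 8,
              dimnames = list("f", d$sample))
  z <- tissue_zscore(m, d)
  expect_equal(unname(z["f", ]), c(-0.5, -0.5, 1.5, -0.5))
  const <- matrix(5, 1, 8, dimnames = list("c", d$sample))
  expect_equal(unname(tissue_zscore(const, d)["c", ]), rep(0, 4))
  r <- tissue_zscore(matrix(runif(8), 1, 8,
                            dimnames = list("r", d$sample)), d)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(sd(r), 1, tolerance = 1e-12)
})

test_that("JS specificity hits 1 for exclusive profiles and the closed
          form for uniform ones", {
  m <- matrix(c(7, 0, 0, 0, 0), 1, 5,
              dimnames = list("x", paste0("t", 1:5)))
  js <- js_specificity(m)
  expect_identical(js$js_score, 1)
  expect_equal(js$js_tissue, "t1")
  # uniform over 2 tissues: direct divergence evaluation
  direct_jsd <- function(p, q) {
    m <- (p + q) / 2
    kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
    kl(p, m) / 2 + kl(q, m) / 2
  }
  u2 <- matrix(c(1, 1), 1, 2, dimnames = list("u", c("a", "b")))
  want <- 1 - sqrt(direct_jsd(c(0.5, 0.5), c(1, 0)))
  expect_equal(js_specificity(u2)$js_score, want, tolerance = 1e-12)
  expect_equal(want, 0.44208, tolerance = 1e-4)
  # uniform over T tissues, checked against the direct oracle
  for (T in c(3, 5, 10, 37)) {
    uT <- matrix(1, 1, T, dimnames = list("u", paste0("t", 1:T)))
    e1 <- c(1, rep(0, T - 1))
    expect_equal(js_specificity(uT)$js_score,
                 1 - sqrt(direct_jsd(rep(1 / T, T), e1)),
                 tolerance = 1e-12)
  }
  # permutation invariance
  set.seed(62)
  p <- runif(6)
  m1 <- matrix(p, 1, 6, dimnames = list("f", paste0("t", 1:6)))
  m2 <- matrix(sample(p), 1, 6, dimnames = list("f", paste0("t", 1:6)))
  expect_equal(js_specificity(m1)$js_score, js_specificity(m2)$js_score)
  # all-zero profiles are reported missing
  z <- matrix(0, 1, 4, dimnames = list("z", paste0("t", 1:4)))
  expect_true(is.na(js_specificity(z)$js_score))
})

test_that("JS score increases as mass concentrates into one tissue", {
  alphas <- seq(0.25, 1, by = 0.05)
  scores <- vapply(alphas, function(a) {
    p <- c(a, rep((1 - a) / 3, 3))
    m <- matrix(p, 1, 4, dimnames = list("f", paste0("t", 1:4)))
    js_specificity(m)$js_score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_equal(scores[length(scores)], 1)
})

test_that("identical groups are never differentially expressed", {
  d <- mini_design(c("a_1", "a_2"))
  m <- matrix(rep(runif(20, 1, 100), each = 4), 20, 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:20), d$sample))
  de <- pairwise_de(m, d, data.frame(tissue_a = "a_1", tissue_b = "a_2"))
  expect_true(all(!de$is_de))
  expect_true(all(de$log2fc == 0))
  expect_error(pairwise_de(m, d, data.frame(tissue_a = "a_1",
                                            tissue_b = "zzz")),
               "unknown tissue")
})

test_that("successive-stage comparisons are derived from tissue names", {
  d <- mini_design(c("anther_1", "anther_2", "anther_3", "leaf"))
  cmp <- successive_stage_comparisons(d)
  expect_equal(cmp$tissue_a, c("anther_1", "anther_2"))
  expect_equal(cmp$tissue_b, c("anther_2", "anther_3"))
})

test_that("KS statistic matches hand-computed ECDF suprema", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:4, 11:14)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3)
})

test_that("Pfaffl folds follow 2^-ddCt", {
  expect_equal(unname(pfaffl_relative_expression(
    c(s1 = 20, s2 = 20), c(s1 = 18, s2 = 18), "s1")), c(1, 1))
  expect_equal(unname(pfaffl_relative_expression(
    c(s1 = 20, s2 = 19), c(s1 = 18, s2 = 18), "s1")), c(1, 2))
  # worked table: target (24, 22), reference (20, 20), calibrator s1
  expect_equal(unname(pfaffl_relative_expression(
    c(s1 = 24, s2 = 22), c(s1 = 20, s2 = 20), "s1")), c(1, 4))
})
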