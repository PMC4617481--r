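# Pearson screens, significance, and hub detection.

test_that("pearson_r handles affine, inverse and hand-computed cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  # symmetry and scale/shift invariance
  set.seed(71)
  a <- rnorm(20)
  b <- rnorm(20)
  expect_equal(pearson_r(a, b), pearson_r(b, a))
  expect_equal(pearson_r(a, b), pearson_r(3 * a - 7, 0.5 * b + 2))
  expect_true(abs(pearson_r(a, b)) <= 1)
})

test_that("cor_pvalue implements the Student-t transform", {
  expect_equal(cor_pvalue(0, 10), 1)
  expect_equal(cor_pvalue(1, 10), 0)
  expect_equal(cor_pvalue(-1, 10), 0)
  # r = -0.5, n = 37: t = 3.416, p = 0.0016
  p <- cor_pvalue(-0.5, 37)
  t <- 0.5 * sqrt(35) / sqrt(1 - 0.25)
  expect_equal(t, 3.4157, tolerance = 1e-4)
  expect_equal(p, 0.0016, tolerance = 0.03)
})

test_that("cor_pvalue agrees with a permutation p-value", {
  set.seed(72)
  x <- rnorm(12)
  y <- 0.6 * x + rnorm(12, 0, 0.8)
  r_obs <- cor(x, y)
  n_perm <- 10000
  perm <- replicate(n_perm, abs(cor(x, sample(y))))
  p_perm <- (sum(perm >= abs(r_obs)) + 1) / (n_perm + 1)
  # agreement within Monte-Carlo error of the permutation estimate
  expect_lt(abs(cor_pvalue(r_obs, 12) - p_perm),
            3 * sqrt(p_perm * (1 - p_perm) / n_perm) + 0.01)
})

test_that("cis screen enforces a strict |r| > 0.5 rule", {
  set.seed(73)
  # profiles with exact sample correlations at and around the cutoff
  mk_pair <- function(r) {
    lp <- latent_correlated_profiles(37, r)
    list(x = lp$anchor, y = lp$partners[1, ])
  }
  pr_hit <- mk_pair(0.8)
  pr_neg <- mk_pair(-0.9)
  lnc <- rbind(L1 = pr_hit$x, L2 = pr_neg$x)
  pcm <- rbind(G1 = pr_hit$y, G2 = pr_neg$y)
  colnames(lnc) <- colnames(pcm) <- paste0("t", 1:37)
  nb <- data.frame(lncrna_locus_id = c("L1", "L2"),
                   pc_gene_id = c("G1", "G2"),
                   side = "upstream", gap_bp = 100L)
  cis <- cis_screen(lnc, pcm, nb)
  expect_setequal(cis$lncrna_id, c("L1", "L2"))
  expect_equal(cis$sign[cis$lncrna_id == "L1"], "positive")
  expect_equal(cis$sign[cis$lncrna_id == "L2"], "negative")
  # |r| = 0.5 exactly is NOT reported: integer profiles with an exactly
  # representable correlation of 0.5
  lnc_e <- rbind(L3 = c(1, 0, -1))
  pcm_e <- rbind(G3 = c(0, 1, -1))
  colnames(lnc_e) <- colnames(pcm_e) <- paste0("t", 1:3)
  stopifnot(cor(lnc_e[1, ], pcm_e[1, ]) == 0.5)
  nb_e <- data.frame(lncrna_locus_id = "L3", pc_gene_id = "G3",
                     side = "upstream", gap_bp = 100L)
  expect_equal(nrow(cis_screen(lnc_e, pcm_e, nb_e)), 0L)
})

test_that("trans screen preserves only r < -0.7 and excludes neighbors", {
  set.seed(74)
  lp <- latent_correlated_profiles(37, c(-0.9, -0.3))
  lnc <- rbind(L1 = lp$anchor)
  pcm <- rbind(G1 = lp$partners[1, ], G3 = lp$partners[2, ],
               G4 = lp$partners[1, ])
  colnames(lnc) <- colnames(pcm) <- paste0("t", 1:37)
  nb <- data.frame(lncrna_locus_id = "L1", pc_gene_id = "G4",
                   side = "upstream", gap_bp = 10L)
  tr <- trans_screen(lnc, pcm, nb)
  # G1 passes; G3 is weak; G4 is a neighbor despite r = -0.9
  expect_equal(tr$pc_gene_id, "G1")
  expect_equal(tr$relation, "trans")
  expect_lt(tr$p, 0.001)
  # r = -0.7 exactly is not preserved: integer profiles whose sample
  # correlation evaluates to the cutoff
  lnc_e <- rbind(LE = c(1, -1, 2, -2, 0))
  pcm_e <- rbind(GE = c(-1, 2, -2, 0, 1))
  colnames(lnc_e) <- colnames(pcm_e) <- paste0("t", 1:5)
  stopifnot(abs(cor(lnc_e[1, ], pcm_e[1, ]) + 0.7) < 1e-15)
  nb0 <- data.frame(lncrna_locus_id = character(0),
                    pc_gene_id = character(0), side = character(0),
                    gap_bp = integer(0))
  expect_equal(nrow(trans_screen(lnc_e, pcm_e, nb0)), 0L)
})

test_that("hub detection uses a strict > 10 target rule with stable
          ranking", {
  mk_pairs <- function(lnc, n) {
    data.frame(lncrna_id = lnc, pc_gene_id = paste0(lnc, "_g", seq_len(n)),
               r = -0.8, p = 1e-4, relation = "trans", sign = "negative",
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk_pairs("A", 20), mk_pairs("B", 15), mk_pairs("C", 12),
                 mk_pairs("D", 11), mk_pairs("E", 10), mk_pairs("F", 2))
  hubs <- find_hubs(pairs)
  expect_equal(hubs$lncrna_id, c("A", "B", "C", "D"))
  expect_equal(hubs$target_count, c(20L, 15L, 12L, 11L))
  expect_false("E" %in% hubs$lncrna_id)
})
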