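make_G <- function(codes, pos = NULL, chrom = "1") {
  codes <- as.matrix(codes)
  p <- ncol(codes)
  if (is.null(pos)) pos <- seq_len(p) * 1000L
  genotype_matrix(sprintf("I%03d", seq_len(nrow(codes))),
                  data.frame(chrom = chrom, pos = pos,
                             id = sprintf("v%03d", seq_len(p)),
                             ref = "A", alt = "G", stringsAsFactors = FALSE),
                  codes)
}

test_that("cis windows are closed, clamped, strand-agnostic intervals", {
  w <- cis_window(5000000, "+")
  expect_equal(unname(w), c(3000000, 7000000))
  expect_equal(unname(diff(w)), 4000000)   # a 4 Mb region
  expect_equal(unname(cis_window(1000000, "-")), c(1, 3000000))
  expect_equal(unname(cis_window(500, "+", half_width = 0)), c(500, 500))
  expect_error(cis_window(0, "+"), "positive")
})

test_that("exact HWE test equals enumeration for all small tables", {
  expect_equal(hwe_test(0, 10, 0), hwe_enum_oracle(0, 10, 0), tolerance = 1e-12)
  expect_equal(hwe_test(10, 0, 0), 1)
  # exhaustive: every genotype table with up to 30 individuals
  for (n in c(2, 3, 5, 8, 13, 21, 30)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_test(nAA, nAa, naa), hwe_enum_oracle(nAA, nAa, naa),
                   tolerance = 1e-10)
    }
  }
  expect_error(hwe_test(-1, 2, 3), "negative")
})

test_that("variant QC applies dedup, MAF and HWE rules", {
  set.seed(1)
  n <- 48
  g_ok <- rbinom(n, 2, 0.3)
  g_rare <- c(rep(1, 3), rep(0, n - 3))        # MAF = 3/96 = 0.03125
  g_mono <- rep(0, n)
  g_hwe <- c(rep(0, 24), rep(2, 24))           # all-homozygote: fails HWE
  codes <- cbind(g_ok, g_rare, g_mono, g_hwe, g_ok)
  G <- make_G(codes, pos = c(1000, 2000, 3000, 4000, 1000))
  G$variants$id[5] <- "dup_of_1"
  out <- filter_variants(G)
  expect_equal(out$variants$id, "v001")
  expect_equal(unname(attr(out, "qc_removed")),
               c(1, 2, 1))  # duplicate; rare+mono by MAF; HWE failure
  # exact HW proportions are kept
  G2 <- make_G(cbind(c(rep(0, 12), rep(1, 24), rep(2, 12))))
  expect_equal(nrow(filter_variants(G2)$variants), 1)
})

test_that("additive scan matches closed-form OLS and handles noiseless fits", {
  g <- c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
  y <- 2 * g
  G <- make_G(cbind(g))
  sc <- additive_scan(G, y)
  expect_equal(sc$beta, 2, tolerance = 1e-12)
  expect_lt(sc$p_nominal, 1e-10)

  # worked 12-individual dataset vs normal equations
  set.seed(2)
  y2 <- 1.5 + 0.7 * g + rnorm(12, 0, 0.5)
  sc2 <- additive_scan(G, y2)
  X <- cbind(1, g)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y2)
  resid <- y2 - X %*% beta_hat
  s2 <- sum(resid^2) / (12 - 2)
  se_hat <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(sc2$beta, beta_hat[2], tolerance = 1e-10)
  expect_equal(sc2$se, se_hat, tolerance = 1e-10)
  expect_equal(sc2$p_nominal, 2 * pt(abs(beta_hat[2] / se_hat), 10,
                                     lower.tail = FALSE), tolerance = 1e-10)
})

test_that("null scans give uniform nominal p-values", {
  set.seed(3)
  n <- 30
  codes <- vapply(runif(1000, 0.1, 0.5), function(q) rbinom(n, 2, q),
                  numeric(n))
  G <- make_G(codes)
  y <- rnorm(n)
  sc <- additive_scan(G, y)
  frac <- mean(sc$p_nominal < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.035); expect_lte(frac, 0.065)
})

test_that("scan results are invariant to order and missing individuals", {
  set.seed(4)
  n <- 40
  codes <- vapply(rep(0.3, 10), function(q) rbinom(n, 2, q), numeric(n))
  y <- rnorm(n) + 0.5 * codes[, 4]
  G <- make_G(codes)
  sc <- additive_scan(G, y)
  # variant order
  perm <- sample(10)
  scp <- additive_scan(G[, perm], y)
  expect_equal(scp$beta[match(sc$id, scp$id)], sc$beta, tolerance = 1e-12)
  # individual order (trait names carry the alignment)
  yn <- setNames(y, G$ids)
  io <- sample(n)
  sci <- additive_scan(G[io, ], yn)
  expect_equal(sci$beta, sc$beta, tolerance = 1e-12)
  # adding an individual with missing genotype leaves stats unchanged
  G2 <- genotype_matrix(c(G$ids, "extra"), G$variants,
                        rbind(G$codes, NA))
  sc2 <- additive_scan(G2, c(yn, extra = 1.0))
  expect_equal(sc2$beta, sc$beta, tolerance = 1e-12)
  expect_equal(sc2$n, sc$n)
})

test_that("the dominance model captures what the additive model misses", {
  set.seed(5)
  g <- rep(c(0, 1, 2), each = 12)
  # pure dominance: het mean equals hom-alt mean
  y <- c(rnorm(12, 0, 0.3), rnorm(12, 1, 0.3), rnorm(12, 1, 0.3))
  G <- make_G(cbind(g))
  gen <- genotypic_scan(G, y)
  add <- additive_scan(G, y)
  expect_lt(gen$p_nominal, add$p_nominal)
  expect_false(gen$fallback)
  # no heterozygotes: falls back to additive
  g2 <- rep(c(0, 2), each = 18)
  y2 <- rnorm(36) + 0.5 * g2
  gen2 <- genotypic_scan(make_G(cbind(g2)), y2)
  expect_true(gen2$fallback)
  expect_equal(gen2$p_nominal, additive_scan(make_G(cbind(g2)), y2)$p_nominal,
               tolerance = 1e-12)
})

test_that("max-T permutation p-values are calibrated and bounded", {
  set.seed(6)
  n <- 30
  codes <- vapply(rep(0.3, 5), function(q) rbinom(n, 2, q), numeric(n))
  G <- make_G(codes)
  # constant trait: all corrected p = 1
  sc_const <- permutation_fwer(G, rep(1, n), n_perm = 200, seed = 1)
  expect_true(all(sc_const$p_fwer == 1))
  # floor at 1/(n_perm + 1)
  y <- 3 * codes[, 2] + rnorm(n, 0, 0.1)
  sc <- permutation_fwer(G, y, n_perm = 200, seed = 2)
  expect_equal(min(sc$p_fwer), 1 / 201)
  expect_true(all(sc$p_fwer >= 1 / 201 & sc$p_fwer <= 1))
  # reproducible under the seed
  sc2 <- permutation_fwer(G, y, n_perm = 200, seed = 2)
  expect_identical(sc$p_fwer, sc2$p_fwer)

  # single-variant scan agrees with a direct permutation test
  G1 <- make_G(codes[, 3, drop = FALSE])
  y1 <- rnorm(n) + 0.4 * codes[, 3]
  sc1 <- permutation_fwer(G1, y1, n_perm = 2000, seed = 3)
  t_obs <- abs(additive_scan(G1, y1)$t)
  set.seed(99)
  t_perm <- replicate(2000, {
    yp <- sample(y1)
    abs(additive_scan(G1, yp)$t)
  })
  p_direct <- (1 + sum(t_perm >= t_obs)) / 2001
  expect_lt(abs(sc1$p_fwer - p_direct), 0.03)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  set.seed(7)
  p <- runif(50)
  q <- bh_adjust(p)
  # hand step-up with monotonicity enforcement
  o <- order(p)
  q_hand <- p[o] * 50 / seq_len(50)
  q_hand <- rev(cummin(rev(q_hand)))
  q_hand <- pmin(q_hand, 1)
  expect_equal(q[o], q_hand, tolerance = 1e-12)
  expect_false(is.unsorted(q[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("run_scan restricts to the cis window, QCs and reports", {
  cfg <- sim_cohort_config(n_lines = 48, n_null_snps = 49, seed = 8,
                           effect_mode = "null")
  co <- simulate_cohort(cfg, events = FALSE)
  y <- setNames(rnorm(48), co$genotypes$ids)
  # two trait individuals lack genotypes: they are excluded, not fatal
  y2 <- c(y, EXTRA1 = 0.5, EXTRA2 = -0.5)
  res <- run_scan(co$genotypes, list(cv = y2),
                  gene = list(name = "g", chrom = cfg$chrom, tss = cfg$tss,
                              strand = "+"),
                  n_perm = 200, seed = 1)
  expect_equal(res$summary$n_individuals, 48)
  expect_true(all(res$scans$cv$pos >= res$window["start"] &
                    res$scans$cv$pos <= res$window["end"]))
  expect_true(all(c("p_fwer", "q_bh") %in% names(res$scans$cv)))
  # disjoint ids: informative error
  expect_error(run_scan(co$genotypes, list(cv = c(X = 1, Y = 2)),
                        gene = list(chrom = cfg$chrom, tss = cfg$tss,
                                    strand = "+")),
               "shared individuals")
})
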