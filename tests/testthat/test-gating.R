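test_that("pooled channel bounds follow the 5th/95th percentile convention", {
  s <- event_table(data.frame(FSC.A = 1, SSC.A = 1, FSC.W = 1, DAPI = 1,
                              FL = 1:100), sample_id = "a")
  b <- pooled_channel_bounds(list(s), "FL")
  expect_equal(b$lower, 5.95)   # linear interpolation between order stats
  expect_equal(b$upper, 95.05)
  expect_equal(b$shift, 0)

  s2 <- event_table(data.frame(FSC.A = 1, SSC.A = 1, FSC.W = 1, DAPI = 1,
                               FL = seq(-3.2, 96.8, length.out = 100)),
                    sample_id = "a")
  # force the 5th percentile to be exactly -3.2
  s2$FL[s2$FL < quantile(s2$FL, 0.05)] <- -3.2
  s2$FL[which.min(abs(s2$FL - quantile(s2$FL, 0.05)))] <- -3.2
  b2 <- pooled_channel_bounds(list(s2), "FL")
  expect_equal(b2$shift, abs(b2$lower))
  expect_error(pooled_channel_bounds(list(), "FL"), "empty")
  sc <- event_table(data.frame(FSC.A = 1, SSC.A = 1, FSC.W = 1, DAPI = 1,
                               FL = rep(2, 50)), sample_id = "a")
  expect_error(pooled_channel_bounds(list(sc), "FL"), "degenerate")
})

test_that("saturation filter retains the closed in-bounds set and shifts", {
  s <- flat_sample(50, seed = 1)
  b <- list(structure(list(channel = "FL", lower = -10, upper = 100, shift = 10),
                      class = "channel_bounds"))
  out <- filter_saturated(s, b)
  expect_equal(nrow(out), 50)
  expect_equal(out$FL, s$FL + 10)

  s$FL[7] <- 1000
  out2 <- filter_saturated(s, b)
  expect_equal(nrow(out2), 49)

  # uniform channels bounded by their own 5/95 percentiles: ~0.90^k retained
  set.seed(4)
  k <- 3
  u <- event_table(data.frame(FSC.A = runif(20000), SSC.A = runif(20000),
                              FSC.W = 1, DAPI = 1, FL = runif(20000)),
                   sample_id = "u")
  bu <- lapply(c("FSC.A", "SSC.A", "FL"), function(ch)
    pooled_channel_bounds(list(u), ch))
  kept <- nrow(filter_saturated(u, bu)) / 20000
  expect_lt(abs(kept - 0.9^k), 0.02)
})

test_that("DAPI stain threshold finds the unstained/stained valley", {
  set.seed(5)
  dapi <- c(rnorm(2000, 0, 0.3), rnorm(8000, 5, 0.5))
  thr <- dapi_stain_threshold(dapi)
  expect_gt(thr, 1); expect_lt(thr, 4)
  kept <- dapi[dapi > thr]
  expect_true(all(kept > thr))
  expect_error(dapi_stain_threshold(rnorm(5000, 5, 1)), "no valley",
               class = "no_valley")
})

test_that("density gates contain their target mass and exclude doublets", {
  set.seed(6)
  pooled <- lapply(1:3, function(i) flat_sample(8000, id = paste0("s", i)))
  g <- density_gate_2d(pooled, "FSC.A", "SSC.A", 0.75)
  inside <- sum(sapply(pooled, function(s) nrow(apply_gate(s, g))))
  frac <- inside / sum(sapply(pooled, nrow))
  expect_gte(frac, 0.75)
  expect_lte(frac, 0.78)

  # self-gate at 0.75 retains within [0.70, 0.80]
  one <- pooled[[1]]
  g1 <- density_gate_2d(list(one), "FSC.A", "SSC.A", 0.75)
  expect_gt(nrow(apply_gate(one, g1)) / nrow(one), 0.70)
  expect_lt(nrow(apply_gate(one, g1)) / nrow(one), 0.80)

  # labeled doublets: inflated FSC.W; 0.80 gate on FSC-A/FSC-W excludes >=90%
  cfg <- sim_sample_config(frac_doublets = 0.05, frac_unstained = 0)
  sd_ <- simulate_sample_events(cfg, 20000, seed = 8, sample_id = "d")
  gd <- density_gate_2d(list(sd_), "FSC.A", "FSC.W", 0.80)
  gated <- apply_gate(sd_, gd)
  n_dbl_in <- sum(gated$kind == "doublet")
  n_dbl <- sum(sd_$kind == "doublet")
  expect_lt(n_dbl_in / n_dbl, 0.10)
  expect_error(density_gate_2d(list(flat_sample(50)), "FSC.A", "SSC.A", 0.75),
               "100")
})

test_that("G1 threshold sits in the inter-peak valley and keeps the G1 peak", {
  set.seed(9)
  g1 <- rnorm(7000, 100, 8); g2 <- rnorm(2000, 200, 12)
  thr <- g1_threshold(c(g1, g2))
  expect_gt(thr, 100); expect_lt(thr, 200)
  expect_gte(mean(g1 < thr), 0.95)

  # 4-SD separation at the generator's G1:G2 odds: retained set is >= 98%
  # pure G1 (large n so the population property, not sampling noise, is read)
  g1b <- rnorm(164000, 100, 25); g2b <- rnorm(36000, 200, 25)
  thr2 <- g1_threshold(c(g1b, g2b))
  purity <- sum(g1b < thr2) / (sum(g1b < thr2) + sum(g2b < thr2))
  expect_gte(purity, 0.98)

  # pure G1: threshold right of the mode, >= 99% retained
  pure <- rnorm(10000, 100, 8)
  thr3 <- g1_threshold(pure)
  expect_gt(thr3, 100)
  expect_gte(mean(pure < thr3), 0.99)
  expect_error(g1_threshold(rnorm(10)), "fewer")
})

test_that("size correction removes the scatter-coupled component of FL", {
  set.seed(10)
  n <- 10000
  lf <- rnorm(n, 10.8, 0.15); ls_ <- rnorm(n, 10.3, 0.2)
  base <- data.frame(FSC.A = exp(lf), SSC.A = exp(ls_), FSC.W = rnorm(n, 70, 4),
                     DAPI = rnorm(n, 100, 6))

  # zero coupling: correction is (almost) the identity
  s0 <- event_table(cbind(base, FL = rnorm(n, 8, 0.4)), sample_id = "a")
  c0 <- size_correct(s0)
  expect_lt(max(abs(c0$FL - s0$FL)), 0.05)

  # strong coupling: post-correction OLS slope ~ 0, correlation < 0.05
  s1 <- event_table(cbind(base, FL = 0.5 * lf + rnorm(n, 0, 0.2)), sample_id = "a")
  c1 <- size_correct(s1)
  expect_lt(abs(unname(coef(lm(c1$FL ~ lf))[2])), 0.02)
  expect_lt(abs(cor(c1$FL, lf)), 0.05)

  # least-squares variant preserves the sample mean exactly
  c2 <- size_correct(s1, method = "ls")
  expect_equal(mean(c2$FL), mean(s1$FL), tolerance = 1e-12)
})

test_that("warp alignment is an identity on identical replicates and monotone", {
  a <- flat_sample(5000, id = "a", seed = 12)
  b <- flat_sample(5000, id = "b", seed = 12)
  w <- warp_align(list(a, b))
  expect_equal(w[[1]]$FL, a$FL, tolerance = 1e-9)

  shifted <- b
  shifted$FL <- b$FL + 0.3
  w2 <- warp_align(list(a, shifted))
  mode_of <- function(x) { d <- density(x); d$x[which.max(d$y)] }
  expect_lt(abs(mode_of(w2[[1]]$FL) - mode_of(w2[[2]]$FL)), 0.05)

  # monotone: sorted input maps to sorted output
  expect_false(is.unsorted(w2[[2]]$FL[order(shifted$FL)]))

  # single sample passes through
  expect_identical(warp_align(list(a)), list(a))
})

test_that("warping leaves the CV of a modestly shifted unimodal sample stable", {
  a <- flat_sample(8000, id = "a", seed = 31)
  b <- flat_sample(8000, id = "b", seed = 32)
  b$FL <- b$FL + 0.1
  w <- warp_align(list(a, b))
  cv <- function(x) sd(x) / mean(x)
  expect_lt(abs(cv(w[[1]]$FL) - cv(a$FL)) / cv(a$FL), 0.01)
  expect_lt(abs(cv(w[[2]]$FL) - cv(b$FL)) / cv(b$FL), 0.01)
})

test_that("K scores equal the brute-force pairwise KS average", {
  set.seed(13)
  grp <- lapply(1:4, function(i) flat_sample(1500, id = paste0("r", i)))
  sc <- replicate_outlier_scores(grp)
  for (i in 1:4) {
    partners <- setdiff(1:4, i)
    k_oracle <- mean(sapply(partners, function(j)
      ks_oracle(grp[[i]]$FL, grp[[j]]$FL)))
    expect_equal(sc$K[i], k_oracle, tolerance = 1e-12)
  }

  # identical replicates: K = 0
  same <- lapply(1:3, function(i) flat_sample(1000, id = paste0("r", i), seed = 14))
  expect_equal(replicate_outlier_scores(same)$K, rep(0, 3))

  # a replicate shifted by 3 SD has the maximum K
  shift <- flat_sample(1500, id = "rs", seed = 15)
  shift$FL <- shift$FL + 3 * sd(shift$FL)
  sc2 <- replicate_outlier_scores(c(grp[1:3], list(shift)))
  expect_equal(which.max(sc2$K), 4L)

  # flags invariant to sample order
  sc3 <- replicate_outlier_scores(c(list(shift), grp[1:3]))
  expect_equal(sort(sc2$K), sort(sc3$K), tolerance = 1e-12)

  # undefined for groups of two
  expect_message(sc4 <- replicate_outlier_scores(grp[1:2]), "undefined")
  expect_true(all(is.na(sc4$K)))
})

test_that("run_gating keeps retention monotone and drops small samples", {
  cfg <- sim_sample_config()
  samples <- c(lapply(1:3, function(r)
    simulate_sample_events(cfg, 20000, seed = 20 + r,
                           sample_id = sprintf("A_r%d", r), line_id = "A",
                           replicate = r)),
    list(simulate_sample_events(cfg, 1500, seed = 30, sample_id = "tiny",
                                line_id = "B", replicate = 1)))
  res <- suppressMessages(run_gating(samples))
  rep <- res$report
  counts <- as.matrix(rep[, c("n_input", "n_saturation", "n_dapi", "n_size",
                              "n_doublet", "n_g1")])
  expect_true(all(apply(counts, 1, function(x) all(diff(x) <= 0))))
  expect_equal(rep$dropped[rep$sample_id == "tiny"], "min-events")
  kept_n <- sapply(res$samples, nrow)
  expect_true(all(kept_n > 1000))
})

test_that("noise-free retention compounds the configured gate fractions", {
  cfg <- sim_sample_config(frac_doublets = 0, frac_unstained = 0,
                           frac_g1 = 0.70, frac_s = 0.15, frac_g2 = 0.15)
  samples <- lapply(1:3, function(r)
    simulate_sample_events(cfg, 20000, seed = 40 + r,
                           sample_id = sprintf("A_r%d", r), line_id = "A",
                           replicate = r))
  res <- suppressMessages(run_gating(samples, gating_config(saturation = FALSE)))
  retention <- sapply(res$samples, nrow) / 20000
  expect_true(all(retention >= 0.75 * 0.80 * 0.70 - 0.03))
})
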