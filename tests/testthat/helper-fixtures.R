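# Shared fixture builders; everything is generated in code at test time.

# bare event table with independent channels, no cell-cycle structure
flat_sample <- function(n, id = "s1", line = "L1", rep = 1L, fl_mean = 8,
                        fl_sd = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  event_table(data.frame(FSC.A = exp(rnorm(n, 10.8, 0.15)),
                         SSC.A = exp(rnorm(n, 10.3, 0.20)),
                         FSC.W = rnorm(n, 70, 4),
                         DAPI = rnorm(n, 100, 6),
                         FL = rnorm(n, fl_mean, fl_sd)),
              sample_id = id, line_id = line, replicate = rep)
}

# brute-force two-sample KS statistic from the two ECDFs
ks_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# exact HWE p by direct enumeration with factorials (independent of the
# lgamma-based implementation path)
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- sapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    factorial(n) / (factorial(hr) * factorial(h) * factorial(hc)) * 2^h
  })
  probs <- probs / sum(probs)
  obs <- probs[hets == nAa]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# clonality rule-table oracle: the printed sentence order applied literally
# to a vector of representativities (percent)
clonality_oracle <- function(reps) {
  if (sum(reps >= 20) >= 2) return("polyclonal")
  if (max(reps) >= 80) return("monoclonal")
  "inconclusive"
}

# build a clonotype table directly from representativities (counts per 1%)
clonotype_from_reps <- function(reps) {
  tab <- data.frame(cdr3_peptide = paste0("CLONE", seq_along(reps), "XXXX"),
                    count = as.integer(reps),
                    representativity = 100 * reps / sum(reps),
                    stringsAsFactors = FALSE)
  class(tab) <- c("clonotype_table", "data.frame")
  tab
}
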