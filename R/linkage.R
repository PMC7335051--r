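#' cis window around a transcription start site
#'
#' Closed 1-based interval `[max(1, tss - half_width), tss + half_width]`.
#' The caller supplies the strand-aware TSS (transcript start for forward
#' genes, transcript end for reverse genes).
#'
#' @param tss 1-based TSS coordinate.
#' @param strand `"+"` or `"-"` (recorded, not used in the arithmetic).
#' @param half_width window half-width in bp (default 2 Mb).
#' @return named integer vector `c(start, end)`.
#' @export
cis_window <- function(tss, strand = c("+", "-"), half_width = 2000000L) {
  strand <- match.arg(strand)
  if (tss <= 0) stop("cis_window: tss must be positive")
  c(start = max(1, tss - half_width), end = tss + half_width)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, the p-value is the total
#' probability of heterozygote counts whose conditional probability does not
#' exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("hwe_test: negative counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("hwe_test: empty table")
  nA <- 2 * n_AA + n_Aa        # minor allele count bookkeeping is symmetric
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_het | allele counts) up to a constant:
  # P ~ n! / (nAA! nAa! naa!) * 2^nAa  with nAA=(nA-h)/2 etc.
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) - lgamma(hom_rare + 1) - lgamma(h + 1) - lgamma(hom_common + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  if (is.na(obs)) stop("hwe_test: inconsistent genotype table")
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' Variant quality control
#'
#' Removes duplicated variant entries (same chrom:pos:ref:alt, first kept),
#' variants with minor allele frequency below `maf_min` (computed from
#' non-missing genotypes), and variants failing the exact Hardy-Weinberg
#' test at `hwe_alpha`.
#'
#' @param G [genotype_matrix()]
#' @param maf_min MAF threshold (kept if MAF >= `maf_min`).
#' @param hwe_alpha HWE significance threshold (removed if p < `hwe_alpha`).
#' @return filtered `genotype_matrix`; attribute `qc_removed` records counts
#'   removed per rule.
#' @export
filter_variants <- function(G, maf_min = 0.05, hwe_alpha = 0.001) {
  key <- with(G$variants, paste(chrom, pos, ref, alt, sep = ":"))
  dup <- duplicated(key)
  G2 <- G[, !dup]
  p <- ncol(G2$codes)
  maf <- apply(G2$codes, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(0)
    f <- sum(g) / (2 * length(g))
    min(f, 1 - f)
  })
  low_maf <- maf < maf_min
  hwe_p <- apply(G2$codes, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  bad_hwe <- !low_maf & hwe_p < hwe_alpha
  keep <- !low_maf & !bad_hwe
  out <- G2[, keep]
  attr(out, "qc_removed") <- c(duplicate = sum(dup), maf = sum(low_maf),
                               hwe = sum(bad_hwe))
  if (!sum(keep)) message("filter_variants: no variants retained")
  out
}

# vectorized per-variant simple regression of y on allele counts with
# variant-wise missing-drop; returns beta, se, t, p, n per variant
scan_stats <- function(codes, y) {
  y0 <- y; y0[is.na(y0)] <- 0
  M2 <- !is.na(codes) & !is.na(y)       # individuals x variants mask
  G0 <- codes; G0[!M2] <- 0
  n <- colSums(M2)
  Sg <- colSums(G0); Sgg <- colSums(G0^2)
  Sy <- colSums(M2 * y0); Syy <- colSums(M2 * y0^2)
  Sgy <- colSums(G0 * y0)
  sxx <- Sgg - Sg^2 / n
  syy <- Syy - Sy^2 / n
  sxy <- Sgy - Sg * Sy / n
  beta <- sxy / sxx
  df <- n - 2
  sse <- pmax(syy - sxy^2 / sxx, 0)
  se <- sqrt(sse / df / sxx)
  t <- beta / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  skip <- sxx <= 0 | n < 3
  beta[skip] <- NA; se[skip] <- NA; t[skip] <- NA; p[skip] <- NA
  data.frame(n = n, beta = beta, se = se, t = t, p_nominal = p)
}

#' Additive association scan
#'
#' Per variant, simple linear regression of the trait on the alternate-allele
#' count (0/1/2); individuals with missing genotype or trait are dropped
#' variant-wise. Two-sided t-test on n - 2 df.
#'
#' @param G [genotype_matrix()]
#' @param y numeric trait vector aligned to `G$ids` (or named by individual).
#' @param min_n minimum non-missing individuals per variant.
#' @return data.frame of class `linkage_scan`: variant records plus `n`,
#'   `beta`, `se`, `t`, `p_nominal` (NA with reason "zero-variance" /
#'   "too-few" for skipped variants).
#' @export
additive_scan <- function(G, y, min_n = 10) {
  y <- align_trait(G, y)
  st <- scan_stats(G$codes, y)
  st$p_nominal[st$n < min_n] <- NA
  out <- cbind(G$variants, st)
  out$skipped <- ifelse(is.na(st$p_nominal),
                        ifelse(st$n < min_n, "too-few", "zero-variance"), "")
  class(out) <- c("linkage_scan", "data.frame")
  attr(out, "model") <- "additive"
  out
}

align_trait <- function(G, y) {
  if (!is.null(names(y))) {
    miss <- setdiff(G$ids, names(y))
    y <- unname(y[match(G$ids, names(y))])
  } else if (length(y) != length(G$ids)) {
    stop("trait vector must be named or aligned to the genotype individuals")
  }
  y
}

#' Association scan with dominance
#'
#' Regression of the trait on the additive code plus a heterozygosity
#' indicator; 2-df F test against the intercept-only model. Variants with no
#' heterozygotes (collinear codes) fall back to the additive model and are
#' flagged in `fallback`.
#'
#' @inheritParams additive_scan
#' @return data.frame of class `linkage_scan` with `F`, `p_nominal`,
#'   `beta_add`, `beta_dom`, `fallback`.
#' @export
genotypic_scan <- function(G, y, min_n = 10) {
  y0 <- align_trait(G, y)
  p <- ncol(G$codes)
  res <- data.frame(n = integer(p), F = NA_real_, p_nominal = NA_real_,
                    beta_add = NA_real_, beta_dom = NA_real_,
                    fallback = FALSE)
  add <- additive_scan(G, y, min_n = min_n)
  for (j in seq_len(p)) {
    g <- G$codes[, j]
    ok <- !is.na(g) & !is.na(y0)
    res$n[j] <- sum(ok)
    if (sum(ok) < min_n || stats::var(g[ok]) == 0) next
    het <- as.numeric(g == 1)
    if (stats::var(het[ok]) == 0 || all(g[ok] != 1)) {
      res$fallback[j] <- TRUE
      res$F[j] <- add$t[j]^2
      res$p_nominal[j] <- add$p_nominal[j]
      res$beta_add[j] <- add$beta[j]
      next
    }
    fit <- stats::lm(y0[ok] ~ g[ok] + het[ok])
    # 2-df F test of the full genotype model vs intercept
    rss0 <- sum((y0[ok] - mean(y0[ok]))^2)
    rss1 <- sum(stats::residuals(fit)^2)
    df2 <- sum(ok) - 3
    if (df2 <= 0 || rss1 <= 0) next
    Fv <- ((rss0 - rss1) / 2) / (rss1 / df2)
    res$F[j] <- Fv
    res$p_nominal[j] <- stats::pf(Fv, 2, df2, lower.tail = FALSE)
    res$beta_add[j] <- stats::coef(fit)[2]
    res$beta_dom[j] <- stats::coef(fit)[3]
  }
  out <- cbind(G$variants, res)
  class(out) <- c("linkage_scan", "data.frame")
  attr(out, "model") <- "genotypic"
  out
}

#' Max-T permutation family-wise error control
#'
#' Permutes the trait `n_perm` times; for each permutation records the
#' maximum |t| across all variants of the scan. The corrected p-value of
#' variant v is `(1 + #{max |t|_perm >= |t|_v}) / (n_perm + 1)`.
#'
#' @param G [genotype_matrix()]
#' @param y trait vector (named or aligned).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param scan optional precomputed [additive_scan()] result (recomputed
#'   otherwise).
#' @return `scan` with an added `p_fwer` column; attribute `perm_max_t`
#'   stores the permutation maxima.
#' @export
permutation_fwer <- function(G, y, n_perm = 10000, seed = 1L, scan = NULL) {
  if (n_perm < 100) stop("permutation_fwer: n_perm must be >= 100")
  y <- align_trait(G, y)
  if (is.null(scan)) scan <- additive_scan(G, y)
  set.seed(seed)
  obs_t <- abs(scan$t)
  keep <- !is.na(y)
  yk <- y[keep]
  if (stats::var(yk) == 0) {       # constant trait: nothing can be extreme
    scan$p_fwer <- rep(1, nrow(scan))
    attr(scan, "n_perm") <- n_perm
    return(scan)
  }
  codes <- G$codes[keep, , drop = FALSE]
  max_t <- numeric(n_perm)
  block <- 250L   # permutations per vectorized block
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    Y <- vapply(seq_len(b), function(i) sample(yk), numeric(length(yk)))
    Tm <- perm_t_matrix(codes, Y)
    max_t[done + seq_len(b)] <- apply(abs(Tm), 2, max, na.rm = TRUE)
    done <- done + b
  }
  p_fwer <- vapply(obs_t, function(tv) {
    if (is.na(tv)) return(NA_real_)
    (1 + sum(max_t >= tv)) / (n_perm + 1)
  }, numeric(1))
  scan$p_fwer <- p_fwer
  attr(scan, "perm_max_t") <- max_t
  attr(scan, "n_perm") <- n_perm
  attr(scan, "seed") <- seed
  scan
}

# t statistics for all variants (columns of `codes`, may contain NA) against
# all permuted trait columns of Y (no missing in Y)
perm_t_matrix <- function(codes, Y) {
  M <- !is.na(codes)
  G0 <- codes; G0[!M] <- 0
  n <- colSums(M)                        # per variant
  Sg <- colSums(G0); Sgg <- colSums(G0^2)
  SY <- crossprod(M, Y)                  # variants x perms: sum y over mask
  SYY <- crossprod(M, Y^2)
  SGY <- crossprod(G0, Y)
  sxx <- Sgg - Sg^2 / n
  syy <- SYY - SY^2 / n
  sxy <- SGY - (Sg / n) * SY
  r2 <- sxy^2 / (sxx * syy)
  r2 <- pmin(r2, 1 - 1e-12)
  df <- n - 2
  tt <- sign(sxy) * sqrt(r2 * df / (1 - r2))
  tt[sxx <= 0 | n < 3, ] <- NA
  tt
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via [stats::p.adjust()].
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_adjust: p outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @export
print.linkage_scan <- function(x, ...) {
  cat(sprintf("linkage_scan (%s model): %d variants", attr(x, "model"), nrow(x)))
  if (!is.null(x$p_fwer)) {
    cat(sprintf(", %d with FWER < 0.05 (%d permutations)",
                sum(x$p_fwer < 0.05, na.rm = TRUE), attr(x, "n_perm")))
  }
  cat("\n")
  top <- x[order(x$p_nominal), ][1, c("id", "chrom", "pos", "beta", "p_nominal")]
  cat("  top variant: ", top$id, sprintf(" (beta %.3g, p %.3g)\n", top$beta,
                                         top$p_nominal))
  invisible(x)
}

#' Full cis-association scan for one gene and trait set
#'
#' For each trait: restricts variants to the +/- `half_width` cis window
#' around the strand-aware TSS, applies variant QC ([filter_variants()]),
#' runs the additive scan, max-T permutation FWER and (per trait
#' independently) BH FDR, and reports associations with corrected p < 0.05.
#'
#' @param G [genotype_matrix()] of the cohort.
#' @param traits data.frame with `individual_id`, one row per individual, and
#'   one numeric column per trait; or a named list of named trait vectors.
#' @param gene list with `name`, `chrom`, `tss`, `strand`.
#' @param n_perm,seed permutation settings.
#' @param half_width cis half-width.
#' @return list of class `cis_scan`: per-trait `linkage_scan` tables
#'   (`scans`), a `summary` data.frame mirroring (protein, trait, n, SNPs,
#'   min corrected p, FDR), and the QC counts.
#' @export
run_scan <- function(G, traits, gene, n_perm = 10000, seed = 1L,
                     half_width = 2000000L) {
  if (is.data.frame(traits)) {
    ids <- traits$individual_id
    if (is.null(ids)) stop("traits data.frame needs an individual_id column")
    tl <- lapply(traits[setdiff(names(traits), "individual_id")],
                 function(v) stats::setNames(v, ids))
  } else tl <- traits
  shared <- intersect(G$ids, names(tl[[1]]))
  if (!length(shared))
    stop("run_scan: no shared individuals between genotypes and traits; ",
         "unmatched: ", paste(setdiff(names(tl[[1]]), G$ids), collapse = ", "))
  Gs <- G[match(shared, G$ids), ]
  win <- cis_window(gene$tss, gene$strand, half_width)
  inwin <- G$variants$chrom == gene$chrom &
    G$variants$pos >= win["start"] & G$variants$pos <= win["end"]
  Gw <- Gs[, which(inwin)]
  Gq <- filter_variants(Gw)
  scans <- list(); summ <- list()
  for (tn in names(tl)) {
    y <- tl[[tn]][shared]
    sc <- additive_scan(Gq, y)
    sc <- permutation_fwer(Gq, y, n_perm = n_perm, seed = seed, scan = sc)
    sc$q_bh <- bh_adjust(sc$p_nominal)
    scans[[tn]] <- sc
    hit <- !is.na(sc$p_fwer) & sc$p_fwer < 0.05
    summ[[tn]] <- data.frame(
      gene = gene$name %||% "gene", trait = tn,
      n_individuals = sum(!is.na(y)), n_snps = nrow(sc),
      n_significant = sum(hit),
      min_p_fwer = suppressWarnings(min(sc$p_fwer, na.rm = TRUE)),
      fdr_at_hits = if (any(hit)) max(sc$q_bh[hit]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(scans = scans, summary = do.call(rbind, summ),
                 qc_removed = attr(Gq, "qc_removed"), window = win),
            class = "cis_scan")
}

#' @export
print.cis_scan <- function(x, ...) {
  cat(sprintf("cis_scan: window [%d, %d], QC removed %s\n",
              x$window["start"], x$window["end"],
              paste(names(x$qc_removed), x$qc_removed, collapse = ", ")))
  print(x$summary)
  invisible(x)
}
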