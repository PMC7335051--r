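#' Configuration for one simulated cytometry sample
#'
#' Defaults emulate a fixed, DAPI-stained lymphoblastoid sample acquired on a
#' cytometer: log-normal scatter, a G1/S/G2 DNA-content structure with the G2
#' mode at twice the G1 mode, a small unstained-debris fraction, doublets with
#' inflated pulse width and doubled DNA signal, and a fluorescence channel
#' simulated directly on log scale as a one- or two-component Gaussian mixture
#' coupled to cell size.
#'
#' @param g1_dapi_mode,g2_dapi_mode DAPI intensity modes of the G1 and G2 peaks
#'   (G2 defaults to twice G1).
#' @param dapi_sd within-phase DAPI standard deviation.
#' @param frac_g1,frac_s,frac_g2 cell-cycle proportions among stained singlets
#'   (must sum to <= 1; any remainder is attributed to G1).
#' @param frac_unstained,frac_doublets fractions of all events that are
#'   unstained debris / doublets.
#' @param size_coupling length-2 numeric: coefficients of centred log(FSC.A)
#'   and log(SSC.A) in the log-fluorescence model. Centring keeps the
#'   configured mixture mean equal to the realized population mean.
#' @param fl_components matrix-like with columns (weight, mean, sd): the
#'   log-scale fluorescence mixture (one row = unimodal).
#' @param log_fsc_mean,log_fsc_sd,log_ssc_mean,log_ssc_sd scatter parameters
#'   (log scale).
#' @param fscw_mean,fscw_sd,doublet_width_factor pulse-width parameters;
#'   doublets have FSC.W inflated by the factor.
#' @return list of class `sim_sample_config`.
#' @export
sim_sample_config <- function(g1_dapi_mode = 100, g2_dapi_mode = 2 * g1_dapi_mode,
                              dapi_sd = 6,
                              frac_g1 = 0.60, frac_s = 0.22, frac_g2 = 0.13,
                              frac_unstained = 0.02, frac_doublets = 0.03,
                              size_coupling = c(0.4, 0.2),
                              fl_components = cbind(weight = 1, mean = 5, sd = 0.6),
                              log_fsc_mean = 10.8, log_fsc_sd = 0.15,
                              log_ssc_mean = 10.3, log_ssc_sd = 0.20,
                              fscw_mean = 70, fscw_sd = 4,
                              doublet_width_factor = 1.6) {
  fl_components <- as.matrix(fl_components)
  if (ncol(fl_components) != 3)
    stop("fl_components must have columns (weight, mean, sd)")
  colnames(fl_components) <- c("weight", "mean", "sd")
  cfg <- list(g1_dapi_mode = g1_dapi_mode, g2_dapi_mode = g2_dapi_mode,
              dapi_sd = dapi_sd, frac_g1 = frac_g1, frac_s = frac_s,
              frac_g2 = frac_g2, frac_unstained = frac_unstained,
              frac_doublets = frac_doublets, size_coupling = size_coupling,
              fl_components = fl_components,
              log_fsc_mean = log_fsc_mean, log_fsc_sd = log_fsc_sd,
              log_ssc_mean = log_ssc_mean, log_ssc_sd = log_ssc_sd,
              fscw_mean = fscw_mean, fscw_sd = fscw_sd,
              doublet_width_factor = doublet_width_factor)
  class(cfg) <- "sim_sample_config"
  validate_sample_config(cfg)
  cfg
}

validate_sample_config <- function(cfg) {
  fr <- c(cfg$frac_g1, cfg$frac_s, cfg$frac_g2, cfg$frac_unstained, cfg$frac_doublets)
  if (any(fr < 0) || any(fr > 1))
    stop("sim_sample_config: fractions must lie in [0, 1]")
  if (cfg$frac_g1 + cfg$frac_s + cfg$frac_g2 > 1 + 1e-9)
    stop("sim_sample_config: frac_g1 + frac_s + frac_g2 must be <= 1")
  if (cfg$frac_unstained + cfg$frac_doublets > 1)
    stop("sim_sample_config: unstained + doublet fractions exceed 1")
  w <- cfg$fl_components[, "weight"]
  if (abs(sum(w) - 1) > 1e-8) stop("fl_components weights must sum to 1")
  if (any(cfg$fl_components[, "sd"] <= 0)) stop("fl_components sds must be > 0")
  invisible(cfg)
}

# draw n singlet events from cfg; returns data.frame with truth columns
draw_singlets <- function(cfg, n) {
  lf <- stats::rnorm(n, cfg$log_fsc_mean, cfg$log_fsc_sd)
  ls <- stats::rnorm(n, cfg$log_ssc_mean, cfg$log_ssc_sd)
  fscw <- stats::rnorm(n, cfg$fscw_mean, cfg$fscw_sd)
  # cell-cycle phase of stained singlets; remainder of the simplex goes to G1
  p <- c(cfg$frac_g1 + max(0, 1 - cfg$frac_g1 - cfg$frac_s - cfg$frac_g2),
         cfg$frac_s, cfg$frac_g2)
  phase <- sample.int(3, n, replace = TRUE, prob = p)
  dapi <- numeric(n)
  dapi[phase == 1] <- stats::rnorm(sum(phase == 1), cfg$g1_dapi_mode, cfg$dapi_sd)
  dapi[phase == 2] <- stats::runif(sum(phase == 2), cfg$g1_dapi_mode, cfg$g2_dapi_mode) +
    stats::rnorm(sum(phase == 2), 0, cfg$dapi_sd / 2)
  dapi[phase == 3] <- stats::rnorm(sum(phase == 3), cfg$g2_dapi_mode, 2 * cfg$dapi_sd)
  comp <- sample.int(nrow(cfg$fl_components), n, replace = TRUE,
                     prob = cfg$fl_components[, "weight"])
  fl <- cfg$fl_components[comp, "mean"] +
    stats::rnorm(n, 0, cfg$fl_components[comp, "sd"]) +
    cfg$size_coupling[1] * (lf - cfg$log_fsc_mean) +
    cfg$size_coupling[2] * (ls - cfg$log_ssc_mean)
  data.frame(FSC.A = exp(lf), SSC.A = exp(ls), FSC.W = fscw,
             DAPI = dapi, FL = fl, phase = phase)
}

#' Simulate one cytometry sample
#'
#' Draws `n_events` events from a `sim_sample_config`: stained singlets with
#' G1/S/G2 DAPI structure, a fraction of unstained near-zero-DAPI debris, and
#' doublets built as sums of two singlets (summed scatter areas and DAPI,
#' log-sum fluorescence) with FSC.W inflated by the configured factor. The
#' hidden columns `phase` (1 = G1, 2 = S, 3 = G2, NA for debris/doublets) and
#' `kind` ("singlet", "unstained", "doublet") carry the simulation truth used
#' by the test oracles; gating never reads them.
#'
#' @param cfg `sim_sample_config`
#' @param n_events number of events (> 0)
#' @param seed integer seed; `NULL` uses the current RNG state (as when called
#'   from [simulate_cohort()]).
#' @param ... metadata passed to [event_table()] (`sample_id`, `line_id`, ...)
#' @return an [event_table()] with truth columns `phase` and `kind`.
#' @export
simulate_sample_events <- function(cfg, n_events, seed = NULL, ...) {
  validate_sample_config(cfg)
  if (n_events <= 0) stop("n_events must be > 0")
  if (!is.null(seed)) set.seed(seed)
  kind <- sample(c("singlet", "unstained", "doublet"), n_events, replace = TRUE,
                 prob = c(1 - cfg$frac_unstained - cfg$frac_doublets,
                          cfg$frac_unstained, cfg$frac_doublets))
  n_sing <- sum(kind == "singlet"); n_uns <- sum(kind == "unstained")
  n_dbl <- sum(kind == "doublet")
  out <- vector("list", 3)
  s <- draw_singlets(cfg, max(n_sing, 1))[seq_len(n_sing), , drop = FALSE]
  s$kind <- rep("singlet", n_sing)
  out[[1]] <- s
  if (n_uns > 0) {
    u <- draw_singlets(cfg, n_uns)
    u$DAPI <- abs(stats::rnorm(n_uns, 2, 1))   # essentially unstained
    u$phase <- NA_integer_
    u$kind <- "unstained"
    out[[2]] <- u
  }
  if (n_dbl > 0) {
    a <- draw_singlets(cfg, n_dbl); b <- draw_singlets(cfg, n_dbl)
    d <- data.frame(FSC.A = a$FSC.A + b$FSC.A, SSC.A = a$SSC.A + b$SSC.A,
                    FSC.W = a$FSC.W * cfg$doublet_width_factor,
                    DAPI = a$DAPI + b$DAPI,
                    FL = log(exp(a$FL) + exp(b$FL)),
                    phase = NA_integer_, kind = "doublet")
    out[[3]] <- d
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  ev <- ev[sample.int(nrow(ev)), , drop = FALSE]  # shuffle acquisition order
  rownames(ev) <- NULL
  event_table(ev, ...)
}

#' Configuration for a simulated mapping cohort
#'
#' Defines the study design the generator emulates: `n_lines` cell lines
#' measured in `n_replicates` independent samples of `n_events` events each,
#' with biallelic genotypes drawn under Hardy-Weinberg proportions and one
#' designated causal SNP whose alternate-allele count modulates the
#' fluorescence distribution according to `effect_mode`:
#' \describe{
#'   \item{dispersion}{log-scale SD multiplied by `effect_size` per alt allele
#'     at strictly fixed log-scale mean.}
#'   \item{mean}{log-scale mean shifted by `(effect_size - 1) * base_sd` per
#'     alt allele at fixed SD.}
#'   \item{bimodality}{mixing weight p1 shifted by `effect_size` per alt
#'     allele (clamped to [0.05, 0.95]).}
#'   \item{null}{all lines share identical parameters.}
#' }
#'
#' @param n_lines,n_replicates,n_events design sizes.
#' @param maf minor-allele frequency of the causal SNP, in (0, 0.5].
#' @param n_null_snps number of non-causal variants (independent draws, MAF
#'   uniform on [0.05, 0.5]).
#' @param effect_mode one of "dispersion", "mean", "bimodality", "null".
#' @param effect_size see above.
#' @param base_mean,base_cv baseline log-intensity mean and CV (SD =
#'   `base_cv * base_mean`).
#' @param rep_noise SD of the zero-mean per-sample shift of the component
#'   mean(s) emulating culture/staining replicate noise.
#' @param seed integer seed.
#' @param chrom,tss,strand coordinates of the simulated gene; variants are
#'   placed uniformly in the +/- 2 Mb cis window.
#' @param sample_config baseline `sim_sample_config` whose fluorescence
#'   components are overwritten per line.
#' @return list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_lines = 48, n_replicates = 6, n_events = 20000,
                              maf = 0.3, n_null_snps = 199,
                              effect_mode = c("dispersion", "mean", "bimodality", "null"),
                              effect_size = 1.5,
                              base_mean = 5, base_cv = 0.12,
                              rep_noise = 0.02, seed = 1L,
                              chrom = "12", tss = 5000000L, strand = "+",
                              sample_config = sim_sample_config()) {
  effect_mode <- match.arg(effect_mode)
  if (n_events <= 0) stop("n_events must be > 0")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (base_cv <= 0) stop("base_cv must be > 0")
  cfg <- list(n_lines = n_lines, n_replicates = n_replicates,
              n_events = n_events, maf = maf, n_null_snps = n_null_snps,
              effect_mode = effect_mode, effect_size = effect_size,
              base_mean = base_mean, base_cv = base_cv, rep_noise = rep_noise,
              seed = as.integer(seed), chrom = chrom, tss = as.integer(tss),
              strand = strand, sample_config = sample_config)
  class(cfg) <- "sim_cohort_config"
  cfg
}

#' Simulate a mapping cohort
#'
#' Draws cohort genotypes and per-sample event tables under the design in a
#' [sim_cohort_config()]. Under `effect_mode = "dispersion"` the configured
#' per-line fluorescence mean is identical across genotype groups while the
#' log-scale SD is scaled by `effect_size^g` for allele count g.
#'
#' @param cfg `sim_cohort_config`
#' @param events if `FALSE`, skip event generation and return only genotypes
#'   and the truth record (used for large calibration sweeps where traits are
#'   derived directly from the truth parameters).
#' @return list with elements `genotypes` (a [genotype_matrix()]), `samples`
#'   (list of [event_table()], one per line x replicate; `NULL` when
#'   `events = FALSE`), and `truth` (causal SNP index/id, per-line genotype and
#'   true parameters, gene coordinates).
#' @export
simulate_cohort <- function(cfg, events = TRUE) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lines
  line_ids <- sprintf("L%03d", seq_len(n))
  g_causal <- stats::rbinom(n, 2, cfg$maf)
  mafs <- stats::runif(cfg$n_null_snps, 0.05, 0.5)
  g_null <- vapply(mafs, function(q) stats::rbinom(n, 2, q), numeric(n))
  p_var <- cfg$n_null_snps + 1L
  pos <- sort(sample.int(4000000L, p_var)) + cfg$tss - 2000000L
  causal_slot <- sample.int(p_var, 1)
  codes <- matrix(0, n, p_var)
  codes[, setdiff(seq_len(p_var), causal_slot)] <- g_null
  codes[, causal_slot] <- g_causal
  ids <- sprintf("snp%04d", seq_len(p_var))
  ids[causal_slot] <- "rs_causal"
  variants <- data.frame(chrom = cfg$chrom, pos = pos, id = ids,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  G <- genotype_matrix(line_ids, variants, codes)

  base_sd <- cfg$base_cv * cfg$base_mean
  g <- codes[, causal_slot]
  true_mean <- rep(cfg$base_mean, n)
  true_sd <- rep(base_sd, n)
  true_p1 <- rep(NA_real_, n)
  if (cfg$effect_mode == "dispersion") {
    true_sd <- base_sd * cfg$effect_size^g
  } else if (cfg$effect_mode == "mean") {
    true_mean <- cfg$base_mean + (cfg$effect_size - 1) * base_sd * g
  } else if (cfg$effect_mode == "bimodality") {
    true_p1 <- pmin(0.95, pmax(0.05, 0.3 + cfg$effect_size * g))
  }
  truth <- list(causal_index = causal_slot, causal_id = "rs_causal",
                gene = list(chrom = cfg$chrom, tss = cfg$tss, strand = cfg$strand),
                lines = data.frame(line_id = line_ids, genotype = g,
                                   true_mean = true_mean, true_sd = true_sd,
                                   true_p1 = true_p1, stringsAsFactors = FALSE))
  samples <- NULL
  if (events) {
    samples <- vector("list", n * cfg$n_replicates)
    k <- 0
    for (i in seq_len(n)) {
      for (r in seq_len(cfg$n_replicates)) {
        k <- k + 1
        scfg <- cfg$sample_config
        shift <- stats::rnorm(1, 0, cfg$rep_noise)
        if (cfg$effect_mode == "bimodality") {
          scfg$fl_components <- cbind(weight = c(true_p1[i], 1 - true_p1[i]),
                                      mean = c(cfg$base_mean - 1.5 * base_sd,
                                               cfg$base_mean + 1.5 * base_sd) + shift,
                                      sd = base_sd / 2)
        } else {
          scfg$fl_components <- cbind(weight = 1, mean = true_mean[i] + shift,
                                      sd = true_sd[i])
        }
        samples[[k]] <- simulate_sample_events(
          scfg, cfg$n_events, seed = NULL,
          sample_id = sprintf("%s_r%d", line_ids[i], r),
          line_id = line_ids[i], protein = "FL", replicate = r, batch = "set1")
      }
    }
  }
  list(genotypes = G, samples = samples, truth = truth)
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(len) {
  paste(sample(aa_alphabet, len, replace = TRUE), collapse = "")
}

#' Simulate a per-read CDR3 annotation table
#'
#' Emulates the post-annotation read table of a CDR3 amplicon clonality assay:
#' each clone is a unique CDR3 peptide, read counts are multinomial at the
#' stated clone frequencies, and a `noise` fraction of reads each violate at
#' least one downstream filter (CDR3 shorter than 5 aa, missing J-region
#' Phe/Trp-Gly-X-Gly motif, CDR3-not-found flag, missing VDJ frame, missing
#' top D gene, or a singleton clonotype).
#'
#' @param clone_freqs named numeric vector: CDR3 peptide -> frequency;
#'   frequencies must be non-negative and sum to <= 1. They are rescaled by
#'   `(1 - noise)`; the remaining mass becomes noise reads.
#' @param n_reads total reads.
#' @param noise fraction of reads that are invalid/singleton noise.
#' @param seed integer seed (`NULL` = current RNG state).
#' @param sample_id,replicate identifiers written into the table.
#' @return data.frame with columns `sample_id`, `replicate`, `cdr3_peptide`,
#'   `cdr3_found`, `vdj_frame`, `top_d_gene`, `j_region_aa`.
#' @export
simulate_cdr3_reads <- function(clone_freqs, n_reads, noise = 0, seed = NULL,
                                sample_id = "S1", replicate = 1L) {
  if (any(clone_freqs < 0)) stop("clone frequencies must be non-negative")
  if (sum(clone_freqs) > 1 + 1e-9) stop("clone frequencies must sum to <= 1")
  if (noise < 0 || noise >= 1) stop("noise must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  pep <- names(clone_freqs)
  if (is.null(pep)) stop("clone_freqs must be a named vector (peptide -> frequency)")
  p <- clone_freqs * (1 - noise)
  p_noise <- 1 - sum(p)
  counts <- stats::rmultinom(1, n_reads, c(p, p_noise))[, 1]
  n_noise <- counts[length(counts)]
  good_j <- "AKDYYGSGSYFDYWGQG"   # carries the [FW]-G-X-G motif
  rows <- list()
  if (any(counts[seq_along(pep)] > 0)) {
    rows[[1]] <- data.frame(
      cdr3_peptide = rep(pep, counts[seq_along(pep)]),
      cdr3_found = "found", vdj_frame = "In-frame",
      top_d_gene = "IGHD3-10*01", j_region_aa = good_j,
      stringsAsFactors = FALSE)
  }
  if (n_noise > 0) {
    type <- rep_len(c("short", "nomotif", "notfound", "noframe", "nod", "singleton"),
                    n_noise)
    noise_rows <- data.frame(
      cdr3_peptide = vapply(seq_len(n_noise), function(i)
        random_peptide(if (type[i] == "short") 3 else 8), character(1)),
      cdr3_found = ifelse(type == "notfound", "NOT_FOUND", "found"),
      vdj_frame = ifelse(type == "noframe", "N/A", "In-frame"),
      top_d_gene = ifelse(type == "nod", "N/A", "IGHD3-10*01"),
      j_region_aa = ifelse(type == "nomotif", "AAAAAAAAA", good_j),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- noise_rows
  }
  out <- do.call(rbind, rows)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  cbind(data.frame(sample_id = sample_id, replicate = as.integer(replicate),
                   stringsAsFactors = FALSE), out)
}

#' Synthetic per-replicate CD23 mixture-parameter table
#'
#' Builds a synthetic stand-in for a per-replicate table of two-component
#' Gaussian mixture parameters (p1, mu1, mu2, sigma1, sigma2) describing CD23
#' expression in 50 cell lines, 6 replicates each. Lines are planted in three
#' archetypes matching the qualitatively distinct distribution shapes seen in
#' such data: 3 lines with a low-expressing bulk and a right tail, 25 lines
#' with a high-expressing bulk and a left tail, and 22 clearly bimodal lines.
#' Used to exercise the averaging / z-scoring / complete-linkage clustering
#' layer; it is simulated data, not a measured table.
#'
#' @param seed integer seed.
#' @param n_replicates replicates per line.
#' @return data.frame with columns `line_id`, `replicate`, `cluster_truth`,
#'   `p1`, `mu1`, `mu2`, `sigma1`, `sigma2`.
#' @export
simulate_cd23_params <- function(seed = 20200703, n_replicates = 6) {
  set.seed(seed)
  arche <- data.frame(
    cluster = 1:3,
    n = c(3, 25, 22),
    p1 = c(0.88, 0.14, 0.45),
    mu1 = c(3.0, 3.4, 3.1),
    mu2 = c(4.6, 5.9, 5.7),
    sigma1 = c(0.35, 0.80, 0.40),
    sigma2 = c(0.90, 0.40, 0.45))
  rows <- list()
  line_no <- 0
  for (a in seq_len(nrow(arche))) {
    for (i in seq_len(arche$n[a])) {
      line_no <- line_no + 1
      # line-level biological jitter around the archetype
      lp <- c(p1 = min(0.97, max(0.03, arche$p1[a] + stats::rnorm(1, 0, 0.03))),
              mu1 = arche$mu1[a] + stats::rnorm(1, 0, 0.12),
              mu2 = arche$mu2[a] + stats::rnorm(1, 0, 0.12),
              sigma1 = max(0.05, arche$sigma1[a] + stats::rnorm(1, 0, 0.04)),
              sigma2 = max(0.05, arche$sigma2[a] + stats::rnorm(1, 0, 0.04)))
      rep_tab <- data.frame(
        line_id = sprintf("LCL%02d", line_no),
        replicate = seq_len(n_replicates),
        cluster_truth = arche$cluster[a],
        p1 = pmin(0.99, pmax(0.01, lp["p1"] + stats::rnorm(n_replicates, 0, 0.015))),
        mu1 = lp["mu1"] + stats::rnorm(n_replicates, 0, 0.06),
        mu2 = lp["mu2"] + stats::rnorm(n_replicates, 0, 0.06),
        sigma1 = pmax(0.02, lp["sigma1"] + stats::rnorm(n_replicates, 0, 0.02)),
        sigma2 = pmax(0.02, lp["sigma2"] + stats::rnorm(n_replicates, 0, 0.02)),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- rep_tab
    }
  }
  out <- do.call(rbind, rows)
  # shuffle line order so cluster recovery cannot ride on ordering
  out <- out[order(match(out$line_id, sample(unique(out$line_id)))), ]
  rownames(out) <- NULL
  out
}
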