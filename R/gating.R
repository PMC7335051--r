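#' Pooled saturation bounds for one channel
#'
#' Computes the lower/upper signal bounds of a channel as the 5th and 95th
#' percentiles of all single-event values pooled over the samples of a batch
#' (linear interpolation between order statistics). If the lower bound is
#' negative, a compensating shift equal to its absolute value is recorded;
#' applying the bounds then adds the shift so retained values are >= 0.
#'
#' @param samples list of [event_table()] from one batch.
#' @param channel channel name.
#' @param probs percentile pair, default `c(0.05, 0.95)`.
#' @return list of class `channel_bounds`: `channel`, `lower`, `upper`,
#'   `shift`.
#' @export
pooled_channel_bounds <- function(samples, channel, probs = c(0.05, 0.95)) {
  pool <- unlist(lapply(samples, function(s) s[[channel]]), use.names = FALSE)
  if (!length(pool)) stop("pooled_channel_bounds: empty pool")
  q <- stats::quantile(pool, probs, names = FALSE, type = 7)
  if (q[1] >= q[2]) stop("pooled_channel_bounds: degenerate bounds (constant channel?)")
  structure(list(channel = channel, lower = q[1], upper = q[2],
                 shift = if (q[1] < 0) abs(q[1]) else 0),
            class = "channel_bounds")
}

#' Remove saturated events and shift negative channels
#'
#' Retains exactly the events lying inside `[lower, upper]` (closed interval)
#' on every bounded channel, then adds each channel's shift so no retained
#' value is negative.
#'
#' @param sample [event_table()]
#' @param bounds list of `channel_bounds` covering the channels to filter.
#' @return filtered, shifted [event_table()]
#' @export
filter_saturated <- function(sample, bounds) {
  keep <- rep(TRUE, nrow(sample))
  for (b in bounds)
    keep <- keep & sample[[b$channel]] >= b$lower & sample[[b$channel]] <= b$upper
  out <- subset_events(sample, keep)
  for (b in bounds)
    if (b$shift > 0) out[[b$channel]] <- out[[b$channel]] + b$shift
  out
}

#' Threshold separating unstained events from DNA-stained events
#'
#' Finds the first peak-valley-peak motif of the kernel density of DAPI
#' intensities and returns the valley intensity; events below it are treated
#' as unstained. Signals a condition of class `no_valley` when the density has
#' no interior valley (unimodal DAPI), in which case callers skip the filter.
#'
#' @param dapi numeric vector of DAPI intensities.
#' @param bw kernel bandwidth (`stats::density` `bw` argument).
#' @return valley intensity (numeric scalar).
#' @export
dapi_stain_threshold <- function(dapi, bw = "nrd0") {
  d <- kde1d(dapi, bw = bw)
  # ignore tail micro-wiggles: a peak must carry real density and the valley
  # must be a genuine dip below the first peak
  peaks <- local_maxima(d$y)
  peaks <- peaks[d$y[peaks] >= 0.01 * max(d$y)]
  valleys <- local_minima(d$y)
  no_valley <- function(msg)
    stop(structure(class = c("no_valley", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  if (length(peaks) < 2 || !length(valleys))
    no_valley("no valley found in DAPI density")
  # first valley strictly between the first two peaks; an unstained
  # population sits below the main (stained) mode, so a valley at or right
  # of the global mode is the G1/G2 valley, not a stain boundary
  v <- valleys[valleys > peaks[1] & valleys < peaks[2]]
  v <- v[v < which.max(d$y) & d$y[v] < 0.9 * d$y[peaks[1]]]
  if (!length(v))
    no_valley("no valley found between the first two DAPI peaks")
  d$x[v[1]]
}

#' Dynamic two-dimensional density gate
#'
#' Builds the highest-density region of a 2-D Gaussian kernel density
#' estimate of the pooled events: the smallest density level set whose
#' contained pooled-event mass is at least `fraction`. The density is
#' evaluated on an `grid x grid` lattice; an event's density is the value at
#' its enclosing cell, and the level is the largest density value such that
#' the fraction of pooled events at or above it reaches `fraction`.
#'
#' @param pooled list of [event_table()] (a batch).
#' @param chX,chY channel names (e.g. `"FSC.A"`, `"SSC.A"`).
#' @param fraction target mass in (0, 1).
#' @param grid lattice size per axis.
#' @param max_kde cap on the number of events used to estimate the kernel
#'   density (a deterministic systematic subsample; the containment level is
#'   still computed from all pooled events). `kde2d` materializes a
#'   `grid x n` matrix, so the cap bounds memory on large batches.
#' @return object of class `gate_region`: grid, density, level, channels.
#' @export
density_gate_2d <- function(pooled, chX, chY, fraction, grid = 256,
                            max_kde = 50000) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  x <- unlist(lapply(pooled, function(s) s[[chX]]), use.names = FALSE)
  y <- unlist(lapply(pooled, function(s) s[[chY]]), use.names = FALSE)
  if (length(x) < 100) stop("density_gate_2d: need at least 100 pooled events")
  sub <- if (length(x) > max_kde)
    unique(round(seq(1, length(x), length.out = max_kde))) else seq_along(x)
  kd <- MASS::kde2d(x[sub], y[sub], n = grid,
                    lims = c(range(x), range(y)))
  dens <- gate_lookup_density(kd, x, y)
  # smallest level set with mass >= fraction
  level <- stats::quantile(dens, 1 - fraction, names = FALSE, type = 1)
  structure(list(kd = kd, level = level, fraction = fraction,
                 chX = chX, chY = chY),
            class = "gate_region")
}

# density value of (x, y) points on the kde2d lattice (nearest grid node);
# points outside the lattice range get density 0 (outside any region)
gate_lookup_density <- function(kd, x, y) {
  nx <- length(kd$x); ny <- length(kd$y)
  inside <- x >= kd$x[1] & x <= kd$x[nx] & y >= kd$y[1] & y <= kd$y[ny]
  out <- numeric(length(x))
  ix <- pmin(nx, pmax(1L, round((x - kd$x[1]) / (kd$x[2] - kd$x[1])) + 1L))
  iy <- pmin(ny, pmax(1L, round((y - kd$y[1]) / (kd$y[2] - kd$y[1])) + 1L))
  out[inside] <- kd$z[cbind(ix[inside], iy[inside])]
  out
}

#' @export
print.gate_region <- function(x, ...) {
  cat(sprintf("gate_region on (%s, %s): HDR at target mass %.2f, level %.3g\n",
              x$chX, x$chY, x$fraction, x$level))
  invisible(x)
}

#' Apply a 2-D density gate to a sample
#'
#' Retains the events whose (chX, chY) coordinates fall inside the gate's
#' density region (density at the event's lattice cell >= the gate level).
#'
#' @param sample [event_table()]
#' @param region [density_gate_2d()] result.
#' @return gated [event_table()]
#' @export
apply_gate <- function(sample, region) {
  dens <- gate_lookup_density(region$kd, sample[[region$chX]],
                              sample[[region$chY]])
  subset_events(sample, dens >= region$level)
}

#' G1 cell-cycle threshold from the DAPI density
#'
#' Locates the flattest point of the falling flank right of the global DAPI
#' density mode: the first interior point where the density's first
#' derivative returns to zero (the G1/G2 valley). For a unimodal population
#' the derivative only vanishes in the deep right tail, so effectively the
#' whole peak is retained. Cells with DAPI below the threshold are called G1.
#'
#' @param dapi numeric DAPI intensities of stained, gated events.
#' @param min_events minimum event count required.
#' @param bw kernel bandwidth.
#' @return threshold intensity.
#' @export
g1_threshold <- function(dapi, min_events = 100, bw = "nrd0") {
  if (length(dapi) < min_events)
    stop("g1_threshold: fewer than ", min_events, " events")
  d <- kde1d(dapi, bw = bw)
  mode_i <- which.max(d$y)
  dy <- diff(d$y)
  right <- seq(mode_i, length(dy))
  # first index right of the mode where the derivative stops being negative
  nonneg <- right[dy[right] >= 0]
  i <- if (length(nonneg)) nonneg[1] else length(dy)
  d$x[i + 1L]
}

#' Cell-size correction of fluorescence
#'
#' Fits `FL ~ log(FSC.A) + log(SSC.A)` per sample (Huber M-estimation by
#' default) and replaces each cell's value by `mean(FL) + residual`, removing
#' the size-driven component of the signal while preserving the sample mean.
#'
#' @param sample [event_table()] with positive scatter values; `FL` is a log
#'   intensity.
#' @param method `"huber"` (robust, default) or `"ls"` (ordinary least
#'   squares, under which the corrected mean equals the original mean
#'   exactly).
#' @return [event_table()] with corrected `FL`.
#' @export
size_correct <- function(sample, method = c("huber", "ls")) {
  method <- match.arg(method)
  lf <- log(sample$FSC.A); ls_ <- log(sample$SSC.A)
  if (any(!is.finite(lf)) || any(!is.finite(ls_)))
    stop("size_correct: FSC.A and SSC.A must be positive")
  if (stats::sd(lf) < 1e-12 || stats::sd(ls_) < 1e-12) {
    message("size_correct: constant scatter channel; no correction applied")
    return(sample)
  }
  y <- sample$FL
  res <- if (method == "huber") {
    fit <- MASS::rlm(y ~ lf + ls_, k = 1.345, maxit = 50, acc = 1e-8)
    stats::residuals(fit)
  } else {
    stats::residuals(stats::lm(y ~ lf + ls_))
  }
  sample$FL <- mean(y) + res
  sample
}

#' Align replicate fluorescence distributions by landmark warping
#'
#' Groups replicates of one cell line and protein, finds up to two primary
#' density landmarks (modes) of `FL` per sample, computes group-consensus
#' landmark positions (means of matched landmarks), and applies to each
#' sample a monotone piecewise-linear warp mapping its landmarks onto the
#' consensus. With a single shared landmark the warp degenerates to a shift.
#' If samples disagree on landmark count, alignment uses the shared leading
#' landmark only.
#'
#' @param group list of [event_table()] of the same line and protein.
#' @param k maximum landmarks per sample (1 or 2).
#' @return list of [event_table()] with warped `FL`.
#' @export
warp_align <- function(group, k = 2) {
  if (length(group) < 2) return(group)
  lmk <- lapply(group, function(s) density_landmarks(s$FL, k = k))
  n_lmk <- min(lengths(lmk))
  if (length(unique(lengths(lmk))) > 1)
    message("warp_align: landmark count differs across replicates; ",
            "aligning on the leading landmark")
  lmk <- lapply(lmk, function(v) v[seq_len(n_lmk)])
  consensus <- colMeans(do.call(rbind, lmk))
  lapply(seq_along(group), function(i) {
    s <- group[[i]]
    from <- lmk[[i]]
    if (n_lmk == 1) {
      s$FL <- s$FL + (consensus - from)
    } else {
      slope <- diff(consensus) / diff(from)
      if (slope <= 0) slope <- 1   # refuse a non-monotone warp
      # piecewise linear: interior segment between landmarks, slope-1 shifts
      # outside so rank order is always preserved
      fl <- s$FL
      out <- numeric(length(fl))
      lo <- fl <= from[1]; hi <- fl >= from[2]; mid <- !lo & !hi
      out[lo] <- fl[lo] + (consensus[1] - from[1])
      out[hi] <- fl[hi] + (consensus[2] - from[2])
      out[mid] <- consensus[1] + slope * (fl[mid] - from[1])
      s$FL <- out
    }
    s
  })
}

#' Replicate reproducibility score K and outlier flags
#'
#' For each sample in a replicate group of size >= 3, K is the mean
#' two-sample Kolmogorov-Smirnov statistic between its `FL` distribution and
#' each replicate partner. A sample is flagged as an outlier when its K
#' exceeds the 95th percentile of the pooled K scores (pooled over the batch
#' by the caller; by default over the group itself).
#'
#' @param group list of [event_table()] replicates (same line and protein).
#' @param pool_k optional numeric vector of K values defining the flagging
#'   pool; defaults to the group's own K scores.
#' @return data.frame with `sample_id`, `K`, `outlier`. Groups smaller than 3
#'   get `K = NA` and no flag.
#' @export
replicate_outlier_scores <- function(group, pool_k = NULL) {
  ids <- vapply(group, function(s) attr(s, "sample_id"), character(1))
  m <- length(group)
  if (m < 3) {
    message("replicate_outlier_scores: group of ", m,
            " replicates; K undefined")
    return(data.frame(sample_id = ids, K = NA_real_, outlier = FALSE))
  }
  ks <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    stat <- suppressWarnings(
      stats::ks.test(group[[i]]$FL, group[[j]]$FL)$statistic)
    ks[i, j] <- ks[j, i] <- unname(stat)
  }
  K <- rowSums(ks) / (m - 1)
  if (is.null(pool_k)) pool_k <- K
  cut <- stats::quantile(pool_k, 0.95, names = FALSE)
  data.frame(sample_id = ids, K = K, outlier = K > cut)
}

#' Gating configuration
#'
#' @param size_fraction,doublet_fraction target masses of the FSC-A/SSC-A and
#'   FSC-A/FSC-W density gates.
#' @param min_events samples with this many events or fewer after G1 gating
#'   are dropped.
#' @param saturation,dapi_filter,g1_gate,size_correction,warp,outlier_scores
#'   logical switches for the individual steps.
#' @param grid density-gate lattice size.
#' @return list of class `gating_config`.
#' @export
gating_config <- function(size_fraction = 0.75, doublet_fraction = 0.80,
                          min_events = 1000, saturation = TRUE,
                          dapi_filter = TRUE, g1_gate = TRUE,
                          size_correction = TRUE, warp = TRUE,
                          outlier_scores = TRUE, grid = 256) {
  structure(list(size_fraction = size_fraction,
                 doublet_fraction = doublet_fraction,
                 min_events = min_events, saturation = saturation,
                 dapi_filter = dapi_filter, g1_gate = g1_gate,
                 size_correction = size_correction, warp = warp,
                 outlier_scores = outlier_scores, grid = grid),
            class = "gating_config")
}

#' Run the full gating pipeline
#'
#' Applies, independently within each batch: (i) pooled 5th/95th-percentile
#' saturation bounds on every channel, (ii) negative-bound shifts, (iii)
#' removal of unstained DAPI events below the first density valley, (iv) a
#' dynamic density gate containing `size_fraction` of pooled events in the
#' FSC-A/SSC-A plane, (v) a `doublet_fraction` gate in the FSC-A/FSC-W plane,
#' (vi) per-sample G1 selection on DAPI, (vii) removal of samples with
#' `min_events` or fewer events, (viii) per-sample cell-size correction of
#' FL, (ix) landmark warping of replicate groups (same line and protein), and
#' (x) replicate-outlier K scores with flags against the batch-level 95th
#' percentile.
#'
#' @param samples list of [event_table()] carrying line/protein/replicate/
#'   batch metadata.
#' @param config [gating_config()]
#' @return list with `samples` (retained, processed event tables) and
#'   `report` (a `qc_report` data.frame: one row per input sample with
#'   per-step retained event counts, K, outlier and drop reason).
#' @export
run_gating <- function(samples, config = gating_config()) {
  batches <- split(seq_along(samples),
                   vapply(samples, function(s) attr(s, "batch"), character(1)))
  kept_all <- list(); report_all <- list()
  for (bi in batches) {
    bs <- samples[bi]
    rep_rows <- data.frame(
      sample_id = vapply(bs, function(s) attr(s, "sample_id"), character(1)),
      batch = attr(bs[[1]], "batch"),
      n_input = vapply(bs, nrow, integer(1)),
      n_saturation = NA_integer_, n_dapi = NA_integer_, n_size = NA_integer_,
      n_doublet = NA_integer_, n_g1 = NA_integer_,
      K = NA_real_, outlier = FALSE, dropped = "", stringsAsFactors = FALSE)
    channels <- c("FSC.A", "SSC.A", "FSC.W", "DAPI", "FL")
    # (i)-(ii) saturation bounds, pooled per batch
    if (config$saturation) {
      bounds <- lapply(channels, function(ch) pooled_channel_bounds(bs, ch))
      bs <- lapply(bs, filter_saturated, bounds = bounds)
    }
    rep_rows$n_saturation <- vapply(bs, nrow, integer(1))
    # (iii) unstained DAPI events, threshold from the pooled density
    if (config$dapi_filter) {
      thr <- tryCatch(
        dapi_stain_threshold(unlist(lapply(bs, `[[`, "DAPI"), use.names = FALSE)),
        no_valley = function(e) {
          message("run_gating: ", conditionMessage(e), "; skipping DAPI filter")
          NULL
        })
      if (!is.null(thr))
        bs <- lapply(bs, function(s) subset_events(s, s$DAPI > thr))
    }
    rep_rows$n_dapi <- vapply(bs, nrow, integer(1))
    # (iv) cell-size gate
    g_size <- density_gate_2d(bs, "FSC.A", "SSC.A", config$size_fraction,
                              grid = config$grid)
    bs <- lapply(bs, apply_gate, region = g_size)
    rep_rows$n_size <- vapply(bs, nrow, integer(1))
    # (v) doublet gate
    g_dbl <- density_gate_2d(bs, "FSC.A", "FSC.W", config$doublet_fraction,
                             grid = config$grid)
    bs <- lapply(bs, apply_gate, region = g_dbl)
    rep_rows$n_doublet <- vapply(bs, nrow, integer(1))
    # (vi) per-sample G1 gate
    if (config$g1_gate) {
      bs <- lapply(bs, function(s) {
        thr <- tryCatch(g1_threshold(s$DAPI), error = function(e) Inf)
        subset_events(s, s$DAPI < thr)
      })
    }
    rep_rows$n_g1 <- vapply(bs, nrow, integer(1))
    # (vii) min-events sample drop
    ok <- rep_rows$n_g1 > config$min_events
    rep_rows$dropped[!ok] <- "min-events"
    bs <- bs[ok]
    # (viii) size correction
    if (config$size_correction) bs <- lapply(bs, size_correct)
    # (ix) warp replicate groups
    grp_key <- vapply(bs, function(s)
      paste(attr(s, "line_id"), attr(s, "protein"), sep = "|"), character(1))
    if (config$warp && length(bs)) {
      for (g in unique(grp_key)) {
        idx <- which(grp_key == g)
        bs[idx] <- warp_align(bs[idx])
      }
    }
    # (x) K scores, batch-level 95th percentile
    if (config$outlier_scores && length(bs)) {
      scores <- lapply(unique(grp_key), function(g)
        suppressMessages(replicate_outlier_scores(bs[grp_key == g])))
      pool <- unlist(lapply(scores, `[[`, "K"))
      pool <- pool[!is.na(pool)]
      for (sc in scores) {
        for (r in seq_len(nrow(sc))) {
          i <- match(sc$sample_id[r], rep_rows$sample_id)
          rep_rows$K[i] <- sc$K[r]
          rep_rows$outlier[i] <- !is.na(sc$K[r]) && length(pool) > 0 &&
            sc$K[r] > stats::quantile(pool, 0.95, names = FALSE)
        }
      }
    }
    kept_all <- c(kept_all, bs)
    report_all[[length(report_all) + 1]] <- rep_rows
  }
  report <- do.call(rbind, report_all)
  class(report) <- c("qc_report", "data.frame")
  list(samples = kept_all, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d dropped, %d outlier-flagged\n",
              nrow(x), sum(nzchar(x$dropped)), sum(x$outlier, na.rm = TRUE)))
  NextMethod()
}
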