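#' Per-sample expression summary
#'
#' Mean, sample SD (n-1 denominator) and coefficient of variation
#' (CV = sd/mean) of a sample's processed log-intensity values.
#'
#' @param fl numeric vector of log intensities (finite, mean > 0).
#' @param meta optional list with `sample_id`, `line_id`, `protein`,
#'   `replicate` (as produced by an [event_table()]'s metadata).
#' @return one-row data.frame: identifiers, `n_cells`, `mean`, `sd`, `cv`.
#' @export
sample_summary <- function(fl, meta = NULL) {
  if (length(fl) < 2) stop("sample_summary: need at least 2 cells")
  if (!all(is.finite(fl))) stop("sample_summary: non-finite values")
  m <- mean(fl)
  if (m <= 0) stop("sample_summary: mean <= 0 invalidates CV on this scale")
  s <- stats::sd(fl)
  data.frame(sample_id = meta$sample_id %||% NA_character_,
             line_id = meta$line_id %||% NA_character_,
             protein = meta$protein %||% NA_character_,
             replicate = meta$replicate %||% NA_integer_,
             n_cells = length(fl), mean = m, sd = s, cv = s / m,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a list of gated event tables
#'
#' @param samples list of [event_table()]
#' @param report optional `qc_report` from [run_gating()]; when given, K and
#'   outlier flags are joined in.
#' @return data.frame of per-sample summaries.
#' @export
summarize_samples <- function(samples, report = NULL) {
  out <- do.call(rbind, lapply(samples, function(s)
    sample_summary(s$FL, meta_of(s))))
  if (!is.null(report)) {
    i <- match(out$sample_id, report$sample_id)
    out$K <- report$K[i]
    out$outlier <- report$outlier[i]
  }
  out
}

#' Locally-weighted trend of CV on mean
#'
#' Fits a lowess regression of per-sample CV on per-sample mean over all
#' samples of one protein (and batch). The returned evaluator predicts the
#' trend CV at any mean; outside the fitted range it extrapolates to the
#' nearest endpoint (and flags it).
#'
#' @param summaries data.frame from [summarize_samples()].
#' @param protein optional protein name to subset on.
#' @param span lowess smoother span.
#' @param iter robustness iterations.
#' @return object of class `cv_mean_trend` with a [predict()] method.
#' @export
fit_cv_mean_trend <- function(summaries, protein = NULL, span = 0.75, iter = 3) {
  if (!is.null(protein)) summaries <- summaries[summaries$protein == protein, ]
  if (nrow(summaries) < 10)
    stop("fit_cv_mean_trend: need at least 10 samples")
  fit <- stats::lowess(summaries$mean, summaries$cv, f = span, iter = iter)
  structure(list(x = fit$x, y = fit$y, span = span, iter = iter,
                 protein = protein, range = range(summaries$mean)),
            class = "cv_mean_trend")
}

#' @param object `cv_mean_trend`
#' @param newmean numeric means at which to evaluate the trend.
#' @param ... unused.
#' @rdname fit_cv_mean_trend
#' @export
predict.cv_mean_trend <- function(object, newmean, ...) {
  stats::approx(object$x, object$y, xout = newmean, rule = 2, ties = mean)$y
}

#' @export
print.cv_mean_trend <- function(x, ...) {
  cat(sprintf("cv_mean_trend%s: lowess span %.2f over mean range [%.3g, %.3g]\n",
              if (is.null(x$protein)) "" else paste0(" (", x$protein, ")"),
              x$span, x$range[1], x$range[2]))
  invisible(x)
}

#' Mean-conditioned CV (expression dispersion)
#'
#' Adds `cv_given_mean = cv - trend(mean)` to a summary table: the residual
#' dispersion after removing the fitted CV-mean dependency. Samples whose
#' mean lies outside the trend's fitted range are extrapolated to the nearest
#' endpoint and flagged in `extrapolated`.
#'
#' @param summaries data.frame with `mean` and `cv` columns.
#' @param trend [fit_cv_mean_trend()] result.
#' @return `summaries` with columns `cv_given_mean` and `extrapolated`.
#' @export
dispersion_residuals <- function(summaries, trend) {
  summaries$cv_given_mean <- summaries$cv - predict(trend, summaries$mean)
  summaries$extrapolated <- summaries$mean < trend$range[1] |
    summaries$mean > trend$range[2]
  summaries
}

#' Average per-sample statistics per cell line
#'
#' Arithmetic mean (and s.e.m.) across replicates of each numeric statistic,
#' excluding outlier-flagged samples. Lines with no retained samples are
#' dropped with a message.
#'
#' @param per_sample data.frame with `line_id`, numeric statistic columns and
#'   optionally `outlier`.
#' @param stats_cols columns to average; defaults to all numeric columns
#'   except counts/flags.
#' @return data.frame with one row per line: `<stat>` means, `<stat>_sem`,
#'   and `n_reps`.
#' @export
line_average <- function(per_sample,
                         stats_cols = setdiff(names(per_sample)[vapply(per_sample, is.numeric, logical(1))],
                                              c("replicate", "n_cells", "outlier"))) {
  if (!is.null(per_sample$outlier)) {
    drop <- !is.na(per_sample$outlier) & per_sample$outlier
    per_sample <- per_sample[!drop, , drop = FALSE]
  }
  empty <- setdiff(unique(per_sample$line_id), per_sample$line_id)
  if (length(empty))
    message("line_average: lines with no retained samples dropped: ",
            paste(empty, collapse = ", "))
  agg <- lapply(split(per_sample, per_sample$line_id), function(d) {
    out <- data.frame(line_id = d$line_id[1], n_reps = nrow(d),
                      stringsAsFactors = FALSE)
    for (cn in stats_cols) {
      out[[cn]] <- mean(d[[cn]])
      out[[paste0(cn, "_sem")]] <- stats::sd(d[[cn]]) / sqrt(nrow(d))
    }
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Cluster cell lines on averaged parameters
#'
#' Z-scores each parameter column across lines (center 0, scale 1),
#' agglomerates with complete linkage on Euclidean distance and cuts the
#' dendrogram into `k` clusters.
#'
#' @param param_table data.frame with `line_id` and parameter columns.
#' @param k number of clusters.
#' @param cols parameter columns; defaults to all numeric columns except
#'   `n_reps` and `_sem` columns.
#' @param drop_constant drop zero-variance columns instead of erroring.
#' @return list of class `line_clusters`: `scaled` matrix, `hclust` tree,
#'   `labels` (named cluster vector), `k`.
#' @export
cluster_lines <- function(param_table, k,
                          cols = NULL, drop_constant = FALSE) {
  if (is.null(cols)) {
    num <- names(param_table)[vapply(param_table, is.numeric, logical(1))]
    cols <- setdiff(num[!grepl("_sem$", num)], c("n_reps", "replicate"))
  }
  if (nrow(param_table) < k) stop("cluster_lines: fewer lines than clusters")
  m <- as.matrix(param_table[, cols, drop = FALSE])
  rownames(m) <- param_table$line_id
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    if (!drop_constant) stop("cluster_lines: constant parameter column(s): ",
                             paste(cols[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  hc <- stats::hclust(stats::dist(z), method = "complete")
  labels <- stats::cutree(hc, k = k)
  structure(list(scaled = z, hclust = hc, labels = labels, k = k),
            class = "line_clusters")
}

#' @export
print.line_clusters <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("line_clusters: %d lines in %d clusters (sizes %s)\n",
              length(x$labels), x$k, paste(sizes, collapse = "/")))
  invisible(x)
}

#' @export
plot.line_clusters <- function(x, ...) {
  plot(x$hclust, main = "Complete-linkage clustering of cell lines",
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Kruskal-Wallis rank-sum test across lines
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected H
#' statistic and the chi-square p-value on (groups - 1) df.
#'
#' @param values_by_line list of numeric vectors (one per line).
#' @return named numeric: `H`, `p`.
#' @export
kruskal_wallis <- function(values_by_line) {
  if (length(values_by_line) < 2) stop("kruskal_wallis: need >= 2 groups")
  kt <- stats::kruskal.test(values_by_line)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Pairwise Spearman correlation of dispersion across proteins
#'
#' Computes, for each protein pair, Spearman's rho (with two-sided p) of the
#' per-line averaged dispersion values over the lines measured for both.
#' Pairs sharing fewer than `min_lines` lines are left `NA` with a message.
#'
#' @param per_line data.frame with `line_id`, `protein` and a `value` column.
#' @param value name of the value column (default `"cv_given_mean"`).
#' @param min_lines minimum shared lines.
#' @return list with matrices `rho`, `p`, `n` (proteins x proteins).
#' @export
spearman_pairs <- function(per_line, value = "cv_given_mean", min_lines = 5) {
  prot <- sort(unique(per_line$protein))
  np <- length(prot)
  rho <- p <- n <- matrix(NA_real_, np, np, dimnames = list(prot, prot))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    a <- per_line[per_line$protein == prot[i], c("line_id", value)]
    b <- per_line[per_line$protein == prot[j], c("line_id", value)]
    m <- merge(a, b, by = "line_id")
    n[i, j] <- nrow(m)
    if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
    if (nrow(m) < min_lines) {
      message("spearman_pairs: fewer than ", min_lines, " shared lines for ",
              prot[i], "/", prot[j])
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(m[[2]], m[[3]], method = "spearman", exact = FALSE))
    rho[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p, n = n)
}

#' Two-sample t-test on replicate-level statistics
#'
#' Welch by default; set `pooled = TRUE` for the equal-variance variant.
#'
#' @param repsA,repsB numeric vectors of replicate-level values (>= 2 each).
#' @param pooled use the pooled-variance (classic) t-test.
#' @return two-sided p-value.
#' @export
ttest_pair <- function(repsA, repsB, pooled = FALSE) {
  if (length(repsA) < 2 || length(repsB) < 2)
    stop("ttest_pair: need >= 2 replicates per line")
  stats::t.test(repsA, repsB, var.equal = pooled)$p.value
}
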