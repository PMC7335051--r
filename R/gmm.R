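#' Two-component Gaussian mixture fit
#'
#' Expectation-maximization for a univariate two-component Gaussian mixture
#' with unequal variances and free mixing weight — the five-parameter
#' description (p1, mu1, mu2, sigma^2_1, sigma^2_2) of a possibly bimodal
#' expression distribution. Runs a deterministic quantile-split
#' initialization plus `n_restarts` random restarts and keeps the best
#' log-likelihood; components are relabeled so that `mu1 <= mu2` (p1 is the
#' weight of the lower-mean component). A variance floor of
#' `1e-6 * var(x)` guards against degenerate single-point components; a
#' restart that still degenerates is discarded.
#'
#' @param fl numeric vector of (log-scale) expression values, `n >= 100`.
#' @param seed integer seed for the random restarts (`NULL`: current RNG).
#' @param n_restarts number of random restarts in addition to the
#'   quantile-split start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @return object of class `gmm2`: `p1`, `mu1`, `mu2`, `var1`, `var2`,
#'   `loglik`, `converged`, `n`, `iters`.
#' @export
fit_gmm2 <- function(fl, seed = NULL, n_restarts = 5, tol = 1e-8,
                     max_iter = 500) {
  if (length(fl) < 100) stop("fit_gmm2: need n >= 100")
  if (!is.null(seed)) set.seed(seed)
  v <- stats::var(fl)
  floor_var <- 1e-6 * v
  starts <- list(quantile_split_start(fl))
  for (r in seq_len(n_restarts)) {
    mu <- sort(sample(fl, 2))
    starts[[r + 1]] <- list(p1 = stats::runif(1, 0.2, 0.8),
                            mu = mu, var = c(v, v) / 4)
  }
  best <- NULL
  for (st in starts) {
    fit <- em_gmm2(fl, st, floor_var, tol, max_iter)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("fit_gmm2: all starts degenerated")
  # label components by ascending mean
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$var <- rev(best$var)
    best$p1 <- 1 - best$p1
  }
  structure(list(p1 = best$p1, mu1 = best$mu[1], mu2 = best$mu[2],
                 var1 = best$var[1], var2 = best$var[2],
                 loglik = best$loglik, converged = best$converged,
                 n = length(fl), iters = best$iters),
            class = "gmm2")
}

quantile_split_start <- function(x) {
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  list(p1 = 0.5, mu = c(mean(lo), mean(hi)),
       var = c(max(stats::var(lo), 1e-8), max(stats::var(hi), 1e-8)))
}

em_gmm2 <- function(x, st, floor_var, tol, max_iter) {
  p1 <- st$p1; mu <- st$mu; va <- st$var
  ll_old <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    d1 <- p1 * stats::dnorm(x, mu[1], sqrt(va[1]))
    d2 <- (1 - p1) * stats::dnorm(x, mu[2], sqrt(va[2]))
    tot <- d1 + d2
    if (any(tot == 0)) tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)   # component vanished
    p1 <- n1 / length(x)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    va <- c(sum(g1 * (x - mu[1])^2) / n1, sum((1 - g1) * (x - mu[2])^2) / n2)
    if (any(va < floor_var)) return(NULL)      # degenerate spike
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(p1 = p1, mu = mu, var = va, loglik = ll, converged = converged,
       iters = it)
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf(
    "gmm2 fit (n = %d): p1 = %.3f, mu = (%.3f, %.3f), sd = (%.3f, %.3f)\n",
    x$n, x$p1, x$mu1, x$mu2, sqrt(x$var1), sqrt(x$var2)))
  cat(sprintf("  loglik %.2f, %s in %d iterations\n", x$loglik,
              if (x$converged) "converged" else "not converged", x$iters))
  invisible(x)
}

#' @export
logLik.gmm2 <- function(object, ...) {
  structure(object$loglik, df = 5, nobs = object$n, class = "logLik")
}

#' Mixture density of a fitted gmm2
#' @param x `gmm2` fit
#' @param at numeric values at which to evaluate the density
#' @return numeric densities
#' @export
gmm2_density <- function(x, at) {
  x$p1 * stats::dnorm(at, x$mu1, sqrt(x$var1)) +
    (1 - x$p1) * stats::dnorm(at, x$mu2, sqrt(x$var2))
}

#' @export
plot.gmm2 <- function(x, data = NULL, ...) {
  if (!is.null(data)) {
    graphics::hist(data, breaks = 60, freq = FALSE,
                   main = "Two-component Gaussian mixture", xlab = "log intensity", ...)
    at <- seq(min(data), max(data), length.out = 400)
  } else {
    at <- seq(x$mu1 - 4 * sqrt(x$var1), x$mu2 + 4 * sqrt(x$var2),
              length.out = 400)
    plot(at, gmm2_density(x, at), type = "n",
         main = "Two-component Gaussian mixture",
         xlab = "log intensity", ylab = "density", ...)
  }
  graphics::lines(at, x$p1 * stats::dnorm(at, x$mu1, sqrt(x$var1)), col = 2)
  graphics::lines(at, (1 - x$p1) * stats::dnorm(at, x$mu2, sqrt(x$var2)), col = 4)
  graphics::lines(at, gmm2_density(x, at), col = 1, lwd = 2)
  invisible(x)
}

#' Draw samples from a fitted gmm2
#' @param object `gmm2` fit
#' @param nsim number of draws
#' @param seed optional seed
#' @param ... unused
#' @export
simulate.gmm2 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- stats::rbinom(nsim, 1, 1 - object$p1)
  stats::rnorm(nsim,
               ifelse(comp == 0, object$mu1, object$mu2),
               ifelse(comp == 0, sqrt(object$var1), sqrt(object$var2)))
}

#' Fit the five mixture parameters to every sample of a protein
#'
#' @param samples list of gated [event_table()]
#' @param seed base seed; sample i uses `seed + i`.
#' @param ... passed to [fit_gmm2()]
#' @return data.frame: sample metadata plus `p1`, `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `loglik`, `converged`.
#' @export
fit_gmm2_samples <- function(samples, seed = 1L, ...) {
  do.call(rbind, lapply(seq_along(samples), function(i) {
    f <- fit_gmm2(samples[[i]]$FL, seed = seed + i, ...)
    m <- meta_of(samples[[i]])
    data.frame(sample_id = m$sample_id, line_id = m$line_id,
               protein = m$protein, replicate = m$replicate,
               p1 = f$p1, mu1 = f$mu1, mu2 = f$mu2,
               sigma1 = sqrt(f$var1), sigma2 = sqrt(f$var2),
               loglik = f$loglik, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
}
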