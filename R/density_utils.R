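# Kernel-density helpers shared by the gating steps. Gaussian kernel with
# Silverman's bandwidth unless the caller overrides; peaks/valleys are local
# extrema of the density evaluated on a regular grid.

kde1d <- function(x, bw = "nrd0", n = 512) {
  stats::density(x, bw = bw, n = n)
}

# indices of local maxima / minima of a numeric vector
local_maxima <- function(y) {
  d <- diff(y)
  s <- sign(d)
  # collapse flat stretches so plateaus count once
  which(diff(s) < 0) + 1L
}

local_minima <- function(y) {
  which(diff(sign(diff(y))) > 0) + 1L
}

# mode (grid x of highest density)
density_mode <- function(x, bw = "nrd0") {
  d <- kde1d(x, bw = bw)
  d$x[which.max(d$y)]
}

# up to k most prominent density modes, in ascending x order.
# Prominence is the peak height relative to the highest peak; peaks below
# `min_prom` of the maximum are ignored (shoulders, tail wiggles).
density_landmarks <- function(x, k = 2, bw = "nrd0", min_prom = 0.2) {
  d <- kde1d(x, bw = bw)
  pk <- local_maxima(d$y)
  if (!length(pk)) return(d$x[which.max(d$y)])
  keep <- pk[d$y[pk] >= min_prom * max(d$y[pk])]
  if (!length(keep)) keep <- pk[which.max(d$y[pk])]
  if (length(keep) > k)
    keep <- sort(keep[order(d$y[keep], decreasing = TRUE)[seq_len(k)]])
  sort(d$x[keep])
}
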