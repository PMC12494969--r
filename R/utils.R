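#' Discrete Gaussian smoothing kernel
#'
#' Builds a normalized Gaussian kernel sampled at integer offsets. The kernel
#' is truncated at `radius = max(1, ceiling(4 * sd))` samples, matching the
#' usual truncation of Gaussian filters at four standard deviations.
#'
#' @param sd Kernel standard deviation in samples (> 0).
#' @return Numeric vector of odd length summing to 1.
#' @keywords internal
gaussian_kernel <- function(sd) {
  stopifnot(is.numeric(sd), length(sd) == 1L, sd > 0)
  radius <- max(1L, ceiling(4 * sd))
  k <- exp(-0.5 * ((-radius:radius) / sd)^2)
  k / sum(k)
}

#' Smooth a vector with a Gaussian filter
#'
#' Convolves `x` with a normalized Gaussian kernel. Edge handling is either
#' reflect padding (default; appropriate for within-trial vectors with no
#' circular continuity) or circular wrapping.
#'
#' @param x Numeric vector.
#' @param sd Kernel standard deviation in samples. `sd <= 0` returns `x`.
#' @param edge `"reflect"` or `"wrap"`.
#' @return Smoothed vector, same length as `x`. The kernel is normalized so a
#'   constant vector is unchanged and total mass is preserved up to edge
#'   effects.
#' @export
gaussian_smooth <- function(x, sd, edge = c("reflect", "wrap")) {
  edge <- match.arg(edge)
  if (sd <= 0) return(x)
  n <- length(x)
  if (n <= 1L) return(x)
  k <- gaussian_kernel(sd)
  radius <- (length(k) - 1L) %/% 2L
  if (edge == "reflect") {
    ii <- seq.int(1L - radius, n + radius)
    # reflect about the boundary samples until inside [1, n]
    while (any(bad <- ii < 1L | ii > n)) {
      ii[ii < 1L] <- 2L - ii[ii < 1L]
      ii[ii > n] <- 2L * n - ii[ii > n]
    }
    xp <- x[ii]
  } else {
    reps <- ceiling(radius / n)
    xp <- c(rep(x, reps), x, rep(x, reps))
    xp <- xp[(reps * n - radius + 1L):(reps * n + n + radius)]
  }
  if (as.numeric(length(xp)) * length(k) > 5e5) {
    # FFT convolution for long series / wide kernels
    m <- length(xp) + length(k) - 1L
    nf <- stats::nextn(m, 2L)
    conv <- Re(stats::fft(stats::fft(c(xp, numeric(nf - length(xp)))) *
                            stats::fft(c(k, numeric(nf - length(k)))),
                          inverse = TRUE)) / nf
    full <- conv[seq_len(m)]
    as.numeric(full[(2L * radius + 1L):(2L * radius + n)])
  } else {
    out <- stats::filter(xp, k, method = "convolution", sides = 2L)
    as.numeric(out[(radius + 1L):(radius + n)])
  }
}

#' Linearly interpolate missing values in a vector
#'
#' NA runs are replaced by linear interpolation between the nearest finite
#' neighbors; leading/trailing NAs take the nearest finite value. Returns the
#' input unchanged when nothing is finite.
#' @param x Numeric vector.
#' @return Vector with NAs filled where possible.
#' @keywords internal
interp_na <- function(x) {
  ok <- is.finite(x)
  if (all(ok) || !any(ok)) return(x)
  idx <- seq_along(x)
  stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
}

#' Locate peaks with prominence and width
#'
#' Finds local maxima of a signal and computes, for each, its prominence
#' (height above the higher of the two flanking valleys, where each valley is
#' the minimum between the peak and the nearest higher point or signal edge)
#' and its width measured at `peak height - rel_height * prominence` by linear
#' interpolation, within the peak's bases. This mirrors the standard
#' peak-detection conventions of scientific signal-processing libraries so
#' that height/prominence/width thresholds carry their usual meaning.
#'
#' Plateau maxima are reported at the (left-rounded) plateau midpoint.
#'
#' @param x Numeric vector (the signal).
#' @param height Minimum peak height (strictly greater than). `-Inf` keeps all.
#' @param prominence Minimum prominence (strictly greater than).
#' @param width Minimum width in samples (strictly greater than).
#' @param rel_height Fraction of prominence below the peak at which width is
#'   measured (default 0.5).
#' @return data.frame with columns `index` (1-based sample), `height`,
#'   `prominence`, `width` (samples); zero rows when no peak qualifies.
#' @export
find_peaks <- function(x, height = -Inf, prominence = 0, width = 0,
                       rel_height = 0.5) {
  n <- length(x)
  out0 <- data.frame(index = integer(0), height = numeric(0),
                     prominence = numeric(0), width = numeric(0))
  if (n < 3L) return(out0)
  x[!is.finite(x)] <- -Inf
  # candidate local maxima, plateau-aware
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        idx <- c(idx, (i + j) %/% 2L)
        i <- j + 1L
        next
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  if (!length(idx)) return(out0)

  res <- lapply(idx, function(p) {
    h <- x[p]
    # left base: minimum between p and nearest strictly-higher sample (or edge)
    li <- p
    lmin <- h
    lbase <- p
    while (li > 1L) {
      li <- li - 1L
      if (x[li] > h) break
      if (x[li] < lmin) {
        lmin <- x[li]
        lbase <- li
      }
    }
    ri <- p
    rmin <- h
    rbase <- p
    while (ri < n) {
      ri <- ri + 1L
      if (x[ri] > h) break
      if (x[ri] < rmin) {
        rmin <- x[ri]
        rbase <- ri
      }
    }
    prom <- h - max(lmin, rmin)
    # width at evaluation height, interpolated within [lbase, rbase]
    wh <- h - rel_height * prom
    wl <- p
    while (wl > lbase && x[wl - 1L] > wh) wl <- wl - 1L
    left_pos <- if (wl > lbase && x[wl - 1L] <= wh) {
      (wl - 1L) + (wh - x[wl - 1L]) / (x[wl] - x[wl - 1L])
    } else as.numeric(wl)
    wr <- p
    while (wr < rbase && x[wr + 1L] > wh) wr <- wr + 1L
    right_pos <- if (wr < rbase && x[wr + 1L] <= wh) {
      wr + (x[wr] - wh) / (x[wr] - x[wr + 1L])
    } else as.numeric(wr)
    c(p, h, prom, right_pos - left_pos)
  })
  res <- do.call(rbind, res)
  out <- data.frame(index = as.integer(res[, 1L]), height = res[, 2L],
                    prominence = res[, 3L], width = res[, 4L])
  out[out$height > height & out$prominence > prominence & out$width > width, ,
      drop = FALSE]
}

#' Prominence of the signal at a given sample
#'
#' Prominence of `x[index]` using the same contour rule as [find_peaks()],
#' defined for any sample (also edge or non-peak samples, where flanking
#' contours are truncated at the signal boundaries). A flat signal has
#' prominence 0 everywhere.
#' @param x Numeric vector.
#' @param index Sample at which to evaluate.
#' @return Non-negative scalar.
#' @export
prominence_at <- function(x, index) {
  n <- length(x)
  stopifnot(index >= 1L, index <= n)
  h <- x[index]
  lmin <- h
  i <- index
  while (i > 1L) {
    i <- i - 1L
    if (x[i] > h) break
    lmin <- min(lmin, x[i])
  }
  rmin <- h
  i <- index
  while (i < n) {
    i <- i + 1L
    if (x[i] > h) break
    rmin <- min(rmin, x[i])
  }
  max(0, h - max(lmin, rmin))
}

#' Percentile with linear interpolation between order statistics
#'
#' @param x Numeric vector.
#' @param p Probability in \[0, 1\].
#' @return The p-th quantile (type 7: linear interpolation), the convention
#'   used for all shuffle-null thresholds in this package.
#' @keywords internal
percentile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, na.rm = TRUE))
}

#' Pearson correlation that returns NA instead of erroring on zero variance
#' @keywords internal
safe_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]
  b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Pearson correlation within groups, computed from grouped moments
#'
#' Vectorized per-group correlation: sums of x, y, x^2, y^2 and x*y are
#' aggregated by group with one pass, giving the same result as calling
#' `cor()` on each group's rows. Groups with fewer than 2 samples or zero
#' variance yield `NA`.
#'
#' @param x,y Numeric vectors.
#' @param g Integer group index per sample (1..n_groups).
#' @param n_groups Number of groups.
#' @return Numeric vector of per-group correlations.
#' @keywords internal
grouped_pearson <- function(x, y, g, n_groups) {
  n <- tabulate(g, n_groups)
  sx <- rowsum_vec(x, g, n_groups)
  sy <- rowsum_vec(y, g, n_groups)
  sxx <- rowsum_vec(x * x, g, n_groups)
  syy <- rowsum_vec(y * y, g, n_groups)
  sxy <- rowsum_vec(x * y, g, n_groups)
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  out <- (n * sxy - sx * sy) / sqrt(vx * vy)
  out[n < 2L | vx <= 0 | vy <= 0] <- NA_real_
  out
}

rowsum_vec <- function(x, g, n_groups) {
  out <- numeric(n_groups)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Derive a child RNG seed from a base seed
#'
#' Deterministic stream splitting that keeps derived seeds inside the 32-bit
#' integer range.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483562) + 1L
}
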