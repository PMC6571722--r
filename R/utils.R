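# numerically-safe log(sum(exp(x))), ignoring -Inf padding
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Locate local maxima of a sampled curve
#'
#' Interior grid points exceeding both neighbours after optional
#' moving-average smoothing.  Each peak is reported with its topographic
#' prominence: the height above the higher of the two valley floors
#' separating it from higher terrain (or from the curve ends).
#'
#' @param x abscissa grid (monotone).
#' @param y ordinate values.
#' @param smooth_window odd moving-average window in grid points (0 or 1
#'   disables smoothing).
#' @param min_prominence report only peaks at least this prominent.
#' @return data.frame with columns `index`, `x`, `y`, `prominence`.
#' @export
find_peaks <- function(x, y, smooth_window = 0, min_prominence = 0) {
  n <- length(y)
  if (n < 3) stop("grid too short: need at least 3 points")
  ys <- y
  if (smooth_window > 1) {
    w <- as.integer(smooth_window)
    if (w %% 2 == 0) w <- w + 1L
    k <- rep(1 / w, w)
    ys <- as.numeric(stats::filter(y, k, sides = 2))
    # keep curve ends unsmoothed rather than NA
    h <- (w - 1L) %/% 2L
    ys[seq_len(h)] <- y[seq_len(h)]
    ys[(n - h + 1L):n] <- y[(n - h + 1L):n]
  }
  idx <- which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] > ys[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    pk <- ys[i]
    lv <- ys[seq_len(i - 1)]
    higher_l <- which(lv > pk)
    left_min <- min(lv[seq.int(from = if (length(higher_l)) max(higher_l) else 1L,
                               to = i - 1L)])
    rv <- ys[(i + 1L):n]
    higher_r <- which(rv > pk)
    right_min <- min(rv[seq.int(from = 1L,
                                to = if (length(higher_r)) min(higher_r) else length(rv))])
    pk - max(left_min, right_min)
  }, 1.0)
  out <- data.frame(index = idx, x = x[idx], y = y[idx], prominence = prom)
  out[out$prominence >= min_prominence, , drop = FALSE]
}

# gaussian smoothing on a regular grid, NA-aware; width in grid steps
gauss_smooth <- function(y, width) {
  if (width <= 0) return(y)
  n <- length(y)
  half <- max(1L, ceiling(3 * width))
  k <- exp(-0.5 * ((-half):half / width)^2)
  out <- y
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- k[j - i + half + 1L]
    ok <- is.finite(y[j])
    if (any(ok)) out[i] <- sum(w[ok] * y[j][ok]) / sum(w[ok])
  }
  out
}
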