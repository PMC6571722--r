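# Microcanonical analysis: conformational (NVU) caloric curves from the 1D
# projection of the DoS, the true-microcanonical (NVE) DoS via kinetic-energy
# convolution, and first/second-order classification of pseudo-phase
# transitions from the derivative of the inverse temperature.

#' Project the 2D DoS onto total conformational energy
#'
#' At fixed stiffness the 1D DoS is `g(U) = sum over macrostates with
#' U = Env + eps_st * nst of g(Env, nst)`; weights are added per energy bin
#' with a log-sum-exp.  The default bin width is the smallest gap between
#' distinct attainable `U` values (so no bin merges two attainable levels);
#' when the attainable values are not resolvable the fallback width is 0.5.
#'
#' @param dos an `sf_dos`.
#' @param eps_st stiffness energy.
#' @param bin_width energy bin width (> 0), or `NULL` for the automatic
#'   lattice width.
#' @return an `sf_dos1d`: data.frame with `U` (bin centers, strictly
#'   increasing) and `log_g`, with attributes `bin_width`, `eps_st`,
#'   `raw_scale`.
#' @export
project_dos_1d <- function(dos, eps_st = 0, bin_width = NULL) {
  if (nrow(dos$table) == 0) stop("empty DoS")
  k <- dos_keys(dos, eps_st)
  if (is.null(bin_width)) {
    u <- sort(unique(round(k$U, 9)))
    gaps <- diff(u)
    gaps <- gaps[gaps > 1e-9]
    bin_width <- if (length(gaps)) min(gaps) else 0.5
    if (!is.finite(bin_width) || bin_width <= 0) bin_width <- 0.5
  }
  if (bin_width <= 0) stop("bin_width must be > 0")
  u0 <- min(k$U)
  bin <- as.integer(round((k$U - u0) / bin_width))
  lg <- tapply(k$log_g, bin, logsumexp)
  out <- data.frame(U = u0 + as.integer(names(lg)) * bin_width,
                    log_g = as.numeric(lg))
  out <- out[order(out$U), ]
  rownames(out) <- NULL
  structure(out, bin_width = bin_width, eps_st = eps_st,
            raw_scale = dos$model_info$raw_scale, class = c("sf_dos1d", "data.frame"))
}

# place a sparse 1D DoS onto its full regular bin grid (-Inf where empty)
dos1d_grid <- function(dos1d) {
  w <- attr(dos1d, "bin_width")
  i <- as.integer(round((dos1d$U - dos1d$U[1]) / w))
  n <- i[length(i)] + 1L
  sb <- rep(-Inf, n)
  sb[i + 1L] <- dos1d$log_g
  list(U = dos1d$U[1] + (seq_len(n) - 1L) * w, SB = sb, w = w)
}

#' Inverse microcanonical temperature from the conformational DoS
#'
#' The Boltzmann entropy is `SB(U) = ln g(U)`; the inverse temperature is
#' its derivative, `1/T(U) = dSB/dU`, evaluated by central differences on
#' the bin grid after optional Gaussian pre-smoothing of `SB` (width in
#' bins).  A second differencing pass gives `d(1/T)/dU`, whose peaks locate
#' and classify pseudo-phase transitions.  Empty interior bins are filled by
#' linear interpolation of `SB` before differencing.
#'
#' @param dos1d an `sf_dos1d` (>= 3 occupied bins).
#' @param smooth_bins Gaussian smoothing width for `SB`, in bins (0 = off).
#' @return an `sf_micro_curve`: data.frame with `U`, `SB`, `Tinv`, `dTinv`
#'   and attributes `ensemble = "NVU"`, `smooth_bins`, `bin_width`.
#' @export
inverse_temperature_U <- function(dos1d, smooth_bins = 0) {
  if (sum(is.finite(dos1d$log_g)) < 3)
    stop("insufficient support: need at least 3 occupied bins")
  g <- dos1d_grid(dos1d)
  sb <- g$SB
  if (any(!is.finite(sb))) {
    ok <- is.finite(sb)
    sb <- approx(g$U[ok], sb[ok], xout = g$U, rule = 2)$y
  }
  sb <- gauss_smooth(sb, smooth_bins)
  n <- length(sb)
  tinv <- rep(NA_real_, n)
  tinv[2:(n - 1)] <- (sb[3:n] - sb[1:(n - 2)]) / (2 * g$w)
  dtinv <- rep(NA_real_, n)
  dtinv[3:(n - 2)] <- (tinv[4:(n - 1)] - tinv[2:(n - 3)]) / (2 * g$w)
  structure(data.frame(U = g$U, SB = sb, Tinv = tinv, dTinv = dtinv),
            ensemble = "NVU", smooth_bins = smooth_bins, bin_width = g$w,
            eps_st = attr(dos1d, "eps_st"),
            class = c("sf_micro_curve", "data.frame"))
}

#' Locate and classify pseudo-phase transitions on a caloric curve
#'
#' Transition points are the local maxima of `d(1/T)/dU` above a prominence
#' floor.  A positive peak value marks a first-order-like transition
#' (backbending / Maxwell construction in `1/T(U)`), a negative one a
#' second-order-like transition (inflection without backbending).  The
#' transition temperature is `T* = 1/Tinv(U*)` at the peak position.
#'
#' @param curve an `sf_micro_curve` (from [inverse_temperature_U()] or
#'   [nve_curve()]).
#' @param min_prominence prominence floor in `d(1/T)/dU` units.
#' @return data.frame with `U_star`, `Tinv_star`, `T_star`, `peak_height`,
#'   `order` (`"first"`/`"second"`) and `ensemble`; zero rows when no peak
#'   qualifies.
#' @export
classify_transitions <- function(curve, min_prominence = 1e-3) {
  ok <- is.finite(curve$dTinv)
  if (sum(ok) < 3)
    return(data.frame(U_star = numeric(0), Tinv_star = numeric(0),
                      T_star = numeric(0), peak_height = numeric(0),
                      order = character(0), ensemble = character(0)))
  u <- curve$U[ok]
  d <- curve$dTinv[ok]
  pk <- find_peaks(u, d, smooth_window = 0, min_prominence = min_prominence)
  if (nrow(pk) == 0)
    return(data.frame(U_star = numeric(0), Tinv_star = numeric(0),
                      T_star = numeric(0), peak_height = numeric(0),
                      order = character(0), ensemble = character(0)))
  tinv_at <- approx(curve$U, curve$Tinv, xout = pk$x, ties = "ordered")$y
  data.frame(U_star = pk$x, Tinv_star = tinv_at, T_star = 1 / tinv_at,
             peak_height = pk$y,
             order = ifelse(pk$y > 0, "first", "second"),
             ensemble = attr(curve, "ensemble") %||% "NVU")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kinetic-energy convolution: NVE density of states
#'
#' The total-energy DoS is `g(E) = C * sum over U of
#' (E - U)^(d/2 - 1) g(U) Theta(E - U)` with `d` momentum degrees of
#' freedom.  The inverse temperature `1/T(E) = d ln g(E) / dE` is evaluated
#' analytically as the conditional average of `(d/2 - 1)/(E - U)`, so the
#' single-support case reproduces the ideal-gas law
#' `T = 2 (E - U0) / (d - 2)` exactly on the grid.
#'
#' @param dos1d an `sf_dos1d`.
#' @param d number of degrees of freedom (>= 2; the package default for a
#'   chain of N beads is `3 N`).
#' @param E_grid total-energy grid; defaults to 800 points from just above
#'   `Umin` to `Umax + 3 d / 2` (covering thermal kinetic energy up to
#'   about T = 3).
#' @return an `sf_micro_curve` over `E`: data.frame with `E`, `log_gE`,
#'   `Tinv`, and attribute `ensemble = "NVE"`.
#' @export
convolve_kinetic <- function(dos1d, d, E_grid = NULL) {
  if (d < 2) stop("d must be >= 2")
  umin <- min(dos1d$U)
  umax <- max(dos1d$U)
  if (is.null(E_grid)) {
    w <- attr(dos1d, "bin_width")
    E_grid <- seq(umin + w / 2, umax + 1.5 * d, length.out = 800)
  }
  if (all(E_grid <= umin)) stop("E_grid must extend above Umin")
  E_grid <- E_grid[E_grid > umin]
  a <- d / 2 - 1
  lg <- dos1d$log_g
  uu <- dos1d$U
  res <- vapply(E_grid, function(E) {
    sel <- uu < E
    lw <- a * log(E - uu[sel]) + lg[sel]
    m <- max(lw)
    wgt <- exp(lw - m)
    sw <- sum(wgt)
    c(m + log(sw), sum(wgt * a / (E - uu[sel])) / sw)
  }, c(0.0, 0.0))
  structure(data.frame(E = E_grid, log_gE = res[1, ], Tinv = res[2, ]),
            ensemble = "NVE", d = d, bin_width = attr(dos1d, "bin_width"),
            eps_st = attr(dos1d, "eps_st"),
            class = c("sf_micro_curve", "data.frame"))
}

#' Conditional distribution of conformational energy at fixed total energy
#'
#' `p(U|E) = (E - U)^(d/2 - 1) g(U) Theta(E - U) / normalization` on
#' `Umin <= U <= min(E, Umax)`.
#'
#' @param dos1d an `sf_dos1d`.
#' @param d degrees of freedom.
#' @param E total energy (> Umin).
#' @return data.frame with `U` and `p` (sums to 1).
#' @export
conditional_U_given_E <- function(dos1d, d, E) {
  if (E <= min(dos1d$U)) stop("E must exceed Umin")
  sel <- dos1d$U < E
  a <- d / 2 - 1
  lw <- a * log(E - dos1d$U[sel]) + dos1d$log_g[sel]
  p <- exp(lw - max(lw))
  data.frame(U = dos1d$U[sel], p = p / sum(p))
}

#' Mean conformational energy as a function of total energy
#'
#' `<U>(E) = sum U p(U|E)` (the third microcanonical variant); pairing it
#' with `1/T(E)` yields the caloric curve `1/T` vs `<U>(E)`, which keeps
#' the transition temperatures of the NVU analysis while the kinetic
#' convolution smooths energy-scale oscillations away.
#'
#' @inheritParams convolve_kinetic
#' @return numeric vector of `<U>(E)` along `E_grid`.
#' @export
mean_U_of_E <- function(dos1d, d, E_grid) {
  vapply(E_grid, function(E) {
    p <- conditional_U_given_E(dos1d, d, E)
    sum(p$U * p$p)
  }, 1.0)
}

#' Full NVE caloric curve against mean conformational energy
#'
#' Combines [convolve_kinetic()] and [mean_U_of_E()]: the curve
#' `1/T` vs `<U>(E)` with its derivative `d(1/T)/d<U>` by central
#' differences, ready for [classify_transitions()].
#'
#' @inheritParams convolve_kinetic
#' @return an `sf_micro_curve` with columns `U` (`= <U>(E)`), `E`,
#'   `Tinv`, `dTinv`; attribute `ensemble = "NVE"`.
#' @export
nve_curve <- function(dos1d, d, E_grid = NULL) {
  cv <- convolve_kinetic(dos1d, d, E_grid)
  um <- mean_U_of_E(dos1d, d, cv$E)
  n <- length(um)
  dtinv <- rep(NA_real_, n)
  dtinv[2:(n - 1)] <- (cv$Tinv[3:n] - cv$Tinv[1:(n - 2)]) /
    (um[3:n] - um[1:(n - 2)])
  structure(data.frame(U = um, E = cv$E, Tinv = cv$Tinv, dTinv = dtinv),
            ensemble = "NVE", d = d, eps_st = attr(dos1d, "eps_st"),
            class = c("sf_micro_curve", "data.frame"))
}
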