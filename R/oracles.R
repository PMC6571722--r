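# Independent desk-scale reference computations.  These share no code path
# with the sampler or the analysis modules they validate: the phantom DoS is
# a closed form, the brute-force DoS samples chains by direct uniform
# shell-volume growth, and the Metropolis reference is a fixed-temperature
# chain with the same move set but Boltzmann acceptance.

#' Favorable-angle probability of an ideal (phantom) chain
#'
#' For independent uniformly-oriented bonds the cosine of the valence angle
#' is uniform on `[-1, 1]`, so an angle falls in `[theta_min, theta_max]`
#' with probability `p0 = (cos theta_min - cos theta_max) / 2` (about
#' 0.0594 for the default window).
#'
#' @param theta_min,theta_max window in degrees.
#' @return numeric probability.
#' @export
phantom_p0 <- function(theta_min = 150, theta_max = 170) {
  (cos(theta_min * pi / 180) - cos(theta_max * pi / 180)) / 2
}

#' Exact density of states of the phantom chain over stiff-angle count
#'
#' With hard-sphere and contact terms disabled the eligible angles are
#' independent, so `nst` is Binomial(`n_angles`, `p0`) and the normalized
#' DoS over `nst` is the binomial mass function.
#'
#' @param n_angles number of eligible angles (>= 1).
#' @param theta_min,theta_max angle window in degrees.
#' @return data.frame with `nst` and exact normalized `g` (sums to 1).
#' @export
phantom_dos <- function(n_angles, theta_min = 150, theta_max = 170) {
  if (n_angles < 1) stop("n_angles must be >= 1")
  p0 <- phantom_p0(theta_min, theta_max)
  data.frame(nst = 0:n_angles, g = dbinom(0:n_angles, n_angles, p0))
}

#' Brute-force DoS by uniform shell-volume chain growth
#'
#' Draws chains bond-by-bond, each bond vector uniform with respect to
#' volume on the shell `[l_min, l_max]`, rejecting chains with hard-sphere
#' overlaps, and histograms the resulting macrostates.  Because the bond
#' parametrization of the coordinates has unit Jacobian, this estimates the
#' relative DoS under the same Cartesian measure the Monte Carlo moves
#' target.  Intended for tiny chains (high rejection otherwise).
#'
#' @param model an [sf_model()] (small `N`).
#' @param n_samples number of chains to draw.
#' @param seed integer seed.
#' @param min_acceptance error below this validity fraction.
#' @return an `sf_dos` whose table carries `count`, multinomial-based
#'   `log_g_se`, and `log_g` (anchored log relative DoS); fields `n_valid`,
#'   `n_samples`.
#' @export
brute_force_dos <- function(model, n_samples, seed = NULL,
                            min_acceptance = 1e-4) {
  if (!is.null(seed)) set.seed(seed)
  r <- cc_brute_force(model_cpp(model), n_samples)
  if (r$n_valid / r$n_samples < min_acceptance)
    stop(sprintf("acceptance rate %.2g below floor %g: chain too large for brute force",
                 r$n_valid / r$n_samples, min_acceptance))
  cnt <- r$count
  p <- cnt / r$n_valid
  tab <- data.frame(Env_raw = r$Env_raw, nst = r$nst,
                    log_g = log(cnt) - max(log(cnt)),
                    visits = cnt, count = cnt,
                    log_g_se = sqrt((1 - p) / cnt))
  dos <- new_dos(tab, model, n_mcs = 0, schedule = NULL, seed = seed,
                 extra = list(n_valid = r$n_valid, n_samples = r$n_samples))
  dos
}

#' Fixed-temperature Metropolis reference
#'
#' Canonical sampling with the same move set as the flat-histogram sampler
#' but standard Boltzmann acceptance at temperature `T`.  Means and
#' autocorrelation-aware standard errors (batch means over `n_batches`
#' blocks of the post-burn-in series) are returned for the total energy and
#' the squared gyration radii; the heat capacity is estimated from the
#' fluctuation formula with a batch-spread standard error.
#'
#' @param model an [sf_model()].
#' @param temperature temperature (> 0).
#' @param n_mcs number of sweeps.
#' @param seed integer seed.
#' @param burn_frac fraction of sweeps discarded as burn-in.
#' @param n_batches number of batches for the error estimate.
#' @param sample_every record observables every this many sweeps.
#' @return list with `U_mean`, `U_se`, `CV`, `CV_se`, `means` (named
#'   vector), `se` (named vector), acceptance rates and the thinned series.
#' @export
metropolis_reference <- function(model, temperature, n_mcs, seed = NULL,
                                 burn_frac = 0.25, n_batches = 20,
                                 sample_every = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (!is.null(seed)) set.seed(seed)
  conf <- initial_conformation(model)
  r <- cc_metropolis(conf, model_cpp(model), temperature, model$eps_st,
                     model$raw_scale, n_mcs, as.integer(sample_every))
  s <- as.data.frame(r$samples)
  s <- s[-seq_len(floor(nrow(s) * burn_frac)), , drop = FALSE]
  nb <- min(n_batches, nrow(s))
  batch <- cut(seq_len(nrow(s)), nb, labels = FALSE)
  bm <- function(x) {
    m <- tapply(x, batch, mean)
    list(mean = mean(x), se = sd(m) / sqrt(length(m)))
  }
  u <- bm(s$U)
  cols <- c("rg2_all", "rg2_S", "rg2_F", "nst")
  ms <- vapply(cols, function(cn) bm(s[[cn]])$mean, 1.0)
  ses <- vapply(cols, function(cn) bm(s[[cn]])$se, 1.0)
  cv_b <- tapply(s$U, batch, function(x) (mean(x^2) - mean(x)^2)) /
    temperature^2
  list(U_mean = u$mean, U_se = u$se,
       CV = (mean(s$U^2) - mean(s$U)^2) / temperature^2,
       CV_se = sd(cv_b) / sqrt(length(cv_b)),
       means = ms, se = ses,
       acc_local = r$acc_local, acc_regrow = r$acc_regrow,
       series = s, temperature = temperature)
}

#' Analytic-limits validation suite
#'
#' Runs three closed-form checks through the package's own analysis code:
#' the ideal-gas kinetic convolution (`T = 2 (E - U0) / (d - 2)` for a
#' single-support conformational DoS), the Schottky two-level heat capacity
#' against `(D/T)^2 e^{D/T} / (1 + e^{D/T})^2`, and the constant inverse
#' temperature of a linear entropy.
#'
#' @return data.frame with `check`, `max_abs_err`, `tol`, `pass`.
#' @export
analytic_limits_suite <- function() {
  out <- list()
  # ideal gas: delta DoS at U0 = -3, d = 6
  d1 <- structure(data.frame(U = -3, log_g = 0),
                  bin_width = 0.5, eps_st = 0, raw_scale = 1,
                  class = c("sf_dos1d", "data.frame"))
  eg <- seq(-2.5, 5, by = 0.25)
  cv <- convolve_kinetic(d1, d = 6, E_grid = eg)
  err1 <- max(abs(1 / cv$Tinv - 2 * (cv$E - (-3)) / (6 - 2)))
  out$ideal_gas <- c(err1, 1e-12)
  # Schottky: two levels 0 and -Delta, equal degeneracy
  delta <- 2
  dos <- fabricate_dos(data.frame(Env_raw = c(0L, -as.integer(delta)),
                                  nst = c(0L, 0L), log_g = c(0, 0)))
  tt <- seq(0.2, 3, by = 0.05)
  cvq <- heat_capacity(dos, tt)$CV
  xref <- delta / tt
  ref <- xref^2 * exp(xref) / (1 + exp(xref))^2
  err2 <- max(abs(cvq - ref))
  out$schottky <- c(err2, 1e-6)
  # linear entropy: SB = a U + b  ->  1/T = a everywhere
  a <- 0.7
  u <- seq(0, 10, by = 0.1)
  dlin <- structure(data.frame(U = u, log_g = a * u + 1),
                    bin_width = 0.1, eps_st = 0, raw_scale = 1,
                    class = c("sf_dos1d", "data.frame"))
  curve <- inverse_temperature_U(dlin)
  err3 <- max(abs(curve$Tinv[is.finite(curve$Tinv)] - a))
  out$linear_entropy <- c(err3, 1e-9)
  data.frame(check = names(out),
             max_abs_err = vapply(out, `[`, 1.0, 1),
             tol = vapply(out, `[`, 1.0, 2),
             pass = vapply(out, function(x) x[1] <= x[2], TRUE),
             row.names = NULL)
}

#' Construct a synthetic DoS object from an explicit macrostate table
#'
#' Convenience for analytic fixtures and tests: wraps a table of
#' `(Env_raw, nst, log_g)` as an `sf_dos` with `raw_scale = 1` (or as
#' given).
#'
#' @param table data.frame with `Env_raw`, `nst`, `log_g` (a `visits`
#'   column is added if missing).
#' @param raw_scale raw-to-physical contact-energy factor.
#' @param nst_max stored bound for the `nst` coordinate.
#' @return an `sf_dos` (fingerprint marked `"synthetic"`).
#' @export
fabricate_dos <- function(table, raw_scale = 1, nst_max = max(table$nst)) {
  if (!"visits" %in% names(table)) table$visits <- 1
  structure(list(
    table = table[order(table$Env_raw, table$nst), , drop = FALSE],
    fingerprint = "synthetic",
    model_info = list(N = NA_integer_, b = NA_integer_, preset = "synthetic",
                      eps_raw = c(-1L, -1L, -1L), raw_scale = raw_scale,
                      phantom = FALSE, nst_max = nst_max),
    n_mcs = 0, schedule = NULL, seed = NULL),
    class = "sf_dos")
}
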