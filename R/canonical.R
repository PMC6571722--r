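# Canonical-ensemble analysis from the 2D density of states.
#
# Every quantity is a Boltzmann-weighted sum over macrostates (Env, nst) with
# energy U = raw_scale * Env_raw + eps_st * nst; the stiffness parameter
# enters only here, so one accumulated DoS serves the whole eps_st axis.

dos_keys <- function(dos, eps_st) {
  t <- dos$table
  U <- dos$model_info$raw_scale * t$Env_raw + eps_st * t$nst
  list(log_g = t$log_g, U = U, Env_raw = t$Env_raw, nst = t$nst)
}

#' Log partition function
#'
#' `log Z(T, eps_st) = logsumexp over macrostates of
#' [log g - (Env + eps_st * nst) / T]`, overflow-safe by max subtraction.
#' Temperatures are in units of `|eps_ff| / kB` with `kB = 1`.
#'
#' @param dos an `sf_dos`.
#' @param temperature temperature (> 0); may be a vector.
#' @param eps_st stiffness energy (defaults to 0).
#' @return numeric log-partition value(s).
#' @export
log_partition <- function(dos, temperature, eps_st = 0) {
  if (nrow(dos$table) == 0) stop("empty DoS")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  k <- dos_keys(dos, eps_st)
  vapply(temperature, function(Tt) logsumexp(k$log_g - k$U / Tt), 1.0)
}

#' Boltzmann-weighted canonical average of a per-macrostate observable
#'
#' @param dos an `sf_dos`.
#' @param A the observable: a function of `(Env_raw, nst)`, a numeric vector
#'   aligned with `dos$table`, or a character column name resolved in
#'   `table` (an `sf_obs` production table).
#' @param temperature temperature (> 0), scalar or vector.
#' @param eps_st stiffness energy.
#' @param table optional `sf_obs` whose per-macrostate means supply `A` when
#'   `A` is a column name.  Macrostates missing from the table are masked
#'   (dropped from both numerator and denominator) with a warning.
#' @return numeric canonical average(s).
#' @export
canonical_average <- function(dos, A, temperature, eps_st = 0, table = NULL) {
  k <- dos_keys(dos, eps_st)
  if (is.character(A)) {
    if (is.null(table)) stop("a production table is needed to resolve '", A, "'")
    if (!A %in% names(table$table)) stop("observable '", A, "' not in table")
    mm <- merge(data.frame(Env_raw = k$Env_raw, nst = k$nst, i = seq_along(k$U)),
                table$table[c("Env_raw", "nst", A)],
                by = c("Env_raw", "nst"), all.x = TRUE)
    mm <- mm[order(mm$i), ]
    a <- mm[[A]]
  } else if (is.function(A)) {
    a <- A(k$Env_raw, k$nst)
  } else {
    a <- as.numeric(A)
    if (length(a) != length(k$U)) stop("A must align with the DoS table")
  }
  keep <- is.finite(a)
  if (!any(keep)) stop("observable undefined on every macrostate")
  if (!all(keep))
    warning(sprintf("observable missing on %d macrostate(s); masked",
                    sum(!keep)))
  vapply(temperature, function(Tt) {
    lw <- k$log_g[keep] - k$U[keep] / Tt
    m <- max(lw)
    w <- exp(lw - m)
    sum(a[keep] * w) / sum(w)
  }, 1.0)
}

#' Heat capacity and canonical moments from the DoS
#'
#' Computes `<U>`, `<U^2>` and `CV = (<U^2> - <U>^2) / T^2` from the
#' fluctuation formula, with both moments accumulated in one
#' max-subtracted pass to avoid catastrophic cancellation at low
#' temperature.
#'
#' @inheritParams log_partition
#' @return data.frame with columns `temperature`, `eps_st`, `logZ`,
#'   `U_mean`, `U2_mean`, `CV` (one row per temperature).
#' @export
heat_capacity <- function(dos, temperature, eps_st = 0) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  k <- dos_keys(dos, eps_st)
  out <- lapply(temperature, function(Tt) {
    lw <- k$log_g - k$U / Tt
    m <- max(lw)
    w <- exp(lw - m)
    sw <- sum(w)
    u1 <- sum(k$U * w) / sw
    u2 <- sum(k$U^2 * w) / sw
    data.frame(temperature = Tt, eps_st = eps_st, logZ = m + log(sw),
               U_mean = u1, U2_mean = u2,
               CV = max(0, (u2 - u1^2)) / Tt^2)
  })
  do.call(rbind, out)
}

#' Canonical probability of each macrostate
#'
#' `rho(Env, nst) = g(Env, nst) exp(-(Env + eps_st nst)/T) / Z`; the
#' returned column sums to 1.
#'
#' @inheritParams log_partition
#' @return data.frame `Env_raw`, `nst`, `U`, `prob`, sorted by decreasing
#'   probability.
#' @export
macrostate_probability <- function(dos, temperature, eps_st = 0) {
  if (length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a positive scalar")
  k <- dos_keys(dos, eps_st)
  lw <- k$log_g - k$U / temperature
  m <- max(lw)
  p <- exp(lw - m)
  p <- p / sum(p)
  out <- data.frame(Env_raw = k$Env_raw, nst = k$nst, U = k$U, prob = p)
  out[order(-out$prob), ]
}

#' Heat-capacity profile along temperature at fixed stiffness
#'
#' Evaluates `CV(T)` on a temperature grid and locates its local maxima
#' (after optional smoothing, with topographic prominence) which signal
#' pseudo-phase transitions or structural rearrangements.
#'
#' @param dos an `sf_dos`.
#' @param eps_st stiffness energy.
#' @param T_grid monotone temperature grid (>= 3 points).
#' @param smooth_window,min_prominence passed to [find_peaks()].
#' @return data.frame with `temperature`, `x` (`|eps_ff|/T`), `U_mean`,
#'   `CV`; local maxima in `attr(, "maxima")`.
#' @export
cv_profile_T <- function(dos, eps_st, T_grid, smooth_window = 0,
                         min_prominence = 0) {
  if (length(T_grid) < 3) stop("grid too short: need at least 3 points")
  if (is.unsorted(T_grid) && is.unsorted(rev(T_grid)))
    stop("T_grid must be monotone")
  hc <- heat_capacity(dos, T_grid, eps_st)
  abs_ff <- abs(dos$model_info$raw_scale * dos$model_info$eps_raw[2])
  out <- data.frame(temperature = hc$temperature, x = abs_ff / hc$temperature,
                    U_mean = hc$U_mean, CV = hc$CV)
  attr(out, "maxima") <- find_peaks(out$temperature, out$CV, smooth_window,
                                    min_prominence)
  out
}

#' Heat-capacity profile along stiffness at fixed temperature
#'
#' Same construction as [cv_profile_T()] with the axes swapped: `CV(eps_st)`
#' at fixed `T` from the single accumulated 2D DoS (valid because the energy
#' depends on `eps_st` only through the `nst` coordinate).  Maxima indicate
#' morphological changes as the chain is stiffened.
#'
#' @param dos an `sf_dos`.
#' @param temperature fixed temperature.
#' @param eps_st_grid monotone grid of stiffness energies (each <= 0).
#' @inheritParams cv_profile_T
#' @return data.frame with `eps_st`, `CV`, `U_mean`; maxima in
#'   `attr(, "maxima")`.
#' @export
cv_profile_stiffness <- function(dos, temperature, eps_st_grid,
                                 smooth_window = 0, min_prominence = 0) {
  if (length(eps_st_grid) < 3) stop("grid too short: need at least 3 points")
  rows <- lapply(eps_st_grid, function(e)
    heat_capacity(dos, temperature, eps_st = e))
  hc <- do.call(rbind, rows)
  out <- data.frame(eps_st = eps_st_grid, CV = hc$CV, U_mean = hc$U_mean)
  attr(out, "maxima") <- find_peaks(out$eps_st, out$CV, smooth_window,
                                    min_prominence)
  out
}

#' Assemble a heat-capacity state diagram
#'
#' Builds the `CV` surface over a grid of normalized stiffness
#' `x = eps_st/eps_ff` and normalized inverse temperature `y = |eps_ff|/T`,
#' together with the loci of `CV` maxima along both axes: maxima of `CV(T)`
#' at fixed stiffness (detector `"T"`) and maxima of `CV(eps_st)` at fixed
#' temperature (detector `"stiffness"`).
#'
#' @param dos an `sf_dos`.
#' @param x_grid grid of `eps_st / eps_ff` (>= 0; both energies negative so
#'   the ratio is positive).
#' @param y_grid grid of `|eps_ff| / T` (> 0).
#' @param smooth_window,min_prominence peak-detector settings.
#' @return an `sf_state_diagram`: list with `x_grid`, `y_grid`, the `CV`
#'   matrix (rows = y, columns = x), `maxima` (data.frame `x`, `y`,
#'   `detector`, `prominence`) and an empty `transitions` slot that
#'   [add_transitions()] fills from microcanonical markers.
#' @export
build_state_diagram <- function(dos, x_grid, y_grid, smooth_window = 0,
                                min_prominence = 0) {
  abs_ff <- abs(dos$model_info$raw_scale * dos$model_info$eps_raw[2])
  eps_ff <- -abs_ff
  if (any(x_grid < 0)) stop("x_grid (eps_st/eps_ff) must be >= 0")
  if (any(y_grid <= 0)) stop("y_grid (|eps_ff|/T) must be > 0")
  T_of_y <- abs_ff / y_grid
  cv <- matrix(NA_real_, nrow = length(y_grid), ncol = length(x_grid),
               dimnames = list(NULL, NULL))
  for (j in seq_along(x_grid)) {
    hc <- heat_capacity(dos, T_of_y, eps_st = x_grid[j] * eps_ff)
    cv[, j] <- hc$CV
  }
  maxima <- list()
  if (length(y_grid) >= 3)
    for (j in seq_along(x_grid)) {
      pk <- find_peaks(y_grid, cv[, j], smooth_window, min_prominence)
      if (nrow(pk))
        maxima[[length(maxima) + 1]] <-
          data.frame(x = x_grid[j], y = pk$x, detector = "T",
                     prominence = pk$prominence)
    }
  if (length(x_grid) >= 3)
    for (i in seq_along(y_grid)) {
      pk <- find_peaks(x_grid, cv[i, ], smooth_window, min_prominence)
      if (nrow(pk))
        maxima[[length(maxima) + 1]] <-
          data.frame(x = pk$x, y = y_grid[i], detector = "stiffness",
                     prominence = pk$prominence)
    }
  maxima <- if (length(maxima)) do.call(rbind, maxima) else
    data.frame(x = numeric(0), y = numeric(0), detector = character(0),
               prominence = numeric(0))
  structure(list(x_grid = x_grid, y_grid = y_grid, CV = cv, maxima = maxima,
                 transitions = NULL, fingerprint = dos$fingerprint,
                 model_info = dos$model_info),
            class = "sf_state_diagram")
}

#' Overlay microcanonical transition markers on a state diagram
#'
#' @param diagram an `sf_state_diagram`.
#' @param transitions data.frame from [classify_transitions()] (needs columns
#'   `T_star` and `order`), plus the stiffness each row belongs to in
#'   `eps_st`.
#' @return the diagram with markers appended to `transitions` (columns `x`,
#'   `y`, `order`, `ensemble`).
#' @export
add_transitions <- function(diagram, transitions) {
  abs_ff <- abs(diagram$model_info$raw_scale * diagram$model_info$eps_raw[2])
  mk <- data.frame(x = transitions$eps_st / -abs_ff,
                   y = abs_ff / transitions$T_star,
                   order = transitions$order,
                   ensemble = if ("ensemble" %in% names(transitions))
                     transitions$ensemble else NA_character_)
  diagram$transitions <- rbind(diagram$transitions, mk)
  diagram
}

#' @export
print.sf_state_diagram <- function(x, ...) {
  cat(sprintf("<sf_state_diagram> %d x %d grid, %d CV maxima, %s transition markers\n",
              length(x$y_grid), length(x$x_grid), nrow(x$maxima),
              if (is.null(x$transitions)) "no" else nrow(x$transitions)))
  invisible(x)
}

#' Plot a state diagram (requires ggplot2)
#'
#' Heat-capacity surface with maxima loci; a convenience, not part of the
#' serialization contract.
#'
#' @param x an `sf_state_diagram`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_state_diagram <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is needed for plotting")
  df <- expand.grid(y = x$y_grid, x = x$x_grid)
  df$CV <- as.vector(x$CV)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$CV)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(epsilon[st] / epsilon[ff]),
                  y = expression(abs(epsilon[ff]) / T), fill = "CV")
  if (nrow(x$maxima))
    g <- g + ggplot2::geom_point(
      data = x$maxima,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$detector),
      inherit.aes = FALSE, colour = "white", size = 1.5)
  g
}
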