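#' Gain schedule for stochastic approximation Monte Carlo
#'
#' The gain at Monte Carlo step `t` is `gamma_t = gamma0 * min(1, t0 / t)`:
#' constant at `gamma0` for the first `t0` sweeps, then decaying like `1/t`.
#'
#' @param gamma0 initial gain (> 0).
#' @param t0 plateau length in MCS (>= 1).
#' @return an object of class `sf_gain_schedule`.
#' @export
gain_schedule <- function(gamma0 = 1, t0 = 1000) {
  if (!(gamma0 > 0)) stop("gamma0 must be > 0")
  if (!(t0 >= 1)) stop("t0 must be >= 1")
  structure(list(gamma0 = gamma0, t0 = t0), class = "sf_gain_schedule")
}

#' Gain value at a given Monte Carlo step
#'
#' @param t MCS index (>= 1); may be a vector.
#' @param schedule an [gain_schedule()] object.
#' @return numeric gain value(s).
#' @export
gain <- function(t, schedule) {
  if (any(t < 1)) stop("t must be >= 1")
  schedule$gamma0 * pmin(1, schedule$t0 / t)
}

#' The two-stage refinement schedule used by default
#'
#' Stage one runs with `gamma0 = 1, t0 = 1e3`; stage two with
#' `gamma0 = 0.01, t0 = 1e4`.
#'
#' @return list of two [gain_schedule()] objects.
#' @export
default_schedules <- function() {
  list(gain_schedule(1, 1e3), gain_schedule(0.01, 1e4))
}

#' SAMC acceptance decision
#'
#' A trial move from a macrostate with log-density `log_g_old` to one with
#' `log_g_new` is accepted with probability
#' `min(1, exp(log_g_old - log_g_new))`, which drives the visit histogram
#' towards flatness.
#'
#' @param log_g_old,log_g_new natural-log DoS values (finite).
#' @return logical.
#' @export
samc_accept <- function(log_g_old, log_g_new) {
  if (!is.finite(log_g_old) || !is.finite(log_g_new))
    stop("log_g values must be finite")
  log_g_new <= log_g_old || runif(1) < exp(log_g_old - log_g_new)
}

new_dos <- function(table, model, n_mcs = 0, schedule = NULL, seed = NULL,
                    extra = list()) {
  table <- table[order(table$Env_raw, table$nst), , drop = FALSE]
  rownames(table) <- NULL
  structure(c(list(
    table = table,
    fingerprint = model_fingerprint(model),
    model_info = list(N = model$N, b = model$b, preset = model$preset,
                      eps_raw = model$eps_raw, raw_scale = model$raw_scale,
                      phantom = model$phantom, nst_max = nst_max(model)),
    n_mcs = n_mcs, schedule = schedule, seed = seed), extra),
    class = "sf_dos")
}

#' @export
print.sf_dos <- function(x, ...) {
  cat(sprintf("<sf_dos> %d macrostates, %g MCS accumulated\n",
              nrow(x$table), x$n_mcs))
  cat(sprintf("  Env_raw in [%d, %d], nst in [%d, %d], fingerprint %s\n",
              min(x$table$Env_raw), max(x$table$Env_raw),
              min(x$table$nst), max(x$table$nst),
              substr(x$fingerprint, 1, 8)))
  invisible(x)
}

#' Anchor a DoS so that max(log_g) = 0
#'
#' The DoS is only defined up to a multiplicative constant; all canonical
#' and microcanonical outputs are invariant under this shift.
#'
#' @param dos an `sf_dos`.
#' @return the anchored `sf_dos`.
#' @export
anchor_dos <- function(dos) {
  dos$table$log_g <- dos$table$log_g - max(dos$table$log_g)
  dos
}

#' Apply one SAMC update to a DoS table
#'
#' Adds `gamma` to the log-density of the macrostate the chain ended the
#' trial in (whether the trial was accepted or not) and increments its visit
#' count, leaving every other entry untouched.  This is the R-level
#' reference of the update rule used inside the compiled sampling loop.
#'
#' @param dos an `sf_dos` whose table contains the key.
#' @param Env_raw,nst macrostate key.
#' @param gamma gain value to add.
#' @return the updated `sf_dos`.
#' @export
samc_update <- function(dos, Env_raw, nst, gamma) {
  i <- which(dos$table$Env_raw == Env_raw & dos$table$nst == nst)
  if (length(i) != 1) stop("macrostate key not registered in the DoS")
  dos$table$log_g[i] <- dos$table$log_g[i] + gamma
  dos$table$visits[i] <- dos$table$visits[i] + 1
  dos
}

#' Run the SAMC flat-histogram sampler
#'
#' Performs `n_mcs` Monte Carlo sweeps, each consisting of `2 N` local
#' displacement trials and one end-cut-and-regrow trial.  Every trial applies
#' the flat-histogram acceptance rule and then adds the current gain to the
#' log-density of the resulting macrostate (the old one when the trial was
#' rejected).  The gain index advances once per sweep.  The run is a pure
#' function of `(model, schedule, n_mcs, seed)`.
#'
#' @param model an [sf_model()].
#' @param n_mcs number of sweeps.
#' @param schedule a [gain_schedule()].
#' @param seed integer seed; when `NULL` the current RNG stream is used.
#' @param init_dos optional `sf_dos` to continue from.
#' @param init_conf optional starting conformation (defaults to
#'   [initial_conformation()]).
#' @param t_offset MCS index offset for the gain schedule (used when a run is
#'   split into checkpointed segments).
#' @return an `sf_dos` with extra fields `conf` (final coordinates),
#'   `acc_local`, `acc_regrow`, `t_next`, and `rng_state`.
#' @export
run_samc <- function(model, n_mcs, schedule = gain_schedule(), seed = NULL,
                     init_dos = NULL, init_conf = NULL, t_offset = 0) {
  if (n_mcs < 0) stop("n_mcs must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_conf)) init_conf <- initial_conformation(model)
  init_conf <- check_coords(init_conf, model)
  if (!is.null(init_dos)) {
    if (init_dos$fingerprint != model_fingerprint(model))
      stop("init_dos was accumulated with a different model (fingerprint mismatch)")
    ke <- init_dos$table$Env_raw; ks <- init_dos$table$nst
    kl <- init_dos$table$log_g; kv <- init_dos$table$visits
  } else {
    ke <- integer(0); ks <- integer(0); kl <- numeric(0); kv <- numeric(0)
  }
  r <- cc_run_samc(init_conf, model_cpp(model), schedule$gamma0, schedule$t0,
                   t_offset, n_mcs, as.integer(ke), as.integer(ks),
                   as.numeric(kl), as.numeric(kv))
  tab <- data.frame(Env_raw = r$Env_raw, nst = r$nst, log_g = r$log_g,
                    visits = r$visits)
  dos <- new_dos(tab, model,
                 n_mcs = n_mcs + if (!is.null(init_dos)) init_dos$n_mcs else 0,
                 schedule = schedule, seed = seed,
                 extra = list(conf = r$coords, acc_local = r$acc_local,
                              acc_regrow = r$acc_regrow,
                              t_next = t_offset + n_mcs,
                              rng_state = get_rng_state()))
  dos
}

get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  get(".Random.seed", envir = globalenv())
}

set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

#' Iterative SAMC refinement
#'
#' Chains several SAMC stages with successively smaller gains, each seeded
#' from the previous stage's DoS and final conformation.  The default is the
#' two-stage schedule of [default_schedules()].
#'
#' @param model an [sf_model()].
#' @param n_mcs numeric vector, sweeps per stage (recycled against
#'   `schedules`).
#' @param schedules list of [gain_schedule()] objects, one per stage.
#' @param seed integer seed for the whole procedure.
#' @return an `sf_dos` with a `stages` field holding per-stage diagnostics
#'   (acceptance rates, visit-histogram flatness, max log-density increment).
#' @export
refine <- function(model, n_mcs, schedules = default_schedules(), seed = NULL) {
  n_stage <- max(length(schedules), length(n_mcs))
  schedules <- rep_len(schedules, n_stage)
  n_mcs <- rep_len(n_mcs, n_stage)
  if (!is.null(seed)) set.seed(seed)
  dos <- NULL
  conf <- initial_conformation(model)
  stages <- vector("list", n_stage)
  for (s in seq_len(n_stage)) {
    prev_lg <- if (is.null(dos)) NULL else dos$table
    dos_s <- run_samc(model, n_mcs[s], schedules[[s]], seed = NULL,
                      init_dos = dos, init_conf = conf)
    conf <- dos_s$conf
    v <- dos_s$table$visits
    dlg <- NA_real_
    if (!is.null(prev_lg)) {
      mm <- merge(prev_lg[c("Env_raw", "nst", "log_g")],
                  dos_s$table[c("Env_raw", "nst", "log_g")],
                  by = c("Env_raw", "nst"))
      if (nrow(mm)) dlg <- max(abs(mm$log_g.y - mm$log_g.x))
    }
    stages[[s]] <- list(schedule = schedules[[s]], n_mcs = n_mcs[s],
                        n_macrostates = nrow(dos_s$table),
                        acc_local = dos_s$acc_local,
                        acc_regrow = dos_s$acc_regrow,
                        flatness = min(v) / mean(v),
                        max_dlog_g = dlg)
    dos <- dos_s
  }
  dos$stages <- stages
  dos
}

#' Average independent DoS determinations
#'
#' The DoS is only defined up to a constant shift of `log_g`, so the runs
#' are first brought to a common gauge: each run is shifted by the median
#' difference of `log_g` against the first run over their shared
#' macrostates (the median makes the alignment robust to individual badly
#' converged keys).  The per-macrostate mean of aligned `log_g` is then
#' taken over the runs in which the macrostate was visited.  Macrostates
#' visited in fewer than `quorum` runs are dropped.  The per-key standard
#' deviation across runs is returned as a convergence diagnostic, and the
#' result is anchored to `max(log_g) = 0`.
#'
#' @param runs list of `sf_dos` objects with identical model fingerprints.
#' @param quorum minimum number of runs a macrostate must appear in.
#' @return an `sf_dos` whose table gains columns `n_runs` and `log_g_sd`.
#' @export
average_dos <- function(runs, quorum = 2) {
  if (length(runs) < 1) stop("need at least one run")
  fps <- vapply(runs, function(d) d$fingerprint, "")
  if (length(unique(fps)) != 1)
    stop("model fingerprint mismatch across runs")
  ref <- runs[[1]]$table
  tabs <- lapply(seq_along(runs), function(i) {
    t <- runs[[i]]$table
    mm <- merge(ref[c("Env_raw", "nst", "log_g")],
                t[c("Env_raw", "nst", "log_g")],
                by = c("Env_raw", "nst"))
    if (nrow(mm) == 0) stop("runs share no macrostates; cannot align")
    t$log_g <- t$log_g - median(mm$log_g.y - mm$log_g.x)
    t$run <- i
    t
  })
  all <- do.call(rbind, tabs)
  key <- paste(all$Env_raw, all$nst)
  lg_mean <- tapply(all$log_g, key, mean)
  lg_sd <- tapply(all$log_g, key, function(x) if (length(x) > 1) sd(x) else 0)
  n_runs <- tapply(all$log_g, key, length)
  vis <- tapply(all$visits, key, sum)
  ks <- strsplit(names(lg_mean), " ", fixed = TRUE)
  tab <- data.frame(
    Env_raw = vapply(ks, function(k) as.integer(k[1]), 1L),
    nst = vapply(ks, function(k) as.integer(k[2]), 1L),
    log_g = as.numeric(lg_mean), visits = as.numeric(vis),
    n_runs = as.integer(n_runs), log_g_sd = as.numeric(lg_sd))
  tab <- tab[tab$n_runs >= min(quorum, length(runs)), , drop = FALSE]
  d <- runs[[1]]
  out <- structure(list(
    table = tab[order(tab$Env_raw, tab$nst), , drop = FALSE],
    fingerprint = d$fingerprint, model_info = d$model_info,
    n_mcs = sum(vapply(runs, function(x) x$n_mcs, 1)),
    schedule = d$schedule, seed = NULL, n_averaged = length(runs)),
    class = "sf_dos")
  rownames(out$table) <- NULL
  anchor_dos(out)
}

#' Production run with a frozen DoS
#'
#' Samples with the flat-histogram acceptance rule and a fixed DoS (no
#' updates), accumulating the per-macrostate means of the morphology
#' observables once per sweep.  Trial moves into macrostates outside the DoS
#' support are rejected; their number is reported.
#'
#' @param model an [sf_model()].
#' @param dos converged `sf_dos` (fingerprint must match `model`).
#' @param n_mcs number of sweeps.
#' @param seed integer seed.
#' @param sample_every accumulate observables every this many sweeps.
#' @param min_count per-macrostate sample floor; keys below it are listed in
#'   the result's `below_floor` field.
#' @param init_conf optional starting conformation.
#' @return an `sf_obs` object: a per-macrostate table of counts, visit
#'   numbers and observable means.
#' @export
production_run <- function(model, dos, n_mcs, seed = NULL, sample_every = 1,
                           min_count = 1000, init_conf = NULL) {
  if (dos$fingerprint != model_fingerprint(model))
    stop("dos was accumulated with a different model (fingerprint mismatch)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_conf)) init_conf <- initial_conformation(model)
  init_conf <- check_coords(init_conf, model)
  r <- cc_production(init_conf, model_cpp(model), n_mcs,
                     as.integer(sample_every),
                     as.integer(dos$table$Env_raw), as.integer(dos$table$nst),
                     as.numeric(dos$table$log_g))
  tab <- data.frame(Env_raw = r$Env_raw, nst = r$nst, count = r$count,
                    visits = r$visits)
  tab <- cbind(tab, as.data.frame(r$means))
  tab <- tab[order(tab$Env_raw, tab$nst), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    table = tab, fingerprint = dos$fingerprint, model_info = dos$model_info,
    n_mcs = n_mcs, sample_every = sample_every, seed = seed,
    observables = colnames(r$means),
    acc_local = r$acc_local, acc_regrow = r$acc_regrow,
    rej_offsupport = r$rej_offsupport,
    below_floor = tab[tab$count < min_count, c("Env_raw", "nst", "count")],
    min_count = min_count),
    class = "sf_obs")
}

#' Pool production observable tables
#'
#' Combines several production runs into one per-macrostate table:
#' counts and visits are summed and observable means are count-weighted.
#' Because the DoS value is constant within a macrostate, per-macrostate
#' means are unbiased under any frozen DoS, so runs made with different
#' (e.g., per-seed) DoS estimates of the same model may be pooled; each
#' run's DoS only affects which macrostates it covers and how often.
#'
#' @param obs_list list of `sf_obs` objects for the same model.
#' @return an `sf_obs` with pooled counts and means.
#' @export
pool_observables <- function(obs_list) {
  if (length(obs_list) < 1) stop("need at least one table")
  fps <- vapply(obs_list, function(o) o$fingerprint, "")
  if (length(unique(fps)) != 1)
    stop("model fingerprint mismatch across tables")
  cols <- obs_list[[1]]$observables
  all <- do.call(rbind, lapply(obs_list, function(o) o$table))
  key <- paste(all$Env_raw, all$nst)
  agg_w <- function(v) {
    w <- all$count
    out <- tapply(v * ifelse(w > 0, w, 0), key, sum, na.rm = TRUE)
    cnt <- tapply(ifelse(is.finite(v), w, 0), key, sum)
    ifelse(cnt > 0, out / cnt, NA_real_)
  }
  cnt <- tapply(all$count, key, sum)
  vis <- tapply(all$visits, key, sum)
  ks <- strsplit(names(cnt), " ", fixed = TRUE)
  tab <- data.frame(
    Env_raw = vapply(ks, function(k) as.integer(k[1]), 1L),
    nst = vapply(ks, function(k) as.integer(k[2]), 1L),
    count = as.numeric(cnt), visits = as.numeric(vis))
  for (cn in cols) tab[[cn]] <- as.numeric(agg_w(all[[cn]]))
  tab <- tab[order(tab$Env_raw, tab$nst), , drop = FALSE]
  rownames(tab) <- NULL
  first <- obs_list[[1]]
  structure(list(
    table = tab, fingerprint = first$fingerprint,
    model_info = first$model_info,
    n_mcs = sum(vapply(obs_list, function(o) o$n_mcs, 1)),
    sample_every = first$sample_every, seed = NULL,
    observables = cols,
    acc_local = NA_real_, acc_regrow = NA_real_,
    rej_offsupport = sum(vapply(obs_list,
                                function(o) o$rej_offsupport, 1)),
    below_floor = tab[tab$count < first$min_count,
                      c("Env_raw", "nst", "count")],
    min_count = first$min_count),
    class = "sf_obs")
}

#' @export
print.sf_obs <- function(x, ...) {
  cat(sprintf(
    "<sf_obs> %d macrostates, %g MCS, %d observables; %d key(s) below the %g-sample floor\n",
    nrow(x$table), x$n_mcs, length(x$observables), nrow(x$below_floor),
    x$min_count))
  invisible(x)
}
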