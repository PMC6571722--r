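two_key_dos <- function() {
  # energies 0 and -1, equal degeneracy
  fabricate_dos(data.frame(Env_raw = c(0L, -1L), nst = c(0L, 0L),
                           log_g = c(0, 0)))
}

test_that("log_partition has the closed forms and gauge invariance", {
  single <- fabricate_dos(data.frame(Env_raw = 0L, nst = 0L, log_g = 0))
  expect_equal(log_partition(single, 0.7), 0)
  expect_equal(log_partition(single, 5), 0)
  d <- two_key_dos()
  expect_equal(log_partition(d, 1), log(1 + exp(1)))
  # adding a constant c to all log_g shifts logZ by exactly c
  dc <- d; dc$table$log_g <- dc$table$log_g + 3.7
  expect_equal(log_partition(dc, 1), log_partition(d, 1) + 3.7)
  expect_error(log_partition(d, 0), "> 0")
  empty <- d; empty$table <- empty$table[0, ]
  expect_error(log_partition(empty, 1), "empty")
})

test_that("canonical averages follow Boltzmann weighting", {
  d <- two_key_dos()
  # constant observable
  expect_equal(canonical_average(d, function(e, s) rep(7, length(e)), 0.5), 7)
  # <U> on the two-level system at T = 1: -e/(1+e)
  U <- function(e, s) as.numeric(e)
  expect_equal(canonical_average(d, U, 1), -exp(1) / (1 + exp(1)))
  # T -> 0+ limit: ground-state value
  expect_equal(canonical_average(d, U, 0.01), -1, tolerance = 1e-6)
  # masking with warning when the observable is missing somewhere
  a <- c(2, NA)
  expect_warning(v <- canonical_average(d, a, 1), "masked")
  expect_equal(v, 2)
  expect_error(canonical_average(d, c(NA_real_, NA_real_), 1), "every")
})

test_that("heat capacity matches the Schottky closed form", {
  # two levels 0 and -Delta with equal degeneracy:
  # CV = (D/T)^2 e^(D/T) / (1 + e^(D/T))^2
  delta <- 3
  d <- fabricate_dos(data.frame(Env_raw = c(0L, -3L), nst = c(0L, 0L),
                                log_g = c(0, 0)))
  tt <- seq(0.3, 4, by = 0.1)
  hc <- heat_capacity(d, tt)
  x <- delta / tt
  expect_equal(hc$CV, x^2 * exp(x) / (1 + exp(x))^2, tolerance = 1e-10)
  expect_true(all(hc$U2_mean >= hc$U_mean^2 - 1e-12))
  single <- fabricate_dos(data.frame(Env_raw = -2L, nst = 0L, log_g = 0))
  expect_equal(heat_capacity(single, 1)$CV, 0)
})

test_that("CV equals the numerical derivative of <U> with respect to T", {
  set.seed(20)
  # smooth synthetic DoS with both coordinates active
  tab <- expand.grid(Env_raw = -(0:12), nst = 0:3)
  tab$log_g <- -0.02 * (tab$Env_raw + 6)^2 - 0.4 * (tab$nst - 1.2)^2
  d <- fabricate_dos(tab)
  for (Tt in c(0.8, 1.5, 3)) {
    h <- 1e-4 * Tt
    du <- (heat_capacity(d, Tt + h, -1)$U_mean -
           heat_capacity(d, Tt - h, -1)$U_mean) / (2 * h)
    cv <- heat_capacity(d, Tt, -1)$CV
    expect_equal(cv, du, tolerance = 1e-6)
  }
})

test_that("macrostate probabilities are a normalized distribution", {
  d <- two_key_dos()
  for (Tt in c(0.3, 1, 4)) {
    p <- macrostate_probability(d, Tt)
    expect_lt(abs(sum(p$prob) - 1), 1e-12)
  }
  single <- fabricate_dos(data.frame(Env_raw = 0L, nst = 0L, log_g = 0))
  expect_equal(macrostate_probability(single, 1)$prob, 1)
  # k equal keys: 1/k each (equal log_g, equal energies)
  dk <- fabricate_dos(data.frame(Env_raw = rep(-2L, 4), nst = 0:3,
                                 log_g = 1.3))
  expect_equal(macrostate_probability(dk, 2, eps_st = 0)$prob, rep(0.25, 4))
  # gauge invariance of all canonical outputs
  dg <- d; dg$table$log_g <- dg$table$log_g - 11
  expect_equal(macrostate_probability(dg, 1)$prob,
               macrostate_probability(d, 1)$prob)
  expect_equal(heat_capacity(dg, 1.3)$CV, heat_capacity(d, 1.3)$CV)
})

test_that("cv_profile_T finds the Schottky peak where theory puts it", {
  delta <- 2
  d <- fabricate_dos(data.frame(Env_raw = c(0L, -2L), nst = c(0L, 0L),
                                log_g = c(0, 0)))
  tg <- seq(0.2, 3, by = 0.01)
  pr <- cv_profile_T(d, 0, tg)
  mx <- attr(pr, "maxima")
  expect_equal(nrow(mx), 1)
  # numerical max of the closed form: T* = 0.417 Delta
  tstar <- optimize(function(Tt) {
    x <- delta / Tt
    -x^2 * exp(x) / (1 + exp(x))^2
  }, c(0.2, 3))$minimum
  expect_equal(mx$x, tstar, tolerance = 0.02)
  expect_equal(tstar / delta, 0.417, tolerance = 1e-3)
  # maxima stable under grid refinement within one coarse step
  pr2 <- cv_profile_T(d, 0, seq(0.2, 3, by = 0.002))
  expect_lt(abs(attr(pr2, "maxima")$x - mx$x), 0.01)
  # monotone stretch of the curve: no maxima
  prm <- cv_profile_T(d, 0, seq(1.2, 3, by = 0.05))
  expect_equal(nrow(attr(prm, "maxima")), 0)
  expect_error(cv_profile_T(d, 0, c(1, 2)), "grid too short")
})

test_that("cv_profile_stiffness uses the nst coordinate of the same DoS", {
  # single nst column: energy independent of eps_st, so CV is too
  d1 <- fabricate_dos(data.frame(Env_raw = -(0:5), nst = 0L,
                                 log_g = -0.3 * (0:5)))
  pr <- cv_profile_stiffness(d1, 1, seq(-6, 0, by = 0.5))
  expect_equal(diff(range(pr$CV)), 0)
  expect_equal(nrow(attr(pr, "maxima")), 0)
  # phantom binomial DoS: angles are a two-level system in eps_st;
  # CV(eps_st) at fixed T has a single Schottky-type maximum
  p <- phantom_dos(8)
  db <- fabricate_dos(data.frame(Env_raw = 0L, nst = p$nst,
                                 log_g = log(p$g)))
  prb <- cv_profile_stiffness(db, 1, seq(-30, -0.25, by = 0.25))
  mxb <- attr(prb, "maxima")
  expect_equal(nrow(mxb), 1)
  # Schottky location: per-angle gap |eps_st| with degeneracy ratio
  # (1-p0)/p0; peak where d/dx of the two-level CV vanishes
  p0 <- phantom_p0()
  up <- optimize(function(e) {
    hc <- heat_capacity(db, 1, eps_st = e)
    -hc$CV
  }, c(-30, -1))$minimum
  expect_equal(mxb$x, up, tolerance = 0.5)
})

test_that("the state diagram surface is consistent with heat_capacity", {
  tab <- expand.grid(Env_raw = -(0:8), nst = 0:2)
  tab$log_g <- -0.05 * (tab$Env_raw + 4)^2 - 0.5 * tab$nst
  d <- fabricate_dos(tab)
  xg <- seq(0, 4, by = 0.5)   # eps_st / eps_ff with eps_ff = -1
  yg <- seq(0.2, 3, by = 0.2) # |eps_ff| / T
  sd_ <- build_state_diagram(d, xg, yg)
  expect_equal(dim(sd_$CV), c(length(yg), length(xg)))
  i <- 4; j <- 3
  hc <- heat_capacity(d, 1 / yg[i], eps_st = -xg[j])
  expect_equal(sd_$CV[i, j], hc$CV)
  # loci live on grid nodes
  if (nrow(sd_$maxima)) {
    expect_true(all(sd_$maxima$x %in% xg))
    expect_true(all(sd_$maxima$y %in% yg))
  }
  # transition markers map onto diagram coordinates
  tr <- data.frame(T_star = 0.5, order = "first", ensemble = "NVU",
                   eps_st = -1)
  sd2 <- add_transitions(sd_, tr)
  expect_equal(sd2$transitions$y, 2)
  expect_equal(sd2$transitions$x, 1)
})
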