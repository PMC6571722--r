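make_dos1d <- function(U, log_g, bin_width = diff(U[1:2]), eps_st = 0) {
  structure(data.frame(U = U, log_g = log_g),
            bin_width = bin_width, eps_st = eps_st, raw_scale = 1,
            class = c("sf_dos1d", "data.frame"))
}

# entropy with a convex intrusion: concave backbone + Gaussian dip, which
# produces a backbending loop in 1/T(U) (first-order fixture)
backbending_sb <- function(U) 30 * sqrt(U + 1) - 3 * exp(-(U - 5)^2 / (2 * 0.8^2))

test_that("projection to 1D conserves weight and merges equal energies", {
  tab <- expand.grid(Env_raw = -(0:6), nst = 0:2)
  tab$log_g <- rnorm(nrow(tab))
  set.seed(1)
  d <- fabricate_dos(tab)
  # eps_st = 0, raw_scale = 1: bins reproduce the Env marginal at width 1
  d1 <- project_dos_1d(d, eps_st = 0)
  expect_equal(attr(d1, "bin_width"), 1)
  expect_equal(nrow(d1), 7)
  marg <- tapply(tab$log_g, tab$Env_raw, function(x) {
    m <- max(x); m + log(sum(exp(x - m)))
  })
  expect_equal(d1$log_g, as.numeric(marg)[order(as.integer(names(marg)))],
               tolerance = 1e-12)
  # total weight conserved
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  expect_lt(abs(lse(d1$log_g) - lse(tab$log_g)), 1e-12)
  # two keys with identical U land in one bin with the log-sum of both
  dd <- fabricate_dos(data.frame(Env_raw = c(-2L, 0L), nst = c(0L, 2L),
                                 log_g = c(0.3, -0.1)))
  p1 <- project_dos_1d(dd, eps_st = -1)   # both keys have U = -2
  expect_equal(nrow(p1), 1)
  expect_equal(p1$log_g, lse(c(0.3, -0.1)))
  # incommensurate eps_st still conserves weight
  p2 <- project_dos_1d(d, eps_st = -sqrt(2))
  expect_lt(abs(lse(p2$log_g) - lse(tab$log_g)), 1e-12)
})

test_that("inverse temperature recovers linear and quadratic entropies", {
  u <- seq(0, 10, by = 0.05)
  lin <- inverse_temperature_U(make_dos1d(u, 0.8 * u + 2))
  expect_equal(lin$Tinv[is.finite(lin$Tinv)],
               rep(0.8, sum(is.finite(lin$Tinv))), tolerance = 1e-10)
  quad <- inverse_temperature_U(make_dos1d(u, -u^2 / 2))
  ok <- is.finite(quad$Tinv)
  expect_equal(quad$Tinv[ok], -u[ok], tolerance = 1e-6)
  expect_error(inverse_temperature_U(make_dos1d(c(0, 1), c(0, 0))),
               "insufficient support")
})

test_that("a constructed backbending entropy is classified first-order", {
  u <- seq(0, 12, by = 0.05)
  curve <- inverse_temperature_U(make_dos1d(u, backbending_sb(u)))
  tr <- classify_transitions(curve)
  tr <- tr[order(-tr$peak_height), ]
  expect_gte(nrow(tr), 1)
  expect_equal(tr$order[1], "first")
  expect_gt(tr$peak_height[1], 0)
  expect_equal(tr$U_star[1], 5, tolerance = 0.5)   # dip center
  expect_equal(tr$T_star[1], 1 / approx(curve$U, curve$Tinv, 5)$y,
               tolerance = 0.05)
  # backbending: 1/T(U) is non-monotone around the transition
  win <- curve$Tinv[curve$U > 3 & curve$U < 7]
  expect_gt(max(diff(win)), 0)
})

test_that("strictly concave entropies yield only second-order labels", {
  u <- seq(0, 10, by = 0.05)
  # concave with an inflection in its derivative: dTinv/dU < 0 everywhere
  sb <- 20 * log1p(u) - 0.5 * u
  curve <- inverse_temperature_U(make_dos1d(u, sb))
  ok <- is.finite(curve$dTinv)
  expect_true(all(curve$dTinv[ok] < 0))
  tr <- classify_transitions(curve, min_prominence = 0)
  if (nrow(tr)) expect_true(all(tr$order == "second"))
})

test_that("kinetic convolution reproduces the ideal-gas caloric law", {
  # delta-function g(U) at U0, d = 6: 1/T(E) = 2/(E - U0) exactly on-grid
  u0 <- -3
  d1 <- make_dos1d(u0, 0, bin_width = 0.5)
  eg <- seq(-2.5, 6, by = 0.25)
  cv <- convolve_kinetic(d1, d = 6, E_grid = eg)
  expect_equal(cv$Tinv, 2 / (cv$E - u0), tolerance = 1e-12)
  # T(E) increasing in E
  expect_true(all(diff(1 / cv$Tinv) > 0))
  expect_error(convolve_kinetic(d1, d = 1), "d must be")
  expect_error(convolve_kinetic(d1, d = 6, E_grid = c(-5, -4)), "above Umin")
})

test_that("the NVE convolution smooths oscillations, keeping the transition", {
  u <- seq(0, 12, by = 0.05)
  sb_osc <- backbending_sb(u) + 0.08 * sin(4 * pi * u)
  d1 <- make_dos1d(u, sb_osc)
  nvu <- inverse_temperature_U(d1)
  nve <- nve_curve(d1, d = 40)
  sign_changes <- function(x) {
    x <- diff(x, differences = 2)
    x <- x[abs(x) > 1e-10]
    sum(diff(sign(x)) != 0)
  }
  # strictly fewer curvature sign flips after convolution
  expect_lt(sign_changes(nve$Tinv), sign_changes(nvu$Tinv[is.finite(nvu$Tinv)]))
  # transition temperature preserved
  t_nvu <- classify_transitions(nvu)
  t_nvu <- t_nvu[which.max(t_nvu$peak_height), ]
  t_nve <- classify_transitions(nve, min_prominence = 1e-4)
  t_nve <- t_nve[which.max(t_nve$peak_height), ]
  expect_equal(t_nve$T_star, t_nvu$T_star, tolerance = 0.05)
  expect_equal(t_nve$ensemble, "NVE")
})

test_that("p(U|E) is normalized with the single-support limit exact", {
  u0 <- 1.5
  d1 <- make_dos1d(u0, 0, bin_width = 0.5)
  for (E in c(2, 5, 40)) {
    p <- conditional_U_given_E(d1, d = 12, E)
    expect_equal(p$p, 1)
    expect_equal(p$U, u0)
  }
  expect_equal(mean_U_of_E(d1, 12, c(2, 5, 40)), rep(u0, 3))
  expect_error(conditional_U_given_E(d1, 12, 1), "exceed")
  set.seed(4)
  for (i in 1:5) {
    u <- seq(0, 8, by = 0.2)
    d2 <- make_dos1d(u, rnorm(length(u), sd = 2))
    p <- conditional_U_given_E(d2, d = 20, E = runif(1, 1, 30))
    expect_lt(abs(sum(p$p) - 1), 1e-12)
    expect_true(all(p$U <= min(max(u), 30)))
  }
})

test_that("NVU finite differences match the binomial oracle exactly", {
  # phantom DoS over U = eps_st * nst: SB differences are those of
  # ln C(n,k) + k ln p0 + (n-k) ln(1-p0), computed here independently
  n <- 8; p0 <- phantom_p0(); est <- -2
  lgk <- lchoose(n, 0:n) + (0:n) * log(p0) + (n - (0:n)) * log(1 - p0)
  d <- fabricate_dos(data.frame(Env_raw = 0L, nst = 0:n, log_g = lgk))
  d1 <- project_dos_1d(d, eps_st = est)
  cur <- inverse_temperature_U(d1)
  # central difference of the closed form on the U = est * k grid
  # (U increasing means k decreasing)
  k_of_u <- cur$U / est
  inner <- which(is.finite(cur$Tinv))
  for (i in inner) {
    k <- k_of_u[i]
    ref <- (lgk[k] - lgk[k + 2]) / (2 * abs(est))  # dSB/dU, U = -2k
    expect_equal(cur$Tinv[i], ref, tolerance = 1e-10)
  }
})

test_that("both analyses recover their closed forms on the angle system", {
  # stiff angles are independent two-level units with gap |eps_st| and
  # degeneracy ratio p0/(1-p0); each analysis has an exact reference
  n <- 12; p0 <- phantom_p0(); est <- -20
  lgk <- lchoose(n, 0:n) + (0:n) * log(p0) + (n - (0:n)) * log(1 - p0)
  d <- fabricate_dos(data.frame(Env_raw = 0L, nst = 0:n, log_g = lgk))
  d1 <- project_dos_1d(d, eps_st = est)
  cur <- inverse_temperature_U(d1)
  # curvatures scale like 1/eps_st^2, so use a prominence floor well below
  tr <- classify_transitions(cur, min_prominence = 1e-7)
  tr <- tr[which.max(tr$peak_height), ]
  expect_equal(tr$order, "second")   # concave entropy: smooth crossover
  # the d(1/T)/dU peak sits at half filling, where the microcanonical
  # temperature equals the crossover value |est| / ln((1-p0)/p0)
  expect_equal(tr$T_star, abs(est) / log((1 - p0) / p0), tolerance = 0.02)
  # the CV(T) peak matches the single-angle Schottky closed form
  pr <- cv_profile_T(d, est, seq(2, 14, by = 0.02))
  mx <- attr(pr, "maxima")
  mx <- mx[which.max(mx$y), ]
  cv1 <- function(Tt) {
    z <- (p0 / (1 - p0)) * exp(-est / Tt)
    (est / Tt)^2 * z / (1 + z)^2
  }
  t_ref <- optimize(function(Tt) -cv1(Tt), c(2, 14))$minimum
  expect_equal(mx$x, t_ref, tolerance = 0.01)
  expect_equal(mx$y, n * cv1(t_ref), tolerance = 1e-3)
})
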