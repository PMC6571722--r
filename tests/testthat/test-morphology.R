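test_that("gyration radii match closed forms", {
  # two beads at distance d: Rg2 = d^2/4
  m2 <- sf_model(N = 2, b = 1)
  f2 <- morphology_features(rbind(c(0, 0, 0), c(1.2, 0, 0)), m2)
  expect_equal(f2$rg2_all, 1.2^2 / 4)
  # straight rod of N beads, spacing l: Rg2 = (N^2 - 1) l^2 / 12
  n <- 8; l <- 1.1
  m8 <- sf_model(N = n, b = 4)
  f8 <- morphology_features(rod_chain(n, l), m8)
  expect_equal(f8$rg2_all, (n^2 - 1) * l^2 / 12)
  # eigenvalue sum equals Rg2 for every subset
  expect_equal(f8$lam1_all + f8$lam2_all + f8$lam3_all, f8$rg2_all,
               tolerance = 1e-10)
  expect_equal(f8$lam1_S + f8$lam2_S + f8$lam3_S, f8$rg2_S,
               tolerance = 1e-10)
})

test_that("order parameters behave at symmetric configurations", {
  n <- 8
  m8 <- sf_model(N = n, b = 4)
  f8 <- morphology_features(rod_chain(n), m8)
  expect_equal(f8$s_nem, 1)            # all S-bonds parallel
  expect_equal(f8$ext_S, 1)            # fully extended S block
  expect_equal(f8$n_folds, 0)
  # antiparallel bonds still give S_nem = 1 (nematic, not polar, order)
  hairpin <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 2, 0), c(1, 2, 0), c(1, 3, 0), c(0, 3, 0))
  mh <- sf_model(N = 8, b = 1)  # alternating S F S F ...: S-S bonds absent
  fh <- morphology_features(hairpin, mh)
  expect_equal(fh$s_nem, 0)    # no S-S bonds at b = 1
  # perfect tetrahedron: zero asphericity
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  m4 <- sf_model(N = 4, b = 1)
  f4 <- morphology_features(tet, m4)
  expect_equal(f4$asph_all, 0, tolerance = 1e-12)
  # demixing ratio is a fraction
  expect_gte(f4$demix, 0); expect_lte(f4$demix, 1)
})

test_that("features are invariant under rigid motions", {
  set.seed(15)
  m <- sf_model(N = 12, b = 3, preset = "S-attract")
  for (i in 1:8) {
    conf <- random_conformation(m)
    a <- morphology_features(conf, m)
    b <- morphology_features(rigid_motion(conf), m)
    expect_equal(as.list(a), as.list(b), tolerance = 1e-8)
  }
})

test_that("compiled production observables equal the R reference", {
  set.seed(16)
  m <- sf_model(N = 16, b = 4, preset = "F-attract", eps_st = -3)
  for (i in 1:10) {
    conf <- random_conformation(m)
    cpp <- sfcopoly:::cc_observables(conf, sfcopoly:::model_cpp(m))
    r <- morphology_features(conf, m)
    expect_equal(cpp[["rg2_all"]], r$rg2_all, tolerance = 1e-12)
    expect_equal(cpp[["rg2_S"]], r$rg2_S, tolerance = 1e-12)
    expect_equal(cpp[["rg2_F"]], r$rg2_F, tolerance = 1e-12)
    expect_equal(unname(cpp[c("lam1_all", "lam2_all", "lam3_all")]),
                 c(r$lam1_all, r$lam2_all, r$lam3_all), tolerance = 1e-9)
    expect_equal(unname(cpp[c("lam1_S", "lam2_S", "lam3_S")]),
                 c(r$lam1_S, r$lam2_S, r$lam3_S), tolerance = 1e-9)
    expect_equal(cpp[["s_nem"]], r$s_nem, tolerance = 1e-9)
    expect_equal(cpp[["s_planar"]], r$s_planar, tolerance = 1e-9)
    expect_equal(unname(cpp[c("nss", "nff", "nsf")]),
                 c(r$nss, r$nff, r$nsf))
    expect_equal(cpp[["ext_S"]], r$ext_S, tolerance = 1e-12)
    expect_equal(cpp[["n_folds"]], r$n_folds)
    expect_equal(cpp[["demix"]], r$demix, tolerance = 1e-12)
  }
})

test_that("the classifier follows the taxonomy on archetypal inputs", {
  m <- sf_model(N = 32, b = 8, preset = "S-attract")
  th <- sf_thresholds()
  base <- morphology_features(rod_chain(32), m)

  # expanded chain, S blocks not extended: Ia
  coil <- base
  coil$rg2_all <- 8; coil$rg2_S <- 4; coil$rg2_F <- 4
  coil$ext_S <- 0.6; coil$s_nem <- 0.2; coil$s_planar <- 0.2
  r <- classify_morphology(coil, m, th)
  expect_equal(r$label, "Ia")
  expect_gt(length(r$trace), 0)

  # expanded chain with extended S blocks: Ib
  ib <- coil; ib$ext_S <- 0.97
  expect_equal(classify_morphology(ib, m, th)$label, "Ib")

  # F blocks collapsed, S blocks still extended: flower/tadpole IIc
  iic <- coil; iic$rg2_F <- 0.6; iic$ext_S <- 0.95; iic$rg2_S <- 6
  expect_equal(classify_morphology(iic, m, th)$label, "IIc")

  # compact, isotropic, few contacts: liquid globule IIa
  iia <- coil
  iia$rg2_all <- 1.8; iia$rg2_S <- 1; iia$rg2_F <- 0.8
  iia$ext_S <- 0.4; iia$s_nem <- 0.2
  iia$nss <- 20; iia$nff <- 20; iia$nsf <- 20   # 3.75 per bead
  expect_equal(classify_morphology(iia, m, th)$label, "IIa")

  # same but densely packed: frozen globule IIb
  iib <- iia; iib$nss <- 40; iib$nff <- 40; iib$nsf <- 40
  expect_equal(classify_morphology(iib, m, th)$label, "IIb")

  # compact and nematically ordered, prolate, loose F shell: dumbbell IIIa
  iiia <- iia; iiia$s_nem <- 0.85; iiia$prol_S <- 0.5; iiia$n_folds <- 0
  iiia$nsf <- 5
  expect_equal(classify_morphology(iiia, m, th)$label, "IIIa")

  # prolate, ordered, dense F shell: lamellar IIIc
  iiic <- iiia; iiic$nsf <- 40
  expect_equal(classify_morphology(iiic, m, th)$label, "IIIc")

  # folded S blocks with adsorbed F shell: IIIe; loose shell: IIIe'
  iiie <- iia; iiie$s_nem <- 0.8; iiie$prol_S <- 0.3; iiie$n_folds <- 3
  iiie$nsf <- 40
  expect_equal(classify_morphology(iiie, m, th)$label, "IIIe")
  iiiep <- iiie; iiiep$nsf <- 4
  expect_equal(classify_morphology(iiiep, m, th)$label, "IIIe'")

  # classification is a pure function of (features, thresholds)
  expect_identical(classify_morphology(iia, m, th),
                   classify_morphology(iia, m, th))
})

test_that("the toroid test distinguishes Saturn-like globules", {
  m <- sf_model(N = 32, b = 8, preset = "S-attract")
  # S beads on a ring of radius 2 (hole), F beads clustered at center
  s_idx <- which(m$types == 1L); f_idx <- which(m$types == 0L)
  coords <- matrix(0, 32, 3)
  ang <- seq(0, 2 * pi, length.out = length(s_idx) + 1)[-1]
  coords[s_idx, ] <- cbind(2 * cos(ang), 2 * sin(ang), 0)
  set.seed(17)
  coords[f_idx, ] <- matrix(rnorm(3 * length(f_idx), sd = 0.4), ncol = 3)
  f <- morphology_features(coords, m)
  # tangential winding: high planar order even though s_nem is small
  expect_gt(f$s_planar, 0.4)
  expect_lt(f$s_nem, 0.6)
  r <- classify_morphology(f, m, sf_thresholds(), coords = coords)
  expect_equal(r$label, "IIId")
  expect_true(any(grepl("hole", r$trace)))
})

test_that("per-macrostate feature means respect counts and limits", {
  m <- phantom_allS(6)
  p <- phantom_dos(4)
  dos <- fabricate_dos(data.frame(Env_raw = 0L, nst = p$nst,
                                  log_g = log(p$g)))
  dos$fingerprint <- model_fingerprint(m)
  obs <- production_run(m, dos, n_mcs = 2e4, seed = 21, min_count = 10)
  ft <- mean_features_by_macrostate(obs)
  expect_equal(nrow(ft), nrow(obs$table))
  expect_equal(sum(ft$count), sum(obs$table$count))
  expect_true(all(ft$lam1_all >= ft$lam2_all - 1e-12))
  expect_true(all(ft$s_nem >= 0 & ft$s_nem <= 1 + 1e-9))
})

test_that("rg2 derivative curves locate the two-level crossover", {
  # keys with distinct Rg2 and an energy gap: the derivative of the
  # reweighted <Rg2> peaks where the two weights cross (x* = log_g gap / dU)
  d <- fabricate_dos(data.frame(Env_raw = c(0L, -2L), nst = c(0L, 0L),
                                log_g = c(2, 0)))
  tab <- list(table = data.frame(Env_raw = c(0L, -2L), nst = c(0L, 0L),
                                 count = c(10, 10), rg2_all = c(10, 2),
                                 rg2_S = c(5, 1), rg2_F = c(5, 1)))
  xg <- seq(0.2, 3, by = 0.02)
  cur <- rg2_derivative_curve(d, tab, eps_st = 0, x_grid = xg)
  # closed form: <Rg2>(x) = (10 + 2 e^(2x-2)) / (1 + e^(2x-2))
  w <- exp(2 * xg - 2)
  expect_equal(cur$rg2, (10 + 2 * w) / (1 + w), tolerance = 1e-10)
  mx <- attr(cur, "maxima")
  expect_equal(mx$x[which.max(mx$y)], 1, tolerance = 0.05)  # 2/2 = 1
  # constant observable: derivative identically zero
  tabc <- list(table = transform(tab$table, rg2_all = 7))
  curc <- rg2_derivative_curve(d, tabc, 0, xg)
  expect_true(all(abs(curc$drg2_dx[is.finite(curc$drg2_dx)]) < 1e-10))
})
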