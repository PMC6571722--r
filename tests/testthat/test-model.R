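test_that("solvent presets carry the published energies and rescaling", {
  ms <- sf_model(N = 16, b = 4, preset = "S-attract")
  expect_equal(c(ms$eps_ss, ms$eps_sf, ms$eps_ff), c(-4, -2, -1))
  expect_equal(ms$raw_scale, 1)
  expect_identical(ms$eps_raw, c(-4L, -1L, -2L))  # ss, ff, sf

  mf <- sf_model(N = 16, b = 4, preset = "F-attract-stronger")
  expect_equal(c(mf$eps_ss, mf$eps_sf, mf$eps_ff), c(-0.25, -0.5, -1))
  expect_identical(mf$eps_raw, c(-1L, -4L, -2L))
  expect_equal(mf$raw_scale, 0.25)

  mn <- sf_model(N = 16, b = 4, preset = "non-selective")
  expect_equal(c(mn$eps_ss, mn$eps_sf, mn$eps_ff), c(-1, -1, -1))

  # Lorentz-Berthelot: |eps_sf| = sqrt(|ss| * |ff|)
  mc <- sf_model(N = 8, b = 2, eps = c(ss = -4, ff = -1, sf = -2))
  expect_equal(abs(mc$eps_sf), sqrt(abs(mc$eps_ss) * abs(mc$eps_ff)))
  expect_error(sf_model(N = 8, b = 2, eps = c(ss = -4, ff = -1, sf = -3)),
               "Lorentz-Berthelot")
  # non-integer raw energies are rejected before anything else
  expect_error(sf_model(N = 8, b = 2, eps = c(ss = -4, ff = -1, sf = -1.5)),
               "integers")
})

test_that("model invariants are enforced", {
  expect_error(sf_model(N = 10, b = 4), "divisible")
  expect_error(sf_model(N = 8, b = 2, l_max = 1.5), "sqrt")
  expect_error(sf_model(N = 8, b = 2, l_min = 1.3, l_max = 1.2), "l_min")
  expect_error(sf_model(N = 8, b = 2, theta_min = 170, theta_max = 150),
               "angle window")
  expect_error(sf_model(N = 8, b = 2, eps_st = 1), "eps_st")

  m <- sf_model(N = 16, b = 4)
  expect_equal(sum(m$types), 8L)                      # equal composition
  expect_identical(m$pattern[1:8], c(rep("S", 4), rep("F", 4)))
  expect_equal(nst_max(m), (m$b - 2) * m$N / (2 * m$b))
  mF <- sf_model(N = 16, b = 4, start_type = "F")
  expect_identical(mF$pattern[1:4], rep("F", 4))
})

test_that("contact counting matches hand-built geometries", {
  # two non-bonded beads at distance 1.2 sigma: one contact; at 1.6: none
  m3 <- sf_model(N = 3, b = 3, pattern = c("S", "S", "S"))
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(1 - 0.28, 0.96, 0))
  expect_equal(sqrt(sum((near[3, ] - near[1, ])^2)), 1.2)
  expect_equal(count_contacts(near, m3)$nss, 1L)
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.28, 0.96, 0))
  expect_equal(sqrt(sum((far[3, ] - far[1, ])^2)), 1.6)
  expect_equal(count_contacts(far, m3)$nss, 0L)

  # perfectly straight S block: all angles at 180, outside [150, 170]
  m6 <- phantom_allS(6)
  expect_equal(count_contacts(rod_chain(6), m6)$nst, 0L)

  # all-S N=4 zig-zag with both angles at 160 degrees
  m4 <- sf_model(N = 4, b = 4, pattern = rep("S", 4), phantom = TRUE)
  expect_equal(count_contacts(zigzag_chain(4, 160), m4)$nst, 2L)
  # and at 140 degrees (outside the window)
  expect_equal(count_contacts(zigzag_chain(4, 140), m4)$nst, 0L)

  # angle eligibility: triplets spanning a block junction never count
  m4sf <- sf_model(N = 4, b = 2)  # S S F F: no all-S triplet
  expect_equal(count_contacts(zigzag_chain(4, 160), m4sf)$nst, 0L)
})

test_that("energy breakdown follows the square-well bookkeeping", {
  m <- sf_model(N = 16, b = 4, preset = "S-attract", eps_st = -2)
  e <- chain_energy(list(nss = 2, nff = 1, nsf = 3, nst = 0), m)
  expect_equal(e$Env, -15)  # -4*2 - 1*1 - 2*3
  e0 <- chain_energy(list(nss = 0, nff = 0, nsf = 0, nst = 0), m)
  expect_equal(c(e0$Env, e0$Est, e0$U), c(0, 0, 0))
  e2 <- chain_energy(list(nss = 2, nff = 1, nsf = 3, nst = 7), m)
  expect_equal(e2$U, -15 + (-2) * 7)  # U = Env + eps_st * nst = -29
  # raw units recover physical units through raw_scale
  mf <- sf_model(N = 16, b = 4, preset = "F-attract")
  ef <- chain_energy(list(nss = 1, nff = 1, nsf = 1, nst = 0), mf)
  expect_equal(ef$Env_raw, -7L)
  expect_equal(ef$Env, -1.75)
  expect_equal(ef$Env, 0.25 * ef$Env_raw)
})

test_that("validation permits bonded interpenetration but not overlaps", {
  m <- sf_model(N = 4, b = 2)
  # bonded pair at 0.9 sigma: valid (interpenetration allowed)
  ok <- rbind(c(0, 0, 0), c(0.9, 0, 0), c(1.9, 0, 0), c(2.9, 0, 0))
  expect_true(validate_conformation(ok, m)$valid)
  # non-bonded pair at 0.9 sigma: hard-sphere violation
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.45, 0.8, 0), c(1.45, 0.8, 0))
  expect_lt(sqrt(sum((bad[3, ] - bad[1, ])^2)), 1)
  v <- validate_conformation(bad, m)
  expect_false(v$valid)
  expect_match(v$violation, "hard-sphere")
  # bond of length 1.3 sigma: outside [0.8, 1.25]
  long <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(2.3, 0, 0), c(3.3, 0, 0))
  v2 <- validate_conformation(long, m)
  expect_false(v2$valid)
  expect_match(v2$violation, "bond")
})

test_that("compiled contact counts agree with the all-pairs R oracle", {
  set.seed(42)
  m <- sf_model(N = 12, b = 2, preset = "S-attract")
  for (i in 1:20) {
    conf <- random_conformation(m)
    expect_identical(count_contacts(conf, m), count_oracle(conf, m))
  }
})

test_that("counts and energies are invariant under rigid motions", {
  set.seed(7)
  m <- sf_model(N = 12, b = 3, preset = "F-attract", eps_st = -5)
  for (i in 1:10) {
    conf <- random_conformation(m)
    moved <- rigid_motion(conf)
    expect_identical(count_contacts(conf, m), count_contacts(moved, m))
    expect_equal(chain_energy(conf, m), chain_energy(moved, m))
    expect_true(validate_conformation(moved, m)$valid)
  }
})

test_that("phantom-chain stiff angles are Binomial(n_angles, p0)", {
  # each eligible angle of an ideal chain is favorable with probability
  # p0 = (cos theta_min - cos theta_max) / 2; direct sampling check
  set.seed(11)
  m <- phantom_allS(10)
  n_ang <- nst_max(m)
  p0 <- phantom_p0()
  n_rep <- 3000
  nst <- replicate(n_rep, count_contacts(random_conformation(m), m)$nst)
  # se of mean(nst) under angle independence: sqrt(n_ang p0 (1-p0) / n_rep)
  se_mean <- sqrt(n_ang * p0 * (1 - p0) / n_rep)
  expect_lt(abs(mean(nst) - n_ang * p0), 3 * se_mean)
  # variance consistent with independence of angles
  expect_equal(var(nst), n_ang * p0 * (1 - p0), tolerance = 0.15)
})

test_that("bonds cannot cross in valid conformations (l_max < sqrt(2) sigma)", {
  seg_dist <- function(p1, p2, q1, q2) {
    # minimum distance between segments [p1,p2] and [q1,q2]
    best <- Inf
    for (s in seq(0, 1, length.out = 21))
      for (t in seq(0, 1, length.out = 21)) {
        a <- p1 + s * (p2 - p1); b <- q1 + t * (q2 - q1)
        best <- min(best, sqrt(sum((a - b)^2)))
      }
    best
  }
  set.seed(3)
  m <- sf_model(N = 10, b = 5, preset = "S-attract")
  for (rep in 1:5) {
    conf <- random_conformation(m)
    for (i in 1:(m$N - 3)) for (j in (i + 2):(m$N - 1)) {
      d <- seg_dist(conf[i, ], conf[i + 1, ], conf[j, ], conf[j + 1, ])
      expect_gt(d, 0.05)
    }
  }
})
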