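fc <- force_constants()

test_that("driving force relaxes towards the desired velocity", {
  a <- agent(1, 0, 0, vx = 0, vy = 0, mass = 80, v0 = 1, tau = 0.5)
  expect_equal(driving_force(a, c(10, 0)), c(160, 0))

  # at desired speed towards the goal: fixed point, zero force
  a2 <- agent(1, 0, 0, vx = 1, vy = 0, mass = 80, v0 = 1, tau = 0.5)
  expect_equal(driving_force(a2, c(10, 0)), c(0, 0))

  # v0 = 0: pure braking
  a3 <- agent(1, 0, 0, vx = 2, vy = -1, mass = 80, v0 = 0, tau = 0.5)
  expect_equal(driving_force(a3, c(10, 0)), -80 * c(2, -1) / 0.5)
})

test_that("social repulsion: magnitude at contact, decay, antisymmetry", {
  ai <- agent(1, 0, 0, radius = 0.25)
  aj <- agent(2, 0.5, 0, radius = 0.25)  # d = r_ij: exponent zero
  f <- social_repulsion(ai, aj, fc)
  expect_equal(f, c(-fc$A_social, 0))

  far <- social_repulsion(ai, agent(2, 40, 0, radius = 0.25), fc)
  expect_lt(sqrt(sum(far^2)), 1e-100)

  # strictly decreasing in distance
  d <- seq(0.5, 3, by = 0.25)
  mags <- vapply(d, function(dd)
    sqrt(sum(social_repulsion(ai, agent(2, dd, 0, radius = 0.25), fc)^2)), 1)
  expect_true(all(diff(mags) < 0))

  expect_equal(social_repulsion(aj, ai, fc), -social_repulsion(ai, aj, fc))
})

test_that("contact force: nullity, radial magnitude and friction sign", {
  ai <- agent(1, 0, 0, radius = 0.25)
  # no contact at d >= r_ij
  expect_equal(contact_force_pair(ai, agent(2, 0.6, 0, radius = 0.25), fc),
               c(0, 0))
  # 1 cm overlap, zero relative velocity: k * 0.01 = 1200 N along n
  f <- contact_force_pair(ai, agent(2, 0.49, 0, radius = 0.25), fc)
  expect_equal(f, c(-1200, 0), tolerance = 1e-12)

  # sliding: tangential component opposes the relative tangential motion
  am <- agent(1, 0, 0, vy = 1, radius = 0.25)
  f2 <- contact_force_pair(am, agent(2, 0.49, 0, radius = 0.25), fc)
  expect_lt(f2[2], 0)

  # approaching agents: damping adds to the repulsion (dissipative sign)
  ap <- agent(1, 0, 0, vx = 1, radius = 0.25)
  f3 <- contact_force_pair(ap, agent(2, 0.49, 0, vx = -1, radius = 0.25), fc)
  expect_lt(f3[1], -1200)
})

test_that("contact force is exactly antisymmetric over random pairs", {
  set.seed(31)
  for (k in 1:10000) {
    ai <- agent(1, runif(1, 0, 1), runif(1, 0, 1), vx = runif(1, -2, 2),
                vy = runif(1, -2, 2), radius = runif(1, 0.25, 0.3))
    aj <- agent(2, runif(1, 0, 1), runif(1, 0, 1), vx = runif(1, -2, 2),
                vy = runif(1, -2, 2), radius = runif(1, 0.25, 0.3))
    fij <- contact_force_pair(ai, aj, fc)
    fji <- contact_force_pair(aj, ai, fc)
    if (any(fij != 0) || any(fji != 0)) {
      expect_identical(fij, -fji)
    }
  }
})

test_that("wall contact force: nullity, radial magnitude, friction sign", {
  seg <- c(0, 0, 0, 10)  # wall along x = 0
  a <- agent(1, 0.5, 5, radius = 0.3)
  expect_equal(wall_contact_force(a, seg, fc), c(0, 0))

  # 2 cm penetration, zero velocity: 1.2e5 * 0.02 = 2400 N along the normal
  a2 <- agent(1, 0.28, 5, radius = 0.3)
  expect_equal(wall_contact_force(a2, seg, fc), c(2400, 0), tolerance = 1e-12)

  # sliding parallel to the wall while overlapping: friction opposes motion
  a3 <- agent(1, 0.28, 5, vy = 1.5, radius = 0.3)
  f <- wall_contact_force(a3, seg, fc)
  expect_lt(f[2], 0)
  expect_equal(f[2], -fc$kappa_friction * 0.02 * 1.5, tolerance = 1e-9)
})

test_that("contact magnitudes: vector cancellation vs scalar compression", {
  # symmetric squeeze: two opposing contacts cancel in the net vector but
  # add in the scalar sum
  crowd <- dplyr::bind_rows(
    agent(1, 0, 0, radius = 0.25),
    agent(2, 0.49, 0, radius = 0.25),
    agent(3, -0.49, 0, radius = 0.25))
  m <- contact_magnitudes(crowd, arena = NULL, fc = fc)
  expect_equal(m$net_N[1], 0, tolerance = 1e-9)
  expect_equal(m$scalar_N[1], 2400, tolerance = 1e-9)
  expect_equal(m$net_N[2], 1200, tolerance = 1e-9)

  # isolated agent: zero
  iso <- contact_magnitudes(agent(9, 5, 5), arena = NULL, fc = fc)
  expect_equal(iso$net_N, 0)
})

test_that("sum of all pairwise forces vanishes over a random crowd", {
  set.seed(32)
  n <- 30
  crowd <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    agent(i, runif(1, 0, 3), runif(1, 0, 3), vx = runif(1, -1, 1),
          vy = runif(1, -1, 1), radius = runif(1, 0.25, 0.3))))
  tot <- c(0, 0)
  mag <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      f1 <- contact_force_pair(crowd[i, ], crowd[j, ], fc) +
        social_repulsion(crowd[i, ], crowd[j, ], fc)
      f2 <- contact_force_pair(crowd[j, ], crowd[i, ], fc) +
        social_repulsion(crowd[j, ], crowd[i, ], fc)
      tot <- tot + f1 + f2
      mag <- mag + sqrt(sum(f1^2)) + sqrt(sum(f2^2))
    }
  }
  expect_lt(sqrt(sum(tot^2)), 1e-9 * mag)
})
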