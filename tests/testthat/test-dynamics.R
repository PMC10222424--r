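# Reaction terms, stepping scheme and its conservation/stability properties.

test_that("reaction terms match hand evaluation", {
  p <- dynamic_params()
  # resting equilibrium of any active region (delta = 0)
  r <- reaction_term(0, 0, "ventricles", p)
  expect_equal(r$du1, 0)
  expect_equal(r$du2, 0)
  # u1 = 1 is the excited root; the gate grows at eps * beta * u1
  r <- reaction_term(1, 0, "atria", p)
  expect_equal(r$du1, 0)
  expect_equal(r$du2, 0.015 * 0.5 * 1)
  # passive tissue carries no source at any state
  r <- reaction_term(0.5, 0.2, "torso", p)
  expect_equal(r$du1, 0)
  expect_equal(r$du2, 0)
  # cubic roots are {0, theta, alpha} and the interval (theta, 1) regenerates
  th <- p$theta_by_region[["atria"]]
  for (u in c(0, th, 1))
    expect_equal(reaction_term(u, 0, "atria", p)$du1, 0)
  expect_gt(reaction_term((th + 1) / 2, 0, "atria", p)$du1, 0)
  expect_lt(reaction_term(th / 2, 0, "atria", p)$du1, 0)
})

test_that("table defaults are wired per region", {
  p <- dynamic_params()
  expect_equal(unname(p$epsilon_by_region[active_regions()]),
               c(0.003, 0.015, 0.015, 0.01, 0.01, 0.005, 0.005))
  expect_equal(unname(p$diffusion_by_region[
    c("torso", "lung", "sinoatrial_node", "atria", "atrioventricular_node",
      "his_bundle", "bundle_branches", "purkinje_fibers", "ventricles",
      "blood_chamber")]),
    c(0.2, 0.2, 0.1, 0.15, 0.1, 0.1, 0.1, 0.3, 0.1, 0.7))
  expect_equal(p$alpha, 1); expect_equal(p$beta, 0.5)
  expect_equal(p$gamma, 1); expect_equal(p$delta, 0)
  expect_error(dynamic_params(diffusion = c(fibrous_barrier = 0.1)),
               "non-conducting")
})

test_that("the resting state is a fixed point of the step", {
  ph <- test_phantom()
  st <- field_state(ph)
  st2 <- uniecg:::advance_field(st, ph, dt = 0.05, nsteps = 50)
  expect_identical(max(abs(st2$u1)), 0)
  expect_identical(max(abs(st2$u2)), 0)
})

test_that("a diffusionless cell reproduces the scalar two-variable ODE", {
  lab <- matrix("ventricles", 1, 1)
  p <- dynamic_params(diffusion = c(ventricles = 0))
  ph <- phantom_from_labels(lab, spacing = 0.5, params = p)
  st <- field_state(ph)
  st$u1[1, 1] <- 0.4
  dt <- 0.05
  # independent scalar Euler integration of the same equations
  u1 <- 0.4; u2 <- 0
  th <- p$theta_by_region[["ventricles"]]
  for (k in 1:400) {
    d1 <- u1 * (u1 - th) * (1 - u1) - u2
    d2 <- 0.005 * (0.5 * u1 - u2)
    u1 <- u1 + dt * d1
    u2 <- u2 + dt * d2
  }
  st2 <- uniecg:::advance_field(st, ph, dt, 400)
  expect_equal(st2$u1[1, 1], u1, tolerance = 1e-12)
  expect_equal(st2$u2[1, 1], u2, tolerance = 1e-12)
})

test_that("steps beyond the stability bound are refused by name", {
  ph <- test_phantom()
  bad <- 10 * ph$spacing^2 / max(ph$params$diffusion_by_region)
  expect_error(step_field(field_state(ph), ph, bad), "stability bound")
})

test_that("the zero-flux Laplacian conserves total u1 in a passive sheet", {
  lab <- matrix("torso", 40, 40)
  ph <- phantom_from_labels(lab, spacing = 0.5)
  st <- field_state(ph)
  set.seed(7)
  st$u1 <- matrix(runif(1600), 40, 40)
  total0 <- sum(st$u1)
  st2 <- uniecg:::advance_field(st, ph, dt = 0.2, nsteps = 2000)
  expect_equal(sum(st2$u1), total0, tolerance = 1e-9)
  # and relaxes toward the spatial mean
  expect_lt(sd(st2$u1), 0.05 * sd(st$u1))
})

test_that("plane-wave speed increases with the diffusion coefficient", {
  # same excitability, Purkinje diffusion (0.3) vs ventricular (0.1)
  fast <- strip_state("purkinje_fibers")
  slow <- strip_state("ventricles")
  dt <- 0.05; nsteps <- 4000
  ffast <- front_column(uniecg:::advance_field(fast$state, fast$phantom,
                                               dt, nsteps)$u1)
  fslow <- front_column(uniecg:::advance_field(slow$state, slow$phantom,
                                               dt, nsteps)$u1)
  expect_gt(fslow, 10)          # both strips propagate at all
  expect_gt(ffast, 1.3 * fslow) # and the high-D strip is clearly faster
})
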