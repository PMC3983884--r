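test_that("formal charges land on the titratable groups and termini", {
  h <- fx_helix30()  # poly-alanine: termini only
  ch <- assign_charges(h)
  expect_equal(sum(ch$q), 0, tolerance = 1e-12)
  expect_equal(sum(ch$q > 0), 1)  # N-terminal N
  expect_equal(sum(ch$q != 0), 2)

  asp <- place_sidechains(build_backbone(new_ca_trace(.hx(5)),
                                         c("ALA", "ALA", "ASP", "ALA", "ALA")))
  qa <- assign_charges(asp)
  side <- qa$q[asp$atoms$resno == 3 & asp$atoms$atom %in% c("OD1", "OD2")]
  expect_equal(side, c(-0.5, -0.5))
  expect_equal(sum(qa$q), -1, tolerance = 1e-12)  # +1 N-term, -1 C-term, -1 Asp

  tt <- fx_tetramer()
  qt <- assign_charges(tt)
  qa1 <- assign_charges(get_chain(tt, "A"))
  expect_equal(sum(qt$q), 4 * sum(qa1$q), tolerance = 1e-9)
})

test_that("the Poisson solver reproduces the Coulomb closed form in uniform dielectric", {
  cfg <- grid_config(dims = 65L, spacing = 1, eps_protein = 80, eps_solvent = 80)
  g <- solve_poisson(data.frame(x = 0, y = 0, z = 0, q = 1, radius = 0), cfg)
  for (r in c(5, 10, 20)) {
    fd <- c2s:::interp_grid(g, cbind(r, 0, 0))
    coulomb <- 1000 * 14.3996454 / (80 * r)
    expect_lt(abs(fd - coulomb) / coulomb, 0.05)
  }
})

test_that("no charges gives the zero field and linearity holds", {
  cfg <- grid_config(dims = 33L)
  g0 <- solve_poisson(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                                 q = numeric(0), radius = numeric(0)), cfg)
  expect_true(all(g0$values == 0))

  q1 <- data.frame(x = 3, y = 0, z = 2, q = 1, radius = 2)
  q2 <- data.frame(x = -4, y = 1, z = -3, q = -0.5, radius = 2)
  tol <- 1e-4
  ga <- solve_poisson(q1, cfg, tol = 1e-8)
  gb <- solve_poisson(q2, cfg, tol = 1e-8)
  gab <- solve_poisson(rbind(q1, q2), cfg, tol = 1e-8)
  expect_lt(max(abs(gab$values - ga$values - gb$values)),
            1e-3 * max(abs(gab$values)))
})

test_that("opposite charges give an antisymmetric axial profile", {
  cp <- make_charge_pair(10)
  expect_equal(sum(cp$q), 0)
  g <- solve_poisson(cp, grid_config(dims = 33L))
  pr <- axial_profile(g)
  expect_equal(pr$phi[pr$z == 0], 0, tolerance = 1e-9)
  expect_equal(pr$phi, -rev(pr$phi), tolerance = 1e-7)
})

test_that("axial profiles interpolate exactly on linear fields", {
  n <- 17
  vals <- array(0, c(n, n, n))
  for (k in 1:n) vals[, , k] <- 2.5 * (k - 9)  # phi = 2.5 * z
  grid <- structure(list(values = vals, origin = c(-8, -8, -8), spacing = 1),
                    class = "PotentialGrid")
  pr <- axial_profile(grid, axis_xy = c(0.3, -0.7), z_range = c(-5, 5))
  expect_equal(pr$phi, 2.5 * pr$z, tolerance = 1e-9)
  # off-node evaluation matches independent trilinear arithmetic
  v <- c2s:::interp_grid(grid, cbind(0.25, 0.5, 1.75))
  expect_equal(v, 2.5 * 1.75, tolerance = 1e-9)
  expect_error(axial_profile(grid, axis_xy = c(99, 0)), "outside")
})

test_that("profile parameterization finds the extrema and flags ties", {
  z <- seq(0, 2 * pi, length.out = 64)
  pr <- structure(data.frame(z = z, phi = sin(z)),
                  class = c("AxialProfile", "data.frame"))
  pp <- profile_params(pr)
  expect_equal(pp$Fmax, max(sin(z)), tolerance = 1e-9)
  expect_equal(pp$Fmin, min(sin(z)), tolerance = 1e-9)
  expect_equal(pp$zmin, z[which.min(sin(z))])
  expect_false(pp$tie)
  flat <- structure(data.frame(z = 1:5, phi = rep(2, 5)),
                    class = c("AxialProfile", "data.frame"))
  pf <- profile_params(flat)
  expect_true(pf$tie)
  expect_equal(pf$Fmax, pf$Fmin)
})

test_that("profile distance is a calibrated metric on the common grid", {
  z <- seq(-10, 10, by = 1)
  a <- structure(data.frame(z = z, phi = sin(z / 3) * 5),
                 class = c("AxialProfile", "data.frame"))
  expect_equal(profile_distance(a, a)$rmse, 0)
  b <- a; b$phi <- b$phi + 1
  d <- profile_distance(b, a)
  expect_equal(d$rmse, 1, tolerance = 1e-12)
  c_ <- a; c_$phi <- c_$phi * 2
  dab <- profile_distance(a, b)$rmse
  dbc <- profile_distance(b, c_)$rmse
  dac <- profile_distance(a, c_)$rmse
  expect_equal(profile_distance(b, a)$rmse, profile_distance(a, b)$rmse)
  expect_lte(dac, dab + dbc + 1e-12)
  # relative deviations use the template values
  expect_equal(profile_distance(c_, a)$dFmax, 1, tolerance = 1e-9)
  z2 <- structure(data.frame(z = z + 100, phi = a$phi),
                  class = c("AxialProfile", "data.frame"))
  expect_error(profile_distance(z2, a), "overlap")
})

test_that("the dielectric boundary matters: burying a charge deepens the pore minimum", {
  # a ring of negative charge inside protein dielectric vs in pure solvent
  ring <- data.frame(x = c(4, -4, 0, 0), y = c(0, 0, 4, -4), z = 0,
                     q = -0.25, radius = 2)
  solv <- solve_poisson(transform(ring, radius = 0), grid_config(dims = 33L))
  prot <- solve_poisson(ring, grid_config(dims = 33L))
  m_solv <- profile_params(axial_profile(solv))$Fmin
  m_prot <- profile_params(axial_profile(prot))$Fmin
  expect_lt(m_prot, m_solv)  # lower screening -> deeper minimum
})
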