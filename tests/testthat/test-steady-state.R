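test_that("three-state steady state is a fixed point of the equations", {
  for (age in c("24h", "48h", "96h")) {
    p <- table1_params(age)
    s <- solve_three_state(p$kinetics, p$prefactors)
    expect_true(all(c(s$l_bar, s$rho_tot, s$N_tot, s$n_G0, s$n_S0) > 0))
    expect_equal(s$l_bar, s$rho_tot / s$N_tot, tolerance = 1e-12)
    expect_equal(s$l_bar, 1 / s$nu_abs, tolerance = 1e-12)
    # eigenvalue condition det(K + I / l_bar) = 0
    expect_lt(abs(s$residual), 1e-9)
    # resubstituting the boundary densities reproduces rho_tot
    k <- p$kinetics
    n_P0 <- (k$k_GP * s$n_G0 + k$k_SP * s$n_S0) / (k$k_PG + k$k_PS)
    rho_back <- 2 * s$l_bar^2 * (s$n_G0 + s$n_S0 + n_P0)
    expect_equal(rho_back / s$rho_tot, 1, tolerance = 1e-9)
  }
})

test_that("the mean-length cubic has a unique positive root at all ages", {
  for (age in c("24h", "48h", "96h")) {
    k <- table1_params(age)$kinetics
    cr <- arborfield:::composite_rates(k)
    A <- cr$K_SG / k$v_S - k$beta * cr$K_GS / k$v_G
    B <- 2 * k$k_b * cr$chi_GP / k$v_G
    C <- 2 * k$k_b * (cr$chi_GP * cr$K_SG + cr$chi_SP * cr$K_GS) /
      (k$v_G * k$v_S)
    rt <- polyroot(c(-1, -A, B, C))
    pos <- Re(rt)[abs(Im(rt)) < 1e-8 & Re(rt) > 0]
    expect_length(pos, 1)
  }
})

test_that("one-state closed forms satisfy their identities", {
  # k_b = v/2 gives unit mean length
  s <- solve_one_state(k_b = 0.5, v_bar = 1)
  expect_equal(s$l_bar, 1)
  set.seed(6)
  for (i in 1:10) {
    kb <- runif(1, 1e-4, 1e-2); v <- runif(1, 0.01, 1)
    s <- solve_one_state(kb, v, alpha_1 = 0.75)
    expect_equal(s$N_tot * s$l_bar, s$rho_tot, tolerance = 1e-14)
    expect_equal(s$N_tot, 0.75 * s$rho_tot^2, tolerance = 1e-12)
  }
  # 48h parameter values give a mean length near 2.9 um
  s48 <- solve_one_state(0.0016, 0.027)
  expect_equal(s48$l_bar, 2.9, tolerance = 0.01)
  expect_error(solve_one_state(0.001, -0.1), class = "arborfield_no_steady_state")
})

test_that("one-state relaxation matches direct ODE integration", {
  skip_if_not_installed("deSolve")
  kb <- k24$k_b; vb <- drift_velocity(k24)
  rel <- one_state_relaxation(kb, vb, l0 = 0.5)
  ts <- seq(0, 300, 5)
  ode <- deSolve::ode(c(l = 0.5), ts, function(t, y, p) list(vb - kb * y^2),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(rel$l_of_t(ts), unname(ode[, "l"]), tolerance = 1e-6)
  # fixed point stays fixed
  rel2 <- one_state_relaxation(kb, vb, l0 = rel$l_ss)
  expect_equal(rel2$l_of_t(c(0, 50, 500)), rep(rel$l_ss, 3), tolerance = 1e-12)
  # monotone approach
  expect_true(all(diff(rel$l_of_t(ts)) > 0))
})

test_that("rescue-dominated switching reduces the three-state model to one state", {
  # with instantaneous escape from the shrinking and paused states the
  # zero-length loss vanishes and branches effectively grow at the drift
  # speed: the one-state closed forms emerge
  k <- k48
  k$beta <- 0
  k$k_SG <- k$k_SG * 100
  k$k_PG <- k$k_PG * 100
  s3 <- solve_three_state(k, pre48)
  s1 <- solve_one_state(k$k_b, drift_velocity(k), alpha_1 = pre48$alpha)
  expect_equal(s3$l_bar / s1$l_bar, 1, tolerance = 0.02)
  expect_equal(s3$rho_tot / s1$rho_tot, 1, tolerance = 0.02)
})

test_that("removing the zero-length sink raises the density", {
  # at beta = 1 every branch that shrinks to zero regrows, so the only loss
  # channel is collision; the steady state densifies and branches shorten
  k <- k48
  k$beta <- 1
  s1 <- solve_three_state(k, pre48)
  s0 <- solve_three_state(k48, pre48)
  expect_gt(s1$rho_tot, s0$rho_tot)
  expect_gt(s1$N_tot, s0$N_tot)
  expect_lt(s1$l_bar, s0$l_bar)
})

test_that("number-length curve approaches the parabola at low density", {
  cur <- parabola_prediction(k48, pre48, c(1e-4, 1e-3))
  expect_equal(cur$N_tot / (pre48$alpha * cur$rho_tot^2),
               rep(1, 2), tolerance = 0.01)
  one <- parabola_prediction(k48, pre48, c(0.05, 0.1, 0.2), model = "one_state")
  expect_equal(one$N_tot, pre48$alpha_1 * one$rho_tot^2, tolerance = 1e-14)
  expect_warning(parabola_prediction(k48, pre48, c(-1, 0.1)), "non-physical")
})

test_that("length distribution is a unit-mass exponential with mean l_bar", {
  s <- solve_three_state(k48, pre48)
  lg <- seq(0, 200, 0.01)
  pdf <- length_distribution(s, lg)
  expect_equal(pdf[1], 1 / s$l_bar, tolerance = 1e-12)
  expect_equal(sum(pdf) * 0.01, 1, tolerance = 1e-3)
  expect_equal(sum(lg * pdf) * 0.01, s$l_bar, tolerance = 1e-2)
})
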