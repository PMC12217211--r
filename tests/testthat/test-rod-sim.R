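test_that("a lone growing rod elongates at its speed", {
  k <- pure_growth(k_b = 0, v = 1)
  cfg <- sim_config(k, "periodic", L = 50, dt = 1, t_max = 5, N_init = 1,
                    one_state = TRUE, record_interval = 1)
  set.seed(8)
  out <- arborfield:::rod_sim_run(cfg, init = cbind(25, 25, 0, 0, 1))
  expect_equal(out$final[1, 4], 5)
  expect_equal(out$record$total_length, 0:5)
})

test_that("a growing rod sweeping across another is removed, the target kept", {
  k <- tip_kinetics(0, v_G = 1, v_S = 0, k_GS = 0, k_GP = 0, k_SG = 0,
                    k_SP = 0, k_PG = 0.1, k_PS = 0.1, beta = 0)
  # target: vertical paused rod through (25, 24)-(25, 26);
  # attacker: horizontal growing rod reaching x = 25 during the step
  init <- rbind(c(25, 24, pi / 2, 2, 3),    # paused
                c(24.5, 25, 0, 0.4, 1))     # growing
  cfg <- sim_config(k, "periodic", L = 50, dt = 1, t_max = 1, N_init = 0,
                    record_interval = 1)
  set.seed(9)
  out <- arborfield:::rod_sim_run(cfg, init = init)
  expect_equal(nrow(out$final), 1)
  expect_equal(out$final[1, 4], 2)                       # target untouched
  expect_equal(out$record$cum_collision[2], 1)
})

test_that("without sources the rod count never increases", {
  k <- k48
  k$beta <- 0
  k$k_b <- 0
  cfg <- sim_config(k, "periodic", L = 100, dt = 0.05, t_max = 200,
                    N_init = 150, record_interval = 1)
  set.seed(10)
  out <- arborfield:::rod_sim_run(cfg)
  expect_true(all(diff(out$record$n_rods) <= 0))
})

test_that("event accounting is exact at every record", {
  cfg <- sim_config(k48, "periodic", L = 150, dt = 0.05, t_max = 400,
                    N_init = 80, record_interval = 2)
  set.seed(11)
  out <- arborfield:::rod_sim_run(cfg)
  r <- out$record
  expect_equal(r$n_rods,
               80 + r$cum_branch - (r$cum_debranch - r$cum_rebranch) -
                 r$cum_collision)
  expect_true(all(diff(r$cum_branch) >= 0))
  expect_true(all(diff(r$cum_collision) >= 0))
})

test_that("the realized rebranching fraction matches beta", {
  cfg <- sim_config(k48, "periodic", L = 150, dt = 0.05, t_max = 500,
                    N_init = 100, record_interval = 5)
  set.seed(12)
  out <- arborfield:::rod_sim_run(cfg)
  r <- out$record
  n_deb <- r$cum_debranch[nrow(r)]
  frac <- r$cum_rebranch[nrow(r)] / n_deb
  expect_gt(n_deb, 500)
  expect_lt(abs(frac - k48$beta),
            3 * sqrt(k48$beta * (1 - k48$beta) / n_deb))
})

test_that("periodic-box steady state tracks the analytic solution", {
  s3 <- solve_three_state(k48, pre48)
  set.seed(13)
  reps <- lapply(1:3, function(i) {
    cfg <- sim_config(k48, "periodic", L = 200, dt = 0.05, t_max = 1200,
                      N_init = 100, record_interval = 2)
    run_periodic(cfg, burn_in = 0.6)$steady_state
  })
  rho <- vapply(reps, `[[`, numeric(1), "rho")
  lb <- vapply(reps, `[[`, numeric(1), "l_bar")
  # density and mean length agree with mean-field theory at the few-percent
  # level; residual bias reflects spatial correlations absent from the
  # closure (see the acceptance suite for the 2-SE comparison)
  expect_lt(abs(mean(rho) / s3$rho_tot - 1), 0.08)
  expect_lt(abs(mean(lb) / s3$l_bar - 1), 0.10)
  # terminal lengths are exponential
  lens <- reps[[1]]$lengths
  lens <- lens[lens > 0]
  ks <- suppressWarnings(stats::ks.test(lens, "pexp", 1 / mean(lens)))
  expect_gt(ks$p.value, 0.01)
})

test_that("halving the time step leaves the steady-state density unchanged", {
  set.seed(14)
  rho_of <- function(dtv) {
    vapply(1:3, function(i) {
      cfg <- sim_config(k48, "periodic", L = 200, dt = dtv, t_max = 1200,
                        N_init = 100, record_interval = 2)
      run_periodic(cfg, burn_in = 0.6)$steady_state$rho
    }, numeric(1))
  }
  a <- rho_of(0.05); b <- rho_of(0.025)
  se <- sqrt(stats::var(a) / 3 + stats::var(b) / 3)
  # systematic dt effect below 2% once replicate noise is accounted for
  expect_lt(abs(mean(a) - mean(b)) - 2 * se, 0.02 * mean(b))
})

test_that("an arbor without branching cannot outrun its tips", {
  k <- k48
  k$k_b <- 0
  k$beta <- 0
  cfg <- sim_config(k, "open_front", D_ini = 20, N_init = 60, dt = 0.05,
                    t_max = 200, record_interval = 10, snapshot_interval = 100)
  set.seed(15)
  out <- run_expanding(cfg)
  rods <- out$final
  tips_r <- sqrt((rods[, 1] + rods[, 4] * cos(rods[, 3]))^2 +
                   (rods[, 2] + rods[, 4] * sin(rods[, 3]))^2)
  expect_lte(suppressWarnings(max(tips_r, 0)), 10 + k$v_G * 200 + 1e-9)
})

test_that("pure length fluctuations still expand the arbor", {
  k0 <- invert_velocities(k48, 0, diffusion_coefficient(k48))
  cfg <- sim_config(k0, "open_front", D_ini = 20, N_init = 80, dt = 0.05,
                    t_max = 700, record_interval = 10, snapshot_interval = 100)
  set.seed(16)
  out <- run_expanding(cfg)
  fr <- out$front_radius
  expect_gt(fr$radius[nrow(fr)], fr$radius[1] + 5)
})

test_that("collision prefactor fitting recovers known parameters", {
  set.seed(17)
  vb <- 0.03; D <- 0.25; a_true <- 1.4; g_true <- 0.6
  # wide log-spaced density range decorrelates the linear and quadratic
  # terms of the collision law
  rho <- exp(seq(log(0.02), log(0.8), length.out = 12))
  K <- a_true * vb * rho + a_true^2 * g_true * D * rho^2
  K <- K * (1 + rnorm(12, 0, 0.005))
  fit <- fit_collision_prefactors(list(rho = rho, K_col = K), vb, D)
  expect_equal(fit$alpha, a_true, tolerance = 0.05)
  expect_equal(fit$gamma, g_true, tolerance = 0.05)
  expect_true(all(is.finite(fit$peclet)))
  # zero-diffusion input reduces to the linear law
  fit1 <- fit_collision_prefactors(
    list(rho = rho, K_col = 0.75 * vb * rho * (1 + rnorm(12, 0, 0.01))),
    vb, 0)
  expect_equal(fit1$alpha_1, 0.75, tolerance = 0.05)
  expect_true(is.na(fit1$gamma))
})
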