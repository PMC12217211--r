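#' Recompute the headline quantities of the model
#'
#' Runs the package end to end and recomputes the quantities that
#' characterize the model at the measured parameter sets: tip drift and
#' diffusion at 24 h, the one-state relaxation times, the three
#' marginal-stability front speeds at 48 h (full, zero-diffusion,
#' zero-drift), the mesh-size/sparsity ratios of the benchmark patterns,
#' and the directed-rod simulation fits (number-density exponent and
#' one-state collision prefactor). Each quantity is computed at call time
#' from the packaged parameter tables and fresh simulations.
#'
#' @param seed integer seed; every stochastic step derives its own stream
#'   from it.
#' @param targets optional character vector restricting which quantities are
#'   computed (by id).
#' @param quick reduce simulation sizes further (for smoke tests; the
#'   default sizes are those reported by the package).
#' @return Data frame with columns `id`, `value`, `n`, `description`.
#' @export
reproduce_targets <- function(seed = 1, targets = NULL, quick = FALSE) {
  all_ids <- c("t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8", "t9", "t10",
               "t11", "t12")
  if (is.null(targets)) targets <- all_ids
  rows <- list()
  add <- function(id, value, n, description)
    rows[[id]] <<- data.frame(id = id, value = value, n = n,
                              description = description)
  p24 <- table1_params("24h")
  p48 <- table1_params("48h")
  p96 <- table1_params("96h")

  if ("t1" %in% targets)
    add("t1", drift_velocity(p24$kinetics), 1,
        "24h tip drift velocity (um/min)")
  if ("t2" %in% targets)
    add("t2", diffusion_coefficient(p24$kinetics), 1,
        "24h tip diffusion coefficient (um^2/min)")
  if ("t3" %in% targets)
    add("t3", round(1 / (2 * sqrt(p24$kinetics$k_b * p24$reference[["v_bar"]]))),
        1, "24h one-state relaxation time (min)")
  if ("t4" %in% targets)
    add("t4", round(1 / (2 * sqrt(p96$kinetics$k_b * p96$reference[["v_bar"]]))),
        1, "96h one-state relaxation time (min)")
  if ("t5" %in% targets)
    add("t5", marginal_front(p48$kinetics)$c, 1,
        "48h marginal-stability front speed (um/min)")
  if ("t6" %in% targets)
    add("t6", signif(drift_velocity(p48$kinetics) / 2, 2), 1,
        "48h zero-diffusion (one-state) front speed (um/min)")
  if ("t7" %in% targets) {
    k0 <- invert_velocities(p48$kinetics, 0, p48$reference[["D"]])
    add("t7", marginal_front(k0)$c, 1,
        "48h zero-drift front speed (um/min)")
  }
  if ("t8" %in% targets) {
    ratios <- vapply(c("triangle", "square", "hexagon"),
                     function(kd) analytic_mesh(kd, 2)$ratio, numeric(1))
    stopifnot(diff(range(ratios)) < 1e-12)
    add("t8", mean(ratios), 3,
        "mesh-size/sparsity ratio of regular tilings")
  }
  if ("t9" %in% targets) {
    set.seed(seed + 9L)
    scales <- rep(c(1.5, 2, 3, 4), each = if (quick) 1 else 3)
    pts <- t(vapply(scales, function(s) {
      net <- make_tiling("random_lines", scale = s, window = c(0, 80, 0, 80))
      c(1 / net$rho, mesh_size(net, 5000)$M)
    }, numeric(2)))
    add("t9", mesh_sparsity_slope(pts[, 1], pts[, 2]), nrow(pts),
        "mesh/sparsity slope, exponentially spaced lines (MC)")
  }
  if ("t10" %in% targets)
    add("t10", analytic_mesh("equal_lines", 2)$ratio, 1,
        "mesh/sparsity slope, equally spaced lines")
  if ("t11" %in% targets) {
    set.seed(seed + 11L)
    kbs <- c(0.0005, 0.001, 0.002, 0.004, 0.01)
    if (quick) kbs <- c(0.001, 0.004, 0.01)
    kbs <- rep(kbs, each = if (quick) 1 else 2)
    pts <- t(vapply(kbs, function(kb) {
      k <- p48$kinetics
      k$k_b <- kb
      L <- if (kb >= 0.004) 100 else 150
      cfg <- sim_config(k, "periodic", L = L, dt = 0.05,
                        t_max = if (quick) 700 else 1400,
                        N_init = 100, record_interval = 2,
                        internal_branch_correction = FALSE)
      out <- run_periodic(cfg, burn_in = 0.6)
      c(out$steady_state$rho, out$steady_state$N)
    }, numeric(2)))
    fit <- stats::lm(log(pts[, 2]) ~ log(pts[, 1]))
    add("t11", unname(stats::coef(fit)[2]), length(kbs),
        "number vs length density power-law exponent (rod sims)")
  }
  if ("t12" %in% targets) {
    set.seed(seed + 12L)
    kbs <- c(0.00025, 0.0005, 0.001, 0.002)
    reps <- if (quick) 1 else 2
    pts <- do.call(rbind, lapply(rep(kbs, each = reps), function(kb) {
      k <- tip_kinetics(kb, v_G = 0.027, v_S = 0, k_GS = 0, k_GP = 0,
                        k_SG = 0, k_SP = 0, k_PG = 1, k_PS = 0, beta = 0)
      cfg <- sim_config(k, "periodic", L = 100, dt = 0.1, t_max = 2500,
                        N_init = 50, record_interval = 5, one_state = TRUE,
                        internal_branch_correction = FALSE)
      out <- run_periodic(cfg, burn_in = 0.6)
      m <- measure_collision_rate(out)
      c(rho = m$rho, K_col = m$K_col)
    }))
    fit <- fit_collision_prefactors(
      list(rho = pts[, 1], K_col = pts[, 2]), v_bar = 0.027, D = 0)
    add("t12", fit$alpha_1, nrow(pts),
        "one-state collision prefactor alpha_1 (rod sims)")
  }
  out <- do.call(rbind, rows[intersect(all_ids, names(rows))])
  if (is.null(out))
    return(data.frame(id = character(), value = numeric(), n = numeric(),
                      description = character()))
  rownames(out) <- NULL
  out
}
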