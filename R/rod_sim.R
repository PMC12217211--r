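#' Directed-rod simulation configuration
#'
#' The directed-rod simulator is the stochastic counterpart of the mean-field
#' model: branches are independent, infinitely thin straight rods that
#' nucleate in proportion to existing length, whose tips follow the
#' three-state kinetics, and that vanish instantly when a growing tip sweeps
#' across any other rod.
#'
#' @param kinetics a [tip_kinetics()] object.
#' @param boundary `"periodic"` (square box, steady-state mode) or
#'   `"open_front"` (expanding disc).
#' @param L box side (um) for the periodic mode.
#' @param D_ini,N_init initial disc diameter (um) and tip count. In the
#'   periodic mode `N_init` zero-length growing tips are scattered uniformly
#'   in the box.
#' @param dt time step (min).
#' @param t_max simulated duration (min).
#' @param record_interval time-series recording interval (min).
#' @param snapshot_interval rod-snapshot interval (min; 0 disables; the final
#'   configuration is always returned).
#' @param one_state run the one-state model instead: all rods grow at
#'   `drift_velocity(kinetics)`, no state transitions or debranching;
#'   collisions and branching only.
#' @param rebranch apply the rebranching probability `beta` at debranching
#'   events (set `FALSE` for the strict no-rebranching variant).
#' @param log_events keep a per-event log (branch/debranch/rebranch/collision
#'   with time and position).
#' @param internal_branch_correction double the per-rod nucleation exponent
#'   (probability `1 - exp(-2 l k_b dt)`). Every real branch is mirrored by
#'   an internal branch of similar length that also hosts nucleation, so with
#'   the correction the rod ensemble is the stochastic counterpart of the
#'   internal-branch-doubled mean-field equations and its densities compare
#'   directly with [solve_three_state()]. Set `FALSE` for the strict
#'   terminal-only variant (nucleation `1 - exp(-l k_b dt)`).
#' @param max_rods abort threshold diagnosing a density blow-up.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(kinetics, boundary = c("periodic", "open_front"),
                       L = 200, D_ini = 10, N_init = 30,
                       dt = 0.05, t_max = 600,
                       record_interval = 1, snapshot_interval = 0,
                       one_state = FALSE, rebranch = TRUE,
                       log_events = FALSE, internal_branch_correction = TRUE,
                       max_rods = 2e5) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(kinetics, "tip_kinetics"), dt > 0, t_max > 0, L > 0)
  ktot_max <- max(kinetics$k_GS + kinetics$k_GP,
                  kinetics$k_SG + kinetics$k_SP,
                  kinetics$k_PG + kinetics$k_PS)
  if (!one_state && dt * ktot_max > 0.5)
    stop("dt * max(k_tot) > 0.5: refuse to run with this time step")
  structure(list(kinetics = kinetics, boundary = boundary, L = L,
                 D_ini = D_ini, N_init = N_init, dt = dt, t_max = t_max,
                 record_interval = record_interval,
                 snapshot_interval = snapshot_interval,
                 one_state = one_state, rebranch = rebranch,
                 log_events = log_events,
                 internal_branch_correction = internal_branch_correction,
                 max_rods = max_rods),
            class = "sim_config")
}

rod_sim_run <- function(cfg, init = NULL) {
  k <- cfg$kinetics
  if (is.null(init)) {
    n <- cfg$N_init
    if (cfg$boundary == "periodic") {
      init <- cbind(stats::runif(n, 0, cfg$L), stats::runif(n, 0, cfg$L),
                    stats::runif(n, 0, 2 * pi), 0, 1)
    } else {
      r <- (cfg$D_ini / 2) * sqrt(stats::runif(n))
      phi <- stats::runif(n, 0, 2 * pi)
      init <- cbind(r * cos(phi), r * sin(phi),
                    stats::runif(n, 0, 2 * pi), 0, 1)
    }
  }
  vG <- if (cfg$one_state) {
    # constant rod speed = drift velocity; plain v_G for a transition-free chain
    if (occupancy_normalization(k) > 0) drift_velocity(k) else k$v_G
  } else k$v_G
  ext <- cfg$D_ini / 2 + (vG / 2) * cfg$t_max + 50 # generous open-front extent
  out <- rod_sim_cpp(c(k$k_GS, k$k_GP, k$k_SG, k$k_SP, k$k_PG, k$k_PS),
                     vG, if (cfg$one_state) 0 else k$v_S,
                     k$k_b * (1 + cfg$internal_branch_correction),
                     k$beta, cfg$one_state,
                     if (cfg$boundary == "periodic") 0L else 1L,
                     cfg$L, ext, cfg$dt,
                     as.integer(ceiling(cfg$t_max / cfg$dt)),
                     max(1L, as.integer(round(cfg$record_interval / cfg$dt))),
                     if (cfg$snapshot_interval > 0)
                       as.integer(round(cfg$snapshot_interval / cfg$dt)) else 0L,
                     init, cfg$rebranch && !cfg$one_state, cfg$log_events,
                     as.integer(cfg$max_rods))
  out$record <- as.data.frame(out$record)
  out$events <- as.data.frame(out$events)
  out$events$type <- c("branch", "debranch", "rebranch",
                       "collision")[out$events$type]
  out$config <- cfg
  class(out) <- "rod_record"
  out
}

#' @export
print.rod_record <- function(x, ...) {
  r <- x$record
  cat(sprintf("rod simulation (%s): %d rods at t = %g min (%d records)\n",
              x$config$boundary, r$n_rods[nrow(r)], r$time[nrow(r)], nrow(r)))
  invisible(x)
}

#' Run a periodic-box rod simulation to steady state
#'
#' Runs the simulator in a square box with periodic boundaries and summarizes
#' the statistical steady state over the final portion of the run: rod
#' number and length densities (per box area), the mean rod length, and the
#' collision rate (collisions per unit time per rod). With the default
#' internal-branch nucleation correction these densities estimate the
#' `N_tot` and `rho_tot` of [solve_three_state()]; without it they are the
#' terminal-only densities.
#'
#' @param cfg a [sim_config()] with `boundary = "periodic"`.
#' @param burn_in fraction of the run discarded before averaging (default
#'   0.5).
#' @return The `rod_record` with an added `steady_state` list: `N`, `rho`
#'   (with block standard errors), `l_bar`, `K_col`, `lengths` (final rod
#'   lengths), and `window` (time range averaged).
#' @export
run_periodic <- function(cfg, burn_in = 0.5) {
  stopifnot(cfg$boundary == "periodic")
  out <- rod_sim_run(cfg)
  if (out$blew_up)
    no_steady_state("rod density exceeded the configured cap: no steady state")
  r <- out$record
  sel <- r$time >= burn_in * max(r$time)
  area <- cfg$L^2
  blocks <- block_means(r$n_rods[sel], 10)
  blocksL <- block_means(r$total_length[sel], 10)
  dcol <- diff(r$cum_collision[sel])
  dtm <- diff(r$time[sel])
  nbar <- (utils::head(r$n_rods[sel], -1) + utils::tail(r$n_rods[sel], -1)) / 2
  out$steady_state <- list(
    N = mean(r$n_rods[sel]) / area,
    N_se = stats::sd(blocks) / sqrt(length(blocks)) / area,
    rho = mean(r$total_length[sel]) / area,
    rho_se = stats::sd(blocksL) / sqrt(length(blocksL)) / area,
    l_bar = mean(r$total_length[sel]) / mean(r$n_rods[sel]),
    K_col = sum(dcol) / sum(dtm * nbar),
    lengths = out$final[, 4],
    window = range(r$time[sel]))
  out
}

block_means <- function(x, nblock) {
  n <- length(x)
  nblock <- max(2, min(nblock, n %/% 2))
  b <- rep(seq_len(nblock), each = ceiling(n / nblock))[seq_len(n)]
  as.numeric(tapply(x, b, mean))
}

#' Run an expanding-arbor rod simulation
#'
#' Initializes tips in a small disc and lets the arbor expand freely;
#' branches nucleate on the circle through the mother branch midpoint.
#' Radial length-density profiles are computed from snapshots and the front
#' radius (at 10% of the central density) is tracked over time.
#'
#' @param cfg a [sim_config()] with `boundary = "open_front"` and a positive
#'   `snapshot_interval`.
#' @param dr radial bin width (um) for the density profiles.
#' @return The `rod_record` with `profiles` (list of data frames `r`, `rho`),
#'   `profile_times`, and `front_radius` (data frame `time`, `radius`).
#' @export
run_expanding <- function(cfg, dr = 2) {
  stopifnot(cfg$boundary == "open_front", cfg$snapshot_interval > 0)
  out <- rod_sim_run(cfg)
  if (length(out$snapshot_times) &&
      abs(utils::tail(out$snapshot_times, 1) - cfg$t_max) < cfg$dt) {
    snaps <- out$snapshots
    times <- out$snapshot_times
  } else {
    snaps <- c(out$snapshots, list(out$final))
    times <- c(out$snapshot_times, cfg$t_max)
  }
  profs <- lapply(snaps, radial_length_profile, dr = dr)
  fr <- vapply(profs, function(p) front_radius_of_profile(p$r, p$rho),
               numeric(1))
  out$profiles <- profs
  out$profile_times <- times
  out$front_radius <- data.frame(time = times, radius = fr)
  out
}

# radial length density rho(r) of a rod snapshot, by sub-sampling rods
radial_length_profile <- function(snap, dr = 2, step = 0.25) {
  if (nrow(snap) == 0 || sum(snap[, 4]) == 0)
    return(data.frame(r = dr / 2, rho = 0))
  pts <- sample_rod_points(snap, step)
  rmax <- max(sqrt(pts[, 1]^2 + pts[, 2]^2)) + dr
  br <- seq(0, rmax + dr, by = dr)
  h <- graphics::hist(sqrt(pts[, 1]^2 + pts[, 2]^2), breaks = br,
                      plot = FALSE)
  mids <- h$mids
  area <- pi * (br[-1]^2 - br[-length(br)]^2)
  data.frame(r = mids, rho = h$counts * pts[1, 3] / area)
}

# sample points along rods every `step` um; third column is the arclength
# weight per point
sample_rod_points <- function(snap, step = 0.25) {
  keep <- snap[, 4] > 0
  snap <- snap[keep, , drop = FALSE]
  if (nrow(snap) == 0) return(matrix(numeric(0), 0, 3))
  nseg <- pmax(1L, ceiling(snap[, 4] / step))
  idx <- rep.int(seq_len(nrow(snap)), nseg)
  f <- (unlist(lapply(nseg, function(n) (seq_len(n) - 0.5) / n)))
  w <- rep.int(snap[, 4] / nseg, nseg)
  cbind(snap[idx, 1] + f * snap[idx, 4] * cos(snap[idx, 3]),
        snap[idx, 2] + f * snap[idx, 4] * sin(snap[idx, 3]),
        mean(w)) # uniform weight: step sizes differ by < step
}

front_radius_of_profile <- function(r, rho, frac = 0.1) {
  if (all(rho <= 0)) return(0)
  # plateau estimate: innermost decile of the grid (at least 3 cells)
  central <- mean(rho[seq_len(max(3, length(r) %/% 10))])
  if (central <= 0) return(0)
  thr <- frac * central
  above <- which(rho >= thr)
  if (length(above) == 0) return(0)
  i <- max(above)
  if (i == length(r)) return(r[i])
  # linear interpolation across the crossing
  r[i] + (r[i + 1] - r[i]) * (rho[i] - thr) / (rho[i] - rho[i + 1] + 1e-300)
}

#' Collision rate versus density from a periodic run
#'
#' The collision rate is the number of collisions per unit time per branch.
#' Estimated over the steady-state window in time blocks, with a block
#' bootstrap standard error, alongside the matching rod length density.
#'
#' @param record a `rod_record` from [run_periodic()].
#' @param nblock number of time blocks.
#' @return List with `rho` (mean rod length density, um^-1), `K_col`,
#'   `K_col_se`, and the per-block values.
#' @export
measure_collision_rate <- function(record, nblock = 10) {
  stopifnot(inherits(record, "rod_record"), !is.null(record$steady_state))
  r <- record$record
  sel <- which(r$time >= record$steady_state$window[1])
  area <- record$config$L^2
  nb <- max(2, min(nblock, length(sel) %/% 4))
  cuts <- round(seq(1, length(sel), length.out = nb + 1))
  kb <- rho_b <- numeric(nb)
  for (i in seq_len(nb)) {
    j <- sel[cuts[i]:cuts[i + 1]]
    dcol <- r$cum_collision[j[length(j)]] - r$cum_collision[j[1]]
    dtm <- r$time[j[length(j)]] - r$time[j[1]]
    kb[i] <- dcol / (dtm * mean(r$n_rods[j]))
    rho_b[i] <- mean(r$total_length[j]) / area
  }
  list(rho = mean(rho_b), K_col = mean(kb),
       K_col_se = stats::sd(kb) / sqrt(nb),
       block_K = kb, block_rho = rho_b)
}

#' Fit collision prefactors from a density sweep
#'
#' Least-squares fit of the collision law `K = alpha v_bar rho +
#' alpha^2 gamma D rho^2` to (density, collision-rate) pairs from a sweep of
#' simulations (linear-in-coefficients fit of `K ~ rho + rho^2` without
#' intercept, then `alpha = b1 / v_bar`, `gamma = b2 / (alpha^2 D)`). With
#' `D = 0` (one-state sweep) the model reduces to the linear law and only
#' `alpha` is estimated.
#'
#' @param points data frame or list with numeric `rho` and `K_col`.
#' @param v_bar tip drift velocity of the swept kinetics.
#' @param D tip diffusion coefficient (0 for a one-state sweep).
#' @return A [collision_prefactors()]-like list with `alpha`, `gamma`
#'   (`NA` when `D = 0`), standard errors, and the per-point Peclet numbers
#'   `v_bar / (alpha gamma D rho)` (advective over diffusive collisions).
#' @export
fit_collision_prefactors <- function(points, v_bar, D) {
  rho <- points$rho; K <- points$K_col
  stopifnot(length(rho) >= 4, length(K) == length(rho))
  if (D > 0) {
    fit <- stats::lm(K ~ 0 + rho + I(rho^2))
    b <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
    alpha <- b[[1]] / v_bar
    if (!is.finite(alpha) || alpha <= 0)
      stop("fitted geometric prefactor is non-positive")
    gamma <- b[[2]] / (alpha^2 * D)
    peclet <- v_bar / (alpha * gamma * D * rho)
    list(alpha = alpha, gamma = gamma,
         alpha_se = se[[1]] / v_bar,
         gamma_se = se[[2]] / (alpha^2 * D),
         peclet = peclet, fit = fit)
  } else {
    fit <- stats::lm(K ~ 0 + rho)
    alpha <- stats::coef(fit)[[1]] / v_bar
    if (!is.finite(alpha) || alpha <= 0)
      stop("fitted prefactor is non-positive")
    list(alpha_1 = alpha,
         alpha_1_se = sqrt(diag(stats::vcov(fit)))[[1]] / v_bar,
         gamma = NA_real_, peclet = rep(Inf, length(rho)), fit = fit)
  }
}
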