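#' Density field on a polar grid
#'
#' State of the moment-reduced mean-field solver: the 0th (number) and 1st
#' (length) moments of the branch density in each tip state, resolved in
#' radial position and branch orientation. Fields are per unit area per
#' radian; cell centers exclude r = 0.
#'
#' @param r_max radial extent (um).
#' @param n_r,n_theta grid resolution (default 200 x 100, radial cells over
#'   `(0, r_max]`, angular cells over `[-pi, pi]`).
#' @return An object of class `density_field` with matrices `N_G`, `N_S`,
#'   `N_P` (um^-2 rad^-1), `rho_G`, `rho_S`, `rho_P` (um^-1 rad^-1), grid
#'   vectors `r`, `theta`, steps `dr`, `dtheta`, and `time`. The fields hold
#'   the total (terminal + internal, i.e. doubled) densities, so
#'   theta-integrated totals compare directly with [solve_three_state()].
#' @export
density_field <- function(r_max = 100, n_r = 200, n_theta = 100) {
  dr <- r_max / n_r
  dtheta <- 2 * pi / n_theta
  z <- matrix(0, n_r, n_theta)
  structure(list(r = (seq_len(n_r) - 0.5) * dr,
                 theta = -pi + (seq_len(n_theta) - 0.5) * dtheta,
                 dr = dr, dtheta = dtheta, time = 0,
                 N_G = z, N_S = z, N_P = z,
                 rho_G = z, rho_S = z, rho_P = z),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  rho_r <- rowSums(x$rho_G + x$rho_S + x$rho_P) * x$dtheta
  cat(sprintf("density field %d x %d (r <= %g um), t = %g min, central rho_tot = %.4g /um\n",
              length(x$r), length(x$theta), max(x$r) + x$dr / 2, x$time,
              mean(rho_r[seq_len(max(3, length(x$r) %/% 10))])))
  invisible(x)
}

#' Initialize a field at the homogeneous steady state behind a sigmoid front
#'
#' Fills the field with the analytic steady-state composition multiplied by
#' an isotropic sigmoid front `1 / (1 + exp((r - r0) / w))`.
#'
#' @param field a [density_field()].
#' @param k,prefactors kinetics and collision prefactors.
#' @param r0 initial front radius (um).
#' @param w sigmoid width (um).
#' @return The initialized field.
#' @export
init_sigmoid_front <- function(field, k, prefactors, r0 = 10, w = 2) {
  sol <- solve_three_state(k, prefactors)
  comp <- steady_state_composition(k, sol)
  shape <- 1 / (1 + exp((field$r - r0) / w))
  nth <- length(field$theta)
  for (f in names(comp))
    field[[f]] <- matrix(rep(comp[[f]] * shape / (2 * pi), nth),
                         ncol = nth)
  field$time <- 0
  field
}

# theta-integrated per-state moments of the analytic homogeneous steady
# state (including the internal-branch doubling so the totals match
# solve_three_state)
steady_state_composition <- function(k, sol) {
  n_P0 <- (k$k_GP * sol$n_G0 + k$k_SP * sol$n_S0) / (k$k_PG + k$k_PS)
  n0 <- c(G = sol$n_G0, S = sol$n_S0, P = n_P0)
  N <- 2 * n0 * sol$l_bar        # doubled, theta-integrated
  rho <- 2 * n0 * sol$l_bar^2
  list(N_G = N[["G"]], N_S = N[["S"]], N_P = N[["P"]],
       rho_G = rho[["G"]], rho_S = rho[["S"]], rho_P = rho[["P"]])
}

# upwind derivative along rows (r): u > 0 takes backward differences
upwind_r <- function(f, u, dr) {
  n <- nrow(f)
  back <- (f - rbind(f[1, , drop = FALSE], f[-n, , drop = FALSE])) / dr
  fwd <- (rbind(f[-1, , drop = FALSE], f[n, , drop = FALSE]) - f) / dr
  pos <- u > 0
  back * pos + fwd * !pos
}

# upwind derivative along columns (theta, periodic)
upwind_theta <- function(f, u, dtheta) {
  m <- ncol(f)
  back <- (f - f[, c(m, seq_len(m - 1)), drop = FALSE]) / dtheta
  fwd <- (f[, c(seq_len(m)[-1], 1), drop = FALSE] - f) / dtheta
  pos <- u > 0
  back * pos + fwd * !pos
}

#' Time derivatives of the moment-reduced mean-field equations
#'
#' Right-hand side of the six moment equations on the polar grid: state
#' transitions, advective boundary sources/sinks, the density-dependent
#' collision sink acting on growing branches, and midpoint transport at half
#' the tip speed (first-order upwind). The boundary fluxes require the
#' zero-length densities, which the moment system does not carry; they are
#' closed with the local exponential length distribution per state,
#' `n_X(0) = N_X^2 / rho_X`. The growing-state birth flux
#' `k_b rho_tot + beta v_S n_S(0)` is distributed isotropically in angle.
#'
#' @param field a [density_field()].
#' @param k,prefactors kinetics and collision prefactors.
#' @param transport,transitions,sources logical switches (all `TRUE` for the
#'   full model; useful for targeted tests).
#' @param nucleation_doubling with the default `TRUE` the birth flux doubles
#'   along with the fields (`2 k_b rho_tot`), making the homogeneous bulk an
#'   exact fixed point of the doubled analytic steady state. `FALSE` applies
#'   the boundary condition verbatim (`k_b rho_tot`): internal branches then
#'   do not feed nucleation at the leading edge, matching the front theory,
#'   which omits them there; use it when extracting front speeds for
#'   comparison with [marginal_front()].
#' @param vb,D drift velocity and diffusion coefficient; computed from `k`
#'   when not supplied (the solver caches them across steps).
#' @return List of six matrices of time derivatives.
#' @export
moment_rhs <- function(field, k, prefactors, transport = TRUE,
                       transitions = TRUE, sources = TRUE,
                       nucleation_doubling = TRUE,
                       vb = drift_velocity(k), D = diffusion_coefficient(k)) {
  eps <- 1e-12
  dth <- field$dtheta
  NG <- field$N_G; NS <- field$N_S; NP <- field$N_P
  rG <- field$rho_G; rS <- field$rho_S; rP <- field$rho_P
  # theta-integrated local totals (fields already carry the doubling)
  rho_tot <- rowSums(rG + rS + rP) * dth
  N_T <- rowSums(NG + NS + NP) * dth
  N_Gi <- rowSums(NG) * dth
  a <- prefactors$alpha
  Kcol <- (a * vb * rho_tot + a^2 * prefactors$gamma * D * rho_tot^2) *
    N_T / pmax(N_Gi, eps)
  Kcol[N_Gi <= eps] <- 0
  # exponential closure for the zero-length shrinking density; the local
  # mean length rS/NS is floored at 0.01 um to keep the closure bounded
  # where both moments vanish
  nS0 <- NS * pmin(pmax(NS, 0) / pmax(rS, eps), 100)
  nS0[NS <= eps] <- 0
  nS0_int <- rowSums(nS0) * dth
  dNG <- dNS <- dNP <- drG <- drS <- drP <- 0 * NG
  if (transitions) {
    dNG <- dNG - (k$k_GS + k$k_GP) * NG + k$k_SG * NS + k$k_PG * NP
    dNS <- dNS + k$k_GS * NG - (k$k_SG + k$k_SP) * NS + k$k_PS * NP
    dNP <- dNP + k$k_GP * NG + k$k_SP * NS - (k$k_PG + k$k_PS) * NP
    drG <- drG - (k$k_GS + k$k_GP) * rG + k$k_SG * rS + k$k_PG * rP
    drS <- drS + k$k_GS * rG - (k$k_SG + k$k_SP) * rS + k$k_PS * rP
    drP <- drP + k$k_GP * rG + k$k_SP * rS - (k$k_PG + k$k_PS) * rP
  }
  if (sources) {
    # boundary birth flux; the fields carry doubled (terminal + internal)
    # densities, so with nucleation_doubling the k_b * rho_tot term doubles
    # as well, while the rebranching flux is already expressed in doubled
    # n_S(0)
    S_G <- ((1 + nucleation_doubling) * k$k_b * rho_tot +
              k$beta * k$v_S * nS0_int) / (2 * pi)
    dNG <- dNG + S_G          # recycled per row, fills each theta column
    dNS <- dNS - k$v_S * nS0
    drG <- drG + k$v_G * NG
    drS <- drS - k$v_S * NS
    # collision losses
    dNG <- dNG - Kcol * NG
    drG <- drG - Kcol * rG
  }
  if (transport) {
    cth <- matrix(rep(cos(field$theta), each = nrow(NG)), nrow(NG))
    # the 1/r angular-transport coefficient is regularized over the three
    # innermost rings, where the solution is isotropic and the term would
    # otherwise make the explicit-in-iteration update unstable
    sth_r <- matrix(rep(sin(field$theta), each = nrow(NG)), nrow(NG)) /
      pmax(field$r, 3 * field$dr)
    urG <- (k$v_G / 2) * cth;  utG <- -(k$v_G / 2) * sth_r
    urS <- -(k$v_S / 2) * cth; utS <- (k$v_S / 2) * sth_r
    adv <- function(f, ur, ut)
      -ur * upwind_r(f, ur, field$dr) - ut * upwind_theta(f, ut, dth)
    dNG <- dNG + adv(NG, urG, utG)
    drG <- drG + adv(rG, urG, utG)
    dNS <- dNS + adv(NS, urS, utS)
    drS <- drS + adv(rS, urS, utS)
  }
  list(N_G = dNG, N_S = dNS, N_P = dNP,
       rho_G = drG, rho_S = drS, rho_P = drP)
}

#' Integrate the moment-reduced mean-field equations
#'
#' Backward-Euler time stepping (fixed-point iteration on the implicit
#' update) of the six moment equations. Negative values produced by the
#' discretization are clipped to zero with the clipped mass accumulated in
#' `mass_clipped`.
#'
#' @param field initial [density_field()].
#' @param k,prefactors kinetics and collision prefactors.
#' @param t_max integration time (min).
#' @param dt time step (min, default 0.05).
#' @param record_interval interval at which radial profiles are stored.
#' @param nucleation_doubling see [moment_rhs()].
#' @param fp_tol,fp_max fixed-point tolerance and iteration cap.
#' @return List: `field` (final state), `times`, `profiles` (matrix, one row
#'   per record: theta-integrated total length density per radial cell),
#'   `central` (central density time series), `mass_clipped`.
#' @export
pde_solve <- function(field, k, prefactors, t_max, dt = 0.05,
                      record_interval = 20, nucleation_doubling = TRUE,
                      fp_tol = 1e-10, fp_max = 50) {
  if (k$v_G * dt / field$dr >= 1)
    warning("v_G * dt / dr >= 1: implicit scheme remains stable but ",
            "transport accuracy degrades")
  nstep <- ceiling(t_max / dt)
  every <- max(1L, round(record_interval / dt))
  fields6 <- c("N_G", "N_S", "N_P", "rho_G", "rho_S", "rho_P")
  vb <- drift_velocity(k)
  D <- diffusion_coefficient(k)
  profiles <- list()
  times <- numeric(0)
  clipped <- 0
  grab <- function(f) rowSums(f$rho_G + f$rho_S + f$rho_P) * f$dtheta
  profiles[[1]] <- grab(field)
  times[1] <- field$time
  for (s in seq_len(nstep)) {
    x0 <- field[fields6]
    xk <- x0
    for (it in seq_len(fp_max)) {
      rhs <- moment_rhs(field, k, prefactors,
                        nucleation_doubling = nucleation_doubling,
                        vb = vb, D = D)
      delta <- 0
      for (f in fields6) {
        new <- pmax(x0[[f]] + dt * rhs[[f]], 0)
        delta <- max(delta, max(abs(new - xk[[f]])))
        xk[[f]] <- new
        field[[f]] <- new
      }
      scale <- max(1e-12, max(abs(xk$rho_G)), max(abs(xk$N_G)))
      if (delta <= fp_tol * scale || it == fp_max) break
    }
    for (f in fields6) {
      raw <- x0[[f]] + dt * rhs[[f]]
      neg <- raw < 0
      if (any(neg)) clipped <- clipped + sum(-raw[neg])
    }
    field$time <- field$time + dt
    if (s %% every == 0) {
      profiles[[length(profiles) + 1]] <- grab(field)
      times[length(times) + 1] <- field$time
    }
  }
  list(field = field, times = times,
       profiles = do.call(rbind, profiles),
       r = field$r,
       central = vapply(seq_along(times), function(i)
         mean(profiles[[i]][seq_len(max(3, length(field$r) %/% 10))]),
         numeric(1)),
       mass_clipped = clipped)
}

#' Extract front speed and decay length from a solution series
#'
#' The front position at each recorded time is the radius where the
#' theta-integrated length density falls to 10% of its central value
#' (linearly interpolated); the front speed is the linear-fit slope of that
#' radius over the fitted time window. The decay length comes from an
#' exponential fit to the outer tail of the final profile, from the
#' outermost edge in to where the density reaches 25% of the central value.
#'
#' @param series result of [pde_solve()] (or any list with `times`, `r`,
#'   `profiles`).
#' @param t_min discard records before this time (transient).
#' @return List with `c` (um min^-1), `lam` (um), and the fitted
#'   `front_radius` data frame.
#' @export
extract_front <- function(series, t_min = 0) {
  sel <- which(series$times >= t_min)
  if (length(sel) < 3) stop("need at least 3 recorded profiles after t_min")
  radii <- vapply(sel, function(i)
    front_radius_of_profile(series$r, series$profiles[i, ]), numeric(1))
  fit <- stats::lm(radii ~ series$times[sel])
  c_hat <- unname(stats::coef(fit)[2])
  # decay length from the final profile
  p <- series$profiles[nrow(series$profiles), ]
  central <- mean(p[seq_len(max(3, length(p) %/% 10))])
  tail_sel <- which(p > 1e-12 * central & p <= 0.25 * central &
                      seq_along(p) > which.max(p))
  lam <- NA_real_
  if (length(tail_sel) >= 3) {
    lf <- stats::lm(log(p[tail_sel]) ~ series$r[tail_sel])
    lam <- -1 / unname(stats::coef(lf)[2])
  }
  list(c = c_hat, lam = lam,
       front_radius = data.frame(time = series$times[sel], radius = radii))
}
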