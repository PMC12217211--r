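#' Collision prefactors
#'
#' Dimensionless prefactors of the empirical collision rate
#' `K_col = alpha * v_bar * rho + alpha^2 * gamma * D * rho^2`:
#' `alpha` is the geometric (advective) prefactor, `gamma` the diffusive one.
#' `alpha_1` is the analogous prefactor of the one-state model, where the
#' collision rate is linear in density.
#'
#' @param alpha geometric prefactor (> 0).
#' @param gamma diffusion prefactor (> 0).
#' @param alpha_1 one-state prefactor (default 0.75).
#' @return An object of class `collision_prefactors`.
#' @export
collision_prefactors <- function(alpha, gamma, alpha_1 = 0.75) {
  if (alpha <= 0 || gamma <= 0 || alpha_1 <= 0)
    stop("collision prefactors must be positive")
  structure(list(alpha = alpha, gamma = gamma, alpha_1 = alpha_1),
            class = "collision_prefactors")
}

# Composite rates obtained by eliminating the paused state: the paused
# residence splits transitions through P into effective G<->S channels.
# The optional rate `s` shifts the paused exit rate (s = c/lambda in the
# co-moving frame of the traveling front; s = 0 for the static steady state).
composite_rates <- function(k, s = 0) {
  d <- s + k$k_PG + k$k_PS
  list(chi_GP = 1 + k$k_GP / d,
       chi_SP = 1 + k$k_SP / d,
       K_GS = k$k_GS + k$k_GP * k$k_PS / d,
       K_SG = k$k_SG + k$k_SP * k$k_PG / d)
}

no_steady_state <- function(msg) {
  stop(structure(class = c("arborfield_no_steady_state", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Homogeneous steady state of the three-state model
#'
#' Solves the homogeneous, isotropic steady state of the three-state
#' mean-field model. Eliminating the paused state reduces the length-resolved
#' balance to a 2x2 linear ODE in branch length whose decaying eigenvalue
#' `-1/l_bar` sets the exponential length distribution. The mean terminal
#' branch length solves the self-consistent cubic
#' `1/l^3 + A/l^2 = B/l + C` with
#' `A = K_SG/v_S - beta*K_GS/v_G`, `B = 2*k_b*chi_GP/v_G`,
#' `C = 2*k_b*(chi_GP*K_SG + chi_SP*K_GS)/(v_G*v_S)`;
#' the total length density then solves the collision-closure quadratic
#' `alpha*v_bar*rho + gamma*D*alpha^2*rho^2 = K_col(l_bar)` obtained from the
#' vanishing of `det(K + I/l_bar)`. Internal branches are incorporated by
#' doubling: `N_tot = 2 N_T`, `rho_tot = 2 rho_T`.
#'
#' @param k a [tip_kinetics()] object.
#' @param prefactors a [collision_prefactors()] object.
#' @return An object of class `steady_state_solution` with fields `l_bar`
#'   (um), `rho_tot` (um^-1), `N_tot` (um^-2), `nu_abs = 1/l_bar`, boundary
#'   densities `n_G0`, `n_S0` (theta-integrated, per um length per um^2),
#'   `K_col` (min^-1), `model = "three_state"`, and a `residual` diagnostic
#'   (value of `det(K + I/l_bar)` at the returned solution).
#' @export
solve_three_state <- function(k, prefactors) {
  stopifnot(inherits(k, "tip_kinetics"), inherits(prefactors, "collision_prefactors"))
  if (k$v_G <= 0 || k$v_S <= 0)
    stop("three-state steady state requires positive v_G and v_S")
  cr <- composite_rates(k)
  A <- cr$K_SG / k$v_S - k$beta * cr$K_GS / k$v_G
  B <- 2 * k$k_b * cr$chi_GP / k$v_G
  C <- 2 * k$k_b * (cr$chi_GP * cr$K_SG + cr$chi_SP * cr$K_GS) / (k$v_G * k$v_S)
  # C*l^3 + B*l^2 - A*l - 1 = 0; companion-matrix roots via polyroot
  rt <- polyroot(c(-1, -A, B, C))
  real <- Re(rt[abs(Im(rt)) < 1e-10 * pmax(1, Mod(rt))])
  pos <- real[real > 0]
  if (length(pos) == 0)
    no_steady_state("no positive mean-length root: no homogeneous steady state")
  l_bar <- min(pos) # unique when a steady state exists; guard anyway
  # required collision rate from det(K + I/l_bar) = 0
  Ap <- cr$K_SG / k$v_S - cr$K_GS / k$v_G
  Bp <- cr$K_SG / k$v_S + cr$chi_SP * cr$K_GS / (cr$chi_GP * k$v_S)
  K_col <- (k$v_G / cr$chi_GP) * (1 + Ap * l_bar) / (l_bar + Bp * l_bar^2)
  if (K_col <= 0)
    no_steady_state("required collision rate is non-positive: no-growth regime")
  vb <- drift_velocity(k)
  D <- diffusion_coefficient(k)
  a <- prefactors$alpha
  g <- prefactors$gamma
  if (g * D > 0) {
    disc <- (a * vb)^2 + 4 * g * D * a^2 * K_col
    rho_tot <- (-a * vb + sqrt(disc)) / (2 * g * D * a^2)
  } else {
    if (vb <= 0)
      no_steady_state("zero diffusion and non-positive drift: no steady state")
    rho_tot <- K_col / (a * vb)
  }
  if (!is.finite(rho_tot) || rho_tot <= 0)
    no_steady_state("no positive density root")
  denom <- cr$K_SG * k$v_G - k$beta * cr$K_GS * k$v_S + k$v_G * k$v_S / l_bar
  n_G0 <- (cr$K_SG + k$v_S / l_bar) / denom * k$k_b * rho_tot
  n_S0 <- cr$K_GS / denom * k$k_b * rho_tot
  # residual of the eigenvalue condition at the solution
  Km <- steady_state_matrix(k, K_col)
  res <- det(Km + diag(2) / l_bar)
  structure(list(l_bar = l_bar, rho_tot = rho_tot, N_tot = rho_tot / l_bar,
                 nu_abs = 1 / l_bar, n_G0 = n_G0, n_S0 = n_S0,
                 K_col = K_col, v_bar = vb, D = D, model = "three_state",
                 residual = res, kinetics = k, prefactors = prefactors),
            class = "steady_state_solution")
}

# coefficient matrix of d/dl (n_G, n_S) in the homogeneous steady state
steady_state_matrix <- function(k, K_col) {
  cr <- composite_rates(k)
  matrix(c(-K_col * cr$chi_GP / k$v_G - cr$K_GS / k$v_G,
           -K_col * cr$chi_SP / k$v_G + cr$K_SG / k$v_G,
           -cr$K_GS / k$v_S,
           cr$K_SG / k$v_S),
         2, 2, byrow = TRUE)
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf("%s steady state: l_bar = %.4g um, rho_tot = %.4g /um, N_tot = %.4g /um^2\n",
              x$model, x$l_bar, x$rho_tot, x$N_tot))
  invisible(x)
}

#' Homogeneous steady state of the one-state model
#'
#' Limit of fast state switching: branches grow at the constant drift speed
#' and disappear only by collision. Closed forms (internal branches included
#' by doubling): `N = 2 k_b / (alpha_1 v_bar)`,
#' `rho = sqrt(2 k_b / v_bar) / alpha_1`, `l_bar = sqrt(v_bar / (2 k_b))`,
#' which satisfy the exact parabola `N = alpha_1 rho^2`.
#'
#' @param k_b branching rate (min^-1 um^-1).
#' @param v_bar drift speed (um min^-1, must be positive).
#' @param alpha_1 one-state collision prefactor.
#' @return A `steady_state_solution` with `model = "one_state"`.
#' @export
solve_one_state <- function(k_b, v_bar, alpha_1 = 0.75) {
  if (k_b <= 0) stop("k_b must be positive")
  if (v_bar <= 0)
    no_steady_state("non-positive drift velocity: one-state model cannot grow")
  l_bar <- sqrt(v_bar / (2 * k_b))
  rho_tot <- sqrt(2 * k_b / v_bar) / alpha_1
  structure(list(l_bar = l_bar, rho_tot = rho_tot, N_tot = rho_tot / l_bar,
                 nu_abs = 1 / l_bar,
                 n_G0 = k_b * rho_tot / v_bar, n_S0 = 0,
                 K_col = alpha_1 * v_bar * rho_tot,
                 v_bar = v_bar, D = 0, model = "one_state",
                 residual = 0), class = "steady_state_solution")
}

#' One-state relaxation towards the steady state
#'
#' The mean branch length of the one-state model obeys the autonomous ODE
#' `dl/dt = v_bar - k_b l^2`, independent of the collision prefactor. Its
#' closed-form solution relaxes monotonically to the fixed point
#' `l_ss = sqrt(v_bar / k_b)` with characteristic time
#' `tau = 1 / (2 sqrt(k_b v_bar))`.
#'
#' @param k_b branching rate (min^-1 um^-1).
#' @param v_bar drift speed (um min^-1).
#' @param l0 initial mean length (um, >= 0).
#' @return List with `tau` (min), `l_ss` (um), and `l_of_t`, a vectorized
#'   function of time returning the closed-form mean length.
#' @export
one_state_relaxation <- function(k_b, v_bar, l0 = 0) {
  if (k_b <= 0 || v_bar <= 0) stop("k_b and v_bar must be positive")
  if (l0 < 0) stop("l0 must be non-negative")
  l_ss <- sqrt(v_bar / k_b)
  tau <- 1 / (2 * sqrt(k_b * v_bar))
  r0 <- (l0 - l_ss) / (l0 + l_ss)
  l_of_t <- function(t) {
    r <- r0 * exp(-t / tau)
    l_ss * (1 + r) / (1 - r)
  }
  list(tau = tau, l_ss = l_ss, l_of_t = l_of_t)
}

#' Number-density versus length-density curve
#'
#' The relation between branch number density and length density traced out
#' by the steady state as the branching rate varies. For the three-state
#' model the collision closure links density and mean length without
#' reference to `k_b`: given `rho`, the collision rate is
#' `K_col = alpha v rho + alpha^2 gamma D rho^2` and `1/l_bar` solves the
#' resulting quadratic, whence `N = rho / l_bar`. As `rho -> 0` (and with the
#' diffusive term dropped) the curve approaches the parabola
#' `N = alpha rho^2`. In one-state mode the parabola `N = alpha_1 rho^2` is
#' exact.
#'
#' @inheritParams solve_three_state
#' @param rho_grid positive total length densities (um^-1).
#' @param model `"three_state"` or `"one_state"`.
#' @return Data frame with columns `rho_tot`, `N_tot`, `l_bar`.
#' @export
parabola_prediction <- function(k, prefactors, rho_grid,
                                model = c("three_state", "one_state")) {
  model <- match.arg(model)
  keep <- is.finite(rho_grid) & rho_grid > 0
  if (!all(keep)) {
    warning("dropping non-physical densities from rho_grid")
    rho_grid <- rho_grid[keep]
  }
  if (model == "one_state") {
    return(data.frame(rho_tot = rho_grid,
                      N_tot = prefactors$alpha_1 * rho_grid^2,
                      l_bar = 1 / (prefactors$alpha_1 * rho_grid)))
  }
  cr <- composite_rates(k)
  vb <- drift_velocity(k)
  D <- diffusion_coefficient(k)
  a <- prefactors$alpha
  Ap <- cr$K_SG / k$v_S - cr$K_GS / k$v_G
  Bp <- cr$K_SG / k$v_S + cr$chi_SP * cr$K_GS / (cr$chi_GP * k$v_S)
  out <- vapply(rho_grid, function(rho) {
    K_col <- a * vb * rho + a^2 * prefactors$gamma * D * rho^2
    # u^2 + (Ap - chi_GP K_col / v_G) u - chi_GP K_col Bp / v_G = 0, u = 1/l
    b1 <- Ap - cr$chi_GP * K_col / k$v_G
    c1 <- -cr$chi_GP * K_col * Bp / k$v_G
    u <- (-b1 + sqrt(b1^2 - 4 * c1)) / 2
    if (!is.finite(u) || u <= 0) return(c(NA_real_, NA_real_))
    c(rho * u, 1 / u)
  }, numeric(2))
  bad <- !is.finite(out[1, ])
  if (any(bad)) warning(sum(bad), " densities had no physical mean length")
  data.frame(rho_tot = rho_grid, N_tot = out[1, ], l_bar = out[2, ])
}

#' Exponential branch-length distribution of a steady state
#'
#' @param sol a `steady_state_solution`.
#' @param l_grid branch lengths (um).
#' @return Density values `exp(-l / l_bar) / l_bar`.
#' @export
length_distribution <- function(sol, l_grid) {
  stopifnot(inherits(sol, "steady_state_solution"))
  exp(-l_grid / sol$l_bar) / sol$l_bar
}
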