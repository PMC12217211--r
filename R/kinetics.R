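#' Microscopic tip-kinetics parameter set
#'
#' Bundles the nine microscopic parameters governing the dynamics of a single
#' dendrite tip: the branching rate, the growing and shrinking speeds, the six
#' Markov transition rates between the growing (G), shrinking (S) and paused
#' (P) states, and the rebranching probability `beta` (the probability that a
#' branch that has shrunk to zero length regrows at the same site instead of
#' disappearing).
#'
#' Rate subscripts read source-to-destination: `k_GS` is the rate of switching
#' from growing to shrinking. Both speeds are stored positive; the shrinking
#' speed enters all derived quantities with a negative sign.
#'
#' @param k_b branching rate (min^-1 um^-1): nucleation rate per unit existing
#'   branch length.
#' @param v_G,v_S growing / shrinking tip speeds (um min^-1, both positive).
#' @param k_GS,k_GP,k_SG,k_SP,k_PG,k_PS state-transition rates (min^-1).
#' @param beta rebranching probability in `[0, 1]`.
#' @param label free-text tag, e.g. a developmental age such as `"48h AEL"`.
#' @return An object of class `tip_kinetics` (a named list).
#' @seealso [steady_state_probabilities()], [drift_velocity()],
#'   [diffusion_coefficient()], [table1_params()]
#' @examples
#' k <- table1_params("48h")$kinetics
#' drift_velocity(k)
#' @export
tip_kinetics <- function(k_b, v_G, v_S, k_GS, k_GP, k_SG, k_SP, k_PG, k_PS,
                         beta = 0, label = "") {
  k <- list(k_b = k_b, v_G = v_G, v_S = v_S,
            k_GS = k_GS, k_GP = k_GP, k_SG = k_SG, k_SP = k_SP,
            k_PG = k_PG, k_PS = k_PS, beta = beta, label = label)
  num <- k[setdiff(names(k), "label")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1))))
    stop("all tip_kinetics parameters must be finite scalars")
  if (any(unlist(num[c("k_b", "v_G", "v_S", "k_GS", "k_GP", "k_SG",
                       "k_SP", "k_PG", "k_PS")]) < 0))
    stop("rates and speeds must be non-negative")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  structure(k, class = "tip_kinetics")
}

#' @export
print.tip_kinetics <- function(x, ...) {
  cat("Tip kinetics", if (nzchar(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  k_b = %g /min/um   v_G = %g, v_S = %g um/min   beta = %g\n",
              x$k_b, x$v_G, x$v_S, x$beta))
  cat(sprintf("  k_GS = %g  k_GP = %g  k_SG = %g  k_SP = %g  k_PG = %g  k_PS = %g  (/min)\n",
              x$k_GS, x$k_GP, x$k_SG, x$k_SP, x$k_PG, x$k_PS))
  invisible(x)
}

#' Transition-rate matrix of the three-state tip chain
#'
#' The generator acting on probability column vectors ordered (G, S, P):
#' `dP/dt = K_TR P`. Columns sum to zero.
#'
#' @param k a [tip_kinetics()] object.
#' @return A 3x3 matrix with dimnames `c("G","S","P")`.
#' @export
transition_matrix <- function(k) {
  m <- matrix(c(-(k$k_GS + k$k_GP), k$k_SG,              k$k_PG,
                k$k_GS,             -(k$k_SG + k$k_SP),  k$k_PS,
                k$k_GP,             k$k_SP,              -(k$k_PG + k$k_PS)),
              3, 3, byrow = TRUE,
              dimnames = list(c("G", "S", "P"), c("G", "S", "P")))
  m
}

occupancy_normalization <- function(k) {
  with(k, k_PG * k_SG + k_PG * k_SP + k_PS * k_SG +
          k_GS * k_PG + k_GP * k_PS + k_GS * k_PS +
          k_GP * k_SG + k_GP * k_SP + k_GS * k_SP)
}

#' Steady-state occupancies of the three tip states
#'
#' Closed-form stationary probabilities of the growing, shrinking and paused
#' states of the Markov tip chain; each is a sum of spanning-tree rate
#' products over a common normalization.
#'
#' @inheritParams transition_matrix
#' @return Named numeric vector `c(P_G, P_S, P_P)` summing to 1.
#' @export
steady_state_probabilities <- function(k) {
  P <- occupancy_normalization(k)
  if (P <= 0)
    stop("degenerate chain: all spanning-tree rate products are zero, ",
         "no stationary distribution")
  with(k, c(P_G = (k_PG * k_SG + k_PG * k_SP + k_PS * k_SG) / P,
            P_S = (k_GS * k_PG + k_GP * k_PS + k_GS * k_PS) / P,
            P_P = (k_GP * k_SG + k_GP * k_SP + k_GS * k_SP) / P))
}

#' Tip drift velocity
#'
#' Mean tip displacement rate `v_bar = P_G * v_G - P_S * v_S`; may be
#' negative when shrinking dominates.
#'
#' @inheritParams transition_matrix
#' @return Signed scalar (um min^-1).
#' @export
drift_velocity <- function(k) {
  p <- steady_state_probabilities(k)
  unname(p["P_G"] * k$v_G - p["P_S"] * k$v_S)
}

#' Tip diffusion coefficient (Green-Kubo)
#'
#' Integrates the stationary velocity autocorrelation of the three-state tip,
#' with velocity vector `(v_G, -v_S, 0)`. The default spectral route
#' eigen-decomposes the transition-rate matrix: with the two decaying modes
#' `-lambda_1`, `-lambda_2` and the expansion of each unit initial condition
#' `e_j = P_ss + a_1 w_1 + a_2 w_2`, the integral evaluates to
#' `D = sum_ij v_i v_j P_j (a_1^(j) w_1i / lambda_1 + a_2^(j) w_2i / lambda_2)`.
#' If the two nonzero eigenvalues are (nearly) degenerate or complex the
#' autocorrelation is integrated numerically instead (4th-order Runge-Kutta
#' propagation of the conditional probabilities, trapezoidal quadrature,
#' relative accuracy ~1e-6).
#'
#' @inheritParams transition_matrix
#' @param method `"spectral"` (default, with automatic fallback) or
#'   `"autocorrelation"` to force direct numerical integration.
#' @return Non-negative scalar D (um^2 min^-1).
#' @export
diffusion_coefficient <- function(k, method = c("spectral", "autocorrelation")) {
  method <- match.arg(method)
  if (k$v_G == 0 && k$v_S == 0) return(0)
  K <- transition_matrix(k)
  ev <- eigen(K)
  ord <- order(abs(Re(ev$values)))
  lam <- -ev$values[ord[2:3]]
  if (method == "spectral") {
    degenerate <- abs(lam[1] - lam[2]) < 1e-10 * max(abs(lam)) ||
      any(abs(Im(lam)) > 1e-12 * max(abs(Re(lam))))
    if (any(Re(lam) <= 0))
      stop("transition matrix has a non-decaying mode: spectrum must be ",
           "one zero and two negative eigenvalues")
    if (!degenerate) {
      Pss <- steady_state_probabilities(k)
      v <- c(k$v_G, -k$v_S, 0)
      W <- Re(ev$vectors[, ord[2:3], drop = FALSE])
      lam <- Re(lam)
      D <- 0
      for (j in 1:3) {
        a <- qr.solve(cbind(Pss, W), diag(3)[, j])
        D <- D + sum(v * (a[2] * W[, 1] / lam[1] + a[3] * W[, 2] / lam[2])) *
          v[j] * Pss[j]
      }
      return(max(unname(D), 0))
    }
  }
  vacf_diffusion(k)
}

# Direct Green-Kubo integral: propagate dP/dt = K P from the three unit
# initial conditions with RK4 and integrate C(t) = sum_ij v_i v_j P_j
# [P(i,t|j,0) - P_i] by the trapezoidal rule.
vacf_diffusion <- function(k) {
  K <- transition_matrix(k)
  rates <- max(sum(abs(K))) # crude scale
  lam_min <- min(abs(Re(eigen(K, only.values = TRUE)$values[1:2])))
  t_end <- 40 / max(lam_min, 1e-8)
  dt <- min(1e-3 * 3 / max(diag(-K)), t_end / 2e4)
  Pss <- steady_state_probabilities(k)
  v <- c(k$v_G, -k$v_S, 0)
  P <- diag(3) # columns: conditional prob started in state j
  cvv <- function(P) sum((v %*% (P - Pss)) * (v * Pss))
  D <- 0
  c_prev <- cvv(P)
  nstep <- ceiling(t_end / dt)
  for (s in seq_len(nstep)) {
    k1 <- K %*% P
    k2 <- K %*% (P + dt / 2 * k1)
    k3 <- K %*% (P + dt / 2 * k2)
    k4 <- K %*% (P + dt * k3)
    P <- P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    c_now <- cvv(P)
    D <- D + dt * (c_prev + c_now) / 2
    c_prev <- c_now
  }
  max(D, 0)
}

#' Simulate a single stochastic tip trajectory
#'
#' Fixed-time-step Monte-Carlo realization of the three-state tip: in each
#' step the tip leaves its state with probability `1 - exp(-k_tot * dt)`
#' (destination chosen proportionally to the individual rates) and its
#' position advances by the state speed times `dt` (`v_P = 0`). Serves as the
#' stochastic oracle for [drift_velocity()] and [diffusion_coefficient()].
#'
#' @inheritParams transition_matrix
#' @param t_max trajectory duration (min).
#' @param dt time step (min); must satisfy `max(k_tot) * dt < 0.1`.
#' @param record_interval interval (min) at which position/state are recorded.
#' @return List with `times`, `positions` (um), `states` (1 = G, 2 = S,
#'   3 = P), and `dwell_times` per visited state (min, one entry per sojourn,
#'   in order; useful for dwell-time statistics).
#' @export
simulate_tip_trajectory <- function(k, t_max, dt = 0.01, record_interval = dt) {
  ktot <- c(k$k_GS + k$k_GP, k$k_SG + k$k_SP, k$k_PG + k$k_PS)
  if (max(ktot) * dt >= 0.1)
    stop("dt too large: max total exit rate * dt must be < 0.1")
  out <- tip_trajectory_cpp(c(k$k_GS, k$k_GP, k$k_SG, k$k_SP, k$k_PG, k$k_PS),
                            c(k$v_G, -k$v_S, 0), t_max, dt,
                            max(1L, round(record_interval / dt)))
  out$times <- out$steps * dt
  out$steps <- NULL
  out
}
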