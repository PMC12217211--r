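#' @section Front selection:
#' In the co-moving frame `z = r - c t`, an exponential front `exp(-z/lambda)`
#' is compatible with the linearized three-state equations only on a curve in
#' the (c, lambda) plane. The marginally stable ("pulled") front travels at
#' the minimum speed on that curve.
#' @name front-selection
#' @keywords internal
NULL

no_growth <- function(msg) {
  stop(structure(class = c("arborfield_no_growth", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# the (c, lambda)-dependent ingredients of the dispersion constraint
dispersion_parts <- function(c_, lam, k) {
  cr <- composite_rates(k, s = c_ / lam)
  aS <- (cr$chi_SP * c_ / lam + cr$K_SG) / (2 * k$v_S)
  aG <- (cr$chi_GP * c_ / lam + cr$K_GS) / (2 * k$v_G)
  P <- aS - aG
  Q <- 4 * aS * aG - cr$K_SG * cr$K_GS / (k$v_G * k$v_S)
  R <- aS + aG
  list(cr = cr, P = P, Q = Q, R = R, sq = sqrt(P^2 + Q))
}

#' Dispersion constraint of the expanding-front solution
#'
#' Evaluates the residual of the (c, lambda) constraint selecting admissible
#' exponential front solutions of the three-state model. A solution exists
#' where the residual vanishes. The constraint is only defined where the
#' angular integral converges, i.e. where
#' `(sqrt(P^2 + Q) - P)^2 > 1/(4 lambda^2)`; outside that region `NA` is
#' returned with attribute `inadmissible = TRUE` rather than a silent `NaN`.
#'
#' @param c_ front speed (um min^-1, > 0).
#' @param lam front decay length (um, > 0).
#' @param k a [tip_kinetics()] object.
#' @return Scalar residual, or inadmissible-flagged `NA`.
#' @export
dispersion_residual <- function(c_, lam, k) {
  if (!is.finite(c_) || !is.finite(lam) || c_ <= 0 || lam <= 0)
    return(structure(NA_real_, inadmissible = TRUE))
  p <- dispersion_parts(c_, lam, k)
  g <- p$sq - p$P
  den <- g^2 - 1 / (4 * lam^2)
  if (!is.finite(den) || den <= 0)
    return(structure(NA_real_, inadmissible = TRUE))
  M <- g / den^1.5
  (p$sq + p$R) * (1 - k$k_b * p$cr$chi_GP * M / k$v_G) -
    (p$cr$K_GS / k$v_G) * (k$beta + k$k_b * p$cr$chi_SP * M / k$v_S)
}

# smallest c making (c, lam) admissible, or NA
admissibility_bound <- function(lam, k, c_max) {
  f <- function(c_) {
    p <- dispersion_parts(c_, lam, k)
    (p$sq - p$P) - 1 / (2 * lam)
  }
  lo <- 1e-10
  if (f(lo) > 0) return(lo)
  if (f(c_max) <= 0) return(NA_real_)
  stats::uniroot(f, c(lo, c_max), tol = 1e-13)$root
}

#' Front speed at fixed decay length
#'
#' Solves the dispersion constraint for the front speed `c` at a given decay
#' length, bracketing between the admissibility bound (where the residual
#' diverges to -Inf) and `c_max`.
#'
#' @inheritParams dispersion_residual
#' @param c_max upper bracket for the speed (um min^-1).
#' @return Front speed, or `NA` if no admissible root exists at this lambda.
#' @export
front_speed_at_lambda <- function(lam, k, c_max = 5) {
  cl <- admissibility_bound(lam, k, c_max)
  if (!is.finite(cl)) return(NA_real_)
  lo <- cl * (1 + 1e-9) + 1e-12
  f <- function(c_) {
    r <- dispersion_residual(c_, lam, k)
    if (is.na(r)) -Inf else r
  }
  fhi <- f(c_max)
  if (!is.finite(fhi) || fhi <= 0) return(NA_real_)
  # walk up from the bound until the residual is finite and negative
  flo <- f(lo)
  while (!is.finite(flo) && lo < c_max) {
    lo <- lo * 2 + 1e-10
    flo <- f(lo)
  }
  if (!is.finite(flo) || flo >= 0) {
    # residual may already be positive very close to the bound; scan inward
    grid <- cl + (c_max - cl) * seq(1e-8, 1, length.out = 100)^3
    vals <- vapply(grid, f, numeric(1))
    i <- which(is.finite(vals) & vals < 0)
    if (length(i) == 0) return(NA_real_)
    lo <- grid[max(i)]
  }
  stats::uniroot(f, c(lo, c_max), tol = 1e-12)$root
}

#' Marginal-stability front of the three-state model
#'
#' Selects the emerging front of an expanding arbor as the minimum of the
#' front speed along the dispersion curve (`dc/dlambda = 0`), the marginally
#' stable "pulled" front. The search is an outer scan/golden-section over
#' lambda with an inner one-dimensional root solve for c at each lambda.
#'
#' @inheritParams dispersion_residual
#' @param lambda_window search window for the decay length (um).
#' @param n_scan number of (log-spaced) lambdas in the initial scan.
#' @return An object of class `front_solution`: `c` (um min^-1), `lam` (um),
#'   `residual` (dispersion residual at the solution), and `is_minimum`
#'   (TRUE when c increases on both sides on a local grid).
#' @export
marginal_front <- function(k, lambda_window = c(0.01, 50), n_scan = 200) {
  if (!growth_allowed(k))
    no_growth("parameters lie below the phase boundary: no expanding front")
  lams <- exp(seq(log(lambda_window[1]), log(lambda_window[2]),
                  length.out = n_scan))
  cs <- vapply(lams, front_speed_at_lambda, numeric(1), k = k)
  ok <- which(is.finite(cs))
  if (length(ok) == 0)
    no_growth("no admissible (c, lambda) found in the search window")
  i <- ok[which.min(cs[ok])]
  lo <- lams[max(min(ok), i - 2)]
  hi <- lams[min(max(ok), i + 2)]
  opt <- stats::optimize(function(l) {
    v <- front_speed_at_lambda(l, k)
    if (is.na(v)) Inf else v
  }, c(lo, hi), tol = 1e-8)
  lam_m <- opt$minimum
  c_m <- opt$objective
  eps <- 1e-3 * lam_m
  side <- vapply(c(lam_m - eps, lam_m + eps), front_speed_at_lambda,
                 numeric(1), k = k)
  structure(list(c = c_m, lam = lam_m,
                 residual = as.numeric(dispersion_residual(c_m, lam_m, k)),
                 is_minimum = all(is.na(side) | side >= c_m - 1e-10)),
            class = "front_solution")
}

#' @export
print.front_solution <- function(x, ...) {
  cat(sprintf("front: c = %.4g um/min, lambda = %.4g um (residual %.2e)\n",
              x$c, x$lam, x$residual))
  invisible(x)
}

#' One-state traveling front
#'
#' In the one-state model the dispersion relation
#' `lambda^2 = v_bar^2 (c^2/v_bar^2 - 1/4)^(3/2) / (k_b c)` admits a single
#' positive decay length for every `c > v_bar/2`; the marginally stable front
#' is the singular limit `c_m = v_bar/2`, `lambda_m = 0`.
#'
#' @param k_b branching rate (min^-1 um^-1).
#' @param v_bar drift speed (um min^-1, > 0).
#' @return A `front_solution` with `c = v_bar/2`, `lam = 0`, plus
#'   `lambda_of_c`, the positive branch of the dispersion relation.
#' @export
one_state_front <- function(k_b, v_bar) {
  if (v_bar <= 0) no_growth("non-positive drift: one-state front cannot expand")
  lambda_of_c <- function(c_) {
    ifelse(c_ >= v_bar / 2,
           sqrt(v_bar^2 * (c_^2 / v_bar^2 - 0.25)^1.5 / (k_b * c_)),
           NA_real_)
  }
  structure(list(c = v_bar / 2, lam = 0, residual = 0, is_minimum = TRUE,
                 lambda_of_c = lambda_of_c),
            class = "front_solution")
}

# growth/no-growth classifier from the phase-boundary condition
growth_allowed <- function(k) {
  cr <- composite_rates(k)
  gap <- cr$K_GS / k$v_G - cr$K_SG / k$v_S
  if (gap <= 0) return(TRUE) # net rescue bias: growth always possible
  (1 - k$beta) * gap^2 < k$k_b * (cr$chi_GP / k$v_G + cr$chi_SP / k$v_S)
}

#' Growth/no-growth phase boundary
#'
#' The boundary in the (drift velocity, diffusion coefficient) plane
#' separating parameters that support an expanding arbor from those that do
#' not: `(1 - beta) (K_GS/v_G - K_SG/v_S)^2 = k_b (chi_GP/v_G + chi_SP/v_S)`.
#' Transition rates are held fixed at the values in `k`; the tip speeds are
#' scanned, and each boundary speed pair is mapped to (v_bar, D) through
#' [drift_velocity()] and [diffusion_coefficient()].
#'
#' @param k a [tip_kinetics()] object supplying the transition rates, `k_b`
#'   and `beta`.
#' @param v_G_scan growing speeds to scan (um min^-1).
#' @param v_S_range bracket for the shrinking speed root at each `v_G`.
#' @return Data frame with `v_G`, `v_S`, `v_bar`, `D` along the boundary
#'   (rows where no boundary crossing exists are dropped).
#' @export
phase_boundary <- function(k, v_G_scan, v_S_range = c(1e-4, 50)) {
  if (length(v_G_scan) == 0) stop("empty speed scan grid")
  crit <- function(vG, vS) {
    k2 <- k; k2$v_G <- vG; k2$v_S <- vS
    cr <- composite_rates(k2)
    gap <- cr$K_GS / vG - cr$K_SG / vS
    # continuous classifier: negative on the growth side
    (1 - k$beta) * max(gap, 0)^2 -
      k$k_b * (cr$chi_GP / vG + cr$chi_SP / vS)
  }
  rows <- lapply(v_G_scan, function(vG) {
    f <- function(vS) crit(vG, vS)
    flo <- f(v_S_range[1]); fhi <- f(v_S_range[2])
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
    vS <- stats::uniroot(f, v_S_range, tol = 1e-10)$root
    k2 <- k; k2$v_G <- vG; k2$v_S <- vS
    data.frame(v_G = vG, v_S = vS, v_bar = drift_velocity(k2),
               D = diffusion_coefficient(k2))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(v_G = numeric(), v_S = numeric(),
                                      v_bar = numeric(), D = numeric())
  out
}

#' Invert tip speeds from target drift and diffusion
#'
#' Finds effective speeds (v_G, v_S) that, with the transition rates of `k`
#' held fixed, reproduce a prescribed drift velocity and diffusion
#' coefficient. Because the occupancies do not depend on the speeds, the
#' drift target is a linear constraint `v_S = (P_G v_G - v_bar) / P_S`; the
#' diffusion target is then a one-dimensional root solve along that line.
#' This is the mapping used to realize phase-diagram axes.
#'
#' @param k a [tip_kinetics()] object (its rates are kept).
#' @param v_bar_target target drift velocity (um min^-1, may be <= 0).
#' @param D_target target diffusion coefficient (um^2 min^-1, > 0).
#' @return A [tip_kinetics()] object with the inverted speeds (label
#'   annotated), satisfying both targets to 1e-6 relative.
#' @export
invert_velocities <- function(k, v_bar_target, D_target) {
  p <- steady_state_probabilities(k)
  vS_of <- function(vG) (p[["P_G"]] * vG - v_bar_target) / p[["P_S"]]
  vG_min <- if (v_bar_target > 0) v_bar_target / p[["P_G"]] else 0
  with_speeds <- function(vG) {
    k2 <- k; k2$v_G <- vG; k2$v_S <- vS_of(vG)
    k2
  }
  g <- function(vG) diffusion_coefficient(with_speeds(vG)) - D_target
  lo <- vG_min + 1e-9
  if (g(lo) > 0)
    stop("infeasible target: D at the minimum admissible v_G already exceeds ",
         "D_target (", signif(g(lo) + D_target, 6), ")")
  hi <- max(1, 2 * lo)
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (g(hi) < 0) stop("infeasible target: D_target not attainable")
  vG <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  k2 <- with_speeds(vG)
  k2$label <- sprintf("%s [inverted v_bar=%g, D=%g]", k$label,
                      v_bar_target, D_target)
  stopifnot(abs(drift_velocity(k2) - v_bar_target) <=
              1e-6 * max(1e-8, abs(v_bar_target)),
            abs(diffusion_coefficient(k2) - D_target) <= 1e-6 * D_target)
  k2
}

#' Front-speed phase diagram
#'
#' Front speed as a function of tip drift velocity and diffusion coefficient,
#' with transition rates held at the reference values in `k`. Each grid point
#' is realized by [invert_velocities()] and solved by [marginal_front()];
#' points below the phase boundary (or with infeasible speed inversions) get
#' speed 0.
#'
#' @inheritParams invert_velocities
#' @param v_bar_grid,D_grid axis values.
#' @return Matrix of front speeds, rows indexed by `v_bar_grid`, columns by
#'   `D_grid`.
#' @export
phase_diagram <- function(k, v_bar_grid, D_grid) {
  out <- matrix(0, length(v_bar_grid), length(D_grid),
                dimnames = list(signif(v_bar_grid, 6), signif(D_grid, 6)))
  for (i in seq_along(v_bar_grid)) {
    for (j in seq_along(D_grid)) {
      k2 <- tryCatch(invert_velocities(k, v_bar_grid[i], D_grid[j]),
                     error = function(e) NULL)
      if (is.null(k2)) next
      fs <- tryCatch(marginal_front(k2),
                     arborfield_no_growth = function(e) NULL)
      if (!is.null(fs)) out[i, j] <- fs$c
    }
  }
  out
}
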