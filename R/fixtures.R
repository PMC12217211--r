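#' Measured tip parameters for the three developmental ages
#'
#' The packaged microscopic parameter sets measured for class IV dendrite
#' tips at 24, 48 and 96 hours after egg-lay: branching rate, tip speeds,
#' the six transition rates, the rebranching probability, and the fitted
#' collision prefactors, stored at their published precision. The
#' `reference` element carries the published derived values (drift velocity,
#' diffusion coefficient) for cross-checking; they are reference data, not
#' inputs to any computation.
#'
#' @param age `"24h"`, `"48h"`, or `"96h"`.
#' @return List with `kinetics` ([tip_kinetics()]), `prefactors`
#'   ([collision_prefactors()]), and `reference` (named numeric).
#' @export
table1_params <- function(age = c("24h", "48h", "96h")) {
  age <- match.arg(age)
  p <- .table1[[age]]
  list(kinetics = tip_kinetics(k_b = p$k_b, v_G = p$v_G, v_S = p$v_S,
                               k_GS = p$k_GS, k_GP = p$k_GP, k_SG = p$k_SG,
                               k_SP = p$k_SP, k_PG = p$k_PG, k_PS = p$k_PS,
                               beta = p$beta, label = paste(age, "AEL")),
       prefactors = collision_prefactors(p$alpha, p$gamma, alpha_1 = 0.750),
       reference = c(v_bar = p$v_bar, D = p$D))
}

.table1 <- list(
  `24h` = list(k_b = 0.0082, v_G = 1.61, v_S = 1.53,
               k_GP = 0.784, k_GS = 0.640, k_PG = 0.335, k_PS = 0.314,
               k_SG = 0.598, k_SP = 0.946, beta = 0.19,
               alpha = 1.564, gamma = 0.602, v_bar = 0.038, D = 0.5039),
  `48h` = list(k_b = 0.0016, v_G = 1.62, v_S = 1.08,
               k_GP = 0.933, k_GS = 0.435, k_PG = 0.155, k_PS = 0.235,
               k_SG = 0.282, k_SP = 1.251, beta = 0.17,
               alpha = 1.462, gamma = 0.580, v_bar = 0.027, D = 0.2673),
  `96h` = list(k_b = 0.0009, v_G = 1.64, v_S = 1.33,
               k_GP = 0.923, k_GS = 0.799, k_PG = 0.116, k_PS = 0.117,
               k_SG = 0.575, k_SP = 1.276, beta = 0.19,
               alpha = 1.359, gamma = 0.678, v_bar = 0.022, D = 0.0216))

#' Read / write tip-kinetics parameter sets as JSON
#'
#' Plain JSON configs with the exact field names of [tip_kinetics()];
#' round-trips preserve values exactly at the stored precision.
#'
#' @param k a [tip_kinetics()] object.
#' @param path file path.
#' @return `read_kinetics` returns a [tip_kinetics()]; `write_kinetics`
#'   returns `path` invisibly.
#' @export
write_kinetics <- function(k, path) {
  jsonlite::write_json(unclass(k), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(tip_kinetics, x[c("k_b", "v_G", "v_S", "k_GS", "k_GP", "k_SG",
                            "k_SP", "k_PG", "k_PS", "beta", "label")])
}

#' Synthetic binary tree with exponential branch lengths
#'
#' Random planar binary tree for exercising the morphometry estimators:
#' branch lengths are exponential with known mean, directions drift from the
#' parent direction by a bounded random turn, and the generator records the
#' ground-truth branch type of every branch.
#'
#' @param n_branches total number of branches (>= 2).
#' @param l_mean mean branch length (um).
#' @param turn maximum absolute turn from the parent direction (rad).
#' @return List with `graph` (a [skeleton_graph()]) and `truth` (data frame
#'   of the generated branches: `type`, `length`, `angle`).
#' @export
exp_tree <- function(n_branches, l_mean = 3, turn = pi / 3) {
  stopifnot(n_branches >= 2)
  # open tips available for splitting; each split converts one terminal
  # branch's end into a branch point with two daughters
  nodes <- data.frame(id = 1:2, x = c(0, stats::rexp(1, 1 / l_mean)), y = 0)
  edges <- matrix(c(1, 2), 1)
  branch_of <- data.frame(tip_node = 2, length = nodes$x[2], angle = 0)
  lens <- branch_of$length
  angs <- 0
  types <- "terminal"
  parent_branch <- NA_integer_
  nb <- 1
  while (nb < n_branches - 1) {
    open <- which(types == "terminal")
    i <- open[sample.int(length(open), 1)]
    base <- branch_of$tip_node[i]
    types[i] <- "internal"
    for (d in 1:2) {
      len <- stats::rexp(1, 1 / l_mean)
      ang <- angs[i] + stats::runif(1, -turn, turn)
      nid <- nrow(nodes) + 1
      nodes <- rbind(nodes, data.frame(
        id = nid,
        x = nodes$x[nodes$id == base] + len * cos(ang),
        y = nodes$y[nodes$id == base] + len * sin(ang)))
      edges <- rbind(edges, c(base, nid))
      branch_of <- rbind(branch_of, data.frame(tip_node = nid, length = len,
                                               angle = ang))
      lens <- c(lens, len)
      angs <- c(angs, ang)
      types <- c(types, "terminal")
      nb <- nb + 1
    }
  }
  g <- skeleton_graph(nodes, edges, soma = 1)
  list(graph = g,
       truth = data.frame(type = types, length = lens, angle = angs))
}

#' Constructed traveling-front density profiles
#'
#' Logistic front profiles `rho0 / (1 + exp((r - R0 - c t) / lam))` with
#' exact speed and decay length, for validating front-extraction code.
#'
#' @param c_ front speed (um min^-1).
#' @param lam decay length (um).
#' @param rho0 plateau density (um^-1).
#' @param times snapshot times (min).
#' @param R0 initial front radius (um).
#' @param r_max,dr radial grid.
#' @return List shaped like a [pde_solve()] result: `times`, `r`,
#'   `profiles`, `central`.
#' @export
traveling_profile <- function(c_, lam, rho0 = 0.1, times = seq(0, 500, 50),
                              R0 = 20, r_max = 150, dr = 0.5) {
  r <- seq(dr / 2, r_max, by = dr)
  profiles <- t(vapply(times, function(t)
    rho0 / (1 + exp((r - R0 - c_ * t) / max(lam, 1e-6))), numeric(length(r))))
  list(times = times, r = r, profiles = profiles,
       central = rep(rho0, length(times)))
}
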