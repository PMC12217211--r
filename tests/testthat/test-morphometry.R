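chain_graph <- function(xy, soma = 1) {
  n <- nrow(xy)
  skeleton_graph(data.frame(id = seq_len(n), x = xy[, 1], y = xy[, 2]),
                 cbind(seq_len(n - 1), 2:n), soma = soma)
}

test_that("branch classification handles simple and binary trees", {
  # unbranched path from the soma: one terminal branch
  g <- chain_graph(cbind(0:3, 0))
  tb <- classify_branches(g)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$type, "terminal")
  expect_equal(tb$length, 3)
  # binary tree with a trunk and three rounds of splitting:
  # 15 branches, 8 terminal and 7 internal
  nodes <- data.frame(id = 0:15)
  edges <- rbind(c(0, 1), t(vapply(2:15, function(i) c(i %/% 2, i),
                                   numeric(2))))
  depth <- c(0, floor(log2(1:15)) + 1)
  nodes$x <- depth
  nodes$y <- c(0, (1:15) * 0.1)
  g2 <- skeleton_graph(nodes, edges, soma = 0)
  tb2 <- classify_branches(g2)
  expect_equal(sum(tb2$type == "terminal"), 8)
  expect_equal(sum(tb2$type == "internal"), 7)
})

test_that("generated trees are classified exactly and counts differ by one", {
  set.seed(26)
  for (n in c(11, 51)) {
    tree <- exp_tree(n, l_mean = 3)
    tb <- classify_branches(tree$graph)
    expect_equal(sum(tb$type == "terminal"), sum(tree$truth$type == "terminal"))
    expect_equal(sum(tb$type == "internal"), sum(tree$truth$type == "internal"))
    expect_equal(sum(tb$type == "terminal") - sum(tb$type == "internal"), 1)
    expect_equal(sort(tb$length), sort(tree$truth$length), tolerance = 1e-9)
  }
})

test_that("exponential length fitting recovers the generating mean", {
  set.seed(27)
  lens <- rexp(1e4, 1 / 3)
  fit <- fit_branch_lengths(lens, bin_width = 1)
  expect_equal(fit$mean, 3, tolerance = 0.05)
  expect_equal(fit$char_length, 3, tolerance = 0.05)
  expect_gt(fit$r_squared, 0.98)
  # constant lengths are flagged as a poor exponential fit
  flat <- fit_branch_lengths(rep(2.5, 100), bin_width = 1)
  expect_true(is.na(flat$char_length) || flat$r_squared < 0.5)
})

test_that("radial angles are zero for spokes and +/- pi/2 for arcs", {
  # radial spoke away from the soma
  g <- chain_graph(cbind(c(0, 5, 10), 0))
  tb <- classify_branches(g)
  expect_equal(abs(tb$radial_angle), 0, tolerance = 1e-9)
  # circumferential arcs centered on the soma: a spoke from the soma ends
  # at a branch point from which two arcs leave, so each arc is its own
  # branch with its midpoint on the circle of radius 10
  th_up <- seq(0, 0.6, length.out = 20)
  th_dn <- seq(0, -0.6, length.out = 20)
  pts <- rbind(c(0, 0), 10 * cbind(cos(th_up), sin(th_up)),
               10 * cbind(cos(th_dn[-1]), sin(th_dn[-1])))
  nodes <- data.frame(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2])
  edges <- rbind(c(1, 2),                               # spoke
                 cbind(2:20, 3:21),                     # upper arc
                 c(2, 22), cbind(22:39, 23:40))         # lower arc
  g2 <- skeleton_graph(nodes, edges, soma = 1)
  tb2 <- classify_branches(g2)
  arcs <- which(tb2$type == "terminal")
  expect_equal(abs(tb2$radial_angle[arcs]), rep(pi / 2, 2), tolerance = 0.05)
})

test_that("order parameter matches closed forms and is rotation invariant", {
  expect_equal(order_parameter(rep(0, 10)), 1)
  grid <- seq(-pi, pi, length.out = 1001)[-1]
  expect_lt(order_parameter(grid), 1e-3)
  # von Mises sample: order parameter -> I1(kappa)/I0(kappa)
  set.seed(28)
  kappa <- 2
  th <- seq(-pi, pi, length.out = 4001)
  cdf <- cumsum(exp(kappa * cos(th))); cdf <- cdf / cdf[length(cdf)]
  sm <- stats::approx(cdf, th, runif(20000), rule = 2)$y
  expect_equal(order_parameter(sm),
               besselI(kappa, 1) / besselI(kappa, 0), tolerance = 0.02)
  # rotating all angles leaves the modulus unchanged
  set.seed(29)
  a <- runif(500, -pi, pi)
  expect_equal(order_parameter(a),
               order_parameter((a + 1.1 + pi) %% (2 * pi) - pi),
               tolerance = 1e-12)
})

test_that("gyration widths match uniform shapes", {
  # segment of length 12 on the x axis
  g <- chain_graph(cbind(c(0, 12), c(0, 0)))
  w <- arbor_widths(g)
  expect_equal(w[["D_x"]], 12, tolerance = 1e-3)
  # uniformly sampled circle outline of radius R: width sqrt(6) R per axis
  R <- 5
  th <- seq(0, 2 * pi, length.out = 400)
  nodes <- data.frame(id = seq_along(th), x = R * cos(th), y = R * sin(th))
  g2 <- skeleton_graph(nodes, cbind(seq_len(length(th) - 1), 2:length(th)),
                       soma = 1)
  w2 <- arbor_widths(g2)
  expect_equal(unname(w2), rep(sqrt(6) * R, 2), tolerance = 0.01)
})

test_that("central densities respond to trimming as expected", {
  set.seed(30)
  # homogeneous periodic snapshot: trimmed density equals the box average
  cfg <- sim_config(k48, "periodic", L = 150, dt = 0.05, t_max = 800,
                    N_init = 80, record_interval = 5)
  out <- run_periodic(cfg, burn_in = 0.6)
  rods <- out$final[out$final[, 4] > 0, ]
  # wrap overhanging rods back into the box so the interior is uniform
  segs <- cbind(rods[, 1], rods[, 2],
                rods[, 1] + rods[, 4] * cos(rods[, 3]),
                rods[, 2] + rods[, 4] * sin(rods[, 3]))
  offs <- expand.grid(ox = c(-150, 0, 150), oy = c(-150, 0, 150))
  all_segs <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    cbind(segs[, 1] + offs$ox[i], segs[, 2] + offs$oy[i],
          segs[, 3] + offs$ox[i], segs[, 4] + offs$oy[i])))
  net <- segment_network(all_segs, c(0, 150, 0, 150))
  n <- nrow(net$segments)
  nodes <- data.frame(id = seq_len(2 * n),
                      x = c(net$segments[, 1], net$segments[, 3]),
                      y = c(net$segments[, 2], net$segments[, 4]))
  g <- skeleton_graph(nodes, cbind(seq_len(n), n + seq_len(n)), soma = 1)
  cd <- central_densities(g)
  box_rho <- net$total_length / 150^2
  expect_equal(cd$rho_central, box_rho, tolerance = 0.03)
  # a network with empty margins gets denser after trimming
  inner <- rods[rods[, 1] > 30 & rods[, 1] < 120 &
                  rods[, 2] > 30 & rods[, 2] < 120, , drop = FALSE]
  ni <- nrow(inner)
  nodes_i <- data.frame(id = seq_len(2 * ni + 2),
                        x = c(0, 150, inner[, 1],
                              inner[, 1] + inner[, 4] * cos(inner[, 3])),
                        y = c(0, 150, inner[, 2],
                              inner[, 2] + inner[, 4] * sin(inner[, 3])))
  g_i <- skeleton_graph(nodes_i, cbind(2 + seq_len(ni), 2 + ni + seq_len(ni)),
                        soma = 1)
  untrimmed <- sum(inner[, 4]) / 150^2
  expect_gt(central_densities(g_i)$rho_central, untrimmed)
})

test_that("front-profile alignment recovers the decay length", {
  set.seed(31)
  mk <- function(lam, R, noise = 0) {
    r <- seq(0.5, 120, 0.5)
    data.frame(r = r, rho = 0.1 / (1 + exp((r - R) / lam)) *
                 (1 + rnorm(length(r), 0, noise)))
  }
  res <- front_profile_decay(list(mk(4, 60), mk(4, 65), mk(4, 70)))
  expect_equal(res$lam, 4, tolerance = 0.02)
  # measurement noise mainly perturbs the alignment point; recovery stays
  # within ten percent
  noisy <- front_profile_decay(list(mk(4, 60, 0.01), mk(4, 65, 0.01),
                                    mk(4, 70, 0.01)))
  expect_equal(noisy$lam, 4, tolerance = 0.1)
  # a step front has decay below the grid resolution
  rstep <- seq(0.5, 60, 0.5)
  step_prof <- data.frame(r = rstep, rho = ifelse(rstep < 30, 0.1, 0))
  res2 <- front_profile_decay(list(step_prof))
  expect_true(is.na(res2$lam) || res2$lam < 1)
})

test_that("rebranching probability is recovered from event logs", {
  set.seed(32)
  cfg <- sim_config(k48, "periodic", L = 150, dt = 0.05, t_max = 600,
                    N_init = 100, record_interval = 5, log_events = TRUE)
  out <- arborfield:::rod_sim_run(cfg)
  est <- rebranching_probability(out$events)
  expect_gt(est$n_debranch, 500)
  # binomial 3 sigma plus room for spontaneous-coincidence background
  expect_lt(abs(est$beta_hat - k48$beta), 3 * est$se + 0.01)
  # beta = 0: only background coincidences remain
  k0 <- k48; k0$beta <- 0
  cfg0 <- sim_config(k0, "periodic", L = 150, dt = 0.05, t_max = 300,
                     N_init = 100, record_interval = 5, log_events = TRUE)
  out0 <- arborfield:::rod_sim_run(cfg0)
  expect_lt(rebranching_probability(out0$events)$beta_hat, 0.02)
  # beta = 1: every debranching event rebranches
  k1 <- k48; k1$beta <- 1
  cfg1 <- sim_config(k1, "periodic", L = 100, dt = 0.05, t_max = 200,
                     N_init = 60, record_interval = 5, log_events = TRUE)
  out1 <- arborfield:::rod_sim_run(cfg1)
  expect_equal(rebranching_probability(out1$events)$beta_hat, 1)
})

test_that("SWC files round-trip through the skeleton graph", {
  set.seed(33)
  tree <- exp_tree(21, l_mean = 3)
  path <- tempfile(fileext = ".swc")
  write_swc(tree$graph, path)
  g2 <- read_swc(path)
  tb1 <- classify_branches(tree$graph)
  tb2 <- classify_branches(g2)
  expect_equal(sort(tb2$length), sort(tb1$length), tolerance = 1e-6)
  expect_equal(table(tb2$type), table(tb1$type))
  # packaged synthetic example reads cleanly
  example <- system.file("extdata", "synthetic_tree.swc",
                         package = "arborfield")
  g3 <- read_swc(example)
  tb3 <- classify_branches(g3)
  expect_equal(sum(tb3$type == "terminal"), sum(tb3$type == "internal") + 1)
})

test_that("frontal rods are radially ordered, central rods are not", {
  set.seed(40)
  k <- table1_params("48h")$kinetics
  cfg <- sim_config(k, "open_front", D_ini = 20, N_init = 80, dt = 0.05,
                    t_max = 700, record_interval = 20, snapshot_interval = 350)
  out <- run_expanding(cfg)
  rods <- out$final[out$final[, 4] > 0.5, ]
  mx <- rods[, 1] + rods[, 4] / 2 * cos(rods[, 3])
  my <- rods[, 2] + rods[, 4] / 2 * sin(rods[, 3])
  rmid <- sqrt(mx^2 + my^2)
  # angle between the rod direction and the outward radial direction,
  # folded so inward/outward alignment both count as radial
  ang <- (rods[, 3] - atan2(my, mx) + pi) %% (2 * pi) - pi
  ang <- atan2(sin(2 * ang), cos(2 * ang)) / 2 # orientation, mod pi
  rf <- max(out$front_radius$radius)
  frontal <- rmid > 0.7 * rf
  central <- rmid < 0.4 * rf
  expect_gt(sum(frontal), 20)
  expect_gt(sum(central), 20)
  expect_gt(order_parameter(2 * ang[frontal]),
            order_parameter(2 * ang[central]))
})
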