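test_that("regular tilings share the closed-form mesh/sparsity ratio", {
  for (kind in c("triangle", "square", "hexagon")) {
    a <- analytic_mesh(kind, scale = 2.7)
    expect_equal(a$ratio, 2 - sqrt(2), tolerance = 1e-12)
  }
  expect_equal(analytic_mesh("equal_lines", 3)$ratio, 0.5)
  expect_equal(analytic_mesh("random_lines", 3)$ratio, log(2))
  # triangle side sqrt(3) has mesh 1 - 1/sqrt(2)
  expect_equal(analytic_mesh("triangle", sqrt(3))$M, 1 - 1 / sqrt(2))
})

test_that("tiling generators hit their analytic length densities", {
  set.seed(18)
  for (kind in c("triangle", "square", "hexagon")) {
    net <- make_tiling(kind, scale = 2, window = c(0, 50, 0, 50))
    expect_equal(net$rho, analytic_mesh(kind, 2)$rho, tolerance = 0.02)
  }
  net <- make_tiling("equal_lines", scale = 2, window = c(0, 50, 0, 50))
  expect_equal(net$rho, 0.5, tolerance = 0.02)
})

test_that("Monte-Carlo mesh sizes match the closed forms within 3%", {
  set.seed(19)
  for (kind in c("triangle", "square", "hexagon", "equal_lines")) {
    net <- make_tiling(kind, scale = 2, window = c(0, 80, 0, 80))
    # mean of three independent 5000-circle estimates
    ms <- replicate(3, mesh_size(net, n_circles = 5000))
    expect_equal(mean(unlist(ms["M", ])), analytic_mesh(kind, 2)$M,
                 tolerance = 0.03)
    expect_true(all(unlist(ms["P_hit_at_M", ]) >= 0.48 &
                      unlist(ms["P_hit_at_M", ]) <= 0.52))
  }
})

test_that("the hit curve is monotone with the right limits", {
  set.seed(20)
  net <- make_tiling("square", scale = 2, window = c(0, 40, 0, 40))
  m <- mesh_size(net, n_circles = 3000)
  expect_true(all(diff(m$curve$P_hit) >= 0))
  expect_lt(m$curve$P_hit[1], 0.1)
  expect_equal(m$curve$P_hit[nrow(m$curve)], 1, tolerance = 0.01)
})

test_that("Poisson-line hit probability follows 1 - exp(-rho D)", {
  set.seed(21)
  net <- make_tiling("random_lines", scale = 2, window = c(0, 200, 0, 200))
  m <- mesh_size(net, n_circles = 8000, d_max = 6)
  # the ensemble law holds up to the sampling noise of the ~100 realized
  # lines; the Monte-Carlo curve itself must match the exact coverage of
  # the realized line set much more tightly
  pred <- 1 - exp(-net$rho * m$curve$D)
  expect_lt(max(abs(m$curve$P_hit - pred)), 0.1)
  ys <- sort(net$segments[, 2])
  a <- 3; b <- 197 # margin-shrunk center window (d_max / 2 = 3)
  exact_phit <- function(D) {
    lo <- pmax(ys - D / 2, a); hi <- pmin(ys + D / 2, b)
    keep <- hi > lo
    if (!any(keep)) return(0)
    iv <- cbind(lo[keep], hi[keep])
    tot <- 0; cur <- iv[1, ]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] > cur[2]) { tot <- tot + cur[2] - cur[1]; cur <- iv[i, ] }
      else cur[2] <- max(cur[2], iv[i, 2])
    }
    (tot + cur[2] - cur[1]) / (b - a)
  }
  M_exact <- uniroot(function(D) exact_phit(D) - 0.5, c(0.01, 30))$root
  expect_equal(m$M, M_exact, tolerance = 0.03)
})

test_that("mesh size is invariant under rotation of the network", {
  set.seed(22)
  net <- make_tiling("square", scale = 2, window = c(0, 60, 0, 60))
  m1 <- mesh_size(net, 4000)$M
  th <- 17 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s <- net$segments
  p1 <- cbind(s[, 1] - 30, s[, 2] - 30) %*% R
  p2 <- cbind(s[, 3] - 30, s[, 4] - 30) %*% R
  rot <- segment_network(cbind(p1 + 30, p2 + 30), c(10, 50, 10, 50))
  m2 <- mesh_size(rot, 4000)$M
  expect_equal(m1, m2, tolerance = 0.05)
})

test_that("sparsity slope is exact on closed-form points", {
  sp <- c(); Ms <- c()
  for (l in c(1.5, 2, 3, 4)) {
    for (kind in c("triangle", "square", "hexagon")) {
      a <- analytic_mesh(kind, l)
      sp <- c(sp, 1 / a$rho); Ms <- c(Ms, a$M)
    }
  }
  expect_equal(mesh_sparsity_slope(sp, Ms), 2 - sqrt(2), tolerance = 1e-12)
})

test_that("rod-simulation snapshots have mesh/sparsity slope near one half", {
  set.seed(23)
  pts <- t(vapply(c(0.001, 0.002, 0.004), function(kb) {
    k <- k48; k$k_b <- kb
    cfg <- sim_config(k, "periodic", L = 150, dt = 0.05, t_max = 900,
                      N_init = 80, record_interval = 5)
    out <- run_periodic(cfg, burn_in = 0.6)
    net <- make_tiling("rod_sim_snapshot", window = c(0, 150, 0, 150),
                       snapshot = out$final)
    c(1 / net$rho, mesh_size(net, 4000, periodic = TRUE)$M)
  }, numeric(2)))
  slope <- mesh_sparsity_slope(pts[, 1], pts[, 2])
  # branch-point-free patterns cluster near 1/2, well below the regular
  # tilings' 0.59
  expect_equal(slope, 0.5, tolerance = 0.2)
  expect_lt(slope, 2 - sqrt(2))
})

test_that("Delaunay triangulations satisfy the empty-circumcircle property", {
  set.seed(24)
  pts <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  dt <- delaunay(pts)
  expect_gt(nrow(dt$triangles), 30) # ~2n triangles for interior-rich sets
  for (t in seq_len(nrow(dt$triangles))) {
    tr <- dt$triangles[t, ]
    cc <- arborfield:::circumcircle(pts[tr[1], ], pts[tr[2], ], pts[tr[3], ])
    d2 <- (pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2
    expect_true(all(d2[-tr] > cc[3] * (1 - 1e-9)))
  }
})

test_that("Voronoi and Delaunay generators yield valid finite networks", {
  set.seed(25)
  v <- make_tiling("voronoi", scale = 50, window = c(0, 30, 0, 30))
  expect_gt(nrow(v$segments), 20)
  expect_true(is.finite(v$rho) && v$rho > 0)
  d <- make_tiling("delaunay", scale = 50, window = c(0, 30, 0, 30))
  expect_gt(d$rho, v$rho) # triangulations are denser than their duals
})
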