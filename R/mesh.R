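#' Planar segment network
#'
#' A set of 2-D line segments in a rectangular window, the input of the
#' mesh-size estimator. Segments are clipped to the window
#' (Liang-Barsky) so the length density refers to the window area.
#'
#' @param segments 4-column matrix or data frame `(x1, y1, x2, y2)` (um).
#' @param window `c(xmin, xmax, ymin, ymax)`.
#' @param clip clip segments to the window (default `TRUE`).
#' @return An object of class `segment_network` with `segments`, `window`,
#'   `total_length`, `area`, and `rho` (length density, um^-1).
#' @export
segment_network <- function(segments, window, clip = TRUE) {
  segments <- as.matrix(segments)[, 1:4, drop = FALSE]
  if (clip) segments <- clip_segments(segments, window)
  if (nrow(segments) == 0) stop("no segments inside the window")
  len <- sqrt((segments[, 3] - segments[, 1])^2 +
                (segments[, 4] - segments[, 2])^2)
  segments <- segments[len > 0, , drop = FALSE]
  len <- len[len > 0]
  area <- (window[2] - window[1]) * (window[4] - window[3])
  structure(list(segments = segments, window = window,
                 total_length = sum(len), area = area,
                 rho = sum(len) / area),
            class = "segment_network")
}

#' @export
print.segment_network <- function(x, ...) {
  cat(sprintf("segment network: %d segments, rho = %.4g /um in %g x %g um window\n",
              nrow(x$segments), x$rho, x$window[2] - x$window[1],
              x$window[4] - x$window[3]))
  invisible(x)
}

# Liang-Barsky clipping of many segments to a rectangle
clip_segments <- function(seg, w) {
  x1 <- seg[, 1]; y1 <- seg[, 2]; x2 <- seg[, 3]; y2 <- seg[, 4]
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- rep(0, nrow(seg)); t1 <- rep(1, nrow(seg))
  ok <- rep(TRUE, nrow(seg))
  for (side in 1:4) {
    p <- switch(side, -dx, dx, -dy, dy)
    q <- switch(side, x1 - w[1], w[2] - x1, y1 - w[3], w[4] - y1)
    par <- p == 0
    ok <- ok & !(par & q < 0)
    r <- ifelse(p == 0, NA_real_, q / p)
    t0 <- ifelse(!par & p < 0, pmax(t0, r), t0)
    t1 <- ifelse(!par & p > 0, pmin(t1, r), t1)
  }
  ok <- ok & t0 < t1
  cbind(x1 + t0 * dx, y1 + t0 * dy, x1 + t1 * dx, y1 + t1 * dy)[ok, ,
                                                                drop = FALSE]
}

# minimum distances from points to any segment, chunked to bound memory;
# optionally with periodic wrapping over a square box of side L
min_dist_to_segments <- function(px, py, seg, periodic = FALSE, L = NULL) {
  nseg <- nrow(seg)
  x1 <- seg[, 1]; y1 <- seg[, 2]
  ex <- seg[, 3] - x1; ey <- seg[, 4] - y1
  e2 <- pmax(ex^2 + ey^2, 1e-300)
  out <- numeric(length(px))
  chunk <- max(1L, floor(2e6 / nseg))
  offs <- if (periodic) expand.grid(ox = c(-L, 0, L), oy = c(-L, 0, L))
          else data.frame(ox = 0, oy = 0)
  for (s in seq(1, length(px), by = chunk)) {
    idx <- s:min(s + chunk - 1, length(px))
    best <- rep(Inf, length(idx))
    for (o in seq_len(nrow(offs))) {
      qx <- outer(px[idx] + offs$ox[o], x1, "-")
      qy <- outer(py[idx] + offs$oy[o], y1, "-")
      tt <- sweep(sweep(qx, 2, ex, "*") + sweep(qy, 2, ey, "*"), 2, e2, "/")
      tt[tt < 0] <- 0; tt[tt > 1] <- 1
      dx <- qx - sweep(tt, 2, ex, "*")
      dy <- qy - sweep(tt, 2, ey, "*")
      best <- pmin(best, sqrt(apply(dx^2 + dy^2, 1, min)))
    }
    out[idx] <- best
  }
  out
}

#' Monte-Carlo mesh size of a segment network
#'
#' The mesh size is the diameter of a randomly placed circle that has a 50%
#' chance of intersecting the network: the median hole size. Circle centers
#' are drawn uniformly in the window shrunk by `d_max / 2` on every side (so
#' the largest trial circle stays inside); a circle of diameter D centered
#' at c hits the network iff the minimum center-to-segment distance is at
#' most D/2. All trial diameters share the same centers (common random
#' numbers), which makes the empirical hit curve monotone by construction;
#' the mesh size is then twice the median center-to-segment distance.
#'
#' @param net a [segment_network()].
#' @param n_circles number of random circles (default 5000).
#' @param d_max largest trial diameter (um); defaults to `4 / rho` capped at
#'   40% of the smaller window side.
#' @param n_curve number of diameters at which the hit curve is reported.
#' @param periodic treat the window as a periodic box (wrapped distances,
#'   no margin shrinkage); for rod-simulation snapshots.
#' @return An object of class `mesh_estimate`: `M` (um), `P_hit_at_M`,
#'   `curve` (data frame `D`, `P_hit`), `n_circles`, `distances`.
#' @export
mesh_size <- function(net, n_circles = 5000, d_max = NULL, n_curve = 50,
                      periodic = FALSE) {
  stopifnot(inherits(net, "segment_network"))
  w <- net$window
  if (is.null(d_max))
    d_max <- min(4 / net$rho, 0.4 * min(w[2] - w[1], w[4] - w[3]))
  margin <- if (periodic) 0 else d_max / 2
  if (w[1] + margin >= w[2] - margin || w[3] + margin >= w[4] - margin)
    stop("window too small for the requested trial diameters")
  px <- stats::runif(n_circles, w[1] + margin, w[2] - margin)
  py <- stats::runif(n_circles, w[3] + margin, w[4] - margin)
  d <- min_dist_to_segments(px, py, net$segments, periodic = periodic,
                            L = w[2] - w[1])
  M <- 2 * stats::median(d)
  Dg <- seq(0, d_max, length.out = n_curve + 1)[-1]
  curve <- data.frame(D = Dg,
                      P_hit = vapply(Dg, function(D) mean(d <= D / 2),
                                     numeric(1)))
  structure(list(M = M, P_hit_at_M = mean(d <= M / 2), curve = curve,
                 n_circles = n_circles, distances = d),
            class = "mesh_estimate")
}

#' @export
print.mesh_estimate <- function(x, ...) {
  cat(sprintf("mesh size M = %.4g um (P_hit(M) = %.3f, %d circles)\n",
              x$M, x$P_hit_at_M, x$n_circles))
  invisible(x)
}

#' Benchmark tilings and line patterns as segment networks
#'
#' Generators for the tilings used to benchmark space-filling economy:
#' regular triangular / square / hexagonal tilings of side `scale`,
#' equally spaced horizontal lines (spacing `scale`), randomly
#' (exponentially) spaced horizontal lines (mean spacing `scale`), Voronoi
#' tessellations and Delaunay triangulations of uniform random points
#' (`scale` = point count), and rod-simulation snapshots.
#'
#' @param kind one of `"triangle"`, `"square"`, `"hexagon"`,
#'   `"equal_lines"`, `"random_lines"`, `"voronoi"`, `"delaunay"`,
#'   `"rod_sim_snapshot"`.
#' @param scale side length / spacing (um), or number of points for
#'   voronoi/delaunay.
#' @param window `c(xmin, xmax, ymin, ymax)`.
#' @param snapshot rod snapshot matrix (`x, y, theta, length, state`) for
#'   `kind = "rod_sim_snapshot"`.
#' @return A [segment_network()].
#' @export
make_tiling <- function(kind = c("triangle", "square", "hexagon",
                                 "equal_lines", "random_lines", "voronoi",
                                 "delaunay", "rod_sim_snapshot"),
                        scale = 1, window = c(0, 10, 0, 10),
                        snapshot = NULL) {
  kind <- match.arg(kind)
  stopifnot(scale > 0)
  w <- window
  wx <- w[2] - w[1]; wy <- w[4] - w[3]
  pad <- 2 * scale
  segs <- switch(kind,
    square = {
      # half-spacing offset keeps lattice lines off the window boundary
      xs <- seq(w[1] - pad + scale / 2, w[2] + pad, by = scale)
      ys <- seq(w[3] - pad + scale / 2, w[4] + pad, by = scale)
      rbind(cbind(xs, w[3] - pad, xs, w[4] + pad),
            cbind(w[1] - pad, ys, w[2] + pad, ys))
    },
    triangle = {
      # three families of parallel lines at 0, 60, 120 degrees,
      # spacing = triangle height
      h <- scale * sqrt(3) / 2
      ext <- max(wx, wy) + 4 * pad
      ctr <- c(mean(w[1:2]), mean(w[3:4]))
      out <- NULL
      for (ang in c(0, pi / 3, 2 * pi / 3)) {
        nrm <- c(-sin(ang), cos(ang))
        dirv <- c(cos(ang), sin(ang))
        # offsets must be exact multiples of the spacing so the three
        # families share their triple intersection points
        for (s in h * seq(ceiling(-ext / h), floor(ext / h))) {
          p0 <- ctr + s * nrm - ext * dirv
          p1 <- ctr + s * nrm + ext * dirv
          out <- rbind(out, c(p0, p1))
        }
      }
      out
    },
    hexagon = {
      # honeycomb of side l: vertices on two interleaved triangular lattices
      l <- scale
      out <- list()
      ny <- ceiling((wy + 4 * pad) / (1.5 * l))
      nx <- ceiling((wx + 4 * pad) / (sqrt(3) * l))
      for (i in seq(-2, nx + 2)) {
        for (j in seq(-2, ny + 2)) {
          cx <- w[1] + i * sqrt(3) * l + (j %% 2) * sqrt(3) / 2 * l
          cy <- w[3] + j * 1.5 * l
          ang <- pi / 6 + (0:5) * pi / 3
          vx <- cx + l * cos(ang); vy <- cy + l * sin(ang)
          for (e in 1:6)
            out[[length(out) + 1]] <- c(vx[e], vy[e],
                                        vx[e %% 6 + 1], vy[e %% 6 + 1])
        }
      }
      m <- do.call(rbind, out)
      # deduplicate shared edges
      key <- apply(round(m, 9), 1, function(r) {
        a <- r[1:2]; b <- r[3:4]
        if (a[1] < b[1] || (a[1] == b[1] && a[2] < b[2]))
          paste(c(a, b), collapse = ",") else paste(c(b, a), collapse = ",")
      })
      m[!duplicated(key), , drop = FALSE]
    },
    equal_lines = {
      ys <- seq(w[3] - pad + scale / 2, w[4] + pad, by = scale)
      cbind(w[1] - 1, ys, w[2] + 1, ys)
    },
    random_lines = {
      ys <- w[3] - pad + cumsum(stats::rexp(ceiling((wy + 4 * pad) / scale * 3) + 10,
                                            rate = 1 / scale))
      ys <- ys[ys <= w[4] + pad]
      cbind(w[1] - 1, ys, w[2] + 1, ys)
    },
    voronoi = {
      n <- max(4, round(scale))
      pts <- cbind(stats::runif(n, w[1], w[2]), stats::runif(n, w[3], w[4]))
      voronoi_edges(delaunay(pts))
    },
    delaunay = {
      n <- max(3, round(scale))
      pts <- cbind(stats::runif(n, w[1], w[2]), stats::runif(n, w[3], w[4]))
      dt <- delaunay(pts)
      tri <- dt$triangles
      m <- rbind(cbind(dt$points[tri[, 1], ], dt$points[tri[, 2], ]),
                 cbind(dt$points[tri[, 2], ], dt$points[tri[, 3], ]),
                 cbind(dt$points[tri[, 3], ], dt$points[tri[, 1], ]))
      key <- apply(round(m, 9), 1, function(r) {
        a <- r[1:2]; b <- r[3:4]
        if (a[1] < b[1] || (a[1] == b[1] && a[2] < b[2]))
          paste(c(a, b), collapse = ",") else paste(c(b, a), collapse = ",")
      })
      m[!duplicated(key), , drop = FALSE]
    },
    rod_sim_snapshot = {
      stopifnot(!is.null(snapshot))
      s <- snapshot[snapshot[, 4] > 0, , drop = FALSE]
      cbind(s[, 1], s[, 2],
            s[, 1] + s[, 4] * cos(s[, 3]), s[, 2] + s[, 4] * sin(s[, 3]))
    })
  segment_network(segs, window)
}

#' Closed-form mesh sizes of benchmark patterns
#'
#' Analytic mesh sizes: for the regular tilings the interior distance to the
#' cell boundary is controlled by the inradius `a`, with
#' `P(miss at D) = ((a - D/2)/a)^2`, so `M = 2a(1 - 1/sqrt(2))`
#' (`a = l/(2 sqrt(3))`, `l/2`, `l sqrt(3)/2` for triangle, square,
#' hexagon); equally spaced lines at spacing `s` give `M = s/2`; Poisson
#' (exponentially spaced) lines of mean spacing `s` give
#' `P_hit(D) = 1 - exp(-D/s)`, hence `M = s ln 2`.
#'
#' @param kind `"triangle"`, `"square"`, `"hexagon"`, `"equal_lines"`, or
#'   `"random_lines"`.
#' @param scale side length / spacing (um).
#' @return List with `M`, `rho` (length density of the pattern), and the
#'   dimensionless ratio `M * rho`.
#' @export
analytic_mesh <- function(kind = c("triangle", "square", "hexagon",
                                   "equal_lines", "random_lines"),
                          scale = 1) {
  kind <- match.arg(kind)
  l <- scale
  out <- switch(kind,
    triangle = list(M = l * (1 - 1 / sqrt(2)) / sqrt(3), rho = 2 * sqrt(3) / l),
    square = list(M = l * (1 - 1 / sqrt(2)), rho = 2 / l),
    hexagon = list(M = l * sqrt(3) * (1 - 1 / sqrt(2)), rho = 2 / (sqrt(3) * l)),
    equal_lines = list(M = l / 2, rho = 1 / l),
    random_lines = list(M = l * log(2), rho = 1 / l))
  out$ratio <- out$M * out$rho
  out
}

#' Mesh-size versus sparsity slope
#'
#' Zero-intercept least-squares slope of mesh size against sparsity (inverse
#' length density), the dimensionless measure of how economically a pattern
#' fills space.
#'
#' @param sparsity inverse length densities (um).
#' @param M mesh sizes (um).
#' @return Scalar slope.
#' @export
mesh_sparsity_slope <- function(sparsity, M) {
  stopifnot(length(sparsity) >= 3, length(M) == length(sparsity))
  sum(sparsity * M) / sum(sparsity^2)
}
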