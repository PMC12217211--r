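# Planar Delaunay triangulation (Bowyer-Watson) and its Voronoi dual.
# Small-n utility backing the tiling generators; O(n^2), fine for the
# few-hundred-point tessellations used as mesh benchmarks.

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2) # center and squared radius
}

#' Delaunay triangulation of planar points
#'
#' Incremental Bowyer-Watson triangulation. Ties (cocircular points) are
#' perturbation-free but assume points in general position; duplicated
#' points are removed.
#'
#' @param pts two-column matrix of point coordinates.
#' @return List with `points` and `triangles` (three-column index matrix,
#'   counterclockwise).
#' @export
delaunay <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 distinct points")
  # super-triangle
  rng <- apply(pts, 2, range)
  ctr <- colMeans(rng)
  span <- max(rng[2, ] - rng[1, ]) * 10 + 1
  P <- rbind(pts,
             ctr + c(-span, -span), ctr + c(span, -span), ctr + c(0, span))
  tris <- list(c(n + 1, n + 2, n + 3))
  ccs <- list(circumcircle(P[n + 1, ], P[n + 2, ], P[n + 3, ]))
  for (i in seq_len(n)) {
    bad <- vapply(seq_along(tris), function(t) {
      cc <- ccs[[t]]
      (P[i, 1] - cc[1])^2 + (P[i, 2] - cc[2])^2 <= cc[3] * (1 + 1e-12)
    }, logical(1))
    # boundary polygon = edges of bad triangles not shared by two of them
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad]
    ccs <- ccs[!bad]
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, ], i)
      cc <- circumcircle(P[tr[1], ], P[tr[2], ], P[tr[3], ])
      if (!is.null(cc)) {
        tris[[length(tris) + 1]] <- tr
        ccs[[length(ccs) + 1]] <- cc
      }
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), logical(1))
  tri_m <- do.call(rbind, tris[keep])
  # orient counterclockwise
  for (t in seq_len(nrow(tri_m))) {
    a <- P[tri_m[t, 1], ]; b <- P[tri_m[t, 2], ]; cc <- P[tri_m[t, 3], ]
    if ((b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]) < 0)
      tri_m[t, 2:3] <- tri_m[t, 3:2]
  }
  list(points = pts, triangles = tri_m)
}

# Voronoi edges dual to a Delaunay triangulation: connect circumcenters of
# adjacent triangles; hull-edge cells are closed by rays clipped later.
voronoi_edges <- function(dt) {
  P <- dt$points
  tri <- dt$triangles
  cc <- t(apply(tri, 1, function(tr)
    circumcircle(P[tr[1], ], P[tr[2], ], P[tr[3], ])[1:2]))
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_tri <- new.env(parent = emptyenv())
  for (t in seq_len(nrow(tri))) {
    for (e in list(tri[t, 1:2], tri[t, 2:3], tri[t, c(1, 3)])) {
      k <- ekey(e[1], e[2])
      edge_tri[[k]] <- c(edge_tri[[k]], t)
    }
  }
  segs <- list()
  for (k in ls(edge_tri)) {
    ts <- edge_tri[[k]]
    if (length(ts) == 2) {
      segs[[length(segs) + 1]] <- c(cc[ts[1], ], cc[ts[2], ])
    } else if (length(ts) == 1) {
      # hull edge: ray from circumcenter through edge midpoint, outward
      ij <- as.integer(strsplit(k, " ")[[1]])
      mid <- (P[ij[1], ] + P[ij[2], ]) / 2
      third <- setdiff(tri[ts, ], ij)
      dirv <- mid - cc[ts, ]
      if (sum(dirv^2) < 1e-20) {
        ev <- P[ij[2], ] - P[ij[1], ]
        dirv <- c(ev[2], -ev[1])
      }
      # orient away from the opposite vertex
      if (sum(dirv * (mid - P[third, ])) < 0) dirv <- -dirv
      dirv <- dirv / sqrt(sum(dirv^2))
      far <- cc[ts, ] + dirv * (10 * max(apply(P, 2, function(x)
        diff(range(x)))) + 1)
      segs[[length(segs) + 1]] <- c(cc[ts, ], far)
    }
  }
  do.call(rbind, segs)
}
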