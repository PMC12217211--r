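#' Decompose a skeleton into branches and classify them
#'
#' Branches are maximal paths between nodes of degree != 2 (or the soma). A
#' terminal branch ends at a free tip (degree-1 node other than the soma);
#' an internal branch connects two branch points, or a branch point and the
#' soma.
#'
#' @param g a [skeleton_graph()].
#' @return A data frame (`branch_table`) with one row per branch: `type`
#'   (`"terminal"`/`"internal"`), `length` (um), `mid_x`, `mid_y`,
#'   `radial_angle` (rad, see [radial_angles()]), and `nodes` (list column of
#'   node ids along the branch, proximal end first).
#' @export
classify_branches <- function(g) {
  ig <- g$graph
  deg <- igraph::degree(ig)
  soma <- as.character(g$soma)
  junction <- deg != 2
  junction[soma] <- TRUE
  nodes <- g$nodes
  xy <- function(v) {
    i <- match(v, as.character(nodes$id))
    cbind(nodes$x[i], nodes$y[i])
  }
  vn <- igraph::V(ig)$name
  adj <- igraph::adjacent_vertices(ig, vn)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  dist_soma <- igraph::distances(ig, v = soma, weights = igraph::E(ig)$length)
  for (v in vn[junction]) {
    for (w in names(adj[[v]])) {
      # walk from junction v through w until the next junction
      path <- c(v, w)
      prev <- v; cur <- w
      while (!junction[cur]) {
        nxt <- setdiff(names(adj[[cur]]), prev)
        if (length(nxt) == 0) break
        prev <- cur; cur <- nxt[1]
        path <- c(path, cur)
      }
      key <- paste(min(path[1], path[length(path)]),
                   max(path[1], path[length(path)]),
                   min(path[2], path[length(path) - 1]), sep = "|")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      p <- xy(path)
      seg_len <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
      ends <- path[c(1, length(path))]
      # orient proximal -> distal by graph distance from the soma
      if (dist_soma[1, ends[1]] > dist_soma[1, ends[2]]) {
        path <- rev(path); p <- p[rev(seq_len(nrow(p))), ]
        seg_len <- rev(seg_len)
        ends <- rev(ends)
      }
      is_term <- deg[ends[2]] == 1 && ends[2] != soma
      rows[[length(rows) + 1]] <-
        list(type = if (is_term) "terminal" else "internal",
             length = sum(seg_len), path = path)
    }
  }
  out <- data.frame(
    type = vapply(rows, `[[`, character(1), "type"),
    length = vapply(rows, `[[`, numeric(1), "length"))
  mids <- t(vapply(seq_along(rows), function(i) {
    branch_point_at(xy(rows[[i]]$path), out$length[i] / 2)
  }, numeric(2)))
  out$mid_x <- mids[, 1]
  out$mid_y <- mids[, 2]
  out$nodes <- I(lapply(rows, `[[`, "path"))
  out$radial_angle <- radial_angles(g, out)
  out
}

# point at arclength s along a polyline
branch_point_at <- function(p, s) {
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  cs <- cumsum(seg)
  i <- which(cs >= s - 1e-12)[1]
  if (is.na(i)) return(p[nrow(p), ])
  s0 <- if (i == 1) 0 else cs[i - 1]
  f <- (s - s0) / seg[i]
  p[i, ] + f * (p[i + 1, ] - p[i, ])
}

#' Radial orientation angles of branches
#'
#' For each branch, the radial direction is the line from the soma to the
#' branch midpoint; the branch direction is a straight-line fit through a
#' 1 um window of the branch around its midpoint, oriented towards the
#' distal end. The radial angle is measured from the radial direction to
#' the branch direction, positive counterclockwise, in `(-pi, pi]`; 0 means
#' perfectly outward-radial.
#'
#' @param g a [skeleton_graph()].
#' @param table branch table from [classify_branches()] (with `nodes` list
#'   column); when omitted, computed internally.
#' @param window tangent-fit window (um, default 1).
#' @return Numeric vector of angles (rad).
#' @export
radial_angles <- function(g, table = NULL, window = 1) {
  if (is.null(table)) table <- classify_branches(g)
  nodes <- g$nodes
  soma_xy <- c(nodes$x[nodes$id == g$soma], nodes$y[nodes$id == g$soma])
  vapply(seq_len(nrow(table)), function(i) {
    path <- table$nodes[[i]]
    idx <- match(path, as.character(nodes$id))
    p <- cbind(nodes$x[idx], nodes$y[idx])
    L <- table$length[i]
    half <- min(window / 2, L / 2)
    a <- branch_point_at(p, L / 2 - half)
    b <- branch_point_at(p, L / 2 + half)
    tangent <- b - a # oriented proximal -> distal
    mid <- c(table$mid_x[i], table$mid_y[i])
    radial <- mid - soma_xy
    if (sum(radial^2) < 1e-24 || sum(tangent^2) < 1e-24) return(NA_real_)
    atan2(radial[1] * tangent[2] - radial[2] * tangent[1],
          sum(radial * tangent))
  }, numeric(1))
}

#' Angular order parameter
#'
#' Modulus of the mean unit phasor, `|mean(exp(i theta))|`: 0 for an
#' isotropic angle distribution, 1 for perfect alignment.
#'
#' @param angles radial angles (rad); `NA`s dropped.
#' @return Scalar in `[0, 1]`.
#' @export
order_parameter <- function(angles) {
  angles <- angles[is.finite(angles)]
  stopifnot(length(angles) >= 1)
  Mod(mean(exp(1i * angles)))
}

#' Fit the branch-length distribution
#'
#' Sample mean plus an exponential characteristic length fitted to the
#' branch-length histogram on log counts (weighted least squares, weights =
#' counts), excluding the first bin, which is depressed by detection limits
#' in skeletonized imaging data.
#'
#' @param lengths branch lengths (um), or a branch table with a `length`
#'   column.
#' @param bin_width histogram bin width (um, default 1).
#' @return List with `mean`, `char_length` (um), `r_squared` of the log-count
#'   fit, and the histogram used.
#' @export
fit_branch_lengths <- function(lengths, bin_width = 1) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  lengths <- lengths[is.finite(lengths) & lengths >= 0]
  stopifnot(length(lengths) >= 30)
  h <- graphics::hist(lengths,
                      breaks = seq(0, max(lengths) + bin_width, by = bin_width),
                      plot = FALSE)
  keep <- which(h$counts > 0)
  keep <- keep[keep > 1] # ignore the first bin
  if (length(keep) < 3) {
    return(list(mean = mean(lengths), char_length = NA_real_,
                r_squared = NA_real_, hist = h))
  }
  fit <- stats::lm(log(h$counts[keep]) ~ h$mids[keep],
                   weights = h$counts[keep])
  list(mean = mean(lengths),
       char_length = -1 / unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       hist = h)
}

# sample points along all edges of a skeleton at fixed arc-length step
sample_skeleton_points <- function(g, step = 0.1) {
  nodes <- g$nodes
  ends <- igraph::ends(g$graph, igraph::E(g$graph))
  a <- match(ends[, 1], as.character(nodes$id))
  b <- match(ends[, 2], as.character(nodes$id))
  x1 <- nodes$x[a]; y1 <- nodes$y[a]; x2 <- nodes$x[b]; y2 <- nodes$y[b]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  npt <- pmax(1L, ceiling(len / step))
  idx <- rep.int(seq_along(len), npt)
  f <- unlist(lapply(npt, function(n) (seq_len(n) - 0.5) / n))
  w <- rep.int(len / npt, npt)
  cbind(x = x1[idx] + f * (x2[idx] - x1[idx]),
        y = y1[idx] + f * (y2[idx] - y1[idx]), w = w)
}

#' Arbor widths from the radius of gyration
#'
#' Widths along the two window axes as `sqrt(12)` times the radius of
#' gyration of the (densely resampled) skeleton mass projected on each axis
#' - exact for a uniformly filled rectangle.
#'
#' @param g a [skeleton_graph()].
#' @param step resampling step (um, default 0.1).
#' @return Named vector `c(D_x, D_y)` (um).
#' @export
arbor_widths <- function(g, step = 0.1) {
  p <- sample_skeleton_points(g, step)
  rg <- function(v, w) sqrt(sum(w * (v - sum(w * v) / sum(w))^2) / sum(w))
  c(D_x = sqrt(12) * rg(p[, 1], p[, 3]),
    D_y = sqrt(12) * rg(p[, 2], p[, 3]))
}

#' Tip and length densities in the trimmed central region
#'
#' Removes the peripheral 5% of the arbor's bounding rectangle on all four
#' sides, then reports the number of tips and the summed branch length
#' inside, each normalized by the trimmed area.
#'
#' @param g a [skeleton_graph()].
#' @param trim fraction trimmed from each side (default 0.05).
#' @return List with `N_central` (tips um^-2), `rho_central` (um^-1), and
#'   the trimmed `window`.
#' @export
central_densities <- function(g, trim = 0.05) {
  nodes <- g$nodes
  bb <- c(range(nodes$x), range(nodes$y))
  wx <- bb[2] - bb[1]; wy <- bb[4] - bb[3]
  w <- c(bb[1] + trim * wx, bb[2] - trim * wx,
         bb[3] + trim * wy, bb[4] - trim * wy)
  deg <- igraph::degree(g$graph)
  tips <- names(deg)[deg == 1 & names(deg) != as.character(g$soma)]
  ti <- match(tips, as.character(nodes$id))
  inside <- nodes$x[ti] >= w[1] & nodes$x[ti] <= w[2] &
    nodes$y[ti] >= w[3] & nodes$y[ti] <= w[4]
  ends <- igraph::ends(g$graph, igraph::E(g$graph))
  a <- match(ends[, 1], as.character(nodes$id))
  b <- match(ends[, 2], as.character(nodes$id))
  segs <- cbind(nodes$x[a], nodes$y[a], nodes$x[b], nodes$y[b])
  cl <- clip_segments(segs, w)
  total <- if (nrow(cl)) sum(sqrt((cl[, 3] - cl[, 1])^2 +
                                    (cl[, 4] - cl[, 2])^2)) else 0
  area <- (w[2] - w[1]) * (w[4] - w[3])
  list(N_central = sum(inside) / area, rho_central = total / area, window = w)
}

#' Mean front profile and decay length
#'
#' Aligns radial density profiles at the radius where each falls to 10% of
#' its central plateau, normalizes by the plateau, averages them on a common
#' grid, and fits an exponential to the outer tail (from the outermost edge
#' in to where the mean profile reaches 25% of the plateau).
#'
#' @param profiles list of data frames with columns `r` and `rho`.
#' @param plateau_frac fraction of the radial range used for the central
#'   plateau estimate (default 0.25).
#' @param dz grid step of the aligned profile (um).
#' @return List with `mean_profile` (data frame `z`, `rho`; `z = 0` at the
#'   10% point), `lam` (um), and `align_radii`.
#' @export
front_profile_decay <- function(profiles, plateau_frac = 0.25, dz = 0.5) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  aligned <- list()
  radii <- numeric(0)
  for (p in profiles) {
    central <- mean(p$rho[p$r <= plateau_frac * max(p$r)])
    if (!is.finite(central) || central <= 0) next
    r10 <- front_radius_of_profile(p$r, p$rho, frac = 0.1)
    radii <- c(radii, r10)
    aligned[[length(aligned) + 1]] <-
      data.frame(z = p$r - r10, rho = p$rho / central)
  }
  if (length(aligned) == 0) stop("no profile had a positive central plateau")
  # common grid restricted to the range covered by every profile, so no
  # profile is flat-extrapolated into the average
  zlo <- max(vapply(aligned, function(a) min(a$z), numeric(1)))
  zhi <- min(vapply(aligned, function(a) max(a$z), numeric(1)))
  zg <- seq(zlo, zhi, by = dz)
  mat <- vapply(aligned, function(a)
    stats::approx(a$z, a$rho, zg, rule = 2)$y, numeric(length(zg)))
  mp <- data.frame(z = zg, rho = rowMeans(mat))
  tail_sel <- which(mp$rho <= 0.25 & mp$rho > 1e-9 & mp$z > min(mp$z))
  tail_sel <- tail_sel[tail_sel > which.max(mp$rho)]
  lam <- NA_real_
  if (length(tail_sel) >= 3) {
    fit <- stats::lm(log(rho) ~ z, mp[tail_sel, ])
    lam <- -1 / unname(stats::coef(fit)[2])
  }
  list(mean_profile = mp, lam = lam, align_radii = radii)
}

#' Rebranching probability from an event log
#'
#' The rebranching probability is the fraction of debranching events
#' (branch disappearance at zero length) that are followed by the
#' appearance of a new branch at the same site within a distance tolerance
#' and time window - the event-count analogue of scoring time-lapse
#' recordings.
#'
#' @param events data frame with columns `time`, `type`, `x`, `y`; `type`
#'   uses the simulator vocabulary: `"debranch"` (disappeared for good),
#'   `"rebranch"` (disappeared and regrew at the site), `"branch"`
#'   (nucleation). A `"rebranch"` row counts as a debranching event with an
#'   instantaneous matched appearance.
#' @param dist_tol matching radius (um, default 0.5).
#' @param time_window matching window after the debranch (min, default 20,
#'   matching a 15-20 min recording).
#' @return List with `beta_hat`, `n_debranch`, `n_matched`, and the binomial
#'   standard error.
#' @export
rebranching_probability <- function(events, dist_tol = 0.5, time_window = 20) {
  stopifnot(all(c("time", "type", "x", "y") %in% names(events)))
  deb <- events[events$type %in% c("debranch", "rebranch"), ]
  app <- events[events$type %in% c("branch", "rebranch"), ]
  n <- nrow(deb)
  if (n == 0) return(list(beta_hat = NA_real_, n_debranch = 0L,
                          n_matched = 0L, se = NA_real_))
  matched <- vapply(seq_len(n), function(i) {
    sel <- app$time >= deb$time[i] & app$time <= deb$time[i] + time_window &
      abs(app$x - deb$x[i]) <= dist_tol & abs(app$y - deb$y[i]) <= dist_tol
    any(sel & (app$x - deb$x[i])^2 + (app$y - deb$y[i])^2 <= dist_tol^2)
  }, logical(1))
  b <- mean(matched)
  list(beta_hat = b, n_debranch = n, n_matched = sum(matched),
       se = sqrt(b * (1 - b) / n))
}
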