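#' Control configuration
#'
#' Parameters of the gesture-to-stage mapping. The commanded planar speed is
#' proportional to how far the hand's centre of mass sits beyond a neutral
#' sphere of radius `rho0` around the gesture sensor; inside the sphere the
#' stage holds still. A speed ceiling keeps the proportional law bounded.
#'
#' @param rho0 neutral-sphere radius, mm (default 50).
#' @param gain mm/s of stage speed per mm of hand displacement beyond `rho0`
#'   (default 1).
#' @param max_speed speed clamp, mm/s (default 20).
#' @param workspace X-Y bounds as `c(xmin, xmax, ymin, ymax)`, mm.
#' @return a list of class `telepalp_control_config`.
#' @export
control_config <- function(rho0 = 50, gain = 1, max_speed = 20,
                           workspace = c(0, 100, 0, 100)) {
  check_scalar_num(rho0, "rho0", 0, strict_lower = TRUE)
  check_scalar_num(gain, "gain", 0, strict_lower = TRUE)
  check_scalar_num(max_speed, "max_speed", 0, strict_lower = TRUE)
  if (length(workspace) != 4 || workspace[2] <= workspace[1] ||
      workspace[4] <= workspace[3])
    abort("workspace must be c(xmin, xmax, ymin, ymax) with positive extent")
  structure(list(rho0 = rho0, gain = gain, max_speed = max_speed,
                 workspace = workspace),
            class = "telepalp_control_config")
}

#' Map a hand sample to a stage velocity
#'
#' With `rho` the distance of the hand position from the sensor centre, the
#' commanded planar velocity is zero on the closed ball `rho <= rho0` and
#' otherwise has magnitude `min(gain * (rho - rho0), max_speed)` along the
#' horizontal (X-Y) projection of the hand displacement. Speed is therefore
#' continuous at the dead-zone boundary.
#'
#' @param hand numeric length-3 hand position relative to the sensor centre,
#'   mm.
#' @param cfg a [control_config()].
#' @return planar velocity `c(vx, vy)`, mm/s.
#' @export
#' @examples
#' gesture_to_velocity(c(60, 0, 0), control_config())  # (10, 0) mm/s
gesture_to_velocity <- function(hand, cfg = control_config()) {
  if (length(hand) != 3 || !all(is.finite(hand)))
    abort("hand must be a finite 3-vector (mm)")
  rho <- sqrt(sum(hand^2))
  if (rho <= cfg$rho0) return(c(0, 0))
  speed <- min(cfg$gain * (rho - cfg$rho0), cfg$max_speed)
  horiz <- hand[1:2]
  hn <- sqrt(sum(horiz^2))
  if (hn == 0) return(c(0, 0))  # purely vertical displacement: no X-Y motion
  speed * horiz / hn
}

#' Advance the stage by one control step
#'
#' Explicit Euler kinematics with silent clamping to the workspace bounds.
#'
#' @param pos_xy current stage position, mm.
#' @param vel_xy commanded velocity, mm/s.
#' @param dt step, s.
#' @param cfg a [control_config()].
#' @return new position `c(x, y)`, mm, inside the workspace.
#' @export
integrate_stage <- function(pos_xy, vel_xy, dt, cfg = control_config()) {
  check_scalar_num(dt, "dt", 0, strict_lower = TRUE)
  p <- pos_xy + vel_xy * dt
  ws <- cfg$workspace
  c(min(max(p[1], ws[1]), ws[2]), min(max(p[2], ws[3]), ws[4]))
}

# --- boundary extraction & area ---------------------------------------------

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area enclosed by a planar path
#'
#' Extracts a compact enclosing boundary of the sampled points and returns
#' its polygon area by the shoelace formula. At `boundary_shrink = 0` the
#' boundary is the convex hull; larger values progressively "dig" long hull
#' edges towards interior points, yielding a tighter concave boundary (a
#' chi-shape-style refinement: an edge longer than a shrink-dependent length
#' threshold is split at the interior point closest to it, provided both new
#' edges are shorter than the edge they replace).
#'
#' @param path two-column matrix or data.frame of planar points (mm); a
#'   data.frame may carry the points in columns `x_mm`/`y_mm` or `x`/`y`.
#' @param boundary_shrink concavity parameter in `[0, 1]` (default 0.5).
#' @return enclosed area, mm^2.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 721)[-721]
#' enclosed_area(cbind(30 * cos(th), 30 * sin(th)))  # ~ pi * 30^2
enclosed_area <- function(path, boundary_shrink = 0.5) {
  pts <- path_points(path)
  check_scalar_num(boundary_shrink, "boundary_shrink", 0, 1)
  pts <- unique(pts)
  if (nrow(pts) < 3) abort("need at least 3 distinct points")
  b <- boundary_indices(pts, boundary_shrink)
  shoelace_area(pts[b, 1], pts[b, 2])
}

path_points <- function(path) {
  if (is.data.frame(path)) {
    cols <- if (all(c("x_mm", "y_mm") %in% names(path))) c("x_mm", "y_mm")
            else c("x", "y")
    if (!all(cols %in% names(path)))
      abort("path data.frame must have columns x_mm/y_mm (or x/y)")
    path <- as.matrix(path[cols])
  }
  if (!is.matrix(path) || ncol(path) != 2 || !is.numeric(path))
    abort("path must be an n x 2 numeric matrix")
  path
}

# Ordered indices of the enclosing boundary polygon.
boundary_indices <- function(pts, shrink) {
  # collinearity check via the rank of centred coordinates
  ctr <- sweep(pts, 2, colMeans(pts))
  if (qr(ctr)$rank < 2) abort("degenerate path: points are collinear")
  hull <- rev(chull(pts))  # counter-clockwise
  if (shrink <= 0) return(hull)

  edge_len <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  hull_lens <- mapply(edge_len, hull, c(hull[-1], hull[1]))
  # nearest-neighbour scale of the sampling
  nn <- mean(vapply(seq_len(min(nrow(pts), 200L)), function(i) {
    d2 <- rowSums(sweep(pts, 2, pts[i, ])^2)
    sqrt(min(d2[d2 > 0]))
  }, numeric(1)))
  threshold <- max((1 - shrink) * max(hull_lens) + shrink * 2 * nn, 2 * nn)

  boundary <- hull
  on_boundary <- rep(FALSE, nrow(pts))
  on_boundary[boundary] <- TRUE
  repeat {
    nxt <- c(boundary[-1], boundary[1])
    lens <- mapply(edge_len, boundary, nxt)
    dug <- FALSE
    for (e in order(lens, decreasing = TRUE)) {
      if (lens[e] <= threshold) break
      i <- boundary[e]; j <- nxt[e]
      cand <- which(!on_boundary)
      if (!length(cand)) break
      di <- sqrt(rowSums(sweep(pts[cand, , drop = FALSE], 2, pts[i, ])^2))
      dj <- sqrt(rowSums(sweep(pts[cand, , drop = FALSE], 2, pts[j, ])^2))
      ok <- di < lens[e] & dj < lens[e]   # both new edges strictly shorter
      if (!any(ok)) next
      cand <- cand[ok]
      p <- cand[which.min((di + dj)[ok])]
      pos <- which(boundary == i)
      boundary <- append(boundary, p, after = pos)
      on_boundary[p] <- TRUE
      dug <- TRUE
      break
    }
    if (!dug) break
  }
  boundary
}

#' Trajectory-tracking error report
#'
#' Compares the area enclosed by a tracked trajectory with the area enclosed
#' by its target: the error rate is the absolute area difference as a
#' percentage of the target area.
#'
#' @param target_path,tracked_path planar paths (see [enclosed_area()]).
#' @param boundary_shrink concavity parameter passed to [enclosed_area()].
#' @return a list with `target_area`, `tracked_area`, `abs_diff` (mm^2) and
#'   `error_rate` (%).
#' @export
trajectory_error <- function(target_path, tracked_path,
                             boundary_shrink = 0.5) {
  ta <- enclosed_area(target_path, boundary_shrink)
  ka <- enclosed_area(tracked_path, boundary_shrink)
  diff <- abs(ka - ta)
  list(target_area = ta, tracked_area = ka, abs_diff = diff,
       error_rate = 100 * diff / ta)
}

#' Generate an ideal target trajectory
#'
#' The characterization targets: a circle of radius `r` or a square of side
#' `s`, sampled at `n` points, centred at `center`.
#'
#' @param kind `"circle"` or `"square"`.
#' @param size radius (circle) or side length (square), mm.
#' @param n number of samples (default 720).
#' @param center centre `c(x, y)`, mm.
#' @return data.frame `t_s`, `x_mm`, `y_mm` (`t_s` is a unit-speed abscissa).
#' @export
target_trajectory <- function(kind = c("circle", "square"), size, n = 720,
                              center = c(50, 50)) {
  kind <- match.arg(kind)
  check_scalar_num(size, "size", 0, strict_lower = TRUE)
  if (n < 4) abort("need at least 4 samples")
  if (kind == "circle") {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    x <- center[1] + size * cos(th)
    y <- center[2] + size * sin(th)
  } else {
    h <- size / 2
    s <- seq(0, 4, length.out = n + 1)[-(n + 1)]  # perimeter parameter
    side <- floor(s)
    f <- s - side
    x <- y <- numeric(n)
    x[side == 0] <- -h + size * f[side == 0]; y[side == 0] <- -h
    x[side == 1] <- h;                        y[side == 1] <- -h + size * f[side == 1]
    x[side == 2] <- h - size * f[side == 2];  y[side == 2] <- h
    x[side == 3] <- -h;                       y[side == 3] <- h - size * f[side == 3]
    x <- center[1] + x
    y <- center[2] + y
  }
  data.frame(t_s = seq(0, 1, length.out = n), x_mm = x, y_mm = y)
}

#' Write / read a planar path as CSV
#'
#' Columns `t_s`, `x_mm`, `y_mm`.
#'
#' @param path data.frame with `t_s`, `x_mm`, `y_mm`.
#' @param file file path.
#' @export
write_path <- function(path, file) {
  write.csv(path[c("t_s", "x_mm", "y_mm")], file, row.names = FALSE,
            quote = FALSE)
  invisible(file)
}

#' @rdname write_path
#' @export
read_path <- function(file) read.csv(file)
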