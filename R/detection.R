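#' Virtual camera traps
#'
#' The field camera's detection zone is an arc sector of radius `r` and
#' central angle `theta`. For fast path intersection it is replaced by
#' the equal-area isosceles triangle with the same apex and apex angle:
#' equal sides of length `s = sqrt(theta * r^2 / sin(theta))`, so that the
#' triangle area `s^2 sin(theta) / 2` equals the sector area
#' `theta r^2 / 2`. With `r = 8` m and `theta = 0.96` rad, `s = 8.66` m
#' and the area is 30.72 m^2.
#'
#' Two capture-counting rules are supported (`capture_rule` in the
#' config). The default `"step"` rule fires once per time step whose
#' movement segment intersects the zone -- the natural count when the
#' camera's recording time equals the step length `dt`, and the rule
#' whose closed-form expectation matches the published density/capture
#' relationship. The `"entry"` rule fires only on outside-to-inside
#' transitions (or a full traversal within one step): consecutive steps
#' inside the zone count once, mirroring the de-duplication of
#' "independent photographs" in field tallies; a later re-entry counts
#' again.
#'
#' @name detection
NULL

.geom_tol <- 1e-9

#' Build a camera detection triangle
#'
#' @param apex length-2 numeric, apex position (m).
#' @param orientation direction of the triangle's bisector, rad.
#' @param r detection radius of the equivalent arc sector, m.
#' @param theta apex (detection) angle, rad; must lie in (0, pi).
#' @return object of class `camera_trap` with fields `apex`,
#'   `orientation`, `r`, `theta`, `side` (equal-side length) and
#'   `vertices` (3 x 2 matrix, counter-clockwise, apex first).
#' @export
#' @examples
#' cam <- build_triangle(c(0, 0), 0, r = 8, theta = 0.96)
#' cam$side          # 8.66 m
#' poly_area(cam$vertices)  # 30.72 m^2 = sector area
build_triangle <- function(apex, orientation, r, theta) {
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  if (theta <= 0 || theta >= pi)
    stop("theta must lie in (0, pi)", call. = FALSE)
  s <- sqrt(theta * r^2 / sin(theta))
  a1 <- orientation - theta / 2
  a2 <- orientation + theta / 2
  v <- rbind(apex,
             apex + s * c(cos(a1), sin(a1)),
             apex + s * c(cos(a2), sin(a2)))
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(apex = apex, orientation = orientation, r = r,
                 theta = theta, side = s, vertices = v,
                 bbox = c(range(v[, 1]), range(v[, 2]))),
            class = "camera_trap")
}

#' @export
print.camera_trap <- function(x, ...) {
  cat("camera_trap: apex (", x$apex[1], ",", x$apex[2], ") m, bisector",
      format(x$orientation, digits = 3), "rad, r =", x$r, "m, theta =",
      x$theta, "rad, side =", format(x$side, digits = 4), "m\n")
  invisible(x)
}

#' Build all cameras of a configuration
#' @param config a `pika_config`.
#' @return list of `camera_trap` objects, one per layout row.
#' @export
make_cameras <- function(config) {
  lay <- config$camera_layout
  lapply(seq_len(nrow(lay)), function(i)
    build_triangle(c(lay$x[i], lay$y[i]), lay$orientation[i],
                   config$r, config$theta))
}

#' Point-in-triangle test
#'
#' Closed-boundary test against a `camera_trap`'s triangle; vectorized
#' over points.
#'
#' @param camera a `camera_trap`.
#' @param x,y point coordinates, m.
#' @return logical vector.
#' @export
point_in_triangle <- function(camera, x, y) {
  v <- camera$vertices
  ok <- rep(TRUE, length(x))
  for (i in 1:3) {
    j <- if (i == 3) 1L else i + 1L
    ex <- v[j, 1] - v[i, 1]; ey <- v[j, 2] - v[i, 2]
    ok <- ok & (ex * (y - v[i, 2]) - ey * (x - v[i, 1]) >= -.geom_tol)
  }
  ok
}

# Vectorized proper/touching intersection of n segments (x0,y0)-(x1,y1)
# with the single segment a-b.
seg_seg_hits <- function(x0, y0, x1, y1, ax, ay, bx, by) {
  d1 <- (bx - ax) * (y0 - ay) - (by - ay) * (x0 - ax)
  d2 <- (bx - ax) * (y1 - ay) - (by - ay) * (x1 - ax)
  d3 <- (x1 - x0) * (ay - y0) - (y1 - y0) * (ax - x0)
  d4 <- (x1 - x0) * (by - y0) - (y1 - y0) * (bx - x0)
  hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
  on_seg <- function(px, py, qx, qy, rx, ry)  # r collinear with p-q: within box?
    rx >= pmin(px, qx) - .geom_tol & rx <= pmax(px, qx) + .geom_tol &
    ry >= pmin(py, qy) - .geom_tol & ry <= pmax(py, qy) + .geom_tol
  hit | (abs(d1) <= .geom_tol & on_seg(ax, ay, bx, by, x0, y0)) |
        (abs(d2) <= .geom_tol & on_seg(ax, ay, bx, by, x1, y1)) |
        (abs(d3) <= .geom_tol & on_seg(x0, y0, x1, y1, ax, ay)) |
        (abs(d4) <= .geom_tol & on_seg(x0, y0, x1, y1, bx, by))
}

# Vectorized closed segment vs closed triangle, with bounding-box
# prefilter (cheap rejection of the vast majority of far-away steps).
seg_tri_hits <- function(camera, x0, y0, x1, y1) {
  bb <- camera$bbox
  cand <- !(pmax(x0, x1) < bb[1] - .geom_tol | pmin(x0, x1) > bb[2] + .geom_tol |
            pmax(y0, y1) < bb[3] - .geom_tol | pmin(y0, y1) > bb[4] + .geom_tol)
  hit <- logical(length(x0))
  idx <- which(cand)
  if (!length(idx)) return(hit)
  cx0 <- x0[idx]; cy0 <- y0[idx]; cx1 <- x1[idx]; cy1 <- y1[idx]
  h <- point_in_triangle(camera, cx0, cy0) | point_in_triangle(camera, cx1, cy1)
  v <- camera$vertices
  for (i in 1:3) {
    if (all(h)) break
    j <- if (i == 3) 1L else i + 1L
    h <- h | seg_seg_hits(cx0, cy0, cx1, cy1,
                          v[i, 1], v[i, 2], v[j, 1], v[j, 2])
  }
  hit[idx] <- h
  hit
}

#' Does a movement segment intersect a camera's detection zone?
#'
#' Closed intersection test: true on endpoint containment, edge crossing
#' or tangency.
#'
#' @param camera a `camera_trap`.
#' @param p0,p1 segment endpoints, length-2 numerics (m).
#' @return logical scalar.
#' @export
segment_hits <- function(camera, p0, p1) {
  seg_tri_hits(camera, p0[1], p0[2], p1[1], p1[2])
}

#' Capture log
#'
#' Per-camera, per-day de-duplicated capture counts `q[i, j]` for camera
#' `i` on day `j`.
#'
#' @param q non-negative integer matrix, cameras x days.
#' @return object of class `capture_log` with fields `q`, `N`, `T`.
#' @export
capture_log <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) < 1 || ncol(q) < 1)
    stop("capture log needs >= 1 camera and >= 1 day", call. = FALSE)
  if (any(q < 0) || any(q != round(q)))
    stop("capture counts must be non-negative integers", call. = FALSE)
  structure(list(q = q, N = nrow(q), T = ncol(q)), class = "capture_log")
}

#' @export
print.capture_log <- function(x, ...) {
  cat("capture_log:", x$N, "cameras x", x$T, "days, total", sum(x$q),
      "captures\n")
  invisible(x)
}

#' Write a capture log as CSV
#'
#' Long format (camera_id, day, count) -- the same schema as simulated
#' and field tallies, so both flow through identical estimation code.
#'
#' @param log a `capture_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_capture_log <- function(log, path) {
  d <- data.frame(camera_id = rep(seq_len(log$N), log$T),
                  day = rep(seq_len(log$T), each = log$N),
                  count = as.vector(log$q))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Count capture events along pika paths
#'
#' Applies the configured capture rule to recorded trajectories. Under
#' `"step"`, a camera fires at every step segment that intersects its
#' zone; under `"entry"`, only when the pika was not already inside the
#' zone at the previous step's end (re-exiting from a burrow resets
#' presence). Steps that wrapped across the toroidal boundary are split
#' into their two real-space pieces before testing, so counts are
#' invariant to seam placement.
#'
#' @param paths list of `pika_path` objects (see [simulate_day()]).
#' @param cameras list of `camera_trap` objects.
#' @param config a `pika_config` (supplies `D_tol` for the log shape).
#' @return a `capture_log` with one row per camera, one column per day.
#' @export
count_captures <- function(paths, cameras, config) {
  N <- length(cameras)
  T_days <- max(config$D_tol, vapply(paths, function(p) p$day, 1L), 1L)
  q <- matrix(0L, N, T_days)
  for (p in paths) {
    seg <- p$segments
    if (is.null(seg) || nrow(seg) == 0) next
    for (ci in seq_len(N)) {
      cam <- cameras[[ci]]
      hit <- seg_tri_hits(cam, seg$x0, seg$y0, seg$x1, seg$y1)
      wrapped <- which((seg$xw != seg$x1 | seg$yw != seg$y1) & !hit)
      if (length(wrapped)) {
        ox <- seg$xw[wrapped] - seg$x1[wrapped]
        oy <- seg$yw[wrapped] - seg$y1[wrapped]
        hit[wrapped] <- seg_tri_hits(cam,
                                     seg$x0[wrapped] + ox, seg$y0[wrapped] + oy,
                                     seg$xw[wrapped], seg$yw[wrapped])
      }
      if (config$capture_rule == "step") {
        events <- sum(hit)
      } else {
        ends_in <- logical(nrow(seg))
        idx <- which(hit)
        if (length(idx))
          ends_in[idx] <- point_in_triangle(cam, seg$xw[idx], seg$yw[idx])
        inside_prev <- FALSE
        events <- 0L
        for (k in seq_len(nrow(seg))) {
          if (seg$new_excursion[k]) inside_prev <- FALSE
          if (hit[k] && !inside_prev) events <- events + 1L
          inside_prev <- ends_in[k]
        }
      }
      q[ci, p$day] <- q[ci, p$day] + events
    }
  }
  capture_log(q)
}
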