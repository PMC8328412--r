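#' Burrow-system landscape generation
#'
#' The landscape model: `n_systems` control points are drawn uniformly in
#' the `[0, L]^2` square and the square is partitioned into Thiessen
#' (Voronoi) cells, one territory per burrow-system family. Each cell
#' receives 9--11 surface entrances (uniform rejection sampling, pairwise
#' spacing >= `l_min`) and a uniform number of resident pikas in
#' `[Q_min, Q_max]`. By the Voronoi property every entrance is closer to
#' its own control point than to any other system's.
#'
#' @name territory
NULL

# Shoelace signed area of a polygon given as a 2-column matrix.
poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (shoelace formula)
#' @param poly 2-column matrix of vertices in order.
#' @return area, m^2.
#' @export
poly_area <- function(poly) abs(poly_signed_area(poly))

# Clip a convex polygon (CCW, 2-col matrix) by the half-plane
# { p : (p - m) . n <= 0 } with unit normal n. Sutherland-Hodgman.
clip_halfplane <- function(poly, nx, ny, mx, my, tol = 1e-9) {
  k <- nrow(poly)
  d <- (poly[, 1] - mx) * nx + (poly[, 2] - my) * ny
  inside <- d <= tol
  if (all(inside)) return(poly)
  ox <- numeric(2 * k); oy <- numeric(2 * k); m <- 0L
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L; ox[m] <- poly[i, 1]; oy[m] <- poly[i, 2]
    }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      ox[m] <- poly[i, 1] + t * (poly[j, 1] - poly[i, 1])
      oy[m] <- poly[i, 2] + t * (poly[j, 2] - poly[i, 2])
    }
  }
  cbind(x = ox[seq_len(m)], y = oy[seq_len(m)])
}

#' Bounded Voronoi (Thiessen) tessellation of a square
#'
#' Each cell is computed as the intersection of the bounding square with
#' the perpendicular-bisector half-planes against other sites, taken in
#' order of increasing distance with an exact security-radius stop: once
#' the next site is farther than twice the current cell's maximal vertex
#' distance from the generator, no remaining site can cut the cell.
#' Unbounded Voronoi cells are thereby clipped to the square.
#'
#' @param points 2-column matrix/data.frame of sites, all inside the square.
#' @param L side length of the `[0, L]^2` bounding square.
#' @return list of cells (2-column CCW vertex matrices), one per site, in
#'   input order. Cell areas sum to `L^2`.
#' @export
#' @examples
#' cells <- bounded_voronoi(cbind(c(2, 8), c(5, 5)), L = 10)
#' sum(vapply(cells, poly_area, 1))  # 100
bounded_voronoi <- function(points, L) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must have two columns", call. = FALSE)
  n <- nrow(pts)
  if (n < 1) stop("need at least one point", call. = FALSE)
  if (any(pts < 0) || any(pts > L))
    stop("all points must lie inside [0, L]^2", call. = FALSE)
  if (anyDuplicated(round(pts, 12)))
    stop("duplicate points: tessellation is degenerate", call. = FALSE)
  square <- cbind(x = c(0, L, L, 0), y = c(0, 0, L, L))
  if (n == 1) return(list(square))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    px <- pts[i, 1]; py <- pts[i, 2]
    d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    ord <- order(d2)
    ord <- ord[ord != i]
    cell <- square
    rmax2 <- max((cell[, 1] - px)^2 + (cell[, 2] - py)^2)
    for (j in ord) {
      if (d2[j] > 4 * rmax2) break  # security radius: bisector cannot reach
      dn <- sqrt(d2[j])
      nx <- (pts[j, 1] - px) / dn; ny <- (pts[j, 2] - py) / dn
      cell <- clip_halfplane(cell, nx, ny, (px + pts[j, 1]) / 2,
                             (py + pts[j, 2]) / 2)
      rmax2 <- max((cell[, 1] - px)^2 + (cell[, 2] - py)^2)
    }
    cells[[i]] <- cell
  }
  cells
}

# Vectorized point-in-convex-polygon test (closed; tolerance in meters).
# Polygon must be CCW, as produced by bounded_voronoi().
in_convex_poly <- function(poly, x, y, tol = 1e-9) {
  ok <- rep(TRUE, length(x))
  k <- nrow(poly)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    ok <- ok & (ex * (y - poly[i, 2]) - ey * (x - poly[i, 1]) >= -tol)
  }
  ok
}

#' Sample burrow-system control points
#'
#' Sequential inhibition (hard-core) sampling: uniform candidates in the
#' square are accepted when at least `l_sys` from every accepted point.
#' The hard core guarantees each Voronoi cell contains a disc of radius
#' `l_sys / 2`, keeping every territory large enough for its entrances;
#' `l_sys = 0` recovers pure uniform sampling (duplicates rejected).
#' Uses the current RNG state.
#'
#' @param n number of points.
#' @param L square side length, m.
#' @param l_sys hard-core distance, m.
#' @param max_attempts cap on candidate draws.
#' @return an `n` x 2 matrix of coordinates.
#' @export
sample_control_points <- function(n, L, l_sys = 0, max_attempts = 1000 * n) {
  px <- numeric(n); py <- numeric(n); got <- 0L; attempts <- 0L
  min2 <- max(l_sys^2, .Machine$double.xmin)  # exact duplicates always rejected
  chunk <- max(64L, n)
  while (got < n) {
    if (attempts >= max_attempts)
      stop("control-point sampling infeasible: ", got, " of ", n,
           " points placed after ", max_attempts, " attempts (l_sys = ",
           l_sys, " m)", call. = FALSE)
    m <- min(chunk, max_attempts - attempts)
    cx <- stats::runif(m, 0, L); cy <- stats::runif(m, 0, L)
    attempts <- attempts + m
    for (t in seq_len(m)) {
      if (got > 0L &&
          min((px[seq_len(got)] - cx[t])^2 + (py[seq_len(got)] - cy[t])^2) < min2)
        next
      got <- got + 1L
      px[got] <- cx[t]; py[got] <- cy[t]
      if (got == n) break
    }
  }
  cbind(px, py)
}

#' Place burrow entrances inside a territory cell
#'
#' Sequential dart throwing: candidates are drawn uniformly in the cell
#' (via its bounding box) and accepted when at least `l_min` from every
#' previously accepted entrance. The entrance count is drawn uniformly
#' from `{H_min, ..., H_max}`. Uses the current RNG state; seed upstream.
#'
#' @param cell convex polygon (2-column CCW matrix).
#' @param H_min,H_max entrance count range.
#' @param l_min minimum pairwise spacing, m.
#' @param max_attempts cap on candidate draws before declaring the cell
#'   infeasible (never silently relaxes `l_min`).
#' @return 2-column matrix of entrance coordinates.
#' @export
place_entrances <- function(cell, H_min, H_max, l_min, max_attempts = 10000) {
  if (nrow(cell) < 3 || poly_area(cell) <= 0)
    stop("degenerate cell: cannot place entrances", call. = FALSE)
  H <- H_min + sample.int(H_max - H_min + 1L, 1L) - 1L
  xr <- range(cell[, 1]); yr <- range(cell[, 2])
  ex <- numeric(H); ey <- numeric(H); got <- 0L
  attempts <- 0L
  chunk <- 64L
  while (got < H) {
    if (attempts >= max_attempts)
      stop("entrance placement infeasible after ", max_attempts,
           " attempts in cell with area ", signif(poly_area(cell), 4),
           " m^2 (H = ", H, ", l_min = ", l_min, ")", call. = FALSE)
    m <- min(chunk, max_attempts - attempts)
    cx <- stats::runif(m, xr[1], xr[2])
    cy <- stats::runif(m, yr[1], yr[2])
    attempts <- attempts + m
    ok <- in_convex_poly(cell, cx, cy)
    for (t in which(ok)) {
      if (got > 0L) {
        d2 <- (ex[seq_len(got)] - cx[t])^2 + (ey[seq_len(got)] - cy[t])^2
        if (min(d2) < l_min^2) next
      }
      got <- got + 1L
      ex[got] <- cx[t]; ey[got] <- cy[t]
      if (got == H) break
    }
  }
  cbind(x = ex, y = ey)
}

#' Allocate pikas to burrow systems
#'
#' Independent uniform draws on `{Q_min, ..., Q_max}`, one per system.
#' Uses the current RNG state.
#'
#' @param n_systems number of systems.
#' @param Q_min,Q_max occupant count range.
#' @return integer vector of occupant counts.
#' @export
allocate_pikas <- function(n_systems, Q_min, Q_max) {
  if (Q_min > Q_max) stop("need Q_min <= Q_max", call. = FALSE)
  as.integer(Q_min + sample.int(Q_max - Q_min + 1L, n_systems,
                                replace = TRUE) - 1L)
}

#' Generate a burrow-system landscape
#'
#' Full territory pipeline: uniform control points, bounded Voronoi
#' tessellation, per-cell entrance placement, pika allocation. Each stage
#' runs under a named child seed of `seed` (one per system for entrance
#' placement), so regeneration is reproducible and order-independent.
#'
#' @param config a `pika_config`.
#' @param seed root seed; defaults to `config$seed`.
#' @return an object of class `pika_landscape`: list with `L`,
#'   `systems` (data.frame: id, cx, cy, n_pikas, n_entrances),
#'   `entrances` (data.frame: system_id, x, y), `cells` (list of vertex
#'   matrices) and `true_density` (pikas per hectare).
#' @export
#' @examples
#' ls <- generate_landscape(sim_config(L = 200, n_systems = 25, seed = 7))
#' ls$true_density
generate_landscape <- function(config, seed = config$seed) {
  n <- config$n_systems; L <- config$L
  pts <- with_child_seed(derive_seed(seed, "control-points"),
                         sample_control_points(n, L, config$l_sys))
  cells <- bounded_voronoi(pts, L)
  ents <- vector("list", n)
  for (i in seq_len(n)) {
    ents[[i]] <- with_child_seed(derive_seed(seed, paste0("system-", i)),
      place_entrances(cells[[i]], config$H_min, config$H_max, config$l_min))
  }
  n_ent <- vapply(ents, nrow, integer(1))
  q <- with_child_seed(derive_seed(seed, "pikas"),
                       allocate_pikas(n, config$Q_min, config$Q_max))
  structure(list(
    L = L,
    systems = data.frame(id = seq_len(n), cx = pts[, 1], cy = pts[, 2],
                         n_pikas = q, n_entrances = n_ent),
    entrances = data.frame(system_id = rep(seq_len(n), n_ent),
                           x = unlist(lapply(ents, function(e) e[, 1])),
                           y = unlist(lapply(ents, function(e) e[, 2]))),
    cells = cells,
    true_density = sum(q) / (L^2 / 1e4)
  ), class = "pika_landscape")
}

#' @export
print.pika_landscape <- function(x, ...) {
  cat("pika_landscape:", x$L, "m square,", nrow(x$systems), "burrow systems,",
      sum(x$systems$n_pikas), "pikas (", format(x$true_density, digits = 4),
      "per ha )\n")
  invisible(x)
}

#' Export / import a landscape as CSV tables
#'
#' Writes `systems.csv` (id, cx, cy, n_pikas), `entrances.csv`
#' (system_id, x, y) and `cells.csv` (system_id, vertex_index, x, y) into
#' `dir`. Coordinates are meters with the origin at the bottom-left
#' corner, y increasing upward. `read_landscape()` is the inverse.
#'
#' @param landscape a `pika_landscape`.
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(landscape$systems[c("id", "cx", "cy", "n_pikas")],
                   file.path(dir, "systems.csv"), row.names = FALSE)
  utils::write.csv(landscape$entrances, file.path(dir, "entrances.csv"),
                   row.names = FALSE)
  cells <- do.call(rbind, lapply(seq_along(landscape$cells), function(i) {
    v <- landscape$cells[[i]]
    data.frame(system_id = i, vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2])
  }))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_landscape
#' @param L side length of the original square, m.
#' @export
read_landscape <- function(dir, L) {
  systems <- utils::read.csv(file.path(dir, "systems.csv"))
  entrances <- utils::read.csv(file.path(dir, "entrances.csv"))
  cells_df <- utils::read.csv(file.path(dir, "cells.csv"))
  cells <- lapply(split(cells_df, cells_df$system_id), function(d) {
    d <- d[order(d$vertex_index), ]
    cbind(x = d$x, y = d$y)
  })
  cells <- cells[order(as.integer(names(cells)))]
  names(cells) <- NULL
  n_ent <- tabulate(entrances$system_id, nbins = nrow(systems))
  systems$n_entrances <- n_ent
  structure(list(L = L, systems = systems, entrances = entrances,
                 cells = cells,
                 true_density = sum(systems$n_pikas) / (L^2 / 1e4)),
            class = "pika_landscape")
}
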