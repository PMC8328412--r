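# Shared fixtures: everything is generated in code at test time.

config_with <- function(defaults, over) {
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

# Small but non-trivial world: ~300 pikas on a 200 m square.
small_config <- function(...) {
  config_with(list(L = 200, n_systems = 60, D_tol = 2, seed = 101), list(...))
}

# Minimal world for determinism / pipeline-shape tests.
tiny_config <- function(...) {
  config_with(list(L = 150, n_systems = 30, D_tol = 2, t_tol = 5, seed = 11),
              list(...))
}

# Brute-force nearest-site index (oracle for the Voronoi property).
nearest_site <- function(px, py, sites) {
  max.col(-((outer(px, sites[, 1], "-"))^2 + (outer(py, sites[, 2], "-"))^2))
}

# Dense-sampling oracle for segment/triangle intersection: point-in-triangle
# membership of many evenly spaced points along the segment.
dense_segment_hit <- function(camera, p0, p1, n = 1000) {
  t <- seq(0, 1, length.out = n)
  any(point_in_triangle(camera,
                        p0[1] + t * (p1[1] - p0[1]),
                        p0[2] + t * (p1[2] - p0[2])))
}

# Hand-built path object for detection tests (unwrapped segments).
make_path <- function(xs, ys, day = 1L, new_excursion = NULL) {
  n <- length(xs) - 1
  seg <- data.frame(pika = 1L, step = seq_len(n),
                    x0 = xs[-length(xs)], y0 = ys[-length(ys)],
                    x1 = xs[-1], y1 = ys[-1],
                    xw = xs[-1], yw = ys[-1],
                    s = sqrt(diff(xs)^2 + diff(ys)^2),
                    intensity = "low",
                    new_excursion = new_excursion %||% c(TRUE, rep(FALSE, n - 1)),
                    returned = FALSE)
  structure(list(pika_id = 1L, day = day, segments = seg,
                 excursions = sum(seg$new_excursion),
                 total_distance = sum(seg$s)),
            class = "pika_path")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
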