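#' Pika ground movement
#'
#' Daily activity model: every pika starts the day in its burrow and
#' spends a total ground-time budget `t_tol` in discrete steps of length
#' `dt`. An excursion begins at a uniformly chosen entrance of the pika's
#' own system. Each step draws an intensity (high with probability
#' `p_high`), a Gaussian speed (`N(v_large, sigma_large)` or
#' `N(v_small, sigma_small)` m/min, truncated at 0), and a uniform
#' heading on `[0, 2*pi)`; the displacement `s_t = min(v_t * dt, d_max)`
#' is applied and the position wrapped torus-style into `[0, L)^2`. When
#' the pika ends a step strictly closer than `l_home` to one of its own
#' entrances it re-enters the burrow; with budget remaining it starts the
#' next excursion from a fresh random entrance on the next step. Only
#' outside time consumes budget, so a pika takes exactly
#' `floor(t_tol / dt)` movement steps per day.
#'
#' @name movement
NULL

#' Toroidal wrap of coordinates into `[0, L)`
#' @param position numeric vector or matrix of coordinates, m.
#' @param L area side length, m.
#' @return wrapped coordinates.
#' @export
#' @examples
#' wrap(c(1001, -1), 1000)  # 1, 999
wrap <- function(position, L) position %% L

#' Draw movement speeds for one intensity class
#'
#' Gaussian draw with the class mean/sd, truncated at 0 (at the default
#' parameters the truncation probability is Phi(-10), i.e. negligible).
#' Uses the current RNG state.
#'
#' @param n number of draws.
#' @param intensity `"high"` or `"low"`.
#' @param config a `pika_config`.
#' @return numeric vector of speeds, m/min.
#' @export
sample_speed <- function(n, intensity = c("high", "low"), config) {
  intensity <- match.arg(intensity)
  v <- if (intensity == "high")
    stats::rnorm(n, config$v_large, config$sigma_large)
  else
    stats::rnorm(n, config$v_small, config$sigma_small)
  pmax(v, 0)
}

#' Advance a single pika state by one step
#'
#' Reference scalar implementation of the position update
#' `x_t = x_{t-1} + s_t cos(phi)`, `y_t = y_{t-1} + s_t sin(phi)` with
#' uniform heading, used for contract checks; the simulation engine
#' applies the same update vectorized. Uses the current RNG state.
#'
#' @param state list with at least `position` (length-2, m), `status`
#'   (`"inside"`/`"outside"`), `budget_remaining` (min), `cum_distance` (m).
#' @param config a `pika_config`.
#' @return the updated state; adds `heading`, `step_distance`,
#'   `intensity`, and the pre-wrap position `position_raw`.
#' @export
advance <- function(state, config) {
  if (!identical(state$status, "outside"))
    stop("advance() requires status == 'outside'", call. = FALSE)
  if (state$budget_remaining <= 0)
    stop("advance() requires budget_remaining > 0", call. = FALSE)
  intensity <- if (stats::runif(1) < config$p_high) "high" else "low"
  s <- min(sample_speed(1, intensity, config) * config$dt, config$d_max)
  phi <- stats::runif(1, 0, 2 * pi)
  raw <- state$position + s * c(cos(phi), sin(phi))
  state$position_raw <- raw
  state$position <- wrap(raw, config$L)
  state$heading <- phi
  state$intensity <- intensity
  state$step_distance <- s
  state$cum_distance <- (state$cum_distance %||% 0) + s
  state$budget_remaining <- state$budget_remaining - config$dt
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Has the pika returned to its burrow?
#'
#' Strict comparison: true iff the minimum distance from `position` to
#' any entrance of the pika's own system is `< l_home`.
#'
#' @param position length-2 numeric, m.
#' @param entrances 2-column matrix/data.frame of own-system entrances, m.
#' @param l_home return threshold, m.
#' @return logical scalar.
#' @export
check_return <- function(position, entrances, l_home) {
  e <- as.matrix(entrances)
  if (nrow(e) == 0) stop("entrances must be non-empty", call. = FALSE)
  min((e[, 1] - position[1])^2 + (e[, 2] - position[2])^2) < l_home^2
}

# Padded per-system entrance coordinate matrices (n_systems x H_max),
# Inf-padded so column-wise pmin over squared distances is exact.
entrance_matrices <- function(landscape) {
  ent <- landscape$entrances
  ord <- order(ent$system_id)
  ent <- ent[ord, ]
  h <- tabulate(ent$system_id, nbins = nrow(landscape$systems))
  Hmax <- max(h)
  Ex <- matrix(Inf, nrow(landscape$systems), Hmax)
  Ey <- Ex
  idx <- cbind(ent$system_id, sequence(h))
  Ex[idx] <- ent$x
  Ey[idx] <- ent$y
  list(Ex = Ex, Ey = Ey, h = h)
}

#' Simulate one day of ground activity for a pika population
#'
#' Vectorized engine: all pikas advance in lockstep through the
#' `floor(t_tol / dt)` steps of the daily budget, with excursion restarts,
#' toroidal wrapping, and (optionally) camera capture counting under the
#' entry-event rule, including the split of wrapped steps into their two
#' real-space pieces. Uses the current RNG state; seed upstream (e.g. via
#' a `"day-j"` child seed).
#'
#' @param landscape a `pika_landscape`.
#' @param config a `pika_config`.
#' @param cameras optional list of `camera_trap`s; `NULL` skips detection.
#' @param record if `TRUE`, return the full per-step trajectory table
#'   (only sensible for small populations).
#' @param pika_systems optional integer vector giving each simulated
#'   pika's system id; defaults to the landscape's allocation.
#' @return list with `distances` (per-pika total daily distance, m), `q`
#'   (per-camera event counts for the day), `n_pikas`, and, if recording,
#'   `steps` (data.frame: pika, step, x0, y0, x1, y1 raw, xw, yw wrapped,
#'   s, intensity, new_excursion, returned).
#' @export
simulate_population_day <- function(landscape, config, cameras = NULL,
                                    record = FALSE, pika_systems = NULL) {
  if (is.null(pika_systems))
    pika_systems <- rep(landscape$systems$id, landscape$systems$n_pikas)
  n <- length(pika_systems)
  ncam <- length(cameras)
  n_steps <- as.integer(floor(config$t_tol / config$dt + 1e-9))
  empty <- list(distances = numeric(n), q = integer(ncam), n_pikas = n,
                steps = if (record) data.frame())
  if (n == 0L || n_steps == 0L) return(empty)

  L <- config$L; dt <- config$dt
  em <- entrance_matrices(landscape)
  PEx <- em$Ex[pika_systems, , drop = FALSE]
  PEy <- em$Ey[pika_systems, , drop = FALSE]
  h_p <- em$h[pika_systems]
  if (any(h_p == 0)) stop("every simulated pika needs >= 1 entrance", call. = FALSE)
  Hmax <- ncol(PEx)

  x <- numeric(n); y <- numeric(n)
  needs_exit <- rep(TRUE, n)
  inside <- if (ncam) matrix(FALSE, n, ncam)
  q <- integer(ncam)
  dist_tot <- numeric(n)
  rec <- if (record) vector("list", n_steps)
  l_home2 <- config$l_home^2

  for (step in seq_len(n_steps)) {
    new_exc <- needs_exit
    ne <- which(needs_exit)
    if (length(ne)) {
      j <- pmin(1L + as.integer(floor(stats::runif(length(ne)) * h_p[ne])),
                h_p[ne])
      x[ne] <- PEx[cbind(ne, j)]
      y[ne] <- PEy[cbind(ne, j)]
      if (ncam) inside[ne, ] <- FALSE
    }
    hi <- stats::runif(n) < config$p_high
    spd <- numeric(n)
    nh <- sum(hi)
    spd[hi] <- stats::rnorm(nh, config$v_large, config$sigma_large)
    spd[!hi] <- stats::rnorm(n - nh, config$v_small, config$sigma_small)
    spd[spd < 0] <- 0
    s <- pmin(spd * dt, config$d_max)
    phi <- stats::runif(n, 0, 2 * pi)
    x1 <- x + s * cos(phi)
    y1 <- y + s * sin(phi)
    xw <- x1 %% L
    yw <- y1 %% L
    wrapped <- (xw != x1) | (yw != y1)

    if (ncam) {
      for (ci in seq_len(ncam)) {
        cam <- cameras[[ci]]
        hit <- seg_tri_hits(cam, x, y, x1, y1)
        if (any(wrapped)) {
          w <- which(wrapped & !hit)
          if (length(w)) {
            ox <- xw[w] - x1[w]; oy <- yw[w] - y1[w]
            hit[w] <- seg_tri_hits(cam, x[w] + ox, y[w] + oy, xw[w], yw[w])
          }
        }
        q[ci] <- q[ci] + if (config$capture_rule == "step") sum(hit)
                         else sum(hit & !inside[, ci])
        ends_in <- logical(n)
        idx <- which(hit)
        if (length(idx))
          ends_in[idx] <- point_in_triangle(cam, xw[idx], yw[idx])
        inside[, ci] <- ends_in
      }
    }

    d2 <- (PEx[, 1] - xw)^2 + (PEy[, 1] - yw)^2
    if (Hmax > 1) for (k in 2:Hmax)
      d2 <- pmin(d2, (PEx[, k] - xw)^2 + (PEy[, k] - yw)^2)
    returned <- d2 < l_home2
    dist_tot <- dist_tot + s

    if (record)
      rec[[step]] <- data.frame(pika = seq_len(n), step = step,
                                x0 = x, y0 = y, x1 = x1, y1 = y1,
                                xw = xw, yw = yw, s = s,
                                intensity = ifelse(hi, "high", "low"),
                                new_excursion = new_exc, returned = returned)
    x <- xw; y <- yw
    needs_exit <- returned
  }
  list(distances = dist_tot, q = q, n_pikas = n,
       steps = if (record) do.call(rbind, rec))
}

#' Simulate one pika's day and return its path
#'
#' Runs the movement engine for a single pika with trajectory recording
#' and packages the result as a `pika_path`.
#'
#' @param pika_id id used to label the path.
#' @param system_id the pika's burrow system (row of `landscape$systems`).
#' @param landscape a `pika_landscape`.
#' @param config a `pika_config`.
#' @param day day index stored on the path.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return object of class `pika_path`: `pika_id`, `day`, `segments`
#'   (per-step table as in [simulate_population_day()]), `excursions`
#'   (count of excursion starts) and `total_distance` (m, pre-wrap
#'   displacement sum).
#' @export
simulate_day <- function(pika_id, system_id, landscape, config, day = 1L,
                         seed = NULL) {
  run <- function() simulate_population_day(landscape, config, cameras = NULL,
                                            record = TRUE,
                                            pika_systems = system_id)
  res <- if (is.null(seed)) run() else with_child_seed(seed, run())
  seg <- res$steps
  structure(list(pika_id = pika_id, day = as.integer(day), segments = seg,
                 excursions = if (nrow(seg)) sum(seg$new_excursion) else 0L,
                 total_distance = res$distances[1]),
            class = "pika_path")
}

#' @export
print.pika_path <- function(x, ...) {
  cat("pika_path: pika", x$pika_id, "day", x$day, "-",
      nrow(x$segments), "steps,", x$excursions, "excursions,",
      format(x$total_distance, digits = 4), "m\n")
  invisible(x)
}

#' Split an engine trajectory table into per-pika paths
#'
#' Converts the `steps` table of a recorded
#' [simulate_population_day()] run into a list of `pika_path` objects
#' (e.g. to feed [count_captures()]).
#'
#' @param steps recorded step table.
#' @param day day index for all paths.
#' @return list of `pika_path` objects.
#' @export
as_pika_paths <- function(steps, day = 1L) {
  lapply(split(steps, steps$pika), function(seg) {
    seg <- seg[order(seg$step), ]
    structure(list(pika_id = seg$pika[1], day = as.integer(day),
                   segments = seg, excursions = sum(seg$new_excursion),
                   total_distance = sum(seg$s)),
              class = "pika_path")
  })
}

#' Dump per-pika paths as a CSV of positions
#'
#' Long format (pika_id, day, t, x, y, intensity) for plotting daily
#' movement tracks. `t` is minutes since the day's first step.
#'
#' @param paths list of `pika_path` objects.
#' @param path output CSV file.
#' @param config a `pika_config` (supplies `dt`).
#' @return `path`, invisibly.
#' @export
write_paths <- function(paths, path, config) {
  rows <- lapply(paths, function(p) {
    s <- p$segments
    if (!nrow(s)) return(NULL)
    data.frame(pika_id = p$pika_id, day = p$day, t = s$step * config$dt,
               x = s$xw, y = s$yw, intensity = s$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
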