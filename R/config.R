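#' Simulation configuration
#'
#' Builds and validates the full parameter set of the pika activity
#' simulator. Defaults are the published baseline: a 1,000 m square holding
#' 2,500 burrow systems, each with 9--11 surface entrances at >= 2 m
#' spacing and 4--6 resident pikas; a daily ground-activity budget of
#' 20 min spent in 0.5 min steps; two-intensity Gaussian movement speeds
#' (high: N(20, 2) m/min, low: N(2, 0.2) m/min, each step high with
#' probability `p_high`); a 1 m return-to-burrow threshold; and six
#' cameras whose detection zone is the isosceles triangle equivalent in
#' area to an 8 m / 0.96 rad arc sector.
#'
#' @param L side length of the square simulation area, m.
#' @param n_systems number of burrow systems (Voronoi control points).
#' @param t_tol daily ground (outside-burrow) activity time per pika, min.
#' @param D_tol number of simulated days.
#' @param l_min minimum spacing between entrances of one system, m.
#' @param l_sys hard-core minimum spacing between burrow-system control
#'   points, m. Guarantees every territory cell contains a disc of radius
#'   `l_sys / 2`, so entrance placement is always feasible; family
#'   territory centers never coincide in the field.
#' @param H_min,H_max entrance count range per system.
#' @param Q_min,Q_max pika count range per system.
#' @param dt time step, min.
#' @param d_max cap on per-step displacement, m.
#' @param v_large,sigma_large high-intensity speed mean / sd, m/min.
#' @param v_small,sigma_small low-intensity speed mean / sd, m/min.
#' @param l_home return-to-burrow distance threshold, m (strict `<`).
#' @param r camera detection radius, m.
#' @param theta camera detection angle, rad (must lie in (0, pi)).
#' @param n_cameras number of virtual cameras.
#' @param camera_layout data.frame with columns `x`, `y`, `orientation`
#'   (apex position, m; bisector direction, rad). `NULL` uses
#'   [default_camera_layout()] with orientations drawn from `seed`.
#' @param p_high probability that a movement step is high-intensity.
#' @param capture_rule how a camera counts: `"step"` (default; one shot
#'   per time step whose movement segment intersects the zone, matching a
#'   trigger whose recording time equals the step length) or `"entry"`
#'   (one shot per outside-to-inside transition or full traversal, the
#'   field de-duplication analogue). See the methods vignette for the
#'   measured sensitivity of lambda to this choice.
#' @param seed root RNG seed; all child streams are derived from it.
#' @return an object of class `pika_config` (a validated named list).
#' @seealso [load_config()], [generate_landscape()], [run_trial()]
#' @export
#' @examples
#' cfg <- sim_config(L = 250, n_systems = 100, seed = 1)
#' cfg$t_tol
sim_config <- function(L = 1000, n_systems = 2500, t_tol = 20, D_tol = 4,
                       l_min = 2, l_sys = 10, H_min = 9, H_max = 11,
                       Q_min = 4, Q_max = 6,
                       dt = 0.5, d_max = 30,
                       v_large = 20, sigma_large = 2,
                       v_small = 2, sigma_small = 0.2,
                       l_home = 1, r = 8, theta = 0.96,
                       n_cameras = 6, camera_layout = NULL,
                       p_high = 0.5, capture_rule = c("step", "entry"),
                       seed = 1L) {
  capture_rule <- match.arg(capture_rule)
  cfg <- list(L = L, n_systems = as.integer(n_systems), t_tol = t_tol,
              D_tol = as.integer(D_tol), l_min = l_min, l_sys = l_sys,
              H_min = as.integer(H_min), H_max = as.integer(H_max),
              Q_min = as.integer(Q_min), Q_max = as.integer(Q_max),
              dt = dt, d_max = d_max,
              v_large = v_large, sigma_large = sigma_large,
              v_small = v_small, sigma_small = sigma_small,
              l_home = l_home, r = r, theta = theta,
              n_cameras = as.integer(n_cameras),
              camera_layout = camera_layout,
              p_high = p_high, capture_rule = capture_rule,
              seed = as.integer(seed))
  if (is.null(cfg$camera_layout)) {
    cfg$camera_layout <- default_camera_layout(L, cfg$n_cameras,
                                               derive_seed(cfg$seed, "cameras"))
  }
  class(cfg) <- "pika_config"
  validate_config(cfg)
  cfg
}

#' @export
print.pika_config <- function(x, ...) {
  cat("pika_config:", x$L, "m square,", x$n_systems, "burrow systems\n")
  cat("  activity: t_tol =", x$t_tol, "min in dt =", x$dt,
      "min steps over", x$D_tol, "days\n")
  cat("  speeds: high N(", x$v_large, ",", x$sigma_large, "), low N(",
      x$v_small, ",", x$sigma_small, ") m/min, p_high =", x$p_high, "\n")
  cat("  cameras:", x$n_cameras, "( r =", x$r, "m, theta =", x$theta,
      "rad ), rule =", x$capture_rule, ", seed =", x$seed, "\n")
  invisible(x)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!isTRUE(ok)) stop("invalid config key '", key, "': ", msg, call. = FALSE)
  }
  pos <- c("L", "dt", "d_max", "l_home", "r", "l_min", "l_sys",
           "v_large", "v_small")
  for (k in pos) chk(is.numeric(cfg[[k]]) && cfg[[k]] > 0, k, "must be > 0")
  for (k in c("sigma_large", "sigma_small", "t_tol"))
    chk(is.numeric(cfg[[k]]) && cfg[[k]] >= 0, k, "must be >= 0")
  chk(cfg$n_systems >= 1, "n_systems", "must be >= 1")
  chk(cfg$D_tol >= 1, "D_tol", "must be >= 1")
  chk(cfg$H_min >= 1 && cfg$H_min <= cfg$H_max, "H_min", "need 1 <= H_min <= H_max")
  chk(cfg$Q_min >= 0 && cfg$Q_min <= cfg$Q_max, "Q_min", "need 0 <= Q_min <= Q_max")
  chk(cfg$p_high >= 0 && cfg$p_high <= 1, "p_high", "must lie in [0, 1]")
  chk(cfg$capture_rule %in% c("step", "entry"), "capture_rule",
      "must be 'step' or 'entry'")
  chk(cfg$theta > 0 && cfg$theta < pi, "theta",
      "must lie in (0, pi) for a valid triangle zone")
  chk(cfg$t_tol == 0 || cfg$dt <= cfg$t_tol, "dt",
      "time step must not exceed t_tol")
  lay <- cfg$camera_layout
  chk(is.data.frame(lay) && all(c("x", "y", "orientation") %in% names(lay)),
      "camera_layout", "need data.frame with columns x, y, orientation")
  chk(nrow(lay) == cfg$n_cameras, "camera_layout",
      "row count must equal n_cameras")
  chk(all(lay$x >= 0 & lay$x <= cfg$L & lay$y >= 0 & lay$y <= cfg$L),
      "camera_layout", "camera apexes must lie inside the area")
  invisible(cfg)
}

#' Default camera layout
#'
#' Six apexes on a 2 x 3 grid at 1/4 and 3/4 of `L` horizontally and
#' 1/4, 1/2, 3/4 vertically (recycled for other `n_cameras`), with
#' orientations drawn uniformly on `[0, 2*pi)` from `seed`.
#'
#' @param L area side length, m.
#' @param n_cameras number of cameras.
#' @param seed integer seed for the orientation draws.
#' @return data.frame with columns `x`, `y`, `orientation`.
#' @export
default_camera_layout <- function(L, n_cameras = 6, seed = 1L) {
  gx <- c(1, 3, 1, 3, 1, 3) / 4
  gy <- c(1, 1, 2, 2, 3, 3) / 4
  i <- ((seq_len(n_cameras) - 1L) %% 6L) + 1L
  ori <- with_child_seed(seed, stats::runif(n_cameras, 0, 2 * pi))
  data.frame(x = gx[i] * L, y = gy[i] * L, orientation = ori)
}

# -- reproducibility plumbing -------------------------------------------------

#' Derive a child seed from a root seed and a stream tag
#'
#' Deterministic 31-based string hash folded modulo 2^31 - 1. All
#' randomness in the package flows from one root seed through named child
#' streams (e.g. `"control-points"`, `"system-17"`, `"day-3"`), so results
#' are reproducible and per-system generation is order-independent.
#'
#' @param root integer root seed.
#' @param tag character (or coercible) stream label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, tag) {
  h <- as.double(as.integer(root) %% 2147483647)
  for (k in utf8ToInt(paste(as.character(tag), collapse = "/")))
    h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so named child streams never disturb surrounding code.
#'
#' @param seed integer seed (typically from [derive_seed()]).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_child_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Run manifest
#'
#' Snapshot of everything needed to reproduce a run bit-identically: the
#' config, the root seed, the named child seeds actually used, the package
#' version and a timestamp.
#'
#' @param config a `pika_config`.
#' @param seed root seed of the run.
#' @return a list of class `pika_manifest`.
#' @export
run_manifest <- function(config, seed = config$seed) {
  streams <- c("cameras", "control-points", "pikas",
               paste0("day-", seq_len(config$D_tol)))
  list(config = unclass(config),
       root_seed = as.integer(seed),
       child_seeds = stats::setNames(
         vapply(streams, function(s) derive_seed(seed, s), integer(1)), streams),
       version = as.character(utils::packageVersion("pikarem")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) |>
    structure(class = "pika_manifest")
}

#' Write a run manifest as JSON
#' @param manifest a `pika_manifest`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

# -- flat key = value config files -------------------------------------------

#' Read a simulation configuration file
#'
#' Flat `key = value` text (TOML-like scalars, `#` comments). Unspecified
#' keys take the package defaults; unknown keys and invariant violations
#' raise errors naming the offending key. The camera layout may be given
#' as comma-separated `camera_x`, `camera_y`, `camera_orientation` lists.
#'
#' @param path file path; an empty file yields the full default config.
#' @return a `pika_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'", call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  scalar_keys <- c("L", "n_systems", "t_tol", "D_tol", "l_min", "l_sys", "H_min",
                   "H_max", "Q_min", "Q_max", "dt", "d_max", "v_large",
                   "sigma_large", "v_small", "sigma_small", "l_home", "r",
                   "theta", "n_cameras", "p_high", "seed")
  cam_keys <- c("camera_x", "camera_y", "camera_orientation")
  string_keys <- "capture_rule"
  unknown <- setdiff(names(kv), c(scalar_keys, cam_keys, string_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  args <- list()
  for (k in intersect(names(kv), scalar_keys)) {
    v <- suppressWarnings(as.numeric(kv[[k]]))
    if (is.na(v)) stop("config key '", k, "' is not numeric: ", kv[[k]], call. = FALSE)
    args[[k]] <- v
  }
  if ("capture_rule" %in% names(kv)) args$capture_rule <- kv$capture_rule
  if (any(cam_keys %in% names(kv))) {
    if (!all(cam_keys %in% names(kv)))
      stop("camera layout needs all of: ", paste(cam_keys, collapse = ", "),
           call. = FALSE)
    parse_list <- function(k) as.numeric(strsplit(kv[[k]], ",")[[1]])
    lay <- data.frame(x = parse_list("camera_x"), y = parse_list("camera_y"),
                      orientation = parse_list("camera_orientation"))
    args$camera_layout <- lay
    args$n_cameras <- nrow(lay)
  }
  do.call(sim_config, args)
}

#' Write a configuration file
#'
#' Inverse of [load_config()]: `write_config()` then `load_config()` is
#' the identity on the config.
#'
#' @param config a `pika_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- c("L", "n_systems", "t_tol", "D_tol", "l_min", "l_sys", "H_min", "H_max",
            "Q_min", "Q_max", "dt", "d_max", "v_large", "sigma_large",
            "v_small", "sigma_small", "l_home", "r", "theta", "n_cameras",
            "p_high", "seed")
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- vapply(keys, function(k) paste(k, "=", fmt(config[[k]])), "")
  lines <- c(lines, paste("capture_rule =", config$capture_rule))
  lay <- config$camera_layout
  lines <- c(lines,
             paste("camera_x =", paste(fmt(lay$x), collapse = ",")),
             paste("camera_y =", paste(fmt(lay$y), collapse = ",")),
             paste("camera_orientation =",
                   paste(fmt(lay$orientation), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
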