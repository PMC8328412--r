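#' Random encounter model (REM) density estimation
#'
#' The REM estimates animal density from unmarked camera-trap captures:
#'
#'   D = (y / t) * pi / (v * r * (2 + theta))
#'
#' where `y` is the number of independent photographs, `t` the camera-days,
#' `v` the animal's daily travel distance, and `(r, theta)` the detection
#' zone radius and angle. The activity-intensity-per-density index
#' `lambda = P / D` (hectares), with `P` the mean daily capture rate per
#' camera, has the closed form `lambda = v * r * (2 + theta) / pi` implied
#' by the REM; it is the expected daily capture rate contributed by one
#' animal per hectare.
#'
#' @name estimation
NULL

#' REM density estimate
#'
#' @param y independent photograph count(s).
#' @param t camera-days deployed.
#' @param v daily movement distance, km/day (converted internally to m/day).
#' @param r detection radius, m.
#' @param theta detection angle, rad.
#' @return object of class `density_estimate`: inputs plus `D`, the
#'   density in individuals per hectare (full precision; round only for
#'   presentation). Vectorized over `y` and `t`.
#' @export
#' @examples
#' rem_density(y = 271, t = 6, v = 0.3, r = 8, theta = 0.96)$D  # ~200 / ha
rem_density <- function(y, t, v = 0.3, r = 8, theta = 0.96) {
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  if (any(y < 0)) stop("y must be >= 0", call. = FALSE)
  if (v <= 0 || r <= 0) stop("v and r must be > 0", call. = FALSE)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  v_m <- v * 1000  # km/day -> m/day
  D_m2 <- (y / t) * pi / (v_m * r * (2 + theta))
  structure(list(y = y, t = t, v = v, r = r, theta = theta,
                 D = D_m2 * 1e4), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("REM density:", paste(round(x$D), collapse = ", "),
      "per ha ( y =", paste(x$y, collapse = ", "), ", t =",
      paste(x$t, collapse = ", "), "days, v =", x$v, "km/day )\n")
  invisible(x)
}

#' Mean daily capture rate per camera
#'
#' Grand total of the capture matrix divided by (days x cameras).
#'
#' @param log a `capture_log` (or bare matrix).
#' @return P, captures per camera per day.
#' @export
mean_capture_rate <- function(log) {
  if (!inherits(log, "capture_log")) log <- capture_log(log)
  sum(log$q) / (log$T * log$N)
}

#' Activity intensity per population density
#'
#' @param P mean daily captures per camera, day^-1.
#' @param D density, ha^-1; must be > 0.
#' @return lambda = P / D, hectares.
#' @export
lambda_index <- function(P, D) {
  if (any(D <= 0)) stop("lambda is undefined for D <= 0", call. = FALSE)
  P / D
}

#' Closed-form lambda implied by the REM
#'
#' @param v daily movement distance, m/day.
#' @param r detection radius, m.
#' @param theta detection angle, rad.
#' @return lambda = v * r * (2 + theta) / pi, hectares.
#' @export
#' @examples
#' lambda_closed_form(300, 8, 0.96)  # 0.226 ha
lambda_closed_form <- function(v, r, theta) {
  if (any(c(v, r, theta) <= 0)) stop("inputs must be > 0", call. = FALSE)
  v * r * (2 + theta) / pi / 1e4
}

#' Least-squares fit of capture rate against density
#'
#' Ordinary least squares of `P` on `D`, reported with the standard
#' intercept model (the default slope) and a through-origin variant for
#' sensitivity. The with-intercept slope estimates lambda.
#'
#' @param D densities, ha^-1 (or a 2-column data.frame/matrix of (D, P)).
#' @param P capture rates, day^-1; omit when `D` holds both columns.
#' @return object of class `pika_fit`: `slope`, `intercept`, `r_squared`,
#'   `slope_origin`, `n_points`.
#' @export
fit_P_vs_D <- function(D, P = NULL) {
  if (is.null(P)) {
    m <- as.data.frame(D)
    D <- m[[1]]; P <- m[[2]]
  }
  if (length(D) != length(P)) stop("D and P lengths differ", call. = FALSE)
  if (length(unique(D)) < 2)
    stop("need >= 2 distinct D values to fit", call. = FALSE)
  fit <- stats::lm(P ~ D)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((P - mean(P))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 slope_origin = sum(D * P) / sum(D * D),
                 n_points = length(D)),
            class = "pika_fit")
}

#' @export
print.pika_fit <- function(x, ...) {
  cat("P ~ D fit:", x$n_points, "points; slope =",
      format(x$slope, digits = 4), "( through origin:",
      format(x$slope_origin, digits = 4), "), intercept =",
      format(x$intercept, digits = 4), ", R^2 =",
      format(x$r_squared, digits = 4), "\n")
  invisible(x)
}
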