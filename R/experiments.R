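#' Monte Carlo experiments
#'
#' Full-pipeline trials (landscape -> movement -> detection -> estimation)
#' and the parameter sweeps used to study how the capture rate `P` and
#' the index `lambda = P / D` respond to true density (via the per-system
#' occupancy range), the daily activity budget `t_tol`, and the two
#' movement speeds.
#'
#' @name experiments
NULL

#' Run one full simulation trial
#'
#' Generates a landscape, simulates `D_tol` days of movement for every
#' pika with capture counting, and summarizes: true density `D`, mean
#' daily capture rate `P`, `lambda = P / D` (0 by convention for an empty
#' landscape), and the mean per-pika daily travel distance. Bit-identical
#' for a fixed seed.
#'
#' @param config a `pika_config`.
#' @param seed root seed of the trial; defaults to `config$seed`.
#' @param keep_log if `TRUE`, attach the `capture_log` and landscape.
#' @return one-row data.frame (a sweep record): `seed`, `n_pikas`,
#'   `D_true`, `P`, `lambda`, `mean_daily_distance`; with attributes
#'   `capture_log` / `landscape` when `keep_log`.
#' @export
run_trial <- function(config, seed = config$seed, keep_log = FALSE) {
  landscape <- generate_landscape(config, seed)
  cameras <- make_cameras(config)
  q <- matrix(0L, length(cameras), config$D_tol)
  dist_sum <- 0; n_pika_days <- 0
  n_pikas <- sum(landscape$systems$n_pikas)
  for (day in seq_len(config$D_tol)) {
    res <- with_child_seed(derive_seed(seed, paste0("day-", day)),
      simulate_population_day(landscape, config, cameras))
    q[, day] <- res$q
    dist_sum <- dist_sum + sum(res$distances)
    n_pika_days <- n_pika_days + res$n_pikas
  }
  log <- capture_log(q)
  P <- mean_capture_rate(log)
  D <- landscape$true_density
  rec <- data.frame(seed = as.integer(seed), n_pikas = n_pikas,
                    D_true = D, P = P,
                    lambda = if (D > 0) P / D else 0,
                    mean_daily_distance =
                      if (n_pika_days > 0) dist_sum / n_pika_days else 0)
  if (keep_log) {
    attr(rec, "capture_log") <- log
    attr(rec, "landscape") <- landscape
  }
  rec
}

sweep_seed <- function(base_seed, tag, trial)
  derive_seed(base_seed, paste0(tag, "-trial-", trial))

#' Density sweep over per-system occupancy ranges
#'
#' Repeats [run_trial()] while varying `(Q_min, Q_max)`; every trial uses
#' a distinct derived seed. The default ranges span true densities of
#' roughly 50--175 pikas per hectare.
#'
#' @param config a `pika_config` (its `Q_min`/`Q_max` are overridden).
#' @param q_ranges list of `c(Q_min, Q_max)` pairs.
#' @param trials trials per range.
#' @param base_seed seed from which all trial seeds are derived.
#' @return data.frame of sweep records with columns `swept_parameter`
#'   (`"Q_range"`), `value` (the range midpoint), `Q_min`, `Q_max`,
#'   `trial`, plus the [run_trial()] columns.
#' @export
density_sweep <- function(config,
                          q_ranges = list(c(1, 3), c(2, 4), c(3, 5),
                                          c(4, 6), c(5, 7), c(6, 8)),
                          trials = 15, base_seed = config$seed) {
  stopifnot(trials >= 1)
  out <- vector("list", length(q_ranges) * trials)
  k <- 0L
  for (g in seq_along(q_ranges)) {
    qr <- q_ranges[[g]]
    cfg <- config
    cfg$Q_min <- as.integer(qr[1]); cfg$Q_max <- as.integer(qr[2])
    validate_config(cfg)
    for (tr in seq_len(trials)) {
      rec <- run_trial(cfg, sweep_seed(base_seed, paste0("Q", qr[1], "-", qr[2]), tr))
      k <- k + 1L
      out[[k]] <- cbind(data.frame(swept_parameter = "Q_range",
                                   value = mean(qr), Q_min = qr[1],
                                   Q_max = qr[2], trial = tr), rec)
    }
  }
  do.call(rbind, out)
}

#' Sweep one behavioral parameter
#'
#' Varies `t_tol`, `v_large` or `v_small` over strictly increasing
#' `values`, with `trials` replicate full-pipeline runs per value.
#'
#' @param config a `pika_config`.
#' @param name one of `"t_tol"`, `"v_large"`, `"v_small"`.
#' @param values strictly increasing parameter values.
#' @param trials trials per value.
#' @param base_seed seed from which all trial seeds are derived.
#' @return data.frame of sweep records (`swept_parameter = name`,
#'   `value`, `trial`, plus the [run_trial()] columns).
#' @export
parameter_sweep <- function(config, name = c("t_tol", "v_large", "v_small"),
                            values, trials = 15, base_seed = config$seed) {
  name <- match.arg(name)
  if (is.unsorted(values, strictly = TRUE))
    stop("values must be strictly increasing", call. = FALSE)
  stopifnot(trials >= 1)
  out <- vector("list", length(values) * trials)
  k <- 0L
  for (v in values) {
    cfg <- config
    cfg[[name]] <- v
    validate_config(cfg)
    for (tr in seq_len(trials)) {
      rec <- run_trial(cfg, sweep_seed(base_seed, paste0(name, "=", v), tr))
      k <- k + 1L
      out[[k]] <- cbind(data.frame(swept_parameter = name, value = v,
                                   trial = tr), rec)
    }
  }
  do.call(rbind, out)
}

#' Group means of a sweep
#'
#' @param records sweep records from [density_sweep()] or
#'   [parameter_sweep()].
#' @return data.frame of per-value group summaries: mean/min/max `lambda`,
#'   mean `P`, mean `D_true`, mean daily distance, trial count.
#' @export
summarize_sweep <- function(records) {
  g <- split(records, records$value)
  out <- do.call(rbind, lapply(g, function(d) data.frame(
    swept_parameter = d$swept_parameter[1], value = d$value[1],
    n_trials = nrow(d),
    lambda_mean = mean(d$lambda), lambda_min = min(d$lambda),
    lambda_max = max(d$lambda),
    P_mean = mean(d$P), D_mean = mean(d$D_true),
    distance_mean = mean(d$mean_daily_distance))))
  out[order(out$value), , drop = FALSE]
}
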