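test_that("toroidal wrap maps coordinates into [0, L)", {
  expect_equal(wrap(c(500, 500), 1000), c(500, 500))
  expect_equal(wrap(c(1001, 500), 1000), c(1, 500))
  expect_equal(wrap(c(-1, -1), 1000), c(999, 999))
})

test_that("speed draws follow the intensity-class Gaussians", {
  cfg <- sim_config()
  set.seed(1)
  v <- sample_speed(1e5, "high", cfg)
  expect_equal(mean(v), 20, tolerance = 0.01)
  expect_equal(stats::sd(v), 2, tolerance = 0.05)
  w <- sample_speed(1e5, "low", cfg)
  expect_equal(mean(w), 2, tolerance = 0.01)
  expect_true(all(w >= 0))  # truncation at 0; P(N(2, .2) < 0) = Phi(-10) ~ 0
  expect_equal(stats::sd(w), 0.2, tolerance = 0.05)
  cfg0 <- sim_config(sigma_large = 0)
  expect_true(all(sample_speed(100, "high", cfg0) == 20))
})

test_that("advance applies the position update contract", {
  cfg <- sim_config(sigma_large = 0, sigma_small = 0, p_high = 1)
  st <- list(position = c(100, 100), status = "outside",
             budget_remaining = 5, cum_distance = 0)
  set.seed(2)
  st2 <- advance(st, cfg)
  # dt = 0.5 min at 20 m/min -> 10 m displacement
  expect_equal(st2$step_distance, 10)
  expect_equal(sqrt(sum((st2$position_raw - st$position)^2)), 10)
  expect_equal(st2$budget_remaining, 4.5)
  expect_equal(st2$cum_distance, 10)

  st$status <- "inside"
  expect_error(advance(st, cfg), "outside")
  st$status <- "outside"; st$budget_remaining <- 0
  expect_error(advance(st, cfg), "budget")
})

test_that("headings are uniform on [0, 2*pi) (KS at alpha = 0.01)", {
  cfg <- sim_config(L = 10000, n_systems = 1, H_min = 1, H_max = 1,
                    t_tol = 0.5, l_home = 1e-9)
  ls <- generate_landscape(cfg, seed = 3)
  res <- with_child_seed(4, simulate_population_day(
    ls, cfg, record = TRUE, pika_systems = rep(1L, 10000)))
  phi <- atan2(res$steps$y1 - res$steps$y0,
               res$steps$x1 - res$steps$x0) %% (2 * pi)
  expect_gt(stats::ks.test(phi, "punif", 0, 2 * pi)$p.value, 0.01)
})

test_that("return detection is strict and uses own entrances only", {
  ent <- rbind(c(10, 10), c(20, 20))
  expect_true(check_return(c(10, 10), ent, 1))
  expect_true(check_return(c(10.5, 10), ent, 1))
  expect_false(check_return(c(11, 10), ent, 1))  # exactly l_home: strict <
  expect_error(check_return(c(0, 0), ent[0, , drop = FALSE], 1), "non-empty")
})

test_that("a zero activity budget yields an empty day", {
  cfg <- tiny_config(t_tol = 0)
  ls <- generate_landscape(cfg, seed = 5)
  p <- simulate_day(1L, 1L, ls, cfg, seed = 6)
  expect_equal(nrow(p$segments), 0)
  expect_equal(p$total_distance, 0)
})

test_that("budget, displacement consistency and segment contiguity hold", {
  cfg <- small_config(t_tol = 7.25)  # not a multiple of dt: floor() steps
  ls <- generate_landscape(cfg, seed = 7)
  p <- simulate_day(2L, 3L, ls, cfg, seed = 8)
  seg <- p$segments
  expect_equal(nrow(seg), floor(cfg$t_tol / cfg$dt))
  # per-segment |p1 - p0| equals s_t (pre-wrap displacement)
  expect_equal(sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2), seg$s,
               tolerance = 1e-12)
  expect_equal(p$total_distance, sum(seg$s))
  expect_true(all(seg$s >= 0 & seg$s <= cfg$d_max))
  # contiguous within an excursion: each step starts where the last ended
  cont <- seg$x0[-1] == seg$xw[-nrow(seg)] & seg$y0[-1] == seg$yw[-nrow(seg)]
  expect_true(all(cont | seg$new_excursion[-1]))
  # wrapped positions stay in the square
  expect_true(all(seg$xw >= 0 & seg$xw < cfg$L & seg$yw >= 0 & seg$yw < cfg$L))
})

test_that("every excursion starts at an own-system entrance", {
  cfg <- small_config()
  ls <- generate_landscape(cfg, seed = 9)
  sys_id <- 4L
  p <- simulate_day(1L, sys_id, ls, cfg, seed = 10)
  seg <- p$segments
  e <- ls$entrances[ls$entrances$system_id == sys_id, ]
  starts <- seg[seg$new_excursion, ]
  for (k in seq_len(nrow(starts))) {
    d <- min((e$x - starts$x0[k])^2 + (e$y - starts$y0[k])^2)
    expect_lt(d, 1e-18)
  }
})

test_that("mean daily distance matches the closed-form expectation", {
  # E[distance] = t_tol * (p_high v_large + (1 - p_high) v_small)
  cases <- list(list(t_tol = 15, p_high = 0.5, expected = 15 * 11),
                list(t_tol = 10, p_high = 0.2, expected = 10 * (0.2 * 20 + 0.8 * 2)))
  for (cs in cases) {
    cfg <- sim_config(L = 300, n_systems = 220, t_tol = cs$t_tol,
                      p_high = cs$p_high, D_tol = 1, seed = 12)
    ls <- generate_landscape(cfg, seed = 12)
    res <- with_child_seed(13, simulate_population_day(ls, cfg))
    expect_gte(res$n_pikas, 1000)
    se <- stats::sd(res$distances) / sqrt(res$n_pikas)
    expect_lt(abs(mean(res$distances) - cs$expected), 3 * se)
  }
})

test_that("l_home extremes control excursion structure", {
  cfg <- small_config(l_home = 1e6)  # always within reach of home
  ls <- generate_landscape(cfg, seed = 14)
  p <- simulate_day(1L, 1L, ls, cfg, seed = 15)
  expect_true(all(p$segments$new_excursion))  # every excursion is one step

  cfg0 <- small_config(l_home = 1e-12)
  ls0 <- generate_landscape(cfg0, seed = 14)
  p0 <- simulate_day(1L, 1L, ls0, cfg0, seed = 15)
  expect_equal(sum(p0$segments$new_excursion), 1L)  # only the day's first exit
})

test_that("population day simulation is reproducible under a fixed seed", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, seed = 16)
  a <- with_child_seed(17, simulate_population_day(ls, cfg, record = TRUE))
  b <- with_child_seed(17, simulate_population_day(ls, cfg, record = TRUE))
  expect_identical(a, b)
})
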