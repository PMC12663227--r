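test_that("a disc measures as a point-like object with the right area", {
  lab <- matrix(0L, 40, 40)
  lab[disc_mask(c(40, 40), c(20, 20), 10)] <- 1L
  tr <- data.frame(track_id = 1L, frame = 0L, label = 1L)
  class(tr) <- c("track_table", "data.frame")
  m <- measure_tracks(tr, list(lab), frame_interval = 15)
  expect_equal(m$area_px2, pi * 100, tolerance = 0.05)
  expect_lte(m$skeleton_len_px, 5)
  expect_gt(m$roundness, 0.9)
  expect_true(is.na(m$load_au))
})

test_that("skeleton length of a spore with a straight germ tube tracks the tube", {
  shape <- c(60, 140)
  L <- 60
  lab <- matrix(0L, shape[1], shape[2])
  lab[disc_mask(shape, c(30, 30), 10)] <- 1L
  lab[rect_mask(shape, c(30, 39 + L / 2), 2, L / 2)] <- 1L
  skel <- skeletonize_mask(lab == 1L)
  len <- skeleton_length(skel)
  # tube length plus a disc-core contribution of at most one radius or so
  expect_gt(len, 0.9 * L)
  expect_lt(len, 1.1 * (L + 12))
})

test_that("noise-free measured load equals the configured truth load", {
  set.seed(16)
  cfg <- simulation_config(n_spores = 3, n_frames = 4, image_shape = c(200, 200),
                           noise_model = list(gaussian_sd = 0, poisson = FALSE),
                           area_jitter_sd = 0)
  pop <- generate_population(cfg)
  masks <- render_truth_masks(pop)
  labs <- lapply(masks, `[[`, "labels")
  loads <- truth_load_series(pop)
  fluor <- lapply(1:4, function(k)
    sporetrack:::fluor_frame(labs[[k]], loads[, k], 0))
  tr <- build_tracks(labs)
  m <- measure_tracks(tr, labs, fluor, frame_interval = 15, compute_length = FALSE)
  for (id in 1:3) {
    got <- m$load_au[m$track_id == id][order(m$frame[m$track_id == id])]
    expect_equal(got, unname(loads[id, ]), tolerance = 1e-12)
  }
  ls <- load_at_start(m)
  expect_equal(ls$load_t0_au, unname(loads[, 1]), tolerance = 1e-12)
})

test_that("germination calls follow the 1.5-fold / 10-h rule", {
  p <- germination_params()
  t480 <- seq(0, 480, 15)
  # monotone trace reaching 1.6x at 8 h -> germinating
  expect_true(call_germination(seq(100, 160, length.out = length(t480)), t480, p))
  # constant trace over >= 10 h -> non-germinating
  t720 <- seq(0, 720, 15)
  expect_false(call_germination(rep(100, length(t720)), t720, p))
  # 1.49x at 10 h, 2.0x at 12 h -> non-germinating (window rule)
  t <- seq(0, 720, 60)
  a <- ifelse(t <= 600, 100 + (149 - 100) * t / 600,
              149 + (200 - 149) * (t - 600) / 120)
  expect_false(call_germination(a, t, p))
  # short censored trace below threshold -> undetermined
  expect_true(is.na(call_germination(c(100, 110, 120), c(0, 15, 30), p)))
  # short trace that already crossed -> germinating
  expect_true(call_germination(c(100, 160), c(0, 15), p))
  expect_error(call_germination(c(0, 10), c(0, 15), p), "positive")
  # invariance under uniform area rescaling
  a2 <- seq(100, 170, length.out = length(t480))
  expect_identical(call_germination(a2, t480, p),
                   call_germination(a2 * 37.5, t480, p))
})

test_that("doubling-time fit recovers exact exponentials and scales with time", {
  t <- seq(0, 480, 15)
  expect_equal(fit_doubling_time(t, 100 * 2^(t / 98), from_fold = NULL), 98,
               tolerance = 1e-10)
  expect_equal(fit_doubling_time(t, 100 * 2^(t / 98)), 98, tolerance = 1e-10)
  # time equivariance: scaling time by c scales T_D by c
  expect_equal(fit_doubling_time(3 * t, 100 * 2^(t / 98), from_fold = NULL),
               3 * 98, tolerance = 1e-9)
  # lag then growth: the from_fold gate skips the flat phase
  lagged <- c(rep(100, 10), 100 * 2^(seq(15, 300, 15) / 98))
  tl <- seq(0, by = 15, length.out = length(lagged))
  expect_equal(fit_doubling_time(tl, lagged), 98, tolerance = 0.5)
  expect_error(fit_doubling_time(t, c(0, rep(1, length(t) - 1))), "positive")
  expect_true(is.na(fit_doubling_time(t, rep(100, length(t)))))  # never crosses
  expect_true(is.na(fit_doubling_time(t, 100 * 2^(-t / 98), from_fold = NULL)))
})

test_that("noisy doubling-time estimates are nearly unbiased", {
  t <- seq(0, 480, 15)
  truth <- 98
  est <- vapply(1:30, function(s) {
    set.seed(100 + s)
    size <- 100 * 2^(t / truth) * exp(rnorm(length(t), 0, 0.05))
    fit_doubling_time(t, size, from_fold = NULL)
  }, numeric(1))
  expect_lt(abs(mean(est) - truth) / truth, 0.05)
})

test_that("maximum-growth window matches the exhaustive enumeration oracle", {
  # piecewise two-slope series: slow then fast
  t <- seq(0, 600, 30)
  size <- ifelse(t <= 300, 100 * 2^(t / 300), 200 * 2^((t - 300) / 60))
  w <- 5L
  # oracle: enumerate every window slope with lm()
  slopes <- vapply(seq_len(length(t) - w + 1L), function(i) {
    j <- i:(i + w - 1L)
    unname(coef(stats::lm(log(size[j]) ~ t[j]))[2])
  }, numeric(1))
  got <- max_growth_doubling_time(t, size, w)
  expect_equal(got$slope_per_min, max(slopes), tolerance = 1e-10)
  expect_equal(got$t_dmax_min, log(2) / max(slopes), tolerance = 1e-9)
  # the selected window sits in the steep segment
  expect_gte(got$window_start_min, 270)
  # pure exponential: T_Dmax equals the global doubling time
  pure <- 100 * 2^(t / 98)
  expect_equal(max_growth_doubling_time(t, pure, w)$t_dmax_min, 98,
               tolerance = 1e-9)
  expect_error(max_growth_doubling_time(t[1:3], size[1:3], 5L), "window")
})

test_that("lag-then-exponential series recovers the bacterial rate", {
  set.seed(17)
  v <- simulate_voxel_series(duration_min = 900, interval_min = 60,
                             lag_min = 360, doubling_time_min = 102,
                             noise_sd = 0.05)
  r <- max_growth_doubling_time(v$time_min, v$voxels, 5L)
  expect_gte(r$window_start_min, 300)  # lag excluded
  expect_equal(r$t_dmax_min / 60, 1.7, tolerance = 0.1)
})

test_that("track summaries call germination consistently with the truth", {
  set.seed(18)
  cfg <- simulation_config(n_spores = 40, germination_probability = 0.5,
                           image_shape = c(64, 64))
  pop <- generate_population(cfg)
  area <- truth_area_series(pop)
  t_min <- (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval
  calls <- apply(area, 1, function(a) call_germination(a, t_min))
  confusion <- mean((calls %in% TRUE) != pop$germinating)
  expect_lt(confusion, 0.05)
})
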