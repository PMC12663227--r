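test_that("empty population gives empty truth and background-only stacks", {
  set.seed(1)
  cfg <- simulation_config(n_spores = 0, n_frames = 3, image_shape = c(64, 64))
  pop <- generate_population(cfg)
  expect_s3_class(pop, "spore_population")
  expect_identical(nrow(pop), 0L)
  stack <- render_timelapse(pop)
  expect_true(all(stack$labels == 0L))
  expect_true(all(stack$fluor == 0))
})

test_that("germination flags follow the configured Bernoulli probability", {
  p <- 0.52
  n <- 200
  counts <- vapply(1:5, function(s) {
    set.seed(s)
    cfg <- simulation_config(n_spores = n, germination_probability = p,
                             image_shape = c(64, 64))
    sum(generate_population(cfg)$germinating)
  }, numeric(1))
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= sd3))
})

test_that("empirical germination fraction is unbiased across many seeds", {
  p <- 0.52
  total <- 0L
  n_per <- 50L
  for (s in 1:30) {
    set.seed(1000 + s)
    cfg <- simulation_config(n_spores = n_per, germination_probability = p,
                             image_shape = c(64, 64))
    total <- total + sum(generate_population(cfg)$germinating)
  }
  bt <- stats::binom.test(total, 30L * n_per, p = p)
  expect_gt(bt$p.value, 0.01)
})

test_that("load-germination coupling lowers germination at high load", {
  set.seed(7)
  cfg <- simulation_config(
    n_spores = 500, germination_probability = 0.5, image_shape = c(64, 64),
    load_germination_coupling = list(type = "logistic",
                                     midpoint = log(1000), slope = 2))
  pop <- generate_population(cfg)
  expect_lt(mean(pop$load0_au[pop$germinating]),
            mean(pop$load0_au[!pop$germinating]))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_config()
  set.seed(42); a <- generate_population(cfg)
  set.seed(42); b <- generate_population(cfg)
  expect_identical(a, b)
  set.seed(42); sa <- render_timelapse(a, frames = 0:2)
  set.seed(42); sb <- render_timelapse(b, frames = 0:2)
  expect_identical(sa$widefield, sb$widefield)
  expect_identical(sa$fluor, sb$fluor)
})

test_that("noise-free fluorescence inside the truth mask conserves the load", {
  set.seed(3)
  cfg <- simulation_config(n_spores = 1, n_frames = 5, image_shape = c(96, 96),
                           noise_model = list(gaussian_sd = 0, poisson = FALSE),
                           area_jitter_sd = 0)
  pop <- generate_population(cfg)
  stack <- render_timelapse(pop)
  loads <- truth_load_series(pop)
  proj <- fluor_projection(stack)
  for (k in 1:5) {
    measured <- sum(proj[[k]][stack$labels[k, , ] == 1L])
    expect_equal(measured, loads[1, k], tolerance = 1e-12)
  }
})

test_that("log true area grows linearly with slope ln2 / doubling time", {
  set.seed(4)
  cfg <- simulation_config(n_spores = 10, n_frames = 40,
                           germination_probability = 1,
                           image_shape = c(64, 64))
  pop <- generate_population(cfg)
  area <- truth_area_series(pop)
  t_min <- (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval
  for (i in 1:10) {
    after <- which(t_min > pop$lag_min[i])
    expect_gt(length(after), 3)
    fit <- stats::lm(log(area[i, after]) ~ t_min[after])
    expect_equal(unname(stats::coef(fit)[2]), log(2) / pop$doubling_time_min[i],
                 tolerance = 1e-10)
    # non-decreasing after lag
    expect_true(all(diff(area[i, after]) >= 0))
  }
})

test_that("non-germinating true traces never reach 1.5-fold in any 10-h window", {
  set.seed(5)
  cfg <- simulation_config(n_spores = 30, germination_probability = 0,
                           image_shape = c(64, 64))
  area <- truth_area_series(generate_population(cfg))
  fold <- apply(area, 1, function(a) max(a) / min(a))
  expect_true(all(fold < 1.5))
})

test_that("corruption-free maps reproduce the truth exactly", {
  masks <- list(labels = touching_discs(), body = touching_discs())
  maps <- simulate_probability_maps(masks, map_corruption(0, 0, 0, 0))
  expect_identical(maps$cell >= 0.5, masks$labels > 0L)
  # the shared ridge between the touching discs is above 0.5
  shared <- masks$labels == 1L &
    (sporetrack:::nb(masks$labels, 0L, 1L, 0L) == 2L |
     sporetrack:::nb(masks$labels, 0L, -1L, 0L) == 2L)
  expect_gt(sum(shared), 0)
  expect_true(all(maps$contour[shared] > 0.5))
})

test_that("germ-tube pixels appear in the cell map but not the body map", {
  set.seed(6)
  cfg <- simulation_config(n_spores = 1, n_frames = 40,
                           germination_probability = 1, lag_mean = 60,
                           lag_sd = 0, image_shape = c(200, 200))
  pop <- generate_population(cfg)
  mk <- sporetrack:::render_frame_masks(pop, cfg, 30)
  tube <- mk$labels > 0L & mk$body == 0L
  expect_gt(sum(tube), 0)
  maps <- simulate_probability_maps(mk, map_corruption(0, 0, 0, 0))
  expect_true(all(maps$cell[tube] >= 0.5))
  expect_true(all(maps$body[tube] < 0.5))
})

test_that("reference segmentation recovers simulated spores at frame 0", {
  set.seed(9)
  cfg <- simulation_config(n_spores = 20, image_shape = c(400, 400))
  pop <- generate_population(cfg)
  mk <- sporetrack:::render_frame_masks(pop, cfg, 0)
  maps <- simulate_probability_maps(mk, map_corruption())
  lab <- filter_objects(integrate_maps(maps), segmentation_params())
  ious <- match_objects(lab, mk$labels)
  expect_gte(mean(ious >= 0.5), 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(frame_interval = 0), "duration")
  expect_error(simulation_config(germination_probability = 1.2), "probability")
  expect_error(simulation_config(n_spores = -1), "n_spores")
  expect_error(simulation_config(initial_load_distribution = list(meanlog = 1)),
               "initial_load_distribution")
  expect_error(simulation_config(load_germination_coupling = list(type = "exp")),
               "coupling")
})
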