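test_that("noiseless environment hits exact sinusoid bounds and night zeros", {
  sc <- sim_scenario(temp_sigma = 0, hum_sigma = 0, rad_sigma = 0)
  env <- gen_environment(sc, days = 3)
  expect_equal(range(env$temperature), c(17, 27))
  hod <- as.numeric(format(env$timestamp, "%H"))
  expect_true(all(env$radiation[hod == 0] == 0))
  expect_true(all(env$radiation[hod < 6 | hod > 18] == 0))
  # humidity anti-phase: coldest hour is the most humid
  expect_equal(which.max(env$humidity[1:24]), which.min(env$temperature[1:24]))
})

test_that("environment generation is reproducible and mean-accurate", {
  sc <- sim_scenario()
  e1 <- gen_environment(sc, days = 4)
  e2 <- gen_environment(sc, days = 4)
  expect_identical(e1, e2)
  e3 <- gen_environment(sc, days = 4, seed = sc$seed + 1)
  expect_false(identical(e1$temperature, e3$temperature))
  # whole-day sample mean within 3 standard errors (AR(1)-inflated)
  n <- nrow(e1)
  se <- sc$temp_sigma * 3 / sqrt(n)
  expect_lt(abs(mean(e1$temperature) - sc$temp_mean), 3 * se)
})

test_that("color kinetics are logistic in thermal time on the simplex", {
  sc <- sim_scenario(t_base = 10, gdd50 = 100, temp_sigma = 0)
  # constant 34 C: each hourly step adds exactly 1 GDD
  env <- tibble::tibble(
    timestamp = as.POSIXct("2024-05-01", tz = "UTC") + 3600 * (0:199),
    temperature = 34)
  traj <- gen_color_trajectory(env, sc)
  expect_equal(traj$gdd, as.numeric(1:200))
  expect_equal(traj$red[100], 0.5) # logistic midpoint, exactly
  expect_equal(traj$red + traj$yellow + traj$green, rep(1, 200))
  expect_true(all(diff(traj$red) > 0))
  expect_true(all(traj$green >= 0 & traj$yellow >= 0))
  expect_error(gen_color_trajectory(env[1:10, ], sc))
})

test_that("trait curves pass through their midpoints and respect directions", {
  sc <- sim_scenario(trait_sigma = c(FI = 0, SSC = 0, SS = 0, TA = 0,
                                     VC = 0, LYC = 0))
  q_mid <- gen_quality(0.54, sc)
  expect_equal(q_mid$FI, 2.0 + 4.5 / 2)
  expect_equal(q_mid$SSC, 4.0 + 2.0 / 2)
  expect_equal(q_mid$SS, 15 + 7.5)
  expect_equal(q_mid$TA, 0.30 + 0.15)
  expect_equal(q_mid$VC, 0.10 + 0.15) # concave peak
  expect_equal(q_mid$LYC, 0.005 + 0.085 / 2)

  a <- seq(0.40, 0.68, length.out = 30)
  q <- gen_quality(a, sc)
  expect_true(all(diff(q$LYC) > 0))
  expect_true(all(diff(q$SSC) > 0))
  expect_true(all(diff(q$FI) < 0))
  expect_true(all(diff(q$TA) < 0))
  expect_true(all(as.matrix(q) >= 0))
})

test_that("trait noise is reproducible under a fixed seed", {
  sc <- sim_scenario()
  a <- runif(10, 0.4, 0.6)
  expect_identical(gen_quality(a, sc, seed = 5), gen_quality(a, sc, seed = 5))
  expect_false(identical(gen_quality(a, sc, seed = 5),
                         gen_quality(a, sc, seed = 6)))
})

test_that("rendered fruit discs recover their target color fractions", {
  all_red <- render_fruit_image(1, 0, 0, size = 48, seed = 2)
  cr <- color_ratios(all_red$image, all_red$mask)
  expect_equal(c(cr$red, cr$yellow, cr$green), c(1, 0, 0))

  half <- render_fruit_image(0.5, 0, 0.5, size = 64, seed = 3)
  cr2 <- color_ratios(half$image, half$mask)
  expect_equal(cr2$red, 0.5, tolerance = 0.02)
  expect_equal(cr2$green, 0.5, tolerance = 0.02)

  mixed <- render_fruit_image(0.3, 0.3, 0.4, size = 64, seed = 4)
  cr3 <- color_ratios(mixed$image, mixed$mask)
  expect_equal(c(cr3$red, cr3$yellow, cr3$green), c(0.3, 0.3, 0.4),
               tolerance = 0.02)

  # mask is exactly the disc
  size <- 48; ctr <- (size + 1) / 2; radius <- 0.42 * size
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  expect_equal(sum(all_red$mask),
               sum((xs - ctr)^2 + (ys - ctr)^2 <= radius^2))
  expect_error(render_fruit_image(0.5, 0.2, 0.2, size = 32, seed = 1))
})

test_that("missingness injection respects rate, run length, and seeding", {
  sc <- sim_scenario(temp_sigma = 0, hum_sigma = 0, rad_sigma = 0)
  env <- gen_environment(sc, days = 6)
  expect_identical(inject_missingness(env, rate = 0), env)

  holed <- inject_missingness(env, rate = 0.05, max_run = 3, seed = 9)
  runs <- rle(is.na(holed$temperature))
  expect_true(all(runs$lengths[runs$values] <= 3))
  expect_gt(sum(is.na(holed$temperature)), 0)
  expect_identical(inject_missingness(env, rate = 0.05, max_run = 3, seed = 9),
                   holed)

  # a long-run setting plants at least one gap beyond the linear branch
  long <- inject_missingness(env, rate = 0.05, max_run = 7, seed = 10)
  runs_l <- rle(is.na(long$temperature))
  expect_gte(max(runs_l$lengths[runs_l$values]), 6)
  expect_error(inject_missingness(env, rate = 1))
})

test_that("a simulated campaign is internally consistent", {
  sc <- sim_scenario(n_plants = 10, days = 3, stagger_days = 1, gdd50 = 30,
                     gdd50_sd = 2, image_size = 40, image_every_hours = 24)
  sim <- simulate_dataset(sc)
  expect_equal(nrow(sim$plants), 10L)
  expect_equal(nrow(sim$colors), 10L * 72L)
  expect_equal(nrow(sim$fruit), 10L * 3L)
  # fractions on the simplex, red non-decreasing per plant
  expect_equal(sim$colors$red + sim$colors$yellow + sim$colors$green,
               rep(1, nrow(sim$colors)))
  for (p in sim$plants$plant_id[c(1, 5)]) {
    expect_true(all(diff(sim$colors$red[sim$colors$plant_id == p]) >= 0))
  }
  expect_true(all(sim$fruit$a_norm >= 0 & sim$fruit$a_norm <= 1))
  # measured red tracks the generating red at the image times
  joined <- dplyr::inner_join(sim$fruit, sim$colors,
                              by = c("plant_id", "timestamp"))
  expect_lt(max(abs(joined$red_meas - joined$red)), 0.05)
})

test_that("windowing by plant never crosses plant boundaries", {
  df <- purrr::map_dfr(c("A", "B"), function(p) {
    tibble::tibble(plant_id = p, x = seq_len(30) + (p == "B") * 100,
                   y = seq_len(30))
  })
  d <- windowize_by_plant(df, 10, vars = c("x", "y"), target_vars = "y")
  expect_equal(dim(d$windows), c(40, 10, 2))
  expect_equal(as.integer(table(d$plant)), c(20L, 20L))
  # windows from plant B only contain B's values
  bw <- d$windows[d$plant == "B", , 1]
  expect_true(all(bw > 100))
})
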