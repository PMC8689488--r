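test_that("rendering is deterministic given a seed", {
  s1 <- render_phantom(fast_phantom_spec(ros_fraction = 0.2, seed = 77))
  s2 <- render_phantom(fast_phantom_spec(ros_fraction = 0.2, seed = 77))
  expect_identical(s1$stack$channels, s2$stack$channels)
  expect_identical(unclass(s1$truth_ros), unclass(s2$truth_ros))
  s3 <- render_phantom(fast_phantom_spec(ros_fraction = 0.2, seed = 78))
  expect_false(identical(s1$stack$channels, s3$stack$channels))
})

test_that("rendered ROS fraction honours the 2% rejection-sampling contract", {
  set.seed(601)
  for (i in 1:30) {
    f <- runif(1, 0.02, 0.6)
    ph <- render_phantom(fast_phantom_spec(
      image_shape = c(192L, 192L), shell_axes = c(64, 40),
      ros_fraction = f, ros_object_count = sample(3:8, 1), seed = 600 + i))
    expect_lte(abs(ph$true_fraction - f) / f, 0.02)
    # truth-ROS strictly inside truth-shell
    expect_true(all(!unclass(ph$truth_ros) | unclass(ph$truth_shell)))
  }
  ph0 <- render_phantom(fast_phantom_spec(ros_fraction = 0.25, seed = 640))
  expect_gte(ph0$true_fraction, 0.245)
  expect_lte(ph0$true_fraction, 0.255)
})

test_that("the maximum projection recovers the clean scene exactly", {
  ph <- render_phantom(fast_phantom_spec(ros_fraction = 0.15, noise_sd = 0,
                                         n_slices = 4L, seed = 88))
  proj <- max_projection(ph$stack)
  ring_and_interior <- unclass(ph$truth_shell)
  # CH2 of the projection must equal ring*I2 + tissue + ros exactly
  expect_true(all(proj$images$ros[unclass(ph$truth_ros)] >= 160))
  outside <- !ring_and_interior
  expect_true(all(proj$images$ros[outside] == 0))
})

test_that("unachievable ROS fractions error out after bounded retries", {
  expect_error(render_phantom(fast_phantom_spec(
    ros_fraction = 0.85, ros_object_count = 1L, seed = 9)),
    "unachievable")
})

test_that("experiment simulation: determinism, zero-SD collapse, truncation", {
  des0 <- experiment_design(
    treatments = data.frame(label = c("a", "b"),
                            mean_fraction = c(0.1, 0.3)),
    containers_per_treatment = 2L, individuals_per_container = 5L,
    between_container_sd = 0, within_container_sd = 0, seed = 1)
  sim0 <- simulate_experiment(des0, render = FALSE)
  expect_identical(nrow(sim0$truth), 20L)
  expect_true(all(tapply(sim0$truth$true_fraction, sim0$truth$treatment,
                         function(v) length(unique(v))) == 1L))

  des1 <- default_design(seed = 42)
  t1 <- suppressMessages(simulate_experiment(des1, render = FALSE))$truth
  t2 <- suppressMessages(simulate_experiment(des1, render = FALSE))$truth
  expect_identical(t1, t2)
  expect_identical(nrow(t1), 180L)
  expect_identical(length(unique(t1$container)), 18L)

  des_t <- experiment_design(
    treatments = data.frame(label = "low", mean_fraction = 0.01),
    containers_per_treatment = 2L, individuals_per_container = 20L,
    between_container_sd = 0, within_container_sd = 0.05, seed = 3)
  expect_message(simulate_experiment(des_t, render = FALSE), "truncated")
  tr <- suppressMessages(simulate_experiment(des_t, render = FALSE))$truth
  expect_true(all(tr$true_fraction >= 0 & tr$true_fraction <= 0.99))
})

test_that("hierarchical variances are recovered from simulated fractions", {
  # the method-of-moments between-container estimate has ~20% sampling SD at
  # 50 containers, so average the estimates over 10 replicate simulations of
  # 500 individuals each (~6% estimator SD) before applying the 20% band
  est <- vapply(1:10, function(r) {
    des <- experiment_design(
      treatments = data.frame(label = "t", mean_fraction = 0.5),
      containers_per_treatment = 50L, individuals_per_container = 10L,
      between_container_sd = 0.05, within_container_sd = 0.08, seed = 10 + r)
    tr <- simulate_experiment(des, render = FALSE)$truth
    stopifnot(nrow(tr) == 500L)
    cm <- tapply(tr$true_fraction, tr$container, mean)
    within_var <- mean(tapply(tr$true_fraction, tr$container, var))
    c(within = within_var,
      between = var(cm) - within_var / 10)  # method-of-moments
  }, numeric(2))
  expect_lt(abs(mean(est["within", ]) - 0.08^2) / 0.08^2, 0.2)
  expect_lt(abs(mean(est["between", ]) - 0.05^2) / 0.05^2, 0.2)
})

test_that("pipeline estimates regress on truth with slope ~1, intercept ~0", {
  set.seed(602)
  fr <- seq(0.02, 0.6, length.out = 25)
  est <- truth <- numeric(length(fr))
  for (i in seq_along(fr)) {
    ph <- render_phantom(phantom_spec(
      image_shape = c(256L, 256L), shell_axes = c(80, 50),
      ring_thickness = 8, n_slices = 3L, ros_fraction = fr[i],
      noise_sd = 16, seed = 700 + i))
    truth[i] <- 100 * ph$true_fraction
    est[i] <- quantify_individual(ph$stack)$ros_percent
  }
  fit <- lm(est ~ truth)
  expect_gte(coef(fit)[2], 0.9)
  expect_lte(coef(fit)[2], 1.1)
  expect_gte(coef(fit)[1], -2)
  expect_lte(coef(fit)[1], 2)
})

test_that("simulated experiments can be written to and read back from disk", {
  des <- experiment_design(
    treatments = data.frame(label = c("a", "b"),
                            mean_fraction = c(0.05, 0.3)),
    containers_per_treatment = 2L, individuals_per_container = 2L, seed = 5)
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(des, phantom_base = fast_phantom_spec(),
                             out_dir = dir)
  expect_true(all(file.exists(sim$stacks)))
  expect_true(file.exists(file.path(dir, "truth_table.csv")))
  labels <- read.csv(file.path(dir, "labels.csv"))
  tab <- quantify_batch(sim$stacks, labels = labels)
  expect_identical(nrow(tab), 8L)
  expect_false(anyNA(tab$treatment))
  m <- tapply(tab$ros_percent, tab$treatment, mean)
  expect_lt(m["a"], m["b"])
})
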