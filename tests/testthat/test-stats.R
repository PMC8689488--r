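test_that("arcsine square-root transform: bounds, closed forms, monotonicity", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6)
  p <- sort(runif(50))
  expect_true(all(diff(arcsine_sqrt(p)) >= 0))
  expect_equal(backtransform_arcsine(arcsine_sqrt(p)), p)
  expect_error(arcsine_sqrt(-0.1), "\\[0, 1\\]")
  expect_error(arcsine_sqrt(1.1), "\\[0, 1\\]")
})

test_that("nested ANOVA matches the explicit-loop SS oracle on 100 designs", {
  set.seed(501)
  for (i in 1:100) {
    a <- sample(2:5, 1); b <- sample(2:4, 1); n <- sample(2:6, 1)
    tab <- sim_table(a, b, n, treat_effects = rnorm(a, 0, 1),
                     container_sd = runif(1, 0, 1))
    an <- nested_anova(tab, response = tab$y)
    or <- ss_oracle(tab, tab$y)
    expect_equal(an$ss_treatment, or$ss_treatment, tolerance = 1e-10)
    expect_equal(an$ss_container, or$ss_container, tolerance = 1e-10)
    expect_equal(an$ss_residual, or$ss_residual, tolerance = 1e-10)
    # additivity and df partition on balanced designs
    sst <- sum((tab$y - mean(tab$y))^2)
    expect_equal(an$ss_treatment + an$ss_container + an$ss_residual, sst,
                 tolerance = 1e-9)
    expect_identical(an$df_treatment + an$df_container + an$df_residual,
                     nrow(tab) - 1L)
    expect_equal(an$F, (or$ss_treatment / (a - 1)) /
                   (or$ss_container / (a * (b - 1))), tolerance = 1e-10)
  }
})

test_that("nested ANOVA is location invariant and scale-equivariant", {
  set.seed(502)
  tab <- sim_table(4, 3, 5, treat_effects = c(0, 0.3, 0.6, 0.9),
                   container_sd = 0.2)
  a0 <- nested_anova(tab, response = tab$y)
  a_shift <- nested_anova(tab, response = tab$y + 17)
  expect_equal(a_shift$ss_treatment, a0$ss_treatment)
  expect_equal(a_shift$F, a0$F)
  expect_equal(a_shift$p_value, a0$p_value)
  a_scale <- nested_anova(tab, response = tab$y * 3)
  expect_equal(a_scale$ss_treatment, 9 * a0$ss_treatment)
  expect_equal(a_scale$ss_residual, 9 * a0$ss_residual)
  expect_equal(a_scale$F, a0$F)
  expect_equal(a_scale$p_value, a0$p_value)
})

test_that("nested ANOVA degenerate and structural errors", {
  tab <- sim_table(3, 2, 3)
  tab$y <- 5
  expect_error(nested_anova(tab, response = tab$y), "identical")

  one_cont <- sim_table(3, 1, 4)
  expect_error(nested_anova(one_cont, response = one_cont$y),
               "one-way ANOVA")

  # container label in two treatments violates nesting
  bad <- sim_table(2, 2, 3)
  bad$container[1] <- bad$container[nrow(bad)]
  expect_error(nested_anova(bad, response = bad$y), "nest")

  # zero container MS with a real treatment effect: infinite F, p -> 0
  d <- expand.grid(ind = 1:3, container = 1:2, treatment = c("a", "b"))
  d$container <- paste(d$treatment, d$container)
  d$y <- ifelse(d$treatment == "a", d$ind, d$ind + 10)  # containers identical
  an <- nested_anova(d, response = d$y)
  expect_true(an$degenerate)
  expect_identical(an$F, Inf)
  expect_identical(an$p_value, 0)
})

test_that("nested ANOVA rejects ~5% of true nulls (type-I calibration)", {
  set.seed(503)
  nrep <- 400
  rej <- 0
  for (i in seq_len(nrep)) {
    tab <- sim_table(6, 3, 10)
    an <- nested_anova(tab, response = tab$y)
    if (an$p_value < 0.05) rej <- rej + 1
  }
  rate <- rej / nrep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.075)
})

test_that("assumption checks: Brown-Forsythe limits and Shapiro calibration", {
  # identical values in every group: zero spread deviations
  tab <- sim_table(3, 2, 4)
  tab$y <- rep(c(1, 2, 3), each = 8)
  ck <- check_assumptions(tab, response = tab$y)
  expect_identical(ck$brown_forsythe_f, 0)
  expect_identical(ck$brown_forsythe_p, 1)
  expect_true(is.na(ck$shapiro_p))

  # zero within-group spread but unequal deviations: flagged degenerate
  tab2 <- sim_table(2, 2, 4)
  tab2$y <- c(rep(1, 8), rep(c(0, 2), 4))  # devs {0,...} vs {1,...}
  expect_error(check_assumptions(tab2, response = tab2$y), "degenerate")

  # type-I calibration of Shapiro-Wilk on normal residuals
  set.seed(504)
  rej <- 0
  for (i in 1:200) {
    tab3 <- sim_table(2, 2, 50)
    if (check_assumptions(tab3, response = tab3$y)$shapiro_p < 0.05)
      rej <- rej + 1
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.09)
})

test_that("Brown-Forsythe equals Levene-with-medians computed by hand", {
  set.seed(505)
  tab <- sim_table(3, 2, 6, treat_effects = c(0, 1, 2))
  tab$y[tab$treatment == "t03"] <- tab$y[tab$treatment == "t03"] * 3
  ck <- check_assumptions(tab, response = tab$y)
  z <- unlist(lapply(split(tab$y, tab$treatment),
                     function(v) abs(v - median(v))))
  g <- factor(rep(names(split(tab$y, tab$treatment)),
                  times = lengths(split(tab$y, tab$treatment))))
  ref <- anova(lm(z ~ g))
  expect_equal(ck$brown_forsythe_f, ref$`F value`[1])
  expect_equal(ck$brown_forsythe_p, ref$`Pr(>F)`[1])
})

test_that("Tukey post hoc: identical data, k = 2 equivalence, shifted group", {
  # identical data in both treatments -> all adjusted p = 1
  tab <- sim_table(2, 2, 4)
  tab$y <- rep(c(1, 2, 3, 4), 4)
  an <- nested_anova(tab, response = tab$y)
  tk <- tukey_posthoc(tab, an, response = tab$y)
  expect_equal(tk$p_adj, 1)

  # k = 2: studentized-range p equals the ANOVA F-test p (q^2 = 2F)
  set.seed(506)
  tab2 <- sim_table(2, 3, 5, treat_effects = c(0, 0.8), container_sd = 0.3)
  an2 <- nested_anova(tab2, response = tab2$y)
  tk2 <- tukey_posthoc(tab2, an2, response = tab2$y)
  expect_equal(tk2$q^2, 2 * an2$F, tolerance = 1e-10)
  # ptukey is evaluated by numerical quadrature; agreement with pf is ~1e-5
  expect_equal(tk2$p_adj, an2$p_value, tolerance = 1e-4)

  # one treatment shifted by 3 sigma: its two pairs significant, other not;
  # cross-checked against an exhaustive container-level permutation oracle
  set.seed(507)
  tab3 <- sim_table(3, 2, 5, treat_effects = c(0, 0, 3), container_sd = 1)
  an3 <- nested_anova(tab3, response = tab3$y)
  tk3 <- tukey_posthoc(tab3, an3, response = tab3$y)
  shifted <- tk3$treatment_a == "t03" | tk3$treatment_b == "t03"
  expect_true(all(tk3$p_adj[shifted] < 0.05))
  expect_true(all(tk3$p_adj[!shifted] > 0.05))

  conts <- unique(tab3$container)
  labs <- rep(c("t01", "t02", "t03"), each = 2)
  perms <- unique(combinat_perms(labs))
  f_obs <- an3$F
  f_perm <- vapply(perms, function(pp) {
    t2 <- tab3
    t2$treatment <- pp[match(t2$container, conts)]
    nested_anova(t2, response = t2$y)$F
  }, numeric(1))
  # F is invariant to renaming the three labels, so the 90 assignments
  # collapse to 15 distinct partitions and the smallest attainable
  # permutation p is 6/90; the observed F must sit at that extreme.
  p_perm <- mean(f_perm >= f_obs - 1e-12)
  expect_lte(p_perm, 6 / 90 + 1e-9)
  expect_lt(an3$p_value, 0.05)
})

test_that("pooled two-sample t-test: limits and summary-statistic oracle", {
  expect_identical(two_sample_t(c(1, 2, 3), c(1, 2, 3) + 0)$df, 4L)
  same <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(two_sample_t(c(2, 2), c(3, 3)), "degenerate")

  # construct n = 4 groups with exact means/SDs like a printed summary
  mk <- function(m, s) m + s * scale(c(-1.2, -0.3, 0.4, 1.1))[, 1] /
    sd(scale(c(-1.2, -0.3, 0.4, 1.1))[, 1])
  a <- mk(2.69, 1.07); b <- mk(2.61, 1.14)
  res <- two_sample_t(a, b)
  sp <- sqrt((3 * 1.07^2 + 3 * 1.14^2) / 6)
  t_summary <- (2.69 - 2.61) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$t, t_summary, tolerance = 1e-10)
  expect_identical(res$df, 6L)
  expect_equal(res$p, 2 * pt(abs(t_summary), 6, lower.tail = FALSE))
})

test_that("treatment means back-transform to percent", {
  tab <- data.frame(treatment = rep(c("a", "b"), each = 4),
                    container = rep(c("a1", "a2", "b1", "b2"), each = 2),
                    ros_percent = c(rep(4, 4), rep(25, 4)))
  tm <- treatment_means(tab)
  expect_equal(tm$mean_ros_percent, c(4, 25), tolerance = 1e-9)
})
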