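#' Arcsine square-root transform for proportions
#'
#' `arcsin(sqrt(p))`, the classical variance-stabilising transform for
#' proportion data, applied to `ros_percent / 100` before ANOVA. Strictly
#' increasing on \[0, 1\], mapping onto \[0, pi/2\].
#'
#' @param p proportions in \[0, 1\] (vectorised).
#' @return transformed values.
#' @export
arcsine_sqrt <- function(p) {
  if (anyNA(p) || any(!is.finite(p))) stop("proportions must be finite")
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Back-transform arcsine square-root values to proportions
#' @param x transformed values in \[0, pi/2\].
#' @return proportions `sin(x)^2`.
#' @export
backtransform_arcsine <- function(x) sin(x)^2

# Validate + normalise an individuals x {treatment, container, response}
# table. Containers must nest cleanly: each container label belongs to
# exactly one treatment.
check_table <- function(table, response) {
  stopifnot(is.data.frame(table),
            all(c("treatment", "container") %in% names(table)))
  if (is.null(response)) {
    if (!"ros_percent" %in% names(table))
      stop("table needs a ros_percent column (or pass `response`)")
    response <- arcsine_sqrt(table$ros_percent / 100)
  }
  if (length(response) != nrow(table))
    stop("response length must match table rows")
  if (anyNA(response) || any(!is.finite(response)))
    stop("responses must be finite")
  map <- unique(table[, c("treatment", "container")])
  if (anyDuplicated(map$container))
    stop("containers must nest within treatments: container label(s) ",
         paste(unique(map$container[duplicated(map$container)]),
               collapse = ", "),
         " appear in more than one treatment")
  list(treatment = factor(table$treatment),
       container = factor(paste(table$treatment, table$container, sep = "/")),
       y = as.numeric(response))
}

#' Nested one-way ANOVA with container as a random factor within treatment
#'
#' Two-level nested decomposition of the response: between treatments, among
#' containers within treatments, and among individuals within containers.
#' Because container is a random factor, the expected-mean-squares rules put
#' the treatment test over the among-container mean square:
#' `F = MS_treatment / MS_container` on
#' `(df_treatment, df_container)` degrees of freedom.
#'
#' @param table an experiment table with `treatment` and `container` columns
#'   (and `ros_percent` when `response` is not given).
#' @param response numeric response vector; defaults to
#'   `arcsine_sqrt(ros_percent / 100)`.
#' @return a `nested_anova` object: sums of squares, degrees of freedom, mean
#'   squares, `F`, `p_value`, plus a `degenerate` flag when the container
#'   mean square vanishes under a non-zero treatment effect.
#' @export
nested_anova <- function(table, response = NULL) {
  d <- check_table(table, response)
  a <- nlevels(droplevels(d$treatment))
  if (a < 2L) stop("need at least 2 treatments")
  cont <- droplevels(d$container)
  b_tot <- nlevels(cont)
  n_tot <- length(d$y)
  df_treatment <- a - 1L
  df_container <- b_tot - a
  df_residual <- n_tot - b_tot
  if (df_container < 1L)
    stop("no replicate containers within treatments (df_container = 0); ",
         "use a one-way ANOVA instead")
  grand <- mean(d$y)
  if (all(d$y == d$y[1L]))
    stop("degenerate input: all observations identical, F undefined")
  t_means <- tapply(d$y, d$treatment, mean)
  t_n <- tabulate(d$treatment)
  c_means <- tapply(d$y, cont, mean)
  c_n <- tabulate(cont)
  c_trt <- tapply(as.integer(d$treatment), cont, `[`, 1L)
  ss_treatment <- sum(t_n * (t_means - grand)^2)
  ss_container <- sum(c_n * (c_means - t_means[c_trt])^2)
  ss_residual <- sum((d$y - c_means[cont])^2)
  balanced <- length(unique(c_n)) == 1L &&
    length(unique(tabulate(factor(c_trt)))) == 1L
  if (!balanced)
    warning("unbalanced design: nested SS additivity is approximate")
  ms_treatment <- ss_treatment / df_treatment
  ms_container <- ss_container / df_container
  ms_residual <- if (df_residual > 0) ss_residual / df_residual else NA_real_
  degenerate <- ms_container == 0
  f <- if (degenerate && ms_treatment > 0) Inf else ms_treatment / ms_container
  p <- if (is.infinite(f)) 0 else pf(f, df_treatment, df_container,
                                     lower.tail = FALSE)
  structure(list(
    ss_treatment = ss_treatment, ss_container = ss_container,
    ss_residual = ss_residual, df_treatment = df_treatment,
    df_container = df_container, df_residual = df_residual,
    ms_treatment = ms_treatment, ms_container = ms_container,
    ms_residual = ms_residual, F = f, p_value = p,
    degenerate = degenerate, n = n_tot, k = a,
    treatment_means = t_means, treatment_n = t_n,
    container_means = c_means), class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Nested one-way ANOVA (container random, nested in treatment)\n")
  tab <- data.frame(
    Df = c(x$df_treatment, x$df_container, x$df_residual),
    `Sum Sq` = c(x$ss_treatment, x$ss_container, x$ss_residual),
    `Mean Sq` = c(x$ms_treatment, x$ms_container, x$ms_residual),
    check.names = FALSE,
    row.names = c("treatment", "container(treatment)", "residual"))
  print(tab)
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g  [treatment over MS container]\n",
              x$df_treatment, x$df_container, x$F, x$p_value))
  if (x$degenerate) cat("note: zero container mean square (degenerate)\n")
  invisible(x)
}

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk on the residuals of the nested model (observation minus its
#' container mean) and the Brown-Forsythe test (Levene's test with group
#' medians as centres) on absolute deviations across treatments.
#'
#' @inheritParams nested_anova
#' @return list with `shapiro_w`, `shapiro_p`, `brown_forsythe_f`,
#'   `brown_forsythe_df`, `brown_forsythe_p`.
#' @export
check_assumptions <- function(table, response = NULL) {
  d <- check_table(table, response)
  if (length(d$y) < 3L) stop("need at least 3 observations")
  if (nlevels(droplevels(d$treatment)) < 2L)
    stop("need at least 2 treatments for Brown-Forsythe")
  resid <- as.numeric(d$y - tapply(d$y, d$container, mean)[d$container])
  if (diff(range(resid)) > 0) {
    sw <- shapiro.test(resid)
    shapiro_w <- unname(sw$statistic); shapiro_p <- sw$p.value
  } else {
    # zero-variance residuals: normality is undefined, not rejected
    shapiro_w <- NA_real_; shapiro_p <- NA_real_
  }
  g <- droplevels(d$treatment)
  z <- abs(d$y - tapply(d$y, g, median)[g])
  k <- nlevels(g)
  n <- length(z)
  zb <- tapply(z, g, mean)
  ng <- tabulate(g)
  ss_b <- sum(ng * (zb - mean(z))^2)
  ss_w <- sum((z - zb[g])^2)
  if (ss_b == 0 && ss_w == 0) {
    bf_f <- 0; bf_p <- 1
  } else if (ss_w == 0) {
    stop("degenerate input: zero within-group spread with unequal ",
         "between-group deviations")
  } else {
    bf_f <- (ss_b / (k - 1)) / (ss_w / (n - k))
    bf_p <- pf(bf_f, k - 1, n - k, lower.tail = FALSE)
  }
  list(shapiro_w = shapiro_w, shapiro_p = shapiro_p,
       brown_forsythe_f = bf_f, brown_forsythe_df = c(k - 1L, n - k),
       brown_forsythe_p = bf_p)
}

#' Tukey HSD post hoc on treatment means over the nested error term
#'
#' All pairwise treatment comparisons with the studentized-range
#' distribution, using the ANOVA's error term (`MS_container` on
#' `df_container`) for consistency of inference level. Unequal treatment
#' sizes are handled Tukey-Kramer style via per-treatment individual counts.
#'
#' @param table the experiment table the ANOVA was computed on.
#' @param anova the corresponding [nested_anova] result.
#' @param response numeric response vector; defaults to
#'   `arcsine_sqrt(ros_percent / 100)`.
#' @return a `data.frame` of class `tukey_result`: one row per unordered
#'   treatment pair with mean difference (transformed scale), studentized
#'   range statistic `q` and adjusted p-value.
#' @export
tukey_posthoc <- function(table, anova, response = NULL) {
  stopifnot(inherits(anova, "nested_anova"))
  d <- check_table(table, response)
  g <- droplevels(d$treatment)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 treatments")
  means <- tapply(d$y, g, mean)
  ns <- tabulate(g)
  if (!isTRUE(all.equal(unname(sort(means)),
                        unname(sort(anova$treatment_means)))))
    warning("table does not appear to match the supplied ANOVA")
  pairs <- utils::combn(levels(g), 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- match(pr[1L], levels(g)); j <- match(pr[2L], levels(g))
    diff <- means[i] - means[j]
    se <- sqrt(anova$ms_container / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (se > 0) abs(diff) / se else if (abs(diff) < 1e-12) 0 else Inf
    p <- if (is.infinite(q)) 0
    else ptukey(q, k, anova$df_container, lower.tail = FALSE)
    data.frame(treatment_a = pr[1L], treatment_b = pr[2L],
               diff = unname(diff), q = unname(q), p_adj = unname(p))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Pooled-variance two-sample Student's t-test
#'
#' Classical equal-variance t with `df = n_a + n_b - 2` and a two-sided
#' p-value (the form used for a paired control comparison such as an
#' anaesthetic check).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  dm <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, df = df, p = 1))
    stop("degenerate input: zero pooled variance with unequal means")
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Back-transformed treatment means for reporting
#'
#' Group means are computed on the transformed scale (where the inference
#' lives) and mapped back to percent via `sin^2`.
#'
#' @inheritParams nested_anova
#' @return `data.frame` with `treatment`, `n`, `mean_transformed`,
#'   `mean_ros_percent`.
#' @export
treatment_means <- function(table, response = NULL) {
  d <- check_table(table, response)
  g <- droplevels(d$treatment)
  m <- tapply(d$y, g, mean)
  data.frame(treatment = levels(g), n = tabulate(g),
             mean_transformed = unname(m),
             mean_ros_percent = unname(100 * backtransform_arcsine(m)))
}
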