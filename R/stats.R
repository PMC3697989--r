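#' Lilliefors-corrected Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the data (Lilliefors correction for the estimated
#' parameters), the usual screen before parametric group comparisons.
#'
#' @param values numeric sample, n >= 4, non-constant.
#' @return List: `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("need at least 4 observations")
  if (sd(values) == 0) stop("constant data: normality is undefined")
  t <- nortest::lillie.test(values)
  list(statistic = unname(t$statistic), p_value = t$p.value,
       n = length(values))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA computed from sums of squares:
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom.
#' Group means are reported with SEM (`SD / sqrt(n)`), the convention
#' of physiology tables.
#'
#' @param values numeric endpoint values.
#' @param groups group labels (coerced to factor), >= 2 groups with
#'   >= 2 values each.
#' @return A list of class `anova_result`: `f`, `df1`, `df2`,
#'   `p_value`, `ms_within`, `group_means`, `group_sem`, `group_n`,
#'   `degenerate` (TRUE when within-group variance is zero).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  n_g <- tapply(values, groups, length)
  if (nlevels(groups) < 2 || any(n_g < 2))
    stop("need >= 2 groups with >= 2 values each")
  k <- nlevels(groups)
  n <- length(values)
  m_g <- tapply(values, groups, mean)
  sd_g <- tapply(values, groups, sd)
  grand <- mean(values)
  ss_b <- sum(n_g * (m_g - grand)^2)
  ss_w <- sum((values - m_g[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  ms_b <- ss_b / df1
  ms_w <- ss_w / df2
  degenerate <- ms_w == 0
  f <- if (degenerate && ms_b == 0) 0 else ms_b / ms_w
  structure(list(
    f = f, df1 = df1, df2 = df2,
    p_value = if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE)
              else NA_real_,
    ms_within = ms_w,
    group_means = m_g, group_sem = sd_g / sqrt(n_g), group_n = n_g,
    degenerate = degenerate
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$f, x$p_value))
  invisible(x)
}

#' Student-Newman-Keuls post-hoc test
#'
#' Step-down studentized-range procedure: group means are sorted and
#' pairs spanning `r` ordered means are compared against
#' `q(1 - alpha, r, df_within) * sqrt(MS_within / n_h)` with `n_h` the
#' harmonic mean group size; a non-significant span protects all pairs
#' nested inside it.  Run unconditionally, with a flag when the omnibus
#' ANOVA is itself non-significant.
#'
#' @param values,groups as in [one_way_anova()].
#' @param anova optional precomputed [one_way_anova()] result.
#' @param alpha significance level.
#' @return A data frame of class `snk_result` with one row per pair:
#'   `group1`, `group2`, `diff`, `span`, `q_obs`, `q_crit`,
#'   `significant`; attributes `omnibus_significant`, `unequal_n`.
#' @export
snk_posthoc <- function(values, groups, anova = NULL, alpha = 0.05) {
  groups <- factor(groups)
  if (is.null(anova)) anova <- one_way_anova(values, groups)
  if (anova$degenerate) {
    m <- sort(anova$group_means)
    k <- length(m)
    pairs <- utils::combn(k, 2)
    out <- data.frame(
      group1 = names(m)[pairs[1, ]], group2 = names(m)[pairs[2, ]],
      diff = m[pairs[2, ]] - m[pairs[1, ]],
      span = pairs[2, ] - pairs[1, ] + 1,
      q_obs = NA_real_, q_crit = NA_real_,
      significant = m[pairs[2, ]] != m[pairs[1, ]])
  } else {
    m <- sort(anova$group_means)
    k <- length(m)
    n_h <- k / sum(1 / anova$group_n)
    se <- sqrt(anova$ms_within / n_h)
    pairs <- utils::combn(k, 2)
    out <- data.frame(
      group1 = names(m)[pairs[1, ]], group2 = names(m)[pairs[2, ]],
      diff = unname(m[pairs[2, ]] - m[pairs[1, ]]),
      span = pairs[2, ] - pairs[1, ] + 1)
    out$q_obs <- abs(out$diff) / se
    out$q_crit <- qtukey(1 - alpha, out$span, anova$df2)
    out$significant <- out$q_obs > out$q_crit
    # step-down protection: a non-significant span shields nested pairs
    for (r in sort(unique(out$span), decreasing = TRUE)) {
      ns <- which(out$span == r & !out$significant)
      for (idx in ns) {
        i <- pairs[1, idx]
        j <- pairs[2, idx]
        nested <- pairs[1, ] >= i & pairs[2, ] <= j
        out$significant[nested] <- FALSE
      }
    }
  }
  attr(out, "omnibus_significant") <-
    is.finite(anova$p_value) && anova$p_value < alpha
  attr(out, "unequal_n") <- length(unique(anova$group_n)) > 1
  class(out) <- c("snk_result", "data.frame")
  out
}

#' Repeated-measures (group x time) ANOVA
#'
#' Mixed two-way ANOVA with subject as the repeated factor, fitted via
#' `aov` with an `Error(subject)` stratum: group is tested between
#' subjects, time and group:time within subjects.  With only two time
#' points sphericity holds trivially and no correction is applied.
#' Subjects with missing values are excluded listwise with a warning.
#'
#' @param data data frame with columns `subject`, `group`, `time`,
#'   `value` (one row per subject x time).
#' @return A list of class `rm_anova_result` with per-effect `f`, `df`
#'   and `p_value` for `group`, `time` and `group_time`.
#' @export
repeated_measures <- function(data) {
  stopifnot(all(c("subject", "group", "time", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$time <- factor(data$time)
  n_t <- nlevels(data$time)
  complete <- names(which(tapply(!is.na(data$value), data$subject, sum)
                          == n_t))
  if (length(complete) < nlevels(data$subject)) {
    warning(sprintf("excluding %d subject(s) with missing time points",
                    nlevels(data$subject) - length(complete)))
    data <- data[data$subject %in% complete, ]
    data$subject <- droplevels(data$subject)
  }
  one_group <- nlevels(data$group) < 2
  form <- if (one_group) value ~ time + Error(subject)
          else value ~ group * time + Error(subject)
  fit <- aov(form, data = data)
  s <- summary(fit)
  tabs <- lapply(s, function(z) as.data.frame(z[[1]]))
  all_rows <- do.call(rbind, tabs)
  pick <- function(name) {
    i <- which(trimws(rownames(all_rows)) == name |
               grepl(paste0("\\.", name, "$"), trimws(rownames(all_rows))))
    if (!length(i)) return(NULL)
    r <- all_rows[i[1], ]
    list(f = r[["F value"]], df1 = r[["Df"]], p_value = r[["Pr(>F)"]])
  }
  structure(list(
    group = if (one_group) NULL else pick("group"),
    time = pick("time"),
    group_time = if (one_group) NULL else pick("group:time"),
    n_subjects = length(unique(data$subject))
  ), class = "rm_anova_result")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors, n >= 3, finite, non-constant.
#' @return List: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  t <- cor.test(x, y, method = "pearson")
  list(r = unname(t$estimate), p_value = t$p.value, n = length(x))
}
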