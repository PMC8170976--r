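# Group-statistics layer: Shapiro-Wilk normality gate, equal-variance
# Student's t with Cohen's d, two-way ANOVA, and cohort comparison tables.

#' Shapiro-Wilk normality gate
#'
#' Tests each group for normality. Groups with fewer than 3 observations are
#' skipped with a warning. The gate records, it does not switch tests:
#' downstream comparisons still use Student's t, and a non-normal group
#' triggers a logged warning.
#'
#' @param groups named list of numeric vectors.
#' @param alpha gate level.
#' @return data.frame: group, n, shapiro_p, normal (NA where skipped).
#' @export
shapiro_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups))
  out <- data.frame(group = names(groups) %||% as.character(seq_along(groups)),
                    n = vapply(groups, length, integer(1)),
                    shapiro_p = NA_real_, normal = NA,
                    stringsAsFactors = FALSE)
  for (k in seq_along(groups)) {
    x <- groups[[k]]
    if (length(x) < 3) {
      warning(sprintf("group '%s' has n < 3: normality gate skipped",
                      out$group[k]))
      next
    }
    p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    if (is.na(p)) {
      warning(sprintf("group '%s': Shapiro-Wilk not computable (constant data?)",
                      out$group[k]))
      next
    }
    out$shapiro_p[k] <- p
    out$normal[k] <- p > alpha
    if (p <= alpha) {
      warning(sprintf("group '%s' fails the normality gate (Shapiro-Wilk p = %.3g)",
                      out$group[k], p))
    }
  }
  out
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' `cohens_d_summary()` computes the same quantity from group summaries
#' (n, mean, sd), so printed summary tables can be used directly.
#'
#' @param a,b numeric vectors.
#' @return Cohen's d (sign follows `mean_a - mean_b`); `NA` with a warning if
#'   the pooled variance is zero.
#' @export
cohens_d <- function(a, b) {
  cohens_d_summary(length(a), mean(a), stats::sd(a),
                   length(b), mean(b), stats::sd(b))
}

#' @rdname cohens_d
#' @param n_a,mean_a,sd_a,n_b,mean_b,sd_b group summaries.
#' @export
cohens_d_summary <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b) {
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) {
    warning("zero pooled variance: Cohen's d undefined")
    return(NA_real_)
  }
  (mean_a - mean_b) / sp
}

#' Two-group comparison (Student's t, Cohen's d, stars)
#'
#' Equal-variance two-sided Student's t-test with Cohen's d and the
#' conventional star labels. A Welch test is available behind `var_equal =
#' FALSE`. The Shapiro-Wilk gate is run on both groups (n >= 3) and recorded;
#' it never switches the test.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param labels length-2 character: names for groups a and b.
#' @param var_equal use the pooled-variance Student's t (default) or Welch.
#' @param gate run the Shapiro-Wilk gate (default TRUE).
#' @return one-row data.frame of class `group_comparison`: group labels, n,
#'   means, sds, shapiro p per group, t_statistic, p_value, cohens_d,
#'   test_used, stars.
#' @export
two_group_test <- function(a, b, labels = c("a", "b"), var_equal = TRUE,
                           gate = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sw <- if (gate) {
    g <- suppressWarnings(shapiro_gate(stats::setNames(list(a, b), labels)))
    g$shapiro_p
  } else c(NA_real_, NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else NA_real_),
               p.value = if (mean(a) == mean(b)) 1 else NA_real_)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  d <- suppressWarnings(cohens_d(a, b))
  out <- data.frame(
    group_a = labels[1], group_b = labels[2],
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    sd_a = stats::sd(a), sd_b = stats::sd(b),
    shapiro_p_a = sw[1], shapiro_p_b = sw[2],
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    cohens_d = d,
    test_used = if (var_equal) "student_t" else "welch_t",
    stars = p_stars(tt$p.value),
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Two-way ANOVA effect table
#'
#' Standard two-way decomposition (main effects and interaction) via
#' `stats::aov`. With a single observation per cell the interaction is not
#' estimable: the additive model is fitted and the interaction row is reported
#' missing. Designs with empty cells are rejected.
#'
#' @param data data.frame containing the columns named below.
#' @param value,factor1,factor2 column names (character).
#' @return data.frame: effect, df, f_statistic, p_value, stars.
#' @export
two_way_anova <- function(data, value, factor1, factor2) {
  stopifnot(all(c(value, factor1, factor2) %in% names(data)))
  f1 <- factor(data[[factor1]]); f2 <- factor(data[[factor2]])
  if (nlevels(f1) < 2 || nlevels(f2) < 2) stop("need >= 2 levels per factor")
  cells <- table(f1, f2)
  if (any(cells == 0)) stop("empty factor cells are not supported")
  df <- data.frame(y = data[[value]], f1 = f1, f2 = f2)
  with_interaction <- min(cells) >= 2
  form <- if (with_interaction) y ~ f1 * f2 else y ~ f1 + f2
  tab <- summary(stats::aov(form, data = df))[[1]]
  eff <- trimws(rownames(tab))
  pick <- function(name) {
    i <- match(name, eff)
    if (is.na(i)) c(NA_real_, NA_real_, NA_real_) else
      c(tab$Df[i], tab$`F value`[i], tab$`Pr(>F)`[i])
  }
  rows <- rbind(pick("f1"), pick("f2"), pick("f1:f2"))
  out <- data.frame(effect = c(factor1, factor2,
                               paste0(factor1, ":", factor2)),
                    df = rows[, 1], f_statistic = rows[, 2],
                    p_value = rows[, 3],
                    stars = p_stars(rows[, 3]),
                    stringsAsFactors = FALSE)
  attr(out, "interaction_estimable") <- with_interaction
  out
}

#' Endpoint-wise two-group comparison of cohort summaries
#'
#' Takes a data.frame of per-animal endpoint values (e.g. motility summaries
#' or quantification tables) plus a group column, and runs [two_group_test()]
#' per endpoint. Missing endpoint values are excluded pairwise and the
#' remaining counts reported.
#'
#' @param df data.frame of endpoints plus a grouping column.
#' @param endpoints character vector of endpoint column names.
#' @param group name of the grouping column (exactly two levels, n >= 2 each).
#' @return data.frame with one `group_comparison` row per endpoint, prefixed
#'   by the endpoint name and the non-missing counts.
#' @export
compare_cohorts <- function(df, endpoints, group = "group") {
  stopifnot(group %in% names(df), all(endpoints %in% names(df)))
  g <- df[[group]]
  lev <- unique(g)
  if (length(lev) != 2) stop("need exactly two groups")
  rows <- lapply(endpoints, function(ep) {
    a <- df[[ep]][g == lev[1]]; b <- df[[ep]][g == lev[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      stop(sprintf("endpoint '%s' has < 2 non-missing values in a group", ep))
    }
    cbind(endpoint = ep,
          suppressWarnings(two_group_test(a, b, labels = as.character(lev))))
  })
  do.call(rbind, rows)
}
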