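#' Summary statistics for one group of replicates
#'
#' All tests in pgscreen run either from raw replicate vectors or from
#' published summary statistics (n, mean, sample SD) — the form screen
#' aggregates are reported in. This constructor builds the summary form.
#'
#' @param label Group label.
#' @param n Number of replicates (>= 2 for testing).
#' @param mean Group mean.
#' @param sd Sample (n - 1) standard deviation.
#' @return A one-row tibble with columns `label`, `n`, `mean`, `sd`.
#' @export
group_stats <- function(label, n, mean, sd) {
  stopifnot(n >= 1, sd >= 0 || is.na(sd))
  tibble::tibble(label = as.character(label), n = as.integer(n),
                 mean = as.numeric(mean), sd = as.numeric(sd))
}

# Coerce a raw numeric vector, a one-row stats frame, or a list with
# n/mean/sd into the canonical one-row group-stats tibble.
as_group_stats <- function(x, label = "group") {
  if (is.numeric(x)) {
    if (length(x) < 2) abort(paste0("group '", label, "' needs >= 2 observations"))
    return(group_stats(label, length(x), mean(x), sd(x)))
  }
  x <- tibble::as_tibble(as.list(x)[c(
    intersect(c("label", "n", "mean", "sd"), names(x))
  )])
  if (!all(c("n", "mean", "sd") %in% names(x))) {
    abort("summary-form groups need fields n, mean, sd")
  }
  if (!"label" %in% names(x)) x$label <- label
  if (any(x$n < 2)) abort("every group needs n >= 2")
  x[c("label", "n", "mean", "sd")]
}

# Normalize a groups argument (named list of raw vectors, or a data frame of
# summary rows) into a stats tibble plus the raw data when available.
normalize_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stats <- dplyr::bind_rows(lapply(seq_len(nrow(groups)), function(i) {
      as_group_stats(groups[i, ], label = as.character(groups$label[i] %||% i))
    }))
    return(list(stats = stats, raw = NULL))
  }
  if (!is.list(groups)) abort("groups must be a named list of numeric vectors or a summary data frame")
  labels <- names(groups) %||% as.character(seq_along(groups))
  labels[labels == ""] <- as.character(which(labels == ""))
  stats <- dplyr::bind_rows(purrr::map2(groups, labels, as_group_stats))
  list(stats = stats, raw = setNames(groups, labels))
}

test_result <- function(method, statistic, df, p_value, adjusted = FALSE, ...) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p_value = p_value, adjusted = adjusted, ...)
}

#' One-way analysis of variance
#'
#' Ordinary (equal-variance) one-way ANOVA across k groups, from raw
#' replicate vectors or from summary statistics. The two forms are
#' algebraically identical: the between- and within-group sums of squares
#' depend on the data only through each group's n, mean, and sample SD.
#'
#' @param groups Either a named list of numeric vectors (raw form) or a data
#'   frame with columns `label`, `n`, `mean`, `sd` (summary form).
#' @return A one-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `adjusted = FALSE`. When every group has zero variance and
#'   all means are equal, F is defined as 0 with p = 1.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' one_way_anova(data.frame(label = c("a", "b"), n = 3, mean = c(2, 3), sd = 1))
#' @export
one_way_anova <- function(groups) {
  g <- normalize_groups(groups)
  stats <- g$stats
  if (nrow(stats) < 2) abort("ANOVA needs >= 2 groups")
  k <- nrow(stats); N <- sum(stats$n)
  df1 <- k - 1; df2 <- N - k
  if (!is.null(g$raw) && any(stats$sd > 0)) {
    y <- unlist(g$raw, use.names = FALSE)
    grp <- factor(rep(names(g$raw), lengths(g$raw)))
    tab <- anova(lm(y ~ grp))
    f <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
  } else {
    # summary route; also used for the degenerate zero-residual-variance
    # case, where lm's F on an exact fit is floating-point noise
    grand <- sum(stats$n * stats$mean) / N
    ssb <- sum(stats$n * (stats$mean - grand)^2)
    ssw <- sum((stats$n - 1) * stats$sd^2)
    msb <- ssb / df1; msw <- ssw / df2
    if (msw == 0) {
      f <- if (msb == 0) 0 else Inf
      p <- if (msb == 0) 1 else 0
    } else {
      f <- msb / msw
      p <- pf(f, df1, df2, lower.tail = FALSE)
    }
  }
  tibble::tibble(method = "one-way ANOVA", statistic = f, df1 = df1, df2 = df2,
                 p_value = p, adjusted = FALSE)
}

welch_from_stats <- function(a, b) {
  se2a <- a$sd^2 / a$n; se2b <- b$sd^2 / b$n
  se2 <- se2a + se2b
  est <- a$mean - b$mean
  if (se2 == 0) {
    t <- if (est == 0) 0 else sign(est) * Inf
    df <- a$n + b$n - 2
  } else {
    t <- est / sqrt(se2)
    df <- se2^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p = p, estimate = est)
}

pooled_t_from_stats <- function(a, b) {
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  est <- a$mean - b$mean
  if (sp2 == 0) {
    t <- if (est == 0) 0 else sign(est) * Inf
  } else {
    t <- est / sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p = p, estimate = est)
}

two_sample_t <- function(a, b, var_equal, method_label) {
  raw <- is.numeric(a) && is.numeric(b)
  sa <- as_group_stats(a, "a"); sb <- as_group_stats(b, "b")
  if (raw && sd(a) + sd(b) > 0) {
    ht <- t.test(a, b, var.equal = var_equal)
    res <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, estimate = mean(a) - mean(b))
  } else {
    res <- if (var_equal) pooled_t_from_stats(sa, sb) else welch_from_stats(sa, sb)
  }
  test_result(method_label, res$statistic, res$df, res$p,
              adjusted = FALSE, estimate = res$estimate)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom, from raw
#' vectors or summary statistics. When both groups have zero variance and
#' equal means the statistic is 0 with p = 1.
#'
#' @param a,b Numeric replicate vectors, or summary forms accepted by
#'   [group_stats()] (a one-row data frame or list with `n`, `mean`, `sd`).
#' @return One-row tibble: `method`, `statistic`, `df` (fractional),
#'   `p_value`, `adjusted`, `estimate` (mean of `a` minus mean of `b`).
#' @export
welch_t <- function(a, b) {
  two_sample_t(a, b, var_equal = FALSE, method_label = "Welch two-sample t-test")
}

#' Student's pooled-variance two-sample t-test
#'
#' Classical equal-variance t-test with `n_a + n_b - 2` degrees of freedom,
#' from raw vectors or summary statistics.
#'
#' @inheritParams welch_t
#' @return One-row tibble as in [welch_t()].
#' @export
student_t <- function(a, b) {
  two_sample_t(a, b, var_equal = TRUE, method_label = "Student two-sample t-test")
}
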