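#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. In `"auto"` mode the exact null
#' distribution is used when both samples have at most 10 observations and
#' there are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction is used (the asymptotic p-values that group
#' comparison tables conventionally report).
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return object of class `trab_test`: `statistic` (U), `p`, `method`,
#'   `n` (per-sample sizes).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs at least 2 values")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = length(x) <= 10 && length(y) <= 10 && !ties,
                  exact = TRUE,
                  asymptotic = FALSE)
  if (exact && ties) stop("exact mode is unavailable with ties")
  if (length(unique(c(x, y))) == 1)
    return(structure(list(statistic = length(x) * length(y) / 2, p = 1,
                          method = "mann-whitney-degenerate",
                          n = c(length(x), length(y))), class = "trab_test"))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "mann-whitney-exact" else "mann-whitney-asymptotic",
                 n = c(length(x), length(y))),
            class = "trab_test")
}

#' Kruskal-Wallis H test
#'
#' Omnibus rank test across three (or more) groups with tie correction and
#' the chi-square asymptotic p-value. When all values are identical the
#' statistic is 0 and p = 1 by convention.
#'
#' @param groups list of numeric samples (>= 2 groups, each >= 2 values).
#' @return a `trab_test` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(structure(list(statistic = 0, p = 1, method = "kruskal-wallis",
                          n = lengths(groups)), class = "trab_test"))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(vals, g)
  structure(list(statistic = unname(kt$statistic), p = kt$p.value,
                 method = "kruskal-wallis", n = lengths(groups)),
            class = "trab_test")
}

#' Pearson correlation with two-tailed significance
#'
#' @param x,y numeric vectors (n >= 3, non-degenerate).
#' @return a `trab_test` with `statistic` = r and the two-tailed p from the
#'   t transform with n - 2 degrees of freedom.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need paired samples of size >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance sample")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(statistic = unname(ct$estimate), p = ct$p.value,
                 method = "pearson", n = length(x)),
            class = "trab_test")
}

#' @export
print.trab_test <- function(x, ...) {
  cat(sprintf("<trab_test> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Pooled total mean from per-level means
#'
#' With equal specimens per vertebral level, the pooled group mean over all
#' specimens equals the mean of the level means.
#'
#' @param level_means per-level mean values.
#' @param digits rounding for the reported value (default 1 decimal, the
#'   printed precision of group summary tables); NULL for no rounding.
#' @return pooled mean.
#' @export
pool_level_means <- function(level_means, digits = NULL) {
  m <- mean(level_means)
  if (!is.null(digits)) m <- round(m, digits)
  m
}

#' Group/level summary table with significance letters
#'
#' Builds the conventional two-group, three-level summary: per (group,
#' level, parameter) mean and SD, a pooled Total column per group,
#' between-group Mann-Whitney tests per level, and within-group level
#' comparisons (Kruskal-Wallis omnibus plus pairwise Mann-Whitney) emitting
#' letters a/b/c marking a significant difference from L4/L5/L6
#' respectively.
#'
#' @param data data.frame of tidy records with columns `specimen`, `group`,
#'   `level`, `parameter`, `value` (one value per specimen/level/parameter).
#' @param alpha significance level (default 0.05).
#' @param mode Mann-Whitney mode (default asymptotic, the reporting
#'   convention).
#' @return object of class `study_summary` with elements `cells` (per
#'   group/level/parameter mean, sd, n, letters), `totals`, `between_group`
#'   (per level/parameter p) and `within_group` (omnibus p per
#'   group/parameter).
#' @export
summarize_study <- function(data, alpha = 0.05, mode = "asymptotic") {
  need <- c("specimen", "group", "level", "parameter", "value")
  if (!all(need %in% names(data))) stop("missing columns: ",
                                        paste(setdiff(need, names(data)), collapse = ", "))
  if (anyNA(data$value)) stop("missing values in records")
  key <- interaction(data$specimen, data$group, data$level, data$parameter, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate (specimen, level, parameter) records")
  data <- data[order(data$group, data$level, data$parameter, data$specimen), ]
  groups <- sort(unique(data$group))
  levels_ <- sort(unique(data$level))
  params <- unique(data$parameter)
  letter_of <- setNames(letters[seq_along(levels_)], levels_)

  cells <- aggregate(value ~ group + level + parameter, data, function(v)
    c(mean = mean(v), sd = sd(v), n = length(v)))
  cells <- cbind(cells[, c("group", "level", "parameter")],
                 as.data.frame(cells$value))
  cells$letters <- ""

  totals <- aggregate(value ~ group + parameter, data, function(v)
    c(mean = mean(v), sd = sd(v), n = length(v)))
  totals <- cbind(totals[, c("group", "parameter")], as.data.frame(totals$value))

  pick <- function(g, l, p) data$value[data$group == g & data$level == l &
                                       data$parameter == p]
  between <- do.call(rbind, lapply(params, function(p) {
    do.call(rbind, lapply(levels_, function(l) {
      if (length(groups) != 2) return(NULL)
      a <- pick(groups[1], l, p)
      b <- pick(groups[2], l, p)
      if (length(unique(c(a, b))) == 1)
        return(data.frame(level = l, parameter = p, p_value = 1))
      data.frame(level = l, parameter = p,
                 p_value = mann_whitney_u(a, b, mode)$p)
    }))
  }))

  within <- if (length(levels_) < 2) NULL else
    do.call(rbind, lapply(params, function(p) {
    do.call(rbind, lapply(groups, function(g) {
      samples <- lapply(levels_, function(l) pick(g, l, p))
      data.frame(group = g, parameter = p,
                 p_value = kruskal_wallis(samples)$p)
    }))
  }))

  if (length(levels_) >= 2) for (p in params) for (g in groups) {
    for (i in seq_along(levels_)) for (j in seq_along(levels_)) {
      if (i == j) next
      a <- pick(g, levels_[i], p)
      b <- pick(g, levels_[j], p)
      if (length(unique(c(a, b))) == 1) next
      if (mann_whitney_u(a, b, mode)$p < alpha) {
        row <- cells$group == g & cells$level == levels_[i] & cells$parameter == p
        cells$letters[row] <- paste0(cells$letters[row], letter_of[levels_[j]])
      }
    }
  }
  structure(list(cells = cells, totals = totals, between_group = between,
                 within_group = within, alpha = alpha),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("<study_summary>\n")
  print(x$cells, row.names = FALSE)
  cat("Totals:\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}
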