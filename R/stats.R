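#' Variance-stabilizing transforms for proportions and ratios
#'
#' Proportions are arcsine-square-root transformed
#' (`asin(sqrt(p))`, mapping 0 to 0 and 1 to pi/2); ratios are natural-log
#' transformed, turning multiplicative shifts into additive ones. Raw values
#' pass through unchanged.
#'
#' @param values Numeric vector.
#' @param kind `"raw"`, `"proportion"` or `"ratio"`.
#' @return Transformed vector.
#' @export
transform_values <- function(values, kind = c("raw", "proportion", "ratio")) {
  kind <- match.arg(kind)
  if (kind == "raw") return(values)
  bad <- if (kind == "proportion") which(values < 0 | values > 1)
         else which(values <= 0)
  if (length(bad))
    stop(sprintf("value out of domain for %s transform at index %s",
                 kind, paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  if (kind == "proportion") asin(sqrt(values)) else log(values)
}

# Cohen's d with pooled SD
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

# Dunn's z-statistic post-hoc for Kruskal-Wallis, Bonferroni-adjusted
dunn_posthoc <- function(values, group) {
  g <- factor(group)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12) * tie_corr * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             z = res["z", ],
             p_adj = pmin(1, res["p", ] * ncol(pairs)),
             row.names = NULL)
}

#' Two- and multi-group comparisons as used across the study's figures
#'
#' Dispatches to the named design: Student's t (unpaired or paired),
#' Mann-Whitney U, one-way ANOVA with Tukey HSD post-hoc, Kruskal-Wallis
#' with Dunn's post test, or repeated-measures two-way ANOVA
#' (time x genotype with subjects). Two-group designs report Cohen's d with
#' pooled SD. Apply [transform_values()] beforehand for proportion or ratio
#' data.
#'
#' @param data Data frame with columns `value`, `group`, and for paired or
#'   repeated-measures designs `subject` (and `time` for the latter).
#' @param design One of `"two_group_t"`, `"paired_t"`, `"mann_whitney"`,
#'   `"anova_tukey"`, `"kruskal_dunn"`, `"rm_two_way_anova"`.
#' @return List of class `comparison_result`: `test_name`, `statistic`,
#'   `p_value`, `effect_size_d` (two-group designs), `posthoc` (multi-group
#'   designs).
#' @export
compare_groups <- function(data, design = c("two_group_t", "paired_t",
                                            "mann_whitney", "anova_tukey",
                                            "kruskal_dunn",
                                            "rm_two_way_anova")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(data), all(c("value", "group") %in% names(data)))
  g <- factor(data$group)
  v <- data$value
  two <- function() {
    if (nlevels(g) != 2L) stop("design needs exactly 2 groups", call. = FALSE)
    split(v, g)
  }
  res <- switch(design,
    two_group_t = {
      s <- two()
      if (any(lengths(s) < 2L)) stop("need n >= 2 per group", call. = FALSE)
      if (var(s[[1L]]) == 0 && var(s[[2L]]) == 0) {
        # degenerate: no within-group spread
        same <- isTRUE(all.equal(mean(s[[1L]]), mean(s[[2L]])))
        list(test_name = "Student t (unpaired)", statistic = if (same) 0 else Inf,
             p_value = if (same) 1 else 0, effect_size_d = 0)
      } else {
        tt <- t.test(s[[1L]], s[[2L]], var.equal = TRUE)
        list(test_name = "Student t (unpaired)",
             statistic = unname(tt$statistic),
             p_value = tt$p.value, effect_size_d = cohens_d(s[[1L]], s[[2L]]))
      }
    },
    paired_t = {
      if (!"subject" %in% names(data))
        stop("paired design needs a subject column", call. = FALSE)
      s <- split(data[order(data$subject), ], g[order(data$subject)])
      if (length(unique(lengths(lapply(s, function(d) d$value)))) != 1L)
        stop("paired design needs matched samples", call. = FALSE)
      d <- s[[1L]]$value - s[[2L]]$value
      if (sd(d) == 0) {
        same <- isTRUE(all.equal(mean(d), 0))
        list(test_name = "Student t (paired)",
             statistic = if (same) 0 else Inf,
             p_value = if (same) 1 else 0, effect_size_d = 0)
      } else {
        tt <- t.test(s[[1L]]$value, s[[2L]]$value, paired = TRUE)
        list(test_name = "Student t (paired)",
             statistic = unname(tt$statistic),
             p_value = tt$p.value, effect_size_d = mean(d) / sd(d))
      }
    },
    mann_whitney = {
      s <- two()
      wt <- wilcox.test(s[[1L]], s[[2L]], exact = FALSE, correct = TRUE)
      p <- wt$p.value
      if (is.nan(p)) p <- 1 # complete ties: no evidence of a shift
      list(test_name = "Mann-Whitney U", statistic = unname(wt$statistic),
           p_value = p, effect_size_d = cohens_d(s[[1L]], s[[2L]]))
    },
    anova_tukey = {
      if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
      fit <- aov(v ~ g)
      an <- summary(fit)[[1L]]
      tk <- TukeyHSD(fit)$g
      list(test_name = "one-way ANOVA + Tukey HSD",
           statistic = an[["F value"]][1L], p_value = an[["Pr(>F)"]][1L],
           posthoc = data.frame(contrast = rownames(tk),
                                diff = tk[, "diff"], p_adj = tk[, "p adj"],
                                row.names = NULL))
    },
    kruskal_dunn = {
      kt <- kruskal.test(v, g)
      list(test_name = "Kruskal-Wallis + Dunn",
           statistic = unname(kt$statistic), p_value = kt$p.value,
           posthoc = dunn_posthoc(v, g))
    },
    rm_two_way_anova = {
      if (!all(c("subject", "time") %in% names(data)))
        stop("repeated-measures design needs subject and time columns",
             call. = FALSE)
      d <- data
      d$subject <- factor(d$subject); d$time <- factor(d$time)
      d$group <- factor(d$group)
      fit <- aov(value ~ group * time + Error(subject/time), data = d)
      s <- summary(fit)
      tab <- tryCatch(s[["Error: subject:time"]][[1L]], error = function(e) NULL)
      btab <- tryCatch(s[["Error: subject"]][[1L]], error = function(e) NULL)
      p_time <- tab[grep("^time", rownames(tab))[1L], "Pr(>F)"]
      p_group <- btab[grep("^group", rownames(btab))[1L], "Pr(>F)"]
      list(test_name = "repeated-measures two-way ANOVA",
           statistic = tab[grep("^time", rownames(tab))[1L], "F value"],
           p_value = p_time,
           posthoc = data.frame(term = c("time", "group"),
                                p = c(p_time, p_group)))
    })
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g", x$test_name, x$statistic,
              x$p_value))
  if (!is.null(x$effect_size_d))
    cat(sprintf(", Cohen's d = %.3g", x$effect_size_d))
  cat("\n")
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' Tukey box-plot summary
#'
#' Median, quartiles, whiskers at the most extreme points within
#' `[q1 - 1.5 IQR, q3 + 1.5 IQR]`, and the points outside that fence flagged
#' as outliers — the box-plot convention used throughout the study.
#'
#' @param values Numeric vector (length >= 1).
#' @return List: `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
tukey_box <- function(values) {
  stopifnot(length(values) >= 1L)
  q1 <- unname(quantile(values, 0.25))
  q3 <- unname(quantile(values, 0.75))
  iqr <- q3 - q1
  lo_f <- q1 - 1.5 * iqr
  hi_f <- q3 + 1.5 * iqr
  inside <- values >= lo_f & values <= hi_f
  list(median = median(values), q1 = q1, q3 = q3,
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = values[!inside])
}
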