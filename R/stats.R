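#' Per-group summary statistics
#'
#' Container for the mean/SD/n triplets printed in clinical cohort tables;
#' SDs are assumed to use the n-1 denominator, the universal convention in
#' such tables.
#'
#' @param groups group labels.
#' @param means,sds,ns per-group means, SDs and counts (equal length).
#' @return A `group_summary` object.
#' @export
group_summary <- function(groups, means, sds, ns) {
  if (!all(lengths(list(means, sds, ns)) == length(groups)))
    stop("groups, means, sds and ns must have equal length")
  ns <- as.integer(ns)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("SDs must be >= 0")
  structure(list(groups = as.character(groups), means = as.numeric(means),
                 sds = as.numeric(sds), ns = ns),
            class = "group_summary")
}

#' Summarize raw grouped data
#'
#' @param values numeric vector of raw observations.
#' @param groups group label per observation.
#' @return A [group_summary()].
#' @export
summarize_groups <- function(values, groups) {
  sp <- split(as.numeric(values), as.character(groups))
  group_summary(names(sp),
                vapply(sp, mean, numeric(1)),
                vapply(sp, stats::sd, numeric(1)),
                vapply(sp, length, integer(1)))
}

stat_result <- function(statistic_name, value, df, p_value,
                        extra = list()) {
  structure(c(list(statistic_name = statistic_name, value = unname(value),
                   df = unname(df), p_value = unname(p_value)), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dftxt <- if (length(x$df)) paste0("(", paste(signif(x$df, 6), collapse = ","), ")") else ""
  cat(sprintf("%s%s = %.4g, p = %.4g\n", x$statistic_name, dftxt,
              x$value, x$p_value))
  invisible(x)
}

#' One-way ANOVA from printed summary statistics
#'
#' Classic (pooled) one-way ANOVA reconstructed from per-group means, SDs and
#' counts: the between-group sum of squares is taken around the
#' count-weighted grand mean, the within-group sum of squares is
#' `sum((n_g - 1) sd_g^2)`, and `F` has `(k - 1, N - k)` degrees of freedom.
#' Exactly equal to [one_way_anova()] on the raw data when the summaries are
#' exact; reconstruction from rounded printed values carries the input
#' rounding into the statistic.
#'
#' @param s a [group_summary()] with at least 2 groups.
#' @return A `stat_result` with statistic `F`.
#' @export
anova_from_summary <- function(s) {
  stopifnot(inherits(s, "group_summary"))
  k <- length(s$ns)
  if (k < 2L) stop("need at least 2 groups")
  N <- sum(s$ns)
  grand <- sum(s$ns * s$means) / N
  ssb <- sum(s$ns * (s$means - grand)^2)
  ssw <- sum((s$ns - 1) * s$sds^2)
  df <- c(k - 1L, N - k)
  Fv <- (ssb / df[1]) / (ssw / df[2])
  stat_result("F", Fv, df, stats::pf(Fv, df[1], df[2], lower.tail = FALSE))
}

#' Two-sample t test from printed summary statistics
#'
#' Pooled-variance (Student) two-sample t; the equivalent `F = t^2` with
#' `(1, N - 2)` degrees of freedom is reported alongside for comparability
#' with ANOVA-style reporting of two-group contrasts.
#'
#' @param s a [group_summary()] with exactly 2 groups.
#' @return A `stat_result` with statistic `t` and extras `F` and `F_df`.
#' @export
t_from_summary <- function(s) {
  stopifnot(inherits(s, "group_summary"))
  if (length(s$ns) != 2L) stop("t_from_summary needs exactly 2 groups")
  n1 <- s$ns[1]; n2 <- s$ns[2]
  sp2 <- ((n1 - 1) * s$sds[1]^2 + (n2 - 1) * s$sds[2]^2) / (n1 + n2 - 2)
  tv <- (s$means[1] - s$means[2]) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  stat_result("t", tv, df, 2 * stats::pt(abs(tv), df, lower.tail = FALSE),
              extra = list(F = tv^2, F_df = c(1L, df)))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction, `df = (rows - 1)(cols - 1)`.
#'
#' @param counts matrix of non-negative integer counts with positive margins.
#' @return A `stat_result` with statistic `chi2`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate margins: a row or column sums to zero")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  stat_result("chi2", ht$statistic, ht$parameter, ht$p.value)
}

#' One-way ANOVA / Kruskal-Wallis on raw grouped data
#'
#' `one_way_anova()` is the classic equal-variance F test (matching
#' [anova_from_summary()] exactly when summaries are exact);
#' `kruskal_wallis()` is the tie-corrected H test.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @return A `stat_result` (`F` or `H`).
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (any(table(g) < 2L)) stop("every group needs n >= 2")
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  stat_result("F", ht$statistic, unname(ht$parameter), ht$p.value)
}

#' @rdname one_way_anova
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ht <- stats::kruskal.test(values, g)
  stat_result("H", ht$statistic, unname(ht$parameter), ht$p.value)
}

#' Bonferroni-corrected pairwise comparisons after ANOVA
#'
#' All pairwise group contrasts using the pooled ANOVA mean-square error with
#' `N - k` degrees of freedom (the classic post-hoc t), p-values multiplied by
#' the number of comparisons and capped at 1.
#'
#' @param values,groups raw grouped data.
#' @return Data frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p_raw`, `p_adjusted`.
#' @export
posthoc_bonferroni <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  sp <- split(as.numeric(values), g)
  ns <- lengths(sp)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  N <- sum(ns)
  mse <- sum(vapply(sp, function(v) sum((v - mean(v))^2), numeric(1))) / (N - k)
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    n1 <- ns[[pr[1]]]; n2 <- ns[[pr[2]]]
    tv <- (mean(sp[[pr[1]]]) - mean(sp[[pr[2]]])) /
      sqrt(mse * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(abs(tv), N - k, lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], t = tv, df = N - k,
               p_raw = p, p_adjusted = min(1, m * p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected Dunn's post-hoc test
#'
#' Large-sample rank-based pairwise z tests following a Kruskal-Wallis
#' omnibus, with the standard tie correction
#' `sum(t^3 - t) / (12 (N - 1))` subtracted from `N (N + 1) / 12` in the
#' standard error; p-values multiplied by the number of comparisons and
#' capped at 1.
#'
#' @param values,groups raw grouped data.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @export
posthoc_dunn <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  x <- as.numeric(values)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
               (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_raw = p, p_adjusted = min(1, m * p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired before/after comparisons
#'
#' Paired Student t test or Wilcoxon signed-rank test, the within-subject
#' comparisons used for stimulation ON vs OFF designs.
#'
#' @param before,after paired numeric vectors of equal length >= 3.
#' @param method `"t"` or `"wilcoxon"`.
#' @return A `stat_result` (`t` or `W`).
#' @export
paired_tests <- function(before, after, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(before) != length(after)) stop("before/after must be paired")
  if (length(before) < 3L) stop("need at least 3 pairs")
  d <- after - before
  if (method == "t") {
    if (all(d == 0))  # identical measurements: no effect, by convention t = 0
      return(stat_result("t", 0, length(d) - 1L, 1))
    ht <- stats::t.test(after, before, paired = TRUE)
    stat_result("t", ht$statistic, unname(ht$parameter), ht$p.value)
  } else {
    if (all(d == 0))
      stop("all paired differences are zero: signed-rank statistic undefined")
    ht <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE))
    stat_result("W", ht$statistic, numeric(0), ht$p.value)
  }
}

#' Correlation with two-sided p-value
#'
#' Pearson product-moment or Spearman rank correlation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `stat_result` (`r` or `rho`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  stat_result(if (method == "pearson") "r" else "rho",
              ht$estimate, numeric(0), ht$p.value)
}

#' Normality screening
#'
#' Shapiro-Wilk and Lilliefors-corrected Kolmogorov-Smirnov tests (the KS
#' normality test of standard clinical statistics software, which estimates
#' mean and SD from the sample). Used to route group comparisons to ANOVA or
#' Kruskal-Wallis.
#'
#' @param x numeric vector, n >= 4, non-constant.
#' @return List of two `stat_result`s: `shapiro_wilk` and
#'   `kolmogorov_smirnov`, plus `normal` (both p > 0.05).
#' @export
normality_tests <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0) stop("constant input: normality tests undefined")
  sw <- stats::shapiro.test(x)
  ks <- nortest::lillie.test(x)
  list(shapiro_wilk = stat_result("W", sw$statistic, numeric(0), sw$p.value),
       kolmogorov_smirnov = stat_result("D", ks$statistic, numeric(0),
                                        ks$p.value),
       normal = sw$p.value > 0.05 && ks$p.value > 0.05)
}

#' Group comparison with automatic test routing
#'
#' Runs [normality_tests()] per group and applies [one_way_anova()] with
#' Bonferroni post-hocs when every group passes, otherwise
#' [kruskal_wallis()] with Dunn post-hocs -- the routing convention of
#' clinical cohort tables.
#'
#' @param values,groups raw grouped data.
#' @return List with `omnibus` (`stat_result`), `posthoc` (data frame), and
#'   `parametric` (logical).
#' @export
compare_groups <- function(values, groups) {
  g <- factor(groups)
  normal <- all(vapply(split(as.numeric(values), g),
                       function(v) normality_tests(v)$normal, logical(1)))
  if (normal) {
    list(omnibus = one_way_anova(values, groups),
         posthoc = posthoc_bonferroni(values, groups), parametric = TRUE)
  } else {
    list(omnibus = kruskal_wallis(values, groups),
         posthoc = posthoc_dunn(values, groups), parametric = FALSE)
  }
}
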