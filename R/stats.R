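# Group-comparison statistics matching the study's analysis plan: pooled
# two-sample t and exact Mann-Whitney U for two groups, Fisher's exact test
# for ventriculomegaly proportions, the two-sided F test for variances,
# Pearson correlation, one-way ANOVA with Tukey's HSD, and the Wilcoxon
# signed-rank test for longitudinal proportions. Each wrapper returns a
# uniform TestResult data.frame. Two-sided p-values throughout; no
# multiple-testing correction beyond Tukey.

testResult <- function(test, statistic, df = NA_real_, p.value,
                       estimate = NA_real_, direction = NA_character_,
                       flagged = FALSE) {
  data.frame(test = test, statistic = statistic, df = df, p.value = p.value,
             estimate = estimate, direction = direction, flagged = flagged,
             stringsAsFactors = FALSE)
}

groupSummary <- function(a, b) {
  data.frame(group = c("a", "b"), n = c(length(a), length(b)),
             mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)))
}

#' Two-group comparison: pooled t test or Mann-Whitney U
#'
#' Student's pooled-variance two-sided t test
#' (\code{df = n_a + n_b - 2}; the pooled form matches the degrees of
#' freedom reported for equal-sized animal groups) for parametric data, or
#' the Mann-Whitney U test for non-parametric data (exact p-value when both
#' groups are small and untied, normal approximation otherwise). The choice
#' of kind is explicit: which metrics are treated as non-parametric is a
#' judgement the caller makes.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param kind "student_t" or "mann_whitney".
#' @return a TestResult data.frame (statistic is t or U) with the group
#'   means and SDs attached as attribute \code{groups}.
#' @examples
#' twoGroupTest(c(1, 2, 3), c(4, 5, 6), "mann_whitney")$p.value  # 0.1
#' @export
twoGroupTest <- function(a, b, kind = c("student_t", "mann_whitney")) {
  kind <- match.arg(kind)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  res <- if (kind == "student_t") {
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
      testResult("student_t", 0, length(a) + length(b) - 2, 1,
                 mean(a) - mean(b), "none", flagged = TRUE)
    else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      testResult("student_t", unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, mean(a) - mean(b),
                 if (mean(a) > mean(b)) "a>b"
                 else if (mean(a) < mean(b)) "a<b" else "none")
    }
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    testResult("mann_whitney", unname(wt$statistic), NA_real_, wt$p.value,
               stats::median(a) - stats::median(b),
               if (stats::median(a) > stats::median(b)) "a>b"
               else if (stats::median(a) < stats::median(b)) "a<b"
               else "none")
  }
  attr(res, "groups") <- groupSummary(a, b)
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric tail summation over all tables
#' with the observed margins.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a TestResult data.frame (estimate is the sample odds ratio).
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))$p.value   # 2/252
#' @export
fisherExact2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2),
            all(table >= 0), all(table == round(table)))
  ft <- stats::fisher.test(table)
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  testResult("fisher_exact", NA_real_, NA_real_, ft$p.value, or)
}

#' Two-sided F test for equality of variances
#'
#' Reports F as the larger over the smaller sample variance with the
#' corresponding (n-1, n-1) degrees of freedom; the two-sided p-value is
#' invariant to the orientation. Two groups with zero variance give p = 1
#' with a flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a TestResult data.frame; \code{df} holds the numerator df, with
#'   the full df pair in attribute \code{df.pair}.
#' @export
varianceFTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    res <- testResult("variance_f", 1, length(a) - 1, 1, flagged = TRUE)
    attr(res, "df.pair") <- c(length(a) - 1, length(b) - 1)
    return(res)
  }
  if (va >= vb) { hi <- a; lo <- b } else { hi <- b; lo <- a }
  vt <- stats::var.test(hi, lo)
  res <- testResult("variance_f", unname(vt$statistic),
                    unname(vt$parameter["num df"]), vt$p.value,
                    unname(vt$statistic),
                    if (va > vb) "a>b" else if (vb > va) "a<b" else "none")
  attr(res, "df.pair") <- unname(vt$parameter)
  res
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return a TestResult data.frame (estimate is r, statistic the t value,
#'   df = n - 2).
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  testResult("pearson", unname(ct$statistic), unname(ct$parameter),
             ct$p.value, unname(ct$estimate),
             if (ct$estimate > 0) "positive"
             else if (ct$estimate < 0) "negative" else "none")
}

#' One-way ANOVA with Tukey's HSD pairwise comparisons
#'
#' Omnibus F over all groups followed by Tukey honestly-significant-
#' difference adjusted p-values per group pair. With only two groups the
#' Tukey-adjusted p equals the pooled two-sample t-test p. All-identical
#' groups give F = 0 and all p = 1 with a flag.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list with \code{anova} (a TestResult data.frame) and
#'   \code{pairs} (data.frame of pairwise mean differences and adjusted
#'   p-values).
#' @export
onewayAnovaTukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (stats::var(values) == 0) {
    cmb <- utils::combn(names(groups), 2)
    pairs <- data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
                        diff = 0, p.adj = 1)
    return(list(anova = testResult("oneway_anova", 0,
                                   length(groups) - 1, 1, flagged = TRUE),
                pairs = pairs))
  }
  fit <- stats::aov(values ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  list(anova = testResult("oneway_anova", an$`F value`[1], an$Df[1],
                          an$`Pr(>F)`[1]),
       pairs = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p.adj = tk[, "p adj"], row.names = NULL))
}

#' Wilcoxon signed-rank test for paired data
#'
#' Exact two-sided p-value for small samples (no zero differences or ties
#' among the absolute differences), normal approximation otherwise; zero
#' differences are discarded in the usual way. All-zero differences give
#' p = 1 with a flag.
#'
#' @param before,after paired numeric vectors of equal length >= 2.
#' @param exactMax largest number of non-zero differences for which the
#'   exact distribution is requested.
#' @return a TestResult data.frame (statistic is V, the positive-rank sum).
#' @export
wilcoxonSignedRank <- function(before, after, exactMax = 15L) {
  if (length(before) != length(after))
    stop("before and after must have equal length")
  if (length(before) < 2) stop("need at least 2 pairs")
  d <- after - before
  if (all(d == 0))
    return(testResult("wilcoxon_signed_rank", NA_real_, NA_real_, 1,
                      0, "none", flagged = TRUE))
  nz <- sum(d != 0)
  wt <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE,
                                            exact = nz <= exactMax))
  testResult("wilcoxon_signed_rank", unname(wt$statistic), NA_real_,
             wt$p.value, stats::median(d),
             if (stats::median(d) > 0) "increase"
             else if (stats::median(d) < 0) "decrease" else "none")
}
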