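# Group comparisons: classical (pooled-variance) Student tests on per-nucleus
# measures and chi-squared tests on category distributions.

#' Classical two-sample Student test
#'
#' Two-sided pooled-variance Student t test, the "classical" form used for
#' per-nucleus spot counts and axis positions. Welch's unequal-variance
#' variant is available behind `var_equal = FALSE`.
#'
#' Degenerate inputs are handled explicitly: when both samples are constant
#' with equal means the test is vacuous and `t = 0`, `p = 1` is returned;
#' constant samples with different means have zero denominator and raise an
#' error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (classical Student) if `TRUE`.
#' @return list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
student_test <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, df = length(a) + length(b) - 2L,
                  p_value = 1, mean_a = mean(a), mean_b = mean(b)))
    }
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

.as_counts <- function(x, what) {
  x <- unlist(x)
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop(what, " must be non-negative counts")
  x
}

#' Chi-squared goodness of fit of category counts
#'
#' Tests observed category counts (e.g. colocalized / adjacent / distant
#' nuclei) against expected proportions, such as the segregation-model
#' expectation for carrier sperm. Standard statistic with `k - 1` degrees of
#' freedom; no continuity correction.
#'
#' @param observed named or unnamed non-negative counts, total > 0.
#' @param expected_proportions expected proportions (rescaled to sum to 1).
#'   A category with expected proportion 0 but a nonzero observed count is
#'   an error (the statistic would be infinite).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi2_goodness_of_fit <- function(observed, expected_proportions) {
  o <- .as_counts(observed, "observed")
  p <- as.numeric(expected_proportions)
  if (length(o) != length(p)) stop("observed and expected lengths differ")
  if (any(is.na(p)) || any(p < 0) || sum(p) <= 0)
    stop("expected proportions must be non-negative and sum to > 0")
  if (sum(o) <= 0) stop("total observed count must be positive")
  if (any(p == 0 & o > 0))
    stop("expected proportion of 0 with a nonzero observed count")
  keep <- p > 0
  ht <- suppressWarnings(stats::chisq.test(o[keep], p = p[keep], rescale.p = TRUE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Chi-squared homogeneity test between two groups of category counts
#'
#' Contingency-table chi-squared test (no continuity correction) comparing
#' the category distribution of two populations, e.g. the
#' colocalized/adjacent/distant distribution of control versus carrier
#' nuclei. Categories empty in both groups are dropped with a warning.
#'
#' @param counts_a,counts_b non-negative counts over the same categories.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi2_homogeneity <- function(counts_a, counts_b) {
  a <- .as_counts(counts_a, "counts_a")
  b <- .as_counts(counts_b, "counts_b")
  if (length(a) != length(b)) stop("groups must share the same categories")
  if (sum(a) <= 0 || sum(b) <= 0) stop("both group totals must be positive")
  empty <- (a + b) == 0
  if (any(empty)) {
    warning(sum(empty), " categor", if (sum(empty) == 1) "y" else "ies",
            " empty in both groups dropped")
    a <- a[!empty]; b <- b[!empty]
  }
  tab <- rbind(a, b)
  if (ncol(tab) < 2L) stop("need at least two non-empty categories")
  if (all(abs(a / sum(a) - b / sum(b)) < .Machine$double.eps^0.5)) {
    # identical distributions: statistic exactly 0, p exactly 1
    return(list(statistic = 0, df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
                p_value = 1))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Mean number of labelled centromeres per chromocenter
#'
#' Divides the number of probe-labelled centromeres in the karyotype by the
#' observed mean number of chromocenters per nucleus. With 6 AC6-labelled
#' acrocentric centromeres and a mean of 1.7 chromocenters this gives 3.53
#' (reported as ~3.5 centromeres per chromocenter); with 11 SSCRS2A-labelled
#' centromeres and 5.9 chromocenters, 1.86.
#'
#' @param labeled_centromeres integer, labelled centromeres per nucleus.
#' @param mean_clusters positive mean chromocenter count per nucleus.
#' @return the mean members per chromocenter, rounded to 2 decimals.
#' @export
mean_members_per_cluster <- function(labeled_centromeres, mean_clusters) {
  stopifnot(is.numeric(labeled_centromeres), is.numeric(mean_clusters),
            length(labeled_centromeres) == 1L, length(mean_clusters) == 1L)
  if (mean_clusters <= 0) stop("mean_clusters must be positive")
  round(labeled_centromeres / mean_clusters, 2)
}

#' Tabulate pair categories in canonical order
#'
#' @param x character/factor vector of categories.
#' @param levels category order.
#' @return named integer vector of counts.
#' @export
category_counts <- function(x, levels = c("colocalized", "adjacent", "distant")) {
  x <- x[!is.na(x)]
  table(factor(as.character(x), levels = levels))
}

#' Compare two measured populations
#'
#' Runs the study's comparisons on two per-nucleus measurement tables (as
#' produced by [measure_population()]): a pooled-variance Student test on
#' every shared numeric measure, and a chi-squared homogeneity test on every
#' shared categorical measure (pair category, morphology classes).
#' Significance is called at `alpha` (0.05 by default); no multiple-testing
#' correction is applied, but the number of tests run is recorded in the
#' `n_tests` attribute of the returned table.
#'
#' Measures that are absent or all-`NA` in either group are skipped with a
#' warning; zero-variance measures with equal means report `p = 1`.
#'
#' @param records_a,records_b data frames with one row per nucleus.
#' @param measures optional character vector restricting the columns tested.
#' @param alpha significance level.
#' @param labels length-2 group labels used in the report.
#' @return data frame with one row per measure: `measure`, `test`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `statistic`, `df`, `p_value`, `significant`.
#' @export
compare_populations <- function(records_a, records_b, measures = NULL,
                                alpha = 0.05,
                                labels = c("control", "t(13;17)")) {
  stopifnot(is.data.frame(records_a), is.data.frame(records_b),
            nrow(records_a) > 0, nrow(records_b) > 0)
  skip_cols <- c("id", "seed", "carrier")
  shared <- setdiff(intersect(names(records_a), names(records_b)), skip_cols)
  if (!is.null(measures)) shared <- intersect(shared, measures)
  rows <- list()
  for (m in shared) {
    xa <- records_a[[m]]; xb <- records_b[[m]]
    if (is.numeric(xa) && is.numeric(xb)) {
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < 2L || length(xb) < 2L) {
        warning("measure '", m, "' skipped: too few observations")
        next
      }
      res <- tryCatch(student_test(xa, xb),
                      error = function(e) {
                        warning("measure '", m, "' skipped: ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      rows[[m]] <- data.frame(
        measure = m, test = "student_t",
        n_a = length(xa), n_b = length(xb),
        mean_a = res$mean_a, mean_b = res$mean_b,
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        stringsAsFactors = FALSE)
    } else if (is.character(xa) || is.factor(xa)) {
      lev <- sort(unique(c(as.character(xa), as.character(xb))))
      lev <- lev[!is.na(lev)]
      if (length(lev) < 2L) next
      ca <- category_counts(xa, levels = lev)
      cb <- category_counts(xb, levels = lev)
      if (sum(ca) == 0 || sum(cb) == 0) {
        warning("measure '", m, "' skipped: no category data")
        next
      }
      res <- suppressWarnings(chi2_homogeneity(ca, cb))
      rows[[m]] <- data.frame(
        measure = m, test = "chi2",
        n_a = sum(ca), n_b = sum(cb), mean_a = NA_real_, mean_b = NA_real_,
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame()
  if (nrow(out)) out$significant <- out$p_value < alpha
  attr(out, "n_tests") <- nrow(out)
  attr(out, "alpha") <- alpha
  attr(out, "labels") <- labels
  out
}
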