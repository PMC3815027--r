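test_that("pooled Student test matches closed-form arithmetic on toy samples", {
  a <- c(4.1, 5.0, 6.2, 5.5, 4.8)
  b <- c(6.9, 7.4, 8.1, 6.5, 7.8)
  res <- student_test(a, b)
  expect_equal(res$statistic, oracle_pooled_t(a, b))
  expect_equal(res$df, 8)
  # cross-check p against the t distribution directly
  expect_equal(res$p_value, 2 * pt(-abs(oracle_pooled_t(a, b)), df = 8))
})

test_that("Student test handles identical and degenerate samples", {
  x <- c(1, 2, 3, 4)
  res <- student_test(x, x)
  expect_equal(res$p_value, 1)

  res0 <- student_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(student_test(c(2, 2, 2), c(3, 3, 3)), "zero pooled variance")

  # clear separation is detected
  expect_lt(student_test(c(1, 2, 3), c(11, 12, 13))$p_value, 0.01)
  expect_error(student_test(1, c(1, 2)), "at least two")
})

test_that("goodness-of-fit statistic matches the brute-force formula", {
  obs <- c(30, 45, 25)
  p <- c(0.2, 0.5, 0.3)
  res <- chi2_goodness_of_fit(obs, p)
  expect_equal(res$statistic, oracle_chi2(obs, sum(obs) * p))
  expect_equal(res$df, 2)

  # exactly proportional observations: statistic 0, p 1
  res0 <- chi2_goodness_of_fit(c(75, 25), c(0.75, 0.25))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(chi2_goodness_of_fit(c(10, 5), c(1, 0)), "expected proportion of 0")
  expect_error(chi2_goodness_of_fit(c(10, 5), c(0.5, 0.3, 0.2)), "lengths differ")
})

test_that("homogeneity statistic matches the hand-computed table value", {
  a <- c(16, 32, 52)
  b <- c(24, 51, 25)
  res <- chi2_homogeneity(a, b)
  expect_equal(res$statistic, oracle_chi2_table(rbind(a, b)))
  expect_equal(res$df, 2)

  # 2x2 toy
  res2 <- chi2_homogeneity(c(10, 20), c(20, 10))
  expect_equal(res2$statistic, oracle_chi2_table(rbind(c(10, 20), c(20, 10))))

  # identical distributions
  expect_equal(chi2_homogeneity(c(5, 5), c(50, 50))$statistic, 0)
  expect_equal(chi2_homogeneity(c(5, 5), c(50, 50))$p_value, 1)

  expect_warning(chi2_homogeneity(c(5, 0, 5), c(3, 0, 7)), "empty in both")
})

test_that("mean members per chromocenter reproduces the worked examples", {
  expect_equal(mean_members_per_cluster(6, 1.7), 3.53)
  expect_equal(mean_members_per_cluster(11, 5.9), 1.86)
  expect_equal(mean_members_per_cluster(7, 7), 1)
  expect_error(mean_members_per_cluster(6, 0), "positive")
})

test_that("members-per-cluster times cluster count recovers the labelled total", {
  k <- build_haploid_karyotype()
  for (probe in c("AC6", "SSCRS2A")) {
    lab <- labeled_centromere_count(k, probe)
    for (x in c(1.3, 1.7, 5.9)) {
      expect_equal(mean_members_per_cluster(lab, x) * x, lab,
                   tolerance = 0.01)
    }
  }
})

test_that("population comparison reports shared measures and self-compare is null", {
  ra <- data.frame(id = 1:6,
                   n_telomere_clusters = c(11, 12, 13, 12, 11, 13),
                   ssc13_ml_pct = c(60, 70, 65, 72, 68, 66),
                   pair_category = c("distant", "adjacent", "distant",
                                     "colocalized", "distant", "adjacent"),
                   stringsAsFactors = FALSE)
  out_self <- compare_populations(ra, ra)
  expect_true(all(out_self$p_value == 1))
  expect_equal(attr(out_self, "n_tests"), nrow(out_self))
  expect_setequal(out_self$measure,
                  c("n_telomere_clusters", "ssc13_ml_pct", "pair_category"))

  rb <- ra
  rb$ssc13_ml_pct <- rb$ssc13_ml_pct - 20
  out <- compare_populations(ra, rb)
  row <- out[out$measure == "ssc13_ml_pct", ]
  expect_lt(row$p_value, 0.01)
  expect_true(row$significant)

  # a measure absent from one group is skipped with a warning
  rb2 <- rb[, setdiff(names(rb), "n_telomere_clusters")]
  out2 <- compare_populations(ra, rb2)
  expect_false("n_telomere_clusters" %in% out2$measure)
})
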