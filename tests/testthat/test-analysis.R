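test_that("descriptive summaries match direct expectations", {
  s <- summarize_values(c(0.5, 0.5, 0.5))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  expect_equal(unlist(s[c("min", "q1", "median", "q3", "max")]),
               c(min = 0.5, q1 = 0.5, median = 0.5, q3 = 0.5, max = 0.5))

  s2 <- summarize_values(c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(s2$median, 0.5)
  expect_equal(s2$q1, 0.25)
  expect_equal(s2$q3, 0.75)
  expect_error(summarize_values(numeric()), class = "utilicit_error_validation")
})

test_that("summaries agree with a brute-force oracle on random vectors", {
  withr::with_seed(99, {
    for (i in 1:50) {
      v <- runif(sample(c(3, 10, 47), 1))
      got <- summarize_values(v)
      want <- oracle_summary(v)
      for (f in names(want)) {
        expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
      }
    }
  })
})

test_that("states rank ascending by mean with id tie-break", {
  t3 <- read_table3_fixture()
  sg_order <- rank_states(dplyr::filter(t3, method == "SG"))
  rs_order <- rank_states(dplyr::filter(t3, method == "RS"))
  expect_equal(sg_order[1:8], c(18L, 17L, 14L, 15L, 10L, 4L, 9L, 3L))
  expect_equal(rs_order[1:8], c(18L, 17L, 14L, 15L, 10L, 9L, 4L, 16L))
  expect_equal(sort(sg_order), 1:18)

  expect_equal(rank_states(stats::setNames(rep(0.5, 18), 1:18)), 1:18)
  expect_error(rank_states(c(`1` = 0.5, `2` = NA)),
               class = "utilicit_error_validation")
})

test_that("rank concordance counts matches and common runs", {
  rc <- rank_concordance(1:18, 1:18)
  expect_equal(glance(rc)$n_same_position, 18L)
  expect_equal(glance(rc)$common_prefix_len, 18L)
  expect_equal(glance(rc)$common_suffix_len, 18L)

  rev_rc <- rank_concordance(1:18, 18:1)
  expect_equal(rev_rc$n_same_position, 0L)  # even-length reversal: no fixed point

  rc2 <- rank_concordance(c(3, 1, 2, 4), c(3, 2, 1, 4))
  expect_equal(rc2$n_same_position, 2L)
  expect_equal(rc2$common_prefix_len, 1L)
  expect_equal(rc2$common_suffix_len, 1L)
  expect_equal(sum(tidy(rc2)$same_state), 2L)

  expect_error(rank_concordance(1:3, 2:4), class = "utilicit_error_validation")
})

test_that("normal-approximation mean CIs reproduce published rows", {
  ci <- mean_ci(0.902, 0.203, 47)
  expect_equal(round(ci$low, 2), 0.84)
  expect_equal(round(ci$high, 2), 0.96)
  ci2 <- mean_ci(0.213, 0.336, 47)
  expect_equal(round(ci2$low, 2), 0.12)
  expect_equal(round(ci2$high, 2), 0.31)
  ci3 <- mean_ci(0.5, 0, 10)
  expect_equal(c(ci3$low, ci3$high), c(0.5, 0.5))
  expect_error(mean_ci(0.5, 0.1, 1), class = "utilicit_error_validation")
  # the t variant is wider than the z variant at every finite n
  expect_gt(mean_ci(0.5, 0.2, 47, method = "t")$high,
            mean_ci(0.5, 0.2, 47, method = "z")$high)
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  withr::with_seed(4, {
    for (i in 1:25) {
      n <- sample(5:47, 1)
      x <- round(runif(n), 2)  # rounding forces ties -> midranks
      y <- round(runif(n), 2)
      expect_equal(spearman_cor(x, y)$rho, oracle_spearman_rho(x, y),
                   tolerance = 1e-12)
    }
  })
  expect_error(spearman_cor(1:4, 1:5), class = "utilicit_error_validation")
})

test_that("Wilcoxon rank-sum p-values behave at the extremes", {
  # no location difference between identical samples
  same <- wilcoxon_rank_sum(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gte(same$p_value, 0.95)
  # complete separation at small n: exact two-sided tail is 2 / C(10, 5)
  sep <- wilcoxon_rank_sum(1:5, 11:15)
  expect_equal(sep$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3),
               class = "utilicit_error_validation")
})

test_that("LOWESS reproduces lines and resists gross outliers", {
  x <- seq(0, 1, length.out = 30)
  y <- 2 * x + 1
  expect_equal(lowess_fit(x, y), y, tolerance = 1e-8)

  expect_equal(lowess_fit(x, rep(0.4, 30), span = 1), rep(0.4, 30))

  y_out <- y
  y_out[15] <- 10  # gross outlier
  robust <- lowess_fit(x, y_out, robust_iters = 3)
  naive <- lowess_fit(x, y_out, robust_iters = 0)
  expect_lt(abs(robust[15] - y[15]), abs(naive[15] - y[15]))

  # fitted values are returned in input order, not sorted order
  shuffle <- sample(length(x))
  expect_equal(lowess_fit(x[shuffle], y[shuffle]), y[shuffle],
               tolerance = 1e-8)
  expect_error(lowess_fit(x, y, span = 0), class = "utilicit_error_validation")
})

test_that("summary tables are built per state and method with invariants", {
  sim <- simulate_study(n = 8, seed = 31)
  t3 <- build_table3(sim$records)
  expect_equal(nrow(t3), 36L)
  expect_equal(t3$method, rep(c("SG", "RS"), each = 18))
  expect_true(all(t3$min <= t3$q1 & t3$q1 <= t3$median &
                    t3$median <= t3$q3 & t3$q3 <= t3$max))
  expect_true(all(t3$sd >= 0))
  expect_true(all(t3$mean >= 0 & t3$mean <= 1))

  # a state with no SG records is reported by name
  drop9 <- sim$records[!(sim$records$state_id == 9 &
                           sim$records$method == "SG"), ]
  expect_error(build_table3(drop9), "9")
})

test_that("the cross-study comparison table carries comparator gaps as NA", {
  t5 <- build_table5(read_table3_fixture(), n = 47)
  expect_equal(nrow(t5), 18L)
  expect_true(is.na(t5$comparator_mean[t5$state_id == 11]))
  expect_true(all(!is.na(t5$mean)))
  # sanity: present-study CI always brackets its mean
  expect_true(all(t5$low <= t5$mean & t5$mean <= t5$high))
})
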