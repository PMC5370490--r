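test_that("paired log t-test matches a closed-form hand computation", {
  # equal vectors: t = 0, two-tailed p = 1
  p <- c(1e-6, 2e-6, 4e-6, 8e-6)
  r0 <- paired_t_log(p, p)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # constant ratio: zero-variance differences flagged, not infinite
  p5 <- c(1e-6, 2e-6, 4e-6, 8e-6, 1.6e-5)
  rc <- paired_t_log(3 * p5, p5)
  expect_true(rc$degenerate)
  expect_true(is.na(rc$p_value))

  # n = 8: textbook t from the 8 log2 differences
  set.seed(4)
  p_h <- exp(rnorm(8, -13, 0.5))
  p_t <- p_h * exp(rnorm(8, 1, 0.6))
  d <- log2(p_t) - log2(p_h)
  t_hand <- mean(d) / (sd(d) / sqrt(8))
  p_hand_two <- 2 * pt(-abs(t_hand), 7)
  p_hand_one <- pt(t_hand, 7, lower.tail = FALSE)
  r2 <- paired_t_log(p_t, p_h, tails = "two")
  r1 <- paired_t_log(p_t, p_h, tails = "one")
  expect_equal(r2$statistic, t_hand)
  expect_equal(r2$p_value, p_hand_two)
  expect_equal(r1$p_value, p_hand_one)

  expect_error(paired_t_log(c(1e-6, 0), c(1e-6, 1e-6)), "non-positive")
})

test_that("the paired log t-test is invariant to the log base", {
  set.seed(5)
  for (i in 1:10) {
    p_h <- exp(rnorm(12, -13, 0.7))
    p_t <- p_h * exp(rnorm(12, 0.5, 0.8))
    # natural-log oracle
    d <- log(p_t) - log(p_h)
    t_ln <- mean(d) / (sd(d) / sqrt(length(d)))
    r <- paired_t_log(p_t, p_h, tails = "two")
    expect_equal(r$statistic, t_ln, tolerance = 1e-12)
    expect_equal(r$p_value, 2 * pt(-abs(t_ln), length(d) - 1),
                 tolerance = 1e-12)
  }
})

test_that("Welch test matches the direct formula evaluation", {
  a <- c(2, 2, 2); b <- c(2, 2, 2)
  r0 <- welch_t(a, b)
  expect_true(is.na(r0$statistic))  # zero variance in both groups
  expect_true(r0$degenerate)

  set.seed(6)
  x <- rnorm(10, 5, 2); y <- rnorm(10, 4, 0.5)
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 10 + var(y) / 10)
  df_hand <- (var(x) / 10 + var(y) / 10)^2 /
    ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  r <- welch_t(x, y)
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df_hand))
  expect_error(welch_t(1, c(1, 2)), "at least 2")

  same <- c(1, 2, 3, 4)
  ri <- welch_t(same, same)
  expect_equal(ri$statistic, 0)
  expect_equal(ri$p_value, 1)
})

test_that("Mann-Whitney matches enumeration for small groups and handles ties", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)       # complete separation
  expect_equal(r$p_value, 1 / 3)     # 2/6 arrangements as extreme

  tied <- mann_whitney(5, 5)
  expect_equal(tied$statistic, 0.5)  # midrank convention

  set.seed(7)
  for (i in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(100, n1); b <- sample(200:300, n2)  # no ties
    got <- mann_whitney(a, b)
    oracle <- oracle_u_exact(a, b)
    expect_equal(got$statistic, oracle$u)
    expect_equal(got$p_value, oracle$p)
  }
})

test_that("large-sample Mann-Whitney approximates the permutation p-value", {
  set.seed(8)
  a <- rnorm(20, 0.4); b <- rnorm(20)
  got <- mann_whitney(a, b)
  pool <- c(a, b)
  r_obs <- sum(rank(pool)[1:20])
  perm <- replicate(1e5, sum(sample(rank(pool), 20)))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(r_obs - mean(perm)))
  expect_lt(abs(got$p_value - p_perm), 0.01)
})

test_that("log2 regression of tumor on blood recovers known structure", {
  p <- exp(rnorm(10, -13, 1))
  ri <- regress_log2(p, p)
  expect_equal(ri$slope, 1, tolerance = 1e-12)
  expect_equal(ri$r_squared, 1, tolerance = 1e-12)

  const <- rep(2e-6, 10)
  rc <- regress_log2(const, p)  # constant response: slope 0, R^2 0
  expect_equal(rc$slope, 0, tolerance = 1e-12)
  expect_equal(rc$r_squared, 0, tolerance = 1e-12)
  expect_error(regress_log2(p, const), "zero variance")

  set.seed(9)
  p_h <- exp(rnorm(20, -13, 0.8))
  p_t <- p_h^0.7 * exp(rnorm(20, -4, 0.4))
  hand <- oracle_ols(log2(p_h), log2(p_t))
  got <- regress_log2(p_t, p_h)
  expect_equal(got$slope, hand$slope)
  expect_equal(got$intercept, hand$intercept)
  expect_equal(got$r_squared, hand$r_squared)
  expect_equal(got$p_value, hand$p_value)
})

test_that("arm-level aneuploidy regression recovers lines exactly", {
  m <- c(1e6, 2e6, 3e6, 4e6, 5e6)
  rc <- arm_aneuploidy_regression(rep(2.5, 5), m)
  expect_equal(rc$slope, 0, tolerance = 1e-12)

  r_line <- 3e-7 * m + 1.2
  rl <- arm_aneuploidy_regression(r_line, m)
  expect_equal(rl$slope, 3e-7, tolerance = 1e-10)
  expect_equal(rl$intercept, 1.2, tolerance = 1e-6)
  expect_equal(rl$r_squared, 1, tolerance = 1e-12)

  set.seed(10)
  noisy <- r_line + rnorm(5, 0, 0.3)
  hand <- oracle_ols(m, noisy)
  got <- arm_aneuploidy_regression(noisy, m)
  expect_equal(got$slope, hand$slope)
  expect_equal(got$p_value, hand$p_value)
})

test_that("GC association reports rank and linear correlation", {
  gc <- seq(0.3, 0.6, length.out = 20)
  r_up <- gc^3 * 10  # strictly increasing in gc
  got <- gc_association(r_up, gc)
  expect_equal(got$spearman, 1)
  expect_gt(got$pearson, 0.9)

  set.seed(11)
  perm <- sample(r_up)
  got_p <- gc_association(perm, gc)
  crit <- qnorm(0.975) / sqrt(20 - 3)  # Fisher null band
  expect_lt(abs(atanh(got_p$pearson)), crit * 2.5)

  flat <- gc_association(rep(1, 10), runif(10))
  expect_true(flat$degenerate)
})

test_that("Giemsa group summaries partition bands by stain", {
  cyt <- new_partition(data.frame(
    interval_id = sprintf("chr1b%02d", 1:15), contig = "chr1",
    start = seq(0, 1400, by = 100), end = seq(100, 1500, by = 100),
    band = sprintf("q%02d", 1:15),
    stain = rep(c("gneg", "gpos50", "gpos100"), each = 5)), "cyt")
  set.seed(12)
  vals <- c(sort(runif(5, 1, 8)), sort(runif(5, -3, 3)),
            sort(runif(5, 0, 5)))
  rr <- data.frame(interval_id = cyt$interval_id, rescaled = vals)
  smry <- giemsa_group_summary(rr, cyt, threshold = 4.2)
  expect_equal(smry$stain, c("gneg", "gpos50", "gpos100"))
  expect_equal(smry$n, rep(5L, 3))
  # n = 5 quartiles are exact order statistics (positions 2, 3, 4)
  g1 <- sort(vals[1:5])
  expect_equal(smry$q1[1L], g1[2L])
  expect_equal(smry$median[1L], g1[3L])
  expect_equal(smry$q3[1L], g1[4L])
  expect_equal(smry$mean[1L], mean(g1))
  expect_equal(smry$n_above_threshold[1L], sum(g1 >= 4.2))

  # single-stain input: one group covering every band
  all_gneg <- cyt; all_gneg$stain <- "gneg"
  expect_message(s1 <- giemsa_group_summary(rr, all_gneg), "omitted")
  expect_equal(s1$n, 15L)
  expect_equal(s1$stain, "gneg")
})

test_that("stratified summaries report group medians, ranges, and tests", {
  coh <- data.frame(participant = paste0("P", 1:4),
                    fold_change = c(2, 2, 4, 4),
                    sex = c("female", "female", "male", "male"),
                    vital_status = c("alive", "alive", "deceased", "alive"))
  s <- stratified_summary(coh, "sex")
  expect_equal(s$summary$median[s$summary$group == "female"], 2)
  expect_equal(s$summary$median[s$summary$group == "male"], 4)
  expect_s3_class(s$test, "numt_test")
  expect_match(s$test$method, "Welch")

  sv <- stratified_summary(coh, "vital_status")
  expect_match(sv$test$method, "Mann-Whitney")

  one <- stratified_summary(transform(coh, sex = "female"), "sex")
  expect_equal(one$summary$n, 4L)
  expect_equal(one$summary$median, median(coh$fold_change))
})

test_that("sex-specific implant ratios are recovered by stratified medians", {
  sim <- simulate_cohort(sim_config(
    seed = 31, n_participants = 16, background_pairs = 50000,
    sex_ratio = c(female = 4.5, male = 3.0)))
  coh <- numt_cohort(quantify_cohort(sim, levels = "gen"))
  s <- stratified_summary(coh$table, "sex")
  truth <- c(female = 4.5, male = 3.0)
  for (g in s$summary$group) {
    x <- coh$table$fold_change[coh$table$sex == g]
    se_med <- 1.2533 * sd(x) / sqrt(length(x))
    expect_lt(abs(s$summary$median[s$summary$group == g] - truth[[g]]),
              3 * se_med + 0.15 * truth[[g]])
  }
})
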