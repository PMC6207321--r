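test_that("median_fluorescence follows the median conventions", {
  ev <- tibble::tibble(CD35 = c(1, 5, 9, 2, 4))
  expect_equal(median_fluorescence(ev, c(TRUE, TRUE, TRUE, FALSE, FALSE),
                                   "CD35"), 5)
  expect_equal(median_fluorescence(ev, c(FALSE, FALSE, FALSE, TRUE, TRUE),
                                   "CD35"), 3)  # mean-of-middle
  expect_error(median_fluorescence(ev, rep(FALSE, 5), "CD35"), "empty gate")
  expect_error(median_fluorescence(ev, rep(TRUE, 5), "CD62L"), "CD62L")
})

test_that("fold_change is a guarded ratio with reciprocal symmetry", {
  expect_equal(fold_change(4.4, 2.2), 2)
  expect_equal(fold_change(3.3, 3.3), 1)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(fold_change(a, b) * fold_change(b, a), 1, tolerance = 1e-12)
  }
  expect_error(fold_change(-1, 2), "positive")
  expect_error(fold_change(2, 0), "positive")
})

test_that("one-way RM-ANOVA matches brute-force sums of squares and aov", {
  set.seed(41)
  y <- matrix(rnorm(12, mean = rep(c(10, 12, 15), each = 4)), nrow = 4,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  fit <- rm_anova_oneway(rm_long(y), value, subject, time)
  oracle <- bruteforce_rm_ss(y)
  expect_equal(fit$ss[["subject"]], oracle$ss_subject, tolerance = 1e-10)
  expect_equal(fit$ss[["time"]], oracle$ss_time, tolerance = 1e-10)
  expect_equal(fit$ss[["error"]], oracle$ss_error, tolerance = 1e-10)
  expect_equal(fit$statistic, oracle$f, tolerance = 1e-10)
  # independent route: aov with a subject Error stratum
  d <- rm_long(y)
  a <- summary(stats::aov(value ~ time + Error(factor(subject)), data = d))
  tab <- a[["Error: Within"]][[1]]
  expect_equal(fit$statistic, tab["time", "F value"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$p_value, tab["time", "Pr(>F)"], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("with two time points the RM-ANOVA F is the squared paired t", {
  set.seed(42)
  y <- matrix(rnorm(16, mean = rep(c(5, 6), each = 8)), nrow = 8,
              dimnames = list(NULL, c("base", "follow")))
  fit <- rm_anova_oneway(rm_long(y), value, subject, time)
  tt <- stats::t.test(y[, 2], y[, 1], paired = TRUE)
  expect_equal(fit$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
  # with k = 2 the Tukey interval reduces to the paired-t interval
  ct <- tidy(fit)
  expect_equal(c(ct$conf_low, ct$conf_high),
               unname(tt$conf.int[1:2] * c(1, 1)), tolerance = 1e-8)
})

test_that("Tukey-adjusted contrasts agree with emmeans on the same model", {
  set.seed(43)
  y <- matrix(rnorm(18, mean = rep(c(3, 4, 6), each = 6)), nrow = 6,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  d <- rm_long(y)
  fit <- rm_anova_oneway(d, value, subject, time)
  a <- stats::aov(value ~ time + factor(subject), data = d)
  em <- summary(emmeans::emmeans(a, pairwise ~ time, adjust = "tukey"))
  ours <- tidy(fit)
  theirs <- em$contrasts
  expect_equal(-ours$difference, theirs$estimate, tolerance = 1e-8)
  expect_equal(ours$p_adj, theirs$p.value, tolerance = 1e-6)
})

test_that("flat-over-time subjects give null differences and unit folds", {
  set.seed(44)
  base <- rnorm(5, 10)
  y <- outer(base, rep(1, 3)) + matrix(rnorm(15, sd = 1e-6), 5)
  colnames(y) <- c("t1", "t2", "t3")
  ct <- tidy(rm_anova_oneway(rm_long(y), value, subject, time))
  expect_equal(ct$difference, rep(0, 3), tolerance = 1e-5)
  expect_equal(ct$fold, rep(1, 3), tolerance = 1e-6)
})

test_that("degenerate inputs raise the documented errors", {
  y <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_error(rm_anova_oneway(rm_long(y), value, subject, time),
               "degenerate variance")
  y2 <- y[1:2, ]
  expect_error(rm_anova_oneway(rm_long(y2), value, subject, time),
               "insufficient data")
})

test_that("subjects with missing time points are excluded as complete-case", {
  set.seed(45)
  y <- matrix(rnorm(15, 10), nrow = 5,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  d <- rm_long(y)
  d <- d[!(d$subject == "S02" & d$time == "t2"), ]
  fit <- rm_anova_oneway(d, value, subject, time)
  expect_equal(fit$n_subjects, 4L)
  expect_identical(fit$excluded_subjects, "S02")
  ref <- rm_anova_oneway(rm_long(y[-2, ]), value, subject, time)
  expect_equal(fit$statistic, ref$statistic, tolerance = 1e-12)
})

test_that("RM-ANOVA is invariant to relabeling and constant shifts", {
  set.seed(46)
  y <- matrix(rnorm(21, 5), nrow = 7,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  d <- rm_long(y)
  fit <- rm_anova_oneway(d, value, subject, time)
  shuffled <- d
  map <- sample(sprintf("S%02d", 1:7))
  names(map) <- sprintf("S%02d", 1:7)
  shuffled$subject <- map[shuffled$subject]
  fit2 <- rm_anova_oneway(shuffled, value, subject, time)
  expect_equal(fit$statistic, fit2$statistic, tolerance = 1e-12)
  shifted <- dplyr::mutate(d, value = value + 100)
  fit3 <- rm_anova_oneway(shifted, value, subject, time)
  expect_equal(fit$statistic, fit3$statistic, tolerance = 1e-9)
  expect_equal(tidy(fit)$difference, tidy(fit3)$difference,
               tolerance = 1e-9)
})

test_that("one-way RM-ANOVA holds its nominal type-I error under the null", {
  set.seed(47)
  n_rep <- 2000
  rejections <- 0
  for (i in seq_len(n_rep)) {
    y <- matrix(rnorm(8 * 3, mean = rnorm(8, sd = 1)[rep(1:8, 3)]),
                nrow = 8, dimnames = list(NULL, c("t1", "t2", "t3")))
    dec <- floodr:::rm_ss_decompose(y)
    f <- (dec$ss_time / dec$df_time) / (dec$ss_error / dec$df_error)
    p <- stats::pf(f, dec$df_time, dec$df_error, lower.tail = FALSE)
    if (p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("two-way RM-ANOVA matches aov error strata on balanced data", {
  set.seed(48)
  d <- tidyr::expand_grid(subject = sprintf("S%d", 1:6),
                          a = c("x", "y"), b = c("t1", "t2", "t3"))
  d$value <- rnorm(nrow(d), mean = 5 + (d$a == "y") * 2 +
                     (d$b == "t3") * 1.5)
  fit <- rm_anova_twoway(d, value, subject, a, b)
  a2 <- summary(stats::aov(
    value ~ a * b + Error(factor(subject) / (a * b)), data = d
  ))
  get_f <- function(stratum, term) {
    tab <- a2[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  eff <- fit$effects
  expect_equal(eff$statistic[eff$term == "factor_a"],
               get_f("Error: factor(subject):a", "a"), tolerance = 1e-8)
  expect_equal(eff$statistic[eff$term == "factor_b"],
               get_f("Error: factor(subject):b", "b"), tolerance = 1e-8)
  expect_equal(eff$statistic[eff$term == "interaction"],
               get_f("Error: factor(subject):a:b", "a:b"), tolerance = 1e-8)
})

test_that("a single-level factor reduces the two-way to the one-way fit", {
  set.seed(49)
  d <- tidyr::expand_grid(subject = sprintf("S%d", 1:6),
                          a = "only", b = c("t1", "t2", "t3"))
  d$value <- rnorm(nrow(d), mean = 5 + (d$b == "t3"))
  fit2 <- rm_anova_twoway(d, value, subject, a, b)
  fit1 <- rm_anova_oneway(d, value, subject, b)
  eff_b <- fit2$effects[fit2$effects$term == "factor_b", ]
  expect_equal(eff_b$statistic, fit1$statistic, tolerance = 1e-10)
  expect_equal(eff_b$p_value, fit1$p_value, tolerance = 1e-10)
  expect_equal(fit2$contrasts$difference, tidy(fit1)$difference,
               tolerance = 1e-12)
})

test_that("two-way subset main effect is calibrated under a null subset", {
  set.seed(50)
  n_rep <- 400
  p_vals <- replicate(n_rep, {
    d <- tidyr::expand_grid(subject = sprintf("S%d", 1:8),
                            a = c("x", "y", "z"), b = c("t1", "t2"))
    subj_eff <- rnorm(8)
    names(subj_eff) <- sprintf("S%d", 1:8)
    d$value <- rnorm(nrow(d)) + subj_eff[d$subject]
    fit <- rm_anova_twoway(d, value, subject, a, b)
    fit$effects$p_value[fit$effects$term == "factor_a"]
  })
  rate <- mean(p_vals < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 4 * se)
  # p-values approximately uniform: KS test should not reject strongly
  expect_gt(stats::ks.test(p_vals, "punif")$p.value, 0.001)
})

test_that("pearson_r2 matches the closed-form computation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r2(x, 2 * x + 1)$r_squared, 1, tolerance = 1e-12)
  y_orth <- c(1, -1, 0, -1, 1)  # orthogonal to centred x
  expect_equal(pearson_r2(x, y_orth)$r_squared, 0, tolerance = 1e-12)
  y <- c(2.0, 4.1, 5.9, 8.3, 9.6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  out <- pearson_r2(x, y)
  expect_equal(out$r_squared, r_hand^2, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * stats::pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(pearson_r2(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r2(x, 1:4), "equal length")
})

test_that("estimated fold changes are unbiased on synthetic cohorts", {
  set.seed(51)
  folds <- vapply(1:50, function(s) {
    co <- simulate_cohort(
      cohort_config(n_subjects = 10L, events_per_sample = 1000L,
                    sessions = "morning", days = c(1L, 8L)),
      seed = 1000 + s
    )
    lat <- vapply(co$events, function(e) mean(e$.label != "other"),
                  numeric(1))
    est <- co$counter_concentration * lat
    mean(est[co$day == 8]) / mean(est[co$day == 1])
  }, numeric(1))
  truth <- 2.24 / 1.78
  se <- stats::sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - truth), 4 * se + 0.02)
})
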