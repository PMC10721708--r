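# Mixed-model donor-effect statistics: closed-form REML against the
# general mixed-model solver, ANOVA contracts, boundary behaviour.

test_that("zero fold effect lands on the boundary with p = 0.5", {
  acc <- matrix(c(0.8, 0.9, 1.0), 3, 4)  # fold means all equal
  res <- lrt_random_effect(acc)
  expect_equal(res$sigma2_A, 0)
  expect_equal(res$LRT, 0)
  expect_equal(res$p_boundary, 0.5)
  expect_error(lrt_random_effect(matrix(c(1, NA, 1, 1), 2, 2)), "unbalanced")
})

test_that("closed-form REML matches lmerTest on random balanced grids", {
  for (rep in 1:3) {
    acc <- simulate_accuracy_table(32, 4, sigma_A = c(0, 0.01, 0.03)[rep],
                                   seed = 100 + rep)
    res <- lrt_random_effect(acc)
    long <- data.frame(acc = as.vector(acc),
                       donor = factor(rep(1:32, 4)),
                       fold = factor(rep(1:4, each = 32)))
    fit <- suppressMessages(lmerTest::lmer(
      acc ~ donor + (1 | fold), data = long,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    rv <- suppressMessages(lmerTest::ranova(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    # lme4 stops at its optimizer tolerance; the closed form is exact
    expect_equal(res$sigma2_A, vc$vcov[1], tolerance = 1e-4)
    expect_equal(res$sigma2, vc$vcov[2], tolerance = 1e-6)
    expect_equal(res$log_likelihood, as.numeric(logLik(fit)),
                 tolerance = 1e-6)
    expect_equal(res$log_likelihood_reduced, rv$logLik[2], tolerance = 1e-6)
    expect_equal(res$LRT, max(0, rv$LRT[2]), tolerance = 1e-5)
    expect_equal(res$p_boundary,
                 if (rv$LRT[2] <= 0) 0.5 else rv$`Pr(>Chisq)`[2] / 2,
                 tolerance = 1e-6)
    expect_equal(res$AIC_reduced, rv$AIC[2], tolerance = 1e-5)
    expect_equal(res$npar_reduced, 33L)
  }
})

test_that("REML optimum satisfies the boundary conditions", {
  # interior optimum: numerical gradient of the restricted likelihood at
  # the estimate is ~0; boundary optimum: one-sided derivative <= 0
  ss_of <- function(acc) deformcyte:::balanced_ss(acc)
  for (sA in c(0, 0.03)) {
    acc <- simulate_accuracy_table(16, 4, sigma_A = sA, seed = 7 + 100 * sA)
    res <- lrt_random_effect(acc)
    ll <- function(s2A) deformcyte:::reml_loglik(acc, s2A, res$sigma2,
                                                 ss_of(acc))
    h <- 1e-7
    if (res$sigma2_A > 0) {
      grad <- (ll(res$sigma2_A + h) - ll(res$sigma2_A - h)) / (2 * h)
      expect_lt(abs(grad) * h, 1e-6)
    } else {
      expect_lte((ll(h) - ll(0)) / h, 1e-6)
    }
  }
})

test_that("donor ANOVA has the design-forced degrees of freedom", {
  acc <- simulate_accuracy_table(32, 4, seed = 5)
  tab <- anova_donor_fixed(acc)
  expect_equal(tab$df, c(31, 96))
  expect_equal(tab$mean_sq, tab$sum_sq / tab$df)
  expect_equal(tab$statistic[1], tab$mean_sq[1] / tab$mean_sq[2])
  expect_error(anova_donor_fixed(acc[, 1, drop = FALSE]), "2 folds")
})

test_that("degenerate zero-residual grids are flagged", {
  acc <- matrix(c(0.8, 0.9, 1.0), 3, 2)  # folds identical per donor
  tab <- suppressWarnings(anova_donor_fixed(acc))  # aov warns: perfect fit
  expect_equal(tab$sum_sq[2], 0)
  expect_equal(tab$statistic[1], Inf)
  expect_equal(tab$p_value[1], 0)
  expect_true(attr(tab, "degenerate"))
  # sums of squares by hand: donor means (.8, .9, 1), grand .9
  expect_equal(tab$sum_sq[1], 2 * (0.01 + 0 + 0.01))
})

test_that("class ANOVA matches its contracts and the pooled t-test", {
  set.seed(21)
  means <- c(rnorm(19, 0.891, 0.02), rnorm(13, 0.893, 0.015))
  classes <- c(rep("adult", 19), rep("fetal", 13))
  tab <- anova_class_difference(means, classes)
  expect_equal(tab$df, c(1, 30))
  tt <- t.test(means ~ classes, var.equal = TRUE)
  expect_equal(tab$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(tab$p_value[1], tt$p.value, tolerance = 1e-10)
  # identical class means: F = 0, p = 1
  m0 <- c(0.1, 0.3, 0.5, 0.1, 0.3, 0.5)
  t0 <- anova_class_difference(m0, rep(c("a", "f"), each = 3))
  expect_equal(t0$statistic[1], 0)
  expect_equal(t0$p_value[1], 1)
  expect_error(anova_class_difference(m0, c("a", rep("f", 5))), "2 donors")
})

test_that("sums of squares decompose on random balanced tables", {
  set.seed(22)
  for (rep in 1:5) {
    D <- sample(4:20, 1)
    F_ <- sample(2:6, 1)
    acc <- matrix(rnorm(D * F_), D, F_)
    ss <- deformcyte:::balanced_ss(acc)
    expect_equal(ss$ss_total, ss$ss_donor + ss$ss_fold + ss$ss_resid,
                 tolerance = 1e-10)
  }
})

test_that("boundary p-values never exceed one half", {
  set.seed(23)
  for (rep in 1:25) {
    acc <- simulate_accuracy_table(8, 4, sigma_A = runif(1, 0, 0.05),
                                   seed = rep)
    expect_lte(lrt_random_effect(acc)$p_boundary, 0.5)
  }
})
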