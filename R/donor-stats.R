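# Donor-effect analysis of the per-donor, per-fold accuracy grid
# A[d, f] = mu + alpha_d + a_f + eps, with donor effects fixed
# (sum-to-zero) and the cross-validation fold effect random,
# a_f ~ N(0, sigma_A^2), eps ~ N(0, sigma^2).
#
# The design is exactly balanced (every donor scored under every fold), so
# the restricted likelihood separates into independent sums of squares and
# the variance components have closed-form REML estimates: with
# lambda1 = sigma^2 + D * sigma_A^2,
#   sigma_A^2 = max(0, (MS_fold - MS_resid) / D),
# where MS_fold is the between-fold mean square (df F-1) and MS_resid the
# donor-by-fold interaction mean square (df (D-1)(F-1)).  The likelihood
# ratio test against sigma_A^2 = 0 tests on the boundary of the parameter
# space, so the chi-square(1) upper-tail p-value is halved.

# Sums of squares of the balanced two-way layout (rows = donors, cols =
# folds).
balanced_ss <- function(acc) {
  D <- nrow(acc)
  F_ <- ncol(acc)
  grand <- mean(acc)
  donor_means <- rowMeans(acc)
  fold_means <- colMeans(acc)
  ss_donor <- F_ * sum((donor_means - grand)^2)
  ss_fold <- D * sum((fold_means - grand)^2)
  fitted <- outer(donor_means, fold_means, "+") - grand
  ss_resid <- sum((acc - fitted)^2)
  list(D = D, F = F_, grand = grand, donor_means = donor_means,
       fold_means = fold_means, ss_donor = ss_donor, ss_fold = ss_fold,
       ss_resid = ss_resid,
       ss_total = sum((acc - grand)^2))
}

# REML log-likelihood of the mixed model at (sigma2_A, sigma2), using the
# conventional restricted-likelihood form with the treatment-contrast fixed
# design matrix (intercept + donor dummies), matching lme4's logLik
# convention.  V's eigenstructure: lambda1 = sigma2 + D*sigma2_A on the
# F-dimensional fold-mean space, sigma2 elsewhere.
reml_loglik <- function(acc, sigma2_A, sigma2, ss) {
  D <- ss$D
  F_ <- ss$F
  n <- D * F_
  lambda1 <- sigma2 + D * sigma2_A
  y <- as.vector(acc)  # column-major: donors vary fastest within a fold
  donor <- factor(rep(seq_len(D), F_))
  fold <- rep(seq_len(F_), each = D)
  X <- model.matrix(~donor)
  # fold-mean projection of each column of X
  Xf <- apply(X, 2, function(col) ave(col, fold))
  XtVinvX <- (crossprod(X) - crossprod(X, Xf)) / sigma2 +
    crossprod(X, Xf) / lambda1
  logdetV <- F_ * log(lambda1) + (n - F_) * log(sigma2)
  yPy <- ss$ss_fold / lambda1 + ss$ss_resid / sigma2
  -0.5 * (logdetV + determinant(XtVinvX, logarithm = TRUE)$modulus[1] +
          yPy + (n - D) * log(2 * pi))
}

#' Boundary likelihood-ratio test for the fold variance component
#'
#' Fits the balanced mixed model by REML (closed-form profile over
#' `sigma_A^2 >= 0`), computes the restricted likelihood-ratio statistic
#' against the model without the random fold effect, and halves the
#' chi-square(1) upper-tail p-value because the null value lies on the
#' boundary of the parameter space.
#'
#' @param acc Donors x folds accuracy matrix (complete and balanced), or an
#'   `accuracy_table` from [per_donor_accuracy()].
#' @return Object of class `mixed_model_result` with the grand mean `mu`,
#'   sum-to-zero donor effects `alpha`, variance components `sigma2_A` and
#'   `sigma2`, REML log-likelihoods, parameter counts and AICs of the full
#'   and reduced models (reduced: no random effect; its parameter count is
#'   the donor mean parameters plus one residual variance), the `LRT`
#'   statistic with `df = 1`, and `p_boundary` in `[0, 0.5]`.
#' @export
lrt_random_effect <- function(acc) {
  if (inherits(acc, "accuracy_table")) acc <- acc$acc
  acc <- as.matrix(acc)
  if (anyNA(acc)) stop("unbalanced accuracy grid: missing entries")
  D <- nrow(acc)
  F_ <- ncol(acc)
  if (D < 2 || F_ < 2) stop("need at least 2 donors and 2 folds")
  ss <- balanced_ss(acc)
  r <- (D - 1) * (F_ - 1)
  ms_fold <- ss$ss_fold / (F_ - 1)
  # reduced model (sigma_A^2 = 0): residual variance over fold + interaction
  sigma2_0 <- (ss$ss_fold + ss$ss_resid) / (F_ - 1 + r)
  # full model REML: unconstrained optimum, else boundary
  sigma2_1 <- ss$ss_resid / r
  if (ms_fold > sigma2_1) {
    sigma2_A <- (ms_fold - sigma2_1) / D
    sigma2 <- sigma2_1
  } else {
    sigma2_A <- 0
    sigma2 <- sigma2_0
  }
  ll_full <- reml_loglik(acc, sigma2_A, sigma2, ss)
  ll_red <- reml_loglik(acc, 0, sigma2_0, ss)
  lrt <- max(0, 2 * (ll_full - ll_red))
  p_boundary <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  npar_full <- D + 2L   # D mean parameters + 2 variances
  npar_red <- D + 1L    # D mean parameters + 1 variance
  structure(list(
    mu = ss$grand,
    alpha = ss$donor_means - ss$grand,
    sigma2_A = sigma2_A, sigma2 = sigma2,
    log_likelihood = ll_full, log_likelihood_reduced = ll_red,
    npar = npar_full, npar_reduced = npar_red,
    AIC = -2 * ll_full + 2 * npar_full,
    AIC_reduced = -2 * ll_red + 2 * npar_red,
    LRT = lrt, df = 1L, p_boundary = p_boundary,
    D = D, F = F_),
    class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result> balanced donor x fold mixed model (REML)\n")
  cat(sprintf("  donors %d, folds %d; mu = %.4f\n", x$D, x$F, x$mu))
  cat(sprintf("  sigma_A^2 (fold) = %.3e, sigma^2 (resid) = %.3e\n",
              x$sigma2_A, x$sigma2))
  cat(sprintf("  reduced model: NPar %d, logLik %.4f, AIC %.4f\n",
              x$npar_reduced, x$log_likelihood_reduced, x$AIC_reduced))
  cat(sprintf("  LRT = %.7f (df 1), boundary p = %.5f\n", x$LRT,
              x$p_boundary))
  invisible(x)
}

#' One-way donor ANOVA of the accuracy grid
#'
#' Fixed-effects analysis without the random fold term: a one-way ANOVA
#' over donors with the folds as replicates (`df_donor = D - 1`,
#' `df_resid = D * (F - 1)`), computed through [stats::aov()].
#'
#' @param acc Donors x folds accuracy matrix or `accuracy_table`.
#' @return Object of class `anova_table` (a data frame with `term`, `df`,
#'   `sum_sq`, `mean_sq`, `statistic`, `p_value`).  A zero residual mean
#'   square is flagged degenerate with an infinite F and p = 0.
#' @export
anova_donor_fixed <- function(acc) {
  if (inherits(acc, "accuracy_table")) acc <- acc$acc
  acc <- as.matrix(acc)
  if (anyNA(acc)) stop("unbalanced accuracy grid: missing entries")
  if (ncol(acc) < 2) stop("need at least 2 folds")
  long <- data.frame(
    acc = as.vector(acc),
    donor = factor(rep(seq_len(nrow(acc)), ncol(acc))))
  tab <- as.data.frame(anova(aov(acc ~ donor, data = long)))
  out <- data.frame(
    term = c("donor", "residual"),
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
  degenerate <- out$sum_sq[2] <= 1e-10 * sum(out$sum_sq)
  if (degenerate) {
    out$statistic[1] <- Inf
    out$p_value[1] <- 0
  }
  structure(out, degenerate = degenerate,
            class = c("anova_table", "data.frame"))
}

#' Between-class ANOVA of donor-averaged accuracies
#'
#' Tests for a difference in mean per-donor accuracy between the two
#' classes: one-factor ANOVA on the donor means (`df_class = 1`,
#' `df_resid = D - 2`), via [stats::aov()].
#'
#' @param donor_means Donor-averaged accuracies (one per donor).
#' @param classes Class label per donor.
#' @return Object of class `anova_table` as in [anova_donor_fixed()].
#' @export
anova_class_difference <- function(donor_means, classes) {
  stopifnot(length(donor_means) == length(classes))
  classes <- factor(as.character(classes))
  if (any(table(classes) < 2)) {
    stop("each class needs at least 2 donors")
  }
  dat <- data.frame(y = as.numeric(donor_means), cls = classes)
  tab <- as.data.frame(anova(aov(y ~ cls, data = dat)))
  out <- data.frame(
    term = c("class", "residual"),
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
  structure(out, degenerate = FALSE, class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  cat("<anova_table>\n")
  print.data.frame(x, row.names = FALSE, digits = 7)
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  (degenerate: zero residual mean square)\n")
  }
  invisible(x)
}

#' Simulate a balanced accuracy grid
#'
#' Draws `A[d, f] = mu + alpha_d + a_f + eps[d, f]` with donor effects
#' `alpha_d ~ N(0, donor_sd^2)`, fold effects `a_f ~ N(0, sigma_A)`.
#' Used for the boundary-behaviour checks of the likelihood-ratio test.
#'
#' @param D,F_ Numbers of donors and folds.
#' @param mu Grand mean.
#' @param donor_sd SD of the (fixed-effect) donor offsets.
#' @param sigma_A SD of the random fold effect (0 for the null).
#' @param sigma Residual SD.
#' @param seed Seed.
#' @return D x F accuracy matrix.
#' @export
simulate_accuracy_table <- function(D = 32L, F_ = 4L, mu = 0.89,
                                    donor_sd = 0.02, sigma_A = 0,
                                    sigma = 0.04, seed = NULL) {
  with_seed(seed, {
    alpha <- rnorm(D, 0, donor_sd)
    a <- rnorm(F_, 0, sigma_A)
    mu + outer(alpha, a, "+") + matrix(rnorm(D * F_, 0, sigma), D, F_)
  })
}
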