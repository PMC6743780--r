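# IWLS bisquare regression and the variance partition built on it.

sim_design <- function(n_ragas = 12, fam_sd = 0.15, seed = 1) {
  set.seed(seed)
  data.frame(tonality = rep(seq(0, 1.4, length.out = n_ragas), 2),
             rhythm = rep(0:1, each = n_ragas),
             familiarity = rnorm(2 * n_ragas, 2.86, fam_sd))
}

test_that("noise-free linear data is recovered exactly", {
  d <- sim_design()
  d$rating <- 2.5 - 1.2 * d$tonality + 0.4 * d$rhythm + 0.1 * d$familiarity
  fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  expect_equal(unname(fit$coefficients), c(2.5, -1.2, 0.4, 0.1),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("clean Gaussian data matches the OLS oracle closely", {
  d <- sim_design(fam_sd = 0.8, seed = 2)
  set.seed(3)
  d$rating <- 2.5 - 1.2 * d$tonality + 0.4 * d$rhythm +
    0.1 * d$familiarity + rnorm(nrow(d), 0, 0.005)
  fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  ols <- lm(rating ~ tonality + rhythm + familiarity, d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-3)
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
})

test_that("fit agrees with the MASS IWLS bisquare implementation", {
  skip_if_not_installed("MASS")
  d <- sim_design(seed = 4)
  set.seed(5)
  d$rating <- 2 + 0.8 * d$tonality - 0.5 * d$rhythm + rnorm(nrow(d), 0, 0.3)
  d$rating[3] <- d$rating[3] + 4  # one gross outlier
  fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  ref <- MASS::rlm(rating ~ tonality + rhythm + familiarity, d,
                   psi = MASS::psi.bisquare, scale.est = "MAD",
                   maxit = 60)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-3)
})

test_that("robust fit resists a gross outlier better than contaminated OLS", {
  d <- sim_design(seed = 6)
  set.seed(7)
  d$rating <- 2.5 - 1.2 * d$tonality + 0.4 * d$rhythm + rnorm(nrow(d), 0, 0.1)
  clean_ols <- coef(lm(rating ~ tonality + rhythm + familiarity, d))
  contaminated <- d
  contaminated$rating[5] <- contaminated$rating[5] + 6
  bad_ols <- coef(lm(rating ~ tonality + rhythm + familiarity, contaminated))
  rob <- fit_rlm(rating ~ tonality + rhythm + familiarity, contaminated)
  expect_lt(sum((rob$coefficients - clean_ols)^2),
            sum((bad_ols - clean_ols)^2))
  expect_lt(min(rob$weights), 0.05)  # the outlier is down-weighted
})

test_that("forcing unit weights reproduces least squares exactly", {
  d <- sim_design(seed = 8)
  set.seed(9)
  d$rating <- 1 + d$tonality + rnorm(nrow(d), 0, 0.5)
  fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, d,
                 weights = rep(1, nrow(d)))
  ols <- lm(rating ~ tonality + rhythm + familiarity, d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("collinear designs fail loudly naming the offending column", {
  d <- sim_design()
  d$rating <- 1 + d$tonality
  d$familiarity <- 3  # constant: collinear with the intercept
  expect_error(fit_rlm(rating ~ tonality + rhythm + familiarity, d),
               "collinear.*familiarity")
})

test_that("variance partition isolates the generating predictor", {
  d <- sim_design()
  d$rating <- 1 + 1.5 * d$tonality  # depends on tonality only
  fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  expect_gt(percent_variance(fit, "tonality"), 95)
  expect_lt(percent_variance(fit, "rhythm"), 1)
  expect_lt(percent_variance(fit, "familiarity"), 1)
  # response independent of all predictors
  set.seed(10)
  d$rating <- rnorm(nrow(d), 2, 0.5)
  fit0 <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  part <- variance_partition(fit0)
  expect_true(all(part$percent_variance < 25))
  expect_equal(part$df1, rep(4L, 3))
  expect_equal(part$df2, rep(20L, 3))
})

test_that("variance shares are invariant to affine response rescaling", {
  d <- sim_design(seed = 11)
  set.seed(12)
  d$rating <- 2 - d$tonality + 0.5 * d$rhythm + rnorm(nrow(d), 0, 0.2)
  f1 <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  d2 <- d
  d2$rating <- 10 + 7 * d$rating
  f2 <- fit_rlm(rating ~ tonality + rhythm + familiarity, d2)
  for (term in c("tonality", "rhythm", "familiarity"))
    expect_equal(percent_variance(f1, term), percent_variance(f2, term),
                 tolerance = 1e-6)
})

test_that("orthogonal additive predictors partition close to their shares", {
  # balanced rhythm and a symmetric tonality grid are orthogonal by
  # design; familiarity is explicitly orthogonalized against both
  d <- sim_design(fam_sd = 0.3, seed = 13)
  d$familiarity <- 2.86 + resid(lm(familiarity ~ tonality + rhythm, d))
  set.seed(14)
  noise <- rnorm(nrow(d), 0, 0.2)
  noise <- resid(lm(noise ~ tonality + rhythm + familiarity, d))
  d$rating <- 2 + 1 * d$tonality + 0.6 * d$rhythm + noise
  fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  # realized decomposition of this particular draw is the oracle
  v_t <- var(1 * d$tonality)
  v_r <- var(0.6 * d$rhythm)
  v_tot <- v_t + v_r + var(noise)
  expect_lt(abs(percent_variance(fit, "tonality") - 100 * v_t / v_tot), 5)
  expect_lt(abs(percent_variance(fit, "rhythm") - 100 * v_r / v_tot), 5)
})

test_that("permutation importance ranks predictors like the partition", {
  d <- sim_design(seed = 15)
  set.seed(16)
  d$rating <- 2 - 1.4 * d$tonality + 0.3 * d$rhythm + rnorm(nrow(d), 0, 0.2)
  fit <- fit_rlm(rating ~ tonality + rhythm + familiarity, d)
  imp <- permutation_importance(fit, n_perm = 200, seed = 17)
  expect_identical(imp, permutation_importance(fit, n_perm = 200, seed = 17))
  get <- function(term) imp$importance[imp$predictor == term]
  expect_gt(get("tonality"), get("rhythm"))
  expect_lt(abs(get("familiarity")), 0.02)  # unused by the generator
  ranking <- order(-imp$importance)
  part <- variance_partition(fit)
  expect_identical(imp$predictor[ranking],
                   part$predictor[order(-part$percent_variance)])
  expect_error(permutation_importance(fit, n_perm = 10), "at least 100")
})
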