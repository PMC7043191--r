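make_randomized <- function(n, seed) {
  set.seed(seed)
  X <- data.frame(age = stats::runif(n, 18, 80),
                  n_fingers_amputated = sample(1:5, n, replace = TRUE),
                  thumb_amputated = stats::runif(n) < 0.25,
                  mechanism = factor(sample(c("clean_cut", "avulsion",
                                              "crush"), n, replace = TRUE)))
  A <- factor(ifelse(stats::runif(n) < 0.65, "replantation",
                     "revision_amputation"),
              levels = treatment_levels())
  list(X = X, A = A)
}

test_that("randomized treatment gives near-marginal predictions with dominant intercept weight", {
  d <- make_randomized(2000, 1)
  pm <- fit_propensity(d$X, d$A, folds = 10, seed = 1)
  # the intercept-only learner is competitive (no covariate carries signal):
  # its CV Brier is within noise of the ensemble and it keeps real weight
  expect_lt(pm$cv_brier[["mean"]] - pm$cv_brier[["ensemble"]], 0.005)
  expect_gt(pm$weights[["mean"]], 0.2)
  # mean absolute calibration error against the known constant propensity
  expect_lt(mean(abs(pm$fitted - 0.65)), 0.05)
  expect_lt(max(abs(pm$fitted - mean(d$A == "replantation"))), 0.2)
})

test_that("stacking weights live on the simplex and reproduce the ensemble prediction", {
  d <- make_randomized(400, 2)
  pm <- fit_propensity(d$X, d$A, folds = 5, seed = 2)
  expect_true(all(pm$weights >= 0))
  expect_equal(sum(pm$weights), 1, tolerance = 1e-8)
  # manual recomposition from base-learner predictions: zero-weight
  # learners contribute nothing
  Xd <- itrtree:::one_hot(d$X)
  preds <- vapply(names(pm$learners), function(l) {
    pm$learner_defs[[l]]$predict(pm$learners[[l]], Xd)
  }, numeric(nrow(Xd)))
  manual <- pmin(pmax(as.numeric(preds %*% pm$weights), pm$bounds[1]),
                 pm$bounds[2])
  active <- pm$weights > 0
  manual_active <- pmin(pmax(
    as.numeric(preds[, active, drop = FALSE] %*% pm$weights[active]),
    pm$bounds[1]), pm$bounds[2])
  expect_equal(manual, pm$fitted, tolerance = 1e-8)
  expect_equal(manual_active, pm$fitted, tolerance = 1e-8)
  # the exported predict method agrees with the training-data fit
  expect_equal(predict(pm, d$X), pm$fitted, tolerance = 1e-8)
})

test_that("perfect separation is clipped to the truncation bounds", {
  n <- 120
  X <- data.frame(x = c(rnorm(n / 2, -4), rnorm(n / 2, 4)))
  A <- factor(rep(treatment_levels(), each = n / 2),
              levels = treatment_levels())
  pm <- suppressWarnings(fit_propensity(X, A, folds = 5, seed = 3,
                                        learners = c("mean", "glm")))
  expect_true(all(pm$fitted >= pm$bounds[1] & pm$fitted <= pm$bounds[2]))
  expect_true(any(pm$fitted == pm$bounds[1]))
  expect_true(any(pm$fitted == pm$bounds[2]))
})

test_that("ensemble CV Brier never exceeds the worst base learner", {
  co <- generate_cohort(franchise_config(), n = 800, seed = 4)
  X <- as.data.frame(co)[, propensity_covariates()]
  pm <- fit_propensity(X, co$treatment, folds = 10, seed = 4)
  base <- pm$cv_brier[setdiff(names(pm$cv_brier), "ensemble")]
  expect_lte(pm$cv_brier[["ensemble"]], max(base) + 1e-10)
})

test_that("propensity predictions are invariant to row order", {
  co <- generate_cohort(franchise_config(), n = 300, seed = 5)
  X <- as.data.frame(co)[, propensity_covariates()]
  A <- co$treatment
  pm1 <- fit_propensity(X, A, folds = 5, seed = 9)
  perm <- sample(nrow(X))
  pm2 <- fit_propensity(X[perm, ], A[perm], folds = 5, seed = 9)
  expect_equal(pm2$fitted, pm1$fitted[perm], tolerance = 1e-8)
})

test_that("balance report matches the closed-form binary ASMD", {
  # binary covariate split 60 / 40 between arms with pooled proportion 0.5
  n <- 400
  A <- factor(rep(treatment_levels(), each = n / 2),
              levels = treatment_levels())
  x <- c(rep(c(TRUE, FALSE), times = c(80, 120)),   # 40% in revision arm
         rep(c(TRUE, FALSE), times = c(120, 80)))   # 60% in replantation arm
  X <- data.frame(flag = x)
  rep_bal <- balance_report(X, A, rep(0.5, n))
  expect_equal(rep_bal$table$asmd_unadjusted, 0.4, tolerance = 1e-12)
  # uniform propensity leaves the weighted ASMD equal to the unadjusted one
  expect_equal(rep_bal$table$asmd_weighted, 0.4, tolerance = 1e-12)
})

test_that("identical arm distributions give zero ASMD and degenerate covariates are skipped", {
  n <- 200
  A <- factor(rep(treatment_levels(), n / 2), levels = treatment_levels())
  X <- data.frame(age = rep(c(30, 40), each = n / 2), constant = 1)
  X$age <- rep(rep(c(30, 40), each = n / 4), 2)  # same mix in both arms
  expect_warning(b <- balance_report(X, A, rep(0.6, n)), "zero pooled SD")
  expect_equal(b$table$asmd_unadjusted[b$table$covariate == "age"], 0)
  expect_false("constant" %in% b$table$covariate)
})

test_that("a correctly specified stacked propensity balances the confounded generator", {
  co <- generate_cohort(franchise_config(), n = 2000, seed = 1)
  X <- as.data.frame(co)[, propensity_covariates()]
  pm <- fit_propensity(X, co$treatment, folds = 10, seed = 1,
                       learners = c("mean", "glm"))
  b <- balance_report(X, co$treatment, pm$fitted)
  expect_gt(max(b$table$asmd_unadjusted), 0.1)  # confounding is real
  expect_lte(max(b$table$asmd_weighted), 0.1)
  expect_length(b$flags, 0)
})
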