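test_that("generation is deterministic given the seed", {
  a <- generate_cohort(franchise_config(), n = 60, seed = 11)
  b <- generate_cohort(franchise_config(), n = 60, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "potential_outcomes"),
                   attr(b, "potential_outcomes"))
  c <- generate_cohort(franchise_config(), n = 60, seed = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("observed outcomes equal the potential outcome of the assigned arm", {
  co <- generate_cohort(franchise_config(), n = 150, seed = 3)
  po <- attr(co, "potential_outcomes")
  idx <- cbind(seq_len(nrow(co)),
               ifelse(co$treatment == "replantation", 2L, 1L))
  for (field in names(po)) {
    expect_equal(co[[field]], po[[field]][idx], tolerance = 1e-12,
                 info = field)
  }
})

test_that("generated cohorts satisfy the schema and have both arms", {
  co <- generate_cohort(franchise_config(), n = 200, seed = 9)
  expect_s3_class(co, "cohort")
  expect_false(anyNA(as.data.frame(co)))
  expect_true(all(table(co$treatment) > 0))
  expect_true(all(co$age >= 18 & co$age <= 82))
  expect_true(all(co$pain_hea_0_100 <= co$pain_inj_0_100))
})

test_that("site, race and work-related injury are strongly associated", {
  co <- generate_cohort(franchise_config(), n = 4000, seed = 5)
  p1 <- stats::chisq.test(table(co$site, co$race_ethnicity))$p.value
  p2 <- stats::chisq.test(table(co$site, co$work_related))$p.value
  expect_lt(p1, 0.001)
  expect_lt(p2, 0.001)
})

test_that("missingness mechanism respects its configuration limits", {
  cfg <- franchise_config()
  co <- generate_cohort(cfg, n = 120, seed = 2)

  # all block probabilities driven to zero: identity
  cfg0 <- cfg
  cfg0$missingness$block_logit[] <- -Inf
  cfg0$missingness$covariate_prob[] <- 0
  expect_identical(as.data.frame(apply_missingness(co, cfg0, seed = 1)),
                   as.data.frame(co))

  # probability one on one block: those fields missing everywhere
  cfg1 <- cfg
  cfg1$missingness$block_logit[["dexterity"]] <- Inf
  miss <- apply_missingness(co, cfg1, seed = 1)
  expect_true(all(is.na(miss$nine_hole_inj_s)))
  expect_true(all(is.na(miss$nine_hole_hea_s)))

  # refuses cohorts that already contain missing values
  expect_error(apply_missingness(miss, cfg, seed = 1), "already contains")
})

test_that("pain-assumption violations are injected only when configured", {
  co0 <- generate_cohort(franchise_config(), n = 400, seed = 8)
  expect_equal(sum(co0$pain_hea_0_100 > co0$pain_inj_0_100), 0)
  cfgv <- franchise_config(pain_violation_prob = 0.3)
  cov <- generate_cohort(cfgv, n = 400, seed = 8)
  expect_gt(sum(cov$pain_hea_0_100 > cov$pain_inj_0_100), 0)
})

test_that("zero-interaction configuration admits a single-action oracle rule", {
  cfg <- franchise_config()
  for (o in names(cfg$outcome_models)) cfg$outcome_models[[o]]$effect <- 0
  cfg$true_rules$strength <- rule_leaf("replantation")
  orc <- oracle_optimal_rule(cfg, "strength", grid_n = 20000, seed = 4)
  # with no effect heterogeneity both arms tie: the declared single action
  # attains the maximum single-arm value within Monte-Carlo error
  expect_lt(abs(orc$value - max(orc$single_action_values)), 3 * orc$mc_se)
})

test_that("the oracle confirms the configured strength rule beats comparators", {
  orc <- oracle_optimal_rule(franchise_config(effect_size = "strong"),
                             "strength", grid_n = 30000, seed = 6,
                             n_comparators = 50)
  expect_gt(orc$value, orc$single_action_values[["replantation"]])
  expect_gt(orc$value, orc$single_action_values[["revision_amputation"]])
  expect_gte(orc$min_margin, -2 * orc$mc_se)
})

test_that("a rule contradicting the encoded optimum is rejected by the oracle", {
  cfg <- franchise_config(effect_size = "strong")
  # the generator encodes revision-iff-dominant for qol; claim the opposite
  flipped <- rule_split("dominant_hand_injured", threshold = 0.5,
                        left = rule_leaf("revision_amputation"),
                        right = rule_leaf("replantation"))
  expect_error(oracle_optimal_rule(cfg, "qol", grid_n = 20000, seed = 7,
                                   rule = flipped),
               "beaten")
})
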