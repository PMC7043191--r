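test_that("standardize centers and scales with sample SD and is idempotent", {
  expect_equal(standardize(c(0, 2)), c(-sqrt(2) / 2, sqrt(2) / 2))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(1, 5), "grip"), "zero variance")
  expect_error(standardize(1), "at least 2")
})

test_that("strength composite matches hand-computed arithmetic on a 4-patient fixture", {
  co <- small_cohort(4)
  co$grip_healthy_kg <- c(40, 40, 40, 40)
  co$grip_injured_kg <- co$grip_healthy_kg + c(-10, -5, 0, -20)
  co$pinch_lateral_hea_kg <- c(9, 9, 9, 9)
  co$pinch_lateral_inj_kg <- co$pinch_lateral_hea_kg + c(-2, -1, 0, -4)
  co$pinch_2pt_hea_kg <- c(6, 6, 6, 6)
  co$pinch_2pt_inj_kg <- co$pinch_2pt_hea_kg + c(-1, -0.5, 0.5, -3)
  co$pinch_3pt_hea_kg <- c(7, 7, 7, 7)
  co$pinch_3pt_inj_kg <- co$pinch_3pt_hea_kg + c(-1.5, -1, 0, -2.5)
  sc <- strength_composite(co)
  expect_equal(sc$scores,
               c(-0.133241, 0.364546, 1.067350, -1.298656),
               tolerance = 1e-5)
  # components are exact z-scores
  expect_equal(mean(sc$component_log$z_grip), 0, tolerance = 1e-10)
  expect_equal(stats::sd(sc$component_log$z_grip), 1, tolerance = 1e-10)
  # the patient with the least negative differences scores highest
  expect_equal(which.max(sc$scores), 3L)
})

test_that("strength composite flags the degenerate all-equal cohort", {
  co <- small_cohort(5)
  for (f in outcome_fields("strength")) co[[f]] <- 30
  expect_error(strength_composite(co), "zero variance")
})

test_that("dexterity score orders a mildly and severely slowed patient correctly", {
  co <- small_cohort(3)
  co$nine_hole_hea_s <- c(20, 20, 19)
  co$nine_hole_inj_s <- c(25, 60, 19.5)
  dx <- dexterity_score(co)
  expect_gt(dx$scores[1], dx$scores[2])
  expect_equal(dx$scores, standardize(co$nine_hole_hea_s - co$nine_hole_inj_s))
  # hand-computed fixture
  co$nine_hole_hea_s <- c(20, 22, 18)
  co$nine_hole_inj_s <- c(25, 40, 18.5)
  expect_equal(dexterity_score(co)$scores,
               c(0.311782, -1.118748, 0.806966), tolerance = 1e-5)
})

test_that("pain score truncates healthy-worse-than-injured records to zero difference", {
  co <- small_cohort(4)
  co$pain_hea_0_100 <- c(0, 20, 5, 0)
  co$pain_inj_0_100 <- c(30, 10, 5, 60)
  ps <- pain_score(co)
  expect_equal(ps$component_log$d_pain, c(-30, 0, 0, -60))
  expect_equal(ps$component_log$violated, c(FALSE, TRUE, FALSE, FALSE))
  # drop mode removes the violating record instead
  ps2 <- pain_score(co, violation = "drop")
  expect_equal(length(ps2$scores), 3L)
  expect_false("S002" %in% ps2$patient_id)
})

test_that("qol score averages standardized MHQ and reversed DASH", {
  co <- small_cohort(4)
  co$mhq_0_100 <- c(80, 60, 95, 70)
  co$dash_0_100 <- c(10, 30, 2, 15)
  q <- qol_score(co)
  expect_equal(q$scores, c(0.305877, -1.212341, 1.147585, -0.241121),
               tolerance = 1e-5)
  # affine identity: standardize(100 - DASH) == -standardize(DASH)
  expect_equal(standardize(100 - co$dash_0_100), -standardize(co$dash_0_100))
  # when MHQ and reversed DASH rank patients identically, qol follows MHQ
  expect_equal(order(q$scores), order(co$mhq_0_100))
})

test_that("composites are invariant to shared shifts and positive rescaling", {
  co <- small_cohort(10)
  base <- strength_composite(co)$scores
  sh <- co
  sh$grip_injured_kg <- sh$grip_injured_kg + 7
  sh$grip_healthy_kg <- sh$grip_healthy_kg + 7
  expect_equal(strength_composite(sh)$scores, base, tolerance = 1e-10)
  sc <- co
  sc$pinch_2pt_inj_kg <- sc$pinch_2pt_inj_kg * 2.2
  sc$pinch_2pt_hea_kg <- sc$pinch_2pt_hea_kg * 2.2
  expect_equal(strength_composite(sc)$scores, base, tolerance = 1e-10)
})

test_that("improving one patient's recovery weakly increases their score", {
  co <- small_cohort(10)
  for (o in c("strength", "dexterity", "pain", "qol")) {
    base <- composite_outcome(co, o)$scores
    up <- co
    # improve patient 1 on the outcome's own scale
    switch(o,
      strength = { up$grip_injured_kg[1] <- up$grip_injured_kg[1] + 5 },
      dexterity = { up$nine_hole_inj_s[1] <- up$nine_hole_inj_s[1] - 3 },
      pain = { up$pain_inj_0_100[1] <- max(0, up$pain_inj_0_100[1] - 10) },
      qol = { up$dash_0_100[1] <- max(0, up$dash_0_100[1] - 10) })
    after <- composite_outcome(up, o)$scores
    expect_gte(after[1] - base[1], 0)
  }
})
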