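test_that("cohort CSV round-trip is the identity on valid cohorts", {
  co <- small_cohort(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)
})

test_that("readers reject schema violations and preserve missingness", {
  co <- small_cohort(3)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- as.data.frame(co)
  bad$not_a_column <- 1
  utils::write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "not_a_column")

  bad <- as.data.frame(co)
  bad$age[2] <- 17  # below the adult cohort minimum
  utils::write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "age")

  bad <- as.data.frame(co)
  bad$dash_0_100[1] <- 120
  utils::write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "dash_0_100")

  ok <- as.data.frame(co)
  ok$grip_injured_kg[2] <- NA
  utils::write.csv(ok, path, row.names = FALSE, na = "")
  got <- read_cohort(path)
  expect_equal(nrow(got), 3L)
  expect_true(is.na(got$grip_injured_kg[2]))
})

test_that("complete_cases filters, preserves order, and is idempotent and monotone", {
  co <- small_cohort(10)
  expect_equal(as.data.frame(complete_cases(co)), as.data.frame(co),
               ignore_attr = TRUE)

  co$mhq_0_100[c(2, 5)] <- NA
  cc <- complete_cases(co, c("age", "mhq_0_100"))
  expect_equal(nrow(cc), 8L)
  expect_equal(cc$patient_id, co$patient_id[-c(2, 5)])
  expect_equal(unname(attr(cc, "removed_per_field")[["mhq_0_100"]]), 2)

  # idempotent
  expect_equal(as.data.frame(complete_cases(cc, c("age", "mhq_0_100"))),
               as.data.frame(cc), ignore_attr = TRUE)
  # monotone: adding required fields never increases the count
  co$pain_inj_0_100[3] <- NA
  n1 <- nrow(complete_cases(co, "mhq_0_100"))
  n2 <- nrow(complete_cases(co, c("mhq_0_100", "pain_inj_0_100")))
  expect_lte(n2, n1)
})

test_that("complete_cases errors when a treatment arm empties", {
  co <- small_cohort(6)
  co$mhq_0_100[co$treatment == "replantation"] <- NA
  expect_error(complete_cases(co, "mhq_0_100"), "arm")
})

test_that("injury group partitions all severity combinations into levels 1-8", {
  combos <- expand.grid(n_fingers_amputated = 1:5,
                        thumb_amputated = c(FALSE, TRUE),
                        amputation_level = c("distal", "proximal"),
                        stringsAsFactors = FALSE)
  g <- derive_injury_group(combos)
  expect_true(all(g %in% 1:8))
  expect_setequal(unique(g), 1:8)
  # each record maps to exactly one level (total function, no NAs)
  expect_false(anyNA(g))

  expect_equal(derive_injury_group(data.frame(
    n_fingers_amputated = 1L, thumb_amputated = FALSE,
    amputation_level = "distal")), 1L)
  expect_equal(derive_injury_group(data.frame(
    n_fingers_amputated = 1L, thumb_amputated = TRUE,
    amputation_level = "proximal")), 4L)
  expect_equal(derive_injury_group(data.frame(
    n_fingers_amputated = 3L, thumb_amputated = TRUE,
    amputation_level = "distal")), 8L)
  # severity ordering within single-digit injuries
  expect_lt(derive_injury_group(data.frame(
    n_fingers_amputated = 1L, thumb_amputated = FALSE,
    amputation_level = "proximal")),
    derive_injury_group(data.frame(
      n_fingers_amputated = 2L, thumb_amputated = TRUE,
      amputation_level = "distal")))
})

test_that("cohort summary uses the documented test choices and counts add up", {
  co <- small_cohort(12)
  # make the two arms identical samples on age: p-value must be 1
  ages <- rep(c(30, 40, 50, 60, 35, 45), 2)
  co$age <- ages[order(co$treatment)]
  s <- summarize_cohort(co, variables = c("age", "sex"))
  expect_equal(s$continuous$p_value[s$continuous$variable == "age"], 1)
  # categorical counts sum to the cohort size
  sex_rows <- s$categorical[s$categorical$variable == "sex", ]
  expect_equal(sum(sex_rows$n_overall), nrow(co))
})

test_that("balanced two-by-two table yields chi-square p-value 1", {
  df <- small_cohort(40)
  df$treatment <- rep(treatment_levels(), each = 20)
  df$sex <- rep(c("male", "female"), 20)  # 10/10 in each arm
  s <- summarize_cohort(df, variables = "sex")
  expect_equal(unique(s$categorical$p_value), 1)
})

test_that("single-level categorical is summarized with a warning, not an error", {
  co <- small_cohort(8)
  co$site <- factor(rep("Asia", 8), levels = c("US", "Asia"))
  expect_warning(s <- summarize_cohort(co, variables = "site"),
                 "single observed level")
  expect_true(all(is.na(s$categorical$p_value)))
})
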