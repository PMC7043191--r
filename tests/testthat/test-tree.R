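test_that("best_single_action maximizes the mean pseudo-outcome with ties to replantation", {
  psi <- cbind(revision_amputation = c(0.2, 0.2), replantation = c(0.5, 0.5))
  expect_equal(best_single_action(psi),
               list(action = "replantation", purity = 0.5))
  psi_tie <- cbind(revision_amputation = c(1, 0), replantation = c(0, 1))
  expect_equal(best_single_action(psi_tie)$action, "replantation")
  # 6-patient fixture against exhaustive evaluation of both arms
  set.seed(1)
  psi6 <- cbind(revision_amputation = rnorm(6), replantation = rnorm(6))
  got <- best_single_action(psi6)
  expect_equal(got$purity, max(colMeans(psi6)))
  expect_equal(got$action,
               treatment_levels()[which.max(colMeans(psi6))])
  expect_error(best_single_action(psi6, integer(0)), "empty")
})

test_that("candidate splits use midpoints, skip constants, and enumerate nominal subsets", {
  X <- data.frame(age = c(30, 40, 50, 30, 40, 50),
                  flat = rep(7, 6),
                  mechanism = factor(rep(c("clean_cut", "avulsion", "crush"),
                                         2)))
  sp_age <- enumerate_candidate_splits(X, "age", 1:6, min_node_size = 1)
  expect_equal(sort(vapply(sp_age, `[[`, 0, "threshold")), c(35, 45))
  expect_length(enumerate_candidate_splits(X, "flat", 1:6, 1), 0)
  sp_mech <- enumerate_candidate_splits(X, "mechanism", 1:6, 1)
  expect_length(sp_mech, 3)  # 2^(3-1) - 1 up to complementation
  # min_node_size excludes children that are too small
  sp_big <- enumerate_candidate_splits(X, "age", 1:6, min_node_size = 3)
  expect_equal(length(sp_big), 0)
})

test_that("best_split equals brute-force maximization on random fixtures", {
  for (seed in 1:20) {
    fx <- random_tree_fixture(n = sample(30:200, 1), seed = seed)
    ctrl <- trl_control(min_node_size = 5, lambda = 1e-6)
    got <- best_split(fx$psi, fx$X, seq_len(nrow(fx$psi)), ctrl)
    ref <- brute_force_depth1(fx$psi, fx$X, min_node_size = 5)
    if (is.null(got)) {
      base <- best_single_action(fx$psi)$purity
      expect_lt(ref$purity - base, 1e-6 + 1e-9)
    } else {
      expect_equal(got$purity, ref$purity, tolerance = 1e-12)
      expect_equal(got$covariate, ref$split$covariate)
      if (got$kind == "numeric") {
        expect_equal(got$threshold, ref$split$threshold)
      } else {
        expect_setequal(got$levels, ref$split$levels)
      }
    }
  }
})

test_that("constructed age heterogeneity is found; homogeneous nodes are not split", {
  set.seed(7)
  n <- 200
  X <- data.frame(age = runif(n, 18, 80),
                  n_fingers_amputated = sample(1:5, n, TRUE))
  young <- X$age <= 42
  psi <- cbind(revision_amputation = ifelse(young, 1, -1) + rnorm(n, 0, 0.1),
               replantation = ifelse(young, -1, 1) + rnorm(n, 0, 0.1))
  sp <- best_split(psi, X, seq_len(n), trl_control(min_node_size = 10))
  expect_equal(sp$covariate, "age")
  expect_lt(abs(sp$threshold - 42), 4)

  psi_flat <- cbind(revision_amputation = rnorm(n, 0.3, 0.01),
                    replantation = rnorm(n, 0.3, 0.01))
  expect_null(best_split(psi_flat, X, seq_len(n),
                         trl_control(min_node_size = 10)))
})

test_that("grow_tree respects max_depth and never undercuts the single-action value", {
  for (seed in 21:30) {
    fx <- random_tree_fixture(n = 150, seed = seed)
    ctrl <- trl_control(max_depth = 1, min_node_size = 10, lambda = 0.01)
    tree <- grow_tree(fx$psi, fx$X, ctrl)
    expect_lte(itrtree:::rule_depth(tree), 1L)
    v_tree <- rule_value(fx$psi, predict_rule(tree, fx$X))
    v_single <- best_single_action(fx$psi)$purity
    v_argmax <- mean(apply(fx$psi, 1, max))
    expect_gte(v_tree, v_single - 1e-12)
    expect_lte(v_tree, v_argmax + 1e-12)
  }
})

test_that("grow_tree output is invariant to record order", {
  fx <- random_tree_fixture(n = 180, seed = 42)
  ctrl <- trl_control(min_node_size = 15)
  t1 <- grow_tree(fx$psi, fx$X, ctrl)
  set.seed(99)
  perm <- sample(nrow(fx$X))
  t2 <- grow_tree(fx$psi[perm, ], fx$X[perm, ], ctrl)
  strip <- function(nd) {
    if (nd$type == "leaf") list(type = "leaf", action = nd$action)
    else list(type = "split", covariate = nd$covariate,
              threshold = nd$threshold, levels = nd$levels,
              left = strip(nd$left), right = strip(nd$right))
  }
  expect_identical(strip(t1), strip(t2))
})

test_that("predict_rule routes deterministically and totally", {
  leaf <- rule_leaf("replantation")
  X <- data.frame(dominant_hand_injured = c(TRUE, FALSE))
  expect_equal(as.character(predict_rule(leaf, X)),
               rep("replantation", 2))

  qol_rule <- rule_split("dominant_hand_injured", threshold = 0.5,
                         left = rule_leaf("replantation"),
                         right = rule_leaf("revision_amputation"))
  expect_equal(as.character(predict_rule(qol_rule, X)),
               c("revision_amputation", "replantation"))

  set.seed(3)
  Xr <- data.frame(dominant_hand_injured = runif(1000) < 0.5,
                   age = runif(1000, 18, 82))
  r2 <- rule_split("age", threshold = 42,
                   left = qol_rule, right = rule_leaf("replantation"))
  out <- predict_rule(r2, Xr)
  expect_false(anyNA(out))
  expect_equal(length(out), 1000L)

  Xm <- data.frame(dominant_hand_injured = c(TRUE, NA), age = c(30, 30))
  expect_error(predict_rule(r2, Xm), "dominant_hand_injured")
})

test_that("rules render in clinical sentence style", {
  expect_equal(render_rule(rule_leaf("replantation")),
               "Treat all patients with replantation")
  qol_rule <- rule_split("dominant_hand_injured", threshold = 0.5,
                         left = rule_leaf("replantation"),
                         right = rule_leaf("revision_amputation"))
  expect_equal(render_rule(qol_rule),
               paste("If the patient injured the dominant hand, treat with",
                     "revision amputation; otherwise, replantation"))
  strength_rule <- rule_split(
    "n_fingers_amputated", threshold = 1.5,
    left = rule_split("age", threshold = 42,
                      left = rule_leaf("revision_amputation"),
                      right = rule_leaf("replantation")),
    right = rule_leaf("replantation"))
  txt <- render_rule(strength_rule)
  expect_match(txt, "had 1 finger amputated and is aged ≤42 y")
  expect_match(txt, "treat with revision amputation; otherwise, replantation")
})

test_that("JSON serialization round-trips a rule with identical routing", {
  fx <- random_tree_fixture(n = 120, seed = 77)
  tree <- grow_tree(fx$psi, fx$X, trl_control(min_node_size = 10,
                                              lambda = 1e-4))
  back <- rule_from_json(rule_json(tree))
  expect_equal(as.character(predict_rule(back, fx$X)),
               as.character(predict_rule(tree, fx$X)))
})
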