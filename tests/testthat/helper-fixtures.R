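# Programmatic fixtures shared across the suite.

# A small fully observed, schema-valid cohort built by hand (no generator),
# n rows cycling over both arms and a mix of covariate values.
small_cohort <- function(n = 8) {
  i <- seq_len(n)
  df <- data.frame(
    patient_id = sprintf("S%03d", i),
    age = 20 + 5 * (i %% 7) + i,
    sex = rep(c("male", "female"), length.out = n),
    site = rep(c("Asia", "Asia", "US", "Asia"), length.out = n),
    race_ethnicity = rep(c("asian", "white"), length.out = n),
    education = rep(c("high_school_or_less", "some_college",
                      "college_graduate"), length.out = n),
    income = rep(c("low", "middle", "high"), length.out = n),
    marital = rep(c("married", "single"), length.out = n),
    employment = rep(c("employed", "unemployed"), length.out = n),
    occupation_group = rep(c("manual", "non_manual"), length.out = n),
    insurance = rep(c("yes", "yes", "no"), length.out = n),
    insurance_type = rep(c("public", "private", "none"), length.out = n),
    work_related = rep(c(TRUE, FALSE), length.out = n),
    n_fingers_amputated = rep(c(1L, 2L, 1L, 3L), length.out = n),
    thumb_amputated = rep(c(FALSE, FALSE, TRUE, FALSE), length.out = n),
    dominant_hand_injured = rep(c(TRUE, FALSE), length.out = n),
    mechanism = rep(c("clean_cut", "avulsion", "crush"), length.out = n),
    amputation_level = rep(c("distal", "proximal"), length.out = n),
    bilateral = rep(c(FALSE, FALSE, FALSE, TRUE), length.out = n),
    treatment = rep(c("replantation", "revision_amputation"),
                    length.out = n),
    grip_injured_kg = 24 + 1.3 * i,
    grip_healthy_kg = 35 + i,
    pinch_lateral_inj_kg = 6 + 0.3 * i,
    pinch_lateral_hea_kg = 8 + 0.25 * i,
    pinch_2pt_inj_kg = 4 + 0.2 * i,
    pinch_2pt_hea_kg = 5.5 + 0.1 * i,
    pinch_3pt_inj_kg = 5 + 0.2 * i,
    pinch_3pt_hea_kg = 6.5 + 0.1 * i,
    nine_hole_inj_s = 24 + i,
    nine_hole_hea_s = 19 + 0.5 * i,
    pain_inj_0_100 = 5 * (i %% 5),
    pain_hea_0_100 = 0,
    mhq_0_100 = 60 + 3 * (i %% 13),
    dash_0_100 = 4 + 2 * (i %% 13),
    stringsAsFactors = FALSE)
  as_cohort(df)
}

# Random psi + covariate fixture for tree-search tests.
random_tree_fixture <- function(n, seed) {
  set.seed(seed)
  X <- data.frame(
    age = round(stats::runif(n, 18, 80)),
    n_fingers_amputated = sample(1:5, n, replace = TRUE),
    thumb_amputated = stats::runif(n) < 0.3,
    mechanism = factor(sample(c("clean_cut", "avulsion", "crush"), n,
                              replace = TRUE),
                       levels = c("clean_cut", "avulsion", "crush")))
  psi <- cbind(revision_amputation = stats::rnorm(n),
               replantation = stats::rnorm(n))
  list(X = X, psi = psi)
}

# Brute-force reference: best depth-1 rule by direct evaluation of every
# enumerated split with per-child best single actions, same tie-break
# convention (candidate order, ascending threshold, strict improvement).
brute_force_depth1 <- function(psi, X, candidates = names(X),
                               min_node_size = 5L) {
  n <- nrow(psi)
  node_purity <- function(idx) {
    max(mean(psi[idx, 1L]), mean(psi[idx, 2L]))
  }
  node_action <- function(idx) {
    if (mean(psi[idx, 2L]) >= mean(psi[idx, 1L])) "replantation"
    else "revision_amputation"
  }
  best <- list(purity = -Inf, split = NULL)
  for (v in candidates) {
    splits <- enumerate_candidate_splits(X, v, seq_len(n), min_node_size)
    for (s in splits) {
      left <- if (s$kind == "numeric") {
        x <- X[[v]]
        xv <- if (is.logical(x)) as.numeric(x) else x
        which(xv <= s$threshold)
      } else {
        which(as.character(X[[v]]) %in% s$levels)
      }
      right <- setdiff(seq_len(n), left)
      p <- (length(left) * node_purity(left) +
              length(right) * node_purity(right)) / n
      if (p > best$purity) {
        best <- list(purity = p, split = s,
                     left_action = node_action(left),
                     right_action = node_action(right))
      }
    }
  }
  best
}
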