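# Internal helpers shared across modules.

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' @noRd
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(0)
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean(((x - mean(x)) / s)^3) * n^2 / ((n - 1) * (n - 2))
}

# Deterministic substream seeds derived from one master seed; kept < 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + match(
    stream,
    c("covariates", "treatment", "outcomes", "missingness", "propensity",
      "outcome_model", "tree", "imputation", "oracle"),
    nomatch = 0L
  ) * 7919L
}

# Canonical row order: lexicographic over treatment then covariate columns.
# Model fits performed in this order are invariant to the caller's row order.
canonical_order <- function(X, A = NULL) {
  cols <- lapply(X, function(col) if (is.factor(col)) as.integer(col) else col)
  if (!is.null(A)) cols <- c(list(as.integer(factor(A))), cols)
  do.call(order, cols)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Latent mean of a truncated normal whose truncated expectation hits target.
trunc_norm_latent_mean <- function(target, sd, lo, hi) {
  f <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a)) - target
  }
  stats::uniroot(f, c(target - 3 * sd, target + 3 * sd), tol = 1e-10)$root
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fixed one-hot encoding, first level as reference; all model learners see
# this numeric design so factor levels unseen in an arm or fold are harmless.
one_hot <- function(X) {
  X <- as.data.frame(X)
  for (v in names(X)) if (is.character(X[[v]])) X[[v]] <- factor(X[[v]])
  mm <- stats::model.matrix(~ ., data = X)
  d <- as.data.frame(mm[, -1, drop = FALSE])
  names(d) <- make.names(colnames(mm)[-1], unique = TRUE)
  d
}

# Align a one-hot design with the column set seen at fit time.
align_design <- function(d, cols) {
  missing <- setdiff(cols, names(d))
  for (m in missing) d[[m]] <- 0
  d[, cols, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
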