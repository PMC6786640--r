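# Shared fixtures and independent oracles used across test files.

# small hand-built dataset: 4 samples x 3 features, both groups, two ages
make_tiny_dataset <- function() {
  x <- matrix(c(10, 20, 30,
                11, 21, 31,
                12, 22, 32,
                13, 23, 33), 4, 3, byrow = TRUE)
  meta <- data.frame(
    sample_id = paste0("s", 1:4),
    group = c("control", "control", "exposed", "exposed"),
    age_days = c(30, 60, 30, 60),
    stringsAsFactors = FALSE
  )
  proteomic_dataset(x, meta, feature_ids = c("f1", "f2", "f3"))
}

# a small single-group cohort with a known linear age signal, direct build
make_cohort <- function(n_per_age = 4, ages = c(30, 60, 90, 120, 150),
                        n_features = 12, n_clock = 4, slope = 0.5,
                        noise = 2, group = "control", seed = 1) {
  set.seed(seed)
  n <- n_per_age * length(ages)
  age <- rep(ages, each = n_per_age)
  base <- runif(n_features, 100, 200)
  sl <- c(rep(slope, n_clock), rep(0, n_features - n_clock))
  x <- matrix(base, n, n_features, byrow = TRUE) +
    outer(age, sl) + matrix(rnorm(n * n_features, 0, noise), n)
  x[x < 0] <- 0
  meta <- data.frame(sample_id = sprintf("%s_%03d", group, seq_len(n)),
                     group = group, age_days = age,
                     stringsAsFactors = FALSE)
  proteomic_dataset(x, meta)
}

# elastic-net loss in the package's declared convention, for monotonicity checks
en_loss <- function(beta, intercept, Xs, y, gamma1, gamma2) {
  sum((y - intercept - Xs %*% beta)^2) +
    gamma1 * sum(abs(beta)) + gamma2 * sum(beta^2)
}

# standardize columns the way fit_clock declares (center, n-1 sd)
standardize_like_fit <- function(X) {
  sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), `/`)
}

# exhaustive pairwise AUC: concordant pairs + half credit for ties
auc_brute <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  cmp <- outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exact two-sided rank-sum p-value by exhaustive enumeration of group
# assignments (no ties assumed), mirroring the doubling rule of the exact test
rank_sum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(p, 1)
}
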