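# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately avoid the code paths (and where practical
# the base helpers) used by the implementation.

# average ranks from first principles: rank of x_i is
# (# strictly smaller) + (ties including self + 1) / 2
avg_rank_oracle <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, 0)
}

# Pearson correlation from the sum formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

spearman_oracle <- function(x, y) {
  pearson_oracle(avg_rank_oracle(x), avg_rank_oracle(y))
}

# OLS by explicit normal equations on [1, X]
ols_oracle <- function(X, y) {
  A <- cbind(1, X)
  drop(solve(t(A) %*% A, t(A) %*% y))
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), original order restored
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) min(1, p[ord[j]] * m / j), 0)
    q_sorted[i] <- min(cands)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# small ready-made synthetic study shared by several tests
make_small_study <- function(n = 60, seed = 3, n_train = 40, n_test1 = 10,
                             n_test2 = 10) {
  cohort <- generate_cohort(cohort_spec(n, seed = seed))
  transcripts <- generate_transcripts(cohort, seed = seed)
  ids <- rownames(cohort$features)
  shuffled <- sample(ids)  # caller controls the RNG
  list(cohort = cohort, transcripts = transcripts,
       split = list(train_ids = shuffled[seq_len(n_train)],
                    test1_ids = shuffled[n_train + seq_len(n_test1)],
                    test2_ids = shuffled[n_train + n_test1 + seq_len(n_test2)]))
}
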