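# Independent oracles and small in-code fixtures shared across the suite.

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled ranks to the first sample and count assignments whose rank-sum
# deviates from its null mean at least as much as the observed one.
# Independent of stats::wilcox.test (handles ties through midranks).
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  w <- colSums(matrix(r[idx, drop = FALSE], nrow = na))
  mu <- na * (length(pooled) + 1) / 2
  w_obs <- sum(r[seq_len(na)])
  mean(abs(w - mu) >= abs(w_obs - mu) - 1e-9)
}

# random ascending-sorted population for mechanism tests
make_pop <- function(n, d, lower = -5, upper = 5) {
  pos <- matrix(runif(n * d, lower, upper), n, d)
  val <- rowSums(pos^2)
  ord <- order(val)
  gazelle:::new_population(pos[ord, , drop = FALSE], val[ord],
                           sorted = TRUE)
}

# wrap a problem so objective evaluations are counted
counting_problem <- function(problem) {
  env <- new.env()
  env$n <- 0L
  inner <- problem$objective
  problem$objective <- function(x) {
    env$n <- env$n + 1L
    inner(x)
  }
  list(problem = problem, counter = env)
}

# tiny linearly separable dataset: feature 1 separates the classes
# perfectly, the remaining columns are pure noise
separable_dataset <- function(n = 60, n_noise = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("case", "control"), each = n / 2)
    x1 <- ifelse(y == "case", 1, -1) + runif(n, -0.2, 0.2)
    noise <- matrix(rnorm(n * n_noise), n)
    df <- data.frame(x1 = x1, noise)
    names(df) <- paste0("x", seq_len(n_noise + 1))
    df$class <- factor(y)
    gazelle:::feature_dataset(df, "class", positive_class = "case")
  })
}
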