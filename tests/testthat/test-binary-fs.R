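test_that("sigmoid transfer is correct, symmetric and stable", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 0.8807971, tolerance = 1e-7)
  x <- c(-30, -3, -0.1, 0.4, 5, 30)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(sigmoid(x) > 0 & sigmoid(x) < 1))
  # extreme inputs saturate without overflowing
  expect_identical(sigmoid(c(-800, 800)), c(0, 1))
})

test_that("binarize thresholds sigmoid(x) at 0.5, i.e. x at 0", {
  expect_identical(binarize(c(-1.2, 0, 3.4, -0.001)), c(0L, 1L, 1L, 0L))
  expect_identical(binarize(rep(-0.5, 4)), rep(0L, 4))
  # threshold equivalence over random positions
  withr::with_seed(1, x <- rnorm(500, sd = 10))
  expect_identical(binarize(x), as.integer(x >= 0))
  expect_identical(as.integer(sigmoid(x) >= 0.5), as.integer(x >= 0))
})

test_that("error rate and sensitivity follow the confusion counts", {
  cc <- list(tp = 40, tn = 40, fp = 10, fn = 10)
  expect_equal(fitness_error_rate(cc), 0.2)
  expect_equal(fitness_error_rate(list(tp = 5, tn = 5, fp = 0, fn = 0)), 0)
  expect_equal(fitness_error_rate(list(tp = 0, tn = 0, fp = 5, fn = 5)), 1)
  expect_error(fitness_error_rate(list(tp = 0, tn = 0, fp = 0, fn = 0)))

  expect_equal(sensitivity(list(tp = 3, fn = 1, fp = 0, tn = 0)), 0.75)
  expect_equal(sensitivity(list(tp = 7, fn = 0, fp = 2, tn = 1)), 1)
  expect_equal(sensitivity(list(tp = 0, fn = 4, fp = 0, tn = 0)), 0)
  expect_true(is.na(sensitivity(list(tp = 0, fn = 0, fp = 3, tn = 5))))

  cc2 <- confusion_counts(c("a", "a", "b", "b"), c("a", "b", "b", "b"), "a")
  expect_equal(cc2, list(tp = 1L, tn = 2L, fp = 0L, fn = 1L))
  expect_equal(cc2$tp + cc2$tn + cc2$fp + cc2$fn, 4L)
})

test_that("subset evaluation separates signal from noise", {
  data <- separable_dataset()
  proto <- eval_protocol("logistic", seed = 3)
  # the perfectly separating feature alone classifies held-out data
  sig <- evaluate_subset(data, c(1, 0, 0), proto)
  expect_equal(sig$fitness, 0)
  expect_true(sig$counts$tp + sig$counts$tn + sig$counts$fp +
                sig$counts$fn > 0)
  # noise-only subsets do worse
  noise <- evaluate_subset(data, c(0, 1, 1), proto)
  expect_gt(noise$fitness, 0)
  expect_true(noise$fitness <= 1)
  # the all-zero mask is maximally penalized
  expect_equal(evaluate_subset(data, c(0, 0, 0), proto)$fitness, 1)
  expect_error(evaluate_subset(data, c(1, 0), proto), "mask length")
})

test_that("every classifier protocol returns a valid error rate", {
  data <- separable_dataset(n = 40)
  for (clf in c("svm", "knn", "logistic")) {
    res <- evaluate_subset(data, c(1, 1, 0), eval_protocol(clf, seed = 2))
    expect_gte(res$fitness, 0)
    expect_lte(res$fitness, 1)
    expect_equal(res$fitness, fitness_error_rate(res$counts))
  }
})

test_that("CSV round-trips exactly and imputes the median", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(x1 = c(1.1, 2.2, 3.3, 4.4), x2 = c(0.5, -1, 2, 7.25),
                   class = factor(c("a", "a", "b", "b")))
  write.csv(df, tmp, row.names = FALSE)
  d <- load_dataset(tmp, "class")
  expect_identical(unname(d$matrix[, "x1"]), df$x1)
  expect_false(any(d$missing_mask))

  # missing cell [1, ?, 3, ?] -> median of observed
  df$x1 <- c(1, NA, 3, NA)
  write.csv(df, tmp, row.names = FALSE, na = "")
  d2 <- load_dataset(tmp, "class")
  expect_equal(unname(d2$matrix[, "x1"]), c(1, 2, 3, 2))
  expect_identical(unname(d2$missing_mask[, "x1"]),
                   c(FALSE, TRUE, FALSE, TRUE))
})

test_that("CSV and ARFF encodings load to identical datasets", {
  g <- synth_fs_data(n_instances = 30, n_features = 6, n_informative = 2,
                     missing_rate = 0.05, seed = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  arff <- withr::local_tempfile(fileext = ".arff")
  write_dataset(g$dataset, csv, "csv")
  write_dataset(g$dataset, arff, "arff")
  a <- load_dataset(csv, "class", positive_class = "case")
  b <- load_dataset(arff, "class", positive_class = "case")
  expect_equal(a$matrix, b$matrix, tolerance = 1e-8)
  expect_identical(a$missing_mask, b$missing_mask)
  expect_identical(as.character(a$labels), as.character(b$labels))
  # round trip reproduces the generated dataset (missing cells re-imputed
  # identically because the observed medians are unchanged)
  expect_identical(a$matrix, g$dataset$matrix)
  expect_identical(a$missing_mask, g$dataset$missing_mask)
})

test_that("loader rejects malformed datasets", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1:4, class = c("a", "a", "b", "b")), tmp,
            row.names = FALSE)
  expect_error(load_dataset(tmp, "label"), "not found")
  expect_error(load_dataset(tmp, "class", positive_class = "zz"),
               "not a label value")
  write.csv(data.frame(x = c(NA, NA, NA, NA),
                       class = c("a", "a", "b", "b")),
            tmp, row.names = FALSE, na = "")
  expect_error(load_dataset(tmp, "class"), "entirely missing")
  write.csv(data.frame(x = 1:3, class = c("a", "a", "b")), tmp,
            row.names = FALSE)
  expect_error(load_dataset(tmp, "class"), "at least 2 instances")
})

test_that("categorical columns are integer-encoded with mode imputation", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(size = c("big", "small", "big", NA, "big", "small"),
                       v = 1:6,
                       class = rep(c("x", "y"), 3)),
            tmp, row.names = FALSE, na = "")
  d <- load_dataset(tmp, "class")
  expect_identical(unname(d$matrix[, "size"]), c(1, 2, 1, 1, 1, 2))
  expect_true(d$missing_mask[4, "size"])
})

test_that("BIMGO selects the single informative feature", {
  # D = 1 informative column: the 2-mask oracle is {select, not}
  withr::with_seed(10, {
    y <- rep(c("case", "control"), each = 20)
    df <- data.frame(x1 = ifelse(y == "case", 2, -2) + rnorm(40, sd = 0.3),
                     class = factor(y))
  })
  data <- gazelle:::feature_dataset(df, "class", positive_class = "case")
  hits <- vapply(1:20, function(s) {
    r <- bimgo_select(data, eval_protocol("logistic"), pop_size = 8,
                      max_iter = 10, seed = s)
    r$mask[1] == 1L
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("selection fitness is reproducible from the stored mask", {
  g <- synth_fs_data(n_instances = 60, n_features = 8, n_informative = 2,
                     effect_size = 3, seed = 5)
  r <- bimgo_select(g$dataset, eval_protocol("knn"), pop_size = 8,
                    max_iter = 12, seed = 4)
  again <- evaluate_subset(g$dataset, r$mask, r$protocol)
  expect_equal(r$fitness, again$fitness)
  expect_equal(r$counts, again$counts)
  expect_equal(r$n_selected, sum(r$mask))
  expect_equal(r$sensitivity, sensitivity(r$counts))
  expect_true(all(diff(r$trace) <= 0))
})

test_that("memoization does not change the search trajectory", {
  g <- synth_fs_data(n_instances = 50, n_features = 6, n_informative = 2,
                     seed = 6)
  r <- bimgo_select(g$dataset, eval_protocol("logistic"), pop_size = 6,
                    max_iter = 8, seed = 3)
  # unmemoized reference: same continuous search, objective re-evaluated
  # from scratch at every call
  proto <- r$protocol
  problem <- new_problem("fs", ncol(g$dataset$matrix), -5, 5,
                         function(x) {
                           evaluate_subset(g$dataset, binarize(x),
                                           proto)$fitness
                         })
  ref <- imgo_minimize(problem, pop_size = 6, max_iter = 8, seed = 3)
  expect_identical(binarize(ref$best_position), r$mask)
  expect_equal(ref$best_value, r$fitness)
  expect_identical(ref$trace, r$trace)
})
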