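# Binary transfer layer (BIMGO) and the wrapper feature-selection engine:
# sigmoid transfer + 0.5 threshold, dataset IO (CSV/ARFF), classifier
# protocol, and the error-rate / sensitivity metrics.

#' Numerically stable sigmoid transfer function
#'
#' `S(x) = 1 / (1 + exp(-x))`, computed without overflow for large `|x|`.
#' Maps a continuous optimizer coordinate to a feature-inclusion
#' probability.
#'
#' @param x Numeric vector.
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Threshold a continuous position into a feature mask
#'
#' Bit d is 1 iff `sigmoid(position_d) >= 0.5`, which for finite positions
#' is exactly the sign test `position_d >= 0` (the boundary 0 maps to 1).
#'
#' @param position Numeric vector (one coordinate per feature).
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(position) {
  as.integer(sigmoid(position) >= 0.5)
}

#' Confusion counts of a binary (one-vs-rest) prediction
#'
#' @param truth,pred Vectors of observed and predicted labels.
#' @param positive The label value treated as positive.
#' @return List with integer `tp`, `tn`, `fp`, `fn` summing to
#'   `length(truth)`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  t_pos <- truth == positive
  p_pos <- pred == positive
  list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
       fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' Classification error rate (wrapper fitness)
#'
#' `1 - accuracy = 1 - (tp + tn) / (tp + tn + fp + fn)`.
#'
#' @param counts Confusion counts from [confusion_counts()].
#' @return Error rate in `[0, 1]`.
#' @export
fitness_error_rate <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("no evaluated instances")
  1 - (counts$tp + counts$tn) / total
}

#' Sensitivity (recall of the positive class)
#'
#' `tp / (tp + fn)`; with no positive instances the quantity is undefined
#' and reported as `NA` rather than 0.
#'
#' @inheritParams fitness_error_rate
#' @return Sensitivity in `[0, 1]`, or `NA` when `tp + fn == 0`.
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fn)
}

# ---------------------------------------------------------------- datasets

# shared constructor: impute, encode, and validate a labeled data.frame
feature_dataset <- function(df, label, positive_class = NULL) {
  if (!label %in% names(df)) {
    stop("label column '", label, "' not found", call. = FALSE)
  }
  labels <- factor(as.character(df[[label]]))
  if (anyNA(df[[label]])) stop("missing values in the label column")
  df[[label]] <- NULL
  if (ncol(df) == 0) stop("dataset has no feature columns")
  if (any(table(labels) < 2)) {
    stop("each class needs at least 2 instances", call. = FALSE)
  }
  n <- nrow(df)
  mat <- matrix(0, n, ncol(df), dimnames = list(NULL, names(df)))
  mask <- matrix(FALSE, n, ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    col <- df[[j]]
    miss <- is.na(col)
    if (all(miss)) stop("column '", names(df)[j], "' is entirely missing")
    mask[, j] <- miss
    if (is.numeric(col)) {
      col[miss] <- median(col[!miss])        # numeric: median imputation
    } else {
      col <- as.character(col)
      tab <- table(col[!miss])
      col[miss] <- names(tab)[which.max(tab)]  # categorical: mode
      col <- as.integer(factor(col))           # then integer encoding
    }
    mat[, j] <- col
  }
  if (any(!is.finite(mat))) stop("non-finite entries after imputation")
  if (is.null(positive_class)) {
    positive_class <- names(which.min(table(labels)))  # minority class
  } else {
    positive_class <- as.character(positive_class)
    if (!positive_class %in% levels(labels)) {
      stop("positive class '", positive_class, "' not a label value")
    }
  }
  structure(
    list(matrix = mat, labels = labels, feature_names = colnames(mat),
         missing_mask = mask, positive_class = positive_class,
         label_name = label),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("<feature_dataset> ", nrow(x$matrix), " instances x ",
      ncol(x$matrix), " features; classes: ",
      paste(levels(x$labels), collapse = "/"),
      " (positive: ", x$positive_class, "); ",
      sum(x$missing_mask), " imputed cells\n", sep = "")
  invisible(x)
}

#' Load a labeled tabular dataset from CSV or ARFF
#'
#' Numeric columns pass through; categorical columns are integer-encoded
#' (alphabetical level order, so CSV and ARFF encodings of the same table
#' load identically).  Missing numeric values are imputed by the column
#' median, categorical by the mode; `missing_mask` records the imputation
#' sites.  CSV missing cells may be empty, `NA` or `?`; ARFF uses `?`.
#'
#' @param path File path.
#' @param label Name of the label column.
#' @param dialect `"csv"`, `"arff"`, or `"auto"` (by file extension).
#' @param positive_class Label value treated as positive; defaults to the
#'   minority class.
#' @return A `feature_dataset`: imputed numeric matrix, factor labels,
#'   feature names, missing-value mask, positive class.
#' @export
load_dataset <- function(path, label,
                         dialect = c("auto", "csv", "arff"),
                         positive_class = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff"
      else "csv"
  }
  df <- switch(dialect,
    csv = read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA", "?")),
    arff = foreign::read.arff(path)
  )
  feature_dataset(df, label, positive_class)
}

#' Write a `feature_dataset` to CSV or ARFF
#'
#' Cells that were imputed at load/generation time are serialized back as
#' missing (empty in CSV, `?` in ARFF), so [load_dataset()] round-trips the
#' file to an equal dataset.  CSV numerics use shortest round-trip
#' representation.
#'
#' @param dataset A `feature_dataset`.
#' @param path Output path.
#' @param dialect `"csv"` or `"arff"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, dialect = c("csv", "arff")) {
  dialect <- match.arg(dialect)
  mat <- dataset$matrix
  mat[dataset$missing_mask] <- NA
  df <- as.data.frame(mat)
  df[[dataset$label_name]] <- dataset$labels
  if (dialect == "csv") {
    # 17 significant digits guarantee exact double round-trip
    for (j in seq_len(ncol(mat))) {
      df[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.17g", df[[j]]))
    }
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    foreign::write.arff(df, path)
  }
  invisible(path)
}

# ---------------------------------------------------------- eval protocol

#' Wrapper evaluation protocol
#'
#' Bundles the classifier, the stratified hold-out fraction and the split
#' seed used by [evaluate_subset()].  The split is fixed per independent
#' run: [bimgo_select()] derives it from the run seed, so the wrapper
#' objective is deterministic within a run.
#'
#' @param classifier `"svm"` (radial-basis support vector classifier,
#'   default), `"knn"` (k-nearest neighbours) or `"logistic"`.
#' @param holdout Held-out fraction of instances (stratified by class).
#' @param k Neighbour count for the KNN classifier (odd avoids vote ties).
#' @param seed Seed for the split when the protocol is used standalone.
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(classifier = c("svm", "knn", "logistic"),
                          holdout = 0.2, k = 5, seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(holdout > 0, holdout < 1)
  structure(list(classifier = classifier, holdout = holdout, k = k,
                 seed = as.integer(seed), split = NULL),
            class = "eval_protocol")
}

# stratified hold-out split derived from a seed; leaves the caller's RNG
# stream untouched
make_split <- function(labels, holdout, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  test <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_test <- max(1, round(length(idx) * holdout))
    n_test <- min(n_test, length(idx) - 2)   # keep >= 2 per class in train
    if (n_test > 0) test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# fit the protocol's classifier on train and predict test labels; isolates
# the global RNG so classifier internals never shift the optimizer stream
fit_predict <- function(protocol, train_x, train_y, test_x) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(protocol$seed)
  # standardize by training statistics (constant columns left unscaled)
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  train_x <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
  test_x <- sweep(sweep(test_x, 2, mu), 2, sdv, "/")
  switch(protocol$classifier,
    svm = {
      fit <- e1071::svm(train_x, train_y, kernel = "radial", scale = FALSE)
      as.character(predict(fit, test_x))
    },
    knn = {
      k <- min(protocol$k, nrow(train_x))
      as.character(class::knn(train_x, test_x, train_y, k = k))
    },
    logistic = {
      y01 <- as.integer(train_y == levels(train_y)[2])
      fit <- suppressWarnings(
        glm.fit(cbind(1, train_x), y01, family = binomial())
      )
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      prob <- 1 / (1 + exp(-drop(cbind(1, test_x) %*% beta)))
      levels(train_y)[1 + as.integer(prob >= 0.5)]
    }
  )
}

#' Held-out error of a classifier on a feature subset
#'
#' Restricts the dataset to the masked-in columns, trains the protocol's
#' classifier on the stratified training partition, and returns the
#' held-out error rate together with the confusion counts for the declared
#' positive class.  The all-zero mask short-circuits to fitness 1 (empty
#' subsets are maximally penalized rather than repaired).
#'
#' @param data A `feature_dataset`.
#' @param mask Integer/logical vector, one bit per feature.
#' @param protocol An [eval_protocol()]; a split is derived from its seed
#'   when not already attached.
#' @return List with `fitness` (error rate) and `counts`.
#' @export
evaluate_subset <- function(data, mask, protocol = eval_protocol()) {
  mask <- as.integer(mask)
  if (length(mask) != ncol(data$matrix)) {
    stop("mask length must equal the number of features")
  }
  if (all(mask == 0)) {
    return(list(fitness = 1,
                counts = list(tp = 0L, tn = 0L, fp = 0L, fn = 0L)))
  }
  if (is.null(protocol$split)) {
    protocol$split <- make_split(data$labels, protocol$holdout,
                                 protocol$seed)
  }
  tr <- protocol$split$train
  te <- protocol$split$test
  if (length(unique(data$labels[tr])) < 2) {
    stop("training partition is single-class")
  }
  cols <- which(mask == 1)
  pred <- fit_predict(protocol,
                      data$matrix[tr, cols, drop = FALSE],
                      droplevels(data$labels[tr]),
                      data$matrix[te, cols, drop = FALSE])
  counts <- confusion_counts(as.character(data$labels[te]), pred,
                             data$positive_class)
  list(fitness = fitness_error_rate(counts), counts = counts)
}

# ------------------------------------------------------------ BIMGO search

#' Wrapper feature selection with the binary IMGO
#'
#' Runs [imgo_minimize()] over a continuous box with one dimension per
#' feature; every candidate position is thresholded through the sigmoid
#' transfer ([binarize()]) and scored by the held-out classifier error
#' ([evaluate_subset()]).  Subset evaluations are memoized by mask, so
#' revisited masks cost nothing.  The hold-out split is derived from the
#' run seed, making the whole selection a deterministic function of
#' `(data, protocol, seed)`.
#'
#' @param data A `feature_dataset` (see [load_dataset()],
#'   [synth_fs_data()]).
#' @param protocol Evaluation protocol; see [eval_protocol()].
#' @param pop_size,max_iter,seed,spiral_constant Passed to the continuous
#'   optimizer (defaults follow the wrapper protocol: 30 individuals, 100
#'   iterations).
#' @param fs_bounds Continuous box per feature dimension; the default
#'   `[-5, 5]` spans sigmoid values (0.007, 0.993) so both bit states stay
#'   reachable.
#' @return A `gazelle_fs`: selected `mask`, `fitness` (held-out error),
#'   `sensitivity`, `n_selected`, confusion `counts`, per-iteration
#'   fitness `trace`, `seed`, and the `protocol` (with its split) for
#'   re-evaluation.
#' @export
bimgo_select <- function(data, protocol = eval_protocol(),
                         pop_size = 30, max_iter = 100, seed = NULL,
                         fs_bounds = c(-5, 5), spiral_constant = 1) {
  stopifnot(inherits(data, "feature_dataset"), length(fs_bounds) == 2,
            fs_bounds[1] < fs_bounds[2])
  seed <- resolve_seed(seed)
  protocol$split <- make_split(data$labels, protocol$holdout,
                               derive_seed(seed, "split"))
  d <- ncol(data$matrix)
  memo <- new.env(parent = emptyenv())
  score_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    hit <- memo[[key]]
    if (is.null(hit)) {
      hit <- evaluate_subset(data, mask, protocol)
      memo[[key]] <- hit
    }
    hit
  }
  problem <- new_problem(
    name = "feature_selection", dim = d,
    lower = fs_bounds[1], upper = fs_bounds[2],
    objective = function(x) score_mask(binarize(x))$fitness
  )
  res <- imgo_minimize(problem, pop_size = pop_size, max_iter = max_iter,
                       seed = seed, spiral_constant = spiral_constant)
  mask <- binarize(res$best_position)
  best <- score_mask(mask)
  structure(
    list(mask = mask, fitness = best$fitness,
         sensitivity = sensitivity(best$counts),
         n_selected = sum(mask), counts = best$counts,
         feature_names = data$feature_names, trace = res$trace,
         evals = res$evals, seed = seed, protocol = protocol),
    class = "gazelle_fs"
  )
}
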