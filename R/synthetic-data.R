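# Synthetic labeled tabular data with known informative-feature ground
# truth, emulating binary-labeled biomedical feature-selection tasks.

#' Generate a synthetic labeled dataset with known informative features
#'
#' Class labels are assigned at the stated balance (exact counts, then
#' shuffled).  Informative columns are class-conditional Gaussians with
#' unit SD and means `+/- effect_size / 2`; redundant columns are random
#' positive linear combinations (weights uniform on (0.5, 1.5)) of the
#' informative columns plus SD-0.1 noise; all remaining columns are
#' standard Gaussian noise.  Missing cells are inserted uniformly at
#' `missing_rate` and imputed by the standard loader rules (median), with
#' the sites recorded in the dataset's `missing_mask`.  Fully
#' seed-deterministic.
#'
#' @param n_instances,n_features Dataset shape.
#' @param n_informative Number of class-separating columns.
#' @param effect_size Class-mean shift in noise-SD units.
#' @param n_redundant Columns built from the informative ones
#'   (`n_informative + n_redundant <= n_features`).
#' @param class_balance Fraction of positive ("case") instances, in (0,1).
#' @param missing_rate Fraction of feature cells set missing, in `[0, 1)`.
#' @param seed Integer seed; `NULL` draws one from the session RNG.
#' @return List with `dataset` (a `feature_dataset`, positive class
#'   `"case"`), `informative` (column indices), and `redundant`.
#' @examples
#' synth_fs_data(n_instances = 40, n_features = 8, n_informative = 2,
#'               seed = 1)$informative
#' @export
synth_fs_data <- function(n_instances = 300, n_features = 50,
                          n_informative = 5, effect_size = 2,
                          n_redundant = 0, class_balance = 0.5,
                          missing_rate = 0, seed = NULL) {
  stopifnot(n_informative >= 1,
            n_informative + n_redundant <= n_features,
            class_balance > 0, class_balance < 1,
            missing_rate >= 0, missing_rate < 1)
  seed <- resolve_seed(seed)
  set.seed(seed)
  n <- n_instances
  n_case <- round(n * class_balance)
  if (n_case < 2 || n - n_case < 2) stop("need >= 2 instances per class")
  y <- sample(rep(c(1L, 0L), c(n_case, n - n_case)))

  special <- sample.int(n_features, n_informative + n_redundant)
  informative <- sort(special[seq_len(n_informative)])
  redundant <- sort(special[-seq_len(n_informative)])

  mat <- matrix(rnorm(n * n_features), n, n_features)
  shift <- ifelse(y == 1, effect_size / 2, -effect_size / 2)
  for (j in informative) mat[, j] <- mat[, j] + shift
  for (j in redundant) {
    w <- runif(n_informative, 0.5, 1.5)
    mat[, j] <- drop(mat[, informative, drop = FALSE] %*% w) +
      rnorm(n, sd = 0.1)
  }
  if (missing_rate > 0) {
    holes <- which(runif(n * n_features) < missing_rate)
    mat[holes] <- NA
  }
  colnames(mat) <- sprintf("x%03d", seq_len(n_features))
  df <- as.data.frame(mat)
  df$class <- factor(ifelse(y == 1, "case", "control"),
                     levels = c("case", "control"))
  list(dataset = feature_dataset(df, "class", positive_class = "case"),
       informative = informative, redundant = redundant)
}
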