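# Multi-run experiment harness: seeded runs over (algorithm x problem)
# cells, mean/std/best aggregation, rank-by-mean with std tiebreak, and
# 5% Wilcoxon rank-sum comparisons.

gazelle_algorithms <- function() list(mgo = mgo_minimize,
                                      imgo = imgo_minimize)

#' Run a seeded multi-run optimization experiment
#'
#' Executes every (algorithm, problem) cell for `runs` independent runs,
#' with each run's seed derived from the root seed and the cell labels (so
#' results are replayable and invariant to execution order).  Cells are
#' aggregated to mean/std/best of the final best values and ranked within
#' each problem by mean, with the standard deviation breaking ties
#' (smaller is better); exact ties share the better rank.
#'
#' @param problems Character vector of benchmark names (see
#'   [benchmark_names()]) or a list of `problem_spec` objects.
#' @param algorithms Subset of `c("mgo", "imgo")`.
#' @param runs Independent runs per cell.
#' @param pop_size,max_iter Optimizer configuration shared by all cells.
#' @param seed Root seed.
#' @param keep_traces Keep the per-run convergence traces (list-column of
#'   runs x iterations matrices).
#' @return A `gazelle_experiment` tibble with one row per cell: `algorithm`,
#'   `problem`, `mean`, `std`, `best`, `rank`, and list-columns `finals`
#'   (and `traces`).
#' @examples
#' ex <- run_experiment("f1", runs = 2, pop_size = 10, max_iter = 20,
#'                      seed = 1)
#' ex[, c("algorithm", "problem", "mean", "rank")]
#' @export
run_experiment <- function(problems, algorithms = c("mgo", "imgo"),
                           runs = 20, pop_size = 30, max_iter = 500,
                           seed = 1, keep_traces = TRUE) {
  algos <- gazelle_algorithms()
  algorithms <- match.arg(algorithms, names(algos), several.ok = TRUE)
  stopifnot(runs >= 1)
  if (!is.list(problems)) {
    problems <- lapply(problems, benchmark_problem)
  }
  cells <- list()
  for (prob in problems) {
    for (alg in algorithms) {
      finals <- numeric(runs)
      traces <- matrix(NA_real_, runs, max_iter)
      failed <- FALSE
      for (r in seq_len(runs)) {
        res <- tryCatch(
          algos[[alg]](prob, pop_size = pop_size,
                                     max_iter = max_iter,
                                     seed = derive_seed(seed, alg,
                                                        prob$name, r)),
          error = function(e) NULL
        )
        if (is.null(res)) {
          failed <- TRUE
          break
        }
        finals[r] <- res$best_value
        traces[r, ] <- res$trace
      }
      cells[[length(cells) + 1]] <- tibble::tibble(
        algorithm = alg, problem = prob$name, failed = failed,
        mean = if (failed) NA_real_ else mean(finals),
        std = if (failed) NA_real_ else sd(finals),
        best = if (failed) NA_real_ else min(finals),
        finals = list(if (failed) numeric(0) else finals),
        traces = list(if (keep_traces && !failed) traces else NULL)
      )
    }
  }
  out <- dplyr::bind_rows(cells)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$problem),
    rank = rank_mean_std(.data$mean, .data$std)
  )
  out <- dplyr::ungroup(out)
  if (!keep_traces) out$traces <- NULL
  class(out) <- c("gazelle_experiment", class(out))
  out
}

# two-sided exact rank-sum p by enumerating all assignments of the pooled
# (mid)ranks to the first sample; feasible for min(n, m) <= 8
ranksum_perm_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  small_first <- na <= length(b)
  if (!small_first) {
    r <- rank(c(b, a))
    na <- length(b)
  }
  idx <- utils::combn(length(pooled), na)
  w <- colSums(matrix(r[idx], nrow = na))
  mu <- na * (length(pooled) + 1) / 2
  w_obs <- sum(r[seq_len(na)])
  mean(abs(w - mu) >= abs(w_obs - mu) - 1e-9)
}

# rank by mean with std as tiebreaker; exact (mean, std) ties share the
# better (smaller) rank
rank_mean_std <- function(mean, std) {
  ord <- order(mean, std)
  rk <- integer(length(mean))
  rk[ord] <- seq_along(ord)
  key <- paste(format(mean, digits = 17), format(std, digits = 17))
  as.integer(stats::ave(rk, key, FUN = min))
}

#' Two-sided Wilcoxon rank-sum comparison at the 5% level
#'
#' Compares two run distributions: exact enumeration when both samples are
#' small (`min(n, m) <= 8`) and tie-free, otherwise the tie-corrected
#' normal approximation with continuity correction.  The verdict is
#' assigned from the perspective of `a` under minimization: `"+"` when
#' p < 0.05 and `a`'s mean is lower (better), `"-"` when p < 0.05 and
#' higher, `"="` otherwise.  Two identical constant samples are degenerate
#' (no rank information): the p-value is reported as `NaN` and the verdict
#' as `"="`.
#'
#' @param a,b Numeric vectors of per-run final values.
#' @return List with `p_value`, `verdict` (`"+"`, `"="`, `"-"`), and
#'   `degenerate`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1) {
    return(list(p_value = NaN, verdict = "=", degenerate = TRUE))
  }
  small <- min(length(a), length(b)) <= 8
  tied <- anyDuplicated(c(a, b)) > 0
  enumerable <- choose(length(a) + length(b),
                       min(length(a), length(b))) <= 2e4
  p <- if (small && tied && enumerable) {
    # exact permutation null over midranks; stats::wilcox.test has no
    # exact mode under ties
    ranksum_perm_p(a, b)
  } else {
    suppressWarnings(
      wilcox.test(a, b, exact = small && !tied, correct = TRUE)
    )$p.value
  }
  verdict <- if (p < 0.05) {
    if (mean(a) < mean(b)) "+" else "-"
  } else "="
  list(p_value = p, verdict = verdict, degenerate = FALSE)
}

#' Compare a reference algorithm against the others per problem
#'
#' Runs [wilcoxon_ranksum()] of the reference algorithm's per-run finals
#' against every other algorithm on every problem of an experiment.
#'
#' @param experiment A [run_experiment()] result.
#' @param reference Algorithm name the verdicts are relative to.
#' @return Tibble with `problem`, `algorithm`, `p_value`, `verdict`,
#'   `degenerate`.
#' @export
compare_algorithms <- function(experiment, reference = "imgo") {
  stopifnot(reference %in% experiment$algorithm)
  rows <- list()
  for (prob in unique(experiment$problem)) {
    sub <- experiment[experiment$problem == prob, ]
    ref <- sub$finals[[which(sub$algorithm == reference)]]
    for (i in which(sub$algorithm != reference)) {
      w <- wilcoxon_ranksum(ref, sub$finals[[i]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        problem = prob, algorithm = sub$algorithm[i],
        p_value = w$p_value, verdict = w$verdict,
        degenerate = w$degenerate
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Tally +/=/- verdicts
#'
#' @param verdicts Character vector of `"+"`, `"="`, `"-"`.
#' @return The summary string `"<wins>/<ties>/<losses>"`.
#' @export
tally_verdicts <- function(verdicts) {
  sprintf("%d/%d/%d", sum(verdicts == "+"), sum(verdicts == "="),
          sum(verdicts == "-"))
}

#' Average rank per algorithm
#'
#' Arithmetic mean of the per-problem ranks, the row used to order
#' algorithms across a whole suite.
#'
#' @param experiment A [run_experiment()] result.
#' @return Tibble with `algorithm` and `avg_rank`.
#' @export
average_rank <- function(experiment) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(experiment),
                                   .data$algorithm),
                   avg_rank = mean(.data$rank), .groups = "drop")
}

#' Write experiment report files
#'
#' Emits `summary.csv` (per-cell mean/std/best/rank), `average_rank.csv`,
#' per-cell mean convergence traces (`trace_<algorithm>_<problem>.csv`),
#' and, when comparisons are supplied, `comparisons.csv` with a trailing
#' `+/=/-` tally row.  Regeneration from the same experiment object is
#' byte-identical.
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @param comparisons Optional [compare_algorithms()] result.
#' @return Character vector of the files written, invisibly.
#' @export
report_experiment <- function(experiment, dir, comparisons = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summary_df <- as.data.frame(
    experiment[, c("algorithm", "problem", "mean", "std", "best", "rank")]
  )
  p <- file.path(dir, "summary.csv")
  write.csv(summary_df, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "average_rank.csv")
  write.csv(as.data.frame(average_rank(experiment)), p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(experiment$traces)) {
    for (i in seq_len(nrow(experiment))) {
      tr <- experiment$traces[[i]]
      if (is.null(tr)) next
      p <- file.path(dir, sprintf("trace_%s_%s.csv",
                                  experiment$algorithm[i],
                                  experiment$problem[i]))
      write.csv(data.frame(iteration = seq_len(ncol(tr)),
                           best_value = colMeans(tr)),
                p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(comparisons)) {
    cmp <- as.data.frame(comparisons[, c("problem", "algorithm",
                                         "p_value", "verdict")])
    cmp$p_value <- as.character(cmp$p_value)
    cmp <- rbind(cmp, data.frame(problem = "+/=/-", algorithm = "all",
                                 p_value = "",
                                 verdict = tally_verdicts(
                                   comparisons$verdict)))
    p <- file.path(dir, "comparisons.csv")
    write.csv(cmp, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
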