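# broom-style accessors and ggplot2 autoplot methods for result objects

#' @export
print.gazelle_result <- function(x, ...) {
  cat("<gazelle_result> ", toupper(x$algorithm), " on ", x$problem,
      ": best value ", format(x$best_value, digits = 6),
      " after ", x$max_iter, " iterations (", x$evals,
      " evaluations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Tidy an optimization result into its convergence trace
#'
#' @param x A `gazelle_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_value`.
#' @export
tidy.gazelle_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), best_value = x$trace)
}

#' One-row summary of an optimization result
#'
#' @inheritParams tidy.gazelle_result
#' @return One-row tibble: algorithm, problem, best value, evaluation
#'   count, configuration and seed.
#' @export
glance.gazelle_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, problem = x$problem,
                 best_value = x$best_value, evals = x$evals,
                 pop_size = x$pop_size, max_iter = x$max_iter,
                 seed = x$seed)
}

#' Convergence-curve plot of an optimization result
#'
#' Best objective value per iteration; the value axis is log-scaled when
#' the whole trace is positive.
#'
#' @param object A `gazelle_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gazelle_result <- function(object, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(.data$iteration, .data$best_value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "best objective value",
                  title = sprintf("%s on %s", toupper(object$algorithm),
                                  object$problem))
  if (all(object$trace > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
print.gazelle_fs <- function(x, ...) {
  cat("<gazelle_fs> ", x$n_selected, "/", length(x$mask),
      " features selected; fitness (error rate) ",
      format(x$fitness, digits = 4), ", sensitivity ",
      format(x$sensitivity, digits = 4), " (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Tidy a feature-selection result into per-feature rows
#'
#' @param x A `gazelle_fs` from [bimgo_select()].
#' @param ... Unused.
#' @return Tibble with `feature` and logical `selected`.
#' @export
tidy.gazelle_fs <- function(x, ...) {
  tibble::tibble(feature = x$feature_names, selected = x$mask == 1L)
}

#' One-row summary of a feature-selection result
#'
#' @inheritParams tidy.gazelle_fs
#' @return One-row tibble with fitness, sensitivity, selected count and
#'   seed.
#' @export
glance.gazelle_fs <- function(x, ...) {
  tibble::tibble(fitness = x$fitness, sensitivity = x$sensitivity,
                 n_selected = x$n_selected, n_features = length(x$mask),
                 seed = x$seed)
}

#' Fitness-trace plot of a feature-selection run
#'
#' @param object A `gazelle_fs`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gazelle_fs <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace),
                       fitness = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "held-out error rate",
                  title = "BIMGO wrapper feature selection")
}

#' Tidy an experiment into per-run rows
#'
#' @param x A `gazelle_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return Tibble with `algorithm`, `problem`, `run`, `final`.
#' @export
tidy.gazelle_experiment <- function(x, ...) {
  tbl <- tibble::as_tibble(x)[, c("algorithm", "problem", "finals")]
  tbl <- tidyr_unnest_finals(tbl)
  tbl
}

# minimal unnest of the finals list-column (avoids a tidyr dependency)
tidyr_unnest_finals <- function(tbl) {
  out <- list()
  for (i in seq_len(nrow(tbl))) {
    f <- tbl$finals[[i]]
    out[[i]] <- tibble::tibble(algorithm = tbl$algorithm[i],
                               problem = tbl$problem[i],
                               run = seq_along(f), final = f)
  }
  dplyr::bind_rows(out)
}

#' Per-cell summary of an experiment
#'
#' @inheritParams tidy.gazelle_experiment
#' @return Tibble with per-cell mean, std, best, and rank.
#' @export
glance.gazelle_experiment <- function(x, ...) {
  tibble::as_tibble(x)[, c("algorithm", "problem", "mean", "std", "best",
                           "rank")]
}

#' Mean convergence curves of an experiment
#'
#' One line per algorithm, faceted by problem; log value axis when all
#' traces are positive.
#'
#' @param object A `gazelle_experiment` with traces retained.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gazelle_experiment <- function(object, ...) {
  if (is.null(object$traces)) stop("experiment was run without traces")
  rows <- list()
  for (i in seq_len(nrow(object))) {
    tr <- object$traces[[i]]
    if (is.null(tr)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      algorithm = object$algorithm[i], problem = object$problem[i],
      iteration = seq_len(ncol(tr)), best_value = colMeans(tr)
    )
  }
  df <- dplyr::bind_rows(rows)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$best_value,
                                        colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~problem, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "mean best objective value")
  if (all(df$best_value > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
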