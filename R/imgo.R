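# Improved mountain gazelle optimizer (IMGO): chaotic-map initialization,
# nonlinear control factor, spiral perturbation with greedy acceptance, and
# neighborhood search around the incumbent best.

#' One step of the ICMIC chaotic map
#'
#' The iterative chaotic map with infinite collapses,
#' `omega' = sin(epsilon / omega)` with `epsilon = 0.7 * pi`, on the domain
#' `[-1, 0) U (0, 1]`.  The divisive form is the canonical
#' infinite-collapses map (the domain excludes 0 because of the division);
#' a multiplicative reading `sin(epsilon * omega)` is exposed for
#' comparison.  An iterate that underflows to exactly 0 is re-perturbed by
#' machine epsilon so the orbit never leaves the domain.
#'
#' @param omega Current state, nonzero, in `[-1, 1]`.
#' @param epsilon Map parameter, `alpha * pi` with `alpha = 0.7`.
#' @param divisive Use the infinite-collapses form `sin(epsilon / omega)`.
#' @return The next state in `[-1, 1]`.
#' @export
icmic_next <- function(omega, epsilon = 0.7 * pi, divisive = TRUE) {
  if (omega == 0) stop("ICMIC state must be nonzero")
  out <- if (divisive) sin(epsilon / omega) else sin(epsilon * omega)
  if (out == 0) out <- .Machine$double.eps
  out
}

# thread one chaotic chain across all N x D position slots in row-major
# order and map each state affinely into the box:
# x = lb + (omega + 1) / 2 * (ub - lb)
icmic_positions <- function(n, lower, upper, divisive = TRUE) {
  d <- length(lower)
  omega <- runif(1, -1, 1)
  if (omega == 0) omega <- 1
  chain <- numeric(n * d)
  for (k in seq_len(n * d)) {
    omega <- icmic_next(omega, divisive = divisive)
    chain[k] <- omega
  }
  # chain is row-major; R matrices fill column-major, so transpose
  pos <- matrix(chain, n, d, byrow = TRUE)
  sweep(sweep((pos + 1) / 2, 2, upper - lower, "*"), 2, lower, "+")
}

#' Initialize a population with ICMIC chaotic mapping
#'
#' Advances a single chaotic chain from a random start across all
#' `n * dim` position slots in row-major order, maps each state into the
#' box, and returns the evaluated, ascending-sorted population.  The
#' chaotic orbit spreads the initial population ergodically over the box.
#'
#' @param problem A `problem_spec`.
#' @param n Population size.
#' @param divisive Use the divisive (infinite-collapses) map form.
#' @return Internal population: list with `pos` (n x dim), `val`, `sorted`.
#' @keywords internal
#' @export
init_population_icmic <- function(problem, n, divisive = TRUE) {
  pos <- icmic_positions(n, problem$lower, problem$upper, divisive)
  sort_population(new_population(pos, eval_rows(problem$objective, pos)))
}

#' Nonlinear control factor
#'
#' `-2 + log2(1 + (1 - iter/max_iter)^2)`: equals -1 at the start and -2 at
#' the end, changing fastest early (wide search) and slowest late (local
#' refinement).  Replaces [control_factor_linear()] in IMGO mode.
#'
#' @inheritParams weight_f
#' @return A scalar in `[-2, -1]`.
#' @export
control_factor_nonlinear <- function(iter, max_iter) {
  -2 + log2(1 + (1 - iter / max_iter)^2)
}

#' Logarithmic-spiral perturbation around the incumbent best
#'
#' `best + exp(c * l) * cos(2 * pi * l) * |best - x|` with a single path
#' coefficient `l ~ U[-1, 1]` shared across dimensions, the whale-style
#' encircling move.  The caller clips to bounds and accepts greedily.
#'
#' @param x Current position.
#' @param best Incumbent best position.
#' @param c Spiral shape constant (default 1).
#' @param l Path coefficient; drawn internally when `NULL` (exposed for
#'   testing).
#' @return Unclipped candidate position.
#' @export
spiral_perturb <- function(x, best, c = 1, l = NULL) {
  if (is.null(l)) l <- runif(1, -1, 1)
  best + exp(c * l) * cos(2 * pi * l) * abs(best - x)
}

#' Uniform draw from the best/second-best neighborhood
#'
#' Samples each coordinate uniformly from
#' `[best_d - |best_d - second_d|, best_d + |best_d - second_d|]`, the
#' neighborhood spanned by the incumbent best and second-best individuals.
#' The caller clips to the problem box and accepts greedily into the
#' incumbent.
#'
#' @param best,second_best Best and second-best positions of the current
#'   sorted population.
#' @return Unclipped candidate position.
#' @export
neighborhood_search <- function(best, second_best) {
  w <- abs(best - second_best)
  runif(length(best), best - w, best + w)
}

#' Minimize a problem with the improved mountain gazelle optimizer
#'
#' Runs the full improved loop: ICMIC chaotic initialization, nonlinear
#' control factor, the four mechanism offspring per individual plus a
#' greedy spiral perturbation of each current individual, ascending elitist
#' selection, and one greedy neighborhood candidate around the incumbent
#' best per iteration.  Uses exactly `5 * pop_size + 1` objective
#' evaluations per iteration.
#'
#' @inheritParams mgo_minimize
#' @param spiral_constant Spiral shape constant `c` of the perturbation.
#' @param icmic Chaotic map form for initialization: `"divisive"`
#'   (infinite collapses, default) or `"multiplicative"`.
#' @return A `gazelle_result`; see [mgo_minimize()].
#' @examples
#' r <- imgo_minimize(benchmark_problem("f9", dim = 2), max_iter = 60, seed = 1)
#' r$best_value
#' @export
imgo_minimize <- function(problem, pop_size = 30, max_iter = 500,
                          seed = NULL, spiral_constant = 1,
                          icmic = c("divisive", "multiplicative")) {
  run_gazelle(problem, pop_size, max_iter, seed, improved = TRUE,
              spiral_constant = spiral_constant, icmic = icmic)
}
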