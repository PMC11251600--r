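# Classical 23-function continuous benchmark suite: unimodal (f1-f7),
# multimodal (f8-f13), and fixed-dimension multimodal (f14-f23) problems,
# with the documented box bounds, default dimensions and known optima.

# -- fixed constant matrices for the classical fixed-dimension functions ----

# Shekel foxholes (f14): 25 foci on a 5x5 grid
.foxholes_a <- local({
  v <- c(-32, -16, 0, 16, 32)
  rbind(rep(v, 5), rep(v, each = 5))
})

# Kowalik (f15)
.kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.1600, 0.0844, 0.0627,
                0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

# Hartmann 3-d (f19) and 6-d (f20)
.hart_c <- c(1, 1.2, 3, 3.2)
.hart3_a <- matrix(c(3, 10, 30, 0.1, 10, 35, 3, 10, 30, 0.1, 10, 35),
                   4, 3, byrow = TRUE)
.hart3_p <- matrix(c(0.3689, 0.1170, 0.2673,
                     0.4699, 0.4387, 0.7470,
                     0.1091, 0.8732, 0.5547,
                     0.0381, 0.5743, 0.8828), 4, 3, byrow = TRUE)
.hart6_a <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                     0.05, 10, 17, 0.1, 8, 14,
                     3, 3.5, 1.7, 10, 17, 8,
                     17, 8, 0.05, 10, 0.1, 14), 4, 6, byrow = TRUE)
.hart6_p <- matrix(c(0.1312, 0.1696, 0.5569, 0.0124, 0.8283, 0.5886,
                     0.2329, 0.4135, 0.8307, 0.3736, 0.1004, 0.9991,
                     0.2348, 0.1451, 0.3522, 0.2883, 0.3047, 0.6650,
                     0.4047, 0.8828, 0.8732, 0.5743, 0.1091, 0.0381),
                   4, 6, byrow = TRUE)

# Shekel family (f21-f23): 10 foci, first m used
.shekel_a <- rbind(c(4, 4, 4, 4), c(1, 1, 1, 1), c(8, 8, 8, 8),
                   c(6, 6, 6, 6), c(3, 7, 3, 7), c(2, 9, 2, 9),
                   c(5, 5, 3, 3), c(8, 1, 8, 1), c(6, 2, 6, 2),
                   c(7, 3.6, 7, 3.6))
.shekel_c <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)

.shekel_fn <- function(m) {
  a <- .shekel_a[seq_len(m), , drop = FALSE]
  cc <- .shekel_c[seq_len(m)]
  function(x) -sum(1 / (rowSums((a - matrix(x, m, 4, byrow = TRUE))^2) + cc))
}

# penalty term shared by f12/f13; the middle branch covers [-a, a] inclusive
.penalty_u <- function(x, a, k, m) {
  out <- numeric(length(x))
  hi <- x > a
  lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  out
}

# registry: each entry has bounds per unit dimension, a default dim, whether
# the dimension is overridable, the objective, and the documented optimum
.bench_registry <- list(
  f1 = list(range = c(-100, 100), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x) sum(x^2)),
  f2 = list(range = c(-10, 10), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x) sum(abs(x)) + prod(abs(x))),
  f3 = list(range = c(-100, 100), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x) sum(cumsum(x)^2)),
  f4 = list(range = c(-100, 100), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x) max(abs(x))),
  f5 = list(range = c(-30, 30), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x) {
              n <- length(x)
              sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
            }),
  f6 = list(range = c(-100, 100), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x) sum((x + 0.5)^2)),
  f7 = list(range = c(-1.28, 1.28), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x, noise = runif(1)) {
              sum(seq_along(x) * x^4) + noise
            }),
  f8 = list(range = c(-500, 500), dim = 30, fixed = FALSE, opt = NA_real_,
            fn = function(x) sum(-x * sin(sqrt(abs(x))))),
  f9 = list(range = c(-5.12, 5.12), dim = 30, fixed = FALSE, opt = 0,
            fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)),
  f10 = list(range = c(-32, 32), dim = 30, fixed = FALSE, opt = 0,
             fn = function(x) {
               n <- length(x)
               -20 * exp(-0.2 * sqrt(sum(x^2) / n)) -
                 exp(sum(cos(2 * pi * x)) / n) + 20 + exp(1)
             }),
  f11 = list(range = c(-600, 600), dim = 30, fixed = FALSE, opt = 0,
             fn = function(x) {
               sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
             }),
  f12 = list(range = c(-50, 50), dim = 30, fixed = FALSE, opt = 0,
             fn = function(x) {
               n <- length(x)
               y <- 1 + (x + 1) / 4
               pi / n * (10 * sin(pi * y[1])^2 +
                           sum((y[-n] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                           (y[n] - 1)^2) + sum(.penalty_u(x, 5, 100, 4))
             }),
  f13 = list(range = c(-50, 50), dim = 30, fixed = FALSE, opt = 0,
             fn = function(x) {
               n <- length(x)
               0.1 * (sin(3 * pi * x[1])^2 +
                        sum((x[-n] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
                        (x[n] - 1)^2 * (1 + sin(2 * pi * x[n])^2)) +
                 sum(.penalty_u(x, 5, 100, 4))
             }),
  f14 = list(range = c(-65.536, 65.536), dim = 2, fixed = TRUE, opt = 0.998004,
             fn = function(x) {
               d <- colSums((.foxholes_a - x)^6)
               1 / (1 / 500 + sum(1 / (seq_len(25) + d)))
             }),
  f15 = list(range = c(-5, 5), dim = 4, fixed = TRUE, opt = 0.0003074861,
             fn = function(x) {
               b <- .kowalik_b
               sum((.kowalik_a -
                      x[1] * (b^2 + b * x[2]) / (b^2 + b * x[3] + x[4]))^2)
             }),
  f16 = list(range = c(-5, 5), dim = 2, fixed = TRUE, opt = -1.0316285,
             fn = function(x) {
               4 * x[1]^2 - 2.1 * x[1]^4 + x[1]^6 / 3 +
                 x[1] * x[2] - 4 * x[2]^2 + 4 * x[2]^4
             }),
  f17 = list(range = c(-5, 5), dim = 2, fixed = TRUE, opt = 0.397887,
             fn = function(x) {
               (x[2] - 5.1 / (4 * pi^2) * x[1]^2 + 5 / pi * x[1] - 6)^2 +
                 10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10
             }),
  f18 = list(range = c(-2, 2), dim = 2, fixed = TRUE, opt = 3,
             fn = function(x) {
               (1 + (x[1] + x[2] + 1)^2 *
                  (19 - 14 * x[1] + 3 * x[1]^2 - 14 * x[2] +
                     6 * x[1] * x[2] + 3 * x[2]^2)) *
                 (30 + (2 * x[1] - 3 * x[2])^2 *
                    (18 - 32 * x[1] + 12 * x[1]^2 + 48 * x[2] -
                       36 * x[1] * x[2] + 27 * x[2]^2))
             }),
  f19 = list(range = c(0, 1), dim = 3, fixed = TRUE, opt = -3.86278,
             fn = function(x) {
               xm <- matrix(x, 4, 3, byrow = TRUE)
               -sum(.hart_c * exp(-rowSums(.hart3_a * (xm - .hart3_p)^2)))
             }),
  f20 = list(range = c(0, 1), dim = 6, fixed = TRUE, opt = -3.32237,
             fn = function(x) {
               xm <- matrix(x, 4, 6, byrow = TRUE)
               -sum(.hart_c * exp(-rowSums(.hart6_a * (xm - .hart6_p)^2)))
             }),
  f21 = list(range = c(0, 10), dim = 4, fixed = TRUE, opt = -10.1532,
             fn = .shekel_fn(5)),
  f22 = list(range = c(0, 10), dim = 4, fixed = TRUE, opt = -10.4029,
             fn = .shekel_fn(7)),
  f23 = list(range = c(0, 10), dim = 4, fixed = TRUE, opt = -10.5364,
             fn = .shekel_fn(10))
)

#' Names of the built-in benchmark functions
#'
#' @return Character vector `c("f1", ..., "f23")`.
#' @export
benchmark_names <- function() names(.bench_registry)

#' Construct a continuous minimization problem
#'
#' A problem bundles an objective, its box bounds, dimension and (when
#' documented) the known global optimum.  Problems are consumed by
#' [mgo_minimize()] and [imgo_minimize()].
#'
#' @param name Problem identifier, one of [benchmark_names()].
#' @param dim Dimension override.  Only the dimension-generic functions
#'   f1-f13 accept an override; f14-f23 have fixed dimensions.
#' @return A `problem_spec`: list with `name`, `dim`, `lower`, `upper`,
#'   `objective` and `known_optimum`.
#' @examples
#' p <- benchmark_problem("f9")
#' p$objective(rep(0, p$dim))
#' @export
benchmark_problem <- function(name, dim = NULL) {
  entry <- .bench_registry[[match.arg(name, benchmark_names())]]
  if (!is.null(dim)) {
    if (entry$fixed) {
      stop(name, " has a fixed dimension of ", entry$dim,
           "; dim cannot be overridden", call. = FALSE)
    }
    stopifnot(dim >= 1)
    entry$dim <- as.integer(dim)
  }
  new_problem(
    name = name,
    dim = entry$dim,
    lower = rep(entry$range[1], entry$dim),
    upper = rep(entry$range[2], entry$dim),
    objective = entry$fn,
    known_optimum = reference_optimum(name, entry$dim)
  )
}

#' Define a custom minimization problem
#'
#' @param name Identifier used in reports.
#' @param dim Positive integer dimension.
#' @param lower,upper Bounds, recycled to length `dim`; must satisfy
#'   `lower < upper` elementwise.
#' @param objective Function mapping a length-`dim` numeric vector to a
#'   single finite value.
#' @param known_optimum Optional documented global minimum value.
#' @return A `problem_spec` list.
#' @export
new_problem <- function(name, dim, lower, upper, objective,
                        known_optimum = NA_real_) {
  dim <- as.integer(dim)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  stopifnot(dim >= 1, all(lower < upper), is.function(objective))
  structure(
    list(name = as.character(name), dim = dim, lower = lower, upper = upper,
         objective = objective, known_optimum = known_optimum),
    class = "problem_spec"
  )
}

#' @export
print.problem_spec <- function(x, ...) {
  cat("<problem_spec> ", x$name, ": dim ", x$dim,
      ", box [", x$lower[1], ", ", x$upper[1], "]",
      if (!is.na(x$known_optimum)) paste0(", optimum ", x$known_optimum),
      "\n", sep = "")
  invisible(x)
}

#' Documented global optimum of a benchmark function
#'
#' Returns the "optimal value" documented for the suite.  The Schwefel
#' function f8 scales with dimension (`-418.9829 * dim`); the Kowalik
#' function f15 is stored at its full classical precision (0.0003075
#' to four significant digits).
#'
#' @inheritParams benchmark_problem
#' @param dim Dimension used for the dimension-dependent f8 optimum.
#' @return The documented minimum objective value.
#' @export
reference_optimum <- function(name, dim = 30) {
  entry <- .bench_registry[[match.arg(name, benchmark_names())]]
  if (name == "f8") return(-418.9829 * dim)
  entry$opt
}

#' Locate a problem's global minimum by multistart local descent
#'
#' Independent verification of the registry: seeds local L-BFGS-B descents
#' from a coarse grid over the box (plus, for the Shekel family, the
#' standard focus points) and returns the best refined value.  Deterministic.
#'
#' @param problem A `problem_spec` (typically fixed-dimension, f14-f23).
#' @param n_grid Grid points per axis used for starts (full factorial up to
#'   `max_starts`, otherwise the best `max_starts` grid evaluations).
#' @param max_starts Cap on the number of local descents.
#' @return List with `value` (best minimum found) and `par`, plus
#'   `n_starts`.
#' @export
multistart_minimum <- function(problem, n_grid = 20, max_starts = 200) {
  d <- problem$dim
  axes <- lapply(seq_len(d), function(j) {
    seq(problem$lower[j], problem$upper[j], length.out = n_grid)
  })
  grid <- as.matrix(expand.grid(axes))
  vals <- apply(grid, 1, problem$objective)
  starts <- grid[order(vals)[seq_len(min(max_starts, nrow(grid)))], ,
                 drop = FALSE]
  if (problem$name %in% c("f21", "f22", "f23")) {
    starts <- rbind(starts, .shekel_a)
  }
  best <- list(value = Inf, par = NULL)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], problem$objective, method = "L-BFGS-B",
            lower = problem$lower, upper = problem$upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$value < best$value) {
      best <- list(value = fit$value, par = fit$par)
    }
  }
  best$n_starts <- nrow(starts)
  best
}
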