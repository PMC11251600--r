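# Baseline mountain gazelle optimizer (MGO).
#
# Each iteration every individual spawns four candidates modeling herd
# behaviors -- territorial solitary males (TSM), maternity herds (MH),
# bachelor male herds (BMH), and migration to search for food (MSF) --
# which are pooled with the parents; the best N survive (elitism).
# All draws come from R's seeded global RNG stream.

#' Young-male herd effect vector BH
#'
#' `BH = X_ra * floor(r1) + M_pr * ceiling(r2)` with `r1, r2 ~ U[0,1)`:
#' `X_ra` is a random member of the worse-fitness third of the ascending-
#' sorted population (indices `ceiling(N/3)..N`, 1-based) and `M_pr` the
#' mean position of `ceiling(N/3)` uniformly chosen individuals.  Since
#' `floor(r1)` is almost surely 0, the formula is implemented literally and
#' BH reduces to `M_pr` with probability one.
#'
#' @param pop Internal population (ascending-sorted).
#' @param details Attach the sampled stratum index `ra` as an attribute
#'   (for diagnostics; the index is invisible in the output because
#'   `floor(r1)` vanishes almost surely).
#' @return A length-D numeric vector.
#' @keywords internal
#' @export
coef_bh <- function(pop, details = FALSE) {
  if (!isTRUE(pop$sorted)) stop("population must be sorted ascending")
  n <- nrow(pop$pos)
  third <- ceiling(n / 3)
  ra <- if (third >= n) n else third + floor(runif(1) * (n - third + 1))
  pr <- sample.int(n, third)
  m_pr <- colMeans(pop$pos[pr, , drop = FALSE])
  r1 <- runif(1)
  r2 <- runif(1)
  out <- pop$pos[ra, ] * floor(r1) + m_pr * ceiling(r2)
  if (details) attr(out, "ra") <- ra
  out
}

#' Iteration-decaying normal weight F
#'
#' A standard-normal D-vector scaled by `exp(2 - 2 * iter / max_iter)`:
#' scale e^2 at the start of the search, 1 at the end.
#'
#' @param dim Problem dimension.
#' @param iter,max_iter Current and maximum iteration.
#' @return A length-`dim` numeric vector.
#' @keywords internal
#' @export
weight_f <- function(dim, iter, max_iter) {
  rnorm(dim) * exp(2 - iter * (2 / max_iter))
}

#' Linear control factor
#'
#' Decays linearly from -1 at `iter = 0` to -2 at `iter = max_iter`; used
#' by the baseline MGO coefficient vectors.
#'
#' @inheritParams weight_f
#' @return A scalar in `[-2, -1]`.
#' @export
control_factor_linear <- function(iter, max_iter) {
  -1 + iter * (-1 / max_iter)
}

#' Random coefficient vector Cof
#'
#' Uniformly selects one of four randomized forms: (1) the scalar
#' `(a + 1) + r3` broadcast to D; (2) `a * N2(D)`; (3) `U[0,1)^D`;
#' (4) `N3(D) * N4(D)^2 * cos(2 r4 * N3(D))` elementwise with scalar `r4`.
#'
#' @param a Control factor in `[-2, -1]` (see [control_factor_linear()],
#'   [control_factor_nonlinear()]).
#' @param dim Problem dimension.
#' @return A length-`dim` numeric vector.
#' @keywords internal
#' @export
coef_vector <- function(a, dim) {
  switch(1L + floor(runif(1) * 4),
    rep((a + 1) + runif(1), dim),
    a * rnorm(dim),
    runif(dim),
    {
      n3 <- rnorm(dim)
      n3 * rnorm(dim)^2 * cos((runif(1) * 2) * n3)
    }
  )
}

# random integer coefficient in {1, 2}
ri12 <- function() 1L + (runif(1) >= 0.5)

#' Territorial solitary male move (TSM)
#'
#' `best - |(ri1 BH - ri2 X_i) * F| * Cof` with `ri1, ri2` uniform on
#' `{1, 2}`.
#'
#' @param pop Internal population.
#' @param i Index of the current individual.
#' @param best Incumbent best position.
#' @param f,bh,cof Precomputed [weight_f()], [coef_bh()] and
#'   [coef_vector()] realizations.
#' @return Unclipped candidate position.
#' @keywords internal
#' @export
step_tsm <- function(pop, i, best, f, bh, cof) {
  best - abs((ri12() * bh - ri12() * pop$pos[i, ]) * f) * cof
}

#' Maternity herd move (MH)
#'
#' `(BH + Cof1) + (ri3 best - ri4 X_rand) * Cof2` with two fresh
#' coefficient vectors and a uniformly chosen random individual.
#'
#' @inheritParams step_tsm
#' @param a Control factor for the fresh coefficient draws.
#' @return Unclipped candidate position.
#' @keywords internal
#' @export
step_mh <- function(pop, i, best, bh, a) {
  d <- ncol(pop$pos)
  cof1 <- coef_vector(a, d)
  cof2 <- coef_vector(a, d)
  x_rand <- pop$pos[1L + floor(runif(1) * nrow(pop$pos)), ]
  (bh + cof1) + (ri12() * best - ri12() * x_rand) * cof2
}

#' Bachelor male herd move (BMH)
#'
#' `(X_i - D) + (ri5 best - ri6 BH) * Cof` where
#' `D = (|X_i| + |best|) * (2 r6 - 1)`, `r6 ~ U[0,1)`.
#'
#' @inheritParams step_tsm
#' @return Unclipped candidate position.
#' @keywords internal
#' @export
step_bmh <- function(pop, i, best, bh, cof) {
  x <- pop$pos[i, ]
  dvec <- (abs(x) + abs(best)) * (2 * runif(1) - 1)
  (x - dvec) + (ri12() * best - ri12() * bh) * cof
}

#' Migration to search for food (MSF)
#'
#' A uniform random point in the box, one `r7 ~ U[0,1)` per dimension.
#'
#' @param lower,upper Box bounds.
#' @return A length-D position inside the box.
#' @keywords internal
#' @export
step_msf <- function(lower, upper) {
  (upper - lower) * runif(length(lower)) + lower
}

# generate the 4 mechanism offspring of gazelle i, clipped to bounds
mechanism_offspring <- function(pop, i, best, a, iter, max_iter,
                                lower, upper) {
  d <- length(lower)
  f <- weight_f(d, iter, max_iter)
  bh <- coef_bh(pop)
  out <- matrix(0, 4, d)
  out[1, ] <- step_tsm(pop, i, best, f, bh, coef_vector(a, d))
  out[2, ] <- step_mh(pop, i, best, bh, a)
  out[3, ] <- step_bmh(pop, i, best, bh, coef_vector(a, d))
  out[4, ] <- step_msf(lower, upper)
  out[] <- clip_bounds(out, rep(lower, each = 4), rep(upper, each = 4))
  out
}

new_opt_result <- function(algorithm, problem, best_pos, best_val, trace,
                           evals, seed, pop_size, max_iter) {
  structure(
    list(algorithm = algorithm, problem = problem$name,
         best_position = best_pos, best_value = best_val, trace = trace,
         evals = evals, seed = seed, pop_size = pop_size,
         max_iter = max_iter),
    class = "gazelle_result"
  )
}

#' Minimize a problem with the baseline mountain gazelle optimizer
#'
#' Uniform random initialization, linear control factor, and per-iteration
#' pooling of the four mechanism offspring of every individual with the
#' parents, of which the best `pop_size` survive.  Uses exactly
#' `4 * pop_size` objective evaluations per iteration.
#'
#' @param problem A `problem_spec` from [benchmark_problem()] or
#'   [new_problem()].
#' @param pop_size Population size (>= 4 so the one-third herd strata are
#'   nonempty).
#' @param max_iter Number of iterations.
#' @param seed Integer seed; `NULL` draws one from the session RNG.  The
#'   result is a deterministic function of `(problem, config, seed)`.
#' @return A `gazelle_result` with the best position/value, the monotone
#'   per-iteration best-value `trace`, the evaluation count and the seed.
#' @examples
#' r <- mgo_minimize(benchmark_problem("f1", dim = 2), max_iter = 50, seed = 1)
#' r$best_value
#' @export
mgo_minimize <- function(problem, pop_size = 30, max_iter = 500,
                         seed = NULL) {
  run_gazelle(problem, pop_size, max_iter, seed, improved = FALSE)
}

# shared optimizer loop; `improved` toggles the IMGO additions
run_gazelle <- function(problem, pop_size, max_iter, seed, improved,
                        spiral_constant = 1,
                        icmic = c("divisive", "multiplicative")) {
  stopifnot(pop_size >= 4, max_iter >= 1)
  icmic <- match.arg(icmic)
  seed <- resolve_seed(seed)
  set.seed(seed)
  obj <- problem$objective
  lower <- problem$lower
  upper <- problem$upper
  d <- problem$dim
  n <- pop_size

  if (improved) {
    pos <- icmic_positions(n, lower, upper, divisive = icmic == "divisive")
  } else {
    pos <- matrix(runif(n * d), n, d)
    pos <- sweep(sweep(pos, 2, upper - lower, "*"), 2, lower, "+")
  }
  pop <- sort_population(new_population(pos, eval_rows(obj, pos)))
  evals <- n
  best_pos <- pop$pos[1, ]
  best_val <- pop$val[1]
  trace <- numeric(max_iter)

  for (t in seq_len(max_iter)) {
    a <- if (improved) control_factor_nonlinear(t, max_iter) else
      control_factor_linear(t, max_iter)
    offspring <- matrix(0, 4 * n, d)
    for (i in seq_len(n)) {
      offspring[(4 * i - 3):(4 * i), ] <-
        mechanism_offspring(pop, i, best_pos, a, t, max_iter, lower, upper)
      if (improved) {
        y <- clip_bounds(spiral_perturb(pop$pos[i, ], best_pos,
                                        c = spiral_constant), lower, upper)
        fy <- obj(y)
        evals <- evals + 1
        if (fy < pop$val[i]) {   # greedy accept of the perturbed position
          pop$pos[i, ] <- y
          pop$val[i] <- fy
          if (fy < best_val) {
            best_pos <- y
            best_val <- fy
          }
        }
      }
    }
    off_val <- eval_rows(obj, offspring)
    evals <- evals + 4 * n
    if (any(!is.finite(c(off_val, pop$val)))) {
      stop("objective returned a non-finite value inside the box")
    }
    pool <- sort_population(new_population(rbind(pop$pos, offspring),
                                           c(pop$val, off_val)))
    best_pos <- pool$pos[1, ]
    best_val <- pool$val[1]
    if (improved) {
      yb <- clip_bounds(neighborhood_search(best_pos, pool$pos[2, ]),
                        lower, upper)
      fyb <- obj(yb)
      evals <- evals + 1
      if (fyb < best_val) {      # greedy accept into the incumbent
        pool$pos[1, ] <- yb
        pool$val[1] <- fyb
        best_pos <- yb
        best_val <- fyb
      }
    }
    pop <- new_population(pool$pos[seq_len(n), , drop = FALSE],
                          pool$val[seq_len(n)], sorted = TRUE)
    trace[t] <- pop$val[1]
  }

  new_opt_result(if (improved) "imgo" else "mgo", problem,
                 pop$pos[1, ], pop$val[1], trace, evals, seed,
                 pop_size, max_iter)
}
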