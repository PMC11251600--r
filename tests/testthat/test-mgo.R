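test_that("BH reduces to the herd mean and samples the young-male stratum", {
  withr::with_seed(1, {
    # identical rows: BH must equal that row whatever is sampled
    pop <- gazelle:::new_population(matrix(2.5, 6, 3), rep(18.75, 6),
                                    sorted = TRUE)
    expect_equal(coef_bh(pop), rep(2.5, 3))

    # floor(r1) kills the X_ra term almost surely, so BH equals the mean
    # of some ceiling(N/3)-subset: its coordinates stay inside the range
    # of the population's coordinates
    pop <- make_pop(9, 4)
    for (k in 1:50) {
      bh <- coef_bh(pop)
      expect_true(all(bh >= apply(pop$pos, 2, min) - 1e-12))
      expect_true(all(bh <= apply(pop$pos, 2, max) + 1e-12))
    }

    # N = 6: stratum indices {2..6} drawn uniformly
    pop <- make_pop(6, 2)
    ra <- replicate(1e4, attr(coef_bh(pop, details = TRUE), "ra"))
    expect_setequal(unique(ra), 2:6)
    freq <- tabulate(ra, 6)[2:6] / 1e4
    expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / 1e4)))
  })
  expect_error(coef_bh(gazelle:::new_population(matrix(0, 4, 2), rep(0, 4))),
               "sorted")
})

test_that("weight F decays from e^2 to unit-variance noise", {
  withr::with_seed(2, {
    expect_equal(sd(weight_f(1e5, 0, 500)) / exp(2), 1, tolerance = 0.02)
    expect_equal(sd(weight_f(1e5, 500, 500)), 1, tolerance = 0.02)
    expect_equal(var(weight_f(1e5, 500, 500)), 1, tolerance = 0.03)
  })
})

test_that("linear control factor spans [-1, -2] linearly", {
  expect_equal(control_factor_linear(0, 500), -1)
  expect_equal(control_factor_linear(500, 500), -2)
  expect_equal(control_factor_linear(250, 500), -1.5)
})

test_that("coefficient vector draws its four forms uniformly", {
  withr::with_seed(3, {
    # row identification: row 1 is constant, row 3 lies in [0,1)^D,
    # rows 2 and 4 are sign-varying noise
    classify <- function(v) {
      if (length(unique(v)) == 1) "r1"
      else if (all(v >= 0 & v < 1)) "r3"
      else "r24"
    }
    draws <- replicate(4e4, classify(coef_vector(-1.5, 8)))
    p1 <- mean(draws == "r1")
    p3 <- mean(draws == "r3")
    sigma <- 3 * sqrt(0.25 * 0.75 / 4e4)
    expect_equal(p1, 0.25, tolerance = sigma / 0.25)
    expect_equal(p3, 0.25, tolerance = sigma / 0.25)
    expect_equal(mean(draws == "r24"), 0.5, tolerance = 0.03)

    # a = -1 makes form 1 equal to the scalar r3 in [0, 1)
    v1 <- replicate(200, {
      v <- coef_vector(-1, 5)
      if (length(unique(v)) == 1) v[1] else NA
    })
    expect_true(all(v1[!is.na(v1)] >= 0 & v1[!is.na(v1)] < 1))
  })
})

test_that("TSM returns the incumbent best when the weighted term vanishes", {
  withr::with_seed(4, {
    pop <- make_pop(6, 3)
    best <- pop$pos[1, ]
    expect_equal(step_tsm(pop, 2, best, f = rep(0, 3), bh = rep(1, 3),
                          cof = rnorm(3)),
                 best)
  })
})

test_that("mechanism formulas match a straight-line transcription", {
  withr::with_seed(11, pop <- make_pop(7, 4))
  best <- pop$pos[1, ]

  withr::with_seed(5, got <- step_tsm(pop, 3, best, f = rep(1, 4),
                                      bh = rep(2, 4), cof = rep(0.5, 4)))
  withr::with_seed(5, {
    ri1 <- 1L + (runif(1) >= 0.5)
    ri2 <- 1L + (runif(1) >= 0.5)
    want <- best - abs((ri1 * rep(2, 4) - ri2 * pop$pos[3, ]) * 1) * 0.5
  })
  expect_equal(got, want)

  withr::with_seed(6, got <- step_mh(pop, 2, best, bh = rep(1, 4), a = -1.3))
  withr::with_seed(6, {
    cof1 <- coef_vector(-1.3, 4)
    cof2 <- coef_vector(-1.3, 4)
    xr <- pop$pos[1L + floor(runif(1) * 7), ]
    ri3 <- 1L + (runif(1) >= 0.5)
    ri4 <- 1L + (runif(1) >= 0.5)
    want <- (rep(1, 4) + cof1) + (ri3 * best - ri4 * xr) * cof2
  })
  expect_equal(got, want)

  withr::with_seed(7, got <- step_bmh(pop, 4, best, bh = rep(-1, 4),
                                      cof = rep(2, 4)))
  withr::with_seed(7, {
    x <- pop$pos[4, ]
    dvec <- (abs(x) + abs(best)) * (2 * runif(1) - 1)
    ri5 <- 1L + (runif(1) >= 0.5)
    ri6 <- 1L + (runif(1) >= 0.5)
    want <- (x - dvec) + (ri5 * best - ri6 * rep(-1, 4)) * 2
  })
  expect_equal(got, want)
})

test_that("BMH with r6 = 0.5 keeps the current position as its base", {
  # D vanishes when 2*r6 - 1 = 0; verified through the closed form
  pop <- gazelle:::new_population(matrix(0, 4, 2), rep(0, 4), sorted = TRUE)
  withr::with_seed(8, {
    got <- step_bmh(pop, 1, best = rep(0, 2), bh = rep(0, 2),
                    cof = rep(1, 2))
  })
  expect_equal(got, rep(0, 2))   # all-zero inputs stay at zero
})

test_that("MSF samples uniformly inside the box", {
  withr::with_seed(9, {
    draws <- t(replicate(1e4, step_msf(c(0, 0), c(1, 1))))
    expect_true(all(draws >= 0 & draws <= 1))
    expect_equal(colMeans(draws), c(0.5, 0.5), tolerance = 0.02)
  })
  expect_equal(step_msf(c(2, 2), c(2, 2)), c(2, 2))   # degenerate box
})

test_that("baseline MGO is elitist, converges, and accounts evaluations", {
  p <- benchmark_problem("f1", dim = 2)
  cp <- counting_problem(p)
  r1 <- mgo_minimize(cp$problem, pop_size = 12, max_iter = 30, seed = 5)
  # init N + 4N per iteration
  expect_equal(cp$counter$n, 12 + 4 * 12 * 30)
  expect_equal(r1$evals, cp$counter$n)
  expect_true(all(diff(r1$trace) <= 0))
  expect_gte(r1$trace[1], r1$best_value)   # elitism: final never worse

  # convergence on the 2-d sphere over several seeds
  finals <- vapply(1:6, function(s) {
    mgo_minimize(p, pop_size = 30, max_iter = 200, seed = s)$best_value
  }, numeric(1))
  expect_true(all(finals < 1e-6))
})

test_that("MGO is bit-for-bit reproducible and respects bounds", {
  p <- benchmark_problem("f9", dim = 3)
  a <- mgo_minimize(p, pop_size = 8, max_iter = 25, seed = 99)
  b <- mgo_minimize(p, pop_size = 8, max_iter = 25, seed = 99)
  expect_identical(a$best_position, b$best_position)
  expect_identical(a$trace, b$trace)
  expect_true(all(a$best_position >= p$lower & a$best_position <= p$upper))
  c_ <- mgo_minimize(p, pop_size = 8, max_iter = 25, seed = 100)
  expect_false(identical(a$trace, c_$trace))
})

test_that("non-finite objectives abort the run", {
  bad <- new_problem("bad", 2, -1, 1, function(x) {
    if (x[1] > 0) NaN else sum(x^2)
  })
  expect_error(mgo_minimize(bad, pop_size = 6, max_iter = 10, seed = 1),
               "non-finite")
})
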