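sphere <- function(x) sum(x^2)

test_that("position initialisation spans exactly the bound interval", {
  expect_equal(abc_position_init(-5, 5, 0), -5)
  expect_equal(abc_position_init(-5, 5, 1), 5)
  expect_equal(abc_position_init(0, 10, 0.25), 2.5)
})

test_that("swarm initialisation is in-bounds, evaluated, and reproducible", {
  set.seed(3)
  sw <- abc_swarm(sphere, c(-5, -2), c(5, 2), sn = 15)
  expect_equal(dim(sw$positions), c(15L, 2L))
  expect_true(all(sw$positions[, 1] >= -5 & sw$positions[, 1] <= 5))
  expect_true(all(sw$positions[, 2] >= -2 & sw$positions[, 2] <= 2))
  expect_equal(sw$obj, apply(sw$positions, 1, sphere))
  expect_equal(sw$best_obj, min(sw$obj))
  expect_equal(sw$trial, integer(15))
  set.seed(3)
  sw2 <- abc_swarm(sphere, c(-5, -2), c(5, 2), sn = 15)
  expect_identical(sw$positions, sw2$positions)
  expect_error(abc_swarm(sphere, c(5, 0), c(5, 2), sn = 5), "lower < upper")
  expect_error(abc_swarm(sphere, -1, 1, sn = 1), "sn")
})

test_that("neighbour moves follow the one-dimension perturbation arithmetic", {
  x <- c(5, 8); p <- c(3, 1)
  expect_equal(abc_neighbor(x, p, 1, phi = 0), x)      # zero perturbation
  expect_equal(abc_neighbor(x, p, 1, phi = 1), c(7, 8))  # 5 + 1*(5-3)
  expect_equal(abc_neighbor(x, x, 2, phi = 0.7), x)    # identical partner
  # guided move: x_j + phi (x_j - p_j) + psi (best_j - x_j)
  b <- c(10, 10)
  expect_equal(abc_neighbor_guided(x, p, b, 1, phi = 0, psi = 0), x)
  expect_equal(abc_neighbor_guided(b, p, b, 1, phi = 0, psi = 0.9), b)
  expect_equal(abc_neighbor_guided(c(2, 0), c(0, 0), c(10, 0), 1,
                                   phi = 0.5, psi = 1)[1], 2 + 1 + 8)
})

test_that("nectar transform matches the two-branch definition and stays positive", {
  expect_equal(fit_transform(0), 1)
  expect_equal(fit_transform(1), 0.5)
  expect_equal(fit_transform(-0.5), 1.5)
  expect_equal(fit_transform(c(0, 1, -0.5)), c(1, 0.5, 1.5))
  set.seed(5)
  expect_true(all(fit_transform(runif(100, -50, 50)) > 0))
  expect_error(fit_transform(NaN), "finite")
})

test_that("selection probabilities normalise nectar values", {
  expect_equal(selection_prob(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(selection_prob(5), 1)
  set.seed(6)
  for (i in 1:20) expect_equal(sum(selection_prob(runif(8, 0.1, 3))), 1)
  expect_error(selection_prob(c(1, 0)), "positive")
})

test_that("onlooker selection frequencies follow the roulette probabilities", {
  fits <- c(8, 1, 1)
  p <- selection_prob(fits)
  set.seed(7)
  draws <- sample.int(3, 10000, replace = TRUE, prob = p)
  observed <- tabulate(draws, 3)
  chi <- sum((observed - 10000 * p)^2 / (10000 * p))
  expect_lt(chi, qchisq(0.999, df = 2))
  expect_gt(mean(draws == 1), 0.75)  # dominant source gets most selections
})

test_that("employed phase applies greedy replacement and failure counting", {
  set.seed(8)
  sw <- abc_swarm(sphere, c(-5, -5), c(5, 5), sn = 10)
  # impossible objective: every candidate is worse -> positions keep, trials +1
  worse <- function(x) 1e9
  sw_bad <- sw; sw_bad$obj[] <- -1e9; sw_bad$best_obj <- -1e9
  out <- employed_phase(sw_bad, worse, "basic")
  expect_identical(out$positions, sw_bad$positions)
  expect_equal(out$trial, rep(1L, 10))
  # ties count as non-improvement
  flat <- function(x) 0
  sw_flat <- sw; sw_flat$obj[] <- 0; sw_flat$fit[] <- 1; sw_flat$best_obj <- 0
  out2 <- employed_phase(sw_flat, flat, "basic")
  expect_equal(out2$trial, rep(1L, 10))
  # on a real objective the best never worsens
  out3 <- employed_phase(sw, sphere, "basic")
  expect_lte(out3$best_obj, sw$best_obj)
  out4 <- onlooker_phase(out3, sphere, "basic")
  expect_lte(out4$best_obj, out3$best_obj)
})

test_that("scout phase replaces only the worst offender past the limit", {
  set.seed(9)
  sw <- abc_swarm(sphere, c(-5, -5), c(5, 5), sn = 6)
  # under the limit: untouched
  expect_identical(scout_phase(sw, sphere, limit = 5, "basic"), sw)
  sw$trial <- c(0L, 9L, 2L, 0L, 0L, 0L)
  out <- scout_phase(sw, sphere, limit = 5, "basic")
  expect_equal(out$trial[2], 0L)
  expect_false(identical(out$positions[2, ], sw$positions[2, ]))
  expect_identical(out$positions[-2, ], sw$positions[-2, ])
  expect_true(all(out$positions[2, ] >= -5 & out$positions[2, ] <= 5))
  # modified variant: deterministic reflection blended with the best
  out_m <- scout_phase(sw, sphere, limit = 5, "modified")
  opposition <- -5 + 5 - sw$positions[2, ]
  expect_equal(out_m$positions[2, ],
               pmin(pmax(0.5 * opposition + 0.5 * sw$best_pos, -5), 5))
})

test_that("the optimiser is reproducible, monotone, and respects t_max", {
  f1 <- abc_optim(sphere, c(-5, -5), c(5, 5), t_max = 40, seed = 12)
  f2 <- abc_optim(sphere, c(-5, -5), c(5, 5), t_max = 40, seed = 12)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$history, f2$history)
  expect_length(f1$history, 40)
  expect_true(all(diff(f1$history) <= 0))
  expect_equal(f1$value, min(f1$history))
  one <- abc_optim(sphere, c(-5, -5), c(5, 5), t_max = 1, seed = 12)
  expect_length(one$history, 1)
  expect_error(abc_optim(sphere, -1, 1, t_max = 0), "t_max")
  expect_error(abc_optim(function(x) NA_real_, -1, 1, t_max = 2, seed = 1),
               "non-finite")
})

test_that("positions stay within bounds after every phase", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  set.seed(14)
  sw <- abc_swarm(rosen, c(-2, -1), c(2, 3), sn = 8)
  for (cycle in 1:15) {
    sw <- employed_phase(sw, rosen, "modified")
    sw <- onlooker_phase(sw, rosen, "modified")
    sw <- scout_phase(sw, rosen, limit = 10, "modified")
    expect_true(all(sw$positions[, 1] >= -2 & sw$positions[, 1] <= 2))
    expect_true(all(sw$positions[, 2] >= -1 & sw$positions[, 2] <= 3))
  }
})

test_that("both variants minimise the sphere benchmark from multiple seeds", {
  vals_basic <- sapply(1:10, function(s)
    abc_optim(sphere, c(-5, -5), c(5, 5), t_max = 100, seed = s)$value)
  vals_mod <- sapply(1:10, function(s)
    abc_optim(sphere, c(-5, -5), c(5, 5), t_max = 100, seed = s,
              variant = "modified")$value)
  expect_true(all(vals_basic < 1e-2))
  expect_true(all(vals_mod < 1e-2))
  # best-guided exploitation: modified at least as good in the median
  expect_lte(median(vals_mod), median(vals_basic))
})
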