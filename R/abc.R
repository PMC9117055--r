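#' Artificial Bee Colony optimisation
#'
#' Minimises a bounded real-vector objective with the Artificial Bee Colony
#' metaheuristic. A colony of `sn` food sources (candidate solutions) is
#' refined over `t_max` cycles of three phases: employed bees perturb each
#' source along one random dimension toward a random partner (greedy
#' acceptance), onlooker bees repeat the perturbation on sources selected by
#' roulette wheel over their nectar values, and a scout re-draws the single
#' source whose consecutive-failure counter exceeds `limit`.
#'
#' The `"modified"` variant changes two ingredients: neighbour moves add a
#' global-best guidance term (`psi ~ U[0, 1.5]` times the distance to the
#' best-ever solution), and scout replacement reflects the abandoned
#' position through the bound midpoint (opposition point) and blends it
#' 50/50 with the global best, instead of a blind uniform re-draw.
#'
#' @param fn objective function taking a numeric vector, returning a finite
#'   scalar; minimised.
#' @param lower,upper numeric bounds per dimension (`lower < upper`).
#' @param sn number of food sources (>= 2).
#' @param limit abandonment threshold; defaults to `sn * D`.
#' @param t_max number of cycles (>= 1).
#' @param variant `"basic"` or `"modified"`.
#' @param seed optional integer seed; the run is fully reproducible.
#' @return Object of class `abc_fit`: `par` (best position), `value` (best
#'   objective), `history` (best-so-far objective after each cycle, length
#'   `t_max`, non-increasing), `evaluations`, plus the settings.
#' @export
#' @examples
#' fit <- abc_optim(function(x) sum(x^2), c(-5, -5), c(5, 5),
#'                  t_max = 50, seed = 1)
#' fit$value
abc_optim <- function(fn, lower, upper, sn = 20, limit = NULL, t_max = 100,
                      variant = c("basic", "modified"), seed = NULL) {
  variant <- match.arg(variant)
  if (t_max < 1) stop("t_max must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dim_n <- length(lower)
  if (is.null(limit)) limit <- sn * dim_n
  if (limit < 1) stop("limit must be >= 1", call. = FALSE)
  swarm <- abc_swarm(fn, lower, upper, sn)
  history <- numeric(t_max)
  for (t in seq_len(t_max)) {
    swarm <- employed_phase(swarm, fn, variant)
    swarm <- onlooker_phase(swarm, fn, variant)
    swarm <- scout_phase(swarm, fn, limit, variant)
    history[t] <- swarm$best_obj
  }
  structure(list(par = swarm$best_pos, value = swarm$best_obj,
                 history = history, evaluations = swarm$evals,
                 sn = sn, limit = limit, t_max = t_max, variant = variant),
            class = "abc_fit")
}

#' Initialise an ABC swarm
#'
#' Draws `sn` positions uniformly within the bounds (each component
#' `lower_j + u * (upper_j - lower_j)` with `u ~ U[0, 1]`; see
#' [abc_position_init()]), evaluates them, and records the best.
#'
#' @inheritParams abc_optim
#' @return A swarm: list with `positions` (sn x D), `obj`, `fit`, `trial`,
#'   `best_pos`, `best_obj`, `lower`, `upper`, `evals`.
#' @export
abc_swarm <- function(fn, lower, upper, sn = 20) {
  if (sn < 2) stop("sn must be >= 2", call. = FALSE)
  if (any(lower >= upper)) stop("need lower < upper per dimension", call. = FALSE)
  dim_n <- length(lower)
  u <- matrix(stats::runif(sn * dim_n), sn, dim_n)
  positions <- matrix(abc_position_init(rep(lower, each = sn),
                                        rep(upper, each = sn), as.vector(u)),
                      sn, dim_n)
  obj <- apply(positions, 1, function(x) eval_objective(fn, x))
  b <- which.min(obj)
  list(positions = positions, obj = obj, fit = fit_transform(obj),
       trial = integer(sn), best_pos = positions[b, ], best_obj = obj[b],
       lower = lower, upper = upper, evals = sn)
}

#' Uniform position initialisation between bounds
#'
#' `lower + u * (upper - lower)`: `u = 0` gives the lower bound, `u = 1`
#' the upper.
#'
#' @param lower,upper bounds (vectorised).
#' @param u uniform draw(s) in \[0, 1\].
#' @return Position component(s).
#' @export
abc_position_init <- function(lower, upper, u) lower + u * (upper - lower)

#' Basic neighbour move
#'
#' Perturbs one dimension `j` of `position` toward/away from the same
#' dimension of a partner source: `v_j = x_j + phi * (x_j - partner_j)`;
#' all other dimensions are copied. The caller clips the result to bounds.
#'
#' @param position,partner numeric vectors (distinct sources).
#' @param j dimension index to perturb.
#' @param phi perturbation scale, drawn `U[-1, 1]` by the phases.
#' @return Candidate position vector.
#' @export
abc_neighbor <- function(position, partner, j, phi) {
  v <- position
  v[j] <- position[j] + phi * (position[j] - partner[j])
  v
}

#' Best-guided neighbour move (modified variant)
#'
#' Adds a global-best guidance term to the basic move:
#' `v_j = x_j + phi * (x_j - partner_j) + psi * (best_j - x_j)` with
#' `phi ~ U[-1, 1]`, `psi ~ U[0, 1.5]`. Guidance improves exploitation
#' around the incumbent best without removing the random partner term.
#'
#' @inheritParams abc_neighbor
#' @param best global best position vector.
#' @param psi guidance scale.
#' @return Candidate position vector.
#' @export
abc_neighbor_guided <- function(position, partner, best, j, phi, psi) {
  v <- position
  v[j] <- position[j] + phi * (position[j] - partner[j]) +
    psi * (best[j] - position[j])
  v
}

#' Nectar (fitness) transform
#'
#' Maps an objective value (minimised) to a positive nectar value
#' (maximised): `1 / (1 + x)` for `x >= 0`, `1 + |x|` for `x < 0`. Output is
#' always strictly positive, so roulette probabilities are well defined.
#'
#' @param x finite objective value(s).
#' @return Nectar value(s) > 0.
#' @export
fit_transform <- function(x) {
  if (any(!is.finite(x))) stop("objective value must be finite", call. = FALSE)
  ifelse(x >= 0, 1 / (1 + x), 1 + abs(x))
}

#' Roulette-wheel selection probabilities
#'
#' Normalises nectar values to probabilities `P_i = fit_i / sum(fit)`.
#'
#' @param fits vector of strictly positive nectar values.
#' @return Probability vector summing to 1.
#' @export
selection_prob <- function(fits) {
  if (any(fits <= 0)) stop("fits must be strictly positive", call. = FALSE)
  fits / sum(fits)
}

eval_objective <- function(fn, x) {
  val <- fn(x)
  if (!is.finite(val))
    stop(sprintf("objective returned a non-finite value at position (%s)",
                 paste(signif(x, 4), collapse = ", ")), call. = FALSE)
  val
}

clip_bounds <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# One greedy trial on source i: build a neighbour candidate, evaluate it,
# replace on strict improvement (trial reset), else count a failure.
greedy_trial <- function(swarm, fn, i, variant) {
  sn <- nrow(swarm$positions)
  k <- sample.int(sn - 1L, 1L)
  if (k >= i) k <- k + 1L
  j <- sample.int(ncol(swarm$positions), 1L)
  phi <- stats::runif(1, -1, 1)
  cand <- if (variant == "modified") {
    abc_neighbor_guided(swarm$positions[i, ], swarm$positions[k, ],
                        swarm$best_pos, j, phi, stats::runif(1, 0, 1.5))
  } else {
    abc_neighbor(swarm$positions[i, ], swarm$positions[k, ], j, phi)
  }
  cand <- clip_bounds(cand, swarm$lower, swarm$upper)
  val <- eval_objective(fn, cand)
  swarm$evals <- swarm$evals + 1L
  if (val < swarm$obj[i]) {
    swarm$positions[i, ] <- cand
    swarm$obj[i] <- val
    swarm$fit[i] <- fit_transform(val)
    swarm$trial[i] <- 0L
    if (val < swarm$best_obj) {
      swarm$best_obj <- val
      swarm$best_pos <- cand
    }
  } else {
    swarm$trial[i] <- swarm$trial[i] + 1L  # ties count as failures
  }
  swarm
}

#' Employed-bee phase
#'
#' Every food source gets one neighbour trial with greedy acceptance: the
#' candidate replaces the source only if its objective is strictly lower
#' (equal values count as failures, so trial counters can grow on plateaus).
#'
#' @param swarm a swarm from [abc_swarm()].
#' @param fn objective function.
#' @param variant `"basic"` or `"modified"` (selects the neighbour move).
#' @return Updated swarm.
#' @export
employed_phase <- function(swarm, fn, variant = "basic") {
  for (i in seq_len(nrow(swarm$positions)))
    swarm <- greedy_trial(swarm, fn, i, variant)
  swarm
}

#' Onlooker-bee phase
#'
#' Performs `sn` roulette-wheel selections over the [selection_prob()]
#' probabilities; each selected source receives one neighbour trial with
#' greedy acceptance, exactly as in the employed phase.
#'
#' @inheritParams employed_phase
#' @return Updated swarm.
#' @export
onlooker_phase <- function(swarm, fn, variant = "basic") {
  sn <- nrow(swarm$positions)
  probs <- selection_prob(swarm$fit)
  chosen <- sample.int(sn, sn, replace = TRUE, prob = probs)
  for (i in chosen) swarm <- greedy_trial(swarm, fn, i, variant)
  swarm
}

#' Scout-bee phase
#'
#' If any trial counter exceeds `limit`, the single worst offender (highest
#' counter; ties toward the lowest index) is abandoned and replaced, with its
#' counter reset to 0. The basic variant re-draws the position uniformly
#' within bounds; the modified variant places the scout at the 50/50 blend of
#' the abandoned position's opposition point (`lower + upper - x`) and the
#' global best.
#'
#' @inheritParams employed_phase
#' @param limit abandonment threshold (>= 1).
#' @return Updated swarm.
#' @export
scout_phase <- function(swarm, fn, limit, variant = "basic") {
  if (max(swarm$trial) <= limit) return(swarm)
  i <- which.max(swarm$trial)
  newpos <- if (variant == "modified") {
    opposition <- swarm$lower + swarm$upper - swarm$positions[i, ]
    clip_bounds(0.5 * opposition + 0.5 * swarm$best_pos,
                swarm$lower, swarm$upper)
  } else {
    abc_position_init(swarm$lower, swarm$upper,
                      stats::runif(length(swarm$lower)))
  }
  val <- eval_objective(fn, newpos)
  swarm$evals <- swarm$evals + 1L
  swarm$positions[i, ] <- newpos
  swarm$obj[i] <- val
  swarm$fit[i] <- fit_transform(val)
  swarm$trial[i] <- 0L
  if (val < swarm$best_obj) {
    swarm$best_obj <- val
    swarm$best_pos <- newpos
  }
  swarm
}

#' @export
print.abc_fit <- function(x, ...) {
  cat(sprintf("ABC fit (%s variant): best objective %.6g after %d cycles (%d evaluations)\n",
              x$variant, x$value, x$t_max, x$evaluations))
  cat("best position:", paste(signif(x$par, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.abc_fit <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "cycle", ylab = "best objective",
                 main = sprintf("ABC convergence (%s)", x$variant), ...)
  invisible(x)
}
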