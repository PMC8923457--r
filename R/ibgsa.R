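#' Parameters of the improved binary gravitational search optimizer
#'
#' @param n_agents Population size N. Default 20.
#' @param n_iterations Movement iterations T after the initial evaluation
#'   sweep; the optimizer evaluates `n_agents * (n_iterations + 1)` candidate
#'   bit strings in total. Default 2, so that the pyramid defaults (8 cycles,
#'   20 agents) spend exactly 480 evaluations.
#' @param g0 Initial gravitational constant G0. Default 100.
#' @param alpha Decay rate of the gravitational constant. Default 8, chosen
#'   so the bit-flip probabilities anneal from exploration to exploitation
#'   over the whole horizon instead of vanishing mid-run.
#' @param k1 Ceiling of the failure-driven floor of the transfer function,
#'   in (0, 1]. Default 1.
#' @param k2 Failure-counter scale of the transfer function. Default 500.
#' @param p_exponent Exponent on the inter-agent distance in the force law.
#'   Default 1 (classic form).
#' @param epsilon Small constant added to the distance term. Default 1e-9.
#' @param v_max Symmetric velocity clamp; keeps `tanh` in its responsive
#'   range. Default 6.
#' @return A list of class `ibgsa_params`.
#' @export
ibgsa_params <- function(n_agents = 20, n_iterations = 2, g0 = 100,
                         alpha = 8, k1 = 1, k2 = 500, p_exponent = 1,
                         epsilon = 1e-9, v_max = 6) {
  p <- list(
    n_agents = as.integer(n_agents), n_iterations = as.integer(n_iterations),
    g0 = as.numeric(g0), alpha = as.numeric(alpha), k1 = as.numeric(k1),
    k2 = as.numeric(k2), p_exponent = as.numeric(p_exponent),
    epsilon = as.numeric(epsilon), v_max = as.numeric(v_max)
  )
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all optimizer parameters must be positive and finite",
      class = "pgsa_error_params"
    )
  }
  if (p$k1 > 1) {
    abort("k1 must lie in (0, 1] so flip probabilities stay in [0, 1]",
      class = "pgsa_error_params"
    )
  }
  structure(p, class = "ibgsa_params")
}

#' Gravitational masses from fitness values
#'
#' Maps fitness to mass by `M_i = (fit_i - worst) / sum_j (fit_j - worst)`
#' with `worst` the population minimum (maximization orientation: higher
#' fitness means heavier). Masses sum to 1 and the worst agent gets mass 0.
#' When all fitnesses are equal the ratio is 0/0; the population is then
#' symmetric and uniform masses `1/N` are returned.
#'
#' @param fitnesses Numeric vector of finite fitness values.
#' @return Numeric vector of masses summing to 1.
#' @examples
#' compute_masses(c(3, 1, 2)) # 2/3, 0, 1/3
#' @export
compute_masses <- function(fitnesses) {
  stopifnot(length(fitnesses) >= 1, all(is.finite(fitnesses)))
  shifted <- fitnesses - min(fitnesses)
  total <- sum(shifted)
  if (total == 0) {
    return(rep(1 / length(fitnesses), length(fitnesses)))
  }
  shifted / total
}

#' Gravitational constant schedule
#'
#' Exponential decay `G(t) = g0 * exp(-alpha * t / t_max)`, strictly
#' decreasing in `t`.
#'
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Total iterations (> 0).
#' @param g0,alpha Schedule parameters.
#' @return The gravitational constant at iteration `t`.
#' @export
gravitational_constant <- function(t, t_max, g0 = 100, alpha = 8) {
  if (t_max <= 0) {
    abort("t_max must be positive", class = "pgsa_error_params")
  }
  g0 * exp(-alpha * t / t_max)
}

#' Size of the attracting elite (Kbest) at iteration t
#'
#' Linear decrease from all `n_agents` at `t = 0` down to 1 at `t = t_max`,
#' rounded half-up; always in `[1, n_agents]`. Only the Kbest heaviest agents
#' exert force, so exploitation sharpens as the schedule shrinks.
#'
#' @param t Current iteration.
#' @param t_max Total iterations.
#' @param n_agents Population size.
#' @return Integer number of attracting agents.
#' @export
kbest_size <- function(t, t_max, n_agents) {
  stopifnot(n_agents >= 1, t >= 0, t <= t_max)
  frac <- if (t_max == 0) 1 else t / t_max
  k <- floor(n_agents - (n_agents - 1) * frac + 0.5) # half-up rounding
  as.integer(min(max(k, 1), n_agents))
}

#' Gravitational forces on each agent
#'
#' Each agent is pulled toward the Kbest heaviest agents:
#' `F_i^d = sum_{j in Kbest, j != i} rand_j * G * M_i * M_j /
#' (R_ij^p + epsilon) * (x_j^d - x_i^d)` with `R_ij` the Euclidean distance
#' between the binary position vectors and `rand_j ~ U(0,1)` drawn once per
#' `(i, j)` pair. Random numbers are consumed agent-major: for each agent `i`
#' in order, over the Kbest members `j` in ascending index order.
#'
#' @param positions N x D binary matrix of agent positions.
#' @param masses Length-N mass vector (see [compute_masses()]).
#' @param g Gravitational constant at this iteration.
#' @param kbest Number of heaviest agents that exert force.
#' @param p_exponent Exponent on the distance. Default 1.
#' @param epsilon Guard added to the distance term. Default 1e-9.
#' @return N x D matrix of forces.
#' @export
compute_forces <- function(positions, masses, g, kbest, p_exponent = 1,
                           epsilon = 1e-9) {
  n <- nrow(positions)
  d <- ncol(positions)
  ord <- order(masses, decreasing = TRUE)
  kset <- sort(ord[seq_len(min(kbest, n))])
  forces <- matrix(0, n, d)
  for (i in seq_len(n)) {
    for (j in kset) {
      if (j == i) next
      diff <- positions[j, ] - positions[i, ]
      r <- sqrt(sum(diff * diff))
      forces[i, ] <- forces[i, ] +
        runif(1) * g * masses[i] * masses[j] / (r^p_exponent + epsilon) * diff
    }
  }
  forces
}

#' Acceleration from force and inertial mass
#'
#' `a_i^d = F_i^d / (M_i + guard)` with a small guard (default 1e-12) so the
#' worst agent, whose mass is exactly 0, still receives a finite (large)
#' acceleration rather than NaN/Inf.
#'
#' @param forces N x D force matrix.
#' @param masses Length-N mass vector.
#' @param mass_guard Division guard. Default 1e-12.
#' @return N x D acceleration matrix, finite everywhere.
#' @export
compute_acceleration <- function(forces, masses, mass_guard = 1e-12) {
  forces / (masses + mass_guard)
}

#' Velocity update with random inertia
#'
#' `v' = rand * v + a`, with `rand ~ U(0,1)` drawn once per agent per
#' dimension (agent-major, dimensions inner), then clamped elementwise to
#' `[-v_max, v_max]`.
#'
#' @param velocities,accelerations N x D matrices.
#' @param v_max Velocity clamp.
#' @return N x D updated velocity matrix.
#' @export
update_velocity <- function(velocities, accelerations, v_max = 6) {
  n <- nrow(velocities)
  d <- ncol(velocities)
  r <- matrix(runif(n * d), nrow = n, ncol = d, byrow = TRUE)
  v <- r * velocities + accelerations
  pmin(pmax(v, -v_max), v_max)
}

#' Bit-flip probability from velocity and failure counter
#'
#' The transfer function `Tfn = A + (1 - A) * tanh(|v|)` with
#' `A = k1 * (1 - exp(-fc / k2))`. While the search keeps improving
#' (`fc = 0`) the flip probability is driven by velocity alone; as failures
#' accumulate, `A` rises toward `k1`, lifting the probability floor and
#' forcing exploration. The result lies in `[0, 1)` for finite inputs.
#'
#' @param v Velocity (any numeric shape; used elementwise as `|v|`).
#' @param fc Non-negative failure counter.
#' @param k1 Floor ceiling in (0, 1].
#' @param k2 Failure scale (> 0).
#' @return Flip probabilities with the shape of `v`.
#' @examples
#' transfer_probability(1, fc = 0) # tanh(1)
#' @export
transfer_probability <- function(v, fc, k1 = 1, k2 = 500) {
  stopifnot(fc >= 0, k1 > 0, k1 <= 1, k2 > 0)
  a <- k1 * (1 - exp(-fc / k2))
  a + (1 - a) * tanh(abs(v))
}

#' Stochastic bit complementation
#'
#' Each bit is complemented independently with its flip probability
#' (`rand() < p`), else left unchanged. Uniform draws are consumed
#' agent-major (agents outer, dimensions inner).
#'
#' @param positions N x D binary matrix.
#' @param flip_probs N x D matrix of probabilities in `[0, 1]`.
#' @return N x D binary matrix.
#' @export
flip_positions <- function(positions, flip_probs) {
  n <- nrow(positions)
  d <- ncol(positions)
  r <- matrix(runif(n * d), nrow = n, ncol = d, byrow = TRUE)
  flip <- r < flip_probs
  out <- positions
  out[flip] <- 1L - out[flip]
  out
}

#' Failure-counter update
#'
#' A failure is an iteration in which the best-found fitness does not
#' strictly improve: the counter then increases by one. On strict
#' improvement it resets to 0. Ties count as failures.
#'
#' @param previous_best,current_best Best fitness before and after the
#'   iteration.
#' @param fc Current counter (>= 0).
#' @return Updated counter.
#' @export
update_failure_counter <- function(previous_best, current_best, fc) {
  stopifnot(fc >= 0)
  if (current_best > previous_best) 0L else as.integer(fc) + 1L
}

#' Improved binary gravitational search
#'
#' Maximizes `fitness_fn` over bit strings of length `dimension`. The
#' population is initialized (each bit Bernoulli(0.5) unless
#' `initial_positions` is given), evaluated, and then moved for
#' `n_iterations` rounds of mass / force / acceleration / velocity / transfer
#' updates; every round re-evaluates all agents, so the total evaluation
#' count is `n_agents * (n_iterations + 1)`. The global failure counter
#' raises the flip-probability floor whenever the best-so-far fitness stalls.
#'
#' Randomness comes from R's global RNG; seed it (e.g. `set.seed()`) for a
#' bit-identical trajectory. Uniform draws are consumed in a fixed order
#' (initialization, then per iteration: forces agent-major, velocities
#' agent-major, flips agent-major), so equal seeds give equal runs.
#'
#' @param fitness_fn Function taking a 0/1 vector of length `dimension` and
#'   returning a finite scalar (higher is better).
#' @param dimension Bit-string length (>= 1).
#' @param params An [ibgsa_params()] object.
#' @param initial_positions Optional N x D binary matrix overriding random
#'   initialization.
#' @param prefer_fewer_bits When `TRUE`, an agent that exactly ties the best
#'   fitness with strictly fewer 1-bits replaces the incumbent best (the
#'   fitness/size tie-break of [compare_agents()]); the failure counter still
#'   keys on strict fitness improvement only. Default `FALSE`.
#' @return A list of class `ibgsa_result`: `best_position` (0/1 vector),
#'   `best_fitness`, `n_evaluations`, and `trace` (tibble with per-iteration
#'   best fitness and failure counter).
#' @examples
#' set.seed(1)
#' onemax <- function(bits) mean(bits)
#' res <- ibgsa_search(onemax, dimension = 10,
#'   params = ibgsa_params(n_agents = 10, n_iterations = 20))
#' res$best_fitness
#' @export
ibgsa_search <- function(fitness_fn, dimension, params = ibgsa_params(),
                         initial_positions = NULL,
                         prefer_fewer_bits = FALSE) {
  stopifnot(dimension >= 1)
  n <- params$n_agents
  t_max <- params$n_iterations
  positions <- if (is.null(initial_positions)) {
    matrix(rbinom(n * dimension, 1, 0.5), nrow = n, ncol = dimension)
  } else {
    stopifnot(
      nrow(initial_positions) == n, ncol(initial_positions) == dimension,
      all(initial_positions %in% c(0, 1))
    )
    initial_positions
  }
  velocities <- matrix(0, n, dimension)

  evaluate <- function(pos) {
    vapply(seq_len(nrow(pos)), function(i) fitness_fn(pos[i, ]), numeric(1))
  }

  fitnesses <- evaluate(positions)
  n_evals <- n
  best_i <- which.max(fitnesses)
  best_fitness <- fitnesses[best_i]
  best_position <- positions[best_i, ]
  fc <- 0L
  trace <- vector("list", t_max + 1)
  trace[[1]] <- tibble(iteration = 0L, best_fitness = best_fitness, fc = fc)

  for (t in seq_len(t_max)) {
    masses <- compute_masses(fitnesses)
    g <- gravitational_constant(t, t_max, params$g0, params$alpha)
    k <- kbest_size(t, t_max, n)
    forces <- compute_forces(
      positions, masses, g, k,
      p_exponent = params$p_exponent, epsilon = params$epsilon
    )
    accel <- compute_acceleration(forces, masses)
    velocities <- update_velocity(velocities, accel, v_max = params$v_max)
    probs <- transfer_probability(velocities, fc, k1 = params$k1, k2 = params$k2)
    positions <- flip_positions(positions, probs)
    fitnesses <- evaluate(positions)
    n_evals <- n_evals + n

    prev_best <- best_fitness
    for (i in seq_len(n)) {
      better <- fitnesses[i] > best_fitness ||
        (prefer_fewer_bits && fitnesses[i] == best_fitness &&
          sum(positions[i, ]) < sum(best_position))
      if (better) {
        best_fitness <- fitnesses[i]
        best_position <- positions[i, ]
      }
    }
    fc <- update_failure_counter(prev_best, best_fitness, fc)
    trace[[t + 1]] <- tibble(iteration = t, best_fitness = best_fitness, fc = fc)
  }

  structure(
    list(
      best_position = best_position,
      best_fitness = best_fitness,
      n_evaluations = n_evals,
      trace = dplyr::bind_rows(trace)
    ),
    class = "ibgsa_result"
  )
}

#' @export
print.ibgsa_result <- function(x, ...) {
  cat(
    "<ibgsa_result> best fitness ", format(x$best_fitness),
    " with ", sum(x$best_position), " bits set (",
    x$n_evaluations, " evaluations)\n",
    sep = ""
  )
  invisible(x)
}
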