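#' Annealing results
#'
#' An `anneal_result` collects the samples of a solver run: one row of
#' `samples` per attempt (binary 0/1 states in QUBO variable order), the
#' matching `energies`, the best sample, and ground-hit bookkeeping when a
#' reference ground energy is supplied.
#'
#' @param samples matrix of 0/1 states, one row per attempt.
#' @param energies numeric energies, one per row.
#' @param solver solver name.
#' @param params parameter list (including the seed, when stochastic).
#' @param ground_energy optional known ground energy used to count hits.
#' @param tol tolerance for a ground hit.
#' @return An object of class `anneal_result`.
#' @export
anneal_result <- function(samples, energies, solver, params = list(),
                          ground_energy = NULL, tol = 1e-9) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(energies))
  hits <- if (is.null(ground_energy)) NA_integer_ else
    sum(energies <= ground_energy + tol)
  best_i <- which.min(energies)
  structure(list(samples = samples, energies = as.numeric(energies),
                 best = samples[best_i, ], best_energy = energies[best_i],
                 n_runs = nrow(samples), n_ground_hits = hits,
                 ground_energy = ground_energy, solver = solver,
                 params = params),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("<anneal_result> %s: %d runs, best energy %.6g", x$solver,
              x$n_runs, x$best_energy))
  if (!is.na(x$n_ground_hits)) {
    cat(sprintf(", %d/%d ground hits", x$n_ground_hits, x$n_runs))
  }
  cat("\n")
  invisible(x)
}

#' SimCIM control parameters
#'
#' Defaults follow common practice for mean-field coherent-Ising-machine
#' emulators: a linear pump ramp from -1 to +1, unit coupling gain on the
#' hardware-rescaled problem, and a small Gaussian noise that breaks the
#' symmetry of the all-zero start. The ramp is deliberately slow (15000
#' steps): on frustrated penalty problems a fast ramp locks spins before the
#' mean field can order them.
#'
#' @param iterations number of update steps per attempt.
#' @param batch number of parallel attempts (independent runs).
#' @param zeta coupling gain multiplying the mean field.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param pump_schedule `"linear"`, `"tanh"`, or a function `f(t, iterations)`
#'   returning the pump value `p_t` for step `t` in `1:iterations`.
#' @param rng_seed integer seed (mandatory for reproducible solves).
#' @return An object of class `simcim_params`.
#' @export
simcim_params <- function(iterations = 15000L, batch = 100L, zeta = 1,
                          noise_sigma = 0.05, pump_schedule = "linear",
                          rng_seed = 1L) {
  stopifnot_scalar_int(iterations, "iterations", min = 1L)
  stopifnot_scalar_int(batch, "batch", min = 1L)
  stopifnot(noise_sigma >= 0)
  sched <- if (is.function(pump_schedule)) pump_schedule
  else switch(match.arg(pump_schedule, c("linear", "tanh")),
    linear = function(t, iterations) {
      if (iterations == 1L) 0 else -1 + 2 * (t - 1) / (iterations - 1)
    },
    tanh = function(t, iterations) {
      if (iterations == 1L) 0 else tanh(4 * ((t - 1) / (iterations - 1) - 0.5))
    })
  structure(list(iterations = as.integer(iterations),
                 batch = as.integer(batch), zeta = zeta,
                 noise_sigma = noise_sigma, pump_schedule = sched,
                 rng_seed = as.integer(rng_seed)),
            class = "simcim_params")
}

#' One SimCIM update step
#'
#' Applies the mean-field update exactly as defined for the algorithm: the
#' field `Phi_i = sum_{j != i} J_ij s_j + b_i` (with `b = p$h` taken as the
#' bias vector of the problem as given), the increment
#' `ds = p_t * s + zeta * Phi + N(0, sigma)`, and the clipping activation
#' `phi(x) = x` for `|x| <= 1`, `x/|x|` otherwise. Note the sign convention:
#' this raw update follows the field of the problem it is handed;
#' [simcim_solve()] hands it the negated problem so that the dynamics descend
#' the Ising energy. Consumes the current RNG stream (the solver seeds it).
#'
#' @param state list with `s`, an `n x batch` matrix of continuous spins in
#'   \[-1, 1\].
#' @param p an [ising_problem] supplying `J` and the bias `b = p$h`.
#' @param t iteration index in `1:params$iterations`.
#' @param params a [simcim_params()].
#' @return The updated state (same shape); also carries `Phi`.
#' @export
simcim_step <- function(state, p, t, params) {
  s <- state$s
  Phi <- p$J %*% s + p$h
  noise <- if (params$noise_sigma > 0) {
    matrix(stats::rnorm(length(s), 0, params$noise_sigma), nrow(s), ncol(s))
  } else 0
  p_t <- params$pump_schedule(t, params$iterations)
  s_new <- s + p_t * s + params$zeta * Phi + noise
  s_new <- pmin(pmax(s_new, -1), 1)
  list(s = s_new, Phi = Phi)
}

#' Minimize an Ising problem with SimCIM
#'
#' Runs `params$batch` independent mean-field annealing attempts of
#' `params$iterations` steps each, starting from `s = 0`. The problem is
#' first rescaled into the hardware coefficient range \[-1, 1\] (argmin
#' invariant); the dynamics follow the energy-descent field (the negated
#' couplings and biases fed to [simcim_step()]). The final discrete
#' configuration is the sign of each `s_i`, with ties at exactly 0 mapped to
#' +1. Reported samples are 0/1 (QUBO convention, `x = (s+1)/2`) and energies
#' are evaluated on the original, unscaled problem.
#'
#' @param p an [ising_problem].
#' @param params a [simcim_params()].
#' @param ground_energy optional known ground energy for hit counting.
#' @return An [anneal_result()].
#' @export
simcim_solve <- function(p, params = simcim_params(),
                         ground_energy = NULL) {
  stopifnot(inherits(p, "ising_problem"))
  ps <- rescale_for_hardware(p)
  descent <- new_ising(-ps$h, -ps$J, 0)
  n <- p$n_vars
  s <- with_seed(params$rng_seed, {
    state <- list(s = matrix(0, n, params$batch))
    for (t in seq_len(params$iterations)) {
      state <- simcim_step(state, descent, t, params)
    }
    state$s
  })
  spins <- ifelse(s >= 0, 1, -1)
  S <- t(spins)
  energies <- ising_energies(p, S)
  anneal_result(spins_to_bits(S), energies, solver = "simcim",
                params = params, ground_energy = ground_energy)
}

# 0/1 state matrix for the integer range [lo, hi] (0-based states), n bits.
bit_matrix <- function(lo, hi, n) {
  ints <- as.integer(seq.int(lo, hi))
  X <- matrix(0L, length(ints), n)
  for (b in seq_len(n)) {
    X[, b] <- bitwAnd(ints, bitwShiftL(1L, b - 1L)) != 0L
  }
  X
}

#' Exhaustive QUBO minimization (verification oracle)
#'
#' Enumerates all `2^n` binary assignments and returns the exact ground
#' energy together with every ground state. Capped at 24 variables.
#'
#' @param q a [qubo_problem].
#' @param cap refuse problems with more variables than this.
#' @param tol degeneracy tolerance for collecting ground states.
#' @return An [anneal_result()] whose `samples` are all ground states;
#'   `n_ground_states` is attached. A 0-variable problem returns its offset.
#' @export
brute_force_solve <- function(q, cap = 24L, tol = 1e-9) {
  stopifnot(inherits(q, "qubo_problem"))
  n <- q$n_vars
  if (n > cap) {
    stop(sprintf("problem has %d variables; brute-force cap is %d", n, cap),
         call. = FALSE)
  }
  if (n == 0L) {
    res <- anneal_result(matrix(0, 1, 0), q$offset, "brute_force")
    res$n_ground_states <- 1L
    res$ground_energy <- q$offset
    return(res)
  }
  chunk <- 2^18
  total <- 2^n
  best_e <- Inf
  ground <- NULL
  lo <- 0
  while (lo < total) {
    hi <- min(lo + chunk, total) - 1
    X <- bit_matrix(lo, hi, n)
    e <- qubo_energies(q, X)
    mn <- min(e)
    if (mn < best_e - tol) {
      best_e <- mn
      ground <- X[e <= mn + tol, , drop = FALSE]
    } else if (mn <= best_e + tol) {
      best_e <- min(best_e, mn)
      ground <- rbind(ground, X[e <= best_e + tol, , drop = FALSE])
    }
    lo <- hi + 1
  }
  res <- anneal_result(ground, rep(best_e, nrow(ground)), "brute_force",
                       ground_energy = best_e)
  res$n_ground_states <- nrow(ground)
  res$n_runs <- 1L
  res$n_ground_hits <- 1L
  res
}

#' Classical simulated annealing baseline
#'
#' Single-flip Metropolis with a geometric temperature schedule, run
#' `restarts` times from random initial states. With `sweeps = 0` the random
#' initial states themselves are returned. The reported state per restart is
#' the best-so-far configuration, so its energy is non-increasing in the
#' number of sweeps.
#'
#' @param q a [qubo_problem].
#' @param sweeps full variable sweeps per restart.
#' @param restarts independent restarts (one sample each).
#' @param t_hot,t_cold initial and final temperatures of the geometric
#'   schedule.
#' @param rng_seed integer seed.
#' @param ground_energy optional known ground energy for hit counting.
#' @return An [anneal_result()].
#' @export
simulated_annealing_solve <- function(q, sweeps = 200L, restarts = 20L,
                                      t_hot = 2, t_cold = 0.05,
                                      rng_seed = 1L, ground_energy = NULL) {
  stopifnot(inherits(q, "qubo_problem"))
  n <- q$n_vars
  Q <- q$Q
  temps <- if (sweeps > 0) {
    t_hot * (t_cold / t_hot)^(seq_len(sweeps) / sweeps)
  } else numeric(0)
  out <- with_seed(rng_seed, {
    samples <- matrix(0, restarts, n)
    energies <- numeric(restarts)
    for (r in seq_len(restarts)) {
      x <- sample(c(0, 1), n, replace = TRUE)
      e <- qubo_energy(q, x)
      best_x <- x; best_e <- e
      for (temp in temps) {
        for (i in sample.int(n)) {
          # energy change of flipping bit i
          de <- (1 - 2 * x[i]) * (Q[i, i] + 2 * sum(Q[i, -i] * x[-i]))
          if (de <= 0 || stats::runif(1) < exp(-de / temp)) {
            x[i] <- 1 - x[i]
            e <- e + de
            if (e < best_e) { best_e <- e; best_x <- x }
          }
        }
      }
      samples[r, ] <- best_x
      energies[r] <- best_e
    }
    list(samples = samples, energies = energies)
  })
  anneal_result(out$samples, out$energies, "simulated_annealing",
                params = list(sweeps = sweeps, restarts = restarts,
                              t_hot = t_hot, t_cold = t_cold,
                              rng_seed = rng_seed),
                ground_energy = ground_energy)
}
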