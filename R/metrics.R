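#' Runs-to-solution at 99% confidence
#'
#' Number of independent runs a stochastic solver needs so that the ground
#' state is seen at least once with probability 0.99, from the binomial
#' model: `R99 = log(1 - 0.99) / log(1 - theta)`. `theta = 0` gives
#' infinity; `theta >= 0.99` is clamped to 1 run (runs are integers >= 1).
#'
#' @param theta per-run success probability in \[0, 1\].
#' @return R99 (possibly `Inf`).
#' @export
r99 <- function(theta) {
  if (any(theta < 0 | theta > 1, na.rm = TRUE)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(theta == 0, Inf,
                ifelse(theta >= 0.99, 1, log(1 - 0.99) / log(1 - theta)))
  out
}

#' Time-to-solution
#'
#' `TTS = t_a * R99(theta)`: total solver time to reach the ground state at
#' least once with probability 0.99, in the units of `t_a` (microseconds for
#' the 20-microsecond default annealing time of a quantum annealer run).
#'
#' @param theta per-run success probability.
#' @param t_a time per run, in microseconds (> 0).
#' @return TTS in microseconds (possibly `Inf`).
#' @export
tts <- function(theta, t_a = 20) {
  if (any(t_a <= 0)) stop("t_a must be positive", call. = FALSE)
  t_a * r99(theta)
}

wilson_interval <- function(hits, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- hits / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, mid - half), upper = min(1, mid + half))
}

# Ground energy for a problem in a synthetic set: exhaustive enumeration
# when the QUBO is small enough; otherwise the vertex-position encoding is
# nonnegative with zero exactly on Hamiltonian paths, so path search settles
# it. Returns NA when neither route applies.
oracle_ground_energy <- function(q, g, cap = 20L) {
  if (q$n_vars <= cap) return(brute_force_solve(q)$best_energy)
  if (q$encoding == "vertex_position" &&
      length(hamiltonian_paths(g, max_paths = 1)) > 0) {
    return(0)
  }
  NA_real_
}

#' Benchmark solvers over a synthetic problem set
#'
#' For every (problem, solver) pair: encode the problem (edge-indicator when
#' acyclic, vertex-position otherwise), establish the exact ground energy
#' with the oracle, run `n_runs` attempts, and record the empirical success
#' probability theta (with a Wilson 95% interval), R99 and TTS. Problems
#' whose ground energy the oracle cannot certify are excluded with a notice.
#'
#' @param ps a [generate_problem_set()] result.
#' @param solvers character subset of `c("simcim", "sa")`.
#' @param n_runs attempts per problem and solver.
#' @param rng_seed base seed; each (problem, solver) pair gets a distinct
#'   derived seed.
#' @param t_a named numeric: nominal per-run time in microseconds per solver
#'   (used for TTS; wall-clock per attempt is also recorded, informationally).
#' @param A penalty coefficient.
#' @param simcim control parameters template ([simcim_params()]); its seed is
#'   replaced per pair.
#' @return `data.frame` with one row per problem x solver: ids, sizes,
#'   encoding, `n_runs`, `n_ground_hits`, `theta` (+ Wilson bounds), `r99`,
#'   `t_a`, `tts`, and measured `wall_us` per attempt.
#' @export
benchmark_suite <- function(ps, solvers = c("simcim", "sa"), n_runs = 100L,
                            rng_seed = 1L,
                            t_a = c(simcim = 20, sa = 20), A = 1,
                            simcim = simcim_params()) {
  stopifnot(inherits(ps, "synthetic_problem_set"))
  solvers <- match.arg(solvers, c("simcim", "sa"), several.ok = TRUE)
  rows <- list()
  pair <- 0L
  for (prob in ps$problems) {
    g <- prob$graph
    acy <- is_acyclic(g)$acyclic
    q <- if (acy) qubo_edge_indicator(g, A) else qubo_vertex_position(g, A)
    e0 <- oracle_ground_energy(q, g)
    if (is.na(e0)) {
      message(sprintf("problem %s excluded: oracle infeasible (%d variables)",
                      prob$id, q$n_vars))
      next
    }
    for (sv in solvers) {
      pair <- pair + 1L
      seed <- (rng_seed * 10007L + pair) %% .Machine$integer.max
      t0 <- proc.time()[["elapsed"]]
      res <- if (sv == "simcim") {
        sp <- simcim
        sp$rng_seed <- seed
        sp$batch <- as.integer(n_runs)
        simcim_solve(qubo_to_ising(q), sp, ground_energy = e0)
      } else {
        simulated_annealing_solve(q, restarts = as.integer(n_runs),
                                  rng_seed = seed, ground_energy = e0)
      }
      wall_us <- (proc.time()[["elapsed"]] - t0) * 1e6 / n_runs
      theta <- res$n_ground_hits / res$n_runs
      wi <- wilson_interval(res$n_ground_hits, res$n_runs)
      ta <- unname(t_a[sv])
      rows[[length(rows) + 1L]] <- data.frame(
        problem = prob$id, length = prob$length, n_vertices = g$N,
        n_edges = g$M, encoding = q$encoding, n_vars = q$n_vars,
        solver = sv, ground_energy = e0, n_runs = res$n_runs,
        n_ground_hits = res$n_ground_hits, theta = theta,
        theta_lower = wi[["lower"]], theta_upper = wi[["upper"]],
        r99 = r99(theta), t_a = ta, tts = tts(theta, ta),
        wall_us = wall_us, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarize benchmark records per sequence length
#'
#' Mean, min, max and 90th percentile of TTS per (length, solver), the
#' column structure used for solver comparisons.
#'
#' @param records output of [benchmark_suite()].
#' @return `data.frame` with one row per length x solver.
#' @export
summarize_benchmarks <- function(records) {
  split_by <- interaction(records$length, records$solver, drop = TRUE)
  out <- lapply(split(records, split_by), function(df) {
    data.frame(length = df$length[1], solver = df$solver[1],
               n_problems = nrow(df),
               mean_tts = mean(df$tts), min_tts = min(df$tts),
               max_tts = max(df$tts),
               p90_tts = as.numeric(stats::quantile(df$tts, 0.9,
                                                    names = FALSE)),
               mean_theta = mean(df$theta), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$solver, res$length), ]
  rownames(res) <- NULL
  res
}

#' Plot TTS against sequence length
#'
#' Log-scale TTS per sequence length, one line per solver. Requires ggplot2.
#'
#' @param records output of [benchmark_suite()].
#' @return A ggplot object.
#' @export
plot_tts <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  smry <- summarize_benchmarks(records)
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$length, y = .data$mean_tts,
                                     colour = .data$solver)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sequence length (nt)",
                  y = "mean time-to-solution (µs)", colour = "solver")
}
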