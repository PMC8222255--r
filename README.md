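# olcanneal

De novo genome assembly posed as quadratic unconstrained binary
optimization (QUBO), solved with annealing-style minimizers.

## What this is for

Overlap-layout-consensus (OLC) assembly orders sequencing reads by their
exact suffix-prefix overlaps: reads are vertices of a directed graph, an
edge `u -> v` means the end of `u` matches the start of `v`, and the
genome is read off a **Hamiltonian path** — a path visiting every vertex
exactly once. Finding that path is NP-hard, which makes it a natural
candidate for annealing hardware and quantum-inspired optimizers. This
package is a self-contained, classical laboratory for that idea, aimed at
people studying annealing formulations of bioinformatics problems:

* synthetic data generation — random short sequences fragmented into
  k-mers, and error-free fixed-length reads drawn from (optionally
  circular) references;
* OLC graph construction, acyclicity checks, single-edge-cut partitioning;
* two QUBO encodings of the Hamiltonian path problem, with exact
  QUBO/Ising conversion and hardware-range rescaling:
  * *vertex-position*: `N^2` variables `x[v,j]` ("vertex `v` at step `j`"),
    energy `A * [rows + columns + non-edge steps]`; a valid path has
    energy 0; works for cyclic graphs;
  * *edge-indicator* (acyclic graphs): `M` per-edge variables; each vertex
    wants one selected incoming and outgoing edge; a Hamiltonian path has
    energy `2A`, and in general the ground energy is `2A x` (minimum
    path-cover size);
* solvers: **SimCIM** (mean-field quantum-inspired annealer with clipped
  continuous spins, `ds = p_t s + zeta * Phi + N(0, sigma)`), classical
  simulated annealing, and an exhaustive brute-force oracle (<= 24
  variables) that returns all ground states;
* Chimera topology modelling (`C_m`: `8m^2` qubits, `16m^2 + 8m(m-1)`
  couplers) with deterministic clique minor embedding, chain handling and
  unembedding;
* decoding, sequence reconstruction, and benchmarking with the
  time-to-solution figures of merit
  `R99 = log(0.01)/log(1-theta)` and `TTS = t_a * R99`.

See the methods vignette (`vignettes/qubo-assembly-methods.Rmd`) for the
model details, parameter meanings and validation scales.

## Worked example

Fragment a sequence into 3-mers, build the overlap graph, encode, solve
exactly, and read the sequence back:

```r
library(olcanneal)
sol <- assemble("ATGGTCAT", k = 3, solver = "exact")
print(sol)
#> <path_solution> hamiltonian, energy 0, 8 bp contig
#> order: kmer_1 -> kmer_2 -> kmer_3 -> kmer_4 -> kmer_5 -> kmer_6
print(sol$graph)
#> <olc_graph> N = 6 vertices, M = 6 edges
sol$sequence
#> [1] "ATGGTCAT"
```

The six 3-mers of `ATGGTCAT` form a graph with one auxiliary edge beyond
the fragmentation chain (`CAT -> ATG`, making it cyclic), so the pipeline
used the vertex-position encoding; `energy 0` certifies a valid
Hamiltonian path.

Benchmark the stochastic solvers against the exact oracle on a small
generated problem set (two problems per length 5–7, 50 attempts each):

```r
ps  <- generate_problem_set(5:7, per_length = 2, k = 3, rng_seed = 7)
rec <- benchmark_suite(ps, solvers = c("simcim", "sa"), n_runs = 50,
                       rng_seed = 7, simcim = simcim_params(iterations = 4000))
summarize_benchmarks(rec)
#>   length solver n_problems mean_tts min_tts max_tts p90_tts mean_theta
#> 1      5     sa          2    20.00   20.00   20.00   20.00       1.00
#> 2      6     sa          2    20.00   20.00   20.00   20.00       1.00
#> 3      7     sa          2    74.96   64.54   85.38   83.29       0.71
#> 4      5 simcim          2    20.00   20.00   20.00   20.00       1.00
#> 5      6 simcim          2    20.00   20.00   20.00   20.00       1.00
#> 6      7 simcim          2    23.54   23.54   23.54   23.54       0.98
```

`theta` is the fraction of attempts that reached the oracle ground energy;
`TTS` converts it into the total per-problem time (at a nominal 20 µs per
attempt) needed to see the ground state with 99% confidence — at
`theta = 1` that is a single 20 µs attempt, and it grows as `theta`
drops.

Hardware-topology modelling:

```r
chimera_graph(16)
#> <chimera_graph> C16: 2048 qubits, 6016 couplers
```

## Command line

A thin wrapper over the same functions lives in
`inst/scripts/olcanneal-cli.R` (after installation:
`system.file("scripts", "olcanneal-cli.R", package = "olcanneal")`):

```sh
Rscript olcanneal-cli.R generate  --config cfg.json --out-dir data/
Rscript olcanneal-cli.R assemble  --input reads.fasta --k 3 --out-fasta contig.fasta --out-report report.json
Rscript olcanneal-cli.R benchmark --config cfg.json --out-csv bench.csv
```

Configs are flat JSON/YAML documents; command-line flags override file
values, and every stochastic run carries an explicit seed.

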