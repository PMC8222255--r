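---
title: "Methods: Hamiltonian-path QUBO assembly and annealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hamiltonian-path QUBO assembly and annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olcanneal)
```

## The problem

In overlap-layout-consensus (OLC) assembly, every read (or k-mer) is a
vertex of a directed graph and an edge $u \to v$ records an exact
suffix-prefix overlap of at least `min_overlap` characters. Ordering all
fragments into the genome is then a Hamiltonian path problem: a directed
path visiting every vertex exactly once. `olcanneal` casts that NP-hard
search as quadratic unconstrained binary optimization (QUBO) so that it can
be handed to annealing-style minimizers — a quantum-inspired mean-field
annealer (SimCIM), classical simulated annealing, or an exhaustive oracle —
and models the extra step a physical annealer would need, minor embedding
into a Chimera hardware topology.

## The two encodings

**Vertex-position encoding.** For an $N$-vertex graph, binary variables
$x_{v,j}$ mean "vertex $v$ is visited at step $j$" ($N^2$ variables,
indexed vertex-major). The energy is a pure penalty,

$$
\mathcal{H} = A\sum_v \Big(1-\sum_j x_{v,j}\Big)^2
            + A\sum_j \Big(1-\sum_v x_{v,j}\Big)^2
            + A\sum_{(u,v)\notin E}\sum_{j} x_{u,j}\,x_{v,j+1},
$$

with $A>0$. The first two terms force a permutation matrix; the third
charges $A$ for every consecutive step pair that is not an edge. A valid
Hamiltonian path has energy exactly $0$; the encoding works on cyclic and
acyclic graphs alike. The third term runs over *ordered* non-edges with
$u \neq v$: traversing an edge backwards is a non-edge and is penalized.

**Edge-indicator encoding.** When the graph is acyclic, one variable per
edge suffices ($M$ variables): $x_{u,v}=1$ means the edge is on the path,
and every vertex asks for one selected outgoing and one selected incoming
edge,

$$
\mathcal{H} = A\sum_{u}\Big(1-\sum_{(u,v)\in E}x_{u,v}\Big)^2
            + A\sum_{v}\Big(1-\sum_{(u,v)\in E}x_{u,v}\Big)^2 .
$$

On a DAG a selection with unit degrees is a set of vertex-disjoint paths,
so the ground energy is $2A$ times the minimum path-cover size; a
Hamiltonian path exists iff the ground energy is $2A$ (the source misses an
incoming edge and the sink an outgoing one). The encoding is rejected for
cyclic graphs, where unit-degree selections could close cycles. No extra
term excludes disjoint-path ground states — the decoder classifies them
(`disjoint_paths`, with the cover size) and the pipeline reports such
samples as assembly failures.

Because both Hamiltonians are pure penalties, any $A > 0$ has the same
minimizers; the default is $A=1$, kept as a parameter because hardware
rescaling interacts with it (energies scale linearly in $A$).

The Ising form used by the solvers comes from the substitution
$x_i = (\sigma_i+1)/2$, tracked so that QUBO and Ising energies agree
configuration by configuration (offsets absorb the constants). Before a
physical device — or its emulator — sees the problem, all fields and
couplings are divided by $\max(|h|_\infty, |J|_\infty)$ when that exceeds
1, which bounds every coefficient to $[-1,1]$ without moving the argmin.

## SimCIM

SimCIM treats each spin as a continuous variable $s_i \in [-1,1]$ evolving
under its mean field. Each iteration computes
$\Phi_i = \sum_{j\neq i} J_{ij} s_j + b_i$, the increment
$\Delta s_i = p_t s_i + \zeta \Phi_i + \mathcal{N}(0,\sigma)$, and clips
$s_i \leftarrow \phi(s_i + \Delta s_i)$ with $\phi(x)=x$ for $|x|\le 1$ and
$x/|x|$ otherwise. After the last iteration the discrete state is
$\mathrm{sign}(s_i)$, ties at $0$ mapped to $+1$. All attempts start from
$s=0$; the noise breaks the symmetry.

One convention deserves care: composed literally with the Ising energy
$E=\sum h\sigma + \sum J\sigma\sigma$, the raw update *ascends* $E$.
`simcim_step()` is therefore the verbatim update for the couplings and
biases it is handed, and `simcim_solve()` hands it the descent field
($J_\mathrm{dyn}=-J$, $b=-h$) so the dynamics minimize the problem energy.

Tunable parameters, with the package defaults:

| parameter | default | meaning |
|---|---|---|
| `iterations` | 15000 | pump-ramp length (steps per attempt) |
| `batch` | 100 | independent attempts run in parallel |
| `zeta` | 1 | coupling gain on the rescaled problem |
| `noise_sigma` | 0.05 | Gaussian noise s.d. per step |
| `pump_schedule` | linear | $p_t$ ramps $-1 \to +1$ (tanh available) |

The defaults were chosen by measuring per-problem ground-hit rates on the
synthetic benchmark set (below): on frustrated 16–25-variable penalty problems
a fast ramp or a weak gain locks spins before the mean field can order
them, collapsing the success probability on a subset of instances. The
slow linear ramp with unit gain on the $[-1,1]$-rescaled problem attains
per-problem $\theta \ge 0.9$ on every length-$\le 7$ instance, stable
across solver seeds and across independently generated problem sets. These
are solver knobs, not scientific claims; all of them are exposed in
`simcim_params()`.

## Exhaustive oracle and the exact assembly route

`brute_force_solve()` enumerates all $2^n$ assignments (chunked, vectorized)
up to a hard cap of 24 variables and returns the exact ground energy with
*all* ground states — it is the reference every stochastic result is
measured against. The end-to-end `assemble(..., solver = "exact")` route
uses it whenever the QUBO fits under the cap; for larger vertex-position
instances (cyclic graphs with $N \ge 5$, i.e. $N^2 \ge 25$ variables) it
exploits the encoding's structure instead: the energy is non-negative and
zero exactly on Hamiltonian paths, so a depth-first path search is an exact
ground-state solver whenever a path exists. The DFS orders successors by
decreasing overlap, which on near-interval overlap graphs finds a path
almost immediately.

## Synthetic benchmark set

`generate_problem_set()` defines the benchmark conditions: for each length
5–10, random uniform A/C/G/T sequences are fragmented into 3-mers until 10
problems per length survive three filters — duplicate 3-mers (a duplicate-
free fragmentation chain guarantees a Hamiltonian path exists), bare chains
($M = N-1$, nothing to optimize), and duplicate problems (same sorted
k-mer list). That yields 60 problems per seed. A retry cap (1000 candidates
per length) bounds generation; exhaustion is a warning with a partial set.

The read simulator draws error-free, forward-strand, fixed-length reads at
uniform starts, with optional circular wrap-around. What this emulates is
a controlled, idealized setting — no sequencing errors, no reverse
complements, no repeats beyond what short random sequences contain, and no
contaminants. Passing tests on these data therefore say nothing about
error-tolerant overlap detection or strand resolution on real libraries;
they validate the graph/QUBO/solver/decoder chain itself.

## Hardware topology and embedding

`chimera_graph(m)` builds the Chimera topology: an $m \times m$ grid of
8-qubit $K_{4,4}$ cells, vertical-shore qubits chained downward, horizontal-
shore qubits chained rightward; $8m^2$ qubits and $16m^2 + 8m(m-1)$
couplers, degree $\le 6$ (for $m=16$: 2048 qubits, 6016 couplers).
`embed_clique()` implements the deterministic triangular clique embedding —
variable $v$ (group $g=\lfloor v/4\rfloor$, offset $o=v\bmod 4$) occupies a
row segment and a column segment meeting in cell $(g,g)$ — giving chains of
length $m'+1$ on the $m' = \lceil n/4\rceil$ sub-grid and capacity $4m$.
Chains carry the logical field spread evenly, logical couplings are split
across the available inter-chain couplers, and intra-chain couplers get a
ferromagnetic tie of $2\max|J|$ by default. Samples with broken chains are
discarded and counted, never majority-voted: discarding is the
unambiguous contract, and repair heuristics are out of scope.

## Benchmark figures of merit

With $\theta$ the empirical fraction of attempts that reach the oracle
ground energy (a Wilson 95% interval is reported alongside),

$$
R_{99} = \frac{\log(1-0.99)}{\log(1-\theta)}, \qquad
\mathrm{TTS} = t_a R_{99},
$$

where $t_a$ is the per-attempt time (20 µs is the customary annealer
default). $\theta=0$ gives infinite $R_{99}$; $\theta \ge 0.99$ is clamped
to $R_{99}=1$ since runs are integers. `benchmark_suite()` uses a nominal,
configurable $t_a$ so results are hardware-independent; measured wall-clock
per attempt is recorded as information only and never asserted.
Per-length summaries report mean, min, max and the 90th percentile over
instances.

## Numerical and design choices

* **Overlaps** are exact-match only and containment produces no edge —
  faithful for error-free data; approximate overlap detection is out of
  scope.
* **Partitioning** (`partition_single_edge_cuts()`) searches combinations
  of bridges of the collapsed undirected graph; a single-edge cut between
  weakly connected blocks is necessarily a bridge, so this is exact. Ties
  between valid splits are broken toward balanced block sizes. Dense
  overlap graphs (e.g. circular, well-covered read sets) have no bridges
  and the failure is a reported status; the read-scale pipeline then falls
  back to whole-graph search.
* **Sign ties** at SimCIM readout go to $+1$; initial state is $s=0$.
* **Degenerate inputs**: all-identical fragments collapse to a one-vertex
  graph (warned, reported degenerate); zero-variable QUBOs return their
  offset; an overlap-free fragment set fails with status, not an error.
* **Ambiguity**: when several distinct ground-state Hamiltonian paths
  exist, the exact route reports their count (`n_ground_paths`) instead of
  pretending the reconstruction is unique.

## Validation scales

The test suite fixes every stochastic input by seed and chooses problem
sizes so the full run completes in minutes on one CPU:

* encoding correctness is checked exhaustively against independent
  combinatorial oracles on all labelled digraphs with $N \le 3$
  (vertex-position, full $2^{N^2}$ enumeration) and all labelled DAGs with
  $N \le 4$ (edge-indicator vs. minimum path cover via bipartite matching),
  plus seeded random samples at $N=4$ digraphs and $N=5,6$ DAGs;
* the round-trip property (assemble, reconstruct, compare k-mer content and
  — for unique paths — the exact sequence) runs over the full 60-problem
  set;
* SimCIM efficacy runs the full default batch on the 30 problems of length
  $\le 7$;
* the read-scale circular benchmark uses a synthetic 5386 bp reference with
  50 error-free 600 bp reads (the benchmark read parameters) and, at toy
  scale, a 1200 bp reference at higher coverage. At ~5.6× coverage a
  random instance occasionally leaves a coverage gap too wide for any
  overlap threshold; such instances have no Hamiltonian path and are
  reported as data failures, which the tests distinguish from method
  failures.

## Known limitations

No error model, no reverse complements, no repeat resolution, no transitive
reduction or unitig construction; the edge-indicator encoding cannot
energetically exclude disjoint path covers; exhaustive verification is
limited to small graphs by $2^n$ growth; the embedding targets Chimera only
and chain breaking is handled by discard, not repair.
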