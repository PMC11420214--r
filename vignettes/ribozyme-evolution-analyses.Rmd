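---
title: "Analysing directed ribozyme evolution: library statistics, population dynamics, quasi-neutral paths, kinetics and folds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing directed ribozyme evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribolandscape)
```

ribolandscape implements the computational half of an in vitro evolution
experiment on ligase ribozymes: a parent ribozyme that ligates
phosphorimidazolide-activated RNA (an "AIP-ligase") is mutagenized into a
doped library, selected over several rounds for ligation of
5'-triphosphorylated RNA (a "PPP-ligase"), and the resulting sequencing,
kinetic and structural data are analysed. The package covers five analyses —
doped-library statistics, sequencing population analysis, quasi-neutral path
finding, kinetics fitting and secondary-structure fold grouping — plus a
seeded synthetic-data generator so that every analysis can be exercised and
tested without access to raw sequencing data. The `analysis/` scripts in the
repository run the five analyses in order as a worked pipeline.

## Doped-library statistics

A doped library mutates each of $L$ positions of a parent sequence
independently with probability $\mu$, choosing uniformly among the three
non-parent bases. The defaults, $L = 40$ and $\mu = 0.21$ (7% per non-parent
base) in a pool of $N = 10^{15}$ molecules, describe the library the package
is designed around. Everything follows from the binomial law for the number
of mutations $K$ per molecule:

$$\Pr(K = k) = \binom{L}{k}\,\mu^k (1-\mu)^{L-k}.$$

`parent_probability()` is $\Pr(K=0) = (1-\mu)^L \approx 8.0\times10^{-5}$
(0.008% of the pool), `mutation_count_tail()` is $\Pr(K \ge k_\min)$ and
`expected_pool_size()` multiplies the tail by $N$. The tail is evaluated
through the binomial survival function on the log scale: the quantities of
interest sit around $10^{-11}$, far below anything a sampling approach could
resolve, and term-wise naive summation is reserved for the test oracle.
`signif1()` exists because pool fractions are conventionally quoted to one
significant figure; full-precision values are always returned by the
underlying functions and the rounding is left to the caller.

The same accounting gives the package's reference points: about $4\times10^4$
of $10^{15}$ molecules carry 28 or more mutations, and fewer than
$2\times10^7$ carry 25 or more — the thin tail from which a winner far from
the parent must have come.

## Sequencing population analysis

`seq_count_table()` holds per-round read counts of the fixed-length variable
region. Reads are uppercased and `T` is transliterated to `U` with a warning;
constant flanks are trimmed upstream with `trim_variable_region()` using
explicit anchor sequences. All distances are Hamming distances over the
variable region only — the library has fixed length, so no indel handling is
attempted.

Clustering (`greedy_cluster()`) is deliberately simple and fully
deterministic: visit sequences in descending read count (ties broken
lexicographically), open a cluster at each unassigned visitable sequence, and
absorb every unassigned sequence within a Hamming `radius` (default 10). The
published analyses this mirrors do not state their clustering algorithm; a
greedy abundance-ranked centroid pass is the natural choice when clusters sit
13+ mutations apart with "little sequence overlap", and the radius is
configurable for tighter or looser selections. Sequences below `min_reads`
cannot seed clusters but can join them. `merge_clusters()` exists because
published tallies sometimes merge related clusters by hand; no automatic
merge criterion is guessed.

`within_cluster_share()` recovers the "% of peak within its cluster" column
of a peak-sequence abundance table from the two overall percentage columns —
useful because published tables print rounded percentages whose algebra can
be checked exactly. `distance_spectrum()` marginalizes a round's abundance
over Hamming distance from a reference (typically the parent), and
`trajectory()` tracks per-sequence abundances with the conventional
">100 reads" display threshold: a count of exactly 100 is censored
(`min_reads = 100` means "more than 100 reads to show"), and a reemergence is
a censored-to-uncensored transition after the sequence has already been above
threshold once.

## Quasi-neutral path finding

The mutational graph (`build_graph()`) has the observed sequences as nodes
and Hamming-distance-1 pairs as edges. Neighbors are found by enumerating the
$3L$ single mutants of a node and testing membership in a hash index, never
by an all-pairs scan, so graphs of $10^5$ observed sequences are cheap.

`shortest_path_toward()` computes single-source shortest paths with unit
edge weights — the only reading of "shortest path over single mutations" —
so Dijkstra's algorithm reduces to breadth-first search, and the test suite
holds the implementation to exact agreement with an independent graph
library. Because the interesting target (the evolved winner) is usually
*absent* from the observed data, the search returns the path to the
reachable node closest in Hamming distance to the target, with ties broken
by path length and then lexicographically so results are reproducible.
`bidirectional_refine()` alternates this search from both endpoints,
accepting a frontier move only when it strictly shrinks the gap (the
residual gap is therefore nonincreasing), and reports the remaining Hamming
gap when the observed data simply contain no intermediates — the typical
outcome when selection has removed everything resembling the parent.
`bridge_single_step_path()` then constructs the designed single-step path
across the gap; the default mutation order is 5'→3' position order, since
the experimental order in such studies is chosen by trial and error and is
not inferable.

Quasi-neutrality (`quasi_neutral_criterion()`) requires an intermediate to
retain at least a `fraction` (default 10%) of the reference ribozyme's rate
enhancement in at least one chemistry: with reference enhancements of
100-fold (AIP) and 1000-fold (PPP), the derived thresholds are 10-fold and
100-fold. The boundary is inclusive ($\ge$), matching the threshold phrasing
"had to show rate enhancements of 10-fold or 100-fold"; the alternative
strict reading differs only on exact boundary values and is available by
adjusting `fraction`. `annotate_path()` labels each intermediate
(`AIP-only`, `AIP+PPP`, `PPP-only`, `fails`) and reports where PPP-ligase
function first emerges; missing activity records are listed, never imputed.

An optional abundance weighting of graph edges was considered and rejected
as a default: hop count is the quantity the neutral-path question is about,
and any weighting scheme would silently change "shortest" into a different
claim.

## Kinetics

Time courses are fitted to a single exponential to an amplitude,
$f(t) = A(1 - e^{-k t})$, with $A$ bounded at 1.05 — ribozyme ligations
commonly plateau below complete conversion, and the bound keeps noisy
near-complete reactions from drifting to unphysical amplitudes. When the
maximum ligated fraction is below 0.05 (or only two points exist) there is no
usable curvature and the fit falls back, flagged, to an initial-rate linear
fit with $A = 1$. Loss is unweighted least squares throughout: the data this
models are published without per-point error models.

Mg²⁺ titrations are fitted to the Hill form
$k_{obs}(c) = k_{max} c^{n} / (K_{1/2}^{n} + c^{n})$ with deterministic
initialization ($K_{1/2}$ at the concentration of half-maximal observed rate,
$n = 1$, $k_{max}$ at the observed maximum) and bounds $n \in (0.2, 8]$,
$K_{1/2} \in (0, 10\,c_{max}]$. The Hill coefficient is reported as a
cooperativity proxy for the number of bound ions — "consistent with $n$
bound Mg²⁺ ions" — not as a binding stoichiometry, and a fitted $K_{1/2}$ at
or beyond the sampled range flags the result as unreliable (no plateau was
observed). pH-rate profiles are fitted as ordinary least squares of
$\log_{10} k_{obs}$ on pH restricted to a linear window (default pH 6–9;
the falling limb above pH 9 is excluded by construction). All fits are
deterministic given their input: fixed initialization, no random restarts.

## Fold grouping

Secondary structures enter as dot-bracket strings (any predictor;
`read_dotbracket_file()` reads FASTA-like multi-record files) and are
compared by base-pair distance — the size of the symmetric difference of
their base-pair sets, a true metric. `group_folds()` walks an ordered series
(the structures along a mutational path) once, opening a new fold whenever
the distance to the current fold's first member exceeds a threshold (default
8 pairs), and records where each fold first appears. Anchoring to the first
member rather than the previous structure keeps slow drift from splitting a
fold while still catching abrupt jumps.

`nussinov_fold()` ships as a self-contained baseline predictor: maximum
Watson–Crick + G·U pairing with a minimum hairpin loop of 3, deterministic
traceback (position $i$ pairs with the smallest admissible partner). It
exists so the fold-grouping machinery is testable without an external
folding engine; it is *not* a thermodynamic model, and fold counts along a
path are predictor-dependent. For that reason the package treats any
specific published fold count (e.g. "seven distinct folds") as a
qualitative, predictor-dependent observation, not a number to reproduce.

## The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume, not a mechanistic replica of the experiment:

* `sample_doped_library()` draws library members under the per-position
  mutation scheme (so empirical mutation-count spectra must match the
  binomial pmf — a standing test);
* `activity_landscape()` places exponential activity peaks
  ($k = k_{bg} + \max_i (k_{max,i}-k_{bg})\,e^{-d_i/\tau_i}$, $d_i$ the
  Hamming distance to centroid $i$) over a flat background, the standard
  "rugged landscape with isolated peaks" picture;
* `simulate_round()` applies first-order survival
  $p = 1 - e^{-k\,t_{\mathrm{eff}}}$ with $t_{\mathrm{eff}}$ = reaction time
  × a Mg²⁺ scaling factor, as binomial thinning, followed by multinomial
  amplification and multinomial sequencing subsampling;
* `generate_kinetics()` evaluates the three kinetic models and applies
  multiplicative log-normal noise (Gaussian on $\log_{10} k$ for pH series,
  the scale on which those profiles are fitted).

Default stringency escalates by shortening reaction times and lowering the
Mg²⁺ scaling each round, emulating such schedules qualitatively; exact
per-round times and concentrations are experiment-specific and the defaults
are documented as illustrative. The Mg²⁺ effect
is a plain multiplicative scaling of $k$ rather than a Hill coupling — the
coupling can be composed from the kinetics module when wanted, but the
simpler model keeps the selection simulation interpretable.

Two deliberate departures from realism matter for interpreting tests.
First, amplification is unbiased multinomial resampling: no PCR jackpots, no
per-cycle mutagenesis (an option for per-sequence amplification efficiency
was considered and left out of the default because none of the standing
analyses depend on it). Second, a simulated pool samples the library at
$10^4$–$10^5$ molecules, ten orders of magnitude below a real pool, so any
*specific* rare genotype — such as the eventual winner, which in a real
$10^{15}$ pool is present as a handful of molecules — would never be drawn.
`selection_config(spike = ...)` therefore plants chosen genotypes into round
0 at stated copy numbers. Passing tests consequently show that the analyses
behave correctly on data with the assumed statistical structure; they do not
show that real selections lack jackpot effects, sequencing errors or
amplification mutations, all of which are out of scope.

All generators take a mandatory seed and restore the caller's RNG state;
there is no hidden global randomness, and identical seeds give identical
datasets.

## Problem sizes and numerical choices

The test suite and the acceptance script use problem sizes chosen to make
sampling error negligible relative to the tested tolerances while keeping
runs interactive: $10^5$ library draws for distribution checks (multinomial
3σ bands per bin), 100 replicates for fit-recovery distributions (median
$K_{1/2}$ within 10%, median $n$ within 0.5, mean pH slope within 0.05),
graphs of ~$10^3$ nodes for the path-search equivalence checks, and
exhaustive structure enumeration up to length 12 for the folding oracle.
Degenerate inputs are defined rather than rejected wherever a sensible
definition exists: a tail from $k_{\min} = 0$ is 1, an empty pool errors, an
isolated source yields the single-node path, a peak that is its whole
cluster holds 100% of it.

## Limitations

The package analyses substitution-only sequence spaces (no indels), consumes
secondary structures rather than predicting them thermodynamically, treats
activity records as measured inputs (it never predicts the activity of an
unmeasured intermediate), and makes no attempt to model the selection
chemistry itself. Published numbers that depend on non-deposited raw
sequencing data — specific round-by-round abundances, the exact identity of
path intermediates, predictor-specific fold counts — are out of reach by
design; what the package reproduces exactly is everything derivable from
printed tables and closed forms, and what it reproduces statistically is the
recovery of stated kinetic parameters under stated noise.
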