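# ribolandscape

Analysis toolkit for directed-evolution experiments on ligase ribozymes — the
setting where a parent ribozyme that ligates phosphorimidazolide-activated RNA
(an AIP-ligase) is partially randomized into a "doped" library and selected,
round by round, for ligation of 5'-triphosphorylated RNA (a PPP-ligase). The
package is written for the people who run and analyse such selections: it
turns per-round sequencing counts, kinetic measurements and predicted
secondary structures into the quantities those studies report.

It implements five analyses over a common set of containers, plus a seeded
synthetic-data generator so everything is testable without raw data:

1. **Doped-library statistics** — the number of mutations per molecule in a
   library doped at rate μ over L positions is Binomial(L, μ), so the parent
   fraction is (1−μ)^L and the fraction with ≥ k mutations is the binomial
   upper tail, evaluated in log space (the interesting tails sit near
   10⁻¹¹). Multiplying by the pool size gives accessible-pool counts.
2. **Population analysis** — per-round fractional abundances, deterministic
   greedy Hamming clustering into peak-sequence clusters, within-cluster
   abundance algebra, distance-from-parent spectra, and read-thresholded
   abundance trajectories with reemergence detection.
3. **Quasi-neutral paths** — a Hamming-1 graph over observed sequences with
   hash-indexed neighbor queries, unit-weight shortest-path search toward a
   (possibly unobserved) target, bidirectional endpoint refinement, designed
   single-step bridges across gaps, and classification of intermediates
   against a ≥10%-of-reference rate-enhancement criterion (10-fold for AIP,
   100-fold for PPP ligation at the defaults).
4. **Kinetics** — first-order fits f(t) = A(1−e^(−kt)) with an initial-rate
   fallback, rate enhancements k_cat/k_bg, Mg²⁺ Hill binding
   k(c) = k_max·cⁿ/(K₁/₂ⁿ + cⁿ), and log₁₀ k_obs vs pH slopes restricted to
   the linear pH 6–9 window.
5. **Fold grouping** — dot-bracket parsing, base-pair (symmetric-difference)
   distance, a baseline maximum-pairing folder, and single-pass grouping of
   the structures along a mutational path into folds with jump detection.

## Worked example

```r
library(ribolandscape)

# How much of a 1e15-molecule library doped at 21% over 40 nt is useful?
m <- doped_library_model(length = 40, mutation_rate = 0.21, library_size = 1e15)
r <- library_report(m, k_min = 28)
sprintf("parent %.4g, >=28-mutation tail %.4g, i.e. %.4g molecules",
        r$parent_probability, r$tail, r$expected_count)
#> "parent 8.037e-05, >=28-mutation tail 3.897e-11, i.e. 3.897e+04 molecules"
```

So 0.008% of the pool is still the unmutated parent, and a winner carrying
28 mutations can only have come from about 4 × 10⁴ of the 10¹⁵ molecules —
the statistical puzzle at the heart of selections that land far from their
parent.

```r
# Check a published cluster table's algebra: peak at 20.59% overall in a
# cluster at 25.23% overall
within_cluster_share(20.59, 25.23)
#> 81.6092

# Recover Mg2+ binding parameters from a noisy synthetic titration
d <- generate_kinetics("hill", c(1, 2, 5, 10, 14, 25, 50, 100, 200),
                       truth = list(k_max = 1, K_half = 14, n = 3),
                       sigma = 0.05, seed = 101)
f <- fit_hill(d$conc_mM, d$kobs_h)
sprintf("[Mg2+]1/2 = %.2f mM, Hill n = %.2f", f$K_half, f$hill_n)
#> "[Mg2+]1/2 = 13.88 mM, Hill n = 3.24"
```

The peak sequence holds 81.61% of its cluster, and the Hill fit recovers a
half-saturation near 14 mM with a cooperativity consistent with ~3 bound
Mg²⁺ ions from a single noisy titration.

The `analysis/` directory runs the five analyses as a pipeline on simulated
data (`01_library_stats.R` … `06_fold_grouping.R`, in order); each script
prints what it finds and writes its tables under `results/`.

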