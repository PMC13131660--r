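---
title: "Methods: retracing and rewriting enhancer activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retracing and rewriting enhancer activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cretrace)
```

This vignette is the package's account of its models and numerical choices:
what each component computes, the assumptions behind it, which knobs matter,
and what the synthetic data can and cannot tell you about real enhancers.

## The setting

An enhancer's activity is assayed by MPRA across orthologs drawn from extant
genomes and reconstructed ancestors; a phylogeny with labeled internal nodes
ties them together. Two analyses sit on top: *retracing* (where along each
lineage did activity change, and which retained mutations explain it) and
*rewriting* (in what order do mutations reconstruct, enhance or ablate
activity, as judged by a sequence-to-accessibility oracle). Everything in
between — alignment, motif scanning, MPRA quantification, epistasis
analytics — is standard machinery, implemented with fixed conventions so
results are exactly reproducible.

## Alignment and mutation events

Pairwise global alignment uses a three-state (Gotoh) dynamic program with
two shipped parameterizations: the *reconstitution* preset (match 1,
mismatch −1, linear gap −1 per base) used to enumerate mutations between an
ancestor and an extant target, and the *orientation* preset (affine, gap
open −2, extend −8, match 1 / mismatch −1) used to decide whether a
retrieved ortholog should be reverse-complemented. Our affine convention
charges a gap run of length $L$ a cost of $\mathrm{open} + (L-1)\cdot
\mathrm{extend}$, so the linear preset is the special case open = extend;
other implementations charge open $+ L\cdot$extend, which differs by one
extension per run and can tip marginal alignments.

Tie-breaking in the traceback is fixed — diagonal over deletion (gap in
target) over insertion (gap in ancestor) — so the same pair always yields
the same alignment and hence the same mutation set. Coordinates are 0-based
half-open throughout. Mismatch columns become single-base substitutions;
maximal runs of same-orientation gap columns merge into one indel event
(a substitution adjacent to a gap stays separate). Under both presets an
optimal alignment never puts opposite-orientation gaps side by side
(a mismatch scores better than two gaps), so "mixed" runs do not arise.
Events are applied in alignment-column space, which makes subset
application order-independent by construction.

Percent identity defaults to matched columns over *all* alignment columns
(gaps count against identity); matched-over-aligned-columns is available
via `denominator = "aligned"`. Sequences containing undetermined bases (N)
are rejected with a named error; `read_fasta(drop_invalid = TRUE)`
reproduces the upstream pipeline behaviour of silently discarding them.
The 0.5–1.5× length-ratio filter on retrieved ortholog intervals is
provided as a standalone predicate (`length_ratio_filter()`); interval
retrieval itself is out of scope.

## Motif scanning and normalization

A PSAM scores a k-mer as the product of per-position weights; rows are
max-normalized at load so the consensus scores 1 before any further
normalization. Every window of a sequence is scored in both orientations;
strand is forward iff forward ≥ reverse.

Raw affinities are placed on a common scale by dividing by a *normalizer*
computed from 10⁶ uniformly random k-mers. The normalizer is the q99.99
quantile of that sample (type-7 interpolated quantiles); taking the sample
maximum instead, or enumerating all $4^k$ k-mers for the exact population
quantile, are options (`method = "max"` / `"exact"`). The quantile reading
was chosen over the maximum because a sample maximum does not converge and
makes normalized values depend on sample size; the exhaustive option exists
precisely so the sampled estimate can be audited (they agree within 5% at
$n = 10^6$ for $k \le 7$).

A window is called a TFBS when its normalized affinity exceeds the
threshold (default 0.05) *strictly*. Redundant paralogs merge by
per-position maximum under a group label ("Gata4/6"). Hits map onto
reference functional sites by any-overlap (≥ 1 shared MSA column);
`affinity_fold_change()` reports per-site affinity ratios between
orthologs, with a "lost" status when a site's columns are deleted rather
than a meaningless ratio.

## Phylogenetic retracing

Lineage paths come from the labeled tree (internal labels are required —
every downstream semantic references named ancestors). Step changes are
log2 ratios of child over parent activity along the path; they are left NA
when either activity is missing or non-positive — log ratios against zero
are never formed — and an activity floor (by default the negative-control
level) flags nodes as inactive for classification without affecting the
ratios. `derived_mutations()` returns differences that are newly present at
a node *and* retained in the extant leaf at the same MSA columns, which is
the set of candidate causal changes for a step on that edge.
`clade_summary()` reports per-clade activity distributions and the Spearman
correlation between percent identity and activity (average ranks for ties;
NA below three points or under constant input).

## The scoring oracle and the surrogate

The oracle contract is deliberately thin: a pure function from sequences to
nonnegative scores plus metadata. A trained accessibility model attaches
through a file-based subprocess contract (FASTA in, two-column TSV out;
`oracle_external()`), which keeps heavyweight models out of the package's
dependency graph.

For testing and simulation the package ships a *motif-gated surrogate*: a
score of $b_0$ unless every member of a required heterotypic module
(Foxa2, Sox17, Gata4/6 by default) reaches its minimum normalized affinity,
and otherwise $\min(c_{\max},\, b_0 + \sum_h w_{tf(h)} \cdot a_h)$ over
called hits. The AND gate encodes the empirical observation that a partial
module confers no activity; the ceiling encodes saturation. Defaults are on
a reporter-activity scale: $b_0 = 0.14$ (minimal-promoter background),
$c_{\max} = 1.4$ (ten-fold above background, consistent with an active
enhancer sitting ~7-fold over baseline before saturation), booster weights
0.03 per module-TF hit and 0.05 for Jun, and module minima of 1.5
normalized affinity — above the value a single-mismatch site reaches under
the default toy PSAMs, so only consensus-grade sites open the gate.

`marginal_footprint()` embeds a candidate at the center of background
sequences (replacing the central bases, so the oracle always sees a fixed
length) and reports mean embedded score over mean background score. The
ratio-of-means reading was chosen as the default; mean-of-ratios is a flag.
Footprints are invariant to uniform rescaling of the oracle and equal the
direct embedded/null ratio with a single background. Backgrounds default to
50 seeded uniform-random sequences — enough to stabilize the null under the
surrogate; a real deployment would supply genomic backgrounds (the
convention of ~1,000 is supported but unnecessary at desk scale).

## Trajectories

Greedy reconstitution scores, at every step, each remaining mutation
applied singly on the current intermediate and commits the argmax gain;
ties break by lowest alignment column then lexicographic derived allele, so
greedy needs no seed. Under a strictly additive oracle this provably equals
introducing mutations in descending single-effect order, which is one of
the package's acceptance checks; under the gated surrogate greedy receives
no gradient until a required module is one step from complete — an honest
consequence of AND-logic worth remembering when interpreting greedy-vs-
random comparisons on gate-dominated elements.

Random trajectories are uniform permutations of the same event set (ten by
default), reproducible under a seed. Phylogeny trajectories use the
ancestral orthologs themselves as intermediates, with percent divergence
from the target (by global alignment) as the x-axis.

De novo tuning is iterative in silico saturation mutagenesis: all $3L$
single-base substitutions are scored each step and the best (enhance) or
worst (ablate) is committed, for 50 steps by default. Only substitutions
are considered, positions may be revisited, and a candidate recreating the
immediately preceding sequence is excluded — a cycle guard that matters
once scores saturate at the ceiling or floor, where argmax ties would
otherwise oscillate. Step $k$ means "after $k$ committed mutations"; the
unmutated start is step 0.

## MPRA quantification

Barcode expression is the RNA/DNA ratio of within-sample-normalized UMI
counts. Per element, the default estimator winsorizes the barcodes'
normalized RNA and DNA values at [1%, 99%] (type-7 quantiles), sums each,
and takes the ratio; "winsorize per-barcode ratios then average" is the
alternative reading, kept behind `mode = "ratios"` and tested alongside.
With `winsor_frac = 0` the default reduces exactly to the plain summed
ratio. Barcodes with RNA but zero DNA are excluded (a pseudocount flag
exists, default 0), association maps are filtered at ≥ 2 reads by default,
and replicate summaries are mean ± standard error. A barcode-level
bootstrap CI is provided as a labeled convenience — it is descriptive, not
a calibrated differential test.

## Epistasis analytics

"Additive" is defined on the linear activity scale
($\hat y = y_0 + \sum_i (y_i - y_0)$, floored at 0) and "multiplicative" as
additive in log2 ($\hat y = y_0 \prod_i y_i / y_0$). Both return the
measured single-mutant activity for singletons, so they only diverge on
combinations. Model comparison uses Spearman correlation between per-step
predictions and measurements. Single-mutation effects are conventionally
measured on the extant background while trajectories start from the
ancestor; the mismatch is recorded in the effect table's metadata rather
than silently ignored.

Order dependence compares the spread of a mutation's per-step log2 effect
across trajectories with the replicate noise expected for a step
difference, propagated in log2 space as
$\sqrt{(\sigma_a/(\mu_a \ln 2))^2 + (\sigma_b/(\mu_b \ln 2))^2}$ and pooled
as a root mean square. Attribution of functional recovery counts only
positive log2 gains (losses are not "recovery"), and the expected share is
mutation-count-based; step classification labels a step *reconstituting*
when it first lifts a reference site across the call threshold,
*optimizing* when it raises an already-above-threshold site, and
*background* otherwise (including overlapping steps that lower affinity —
the three-class scheme has no better home for them).

## The synthetic-data module

`simulate_evolution()` evolves a root sequence down the labeled tree:
per-branch substitution counts are Poisson($L \times$ rate $\times$ branch
length) with uniform positions and alternatives (Jukes–Cantor-style — real
mammalian context dependence is deliberately not modeled), indels are
Poisson with geometric lengths (mean 1.5) and are forbidden inside planted
motif windows so ground truth stays well-defined. Planted events (motif
gains to consensus, motif losses by scrambling) apply last on their branch
and are logged. Every residue carries an identity token, so the simulator
emits an *exact* MSA (tokens are columns) and exact retained-in-leaf flags;
reversions are allowed naturally and detected by token-state comparison.

Two canonical scenarios are built by `make_fixture_suite()`:
*repurposed* — 16 leaves, 180 bp, low substitution rate (0.02/site/unit),
the three-TF module planted on the stem of one small terminal clade, so
activity gain is clade-restricted; *module* — 24 leaves, the module present
at the root, a higher rate (0.04), two independent module losses and two
Jun booster gains in distinct subclades. Branch lengths are uniform on
[0.05, 0.3] substitutions/site — shallow-mammalian scale.

`simulate_mpra()` draws lognormal barcode DNA shares (library composition,
fixed across replicates), multinomial DNA counts at depth 10⁶ per sample,
and RNA counts proportional to activity × a 5% lognormal per-replicate
jitter × DNA share. What this does *not* emulate: PCR jackpotting beyond
the UMI model, barcode cross-talk, position effects, integration biases,
or trans-environment differences — so passing recovery tests bounds
estimator correctness, not assay realism.

## Validation design and problem sizes

The test-suite checks run at sizes chosen for exactness and speed:
alignment optimality against a memoized recursive oracle on 500 pairs of
length ≤ 8 (where brute force is feasible); mutation round-trips on 200
simulated pairs; normalizer convergence for $k \le 7$ against the
exhaustive $4^k$ enumeration at $n = 10^6$; greedy local optimality audited
exhaustively on instances with ≤ 8 mutations; random-order uniformity by a
χ² test over all 24 orders of a 4-event set with 10,000 draws; estimator
recovery at sequencing depth 10⁶ across 40 elements spanning the activity
range; planted-branch recovery across 50 simulated phylogenies quantified
end-to-end from simulated counts with minP-level baseline controls.

The epistasis model-selection calibration uses 14-step trajectories with
log2 effects drawn from N(0, 1.5) and 5% lognormal measurement noise. The
length and effect spread matter: on short trajectories with modest effects
the additive and multiplicative models make rank-identical predictions and
*no* method can tell them apart by rank correlation — the chosen conditions
are the regime where the question is answerable, which is itself a useful
fact about the limits of trajectory-based model discrimination.

## Known limitations

- The surrogate's hard AND gate gives step-function responses; real
  accessibility models produce graded partial-module signals, so greedy
  trajectories on real oracles are better-ordered than the surrogate
  suggests.
- Ancestral sequences are inputs (or simulator outputs); reconstruction
  uncertainty is not propagated.
- The affine-gap convention differs by one extension charge per gap run
  from some other aligners (documented above); scores are comparable only
  within one convention.
- MSA construction is not re-implemented; real analyses should supply a
  curated alignment, and the simulator's token-exact MSA is a best case no
  real aligner achieves.
- The bootstrap CI over barcodes ignores replicate-level variance and is
  not a substitute for a differential-activity test.
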