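---
title: "Detecting compensatory evolution of dispersed G+C encodings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compensatory evolution of dispersed G+C encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compevo)
```

## The problem

Nucleosome occupancy in yeast is encoded quantitatively: it tracks the A+T
content of a window of sequence rather than particular bases at particular
positions. If selection conserves such a dispersed encoding, it acts on a
*sum* over many loci, each with a tiny fitness contribution. Purifying
selection then cannot purge every deleterious composition change; some fix,
and the encoding is restored by adaptive fixations of the opposite
composition class at nearby positions. Three observable signatures follow:

1. asymmetric substitution rates — A/T-losing substitutions slow down in
   A+T-rich (low-occupancy) sequence without a matching slowdown of
   A/T-gaining ones;
2. spatial coupling — A/T gains concentrate next to recent A/T losses and
   vice versa, beyond the genome's general substitution clustering;
3. allele-frequency shifts — deleterious composition-changing SNPs
   segregate at lower frequencies, beneficial ones at higher frequencies.

`compevo` implements the full chain from raw inputs to these three
signatures, together with the population-genetic model that predicts them,
and a synthetic-data generator that supplies every input with known ground
truth.

## The substitution model and its inference

Substitutions are modeled per lineage of a fixed rooted phylogeny, with a
free conditional probability table per lineage: `P(child | parent, 5'
flank, 3' flank)` — 16 flanking contexts, each a 4x4 row-stochastic matrix.
No global rate matrix, no branch lengths, no reversibility or
stationarity assumptions: lineages are free because extant composition
differs between species. Flanking context is read from the *ancestral*
(parent) sequence, since rates condition the mutational process that acted
on the ancestor; conditioning on extant flanks would mix cause and effect.

Ancestral inference uses loopy belief propagation on a factor graph with
one variable per (internal node, site):

* per branch and site, a factor over (parent site−1, parent site, parent
  site+1, child site) carrying the context-dependent table; observed
  leaves enter with the child index clamped, and a masked leaf symbol
  drops its factor (a row-stochastic table carries no evidence when the
  child is summed out);
* along the root, a second-order Markov chain: a factor per triple of
  adjacent root sites plus a joint factor over the first two.

The graph is loopy because adjacent sites share flank variables. Messages
are updated in sequential sweeps with alternating direction, with damping
0.2 and convergence declared when no message component moves by more than
`tol` (default 1e-6; non-convergence raises an error carrying the
iteration trace). When the context coupling is switched off (all 16
contexts equal) and the root is memoryless, the graph decouples by site and
BP is exact — the test suite verifies agreement with brute-force
enumeration to 1e-8 on trees of up to 4 leaves.

Sequences are processed in blocks of 10,000 sites overlapping by 2 sites
(the flank reach), so memory stays flat in genome length. At a block's
outermost sites the missing flank is marginalized out of the factor table
uniformly; these two boundary sites per block edge are excluded from
expected-count accumulation.

Parameter estimation is generalized EM: the E step accumulates expected
(flank, parent, child) counts from the BP factor beliefs; the M step
row-normalizes them per lineage and context and re-estimates the root
model. Columns containing any non-ACGT leaf symbol are masked entirely
(gaps are not generated by the simulator; the masking path is how real
alignments would be handled). Contexts with fewer than `min_columns`
(default 200) expected informative sites keep their initial rates and are
flagged. EM stops when no conditional probability moves by more than
`tol` (default 1e-3) — an absolute criterion on probabilities, chosen over
a likelihood criterion because the BP likelihood is itself approximate
(Bethe); the expected complete-data log-likelihood is traced for
diagnostics.

**Identifiability.** Without a molecular clock, the division of divergence
between the two branches incident to the root is only weakly identifiable
(the classic root-placement ambiguity); their estimated tables can trade
off against each other and the root model. Branches below a constrained
internal node are pinned by the data: in the recovery experiment (200 kb,
3 leaves, 15 EM iterations from a context-free initialization),
well-supported elevated entries on such branches come back within 10%
relative error, and the rate-recovery test asserts exactly that. Analyses
of root-adjacent lineages should treat absolute rates with caution — the
reverse-complement-averaged, context-relative structure is robust.

Parsimony validation uses exhaustive enumeration of internal labelings per
column (feasible because unique column patterns are few), keeping only
columns whose minimal-substitution placement is unique; ambiguous columns
are tallied and excluded rather than fractionally assigned. A column such
as (A, A, G) on a three-leaf tree is genuinely ambiguous — the change can
sit on the terminal branch or on the other root edge — and is excluded;
with outgroup support the placement resolves.

## The coupling statistic

From the focal branch's (parent, child) pair posteriors, each position j
gets an expected A/T gain g(j) (ancestral C/G, descendant A/T) and loss
l(j) (the reverse); conserved and within-class changes contribute zero.
The *net A/T divergence* D(j) sums g − l over the `horizon` positions
strictly preceding j (default 5 bp; 1, 3 and 10 as robustness variants).
Labels: D > 0.9 is a gaining context, D < −0.9 a losing context, and a
*conserved* window (total event mass below 1 − 0.9) is background. Windows
that are mixed, or truncated at the sequence start, fall in none of the
strata. Because a position's own event mass is never in its own window,
and each position belongs to at most one stratum, every unit of posterior
substitution mass is counted exactly once (a test verifies the accounting
identity).

Conditional rates divide the summed event mass in a stratum by the
posterior-weighted count of opportunity sites (ancestral C/G for gains,
A/T for losses), optionally within occupancy bins (5 by default).
Compensation appears as rate(gain | losing context) > rate(gain | gaining
context), and the reciprocal for losses.

The significance test must reject spatial *compensation* specifically, not
mere clustering of substitutions. The null therefore keeps the context
labels and all totals fixed and only re-assigns events to contexts: the
total gains are drawn without replacement from the pooled C/G opportunity
sites of the gaining and losing contexts (a hypergeometric draw), losses
likewise from the pooled A/T sites, and the statistic is the number of
compensatory events (gains in losing contexts plus losses in gaining
contexts). 100,000 resamples by default; expected counts are rounded to
integers for resampling; the p-value is the add-one fraction of resamples
reaching the observed statistic, so p is never below 1/(B+1). On small
instances the Monte-Carlo p agrees with exact convolution of the two
hypergeometrics, and on null-generated counts the p-values are uniform —
both are tested.

## The evolutionary model

A population of N identical-length binary genomes (A/G, length L = 20)
evolves by fitness-proportional resampling and per-site mutation. The
faster mutation direction is G/C→A/T (7e-7 per site per generation, vs
3e-7 for A/T→G/C), giving a neutral stationary G+C content of
3/(3+7) = 30%; the population-scaled rate θ = 2N·max(μ) = 0.014 keeps the
process drift-dominated (below the 0.04 bound). Substitutions are counted
against a reference genome updated whenever a site's major allele exceeds
frequency 0.95 and differs from it; exposure and fixation counters start
after a burn-in of 4 coalescent times (4N generations). Rates are reported
per site-generation of the population-average genome, so at neutrality
they equal the mutation rates exactly. The starting population carries the
neutral composition (6 G in 20) so the counted stretch begins near
stationarity.

Two fitness landscapes are built in, both strictly positive and neutral at
η = 0:

* **goal**: f(n) = exp(−η (n − n_opt)²) — log-quadratic, symmetric about
  the optimum; a truncated parabola 1 − η(n−n_opt)² would go non-positive,
  which both the sampler and the fixation probability forbid;
* **threshold**: f(n) = 1 for n ≤ n_opt, exp(−η (n − n_opt)) above — moves
  toward fewer G/C are never deleterious.

The analytic approximation collapses the population to one G/C count n
performing a birth–death walk: λ⁺(n) = N μ_{→GC} (L−n) u(s⁺),
λ⁻(n) = N μ_{→AT} n u(s⁻), with s the marginal fitness change of the move
and u(s) = (1−e^(−2s))/(1−e^(−2Ns)) the haploid diffusion fixation
probability (u(0) = 1/N analytically; overflow-prone regimes use
asymptotic branches, and a rate that underflows to zero is treated as an
absorbing wall with no stationary mass beyond it). The stationary
distribution follows from detailed balance in log space; at η = 0 it is
exactly Binomial(L, 0.3). A brute-force chain over full population
compositions (N = 16, L = 2) confirms the approximation within 5% at
θ = 0.0064.

The model's characteristic predictions, all covered by tests: 30% neutral
content; collapse of both rates and convergence to the 20% optimum under
strong selection (the mirrored high-G+C landscape, optimum 8/20, reaches
40%); and at intermediate intensity an A/T-gain rate *above* neutral — up
to 1.24x in the threshold landscape — the compensatory elevation.
Desk-scale simulations rescale (N/k, μ·k, η·k), preserving θ and N·η and
hence the stationary behavior.

## The synthetic world

The generator supplies what the analyses consume: a root sequence from a
second-order Markov model; branch evolution by K sub-steps per branch with
per-site transition tables conditioned on the current flanks, K chosen so
per-sub-step substitution probabilities stay below 0.01 (an instantaneous
context-dependent rate matrix is ill-defined, so the process is *defined*
by this small-step limit). Sub-step tables are exact matrix K-th roots, so
under context-free rates the realized one-branch transition equals the
specified table — a testable calibration. All sites update simultaneously
within a sub-step; contexts drift between sub-steps.

Occupancy is modeled as an affine, strictly increasing function of
windowed G+C (default 20 bp window) plus Gaussian noise, optionally
calibrated by a monotone affine map so that the −2.5/0.4 thresholds cut
off the bottom 14% and top 21% of positions — the class geometry the
thresholds are meant to produce. This is a stand-in with the right sign
and strength of coupling, not a claim of biophysical fidelity: real tracks
have nucleosome-scale (147 bp) structure, dinucleotide periodicity and
measurement artifacts the generator does not emulate, so passing tests
establish correctness of the machinery, not realism of the track model.

Planted compensatory pairs flip a conserved A/T site to C/G and a nearby
(within the horizon) conserved C/G site to A/T on a terminal branch, at
`excess` pairs per kb. The positive-control tests plant 5 pairs/kb over a
5% background divergence — set by a power calculation: the planted signal
must dominate Poisson noise even when detection uses 1 bp windows, where
only ~1/10 of the planted pairs are adjacent.

SNP panels draw minor-allele counts from the folded frequency spectrum
tilted by a scaled selection coefficient S = 2Ns: density proportional to
(1 − e^(−S(1−x))) / ((1 − e^(−S)) x (1−x)), which tends to the neutral 1/x
as S → 0; negative S shifts mass toward rare alleles. Allele pairs, flanks
and occupancy classes are assigned consistently with the intended class,
so classification and rare-fraction machinery can be validated against
known truth. The spectrum is the standard equilibrium diffusion form — no
demography, linkage or ascertainment, which is exactly what the type-I
control tests rely on.

## Conventions and numerical choices

* Coordinates are 1-based closed intervals in R (the Bioconductor
  convention); BED/bedGraph files are written 0-based half-open.
* Occupancy thresholds compare strictly; boundary scores fall in "mid".
  TSS proximity is inclusive (≤ 200 bp), strand-agnostic. Quantile-bin
  ties break by genomic coordinate, making bins reproducible.
* `gc_windows` uses non-overlapping windows (a 20 bp window spectrum is
  then comparable to a Binomial(20, p) reference); a trailing partial
  window is dropped.
* Reverse-complement averaging maps P(child | parent, a, b) onto
  P(rc(child) | rc(parent), rc(b), rc(a)); it is idempotent and exactly
  symmetrizes the table.
* SNP ties (exact 50/50 counts) have no major allele and are excluded but
  tallied; frequencies use per-site called-strain counts, not a fixed
  denominator, since call counts vary. The 2x2 chi-squared uses no
  continuity correction (counts are large; the small-expected-cell case is
  flagged on the result instead).
* Problem sizes in the test suite — 200 kb for rate recovery, 100 kb for
  coupling controls, 30 kb for the stationarity check, rescale factors
  10–100 and 1e5–6e5 generations for the forward runs — were chosen so
  every stochastic assertion has at least ~3 standard errors of headroom
  under its stated tolerance.

## Limitations

Indels and alignment uncertainty are out of scope (the generator is
gapless; real alignments enter through column masking). The factor-graph
posterior is an approximation away from the context-free case, and EM
inherits its fixed points; rates on root-adjacent branches are weakly
identifiable, as discussed. The coupling analysis is single-lineage and
strand-agnostic with "preceding" meaning lower coordinates. The
Wright–Fisher model is haploid, unlinked and panmictic with a rigid
fitness-of-count landscape; it is a mechanism demonstration, not a fitted
model of any particular genome.
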