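---
title: "Estimating Y-STR mutation and male differentiation rates from two-man pedigrees"
author: "ystrpedigree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Y-STR mutation and male differentiation rates from two-man pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrpedigree)
```

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are inherited patrilineally
without recombination; the only source of difference between two men on the
same paternal line is mutation. In historical-remains and missing-persons
casework, the reference sample is often a distant paternal relative — a
first cousin (4 meioses) up to a seventh cousin (16 meioses) — and the
analyst must judge whether a handful of allelic mismatches is compatible
with true relatedness. Two quantities drive that judgement:

* the **per-locus mutation rate** $\mu_\ell$, estimated as
  $\hat\mu_\ell = x_\ell / N$ where $x_\ell$ is the number of mutations
  inferred at marker $\ell$ over all pairs and $N$ the total number of
  meioses, and
* the **male relative differentiation rate**: the proportion of related
  pairs at a given meiotic separation that show at least one allelic
  difference across the panel.

`ystrpedigree` implements this estimation workflow for two-man pedigrees —
exactly two typed males per family, so pairwise and actual meioses coincide
and no transmission is double-counted — together with a stepwise-mutation
pedigree simulator used to validate every stage.

## Parsimony mutation counting

Between non-adjacent relatives the meiosis in which a mutation occurred is
unobservable, so events are *inferred* under a minimum-mutation (parsimony)
rule. The counting model makes three assumptions:

1. identical haplotypes imply zero mutations along the unobserved links
   (back and parallel mutations are knowingly uncounted);
2. a multi-step difference at a single-copy marker is decomposed into that
   many single-step mutations distributed along the connecting lineage
   (alleles 10 vs 12 count as two single-step events);
3. among all explanations of an observed difference, the one requiring the
   fewest mutational events is chosen.

Concretely, for two alleles of the same microvariant class the cost is the
absolute repeat difference, emitted as that many `single_step` events. The
remaining rules cover the observation types that integer steps cannot
explain:

* **Microvariant mismatch** (e.g. 16 vs 16.2): one irreducible `complex`
  event. Partial-repeat changes arise by indels inside a repeat unit, not by
  the stepwise polymerase-slippage process, so decomposing them into repeat
  steps has no biological meaning; a single event is also the
  parsimony-minimal choice.
* **Null versus called allele**: one `deletion` event (a locus deletion or a
  primer-binding-site mutation; the package does not attempt to
  distinguish the two). Two nulls are a shared inherited state: zero events.
* **Multi-copy markers** (DYS385, DYF387S1 report two copies): equal-size
  multisets are matched by the minimum-total-cost bijection (all $\le 4!$
  bijections are scored; ties are broken deterministically by the order of
  the canonically sorted alleles). A copy-number difference contributes one
  `duplication`/`deletion` event per gained or lost copy — never more,
  regardless of the gained allele's size — with the changed copy chosen to
  minimise the residual step cost and ties broken toward the smaller
  allele. The event is labelled a duplication when the larger multiset
  exceeds the marker's expected copy number, a deletion otherwise.
* **Homoallelic ambiguity**: a single peak at a two-copy marker may be a
  one-copy state or two same-length copies. Both readings are scored and
  the cheaper wins; on a tie the homoallelic reading (no copy-number
  event) is preferred, because single-peak electropherograms cannot
  positively evidence a deletion.

Identical multisets — including a duplication seen in *both* men — count
zero events: the variant is inherited, not a mutation in the observed pair.
Each emitted event row counts as exactly one mutation; a decomposed
$k$-step difference therefore contributes $k$ to $x_\ell$, and the
event-type totals (`single_step` + `duplication` + `deletion` + `complex`)
always sum to the mutation total.

Pairs whose haplotypes need more than 15 mutations to reconcile are
excluded from estimation (`filterPairs()`): at study-scale rates such
divergence is far likelier to reflect mis-recorded genealogy or
non-paternity than mutation. The threshold keeps a pair at exactly 15.

The multi-copy matcher is verified against an independent brute-force
oracle that enumerates every copy-assignment scenario for multisets of up
to three copies, and the whole counter is checked for symmetry
($d(h_1,h_2) = d(h_2,h_1)$), identity, and the lower-bound property that
parsimony never overcounts net drift on simulated walks.

## Rate estimation and intervals

`estimateRates()` sums events and meioses over kept pairs and reports
$\hat\mu_\ell = x_\ell/N$ with a binomial confidence interval:

* **Clopper–Pearson** (default, the interval used throughout reporting):
  exact beta-quantile bounds, lower $= B_{\alpha/2}(x,\, N-x+1)$ and upper
  $= B_{1-\alpha/2}(x+1,\, N-x)$, with the conventional endpoint
  conventions at $x=0$ and $x=N$;
* **Wilson** score interval as the narrower, approximate alternative.

$\alpha$ defaults to 0.05. Rates and bounds are reported both at full
precision and rounded half-up to three decimals (`roundHalfUp()`), the
precision used in published rate tables; percentages are rounded half-up
to one decimal. Half-up rounding is deliberate — banker's rounding would
turn 0.0025 into 0.002.

Cross-study comparison uses the two-sided Fisher exact test on
$[[x_1, N_1-x_1], [x_2, N_2-x_2]]$ with the standard "sum of
hypergeometric probabilities not exceeding the observed table's"
convention (other two-sided conventions exist; this is the one implemented,
and it matches `stats::fisher.test`). Reference studies often publish only
rates: `reconstructCounts()` recovers $x_2 = \mathrm{round}(\text{rate}
\times N_2)$ and warns that p-values computed from reconstructed counts are
approximate, since the printed rate is itself rounded. The implementation
is validated against a full binomial-coefficient enumeration for every
2×2 table with total count up to 60.

## Differentiation rates

A pair is *differentiated* when at least one marker carries at least one
inferred event of any kind — copy-number and complex events count, since
they are allelic differences an analyst would see. `differentiationRate()`
reports the overall rate, one stratum per meioses value, and any requested
inclusive ranges (4–13 is a common comparison window), each with a
Clopper–Pearson interval. `discordanceDistribution()` gives the histogram
of per-pair mutation counts (including the zero bin, so it sums to the
number of pairs) and per-marker pair counts. `uniqueHaplotypeCount()`
counts distinct full-panel haplotypes under per-locus multiset equality,
the basis of a haplotype discrimination capacity figure.

## The simulator: what it emulates and what it does not

`simulatePairs()` generates study-like data with known truth. For each
pedigree a founder haplotype is drawn uniformly from per-marker founder
ranges (bundled typical Yfiler Plus allele ranges); the pair's $m$ meioses
are split into two branches descending from the founder with
$m_1 \sim \mathrm{Uniform}\{1, \dots, m-1\}$ — pedigree shape does not
affect pairwise counting, so any split is equivalent; uniformity simply
varies the shape. Along each branch every marker mutates independently per
meiosis with probability $\mu_\ell$; a mutation moves a uniformly chosen
copy by ±1 repeat with equal probability. Gain/loss symmetry is the
default because direction is unmodelled in pairwise counting; a
`pMultistep`/`stepGeomP` knob adds geometric multi-step events when
desired (default off). Multi-copy markers additionally undergo copy-number
events with per-meiosis probability `pDupDel` (gain = copy an existing
allele shifted −1/0/+1, capped at four copies; loss = remove a uniform
copy, floored at one). Alleles reflect at one repeat, and every event is
written to a truth log.

`studyLikeConfig()` fixes the study conditions: 183 pairs; per-marker
$\mu_\ell$ equal to the study's estimates ($x_\ell/1576$ at full
precision); meioses $\sim 4 + \mathrm{Binomial}(12,\, 0.3843)$, a smooth
unimodal distribution on 4–16 whose mean $1576/183 = 8.612$ makes the
expected meioses total 1576 (the empirical per-meioses pair counts were
never published, so only support and mean are matched and tests avoid
assuming exact stratum counts); and `pDupDel` $= 2/1576$ at each of the two
multi-copy markers, giving four expected copy-number events per run, the
order observed in study-scale data.

What the simulator does **not** emulate: microvariant founders and
microvariant-creating mutations (microvariants appear in real data as
inherited states; the counter handles them, the generator does not create
them), allele-length-dependent or direction-biased mutation rates,
population structure among founders, genotyping error, and
partial/degraded profiles. Passing simulation tests therefore validates
the estimation machinery under the stepwise model, not the full error
structure of casework data.

Two validation properties tie the simulator to the estimator. First, with
multi-step and copy-number events disabled, the parsimony count at any
locus can never exceed the simulated event count (net drift is a lower
bound on events). Second, across 50 replicates of the study-scale
configuration, per-marker mean estimates recover the true per-locus event
rate ($\mu_\ell$, plus `pDupDel` at the multi-copy markers, whose
copy-number events the counter rightly counts as mutations) within three
Monte-Carlo standard errors, and Clopper–Pearson intervals cover truth at
nominal level for markers with $\mu_\ell \ge 0.003$. Parsimony biases
estimates slightly downward (a back-mutation cancels an earlier event with
probability ½ once two events hit the same lineage and locus); at
study-scale rates and $m \le 16$ the expected loss is below
$\binom{m}{2}\mu^2 \approx 0.006$ events per pair at the fastest marker,
well inside the Monte-Carlo tolerance, which is why the bias is tolerated
rather than corrected.

## Numerical and design choices

* Alleles are stored as numeric repeat counts but all step arithmetic and
  microvariant-class comparisons run on integer deci-repeats
  (`round(10a)`), so 15 and 15.0 are the same allele and floating-point
  representation cannot perturb a count.
* The two-copy markers are treated as unordered multisets throughout;
  electrophoresis does not reveal which physical copy is which.
* Fisher p-values use a $1 + 10^{-7}$ relative guard when comparing table
  probabilities, the standard defence against ties broken by rounding
  error.
* Simulation scale in the test-suite: 50 replicates of 183 pairs for rate
  recovery, 1000–2000 pairs for distribution-level checks, 300–400 pairs
  per point for monotonicity — sizes at which Monte-Carlo standard errors
  are a few percent, matched to the three-standard-error test margins.
* Empty strata are reported as `n_pairs = 0` rows with `NA` rates and an
  `empty` flag rather than dropped, so stratified tables keep a stable
  shape.
* `runPipeline()` output is deterministic given its inputs: re-running on
  the same data writes byte-identical TSV/JSON.

## Known limitations

* Parsimony undercounts in expectation (back/parallel mutations); the bias
  grows with $m\mu$ and the package neither corrects nor hides it — the
  simulator quantifies it.
* Null alleles are counted as deletions; a primer-binding-site mutation
  masquerading as a null is indistinguishable without alternate primers.
* Reference-study comparisons from published rates (rather than raw
  counts) are approximate by construction and flagged as such.
* The likelihood-ratio evaluation of competing pedigree hypotheses is out
  of scope; the rates produced here are inputs to such frameworks, not a
  replacement for them.
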