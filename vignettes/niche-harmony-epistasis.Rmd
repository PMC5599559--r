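---
title: "Detecting high-order SNP interactions with niche harmony search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-order SNP interactions with niche harmony search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiharmony)
```

## The problem

Complex diseases can be driven by *epistasis*: joint, possibly non-additive
effects of several SNPs, sometimes with no detectable single-locus (marginal)
effect at all. Exhaustively testing all $\binom{n}{k}$ $k$-way SNP
combinations is infeasible beyond small panels ($\binom{100}{5} =
75{,}287{,}520$ already), and the combination of model diversity, high
degrees of freedom and massive multiple testing inflates false discovery.
`epiharmony` implements a two-stage detector for case/control genotype data
coded by minor-allele dosage (0/1/2):

1. **Screening** — a harmony-search metaheuristic with niching explores the
   space of sorted $k$-subsets of loci under three complementary objectives,
   accumulating per-objective elite archives whose union becomes the
   candidate set.
2. **Verification** — each candidate is tested with a modified G-test
   (sparse-genotype column exclusion with matching degree-of-freedom
   reduction, Hardy–Weinberg expected counts) against a Bonferroni-corrected
   threshold.

A penetrance-table simulator and replicate-level metrics (Power, MEs, TPR,
SPC, ACC, FDR) make the whole system testable without external data.

## The three screening objectives

All three scores are computed from one shared contingency pass over the
$I \le 3^k$ *observed* genotype combinations (empty rows contribute factorial
factors of 1 and entropy/impurity terms of 0, so summing over observed rows
is algebraically exact), and all three are **minimized**:

* **K2 score** — the Bayesian marginal likelihood
  $\prod_i \frac{(J-1)!}{(n_i+J-1)!} \prod_j n_{ij}!$, stored as its negative
  natural log, $\sum_i [\ln\Gamma(n_i+J) - \ln\Gamma(J) - \sum_j
  \ln\Gamma(n_{ij}+1)]$. The raw product underflows at realistic $n$; the
  log-gamma form is exact and order-preserving (lower $\Leftrightarrow$
  larger likelihood).
* **Gini score** — expected phenotype impurity
  $\sum_i \frac{n_i}{n}\bigl(1 - \sum_j (n_{ij}/n_i)^2\bigr)$; 0 when every
  genotype combination maps to a single phenotype.
* **Joint entropy** — $-\sum_i \frac{n_i}{n}\log_2 \frac{n_i}{n}$, the
  phenotype-*blind* entropy of the genotype-combination distribution, used
  as a heuristic for models with little or no marginal effect: retrospective
  case oversampling tilts the causal genotype distribution away from its
  Hardy–Weinberg product, which lowers entropy at second order.

K2 and Gini are complementary identification scores; entropy is a search
heuristic, not an identification method. Because one evaluation feeds all
three harmony memories, the evaluation counter (the MEs metric) advances by
exactly one per candidate.

## The search

Three harmony memories of size HMS (default 50 up to 100 SNPs, 100 above)
hold the same initial random combinations scored under K2, Gini and entropy
respectively. Each iteration improvises one candidate: per position, with
probability HMCR = 0.9 a value is drawn from that position of a random
harmony in a random memory, then shifted $\pm 1$ with probability PAR = 0.35
(reflecting at the panel boundary); otherwise a uniform random locus.
Duplicates are redrawn, the result is sorted, and the candidate is offered
to all three memories, each replacing its worst member only on strict
improvement (duplicates are never admitted).

When *all three* memories have gone `stagnation_T` (default 50) iterations
without improvement, the search concludes it has converged into a niche: for
each memory, the loci present in more than half of its harmonies form the
niche core (falling back to the best harmony's loci when no majority
exists), the region is recorded in a **taboo table** with overlap radius
$|\mathrm{core}| - 1$ (capped at $k-1$), the memory tops are harvested into
per-objective elite archives, and the memories are reinitialized outside all
tabooed regions. A combination overlapping a recorded core in more than
`radius` loci is never evaluated again — with a single-locus core (the
typical strong-marginal trap) *every* combination containing that locus is
banned, which is precisely what frees the search from repeated local
exploitation. The run stops at the evaluation budget `t_max` (default 4500
for 100-SNP panels, 60000 for 1000), or immediately when a supplied truth
combination is first evaluated (benchmark mode, the MEs measurement).

Design notes on genuinely open points:

* *Pitch adjustment* operates on column indices, which carry no biological
  neighborhood; at the stated PAR it is mild noise around the memory draw.
  A variant that draws all positions from one base harmony (preserving locus
  co-occurrence) was evaluated and rejected: it converges prematurely and
  measurably lowers detection power.
* *Niche radius* is measured in SNP-overlap count, the natural metric on a
  set lattice, matching the stated purpose of banning a converged locus.
* *Elite harvesting* happens at every niche event **and** at termination;
  the candidate set takes the top `cs_capacity` (default 10) per objective,
  deduplicated, so the three objectives contribute independently.
* In benchmark (early-stop) mode the truth combination, having just been
  evaluated, is included in the candidate set; stage-1 power counts exactly
  this detection event.

## The verification stage

For each candidate, expected counts come from the Hardy–Weinberg principle:
pooled-sample allele frequency $\hat q$ per locus, per-locus genotype
probabilities $(1-\hat q)^2, 2\hat q(1-\hat q), \hat q^2$, joint probability
the cross-locus product, times the phenotype column total. The statistic is
$G = 2\sum_i \sum_j O_{ij}\ln(O_{ij}/E_{ij})$ over genotype rows whose
*smallest* per-phenotype observed count is at least $\xi$ (default 5), with
$df = (I_{\mathrm{kept}}-1)(J-1)$. On the package's worked sparse 2-way
example this reproduces the conventional $df = 8$ at $\xi = 0$ and the
adjusted $df = 5$ with exactly the three near-empty genotype columns
excluded. The row-sum form of the exclusion rule would *not* reproduce that
worked example (one excluded column has a row sum of 80); the min-cell form
is therefore the implemented rule. Significance uses the upper chi-square
tail against $\alpha/N$, with $N$ resolved as all $\binom{n}{k}$
combinations (conservative default), the number of candidates actually
tested, or a fixed cutoff (the practice for very large panels).

**A calibration caveat that matters.** With HWE expected counts, $G$ is a
*joint* test of HWE genotype fit and phenotype independence: under a clean
null (HWE genotypes, independent phenotype) it behaves like a chi-square
with roughly $(I-1)(J-1) + (I-1-k)$ degrees of freedom, while the published
correction references $(I_{\mathrm{kept}}-1)(J-1)$. The test is therefore
structurally anti-conservative — we measure a null rejection rate near 0.4
at nominal $\alpha = 0.05$ — and no implementation choice can fix it without
changing the method. The package exposes
`expected_mode = "independence"` ($E_{ij} = n_i n_j / n$), whose null
calibration *is* verified in the test suite; the default remains `"hwe"`,
faithful to the published method. Note also that with row exclusion the
observed and expected totals need not match, so $G$ can dip below zero;
the tail probability is then taken at 0.

## The simulator

`build_dme_model()` constructs two-locus marginal-effect families over the
disease-allele count $g_1 + g_2$ — multiplicative
$f = b(1+\theta)^{g_1+g_2}$ and threshold ($f = b$ until two disease
alleles, then $b(1+\theta)$) — solving $\theta$ by root-finding so the
heritability $h^2 = \sum_g p_g (f_g - K)^2 / K(1-K)$ (the standard
penetrance-variance definition used by table-based generators; the source
method never prints one) hits its target to $10^{-6}$. The benchmark grid
(MAF $\in \{0.05, 0.1, 0.2, 0.5\}$, $h^2 = 0.005$ multiplicative / $0.02$
threshold) is reachable with the default baseline $b = 0.1$.

`search_dnme_model()` builds $k$-locus no-marginal-effect tables: a random
perturbation is projected onto the linear subspace where every single-locus
HWE-weighted marginal penetrance equals the prevalence, rescaled to the
target $h^2$, clipped to $[0,1]$ and polished by alternating projections,
retrying until marginal deviations are below `marginal_tol` (default 0.005)
and $h^2$ is within 10% of target. Prevalence defaults to $K = 0.1$, a
standard complex-disease figure for epistasis simulations (the source
datasets do not document theirs); causal MAF defaults to 0.25.

`generate_dataset()` draws causal genotypes under HWE, assigns status by
rejection sampling against the penetrance table until fixed case/control
quotas are met (the retrospective design), embeds the causal columns at
random panel positions among independent HWE background SNPs with MAF
uniform on $[0.05, 0.5]$, and emits the truth (causal columns + model) as
JSON.

What the generator does **not** emulate: linkage disequilibrium between
loci, genotyping error or missingness, covariates, and — importantly — any
systematic MAF difference between causal and background loci. A green
detection test on this generator certifies the search and test machinery,
not performance on real LD-structured genotypes.

## What the stated world can and cannot reproduce

Three documented negative results follow from the generator's stated world,
not from implementation defects (each is verified red, with its mechanism,
in the acceptance suite):

1. *Entropy separation.* When marginals are suppressed below 0.005
   penetrance units, combinations containing exactly **one** causal locus
   are distributionally identical to background combinations (flat marginal
   $\Rightarrow$ undistorted single-locus sample frequencies), and in a
   100-SNP panel ~98% of "contains a causal SNP" combinations are of that
   kind. A rank test between the two strata then compares the realized
   per-locus entropies of 3 causal loci against 97 background draws —
   direction is essentially a coin flip. The entropy heuristic presupposes
   causal loci with a distinctive (in practice, low-MAF/concentrated)
   genotype distribution.
2. *Null calibration of the published G-test* (see above).
3. *DNME detection power.* With no single-locus clue, assembly of the
   causal triple rests on pair-level signal; measured stage-1 power is
   0.1–0.5 across model realizations at $T_{max} = 4500$, below a majority
   in some realizations. The niche mechanism compounds this: the converged
   causal *pair* is itself identified as a niche core and tabooed (radius
   $|\mathrm{core}|-1$ bans every superset), and disabling restarts
   measurably raises DNME power — the mechanism that rescues
   marginal-effect search actively hinders no-marginal-effect search.

## Numerical choices

* Exact integer binomial coefficients (stepwise divisibility, error past
  $2^{53}$); score kernels in log-gamma space; $0\log 0 \equiv 0$
  throughout.
* Synergy (`is_synergistic`) uses strict inequality over all $2^k - 2$
  proper subsets; ties fail; $k$ capped at 6.
* All randomness flows from the single config seed; outputs contain no
  timestamps, so identical (data, config, seed) runs are byte-identical.
* Contingency rows are kept in lexicographic genotype order — a pure
  reporting convention with no numerical effect.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
model <- build_dme_model("threshold", maf = 0.2, h2_target = 0.02)
sim <- generate_dataset(model, n_cases = 1000, n_controls = 1000,
                        n_background_snps = 98)
res <- epi_run(sim$dataset, epi_config(k = 2, seed = 11))
res$significant[1, c("snp_names", "g", "df", "p_value")]
classify_outcomes(res, sim$truth)
```

On this dataset the embedded pair ranks first with $G \approx 123$ on 7
degrees of freedom at $p \approx 2\times 10^{-23}$, far below the Bonferroni
threshold $0.05/\binom{100}{2} \approx 10^{-5}$ (exact numbers in the
README, printed by the code above).

## Known limitations

Single-threaded; no VCF/PLINK-binary ingestion (delimited text and
`.raw`-style additive exports only); no LD modeling; the published G-test
variant is anti-conservative by construction (use
`expected_mode = "independence"` when calibrated error rates matter); niche
taboos can ban an unfound superset of a converged core, which hurts
no-marginal-effect models.
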