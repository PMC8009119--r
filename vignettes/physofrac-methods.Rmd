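---
title: "Methods: analysing FACS-sorted physiological fractions of the gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing FACS-sorted physiological fractions of the gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk 16S rRNA amplicon sequencing of a stool sample describes who is there,
not who is doing anything. Flow cytometry can split a community into
physiologically defined subpopulations before sequencing: cells with high vs
low nucleic acid content (HNA/LNA, a SYBR Green I bimodal split used as a
bulk activity proxy), translationally active cells labelled by BONCAT
(bioorthogonal non-canonical amino acid tagging of nascent proteins, sorted
as BONCAT+ vs BONCAT−), and membrane-damaged cells stained by propidium
iodide (PI+). Sorting each gate and sequencing the sorted pools
("FACS-Seq") links taxonomy to physiology.

`physofrac` implements the statistical machinery of such an experiment —
sorting-depth design, decontamination, phylogenetic beta diversity,
PERMANOVA, beta-binomial differential abundance/dispersion, core-microbiome
partitioning and cytometric fraction-proportion statistics — together with a
synthetic cohort generator so that every stage can be validated end to end
without any external data.

# Sorting-depth design

The number of cells of a taxon at prevalence $p$ captured among $N$ sorted
events is $X \sim \mathrm{Binomial}(N, p)$. `capture_probability(N, p, k)`
returns the tail $P(X \ge k) = 1 - F(k-1; N, p)$, evaluated through the
regularised incomplete beta function, so it is stable at $N$ in the
hundreds of thousands. The "at least $k$" convention is used throughout.
`min_events(p, k, conf)` inverts the tail by doubling-and-bisection on $N$,
which is valid because the tail is nondecreasing in $N$. A purity-adjusted
variant ($p' = p(1-\text{gate error})$) is available and off by default.
At the default design point, sorting 25,000 events captures a 0.5%-prevalence
taxon 125 times in expectation, with $P(X \ge 100) > 0.95$; 180,000 events
give a wide safety margin.

# The synthetic cohort generator

The generator is first-class, tested code. Its defaults *are* the study
conditions it emulates: ten unrelated individuals; 838 ASVs of which 12 are
core (present in all ten), 477 unique to one individual and 32 present in at
least 8/10; gate proportions with means/SDs of 51.73 ± 17.59 % (HNA),
49.01 ± 18.54 % (BONCAT+) and 15.73 ± 14.58 % (PI+) and cross-correlations
$r(\mathrm{HNA},\mathrm{PI{+}}) = 0.74$,
$r(\mathrm{HNA},\mathrm{BONCAT{+}}) = -0.62$; 180,000 sorted events per gate
with 20 % BONCAT+ gate error (80 % purity) and 5.7 % BONCAT− gate error;
30,000 reads per sample; and sheath-fluid contamination of 341–2,333 reads
spread over two Pseudomonas-like ASVs, with one sheath-only negative control
per sort day (one per individual).

## Correlated gate proportions

The triple (HNA, BONCAT+, PI+) is drawn from a Gaussian copula with
truncated-normal marginals on $[0, 100]$. Two calibration steps make the
*realised* moments equal the configured ones, which is the property the
generator exists to provide:

* the marginal location/scale parameters are solved (Nelder–Mead on the
  closed-form truncated-normal moments) so each truncated marginal has
  exactly the target mean and SD. This matters: a normal with mean 15.73 and
  SD 14.58 has about 14 % of its mass below zero, so naive truncation would
  shift the PI+ mean to ~19.4;
* each pairwise latent correlation is root-found so that the realised
  Pearson correlation of the transformed variables equals the target (the
  NORTA construction), evaluated on a fixed-seed common-random-number panel
  so calibration is deterministic and independent of user seeds.

A box-rejection scheme (redraw the triple until all coordinates are in
range) was considered and rejected: the rejection event is correlated with
every coordinate, which biases the HNA mean upward by about 3 percentage
points and attenuates $r(\mathrm{HNA},\mathrm{PI{+}})$ to ~0.65, and no
setting of latent parameters restores all nine moments simultaneously.
The third correlation, $r(\mathrm{BONCAT{+}},\mathrm{PI{+}})$, is not among
the emulated statistics; it is completed as the product
$0.74 \times (-0.62) = -0.4588$, the conditional-independence completion,
which keeps the matrix positive semi-definite. LNA is deterministic,
$100 - \mathrm{HNA}$, mirroring the complementary SYBR gates.

## Abundances and the core/unique/shared structure

Presence is assigned so the prevalence structure is *exact*: 12 taxa in
10/10 individuals, 477 in exactly one, 32 in ≥ 8/10, the remainder in 2–7.
Nonzero abundances are log-normal. Two deliberate design choices shape them:

* **Occupancy–abundance with conservation.** Core and relaxed-core taxa
  receive a higher taxon-level log-mean (+2 and +1) that is shared across
  individuals, with only modest individual scatter (sdlog 0.3 and 0.5),
  while transient (shared/unique) taxa vary with the full configured sdlog
  (default 2). Prevalent gut taxa being both abundant and conserved is the
  well-documented occupancy–abundance relation, and it is what makes the
  HNA fraction — which up-weights core taxa — more similar across
  individuals than the whole community.
* **A presence floor.** After row normalisation, present taxa are floored at
  a relative abundance of 5e-4 (or half the reciprocal of the richest
  individual's richness, if smaller) and rows renormalised. At the default
  30,000-read depth the probability that a present taxon receives zero reads
  is then < 1e-6, so the configured partition counts survive multinomial
  sequencing exactly rather than only in expectation.

## Propensities, calibration, sorting and sequencing

Each taxon has a per-gate membership probability
$\theta_{tf} = \mathrm{logistic}(\mathrm{logit}(\text{base}_f) +
\text{phylum offset} + \text{core/unique offset} + \text{noise})$, shared
across individuals. Defaults skew Firmicutes into HNA and PI+ and
Actinobacteria out (reproducing the phylum-level contrast between the HNA
and whole communities, ~81 % vs ~61 % Firmicutes), push core taxa into HNA
(+2.5 logits) and unique taxa out (−2.5 logits). These per-taxon propensities
are not reported quantities anywhere; the defaults were chosen once to
reproduce the phylum-level and core-enrichment contrasts approximately, not
exactly.

Because aggregate membership $\sum_t a_t \theta_{tf}$ need not equal an
individual's drawn gate proportion $\pi_{if}$, a single additive logit
offset $\delta_{if}$ is calibrated per individual and gate by bisection
(`calibrate_propensities()`); the aggregate is strictly monotone in
$\delta$, so the root is unique and solved to 1e-10. LNA and BONCAT− use
complement propensities $1 - \theta$.

Sorting draws, per gate, a binomial number of truly in-gate events at
$1 - \text{gate error}$, then multinomial taxon tallies from the in-gate
distribution $a_t\theta_{tf}$ and the complement distribution for leaked
events; the latent true/leaked split is recorded so re-acquired purity can
be measured. Sequencing is multinomial at fixed depth; sorted samples
additionally receive a uniform draw from the sheath-read range spread over
the contaminant ASVs, which never occur in Whole samples. 16S copy-number
variation and PCR bias are not modelled: reads are proportional to cell
tallies. BONCAT and SYBR gates are treated as independent measurements of
one latent population, since the experimental linkage is not characterised.

Treatment incubations (glucose, digoxin, nizatidine vs control) redraw gate
proportions from per-treatment truncated normals with the reported treated
means and replicate SDs — stored as absolute target means, the form in which
such results are reported — re-calibrate $\delta$, and re-run sorting and
sequencing per replicate.

# Preprocessing

Filters are applied in a fixed order, each returning a report that
reconciles read totals exactly:

1. **Sheath decontamination** — any ASV with reads in a sheath control but
   zero reads in *every* Whole sample (pooled across individuals) is
   removed everywhere; sheath controls are then dropped. On generator
   output this recovers the injected contaminants with precision and
   recall 1 by construction.
2. **Unassigned phylum** — ASVs with empty/NA phylum are removed.
3. **Prevalence** — keep an ASV iff it has ≥ 6 reads in each of ≥ 2 samples.
   The per-sample reading of the threshold (rather than a summed total) is
   a documented interpretation, matching the common phyloseq filtering
   idiom.
4. **Named taxa** — an explicit drop list, for contaminants identified by
   inspection.

The variance-stabilising transform is the median-of-ratios size factor
(the DESeq2 estimator: $s_j = \mathrm{median}_i\, c_{ij}/\mathrm{geomean}_i$
over ASVs with nonzero geometric mean) followed by $\log_2(c_{ij}/s_j + 1)$.
This replaces a regularised-log (rlog) shrinkage transform: the transform is
used here only as a variance stabiliser ahead of ordination-adjacent
reporting, for which the shrinkage component is inessential, and the
median-of-ratios form is transparent and exactly testable. When no ASV is
present in all samples the size factors fall back to relative library sizes
with a warning.

Rarefaction (without replacement, via `vegan::rrarefy`) applies only to
alpha diversity, at a default depth of 10,534 reads; beta diversity uses
relative abundances of the filtered counts.

# Diversity and ordination

Weighted UniFrac is computed from per-branch descendant masses accumulated
in one postorder pass: $d(A,B) = \sum_i l_i\,|p_{Ai} - p_{Bi}|$, with an
optional normalised variant dividing by $\sum_i l_i (p_{Ai} + p_{Bi})$. The
raw variant is the default since the dialect of the original computation is
not pinned down. UniFrac consumes relative abundances of filtered counts,
not VST values: branch masses must be non-negative proportions, and how
log-scale values would enter a UniFrac computation is undefined. This is a
documented interpretation. Unweighted UniFrac is the unshared fraction of
branch length over presence sets, and Bray–Curtis the usual
$\sum|a-b|/\sum(a+b)$ on proportions.

PCoA Gower-centres $-D^2/2$ and eigendecomposes; coordinates are
eigenvectors scaled by $\sqrt{\lambda}$, negative eigenvalues are reported
but excluded, and no Cailliez/Lingoes correction is applied by default.
Shannon diversity uses natural logarithms.

# Inference

**PERMANOVA.** The McArdle–Anderson decomposition on the Gower-centred
matrix, with pseudo-$F = (SS_b/df_b)/(SS_w/df_w)$ and $p$ from free
permutation of sample labels (no strata), using the $(1+b)/(1+m)$ estimator
so Monte-Carlo $p$ is never zero; exact enumeration (for up to 9 samples)
uses the plain fraction, since the identity permutation is included. The
nested fit codes the inner factor as outer×inner cell dummies after the
outer main effect, with sequential (Type I) sums of squares.

The xenobiotic effect-size table reports one *separate* model per row —
physiology alone, treatment alone, and the physiology×treatment cell-means
model for the nested row. The magnitudes this design reports (e.g.
physiology ~0.65 and nested ~0.75 on the same distances) can only arise
from separate models, since sequential terms of one model would be bounded
by $R^2 \le 1$ in total; the cell-means model also always explains at least
as much as physiology alone, which is why the nested row carries the
largest effect size.

**Beta-binomial tests.** For a taxon with counts $y$ out of library sizes
$n$, the beta-binomial with mean $\mu$ and overdispersion $\phi$ (shapes
$\alpha = \mu(1-\phi)/\phi$, $\beta = (1-\mu)(1-\phi)/\phi$) is fitted by
maximum likelihood on logit scales (L-BFGS-B, three restarts, convergence
1e-8 on the log-likelihood). Differential *abundance* is the likelihood
ratio of group-specific vs shared $\mu$ at shared $\phi$; differential
*dispersion* is group-specific vs shared $\phi$ at group-specific $\mu$;
both are $\chi^2_{G-1}$. Likelihood-ratio tests replace a Wald machinery:
they are asymptotically equivalent, simpler, and their null calibration is
verified by simulation (type-I error within [0.03, 0.07] at nominal 0.05
over 1,000 null taxa with 20 samples/group, 50 trials, $\phi = 0.1$).
All-zero or non-converging taxa are flagged, not silently dropped.
Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied across
taxa, pairs or treatments as appropriate.

**Rank tests.** Kruskal–Wallis delegates to `stats::kruskal.test`;
Dunn's post hoc $z$ uses the tie-corrected variance
$\left(\frac{N(N+1)}{12} - \frac{\sum(t^3-t)}{12(N-1)}\right)
\left(\frac{1}{n_i}+\frac{1}{n_j}\right)$ with two-sided normal $p$ and BH
adjustment across pairs. Treatment proportions are compared against control
with classical one-way ANOVA plus per-treatment Welch $t$ tests (unequal
variances suit $n = 3$ replicates with heterogeneous SDs), BH-adjusted.

**Core partitioning.** Presence is called from each individual's Whole
sample after filtering (pooling across all of an individual's samples is
available by flag; Whole-only is the default because the partition is a
statement about the unsorted community). Core = present in ≥ threshold
individuals, unique = exactly one, shared = remainder; thresholds below 2
are rejected as they would merge core and unique semantics. Percentages are
printed to one decimal with round-half-even: 349/838 prints as 41.6 even
where 41.5 may appear elsewhere from a different rounding rule — the
computed value is reported, with this note.

# Problem sizes and determinism

Every stochastic routine takes a seed and is reproducible bit-for-bit;
composed stages derive child seeds (kept within 32-bit range) so components
do not perturb each other. The test suite exercises full-size default
cohorts (10 individuals × 838 ASVs, 180,000 events) for the qualitative
structure checks across 10 seeds, and reduced cohorts (60 ASVs, 20,000
events, 4,000 reads) elsewhere; moment-recovery checks use 2,000–10,000
simulated individuals, and the beta-binomial calibration uses 1,000 null
taxa. These sizes were chosen to keep each check's Monte-Carlo error well
inside its assertion band.

# What passing tests do and do not show

The generator emulates the *statistical* structure of a sorted-fraction
study: moments and correlations of gate proportions, exact prevalence
structure, gate-error leakage, contaminant placement, treatment shifts. It
does not emulate fluorescence intensity distributions, chimeras or
sequencing error, PCR or copy-number bias, compositional coupling between
gates beyond the copula, or phylogenetic signal in propensities beyond the
phylum offsets. Pipeline results on real data therefore inherit the usual
caveats of 16S analyses; what the passing suite establishes is that the
implemented statistics compute what they claim (verified against
independent oracles) and that the end-to-end pipeline recovers known truth
under the emulated design.
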