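---
title: "Methods: moderated differential expression, cis pairing and differential coexpression hubs"
author: "cncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated differential expression, cis pairing and differential coexpression hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cncnet)
```

## The analysis problem

cncnet implements a complete small-sample transcriptomics workflow of the
kind used to study long noncoding RNA (lncRNA) involvement in disease from
two-group expression profiling — here modelled on chronic thromboembolic
pulmonary hypertension (CTEPH), where pulmonary-artery tissue from a
handful of patients is compared against matched controls on gene-level
microarrays. Four questions are answered in sequence:

1. Which lncRNAs and mRNAs are differentially expressed between disease
   and control, given only ~5 samples per group?
2. Which differentially expressed lncRNAs sit close enough to
   differentially expressed protein-coding genes (within 300 kb, or
   overlapping/antisense) to plausibly act in *cis*, and do such pairs
   move in the same direction?
3. Which genes change their *connectivity* between the disease and
   control coexpression networks — candidate core regulators?
4. Which functional categories are over-represented among the selected
   coding genes?

Every stage is exercised end-to-end on a bundled synthetic-data generator
with known ground truth, because the workflow is aimed at designs for
which raw public data is typically unavailable.

## The random variance model moderated t-test

With $n_1 = n_2 = 5$ the per-gene variance estimate is the weakest link of
an ordinary t-test. The random variance model assumes the per-gene
precision is exchangeable across genes,

$$\frac{1}{\sigma_g^2} \sim \mathrm{Gamma}(a,\, b) \quad (\text{shape } a,
\text{ scale } b),$$

which implies that across genes the scaled pooled variances $a b s_g^2$
follow an $F(f, 2a)$ distribution, with $f = n_1 + n_2 - 2$ the residual
degrees of freedom. `fit_rvm_prior()` estimates $(a, b)$ by maximising
that F likelihood: quasi-Newton (BFGS) on $(\log a, \log b)$ with a
relative tolerance of $10^{-12}$ on the objective, started from the best
point of a coarse grid centred on a log-moment-matching estimate
($\mathrm{E}\log s^2$ and $\mathrm{Var}\log s^2$ have digamma/trigamma
closed forms under the model, and remain finite for every $a > 0$, unlike
raw moments which require $a > 2$). Genes with $s^2 = 0$ are excluded
from fitting with a logged count but are still tested.

The moderated test statistic for gene $g$ is

$$\tilde s_g^2 = \frac{f s_g^2 + 2/b}{f + 2a}, \qquad
t_g = \frac{\bar x_{g,\mathrm{dis}} - \bar x_{g,\mathrm{con}}}
{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}},$$

referred to a t distribution with $f + 2a$ degrees of freedom (two-sided,
symmetric tail doubling). $\tilde s^2$ is a convex combination of the
observed $s^2$ and the prior variance $(2/b)/(2a) = 1/(ab)$, so the prior
contributes the equivalent of $2a$ extra degrees of freedom — the whole
point in a 5-vs-5 design. As the prior vanishes ($a \to 0$, $2/b \to 0$)
the statistic converges to the ordinary pooled t, which the test suite
checks to $10^{-6}$.

Selection defaults to raw $P < 0.05$ (strict inequality) with no
fold-change cutoff, mirroring common practice for such designs;
Benjamini–Hochberg q-values are always reported alongside, and both a
q-value gate (`de_use_q`) and a linear fold-change gate
(`de_fc_threshold`) are available. `cluster_de_genes()` provides the
customary unsupervised display ordering: average-linkage agglomeration on
the correlation distance $1 - r$, on genes and samples, with
zero-variance rows excluded (their correlation is undefined).

## Cis lncRNA–mRNA pairing

Coordinates are 0-based half-open (BED convention) everywhere inside the
package; GTF input is converted on read. `classify_relation()` assigns
each (lncRNA, mRNA) pair exactly one of:

* **overlap** — intervals intersect, same strand (distance 0);
* **antisense** — intervals intersect, opposite strand (distance 0);
* **upstream / downstream** — disjoint intervals whose boundary gap is
  strictly below 300 kb, judged relative to the mRNA's strand: a lncRNA
  entirely 5′ of the mRNA's transcription start is upstream, entirely 3′
  of its end is downstream.

Three conventions were genuinely open and are settled as follows.
Distance is the gap between nearest interval boundaries (gene-body gap),
the weaker and more inclusive reading of "within 300 kb"; a TSS-based
variant would shrink the candidate set without changing the machinery.
Orientation is anchored on the mRNA (the coding gene is the reference);
`anchor = "lnc"` switches to the other convention. Overlap/antisense
dominate upstream/downstream — under half-open interval logic a
non-overlapping lncRNA cannot straddle the mRNA start, so no further
tie-break is needed and the four categories are disjoint. A lncRNA may
pair with many mRNAs and vice versa; each ordered pair is reported once.

`summarize_pairs()` reports counts per category and the direction
concordance (fraction to 4 decimals, percentage to 1 decimal); with zero
pairs the fraction is reported as not available rather than NaN.

## Coding–noncoding coexpression networks and diffK

For each group separately, candidate nodes are the selected DE lncRNAs
and mRNAs; an edge joins a pair whose within-group Pearson correlation
satisfies $|r| \ge 0.97$ (the sign is kept, so negative regulatory
associations are representable; `corr_use_absolute = FALSE` restores the
literal signed reading $r \ge 0.97$). By default only lncRNA–mRNA edges
are formed (`cnc_only = TRUE`): the coding–noncoding network is defined
by its lncRNA–mRNA coexpression pairs, and this is also what keeps hub
connectivity interpretable as "number of regulated coding partners".
Same-biotype edges can be enabled with `cnc_only = FALSE`. Nodes without
any edge are dropped — only connected genes are network members. With 5
samples per group no correlation p-value gate is applied beyond the 0.97
threshold; at that sample size the threshold itself is the (blunt)
multiplicity control, and this is deliberate and documented rather than
hidden behind an approximate test.

Per network, each node gets its degree, its k-core index (the largest
$k$ such that the node survives iterative deletion of nodes with degree
$< k$; computed via igraph's coreness and cross-checked in the tests
against a direct pruning loop), and its normalised connectivity
$K = \mathrm{degree}/\max(\mathrm{degree})$ (alternative: divide by
$n - 1$, via `diffk_normalization`). The differential connectivity is

$$\mathrm{diffK} = K_{\mathrm{disease}} - K_{\mathrm{control}},$$

with $K = 0$ for a node absent from a network; genes are ranked by
$|\mathrm{diffK}|$ descending, ties broken by node id so output is
deterministic. A caveat of max-degree normalisation worth knowing: in a
very sparse network (e.g. a single spurious edge) the maximum degree is
tiny, so an otherwise unremarkable node can reach $K = 1$ and
$|\mathrm{diffK}| = 1$. The hub-recovery experiment below therefore
isolates the planted module; on real data, diffK rankings should be read
jointly with the raw degrees, which the node-stats table always carries.

## Over-representation analysis

Each term of a user-supplied GMT map is tested against the selected gene
set with the two-sided Fisher exact test (sum of hypergeometric point
probabilities no larger than the observed table's) and the 2×2 Pearson
chi-squared test without continuity correction (expected counts are
reported, with a warning below 5). Up- and downregulated sets are tested
independently; BH adjustment runs over all terms within one
mode/direction stratum. GO-style significance requires $P < 0.01$ and
FDR $< 0.01$; pathway mode uses $P < 0.05$ and is plain
over-representation — no topology-based impact scoring is performed,
which is a deliberate simplification. The universe defaults to the
measured mRNAs, and term maps are static files, so results are
reproducible offline. Fisher and chi-squared p-values can disagree on
small tables; both are reported and the Fisher p drives selection and
FDR.

## The synthetic-data generator

`synthetic_config()` fixes the emulated study design; its defaults are
the package's reference conditions: 15,000 mRNAs and 3,000 lncRNAs on 24
chromosomes of $3\times10^8$ bp, 5 samples per group, 5% planted DE with
a 1.5 log2 effect, Gamma$(2, 0.5)$ precisions (mean variance
$1/(b(a-1)) = 1$ on the log2 scale), 10 planted cis pairs per relation
category with 95.3% direction concordance, and two 10-gene modules with
hub correlation 0.99 in disease and 0.3 in control. Baseline means are
uniform on log2 $[6, 14]$, mimicking an array intensity range.

Layout guarantees are what make the generator a usable oracle:

* each planted pair is constructed so the classifier must recover
  exactly the intended relation (overlap offsets guarantee intersection;
  cis gaps are drawn in $[1000, 290000]$);
* every other feature is placed $\ge 300{,}001$ bp from any feature of
  another placement unit, so background genes participate in no relation
  at the 300 kb window;
* a configuration whose features cannot fit under these constraints is
  refused with an error, never silently packed.

Module members are generated from a latent factor equal to the hub's
realised within-group profile, with noise orthogonalised in-sample, so
the *sample* correlation between hub and member equals the target
exactly in each group. This makes planted coexpression structure behave
deterministically under hard thresholding — the property the
hub-recovery validation relies on — at the cost of slightly
"cleaner-than-life" modules: member–member correlations are
$\approx \rho^2$ and the member's within-group sample variance is exact.
All randomness flows from the single config seed (annotation and
expression use derived seeds), and identical configurations reproduce
byte-identical bundles across runs and platforms.

What the generator deliberately does **not** emulate: probe-level
effects and RMA normalisation (the pipeline starts from a normalised
matrix), batch effects, missing values, correlated background genes,
heavy-tailed noise, or annotation ambiguity (one interval per feature).
Passing tests therefore demonstrate correctness of the algorithms under
the model's own assumptions, not robustness to everything real arrays
do.

## Validation experiments and problem sizes

The test suite's deeper checks, with the sizes chosen for them:

* **Null calibration** — 2,000 genes (1,600 mRNA + 400 lncRNA), 5 vs 5,
  no signal: the moderated test's type-I error at $\alpha = 0.05$ must
  land in $[0.04, 0.06]$ and p-values must pass a KS uniformity test at
  $p > 0.01$.
* **Prior recovery** — 10 seeds × 20,000 variances drawn from the
  scaled-F law at $(a, b) = (2, 0.5)$, $f = 8$: both estimates within
  15% (observed errors are ~1–3%).
* **Pairing** — 1,000 random annotations of up to 200 features each:
  the pair finder must agree exactly with an exhaustive $O(n^2)$ scan
  written independently in the tests.
* **k-core** — 100 Erdős–Rényi graphs ($n = 30$, $p = 0.2$) against an
  iterative-pruning oracle, exact agreement.
* **Hub recovery** — 100 seeded replicates of a single 10-gene module
  (hub correlation 0.99 vs 0.3) with no other planted signal: the hub
  must rank first by $|\mathrm{diffK}|$ in at least 95 replicates (with
  exact in-sample correlation planting it does so in all 100). The
  module-only design is intentional; see the diffK caveat above.
* **Enrichment null** — 100 random 200-gene sets against 40 random
  100-gene terms in a 2,000-gene universe: the Fisher rejection rate at
  0.05 must match the exact discrete level computed by enumeration
  (about 0.039 for these margins — the exact test is conservative) and
  stay within 2 points of the nominal 5%.
* **Determinism** — the full pipeline run twice on the same simulated
  bundle must produce byte-identical output files.

## Numerical and degenerate-input policy

* Correlations are clamped to $[-1, 1]$ after computation; constant
  genes are skipped from network construction with a logged count, and
  excluded from clustering with a warning.
* A zero moderated variance (possible only for $s^2 = 0$ with an
  uninformative prior) yields $p = 0$ when the means differ and $p = 1$
  otherwise, with a warning.
* `NA` p-values are rejected rather than propagated through BH.
* Empty DE sets, empty pair tables and empty networks flow through the
  whole pipeline without error, producing empty (but valid and
  re-readable) outputs; both-networks-empty diffK warns.
* All boundary comparisons are strict where the thresholds are stated as
  strict: $P < 0.05$, gap $< 300$ kb; the correlation threshold is
  inclusive ($\ge 0.97$).

## Known limitations

* With $n = 5$ per group the sampling variability of a Pearson
  correlation is large; the 0.97 threshold is a screen, not an
  inference, and spurious edges occur at a small but nonzero rate (the
  network tests measure this directly).
* diffK with max-degree normalisation saturates in sparse networks (see
  above).
* The pairing stage is gene-body based; exon-aware or TSS-anchored
  variants would need richer annotation than BED6.
* Pathway mode is over-representation only.
* The RVM prior is fitted once on all genes; strong signal contaminates
  the variance pool only mildly (signal shifts means, not within-group
  variances), so no iterative refit is attempted.
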