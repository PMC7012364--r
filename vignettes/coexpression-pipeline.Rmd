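---
title: "Moderated differential expression and lncRNA coexpression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated differential expression and lncRNA coexpression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncoexnet)
```

## The analysis problem

Malignant transformation of oral epithelium proceeds through recognizable
histological stages — normal mucosa, epithelial dysplasia, invasive
carcinoma — and expression series that sample all three stages make it
possible to ask which transcripts, in particular which long noncoding RNAs
(lncRNAs), change along the way and which protein-coding genes they may
regulate. `lncoexnet` implements that analysis as a reusable pipeline over
any three-group log2-intensity matrix:

1. flag lncRNA probes by GENCODE gene-type lookup,
2. screen each pairwise contrast with an empirical-Bayes moderated
   t-statistic and Benjamini–Hochberg (BH) correction,
3. select probes with fold change > 2 or < 1/2 and adjusted p < 0.05,
4. predict lncRNA target genes by Pearson-correlation thresholding across
   **all** samples (|r| > 0.8, correlation-test p < 0.05),
5. link lncRNA pairs that share predicted targets into a coregulation
   network weighted by shared-target counts,
6. characterize target sets by hypergeometric over-representation, and
7. cluster samples and selected probes with 1 − Pearson distance and
   complete linkage.

Because the interesting statistical behaviour of such a pipeline (error
calibration, recovery power, threshold effects) cannot be audited on real
data where the truth is unknown, the package ships a first-class synthetic
generator with planted structure, and every stage is validated against it.

## The moderated t-statistic

For a contrast between groups $a$ and $b$ with $n_a$ and $n_b$ samples,
each probe yields a mean difference (log2 fold change), a pooled variance
$s^2$ on $df = n_a + n_b - 2$ degrees of freedom. With tens of thousands of
probes and few samples, per-probe variances are noisy; the empirical-Bayes
approach places a scaled inverse-chi-square prior with hyperparameters
$(d_0, s_0^2)$ on the true variances and replaces $s^2$ with the posterior
blend

$$\tilde{s}^2 = \frac{d_0 s_0^2 + df\, s^2}{d_0 + df},$$

testing $t = \mathrm{log2fc} / \sqrt{\tilde s^2 (1/n_a + 1/n_b)}$ against a
t distribution on $df + d_0$ degrees of freedom. The hyperparameters are
estimated by the method of moments on $\log s^2$: under the model
$s^2/s_0^2 \sim F(df, d_0)$, so

$$\mathrm{var}(\log s^2) = \psi'(df/2) + \psi'(d_0/2),$$

and the excess of the observed log-variance dispersion over the sampling
term $\psi'(df/2)$ is inverted through the trigamma function by Newton
iteration (tolerance $10^{-8}$). Two degenerate regimes are handled
explicitly: when the observed dispersion does not exceed the sampling
dispersion the prior is effectively infinitely informative ($d_0 = \infty$,
$s_0^2$ set to the mean observed variance, normal reference distribution),
and $d_0 = 0$ recovers the classical pooled two-sample t-test exactly —
both limits are pinned by tests. A zero posterior variance with a nonzero
fold change is reported as an infinite statistic with $p = 0$; a zero fold
change as $t = 0$, $p = 1$.

Contrasts are fitted **pairwise** on the two groups' samples only, each
with its own BH correction across the contrast's probes. A single
three-group model with a pooled variance would gain a little power, but
pairwise fits keep the three screening lists independent of the third
group's composition, match how three-way Venn comparisons of DEG lists are
usually produced, and keep the residual degrees of freedom uniform for the
prior fit. Probes with missing values in a contrast's samples are excluded
from that contrast (and counted), for the same uniformity reason.

"Differential among all three groups" is defined as the intersection
region of the three pairwise DEG sets (the center of the Venn partition).

## Selection thresholds

Selection uses fold change strictly greater than 2 (or strictly below 1/2)
together with BH-adjusted p strictly below 0.05; fold changes are ratios of
geometric means, i.e. $2^{\mathrm{log2fc}}$ on log2 data. Both
inequalities are deliberately strict — a probe at fold change exactly 2.0,
or a pair at correlation exactly 0.8, is *excluded* — and the tests pin
this boundary behaviour with fixtures whose sample statistics hit the
bounds exactly in floating point.

## Target prediction and coregulation

Coexpression is computed across **all** samples of the matrix, not only the
two groups of the contrast that produced the DE lists: the correlation is
meant to capture a stable lncRNA–mRNA relationship over the whole
progression series, and the larger $n$ (229 in the motivating design)
makes the correlation test sharp (at $r = 0.8$, $n = 229$:
$t \approx 20.1$, $p < 10^{-15}$). An (lncRNA, mRNA) pair becomes an edge
when $|r| > 0.8$ and the correlation-test p < 0.05; the mRNA is then a
predicted target of the lncRNA. The absolute-value rule is the default
because strongly anti-correlated pairs are biologically meaningful
(repression) and representable in the exported networks through the sign
of $r$; a signed mode (`r > 0.8` only) is available where the positive
reading of the threshold is wanted. Correlation p-values are left
uncorrected by default — the screen is already conditioned on DE lists and
a hard $|r|$ threshold dominates the decision at any realistic $n$ — with a
BH option available.

Two lncRNAs *coregulate* when they share at least one predicted target;
the edge weight is the shared-target count (the quantity line thickness
encodes in typical network renderings), and the union of all shared
targets is reported as the coregulated target-gene set that downstream
enrichment consumes.

## The synthetic generator and what it does (not) emulate

The generator emits a log2-scale probe × sample matrix for three labeled
groups, defaulting to 45 control / 17 dysplasia / 167 cancer — the group
sizes of the motivating oral-cancer series — with per-probe baselines
uniform on [4, 12] (the bulk of normalized 3'-IVT array intensities) and
Gaussian residuals with `noise_sd = 0.5` log2 units, a typical residual
scale for normalized arrays. The fraction of probes flagged lncRNA
defaults to 0.055, matching the share of long-noncoding probes such a
platform annotates. Neither noise magnitude nor baseline range is a claim
about any particular dataset; they are fixed calibration choices.

Planted differential expression shifts a dedicated block of probes by
±`planted_log2fc` (alternating sign, so both filter arms are exercised) in
the first-named group of each contrast. A consequence worth spelling out:
with three groups, a mean shift in one group necessarily perturbs **two**
pairwise contrasts, so a probe cannot be differential in exactly one
contrast. The truth object therefore exposes `implied_log2fc()`, the
population mean difference of every planted probe under every contrast,
and recovery metrics count a discovery as false only when that implied
difference is zero.

Planted coexpression modules draw a standard normal latent signal $z$ per
module lncRNA and construct each target as
$\rho z + \sqrt{1-\rho^2}\,\varepsilon$ before rescaling to the probe's
baseline and spread, which gives a population correlation of exactly
$\rho$ — so edge-recovery tests compare against an exact generative value
rather than a simulated estimate. An optional variance prior draws
per-probe true variances from a scaled inverse-chi-square law, used to
validate hyperparameter recovery end to end.

The generator deliberately omits probe-level array artifacts (spatial
effects, background, cross-hybridization), batch effects, intensity-
dependent variance, and correlated null probes. Passing tests therefore
demonstrate the pipeline's statistical correctness under its own model
assumptions, not robustness to real microarray pathology; on real data the
usual preprocessing (normalization, QC) remains the caller's
responsibility.

## Numerical and design choices

* **Problem sizes in the test-bed.** Calibration and recovery tests run at
  5,000 probes with groups 20/10/40; network recovery at 400 probes with
  the full 229-sample design; the end-to-end pipeline check at 2,000
  probes × 74 samples. These sizes put Monte-Carlo error well below the
  asserted tolerances while keeping the whole suite fast.
* **Determinism.** One integer seed fixes the dataset, every derived list
  and the run report byte-for-byte (timestamp aside). Clustering
  tie-breaks are delegated to `stats::hclust`, which is deterministic; on
  data with distinct distances the tree is invariant to input order, which
  is the property the tests assert.
* **Series-matrix scale.** Files are assumed log2; if the table maximum
  exceeds 50 the parser applies `log2(x + 1)` and says so. Values are
  written with 17 significant digits so write→parse is the identity.
* **Annotation conventions.** Multi-mapped probe cells (`"A /// B"`) keep
  the first symbol (configurable to drop); probes without a symbol, or
  with a symbol absent from the GENCODE type map, count as ordinary gene
  probes, so lncRNA/gene probe counts always partition the platform.
  Symbol matching is exact and case-sensitive after whitespace trimming.
* **Heatmap display.** Rows are z-scored for display only; constant rows
  render as zeros with a note. Statistics never consume the scaled
  values.
* **Enrichment background.** The default universe is all platform symbols
  — the measurable background — and only over-representation (upper
  hypergeometric tail) is tested; depletion is out of scope.

## Known limitations

Covariate adjustment, surrogate-variable correction and array weights are
out of scope; so are partial-correlation or mutual-information network
inference and genomic-distance (cis/trans) target filters — the target
notion here is purely correlational. The enrichment stage is a generic
hypergeometric test over a user-supplied GMT collection; it does not
reproduce any specific web service's modified statistics or term
clustering. Real-data runs require the platform annotation and GTF to be
supplied as local files.
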