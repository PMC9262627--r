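---
title: "Methods: network bias, staged propagation, and uncertainty-aware fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network bias, staged propagation, and uncertainty-aware fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tfnresponse)
```

# The scientific question and the model

A shift in RNA polymerase (RNAP) concentration is a genome-wide
perturbation: in the short term every gene's transcription rate tracks the
RNAP level through its own promoter kinetics, and only tens of minutes
later — once the perturbed mRNAs have been translated — do the changed
abundances of transcription factors (TFs) reach their target genes. The
package analyses this staged response against the known topology and logic
of the transcription-factor network (TFN).

The logic enters through one number per gene. Each input TF carries a
regulatory effect $r \in \{+1, -1, 0\}$ (activating, repressing,
unknown/dual). With $K_{TF}$ the number of distinct input TFs, the *bias*

$$ b \;=\; \Bigl|\sum_{j \in \text{inputs}} r_j\Bigr| $$

measures the imbalance of the inputs. If all input TFs drop together (as
they do when RNAP drops), their pushes on a balanced target cancel
($b = 0$) but add up coherently on an unbalanced one ($b$ large). The
cohort-level prediction is that mid-term $\mu_{|LFC|}$ grows with
$\mu_{|b|}$, while short-term responses show no such dependence.

## Network assembly rules

* Records target genes, TFs, operons or transcription units (TUs). A
  unit-level record expands to one edge per member gene — all members share
  the unit's promoter, hence its regulation.
* One (regulator, target-gene) pair contributes **one** input TF to
  $K_{TF}$ no matter how many records assert it (e.g. a direct TF–gene
  record plus the gene's operon record). A single consistent sign is kept;
  conflicting signs collapse to $r = 0$. Dual ("+-") effects map to 0
  like unknown ones: the signed logic only admits $\{-1, 0, +1\}$, and this
  choice keeps $b \le K_{TF}$.
* Self-regulation is a real input: self-loops count toward $K_{TF}$ and
  appear in the topology tallies. They are, however, excluded from
  input–output *pair* lists (a gene trivially "predicts" itself).
* Gene names are matched exactly after Unicode NFC normalization (when
  `stringi` is available; gene symbols are ASCII in practice) and
  lower-casing. Unresolvable regulator names are skipped with a warning and
  a count, never silently.
* Path lengths ignore edge signs; by construction every intermediate node
  on a directed path is a TF-coding gene.

# The synthetic generator: what it emulates

`generate_network()` and `simulate_shift()` implement the minimal
mechanistic model consistent with the staged-response picture:

$$ \mathrm{lfc}_{\text{short}, i} = s_i \log_2 \rho + \varepsilon_i,
\qquad
\mathrm{lfc}_{\text{mid}, i} = \mathrm{lfc}_{\text{short}, i}
 + w \sum_{j \to i} r_{ji}\,\mathrm{lfc}_{\text{short}, j}
 + \varepsilon_i' $$

with $\rho$ the shifted/control RNAP concentration ratio, $s_i$ a per-gene
sensitivity and $w$ the propagation weight of direct input-TF changes.
Pre-shift LFCs are pure noise. Defaults, chosen once as the study
conditions:

| parameter | default | rationale |
|---|---|---|
| genes / TFs | 4000 / 300 | scale of the measured *E. coli* transcriptome and its annotated TF set |
| mean in-degree | 1.2 | ~4700 interactions over ~4500 genes in the curated network |
| out-degree tail exponent | 2.5 | puts the largest hub at ~5–15% of all interactions, the share real master regulators (CRP-class) hold; flatter tails concentrate half the network under one TF and create spurious shared-input correlations at all path lengths |
| operon sizes 1..5 | 0.55/0.20/0.12/0.08/0.05 | most units are single genes; multi-gene operons of 2–5 members |
| $\rho$ | 0.5 | the mid-strength dilution condition |
| $w$ | 0.4 | a mid-term TF push clearly smaller than the direct RNAP effect |
| $s_i$ | lognormal, mean 1, CV 0.3 | gene-to-gene diversity standing in for unmodelled promoter features |
| $\sigma_{\text{short}}, \sigma_{\text{mid}}, \sigma_{\text{prior}}$ | 0.2 / 0.05 / 0.05 | the mid-term increment covers only ~55 min on top of the short-term state; with $w = 0$ the mid-term table must remain statistically indistinguishable from the short-term one, which bounds its independent noise |
| replicates, $\sigma_{\text{rep}}$ | 3, 0.3 | triplicate RNA-seq designs and their typical replicate spread |

`emit_de_table()` observes the truth through $n_{rep}$ noisy replicates,
reports the replicate mean/SEM, a t-based p-value and Benjamini–Hochberg
FDR, and (by default) centers each replicate column across genes — the
zero-sum LFC convention that median-of-ratios normalization with
zero-centered shrinkage enforces on real tables. Centering means the
uniform genome-wide drop is *not observable*; all analyses work on
deviations from the genome mean, exactly as with real normalized data.

What the generator does **not** emulate: count-level noise (negative
binomial sampling, library size), length/GC biases, correlated replicate
structure, TF activity regulation that bypasses transcript abundance
(allostery, small molecules), and long-term (> 180 min) dynamics. Passing
tests therefore validate the pipeline's logic and statistics under the
staged model, not the biological claim itself on real data.

# The ensemble approach as realized

Cohorts of `size = 10` genes are drawn with replacement from the regulated
genes ($K_{TF} \ge 1$) in one common stream; each draw is routed to the
nearest grid point of the imposed mean attribute if it falls within half a
grid step, until every point reaches its cap or the draw budget is spent.
Defaults: grid 0–5 in steps of 0.25, cap 25 000 cohorts per point (the
analysis scripts use 2 000), budget $10^6$ draws. The constrained variant
(`conditional_cohorts()`) additionally requires the *fixed* attribute's
cohort mean to lie within half a step of its target; both constraints are
re-verifiable from the returned member lists. Everything is reproducible
bit-for-bit from the seed. Infeasible grid points are omitted with a
warning, never silently imputed.

Two structural facts are worth knowing when reading the curves. First,
$\mu_{|b|}$ and $\mu_{K_{TF}}$ co-vary over cohorts — that correlation is
the phenomenon the conditional cohorts disentangle. Second, at the low end
of the $|b|$ grid the paired $\mu_{K_{TF}}$ *rises* again: balanced inputs
require $K_{TF} \ge 2$, so cohorts forced to a very low mean bias
preferentially contain high-in-degree balanced genes.

# The statistics layer

**Monte-Carlo expanded OLS** (`mc_ols`). Each of the $N$ points is expanded
into $m = 1000$ draws from $\mathcal{N}(y_i, \mathrm{SEM}_i)$ and a line is
fitted to the $N \times m$ cloud. p-values are computed with standard
errors and degrees of freedom on the $N$-point scale ($df = N - C$): the
cloud inflates the sample size $m$-fold, and without this correction every
fit would be "significant" by pseudo-replication. P-value₁ tests the
horizontal-line null; P-value₂ (when $N > 3$) tests the $x^2$ coefficient
of a quadratic fit, rejecting linearity below 0.1. The 68.2% confidence
band is the pointwise central interval of the $m$ per-draw fitted lines
(cloud quantiles), so with all SEMs zero it collapses onto the fitted line
and the whole procedure reduces exactly to textbook OLS.

One calibration caveat is intrinsic to the construction: the cloud's
residual variance is the *sum* of the between-point scatter and the
per-point SEM². P-value₁ is therefore exactly calibrated when the SEMs are
small relative to the scatter (the usual case for the cohort curves, whose
SEMs shrink with the number of cohorts) and conservative when the SEMs
dominate — uncertainty widens the residual variance and weakens claims,
never strengthens them.

**Null model** (`null_model_fit`). X and Y values are resampled without
replacement, independently, destroying the pairing; $K =
\mathrm{Max}_{size} / (0.05\,\cdot\,\mathrm{size}_{XY})$ samplings of 5% each
(Max_size = 45980/2) are pooled and fitted by OLS. Because the pool
over-represents the original points, the slope test runs at
$df = \mathrm{size}_{XY} - C$ with the standard error rescaled to
$\mathrm{size}_{XY}$ effective points. Fewer than 20 observations fall back
to a single full permutation, flagged in the output.

**Sigmoid fits** (`sigmoid_mc_fit`). The four-parameter logistic
$y = a + (c-a)/(1+e^{-k(t-t_0)})$ is fitted by Levenberg–Marquardt least
squares to each of 1000 Monte-Carlo resamples of the series;
non-convergent iterations are dropped and counted (an error above 50%).
Parameters and curve are iteration means with 68.2% bands from the central
interval. Recovery is judged per parameter against two band half-widths:
four simultaneous ~95% intervals jointly fail ~19% of the time by
construction, so a joint criterion would be miscalibrated.

**ANCOVA** (`ancova_compare`). Slope equality is the t-test on the
group-by-x interaction of `y ~ x * group`; intercept equality the t-test on
the group term of the parallel-slopes model. Exactly duplicated groups give
0/0 t-statistics, resolved to p = 1 (equality not rejected). Basic tests
(Welch t, two-sample KS, one-sample Z against an external Normal, Fisher
exact two-sided) all decide at the 10% level.

**Degenerate inputs and conventions.** Singleton cohorts have SEM 0 and are
treated as exact points downstream; clustering coefficients of nodes with
fewer than two neighbours are 0; eccentricity and mean path length are
taken over the out-reachable set (0 when empty); the DEG |LFC| comparison
is strict (`>`); genes with missing FDR join neither the DEG threshold mean
nor DEG eligibility; duplicated genes in with-replacement cohorts count
with multiplicity.

# Problem sizes used by the test-suite

The suite exercises: exact-agreement sweeps against brute-force oracles
(edge-list scans and Floyd–Warshall matrices) over 1000 random graphs of up
to 50 nodes per operation; 200-simulation calibration of P-value₁ and of
the 68.2% band coverage; 50 independence simulations of the null model; ten
end-to-end synthetic studies of 4000 genes each for the mechanism-recovery
block, with ensemble caps of 2000 cohorts per grid point; one
$10^5$-gene network for the closed-form bias check (classes with at least
5000 genes, a precision floor giving the 2% band a ≥3σ margin); and 20
seeded sigmoid recoveries at 200 iterations each. These sizes are the
package's own choice of a thorough-but-quick regression suite; all
module-level defaults remain at their documented values.

# Known limitations

* **Residual $K_{TF}$ trend at constant $|b|$.** In the linear propagation
  model the mid-term push is $w \sum_j r_j\,\mathrm{lfc}_{\text{short},j}$:
  its *mean* is set by $b$, but its *variance* grows with $K_{TF}$, since
  every additional input contributes an independent $s_j$-driven term.
  $E|X|$ grows with the variance of $X$, so cohorts at fixed mean $|b|$
  still gain a little $\mu_{|LFC|}$ with $\mu_{K_{TF}}$ — directly
  verifiable on noise-free truth tables, e.g. at $b = 1$ the mean
  mid-term $|LFC|$ moves from 0.44 ($K_{TF}=1$) to 0.56 ($K_{TF}=5$). The
  effect is about five times smaller than the $\mu_{|b|}$ slope, but the
  ensemble curves are precise enough to detect it. With $w = 0$ both the
  bias curve and the control are flat, which is the model's clean contrast.
  On real data the corresponding control shows no trend; a mechanistic
  model reproducing that exactly would need propagation terms whose spread
  does not accumulate per input (e.g. saturating promoter logic), which is
  beyond the minimal model's scope.
* **Absolute-value pair correlations are weak.** Only $|LFC|$ can be
  correlated between input and output genes (the sign information is not
  recoverable from the analysis design), and taking absolute values of
  weakly correlated signed quantities roughly squares the correlation. At
  $w = 0.4$ the direct-neighbour $R^2$ is of order $10^{-3}$ at ~4700
  pairs, so the L = 1 significance at the 10% level holds in a majority of
  seeds, not in all of them; L = 2, 3 pairs carry no signal beyond hub
  confounding.
* The generator draws unit memberships and TF targets independently; real
  operons have functionally coherent membership and TF targeting is far
  from uniform.
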