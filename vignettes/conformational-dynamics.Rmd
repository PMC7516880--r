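---
title: "Conformational dynamics of coarse-grained protein chains: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational dynamics of coarse-grained protein chains: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaindyn)
```

# Scope and model

`chaindyn` post-processes alpha-carbon protein trajectories treated as
polymer chains. A trajectory is a frames x beads x 3 array of Cα
coordinates in Ångström with a temperature label, a replica id and a frame
time step; an ensemble is a temperature x replica grid of such
trajectories analysed over one or more time windows. The package covers
five analysis stages, plus a seeded generator that stands in for
molecular-dynamics data.

## Chain extension and the size exponent

The end-to-end vector of a chain $r_0 \dots r_N$ is
$\vec R = \vec r_N - \vec r_0$, the sum of the bond vectors
$\vec\tau_j$. For an ideal (freely jointed) chain the bond vectors are
uncorrelated, $\langle \vec\tau_i \cdot \vec\tau_j\rangle = \tau^2
\delta_{ij}$, giving $\langle R^2 \rangle = N\tau^2$. The scaling law
$R \sim \tau N^\mu$ defines the Flory–De Gennes size exponent, estimated
as

$$\mu = \frac{\ln(R/\tau)}{\ln N},$$

with $R$ the RMS end-to-end distance over a window. The log ratio is
base-independent; natural logs are used internally. $\mu = 1/2$ marks the
ideal chain; compact globular chains fall toward $1/4$, and serum
albumin sits near $0.4$. For Cα traces $\tau = 3.8$ Å, the canonical
Cα–Cα distance.

The chain-size parameter $N$ has **no default** anywhere in the package.
The published albumin summaries shipped in `inst/extdata/albumin/` are
internally consistent only with $N = 576$ even though the protein has 579
residues (578 virtual bonds); all ten published exponent values are
reproduced at four decimal places from the published RMS values with
$N = 576$, and none are with $N = 578$. Rather than silently picking a
side, every function takes `n_bonds` explicitly; the acceptance checks use
576 to match the published table, and the synthetic-ensemble analyses use
578, the actual bond count of the generated chains.

## RMSD

Per frame, $\mathrm{RMSD} = \sqrt{\sum_i R_i \cdot R_i / n}$ with $R_i$
the displacement of bead $i$ from a reference. The displacement origin is
a genuine convention choice; three alignments are provided:

* `"centroid"` (default): both structures are translated to a common
  centroid first — the conventional minimal alignment;
* `"none"`: raw differences from the reference coordinates, the most
  literal reading of the formula;
* `"centroid+rotation"`: full least-squares (Kabsch, SVD-based)
  superposition.

The default reference is the first frame of the analysis window.

## Backbone angles and conformational entropy

On a Cα trace the backbone is parameterised by the planar angle $\phi_i$
at each interior bead (the angle subtended at bead $i$ by its neighbours,
in $[0, \pi]$) and the dihedral $\psi_i$ over beads
$(i-1, i, i+1, i+2)$, signed with the IUPAC convention (cis $= 0$,
domain $(-\pi, \pi]$). Coincident consecutive beads make individual
angles undefined; these become `NA` values that downstream histograms
drop, rather than errors.

Angle pairs are pooled on a fixed $50 \times 50$ grid ($\phi$ on
$[0,\pi]$, $\psi$ on $(-\pi,\pi]$) — 50 bins per axis balances histogram
resolution against smoothness. The conformational entropy of the
normalized histogram $p$ is

$$S = -R_0 \sum_i p_i \ln p_i, \qquad R_0 = 8.314\ \mathrm{J\,K^{-1}\,mol^{-1}},$$

bounded by $0$ (one occupied bin) and $R_0 \ln B$ (uniform over $B$
bins). Because the estimate depends on the grid, it is only meaningful
for comparisons across histograms built on the same grid. The entropy
*series* evaluates the single-frame histogram across beads at every
`stride`-th frame, which yields the per-time-point series the periodicity
test consumes; a `"marginal"` variant (sum of the two 1-D histogram
entropies, i.e. $\phi \perp \psi$) is available, with the joint 2-D
histogram as default.

## Fisher's exact g-test

Entropy series are modelled as
$y_n = \beta\cos(n\omega + \alpha) + \epsilon_n$ and tested for
$\beta = 0$. The periodogram follows the literal convention

$$I(\omega) = \frac{1}{N}\Big|\sum_{j=0}^{N} e^{-i\omega j}\, y_j\Big|^2,
\qquad \omega_k = \frac{2\pi k}{N},\ k = 1 \dots q,\ q = \lfloor (N-1)/2 \rfloor,$$

for a series of $N+1$ points — note the denominator $N$, not $N+1$, so
this is *not* the standard DFT grid and `stats::spec.pgram` is not
equivalent. Fisher's statistic is $g = \max_i I(\omega_i) / \sum_i
I(\omega_i)$, ties broken toward the lowest frequency, and its exact null
tail is

$$P(g \ge x) = \sum_{j=1}^{p} (-1)^{j-1} \binom{q}{j} (1 - jx)^{q-1},$$

with $p$ the largest integer below $1/x$. The alternating sum is
evaluated with log-binomial coefficients and clamped to $[0,1]$. The test
suite calibrates this distribution against seeded Gaussian noise (10,000
replicates at $N+1 = 101$) and checks that the type-I error at
$\alpha = 0.05$ lands in $[0.04, 0.06]$.

Two numerical facts about this convention are worth knowing:

* For fixed $x$, the tail *decreases* as $q$ grows — the null $g$
  concentrates near $(\ln q)/q$, so a fixed threshold becomes ever more
  extreme. (Confirmed against Monte-Carlo tails at several $q$.)
* Because the frequencies use denominator $N$ over $N+1$ points,
  $\sum_{j=0}^{N} e^{-i\omega_k j} = 1$ exactly for every $k$: a constant
  offset $c$ leaks a uniform floor $c^2/N$ into every ordinate. Entropy
  series have a large offset ($\sim R_0 \ln B$) and small fluctuations,
  so under the literal formula $g \to 1/q$ and p-values saturate at 1.
  By design the default applies **no mean removal** (the literal
  equations mention none), and a `demean` flag is provided; the analysis
  scripts report both. Constant series are rejected explicitly, since
  their periodogram is *not* zero under this convention yet contains no
  testable fluctuation.

Per-temperature p-values are aggregated by plain arithmetic mean and read
as continuous descriptive parameters; deliberately, no multiplicity
correction is applied anywhere.

## Rank tests

Kruskal–Wallis uses pooled mid-ranks and the uncorrected statistic

$$H = \frac{12}{N(N+1)} \sum_i^k \frac{rs_i^2}{n_i} - 3(N+1),$$

because that is the printed form the summaries report; a tie-corrected
variant sits behind a flag. (`stats::kruskal.test` always applies the
tie correction, which is why the statistic is authored here and the base
function serves as the tie-free cross-check in the tests.) The
Conover–Iman pairwise criterion compares $|rs_i/n_i - rs_j/n_j|$ against

$$t_{1-\alpha/2,\,N-k}\ \sqrt{\frac{S_r - C}{N-1}\cdot\frac{N-1-H}{N-k}
\Big(\frac{1}{n_i}+\frac{1}{n_j}\Big)}, \qquad C = \tfrac14 N(N+1)^2,$$

with $S_r$ the sum of squared ranks. Both sides are returned so the
caller owns the significance decision; $\alpha$ defaults to 0.05 only in
the orchestrated pipeline.

## Kullback–Leibler comparison

Scalar summaries (per-replica RMS end-to-end, mean RMSD, or pooled
per-frame signals) are binned on 50 equal-width bins spanning the pooled
range of the compared set, so all distributions share edges. Divergence
is $KL(p, q) = \sum_i p_i \ln(p_i/q_i)$ in nats, with $q$ the reference;
the symmetric distance is the average of the two divergences. Matrix
output puts the *reference* on rows.

$KL$ is undefined when $q_i = 0 < p_i$. The smoothing rule is additive:
one pseudo-count per bin in both histograms, then renormalize — applied
**only when a zero bin is present** (`smooth = "auto"`), so
fully-positive inputs give the exact textbook value. `"always"` and
`"never"` are available. The log base is natural throughout.

# The synthetic-data generator

The generator replaces undeposited MD trajectories with seeded ensembles
whose *statistics* exercise every pipeline stage; it makes no claim of
physical realism. Three chain models bracket the regimes of interest:

* **freely_jointed** — i.i.d. uniformly oriented bonds per frame; the
  $\mu = 1/2$, $\langle R^2\rangle = N\tau^2$ reference point, used for
  oracle recovery tests.
* **confined** — each bond direction mixes a uniform draw with the unit
  pull toward the running centroid of the beads placed so far
  (`confinement` strength, then renormalized so bond lengths are exact).
  The default strength 0.08 was fixed by a one-off calibration so that a
  579-bead chain at $\tau = 3.8$ Å has RMS end-to-end $\approx 47$ Å,
  i.e. $\mu \approx 0.4$ — the albumin regime.
* **rigid_helix_noise** — a fixed ideal-helix template (radius 2.3 Å,
  rise 1.5 Å, 100° twist, scaled to the exact bond length) plus Gaussian
  coordinate noise with AR(1) correlation across frames; emulates a
  rigid protein with small, temporally coherent angular fluctuation.

Frames are statistically independent in the first two models (no
Langevin dynamics): the downstream statistics consume marginal
distributions, and time correlation can be injected through the helix
model's AR(1) parameter when needed. One master seed expands into a
deterministic stream per (temperature, replica) cell, so replicas are
independent yet each is reproducible in isolation.

The study design frozen in `analysis/00_config.R` is 5 temperatures
(300–312 K) × 9 replicas, 579 beads, 100 frames at 1 ns (covering both
the 0–30 ns and 70–100 ns windows), entropy stride 1 — sizes at which the
full pipeline runs in seconds while every table family is populated.
Per-temperature "shifts" scale the effective bond length by $1 +
\mathrm{shift}$; the configured values (within ±0.8%) reproduce the
roughly 1% per-temperature spread of the published RMS summaries, giving
the rank-test and KL stages realistic, small between-group structure.
The bond-length-conservation invariant holds at each trajectory's
recorded effective bond length (equal to the configured one at zero
shift).

The cosine signal model is generated directly
($y_n = \beta\cos(n\omega+\alpha)+\epsilon_n$) for periodicity power
checks, since the chain models deliberately contain no oscillation.

**What passing tests do and do not show.** The synthetic ensembles share
the study's marginal statistics (chain extension, exponent range,
between-group shifts) but not the temporal correlation, secondary
structure, or force-field physics of real MD data. Green tests therefore
validate the *statistical machinery* — estimators, exact distributions,
table layouts — not any biological claim about albumin.

# Numerical and design choices

* **Windows** are half-open, $[\mathrm{start}, \mathrm{end})$ ns, so
  adjacent windows never double-count a frame.
* **Degenerate geometry** (zero-length bonds) flags angles as `NA`
  instead of erroring; histograms drop `NA` pairs.
* **Angle domains**: boundary values land in the terminal bins
  (right-closed binning with closed lowest edge); $\psi = -\pi$ is mapped
  to $\pi$ to honour the $(-\pi, \pi]$ domain.
* **Tie-breaking**: periodogram maxima toward the lowest frequency;
  rank ties as mid-ranks.
* **Zero-width histograms** (all values equal) collapse to a single bin
  with a warning rather than an error.
* **Temperature labels are opaque strings**; no computation parses a
  numeric temperature out of them.
* The p-value formula caps the alternating-sum upper limit at $q$ and
  clamps to $[0, 1]$; $x = 1$ returns exactly 0.
* The interface is the package's exported functions plus the numbered
  scripts under `analysis/`; the orchestrated `run_pipeline()` writes
  every table family (summary, Fisher, Kruskal–Wallis, Conover–Iman, KL)
  as labelled CSV with a JSON manifest, and multi-model PDB I/O (via
  bio3d) covers interchange with structure tools. No separate
  command-line binary is shipped — the scripts *are* the command line of
  an analysis repository.

# Known limitations

* The generator's chains have no excluded volume and no solvent; the
  confined model's $\mu \approx 0.4$ is a statistical emulation, not a
  physical derivation.
* Entropy estimates are grid-dependent (as any histogram entropy is) and
  are not extrapolated to the continuum.
* KL values from 9-sample histograms are extremely noisy; they are
  reported as descriptive distances, as in the source workflow, not as
  test statistics.
* The bonded-energy evaluator computes the bond/angle/dihedral terms for
  user-supplied parameters only; it assigns no force-field parameters
  and evaluates no non-bonded terms.
* Copula fitting for the bivariate histograms is out of scope; only the
  joint histogram is produced.
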