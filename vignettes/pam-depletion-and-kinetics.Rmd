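---
title: "PAM depletion screens and helicase assay fitting with pamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAM depletion screens and helicase assay fitting with pamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`pamkit` analyses protospacer adjacent motif (PAM) depletion screens and the
quantitative biochemistry that typically accompanies the characterization of
a CRISPR-associated helicase. This vignette explains the models the package
implements, the assumptions behind its synthetic-data generator, the tunable
parameters and their defaults, and the numerical choices made where the
design was genuinely open.

```{r}
library(pamkit)
```

## The depletion-screen model

A PAM library screen transforms cells carrying either an active (targeting)
or inactive (control) CRISPR immune system with a plasmid pool in which the
five positions immediately 5' of a fixed target sequence are fully
randomized — all $4^5 = 1024$ PAMs. After growth under selection, plasmids
whose PAM licenses interference are cleared from the targeting cultures but
not from the controls. Deep sequencing of the amplicon across the PAM then
turns immunity into a counting problem.

### From reads to counts

`extract_pam()` anchors each read by an *exact* match to the known target
sequence and takes the five bases immediately upstream. Exact matching is
deliberate: the assay defines a "correct target sequence", and tolerating
mismatches would let sequencing errors in the target leak reads into wrong
PAM bins. Reads in which the target occurs zero or multiple times, has fewer
than five upstream bases, or yields a PAM containing a non-ACGT character,
are counted as unassigned, so for every sample

$$\text{assigned} + \text{unassigned} = \text{reads processed}.$$

With `search_revcomp = TRUE` the reverse complement of an unanchored read is
also searched (a forward hit always wins), which makes the counting
invariant under strand flips of the library.

### The depletion score

Counts are pooled (summed) across replicates within each arm, and every PAM
receives

$$\text{score} =
  \frac{\text{total control reads}}{\text{total targeting reads}} \times
  \frac{\text{control PAM reads}}{\text{targeting PAM reads}}.$$

A score of 1 means the PAM does not license clearance; large scores mean
strong interference. Two open points required decisions:

* **Depth orientation.** As written, the total-reads factor multiplies
  rather than divides the per-PAM ratio, which is the opposite of a
  depth-normalizing proportion ratio
  $\frac{\text{control PAM}/\text{total control}}
        {\text{targeting PAM}/\text{total targeting}}$.
  The written form is the default for fidelity; the proportion-ratio variant
  is available as `depletion_scores(..., proportion_ratio = TRUE)`. The two
  differ only by the constant factor
  $(\text{total control}/\text{total targeting})^2$, so rankings, position
  preferences and the consensus are identical under either choice.
* **Zero handling.** A fully depleted PAM has zero targeting reads and an
  infinite raw score. A pseudocount (default 0.5, configurable) is added to
  the two *per-PAM* counts only; the totals are raw pooled sums. With equal
  arms the score is exactly 1 for every PAM regardless of the pseudocount.

`depletion_scores()` also reports per-replicate scores (each replicate
against the pooled opposite arm) as a dispersion diagnostic; the headline
statistic always uses the pooled counts.

### Position preferences and the consensus

Figure-level summaries of such screens report *percent depletion per base
and position*. The package uses the marginal-pooling reading: for position
$p$ and base $b$, counts are pooled over the 256 PAMs carrying $b$ at $p$,
and

$$\text{percent depletion}(p, b) = 100 \left(1 -
  \frac{\text{targeting pool}/\text{total targeting}}
       {\text{control pool}/\text{total control}}\right).$$

(The alternative — averaging per-PAM scores within the margin — weighs rare
and abundant PAMs equally and is more noise-sensitive; marginal pooling is
the natural plug-in estimator of the marginal clearance probability.)
Positive cells indicate preference (the base promotes clearance), negative
cells enrichment in the targeting arm: *anti-targeting* bases, which in
type IV-A systems mirror the system's own CRISPR repeat and mark self
sequences that must not be attacked.

`call_consensus()` turns the $5 \times 4$ table into an IUPAC string: per
position, the preferred set is the bases at or above `prefer_threshold`
(default 50 percent depletion), coded with the degenerate alphabet
(empty set $\to$ N); bases at or below `anti_threshold` (default $-50$) are
reported as anti-targeting. The screens this models show qualitative,
well-separated preferences rather than graded ones, so a symmetric $\pm 50$
default separates planted signal from sampling noise by a wide margin at
realistic depths (at $6 \times 10^5$ pooled reads per arm the sampling
error of a marginal cell is a few tenths of a percent). Both thresholds are
arguments, not constants.

`export_krona()` writes the 1024 scores in the Krona `importText` dialect —
magnitude, then one single-base node per ring, ordered $-5 \to -1$ so the
wheel reads 5'→3' outward (ring order is a presentation choice; the
importer accepts any).

### The synthetic screen and what it does (not) emulate

`simulate_pam_library()` emulates the screen with a multiplicative survival
model: each (position, base) pair carries a survival multiplier in $(0,1]$,
and a PAM's survival is the product over its five positions. Control
samples draw PAMs uniformly (optionally from a supplied library-bias
distribution); targeting samples draw from the uniform-times-survival
distribution, renormalized. Reads are single-end,
`flank + PAM + target + flank`, with iid substitution errors
(default $10^{-3}$ per base, a typical post-filter short-read accuracy);
a `revcomp_fraction` argument emits a fraction of reads on the opposite
strand to exercise strand handling. Defaults follow the emulated study:
three replicates per arm and $5 \times 10^5$ reads per sample (the study's
samples yielded roughly 500 000–600 000 reads each). The target sequence of
the real screen is not public, so the default anchor is an arbitrary fixed
32-nt sequence; the anchoring logic is sequence-agnostic and the flank
lengths are free parameters because the amplicon layout around the primers
is not specified.

The position-independence (multiplicative) assumption makes ground truth
analytically tractable — the expected targeting frequency of any PAM is
available in closed form (`expected_pam_freq()`), and marginal percent
depletion can be verified by brute-force summation over all 1024 PAMs. It
is also exactly the structure a per-position marginal readout can resolve.
What the generator does *not* emulate: PCR amplification bias, quality-score
structure, indels, adapter read-through, position-epistatic PAM recognition,
and growth-competition noise between replicates. Passing recovery tests
therefore demonstrate that the pipeline inverts the assay's sampling model
faithfully, not that real screens are free of those artifacts.

`gnawn_truth()` is the canonical planted structure: survival 0.1 for G at
$-5$; at $-3$ survival 0.1 for A, 1.0 for C, 0.5 for G/T; at $-2$ survival
0.15 for A/T and 1.0 for C/G; positions $-4$/$-1$ neutral. The 1.0-survival
bases sit *above* their position's average survival, so they enrich in the
targeting arm and surface as anti-targeting — this is why the background at
$-3$ must be mildly depleted (0.5): with G/T fully neutral, C would sit only
$\approx 29\%$ above the position average, below the $-50$ flag threshold,
which would misrepresent a self-avoiding screen in which the repeat-matching
base is actively spared while the position is otherwise under selection.

```{r, eval = FALSE}
truth <- gnawn_truth(n_reads_per_sample = 2e5, seed = 83)
run <- simulate_pam_library(truth)
counts <- count_pams(run)
scores <- depletion_scores(counts)
prefs <- position_preferences(scores)
call_consensus(prefs)
#> Consensus PAM: 5'-GNAWN-3'
#>   thresholds: preferred >= 50%, anti-targeting <= -50%
#>   position -5: preferred G
#>   position -3: preferred A; anti-targeting C
#>   position -2: preferred A/T; anti-targeting C/G
```

(Tests run this end-to-end recovery at $2 \times 10^5$ reads per sample —
six samples, $1.2 \times 10^6$ reads total — which resolves every planted
margin to well under one percent sampling error while keeping the suite
fast; the generator's *default* depth remains the study-scale
$5 \times 10^5$.)

Plasmid-clearance validation experiments reduce to `clearance_ratio()`:
per-replicate target/non-target colony-forming-unit ratios with mean and
SD; a zero non-target count is an error rather than an infinite ratio,
since it indicates a failed transformation, not perfect clearance.

## The kinetics and binding models

### Malachite-green ATPase kinetics

The phosphate calibration (`fit_standard_curve()`, known orthophosphate
0–100 uM) is an ordinary least-squares line; `invert_curve()` maps
absorbance to concentration. `initial_velocity()` takes the least-squares
slope of product versus time inside a configurable window defaulting to the
assay's 30–150 s quench span; the intercept is left unconstrained, since
quench-and-develop chemistry can offset the zero point without affecting
the slope. Velocities against substrate are fitted by nonlinear least
squares to the Michaelis–Menten equation

$$v = \frac{V_{max}\,[S]}{K_M + [S]},$$

with `fit_michaelis_menten()` (Levenberg–Marquardt, all replicate points
jointly rather than on means — means would discard the replicate variance
that the asymptotic standard errors estimate). Starting values are
data-driven ($V_{max}$ from the largest velocity, $K_M$ from the median
substrate) so convergence does not depend on user guesses; estimates are
bounded below at zero, and non-convergence or a non-positive estimate is
*flagged* on the returned object rather than raised — mirroring how a basal
condition without saturable signal disallows a fit. With the total enzyme
concentration, $k_{cat} = V_{max}/E_0$ is derived with its delta-method
standard error. `beer_lambert()` handles substrate quantitation
($c = A/\varepsilon l$; for ATP $\varepsilon = 15\,400\ \mathrm{M^{-1}cm^{-1}}$).

Recovery tests simulate the wild-type design — 10 nM enzyme, substrate
11–2000 uM in triplicate, 5% multiplicative noise, true
$k_{cat} = 32\ \mathrm{s^{-1}}$ — and require the fitted $k_{cat}$ within
10%. The enzyme's true $K_M$ is reported only in supplementary material not
reproduced here, so simulations use $K_M = 150$ uM, comfortably inside the
assayed span; $k_{cat}$ recovery is insensitive to this choice as long as
the design brackets $K_M$.

### Anisotropy binding

`fit_binding()` fits the single-site saturation model
$\Delta r = B_{max}[P]/(K_d + [P])$ to titration data (default), or, behind
`quadratic = TRUE`, the ligand-depletion form that accounts for a probe
concentration comparable to $K_d$ (here 10 nM probe versus
$K_d \approx 25$ nM, so depletion is not negligible in principle). The
simple hyperbola remains the default because it is the named model of the
emulated analysis; the quadratic form is provided for users who want the
bias-corrected estimate. Recovery tests titrate 1–2500 nM (12 log-spaced
points, 2% noise) at true $K_d = 25$ and 26 nM — the reported values with
and without a non-hydrolyzable ATP analog — require each within 15%, and
check the two conditions are statistically indistinguishable (overlapping
Wald intervals and a non-significant z-test on the difference), reproducing
the no-nucleotide-enhancement conclusion.

### Unwinding, CD, and the synthetic assay generator

`percent_unwound()` is the displaced fraction
$100\,u/(u + d)$ of gel band intensities; `unwinding_course()` summarizes
replicate time courses (mean $\pm$ SD) and classifies whether the endpoint
exceeds the 50% cutoff used to call a substrate productively unwound.
`cd_convert()` converts spectropolarimeter machine units (mdeg) to
per-residue $\Delta\epsilon$. The conversion expression as commonly printed,
$\Delta\epsilon = \theta \times (0.1 \times MRW)/(P \times Conc) \times 3298$,
parses with 3298 multiplying, while the conventional formula divides by
3298; both parsings are implemented (`divide_by_3298`), default the printed
form, without asserting which was intended — they differ by a constant
factor only, so spectral shape is unaffected.

`simulate_assay()` generates all plate-reader-style inputs from a declared
`assay_truth()` — Michaelis–Menten, single-site binding, exponential
unwinding, or linear progress — with seeded *multiplicative* Gaussian noise
($y = \mu(x)(1+\varepsilon)$), reflecting that plate-reader error scales
with signal. It does not emulate instrument drift, pipetting series
correlation, or inner-filter effects.

## Numerical choices and limitations

* Optimizer: `minpack.lm::nlsLM`, 200 iteration cap, zero lower bounds;
  noiseless data are recovered to $10^{-8}$.
* All simulations are exactly reproducible from integer seeds; identical
  truths give byte-identical FASTQ.
* Degenerate inputs fail loudly at the boundary (zero totals in an arm,
  both gel bands zero, zero non-target CFU, non-positive extinction
  coefficients) rather than propagating NaN.
* The pipeline measures positions $-5..-1$ only; contributions from further
  upstream are outside the assay's reach. No significance testing is
  attached to depletion scores (the emulated analysis performs none); the
  per-replicate scores support informal dispersion checks only.
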