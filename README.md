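# pamkit

Analysis of **PAM depletion screens** for CRISPR immune systems, plus the
quantitative assay fitting used when characterizing a CRISPR-associated
helicase — for microbiologists and biochemists who have sequencing reads
from a plasmid-curing PAM library and plate-reader/gel data from the
accompanying biochemistry, and want a tested, reproducible path from raw
inputs to a consensus PAM and fitted constants.

## What it computes

**Screen pipeline.** A PAM library places all 4⁵ = 1024 five-nucleotide
combinations 5′ of a fixed target; an active (targeting) immune system
clears plasmids whose PAM licenses interference, an inactive (control)
system does not. From FASTQ reads, `pamkit` extracts the 5-nt PAM anchored
to an exact target match, counts over the full 1024-PAM space, pools
replicates within each arm, and scores every PAM with

```
score = (total control reads / total targeting reads)
        × (control PAM reads / targeting PAM reads)
```

(pseudocount 0.5 on the per-PAM counts; a proportion-ratio variant is one
flag away). Marginal per-position percent depletion,

```
100 × (1 − (targeting pool / total targeting) / (control pool / total control)),
```

feeds an IUPAC consensus call that also flags **anti-targeting** bases —
bases enriched under targeting, the self-avoidance signature of bases that
match the system's own CRISPR repeat. A Krona `importText` export draws the
classic PAM wheel, and `clearance_ratio()` handles the CFU validation
ratios.

**Assay fitting.** Malachite-green phosphate standard curves and initial
velocities; Michaelis–Menten fits `v = Vmax·[S]/(Km + [S])` with
`kcat = Vmax/E0`; Beer–Lambert quantitation `c = A/(εl)`; single-site
anisotropy binding fits `Δr = Bmax·[P]/(Kd + [P])` (ligand-depletion
quadratic behind a flag); helicase percent-unwound time courses; CD
machine-unit conversion.

**Synthetic data.** `simulate_pam_library()` and `simulate_assay()` generate
every raw input from declared ground truth (multiplicative per-position
survival model; seeded, byte-reproducible), so the whole pipeline is
testable by parameter recovery without any external download.

## Worked example

Simulate a screen with a planted GNAWN structure and recover it:

```r
library(pamkit)
truth <- gnawn_truth(n_reads_per_sample = 2e5, seed = 83)
run    <- simulate_pam_library(truth)    # 6 FASTQ files, 3 per arm
counts <- count_pams(run)                # 1024 x 6 count table
scores <- depletion_scores(counts)
prefs  <- position_preferences(scores)
prefs
#> Percent depletion by PAM position (negative = anti-targeting):
#>        A     C     G     T
#> -5 -29.0 -28.7  87.0 -28.9
#> -4   0.0  -0.4   0.3   0.0
#> -3  80.8 -90.6   5.0   5.0
#> -2  73.8 -73.8 -73.8  73.9
#> -1   0.0   0.4  -0.6   0.2
call_consensus(prefs)
#> Consensus PAM: 5'-GNAWN-3'
#>   thresholds: preferred >= 50%, anti-targeting <= -50%
#>   position -5: preferred G
#>   position -3: preferred A; anti-targeting C
#>   position -2: preferred A/T; anti-targeting C/G
```

Reading the table: G at −5 is 87% depleted under targeting (preferred),
while C at −3 and C/G at −2 are *enriched* (negative cells, anti-targeting)
— the planted self-avoidance pattern, recovered from reads alone.
`export_krona(scores, "wheel.txt")` writes the PAM wheel input.

Fit simulated ATPase kinetics at a realistic design (10 nM enzyme,
11–2000 µM ATP, triplicate, 5% noise, true kcat 32 s⁻¹):

```r
tr  <- assay_truth("michaelis_menten", list(Vmax = 0.32, Km = 150),
                   noise_sd = 0.05, seed = 2201)
obs <- simulate_assay(tr, c(11, 22, 44, 88, 175, 350, 700, 1400, 2000),
                      replicates = 3)
fit_michaelis_menten(obs$x, obs$y, enzyme_conc = 0.01)
#> Michaelis-Menten fit
#>   Vmax  = 0.3239 +/- 0.00438
#>   Km    = 154.3 +/- 7.73
#>   kcat  = 32.39 +/- 0.438 1/s (E0 = 0.01 uM)
```

kcat comes back at 32.4 ± 0.4 s⁻¹ against a truth of 32 — the recovery the
test suite asserts within 10%.

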