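# goldstereo

Quantitative analysis of immunogold electron-microscopy labelling over
membrane compartments, for protein-localisation studies on annotated
cryo-section micrographs — e.g. deciding whether a transporter sits on the
plasma membrane, the nuclear envelope, endo-membranes or the mitosomes of
a microsporidian meront.

Raw gold counts cannot answer that question: compartments differ in how
much membrane they expose per section, and antisera bind nonspecifically.
The package implements the standard correction chain:

* **Membrane length by stereology.** A square test-line lattice of
  spacing *d* is placed on each micrograph with uniform random offset and
  rotation; from *I* crossings with the membrane profiles of a
  compartment, profile length is estimated as *L̂ = (π/4)·d·I*
  (design-unbiased for membranes of any orientation).
* **Membrane association.** A gold particle is membrane-associated if its
  centre lies less than one particle width (default 15 nm for 10 nm gold)
  from the nearest membrane profile; labelling density is
  *D = N / L̂* in gold/µm, pooled within an experiment by ratio of sums.
* **Specificity correction.** Against a peptide-inhibition control:
  *D(sp) = D(0) − D(−)*, specific fraction *F(sp) = D(sp)/D(0)*, and the
  specific gold distribution *Ng(sp) = F(sp) × N(0)* per compartment.
  Negative *D(sp)* is reported as-is; *F(sp)* is clamped to [0, 1] for the
  distribution (raw value retained).
* **Replication.** Statistics are computed per experiment and summarised
  across replicates (default 3) as mean ± SEM.

A seeded synthetic generator (`makeScene()`, `placeGold()`,
`simulateStudy()`) emulates meront sections — plasma-membrane blob,
nuclear envelope, endo-membrane tubules, 50–300 nm elliptical mitosomes —
with known labelling parameters, so the whole pipeline is testable by
parameter recovery without any real micrographs.

## Worked example

Simulate a study at protocol scale (3 experiments × 18 micrographs per
condition; specific plasma-membrane labelling 5 gold/µm, none on
mitosomes, uniform background, complete peptide inhibition), quantify it
blind, and correct for specificity:

```r
library(goldstereo)
study <- simulateStudy(SceneParams(), LabellingModel(), nExperiments = 3L,
                       micrographsPerCondition = 18L, seed = 42L)
quant <- quantifyAnnotations(study$annotations, seed = 43L)
spec  <- specificityAnalysis(quant)
subset(spec, experiment_id == "exp1",
       c(compartment, D0, Dminus, Dsp, Fsp_raw, N0, Ngsp))
#>        compartment   D0 Dminus   Dsp Fsp_raw  N0  Ngsp
#> 1    endo_membrane 2.19  1.048 1.139  0.5206 146  76.0
#> 2         mitosome   NA     NA    NA  0.0968  31   3.0
#> 3 nuclear_envelope 1.78  0.889 0.895  0.5018  94  47.2
#> 4  plasma_membrane 5.63  0.847 4.779  0.8494 646 548.7

aggregateSpecificity(spec, "Ngsp")
#>   antibody_id      compartment   mean    sem n statistic
#> 1         ab1    endo_membrane  77.10  2.614 3      Ngsp
#> 2         ab1         mitosome   1.33  0.882 3      Ngsp
#> 3         ab1 nuclear_envelope  58.99  6.123 3      Ngsp
#> 4         ab1  plasma_membrane 531.38 10.217 3      Ngsp
```

Reading experiment 1: the native plasma-membrane density *D(0)* = 5.63
gold/µm drops to *D(−)* = 0.85 under the inhibition control, so
*D(sp)* = 4.78 gold/µm of the signal is specific (the simulation truth is
5) and *F(sp)* = 0.85 of the 646 plasma-membrane gold particles — about
549 — are attributed to specific binding. Mitosomes, simulated with zero
specific labelling, keep a count-rate-based fraction near zero and
contribute ~1 of ~670 specific gold particles in the cross-experiment
summary: the protein localises to the plasma membrane. `runPipeline()`
wraps the same steps around annotation JSON files on disk and writes the
density table, the *Ng(sp)* distribution with mean ± SEM, and a
provenance record.

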