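## Shared fixtures, built in code at test time.

smallStudy <- function(seed = 31L)
  simulateStudy(SceneParams(), LabellingModel(), nExperiments = 2L,
                micrographsPerCondition = 3L, seed = seed)

## Hand-built quantified table: two experiments with exact densities, one
## compartment with induced signal (D0 < D-), one count-only compartment.
fakeQuantified <- function() {
  row <- function(exp, cond, comp, N, L) data.frame(
    compartment = comp, N = N, L_nm = L,
    D = if (is.na(L) || L == 0) NA_real_ else N / (L / 1000),
    density_defined = !is.na(L) && L > 0, condition = cond,
    experiment_id = exp, antibody_id = "ab1", sampling_stream = "sur",
    n_micrographs = 10L)
  rbind(
    row("e1", "native", "plasma_membrane", 100, 10000),
    row("e1", "native", "nuclear_envelope", 10, 5000),
    row("e1", "native", "mitosome", 6, NA),
    row("e1", "inhibited", "plasma_membrane", 20, 10000),
    row("e1", "inhibited", "nuclear_envelope", 15, 5000),
    row("e1", "inhibited", "mitosome", 3, NA),
    row("e2", "native", "plasma_membrane", 90, 9000),
    row("e2", "native", "nuclear_envelope", 12, 6000),
    row("e2", "native", "mitosome", 0, NA),
    row("e2", "inhibited", "plasma_membrane", 18, 9000),
    row("e2", "inhibited", "nuclear_envelope", 6, 6000),
    row("e2", "inhibited", "mitosome", 2, NA))
}
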