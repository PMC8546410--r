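# latticefret

Single-molecule protein fingerprinting by FRET X reads out the FRET
efficiency between an acceptor dye at a protein's N terminus and donor dyes
on DNA tags attached to residues of selected types (C, K, R), one pair at a
time via exchangeable imager strands. The set of efficiencies per residue
type — the *fingerprint* — encodes where those residues sit in the folded
structure, and is distinctive enough to identify proteins in mixtures.

`latticefret` implements the complete in-silico stack for this method:

* a coarse-grained folding model on a body-centered cubic lattice (one
  pseudo-atom per residue, bonds along the eight (±1,±1,±1) directions,
  3.8 Å per bond) with a six-term energy
  `E_tot = E_AA + E_sol + E_ss + E_dsb + E_tag + E_reg`
  covering empirical residue contacts, solvent exposure, native secondary
  structure re-formation (−25), disulfide bridges (−50), DNA-tag steric
  clearance (+100 per blocking residue) and single-step reorganization;
* two-chain Metropolis Monte Carlo minimization (temperatures 0.01/0.001,
  `P_accept = min{1, exp(-dE/T)}`) with replica exchange every 100
  iterations (`P_exchange = min{1, exp(dE * d(1/T))}`) and early
  termination once all tags fit without hindrance;
* simulated fingerprint extraction: 100 post-folding snapshots, random
  accessible dye orientations with a 70°/20 Å tag-repulsion constraint,
  block-averaged distances, `E = 1/(1+(R/R0)^6)` with R0 = 54 Å, binned at
  0.01 E;
* SVM identification of proteins from fingerprints with stratified
  10-fold cross-validation, train-only resolution tuning and the
  well-identifiable statistic (> half of replicates correct);
* experimental trace analysis: per-molecule two-state K-means event
  detection (events must exceed 3 frames), proximity-ratio FRET per event,
  Gaussian-mixture fingerprint fitting;
* synthetic generators for model peptides, stable helical test proteins,
  two-state intensity traces and class-structured fingerprint datasets, so
  every analysis can be exercised end to end without external data.

Structure input comes from single-chain PDB files (`load_atomistic`, with
R-free < 0.21 / canonical-residue / single-chain quality filters and
helix-preserving lattice fitting) or from bare sequences as stretched
chains. See the methods vignette
(`vignettes/lattice-fret-fingerprinting.Rmd`) for the model's assumptions,
parameter defaults and limitations.

## Worked example

Simulate and identify the four model peptides (lysine reference at the N
terminus, cysteine at position 10, 20, 30 or 40, inert filler):

```r
library(latticefret)
res <- run_pipeline(run_config(seed = 1, replicates = 10))
round(res$mean_e, 3)
#> pep_cys10 pep_cys20 pep_cys30 pep_cys40
#>     0.805     0.745     0.705     0.577
```

The mean fingerprint FRET efficiency decreases monotonically as the
cysteine moves away from the reference — the peptides behave as
self-avoiding coils whose FRET-pair separation grows with sequence
separation. A single molecule:

```r
pep <- make_peptide(40, cys_position = 10)
fp <- simulate_fingerprint(pep$structure, default_scheme("C"),
                           params = energy_params(inert_types = c("G", "S")),
                           seed = 1)
fp
#> fingerprint: 1 channel(s), 9 frames, resolution 0.01
#>   C: 9 value(s), mean E = 0.798
```

Trace analysis on synthetic data with known ground truth:

```r
st <- trace_recovery_study(seed = 1, true_e = 0.6)
c(events = st$n_events, dominant = round(st$dominant_e, 3))
#>   events dominant
#>    654.0      0.6
```

A thin command-line interface over the same functions is in
`inst/cli/latticefret.R` (subcommands `run`, `fold`, `fingerprint`,
`traces`, `synth`).

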