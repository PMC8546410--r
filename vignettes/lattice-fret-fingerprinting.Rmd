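---
title: "Simulating FRET X protein fingerprints on a BCC lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating FRET X protein fingerprints on a BCC lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticefret)
```

## The problem

FRET X fingerprinting identifies single protein molecules by reading out,
one pair at a time, the FRET efficiency between an acceptor dye anchored at
the N terminus and donor dyes on DNA tags conjugated to residues of selected
types (cysteine, lysine, arginine). Each tagged residue type contributes a
set of FRET efficiencies — the *fingerprint* — that reflects where those
residues sit in the three-dimensional structure. `latticefret` implements
the full in-silico counterpart: a coarse-grained folding model that predicts
fingerprints from sequence/structure, a classifier that identifies proteins
from fingerprints, and the analysis of experimental donor/acceptor intensity
traces.

## The structural model

Each residue is a single pseudo-atom on a vertex of a body-centered cubic
lattice. Valid vertices are integer triples whose coordinates are all even
or all odd; bonded residues differ by one of the eight
$(\pm 1,\pm 1,\pm 1)$ vectors, so every bond has the same length and each
residue has eight possible bond directions and up to six non-bonded
contacts. The physical scale is fixed by the canonical Cα–Cα virtual bond:
one bond = 3.8 Å, i.e. $3.8/\sqrt{3}$ Å per lattice unit. The BCC lattice
admits a regular helix with one turn per five residues (a four-bond cycle
whose residues $i$ and $i+4$ differ by a pure axis translation), which the
package uses both to fit atomistic helices and to score helix re-formation.

A structure's energy is

$$E_{tot} = E_{AA} + E_{sol} + E_{ss} + E_{dsb} + E_{tag} + E_{reg}$$

* **$E_{AA}$** sums an empirical pairwise contact energy over all
  lattice-adjacent, non-chain-neighbour residue pairs. The bundled table is
  derived from the Miyazawa–Jernigan per-residue contact-energy scale by a
  centered one-body approximation anchored to the canonical strong pairs
  C–C (−5.44) and F–F (−7.26); hydrophobic pairs attract, polar–polar pairs
  are near zero or repulsive. Any symmetric 20×20 table can be substituted.
* **$E_{sol}$** charges a per-residue-type energy for every unoccupied
  neighbour vertex. Because the bundled contact table is solvent-referenced,
  the default solvent energy is zero; the term is retained for
  non-referenced tables.
* **$E_{ss}$** grants −25 per residue that re-forms its *native* secondary
  structure: a natively helical residue whose window $i..i{+}4$ realizes the
  lattice helix (each bond the same 90° rotation of its predecessor about a
  common axis), or a natively sheet residue in lattice contact with a
  non-neighbouring sheet residue. The window bonus is anchored at the
  residue owning the window; a run of $n$ helical residues earns $n-4$
  bonuses.
* **$E_{dsb}$** grants −50 per contacting cysteine pair in a maximum
  matching (one bridge per cysteine).
* **$E_{tag}$** charges +100 per residue blocking a DNA tag's best route to
  the periphery. The tag occupies all vertices within Euclidean distance 2
  lattice units of its backbone (the 8 bond neighbours plus the 6 axial
  two-step vertices of each backbone vertex); candidate routes are straight
  rays along the eight bond directions and, when all are blocked,
  single-bend routes (first leg 1–3 steps). The tagged residue and its two
  bonded neighbours never count as blockers — they are covalently forced
  into the tag's vicinity. Under this volume, every position of the lattice
  helix and of extended chains is clear, while residues buried inside
  compact cores are not; buried tags therefore force local unfolding, which
  is the intended physics. We also evaluated the fatter "within two bonds"
  volume and rejected it: it makes *every* interior residue of any compact
  structure a permanent blocker, so every tagged structure is forced through
  +100-buyout deformations that leave free hinges and wildly variable
  fingerprints, incompatible with stable protein fingerprints and with
  early termination on clearance.
* **$E_{reg}$** penalizes violent single-step reorganizations:
  `weight * max(0, D - threshold)` with `D` the summed per-residue
  displacement of the move in lattice units. It enters the Metropolis
  acceptance only; recorded structure energies always use the structure as
  its own reference. Defaults are weight 1 and threshold 1000. The
  threshold is deliberately far above the displacement of ordinary
  peptide-scale branch rotations: at the model's temperatures any penalized
  move is effectively always rejected, so a small threshold would
  categorically veto pivot moves — yet stretched peptides must relax to
  coil dimensions within the single 500-iteration window the
  hindrance-check stopping rule allows them. The penalty therefore bites
  only for reorganizations of large-protein scale.

Tagged residues lose all interactions: they contribute nothing to
$E_{AA}$, $E_{ss}$ or $E_{dsb}$.

## Minimization

Two chains run Metropolis Monte Carlo from copies of the start structure at
unitless temperatures 0.01 (hot) and 0.001 (cold). Moves are drawn
uniformly among three kinds at uniformly random positions: *branch
rotations* (a random element of the 24-element lattice rotation group
applied to everything after a pivot), *corner flips* (one residue moved to
another vertex bonded to both chain neighbours) and *crankshafts* (two
consecutive residues moved, preserving all bonds). Proposals that break
self-avoidance count as rejections. Acceptance follows
$P = \min\{1, e^{-\Delta E/T}\}$; every 100 iterations the chains attempt
to swap models with $P = \min\{1, e^{(E_{hot}-E_{cold})(1/T_{hot}-1/T_{cold})}\}$,
a sign convention under which a hot chain holding the lower energy always
hands it to the stricter chain. Every 500 iterations the cold chain is
checked for tag hindrance and the run stops once $E_{tag}=0$ there; the cap
is 60,000 iterations. The returned structure is the hindrance-free
structure of lowest recorded $E_{tot}$ from either chain.

One exact shortcut keeps the engine fast: when the current structure is
already tag-clear, a proposal's $E_{tag}$ is non-negative, so if the
remaining terms alone raise the energy by more than $40T$ the move is
rejected (probability below $e^{-40}$) without running the clearance
search.

## Fingerprint extraction

After clearance the cold chain continues for 1,000 steps and every 10th
structure is recorded — 100 snapshots. On each snapshot every tag draws an
orientation uniformly from the accessible lattice directions (those whose
first two arm vertices have an unoccupied swept volume); orientations of
tag pairs closer than 20 Å are redrawn until both the inter-tag angle and
the dihedral about the inter-residue axis are at least 70°. The dye sits
`dye_offset` Å from the residue along the orientation. Donor–acceptor
distances are averaged over consecutive non-overlapping blocks of 10
snapshots — emulating molecular motion within one camera frame — and each
block mean is converted with $E = 1/(1+(R/R_0)^6)$, $R_0 = 54$ Å
(Cy3–Cy5). The 10 frame values per channel are binned (default width
0.01 E) and normalized over the number of frames. Snapshots with no
admissible dye placement are dropped and the remaining frames renormalized;
molecules that never clear their tags, or lose too many snapshots, are
skipped and `simulate_replicates()` draws fresh molecules until the
requested count is measured.

The dye standoff is the one calibrated parameter. The reported four-peptide
fingerprints constrain it tightly, and the method's own development
likewise tuned tag-interaction geometry against those peptides. Scanning
10–36 Å with all other parameters at their defaults, 22 Å (about a 6-bp
duplex segment plus linker) reproduces the four reported means; it is fixed
as the default and not adjusted per experiment.

## The model peptides

The four 40-residue model peptides carry the reference lysine at position 1
and a cysteine at position 10, 20, 30 or 40. The true backbone sequence is
a designed synthetic linker; the generator uses a glycine/serine filler and
models it as *non-interacting* (`energy_params(inert_types = c("G","S"))`
zeroes its contact energies), the literal reading of an inert flexible
linker. The peptide system is then a self-avoiding coil decorated with tag
sterics and repulsion — which is exactly the regime the reported
fingerprints display: starting stretched, the chain relaxes through free
pivot moves within the 500-iteration window and the mean fingerprint E
decreases monotonically with FRET-pair separation. A real backbone with
full energetics can be supplied through `make_peptide(filler = ...)`.

## Classification

Fingerprints become fixed-length features by concatenating each channel's
histogram in a fixed channel order; re-binning merges bins by summation. A
radial-basis SVM (`e1071::svm`, default cost and gamma) is evaluated by
stratified k-fold cross-validation — one replicate of every protein per
fold when replicates equal folds — and accuracy is the arithmetic mean of
per-fold test accuracies. `tune_resolution()` optionally selects the bin
width on training data only (steps of 0.01 E, ties toward finer).
*Well-identifiable* proteins are those correctly classified in strictly
more than half of their replicates.

## Trace analysis

Experimental traces are analysed per molecule: two-state K-means on the
summed donor + acceptor intensity (deterministically initialized at the
extremes) marks bound frames; runs of more than three consecutive bound
frames become events; a trace whose two intensity levels are separated by
less than three pooled within-cluster standard deviations yields no events
(pure noise splits at about 2.7). Per-frame FRET is the raw proximity
ratio $I_A/(I_A+I_D)$ (optional leakage/gamma corrections are available but
default to none, since no correction factors are published for this assay),
and the event value is its mean. Gaussian-mixture components (count chosen
by BIC, up to 3 by default) fitted to the event means constitute the
experimental fingerprint; a collapsed component triggers an equal-variance
refit.

## The synthetic generators

`simulate_trace()` emulates transient imager binding as alternating
exponential dwells (defaults 2 s bound / 2 s unbound, 0.1 s frames)
discretized to frames, with signal split $I_A = S\,E$, $I_D = S\,(1-E)$
plus Gaussian noise and a flat background; it omits photobleaching
(mitigated in the assay by dye replenishment), blinking and spectral
crosstalk, so passing recovery tests bounds estimator bias under ideal
photophysics only. `make_fingerprint_classes()` builds class-structured
fingerprint datasets directly (peak positions jittered per replicate) for
classifier tests without folding. `helical_test_protein()` provides stable
folded test proteins: an alanine backbone in its native lattice helix,
where the −25/residue window bonus pins the fold so replicate fingerprints
are tight; these stand in for the stable PDB-derived structures of the full
benchmark, which requires structure downloads and is out of scope here.

## Desk-scale reference studies

The packaged studies (also recomputed by `scripts/acceptance.R`) use these
problem sizes, chosen to finish in minutes on one core while keeping
standard errors useful: four peptides × 20 molecules (`peptide_study`);
6-residue chains, 50 folding runs against exhaustive enumeration
(`fold_benchmark`, first bond fixed, ~2,400 conformations); 3 helical
variants × 10 molecules (`spliceoform_study`); 6 helical proteins × 10
molecules × 2 labeling scenarios (`robustness_study`, fingerprints at
0.05 E — with 10 frames per channel, 0.01 E bins are sparser than the
information content, and reported accuracies are insensitive to resolution
up to ~0.1 E); one 24,000-frame trace (`trace_recovery_study`). The
classifier studies cap folding at 5,000 iterations: stable helical starts
clear their tags at the first check, and the cap only curtails the rare
molecule that never clears, which is skipped and resampled.

## Numerical and design choices

* Sign conventions: bonuses lower the energy (−25, −50), penalties raise it
  (+100); minimization semantics throughout.
* The E_ss helix rule demands a consistent rotation sense across the
  window's four bonds; degenerate tie-breaks cannot occur because the
  window either matches or does not.
* Disulfide pairing uses exact maximum matching (branch-and-bound on the
  tiny cysteine contact graph).
* Corner-flip and crankshaft candidate sets exclude the current position,
  so a proposed move always changes the structure; every such move has an
  inverse at the same position, as Markov-chain reversibility requires.
* `fold()` treats an invalid proposal (no candidates, or self-avoidance
  broken) as a rejected iteration.
* All randomness flows through R's session RNG; every user-facing entry
  point takes a seed, and pipeline stages derive per-stage seeds from the
  global one by a fixed multiplicative hash below $2^{31}$.
* Dihedral degeneracy: when a tag orientation is parallel to the
  inter-residue axis its dihedral is undefined and the constraint is
  treated as satisfied.

## Known limitations

* The contact table is a one-body approximation to the cited empirical
  potential, not the full 20×20 tabulation; relative hydrophobic ordering
  is preserved but pair-specific detail (e.g. aromatic–arginine) is not.
* Fingerprints rest on 100 snapshots of a single folding trajectory;
  slowly interconverting conformers are under-sampled.
* The simulated arm omits photophysics; experimental fingerprints carry
  donor-leakage populations that the simulation never produces.
* Lattice discretization quantizes distances to multiples of
  $3.8/\sqrt{3}$ Å and orientations to eight directions; sub-Å fingerprint
  structure is below the model's resolution.
* The full several-hundred-protein benchmark needs externally obtained
  atomistic structures; the package ships the machinery (`load_atomistic`,
  `passes_filters`, `fit_to_lattice`) but not the data.

## A worked example

```{r example, eval = FALSE}
pep <- make_peptide(40, cys_position = 10)
scheme <- default_scheme("C")
fp <- simulate_fingerprint(pep$structure, scheme,
                           params = energy_params(inert_types = c("G", "S")),
                           seed = 1)
mean(fp$channels$C$values)
```
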