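---
title: "Models and methods behind trnarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trnarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnarray)
```

`trnarray` models a radiolabeled-tRNA microarray experiment end to end:
probe-panel design from a gene catalog, array geometry, phosphorimager
image formation, spot quantification, and the downstream analytics usually
run on such profiles. This vignette records the models, the tunable
parameters with their defaults and units, and the design choices made
where more than one reasonable option existed.

## Why metabolic labeling makes spot signal a linear proxy

All cellular RNAs are assembled from a common nucleotide pool, so growing
cells in medium spiked with [³²P] orthophosphate labels every RNA in
proportion to its phosphate content. For molecules of near-identical
length — tRNAs, 74–93 nt — the expected activity per molecule is the same
across species, and the activity under a probe spot is proportional to the
summed abundance of the species it captures.

The closed forms in `labeling_report()` quantify this. A spike of
`spike_uCi_per_ml` (default 10 µCi/ml) at specific activity
`specific_activity_Ci_per_mmol` (default 1 Ci/mmol) corresponds to a
molarity of spike/SA µmol/L — 10 µmol/L at the defaults. Against
`media_phosphate_mM = 22` (the phosphate content of an M9-style defined
medium) that is a **2200-fold isotopic dilution**; the spike's own
contribution to the pool (three orders of magnitude smaller) is neglected.
Each of a molecule's ≈`length` phosphates is then hot independently with
probability 1/dilution, so the label count is Poisson with
λ = length/dilution ≈ 0.035 for a 76-nt tRNA, and the probability of two
or more atoms, `1 − e^{−λ}(1+λ)` ≈ 6×10⁻⁴, is negligible: a molecule
carries at most one atom in practice, and counting statistics are the only
noise source the simulator needs.

## Probe design

**Window.** Probes are reverse complements of the 3′-terminal
`window_length = 70` nt of the mature body after removing the universal
terminal CCA (`exclude_terminal_cca = TRUE`); the CCA is shared by all
tRNAs and carries no discriminating information. Bodies shorter than the
window contribute their whole body. Catalog species store the CCA-less
body with a flag recording which form the input carried, so the exclusion
is applied exactly once even when a body happens to end in CCA.

**Mismatch metric.** Windows are compared 3′-anchored and ungapped: count
differing overlapped positions plus one per unpaired 5′ residue. Probes
hybridize the 3′ end, and nothing in the hybridization geometry suggests
gapped alignment; the metric is symmetric, zero iff identical, and is
tested against an independent brute-force oracle.

**Clustering.** Species differing at fewer than `mismatch_threshold = 8`
window positions cannot be discriminated at hybridization stringency and
are merged by single-linkage (connected components of the `< 8` graph):
any chain of near-identical isodecoders must share one probe, and
single-linkage is the simplest deterministic rule with that property. The
merge condition is strictly less-than — eight or more differences are
distinguishable — which is the reading under which 48 unique species
collapse onto exactly 42 probes. Raising the threshold can only merge
more, so the probe count is monotone non-increasing in it (a tested
invariant).

**Consensus.** Each cluster column becomes the IUPAC code of the union of
observed bases (shorter members are padded 5′ as fully degenerate); every
member window therefore matches the consensus position by position
(tested). The degenerate-position count is the number of ambiguous
columns.

**GC and Tm.** GC% scores ambiguity codes by their expected G+C fraction
under a uniform base choice (unbiased, and the only choice that keeps the
panel mean meaningful). Tm uses the salt-adjusted Marmur–Schildkraut–Doty
relation `81.5 + 16.6·log10([Na+]) + 0.41·GC% − 675/L` at
`sodium_molarity = 0.3` (2X SSC), documented as a composition-only formula
valid for oligos ≥ 14 nt and replaceable by anything fancier downstream —
the probe table carries plain sequences. On the synthetic panel it yields
a mean near 87 °C at mean GC near 57%.

**Audit.** Every probe × non-target species pair gets an IUPAC-aware
3′-anchored mismatch count; counts below the threshold are flagged as
cross-hybridization risks. On well-separated panels the audit is empty.

## Array geometry and image formation

`build_layout()` places `replicates = 8` contiguous spots per probe
row-major on a `grid_cols = 24` grid at `pitch_um = 600` center-to-center
with `diameter_um = 300` spots — 336 spots for a 42-probe panel. The
layout is a pure function of its inputs, so the GAL-like TSV (written in
binary mode with fixed 0.1 µm formatting) is byte-identical across runs; a
seeded `shuffle_seed` scatters replicates for robustness experiments.

`render_array()` models the phosphor screen readout as: expected counts
per pixel = `background_rate` (default 2 counts/pixel) + for each spot its
mass `exposure_scale × signal` spread as a symmetric 2-D Gaussian
(`psf_sigma_um = 75`, i.e. 1.5 pixels at the 50 µm scanner resolution),
integrated exactly over each pixel with separable normal-CDF differences.
Realized counts are Poisson with the seed in `sim_params` — pure counting
statistics, no saturation model (real protocols adjust exposure time
instead, and `exposure_scale` is exactly that dial; the default 5×10⁵
puts typical spot masses at ~10⁴ counts, i.e. percent-level Poisson
error). The Gaussian spot is the simplest morphology that exercises the
integration and background code; comet tails, scratches and grid rotation
are deliberately out of scope. A pitch of 8 pixels with a 3-pixel
quantification radius keeps neighboring spots ≥ 4σ away from each other's
background annuli.

## Quantification

* **Registration**: integer-pixel translation maximizing total in-disk
  intensity over a `search_px` window; ties broken by smallest |dx|+|dy|
  then lexicographically, so featureless images register at the origin.
  Manual gridding has no published model; translation-only is the minimal
  correction.
* **Spot measurement**: raw = pixel sum over a disk of `radius_px = 3`;
  background level = median of the annulus between 1× and
  `annulus_factor = 2`× the radius. The local annulus median is robust to
  neighboring-spot leakage and flat offsets (adding a constant to the
  image leaves every net signal unchanged — a tested invariant). Net
  signal is clamped at zero: negative radioactivity is unphysical, at the
  documented cost of a small positive bias on empty spots.
* **Replicates**: median of the eight replicate net signals after flagging
  values more than 3 scaled MADs from the replicate median; an all-flagged
  probe is an error rather than a silent zero.
* **Normalization**: percent of total over all probes, making profiles
  from different exposure times directly comparable. Scaling the whole
  image leaves the profile unchanged.

Because the disk captures a fixed fraction of every spot's Gaussian mass
and the annulus over-subtracts the same fraction everywhere, these biases
cancel in percent-of-total; the noiseless simulate→quantify loop recovers
ground-truth probe levels to ~10⁻⁵ percentage points, and the
Poisson-noise path shows a mean absolute relative error well under 1% at
default gain (measured in `scripts/acceptance.R`, 42 probes × 8 replicates
× 10 seeds).

## Downstream analytics

Replicate statistics report per-probe median/SD/CV across arrays; the CV
is the "false change" scale — the apparent fold change technical error
alone can produce. Class fractions sum levels by size class (class II =
Leu, Ser, SeC, Tyr acceptors; the 74–77 nt vs 85–93 nt length ranges are
used only as a consistency check, since 78–84 nt is undefined, and a
disagreement warns rather than overrides). Fold changes are level ratios
with zero-control entries reported as undefined rather than infinite.
Copy-number and operon views divide levels by the total gene copies behind
each probe and group genes by operon label.

**Codon-usage correlation.** A species decodes the sense codons whose
first two bases Watson–Crick pair anticodon positions 36–35 and whose
third base is readable by the wobble base (position 34) under the Crick
rules — G34→{C,U}, C34→{G}, U34→{A,G}, A34 treated as inosine →{U,C,A} —
overridable per base, since modified wobble nucleosides can deviate. A
codon's usage is split equally among all its decoders, the simplest rule
that conserves total usage mass (a tested invariant); winner-takes-all is
provided for sensitivity analysis. The correlation statistic is squared
Pearson between percent levels and per-probe summed effective frequency,
with the SeC probe excluded by default (UGA readthrough is
context-dependent, not routine decoding). Profiles constructed
proportional to the effective frequency recover R² = 1 through the full
simulate→quantify loop.

## The synthetic gene set: what it does and does not show

`synthetic_ecoli_catalog()` generates a gene set with the census structure
of the E. coli K-12 tRNA complement: 86 genes, 48 unique species, 40
anticodon families, copies 1–6 per species, class II sizes for the
Leu/Ser/SeC/Tyr acceptors, six isodecoder groups at 1–5 window mismatches
(initiator and elongator Met kept far apart, as are the two probe-split
Ser-TGA isodecoders), loci scattered over a 4.64-Mb chromosome, and 14
genes of 6 species labeled as members of mixed tRNA/rRNA operons. Sequence
bodies are random at 57% GC — the generator emulates the *census*, not the
real sequences, and is labeled synthetic throughout.

Consequently, passing tests show that the pipeline's combinatorics
(86→48→40→42, six degenerate probes), its physico-chemical summaries
(panel GC/Tm means), and its measurement chain (truth recovery through
simulated images) behave correctly. They do not validate biological
quantities: measured class fractions, per-species abundances, the 15-fold
abundance spread, overexpression folds, or free-vs-polysomal codon-usage
R² values all depend on physical samples and real sequences. The package
reproduces the *computations* behind those results on synthetic stand-ins.

Ground-truth abundance draws default to log-normal with `sdlog = 1`
(normalized), giving a realistic max/min spread above 10-fold across 48
species; `sdlog = 0` gives the uniform profile used in calibration tests.

## Numerical choices and degenerate inputs

Deterministic ordering everywhere: species sort by amino acid, anticodon,
then sequence; clusters by first member; layouts row-major. Empty FASTA,
non-matching headers, genes under 70 nt, non-ACGT bodies, empty annuli,
all-zero profiles, all-flagged replicates, zero-variance correlation
vectors and malformed layout files are all hard errors naming the
offender; zero-control fold changes and codons decoded by no species are
soft (NA / warning), since both occur in legitimate data. All simulation
and sampling entry points take explicit integer seeds; fixed seeds give
bit-identical images and catalogs. Problem sizes in the test-suite and
acceptance runs (42 probes × 8 replicates, ~300×180-pixel images, 10
noise seeds) were chosen as the smallest sizes at which panel census,
recovery error and invariants are all meaningfully exercised.

## Known limitations

No nearest-neighbor duplex thermodynamics or hybridization kinetics; the
mismatch threshold is a proxy for stringency, not a free-energy model. No
intron handling (the target complement is intron-less) and no
posttranscriptional-modification effects on hybridization. Registration
is translation-only and integer-pixel. The simulator's PSF width at 50 µm
scanning is a configurable guess (`psf_sigma_um`), not a measured
instrument property. Mammalian-scale panels (many more isodecoders) are
not forbidden by the design code but have no fixtures here.
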