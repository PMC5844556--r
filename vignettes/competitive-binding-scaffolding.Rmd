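---
title: "Scaffolding contigs on competitive-binding optical DNA maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding contigs on competitive-binding optical DNA maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbscaffold)
```

# The problem

Competitive-binding optical DNA mapping stretches single DNA molecules in
nanochannels after staining with two competing ligands: the fluorescent
intercalator YOYO-1 and the non-fluorescent, AT-specific minor-groove binder
netropsin. Netropsin displaces the dye from AT-rich tracts, so the recorded
fluorescence profile along the molecule — its *barcode* — reflects local
sequence composition at roughly kilobase resolution. Because the barcode of
a sequence can also be predicted from theory, optical maps can anchor
sequence contigs from a shotgun assembly: a contig whose predicted barcode
matches a unique stretch of the experimental consensus barcode of, say, a
plasmid can be placed there, ordered and oriented without any further
sequencing. This package implements that scaffolding method end to end for
circular references (plasmids), together with a synthetic-data module that
generates every input needed for calibration studies.

The pipeline has four stages, each exposed as ordinary functions:

1. **Theory barcodes** (`sequence_to_barcode()`): per-basepair YOYO-1
   binding probabilities from a two-ligand lattice equilibrium, blurred by
   the optical point spread function and sampled at pixel resolution.
2. **Match scores** (`sliding_pearson()`): Pearson correlations of the
   contig barcode against every circular window of the reference, in both
   orientations.
3. **P-values** (`null_fit_for()`, `score_to_pvalue()`): the maximum match
   score of each contig is calibrated against autocorrelation-matched
   random barcodes scored the same way.
4. **Placement** (`build_bids()`, `solve_auction_exact()`): significant
   positions become interval bids with score $-2\log p$, and an exact
   combinatorial-auction dynamic program maximizes the summed score under
   the constraints that each reference pixel is sold at most once and each
   contig is placed at most once.

# The binding model

DNA is modelled as a 1-D lattice of basepairs. A bound ligand of species
$s$ covers `footprint` consecutive basepairs (4 by default for both
species, matching the tetramer parameterization of netropsin specificity)
and contributes a statistical weight $K_s(i)\,c_s$, where $K_s(i)$ is the
binding constant for the site starting at basepair $i$ and $c_s$ the free
ligand concentration. YOYO-1 uses a single constant ($26\,\mu M^{-1}$ by
default); netropsin uses a per-4-mer table, strand-symmetrized because a
ligand cannot tell the two strands apart. No ligand–ligand cooperativity is
modelled. The partition function over all non-overlapping placements is
computed by the standard sequential transfer-matrix recursion
(`src/lattice.cpp`), forward and backward, giving per-start placement
probabilities in $O(L)$; circular molecules are handled exactly by
conditioning on the content of one cut (no ligand crosses it, or a specific
wrapped placement does). The recursion is verified against brute-force
configuration enumeration to $10^{-10}$ on random lattices in the test
suite.

The package ships a *synthetic* netropsin table
(`extdata/netropsin_constants_synthetic.tsv`): $\log K$ rises linearly with
the AT count of the 4-mer, from $0.5$ to $150\,\mu M^{-1}$. This is a
documented stand-in — measured tables in the same two-column text format
drop in via `read_binding_constants()`. Default concentrations
($0.5\,\mu M$ YOYO-1, $6\,\mu M$ netropsin, $0.4\,\mu M$ basepairs of DNA)
are of the magnitude used in mapping experiments; all are configurable in
`ligand_params()`.

Free (unbound) concentrations are not the totals: binding depletes both
ligands. `free_concentrations()` solves the mass balance
$c_{\mathrm{tot}} = c_{\mathrm{free}} + n(c_{\mathrm{free}})\,c_{\mathrm{DNA}}$
for both species simultaneously by an adaptively damped fixed-point
iteration (relative tolerance $10^{-9}$, at most 200 iterations, failure is
an error reporting residuals). Because the DNA concentration is small
relative to ligand totals, the iteration typically converges in fewer than
ten steps.

## Optics

The binding probability vector is convolved with a Gaussian kernel of
standard deviation $\sigma$ (default $1000$ bp, the scale of the optical
point spread function). Circular profiles use exact wrap-around convolution
(which conserves the mean); linear profiles renormalize the kernel at the
ends so the kernel mass in use always sums to one. The smoothed profile is
then interpolated at pixel centers (default 500 bp/px; block averaging is
available as an option — for any locally linear signal both give the same
values; the pixel scale itself varies between instruments and is a
configuration knob).

# Match scores and p-values

Contig barcodes slide along the circular reference at integer pixel
offsets, forward and reversed, giving $2x_{\max}$ Pearson coefficients
$C_{n,x}$ per contig; $\hat C_n = \max_x C_{n,x}$. Windows are precomputed
as z-scored rows of a matrix so that scoring one contig — or a thousand
random barcodes — is a single matrix product. Degenerate (zero-variance)
windows score 0 by convention rather than NaN.

A high $\hat C$ alone is not evidence: short or smooth barcodes reach high
maxima by chance. Significance is therefore calibrated per contig length:
$R = 1000$ random barcodes with the contig's autocorrelation are scored
against the same reference, and a parametric density is fitted to their
maxima. Two choices here deserve explanation:

* **Null generator.** Barcodes are smooth because of the PSF, whose shape
  is known; their autocorrelation is Gaussian in the lag,
  $\rho(k) = e^{-k^2/(4\sigma_{px}^2)}$, not exponential. The pipeline
  therefore generates Gaussian-kernel-filtered white noise matched to the
  contig's lag-1 autocorrelation (`method = "kernel"`); the AR(1)
  construction is also available and is the default of the exported
  `generate_random_barcodes()`. On short contigs the sample lag-1 estimate
  is biased low (a 26-px smooth series underestimates 0.94 by ~0.1), so the
  pipeline floors the estimate at the PSF-implied value
  $e^{-(\mathrm{bp/px} / \sigma)^2/4}$ — an instrument property, not a
  tuning constant. Without the floor, short-contig nulls are too rough and
  their p-values anti-conservative by an order of magnitude.
* **Parametric form.** `fit_null()` fits the classical form for the
  maximum of $n_{\mathrm{eff}}$ effective independent Pearson coefficients
  of $\nu_{\mathrm{eff}}$ effective samples,
  $F(\hat c) = G(\hat c;\nu_{\mathrm{eff}})^{n_{\mathrm{eff}}}$ (with a
  Gumbel baseline for comparison), which recovers its own parameters and
  quantiles well and is reported for diagnostics. However, fitted to
  maxima of *smooth* barcodes its right tail is systematically too heavy:
  fresh null barcodes then pass $p < 0.01$ at rates of $10^{-3}$ or less,
  breaking the method's contract that the threshold controls the error
  rate. The p-value tail is therefore taken from a generalized
  extreme-value fit to $\operatorname{atanh}\hat C$ — the natural limit
  family for maxima, whose negative shape parameter captures the sharp
  upper edge. With it, $P(p < \alpha) \approx \alpha$ holds at
  $\alpha \in \{0.01, 0.05\}$ on fresh nulls, which the test suite asserts.
  If the GEV fit fails, `score_to_pvalue()` falls back to the CDF-power
  form.

Fits are cached by (length in pixels, autocorrelation rounded to two
decimals); a cache belongs to one reference barcode and can be serialized
to JSON. P-values are floored at $10^{-15}$ so the Fisher transform
$-2\log p$ stays finite.

Contigs shorter than $\ell_{\mathrm{thresh}} = 12\sigma \approx 12$ kbp are
discarded before any of this: below a dozen PSF widths a barcode carries
too little spatial information for the null to be meaningful, and in
practice such contigs cannot reach significance anyway.

# The placement auction

Every position/orientation with $p < p_{\mathrm{thresh}}$ (strict, default
0.01) becomes a bid $b_{n,x} = -2\log p_{n,x} > 0$ for the interval of
pixels the contig would occupy; natural logarithms, in the spirit of
Fisher's method for combining p-values. The optimization maximizes the
summed score of accepted bids subject to: no pixel sold twice, no bidder
winning twice. `solve_auction_exact()` is an exact dynamic program that
sweeps bid end-positions in increasing order; its state is the subset of
already-served bidders among those currently *relevant* (between their
first and last bid ends). Positions without ending bids cost nothing, and a
bidder leaves the state as soon as no future bid of theirs exists, so the
bitmask stays narrow when bids cluster — the expected cost is
$A B^2 2^C$ with $A$ the number of active bidders, $B$ the bid-carrying
pixels and $C$ the maximum simultaneous relevance
(`estimate_complexity()`). Instances that would need more than
`max_mask_bits` (default 20) simultaneous bidders raise an "instance too
entangled" error rather than degrade to a heuristic. Circular references
are solved exactly by conditioning on the cut between the last and first
pixel: either no interval crosses it, or one specific wrapping bid does.
Equal-score optima resolve to the lexicographically smallest (bidder,
end-pixel, forward-first) set, so results are reproducible. The solver is
validated against exhaustive search (`brute_force_auction()`) on hundreds
of random instances.

# Synthetic data and what it does (not) show

`random_genome()`, `cut_contigs()`, `pseudo_experimental_barcode()` and
`mixed_sample()` generate every input from seeds:

* genomes are i.i.d. bases at a chosen GC content;
* contigs tile the genome with inter-cut distances from an exponential
  distribution truncated at the genome length (mean 24.5 kbp by default,
  the scale of real short-read assemblies of plasmid-bearing samples),
  random orientations, and a recorded truth table;
* pseudo-experimental reference barcodes are the theory barcode plus
  additive stationary Gaussian noise (`noise_sd`, default 0.3 in
  z-normalized units) whose lag-1 correlation defaults to the PSF-implied
  pixel value, i.e. the noise has passed the same optics as the signal.

The calibration studies (`calibrate_misallocation()`,
`calibrate_pure_scaffold()`, `calibrate_foreign_rejection()`) reproduce the
method's statistical contracts on this synthetic world: misallocations of
independently placed contigs near the 1% threshold rate, correct/placed
ratios near 99% for the full pipeline on pure samples, and foreign contigs
passing at about the threshold rate. Problem sizes are chosen to finish on
a single desktop core: a 138-kbp reference with 250 contigs per length for
misallocation, a 220-kbp reference with 30 replicate cut plans at four mean
contig sizes for the pure-sample study, and a 2-Mbp foreign genome cut 30
times for rejection; the test suite runs the same studies at reduced
replicate counts with binomial tolerances widened accordingly.

What passing these simulations does *not* show: real consensus barcodes
carry stretch-factor variability, photophysics (bleaching, camera noise
with non-Gaussian tails), and alignment artifacts from the kymograph stage,
none of which are modelled; real genomes have repeats and compositional
structure that i.i.d. sequences lack, which makes the synthetic placement
problem slightly easier at a given noise level; and the bundled binding
constants are synthetic, so absolute barcode shapes will not match
laboratory profiles until a measured table is supplied.

# Numerical choices and degenerate inputs

* Lattice partial partition functions are kept as mantissa/exponent pairs
  in powers of $2^{256}$, so megabase molecules neither overflow nor cost
  transcendental calls per basepair.
* The free-concentration iteration starts undamped and halves its step
  whenever the residual grows; non-convergence is an error, never a
  warning.
* Zero-variance barcodes or windows: windows score 0 silently (flagged in
  `reference_windows()`), a zero-variance contig scores 0 with a warning,
  and a zero-variance input to `estimate_autocorrelation()` or
  `fit_null()` is an error.
* Ambiguity codes in FASTA input are rejected by default; an explicit
  policy resolves them by seeded uniform draws from the compatible bases.
* All stochastic components derive 31-bit substreams deterministically
  from one master seed and a string key, so whole-pipeline runs are
  byte-reproducible.

# Known limitations

Only integer-pixel offsets are scored — no sub-pixel interpolation and no
local stretch correction, so placements are accurate to a pixel at best
(the default "correct placement" tolerance is 5 px, and both stricter and
looser counts are available from `correct_placement_ratio()`). The null
model treats the reference as fixed; references assembled from very few
molecules would add reference-side noise that the calibration studies only
emulate through `noise_sd`. The false-pass rate also inherits some
reference-realization variability — sequence-derived barcodes can correlate
slightly better with a particular reference than Gaussian random barcodes
do — so the threshold should be read as controlling the error rate's order
of magnitude, not its second decimal. And the auction guard refuses pathologically
entangled instances rather than solving them approximately; such instances
did not arise in any simulation here, but extremely permissive thresholds
on repeat-rich references could produce them.
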