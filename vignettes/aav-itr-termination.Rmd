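---
title: "Methods: quantifying AAV packaging termination at ITRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying AAV packaging termination at ITRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavterm)
```

# The multimer species model

AAV packaging is coupled to replication: concatemeric replication
intermediates present a ladder of single-stranded genome species to the
capsid, and packaging that starts at the origin ITR may terminate at any
downstream ITR. A species with $N$ ITR junctions carries $N-1$ gene copies
and has length

$$L(N) = N\,I + (N-1)\,G, \qquad G = \text{unit length} - 2I,$$

where $I$ is the nucleotide contribution of one ITR junction and $G$ the
internal gene segment. The packageable set is $\{N \ge 2 : L(N) \le
\text{capacity}\}$; the empty capsid is carried alongside as the zero-genome
pseudo-species.

**Why $I = 130$ and not 145.** A complete AAV ITR is 145 nt, but the
observed multimer ladders (848 → 1,566 → ... and 1,320 → 2,510 → ...) have a
constant increment of $\text{unit length} - I$ that forces $I = 130$ in both
cases. The likeliest explanation is a convention about which part of the
terminal repeat is counted at an internal junction (e.g. a D-sequence
convention), but no authoritative value exists, so $I$ is a plain parameter
defaulting to 130; the pipeline logs a notice whenever it differs from 145.
We deliberately do not guess a mechanism.

**Capacity.** The canonical rAAV limit is ~5.2 kb, but the effective cutoff
is preparation-dependent: the 848-nt construct's observed ladder stops at
6 species (4,438 nt), which requires a cutoff below 5,156 nt, while the
1,320-nt construct's 4 species are consistent with 5,200. Capacity is
therefore per-construct configuration (presets: 4,700 and 5,200 nt), not a
physical constant of the package.

**Restriction collapse.** `digest_to_units()` models the diagnostic digest
that collapses multimers to unit-length bands: one cut at the midpoint of
each *internal* ITR yields exactly $N-1$ unit-scale fragments whose lengths
sum to $L(N)$. This is deliberately simplified geometry — real sites sit
asymmetrically within the ITR and terminal fragments differ by half an ITR —
sufficient to reproduce the "only unit-length bands" observation.

# The mass model

Predicted particle mass is $M(N) = M_\text{capsid} + L(N)\, m_\text{nt}\,
c$:

* $M_\text{capsid}$: the 5:5:50 VP1:VP2:VP3 stoichiometry-weighted subunit
  sum. Subunit masses are **required** inputs (a silent default would hide a
  megadalton-scale assumption); `aav8_capsid_preset()` provides approximate
  sequence-based AAV8 values (empty capsid 3.7295 MDa).
* $m_\text{nt} = 308.9$ Da/nt: mean ssDNA residue mass (free-acid form).
  Sequence-exact masses are out of scope; the error is $\ll$ the mass
  windows.
* $c = 1.04$: the counterion correction. Measured packaged-genome masses run
  around 4% above bare-sequence predictions, attributed to bound salt
  counterions; the factor is applied to the DNA term only (the capsid is not
  salt-inflated) and scales with genome length alone — whether part of the
  excess tracks capsid surface is unknown, and we implement the simplest
  reading.

**Assignment windows.** Each species gets the window $M(N)\,(1 \pm w)$ with
$w = 2.5\%$ by default, clipped at the arithmetic midpoint of adjacent
predicted masses when windows would overlap. For a ~718-nt ladder step
(~0.23 MDa on a 4–5 MDa particle) and instrument-typical mass spread,
$w = 2.5\%$ keeps adjacent windows separated through the middle of the
ladder and degrades gracefully (midpoint partition) at the top. The window
bound choice is a convention — published spectra shade the ranges without
stating how they were bounded — so $w$ is configuration with this documented
default.

# The CD-MS simulator

`simulate_ions()` emulates single-ion charge-detection acquisition:
$\ge 10^4$ ions per dataset, a measured charge with additive Gaussian error
(presets: $\sigma_z = 1\,e$ "standard", $0.5\,e$ "high-resolution" — the two
trapping modes), and a measured m/z with multiplicative error
($\text{cv} = 0.002$). Derived mass is the product of the two measurements.

**Charge model.** All species share one true-charge law,
$z \sim \mathcal N(155, 3)\,e$. The shared mean encodes the empirical
observation that fully packaged particles of different genome length carry
similar charge (DNA inside the capsid barely changes the surface); 155 e is
realistic for ~4 MDa electrosprayed particles but is a free parameter — no
charge values are published for these ions — and it cancels out of every
abundance estimate. The spread (3 e) also cancels exactly in derived mass
because the true m/z compensates the drawn charge; it exists so simulated
charge data look like charge data.

**The "partial" component.** Real preparations contain capsids with DNA of
intermediate, model-unassignable mass; in mass histograms these are the gray
regions *between* the species windows, and published subpopulation tables
quantify them implicitly (the listed species shares do not reach 100%).
`mixture_spec()` therefore completes any mixture summing to $<1$ with a
reserved `"partial"` component, and the simulator draws partial ions'
**measured** masses uniformly over the inter-window gaps. Because "partial"
is phenomenologically defined by where it lands in the spectrum, this is the
faithful emulation; drawing *true* masses in the gaps and adding noise
would leak ~40% of partials into adjacent species windows and distort the
very shares the generator is meant to realize. The cost is that the
simulator cannot probe how a *specific* truncation-length distribution maps
into gray regions — it does not model truncation physics at all.

**Resolution conventions.** The instrument's nominal "mass resolution of
100" at $\sigma_z = 1\,e$ sits between the two common conventions at our
defaults: with mean charge 155 e the relative mass s.d. is
$\sqrt{(\sigma_z/\mu_z)^2 + \text{cv}^2} \approx 0.68\%$, i.e.
$M/\sigma \approx 148$ but $M/\text{FWHM} \approx 63$.
`estimate_resolution()` reports the conventional $M/\text{FWHM}$; the test
suite checks the simulation against the closed form within ±30% and the
closed form against the nominal 100 within a factor of two, rather than
forcing agreement to a number whose convention is unstated. No generator
default was tuned to a test.

**What a green test does not establish.** The simulator draws species ions
at *exactly* the predicted mass (no species-internal mass heterogeneity),
uses Gaussian errors with no drift, tails, or charge quantization, and
treats partials as spectrum-defined. Green round-trip tests therefore
establish that the quantification machinery is consistent and unbiased
*under the model's own assumptions* — not that the model captures every
instrumental artifact of real acquisitions.

# CD-MS quantification

Ions are assigned by window containment on raw derived masses (binning is
display-only and never affects estimates). Deterministic tie-break: a mass
exactly on a shared clipped boundary goes to the lower-mass species —
measure-zero under noise, but reproducible. Ions below half the
empty-capsid mass or above the top window +10%, or in gaps, are counted as
unassigned, never dropped: count conservation (assigned + unassigned =
total) is asserted for every input. With midpoint-clipped windows,
containment assignment coincides with nearest-predicted-mass assignment
wherever an ion is inside any window (tested against that brute-force
oracle). Relative abundances are shares of *all* ions, matching the
convention of published subpopulation tables; rounding to the mixed one/two
decimal display convention happens only at rendering.

The elevated-charge screen flags any filled species whose mean measured
charge exceeds the empty-capsid mean by more than 3 combined standard
errors (one-sided — only *elevated* charge suggests DNA trailing outside
the capsid). Under the shared-charge model nothing is flagged; a spiked
+20 e species is (both tested).

# The gel arm

`simulate_lane()` renders discrete bands as Gaussians at
$\text{position} = a - b\log_{10} L$ ($a = 100$, $b = 55$ — arbitrary
documented units; the 848-ladder lands at negative positions, which is
harmless since the axis is unanchored), areas proportional to
mass-intensity fractions, plus additive noise (s.d. 0.002 on a lane of unit
total band area, ~2% of a dominant band's peak height — a realistic
densitometry floor chosen once). `quantify_bands()` integrates
baseline-subtracted signal in ±2 band-sigma windows around expected
positions, midpoint-clipping overlaps; the baseline is the median off-window
signal (robust, parameter-free), and a lane whose in-window mean signal
nowhere exceeds 5× the off-window noise floor raises an explicit no-bands
error.

**Accuracy limits.** For well-separated ladders (the 1,320 construct) the
zero-noise round trip recovers fractions to <0.15 points. The top of the
848 ladder is crowded (4.2 position units ≈ 2.8 band-sigma between the last
two bands), and window clipping cross-talk caps zero-noise accuracy near
0.5 points there; with default noise, 100-replicate worst-case error stays
under 2 points. A linear least-squares fit of known band shapes would
remove the cross-talk, but window integration is retained as the method
that mirrors how gel ladders are actually quantified. ITR-containing
fragments are known to migrate anomalously; this is acknowledged and not
modeled — expected positions are taken as exact.

`molar_correct()` converts mass-intensity shares to molar shares
(divide by length, renormalize). It is OFF by default everywhere because
published gel percentages are raw-intensity shares; the correction is
self-inverse (tested).

# Termination statistics

The species with $N$ ITRs terminated at sequential ITR $k = N - 1$ (the
packaging-origin ITR is never a terminator). The termination profile is the
packaged-species abundance vector normalized over its own total — empty
capsids and unassigned/partial ions are excluded from the denominator,
which is the convention that reproduces published per-ITR percentages from
published subpopulation tables. Profiles are scale-invariant; entry ratios
equal raw-abundance ratios. When the input is ion counts, multinomial
standard errors $\sqrt{p_k(1-p_k)/n}$ are attached. Cross-method agreement
is summarized by per-ITR absolute differences and total variation distance
$\tfrac12\sum_k |p_k - q_k|$.

# Pipeline, determinism, degenerate inputs

Every stochastic stage takes a mandatory integer seed; identical config and
seeds give byte-identical outputs (tested). Stage CSVs carry a header
comment with a 32-bit FNV-1a config fingerprint and the stage seed. The
JSON config is schema-validated at load with field-level error messages.
Degenerate inputs fail loudly and specifically: empty ion sets, all-zero
abundance vectors, zero-length fragments, sub-unit capacities, bandless
lanes, malformed CSV rows (with row number), unknown mixture labels.

# Known limitations

* The effective ITR junction length and the per-construct capacity are
  conventions fitted to observed ladders, not mechanistic quantities.
* Partial packages are spectrum-defined; truncation physics is not modeled.
* Mean ion charge is unanchored by published data (it cancels from all
  reported quantities).
* Gel migration anomalies of ITR-containing fragments are not modeled.
* The quantifier is window integration by design; mixture-model fits
  (CD-MS) and band-shape regression (gel) are out of scope.
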