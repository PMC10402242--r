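---
title: "Models and methods in nativeTDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nativeTDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativeTDP)
```

# The problem and the data model

Native electrospray of a non-denatured protein assembly of neutral mass
$M$ produces ions at

$$ m/z = \frac{M + z\,p}{z}, \qquad p = 1.0072765\ \mathrm{Da}, $$

over a narrow set of low charge states $z$. Collisional activation (HCD)
of an isolated charge state ejects a monomer that carries a
disproportionate share of the charge; a second activation stage fragments
the monomer into b/y backbone ions. `nativeTDP` identifies the
**complexoform** — the exact multiset of proteoforms plus metal cofactors —
that explains the MS¹ mass, and characterizes each subunit from the MS³
evidence.

Three S4 classes carry the data: `Proteoform` (processed sequence,
terminal/site modifications, disulfides, truncation record), `Complexoform`
(subunit multiset + metal counts) and `Spectrum` (centroided peaks with
MS level and precursor linkage). Modifications are registry entries
(`modDelta()`); compositions are plain named count vectors so that all
mass arithmetic reduces to one code path (`compositionMass()`).

# Mass conventions

* **Monoisotopic masses are the primary matching currency**; average
  masses are computed alongside and selectable (`massType = "avg"`)
  everywhere a theoretical mass is compared to an observation. Species in
  the size range handled here are isotopically resolvable on modern
  Orbitrap instruments, and a single convention keeps error bookkeeping
  interpretable. The deconvolver reports one experimental neutral mass; it
  is the caller's choice which theoretical mass to match it against.
* The **monoisotopic mass of an element is the mass of its most abundant
  isotope** — for Cu and Zn this is not the lightest isotope.
* A bound metal cation **displaces protons on the neutral species**
  (divalent: 2, configurable per call), so the adduct delta is
  $m_\mathrm{metal} - n_H \cdot 1.0078250$ and the observed charge stays
  equal to the protonation count. This is the standard native-MS
  bookkeeping; nothing else in the engine depends on it, so a different
  convention can be injected through `metalAdductDelta(displaced = )`.

# Isotope distributions

`isotopeDistribution()` convolves per-element isotope vectors (binary
exponentiation over atom counts) and aggregates into **nominal-mass bins**
(isotopologues whose masses round to the same integer merge into an
abundance-weighted centroid). Validation overlays in this field are read
at isotopic, not hyperfine, resolution, and unit-resolution aggregation
keeps the distributions small and stable. Intermediate convolutions are
floored at $10^{-12}$ relative abundance to bound memory; the user-facing
`prune` threshold is applied once at the end, followed by renormalization
to sum 1.

`averagineComposition()` scales the averagine unit
(C~4.9384~H~7.7583~N~1.3577~O~1.4773~S~0.0417~, 111.1254 Da average) to a
target mass, rounds the heavy elements and balances with hydrogens so the
**monoisotopic** mass (default; `type = "avg"` selects average) lands
within half a hydrogen of the target — envelope fitting anchors on the
monoisotopic peak position, so that is the quantity worth pinning.

# Charge inference and deconvolution

For two adjacent peaks of one species at consecutive charges,
`inferChargePair()` applies
$z_\mathrm{low} = \mathrm{round}\!\big((mz_\mathrm{low} - p)/(mz_\mathrm{high} - mz_\mathrm{low})\big)$
and rejects solutions whose rounding deviation exceeds 0.15 charge units.

`deconvolveSeries()` is intentionally minimal — native MS¹ spectra of
SEC-fractionated samples contain few, well-separated envelopes, and full
spectral deconvolution engines are out of scope. It is greedy and
intensity-first: at the most intense unexplained peak every charge
hypothesis up to `maxCharge` is tested by walking to neighboring charges;
the accepted hypothesis maximizes member count, then **prefers the higher
charge**, then the lower RMS residual. The higher-charge tie-break exists
because a $z/2$ sub-harmonic explains the alternate (even-charge) peaks of
a true series with zero residual; the true $z$ explains at least as many
peaks, so it wins whenever the data cannot refute it. Series need at
least two members — a lone peak is charge-ambiguous and is returned among
the leftovers rather than guessed. The per-peak neutral-mass consistency
tolerance `tolDa` should sit at several sigma of $z \cdot \sigma_{m/z}$;
the pipeline default of 1 Da matches the low-noise regime the engine
targets.

# The complexoform search

`expandSearchSpace()` enumerates candidate proteoforms per protein as
sequence variants (full, Met-cleaved, explicit truncations) × N-terminal
modification options × modification count multisets. Counts, not
positions: intact mass cannot distinguish positional isomers, so
**matching happens at mass level with unlocalized modifications** and
localization is deferred to fragment evidence. The expansion is capped
(default $10^6$, with the offending protein named on overflow).

`enumerateCandidates()` walks subunit multisets over the mass-sorted
proteoform list with partial-sum pruning, adds every allowed metal
submultiset, and keeps combinations within ±`tol` (default 1 Da, applied
at the complex level; a per-subunit check can be emulated by searching
monomer masses) of the observed mass. Correctness is defined — and tested
— against an exhaustive brute-force oracle. Ranking is by absolute error
with ties broken by fewer modifications, fewer metals, then label;
candidates whose theoretical masses lie within `ambigTol` (default
0.05 Da) of each other form an **ambiguity set sharing a rank**, because
differences such as trimethyl vs acetyl (0.0364 Da) are below realistic
intact-mass accuracy at tens of kDa. All candidates are reported; there is
no silent winner-takes-all.

# Fragment evidence

`generateByLadder()` emits neutral monoisotopic b/y ladders. With intact
disulfides (default), cleavage sites strictly inside a loop yield no
fragments and fragments spanning a whole loop carry its −2.01565 Da; a
`"reduced"` mode ignores disulfides. When metals are supplied each
fragment also appears in holo forms carrying metal submultisets (≤ 2 by
default), reflecting **all-or-none retention** during HCD; partial
scrambling is not modeled. Only b/y series are generated — the engine
models beam-type collisional activation, which produces these
predominantly; c/z and a/x ions of other activation modes are out of
scope.

Matching (`matchFragments()`) is one-to-one in ascending |ppm| with apo
preferred on exact ties, in neutral-mass space: fragment spectra are
assumed decharged/deisotoped upstream (the simulator renders fragments
singly protonated; `fragmentCharge` in the pipeline config controls the
decharge assumption). Tolerance is in ppm (default 10, the Orbitrap
norm).

## The P-score

With acceptance windows of half-width `tolPpm` around each of the $T$
theoretical fragments inside an observed mass window $W$, a uniformly
placed observed mass hits some window with probability

$$ q = \min\!\Big(1,\ \sum_{f=1}^{T} \frac{2\,\mathrm{tol} \cdot 10^{-6} m_f}{|W|}\Big), $$

summed without overlap correction (overlaps only make $q$ an
overestimate, hence the score conservative). The P-score is the Poisson
tail $P(X \ge n_\mathrm{matched})$ at $\lambda = n_\mathrm{obs}\, q$;
`n_matched = 0` scores 1. The analytic form is validated against a
Monte-Carlo null and its false-positive rate is checked to stay within
1.5× the nominal level at $\alpha \in \{0.05, 0.01\}$.

## Localization, levels, metal sites

A modification is localized to site $s$ by **bracketing**: left-boundary
evidence (unshifted $b_{s-1}$ or shifted $y_{n-s+1}$) together with
right-boundary evidence (shifted $b_s$ or unshifted $y_{n-s}$); a
terminus substitutes for a missing boundary. Several supported sites are
reported as an ambiguity set — never an arbitrary pick — and $k$ copies of
the same modification with exactly $k$ supported sites localize one copy
per site. Accidental isobars within the ppm window can make a wrong site
bracket-consistent on dense ladders; the engine then reports the ambiguity
set (which, by construction of the evidence rules, contains the true
site) rather than a false exclusive call. Simultaneous localization of
several *interacting* unplaced modifications is not attempted; each is
assessed against the ladder of the localized ones.

Characterization levels follow the standard graded taxonomy: **1** all
modifications localized under significant fragment evidence
($P \le \alpha$, default $10^{-4}$); **2A** modification identified by
mass shift but not localized; **2B** near-isobaric candidate ambiguity;
**3** modification count uncertain; **4** protein but not proteoform;
**5** mass-only observation.

Metal binding sites: a holo $b_i$ implies *all* coordinating residues of
that metal lie in $1..i$, so the smallest holo b index bounds the
coordinating set from above, and symmetrically the smallest holo y index
bounds it from below at $n - j + 1$; the reported interval is the
intersection of these all-residue bounds and therefore **contains the full
coordinating set** on correct data. Apo-only fragments carry existence
constraints (at least one coordinating residue beyond the fragment); they
cannot tighten a containment interval for a multi-residue site — an
apo-only bound pins only the last coordinating residue — so they are used
as consistency checks, and contradictory evidence (e.g. holo $b_{10}$
with apo-only $b_{20}$) flags the metal inconsistent.

# Isotope validation

`fitIsotopes()` charges a theoretical distribution into m/z space, pairs
isotopologues with the nearest centroids within `mzTol` (unmatched
isotopologues count as zero-intensity), chooses the intensity scale by
least squares and scores $1 - \mathrm{NRMS}$ (RMS residual over the scaled
base peak, clamped to $[0,1]$). The choice of metric is a package
decision — visual overlay practice has no quantitative standard — so
cosine similarity and a normalized $\chi^2$ variant are exposed as
options. The score is scale-invariant, 1 exactly on self-generated
noiseless patterns, and strictly below 1 for a hypothesis shifted by
+1 Da. `compareHypotheses()` ranks fits and flags ties (score difference
below `tieTol`) as indistinguishable instead of breaking them.

# The simulator and what passing tests mean

`simulationSpec()`/`simulateRun()` emulate: MS¹ charge envelopes at
`mzFor(M, z)` with a bell-shaped intensity profile; HCD ejection of each
distinct subunit with the **asymmetric charge partition**
$z_\mathrm{monomer} = \lceil z \cdot m/M + \mathrm{bonus} \rceil$ (bonus
default +2, clamped to $1..z-1$ — a 12+ trimer of equal subunits ejects a
6+ monomer; symmetric partition, bonus 0, gives 6+ from an 11+ dimer);
exact mass and charge conservation in every dissociation; metal retention
on the monomer (default) or remnant; MS³ b/y ladders with holo forms for
fragments spanning all planted coordinating residues, thinned by a
detectability probability (default 0.8); uniform decoy peaks (Poisson
rate 5 per fragment spectrum); Gaussian m/z noise (default
$\sigma = 1$ mTh, a high-resolution-Orbitrap-like centroid precision,
applied uniformly — the simulator does **not** model m/z-dependent error,
profile peak shapes, detector saturation, chromatographic or ion-mobility
separation); multiplicative log-normal intensity noise
($\sigma = 0.05$). Every non-decoy peak carries a truth annotation, and a
seed fully determines the output.

The fixture suite (`makeFixtureSuite()`) instantiates four archetypes: a
53,070.9 Da homodimer at 15+/16+ with two deamidations to localize; ~37
kDa trimer arrangements (unmodified / K77-acetyl / C80-nitrosyl subunits)
whose 12+ ions fall in the 3080–3100 Th window; a Cu/Zn metalloprotein
homodimer with an intact C57–C111 disulfide, N-terminal acetylation and
planted coordinating residues; and Met-cleaved K4/K55/K63 methyl/acetyl
combinatorics including a trimethyl-vs-acetyl near-isobaric pair. All
sequences are synthetic stand-ins built from repeating motifs with site
residues placed where the scenario needs them and short tails tuning the
masses; passing tests therefore demonstrate correctness of the inference
chain under the stated noise model, not performance on real instrument
data, real sequence compositions, co-isolation, or unmodeled adducts.

# Numerical choices and degenerate inputs

* Proton mass fixed at 1.0072765 Da; only protonation is considered in
  charging (positive-mode native ESI).
* Tie-breaks are deterministic everywhere (apo before holo, higher charge
  for harmonically related deconvolution hypotheses, label order for
  equal-mass candidates), so identical inputs give identical reports.
* Degenerate inputs fail fast with named errors: unknown elements or
  modifications, malformed proteoform text (with character offset),
  unsorted or negative peak lists (with line number), zero-width mass
  windows, dangling or cyclic precursor references, search-space cap
  overflow (with the offending protein).
* Test problem sizes: oracle equivalence runs 50 random spaces of at most
  a few thousand combinations; the P-score null uses $10^4$ trials (and a
  $10^5$-replicate Monte-Carlo for the analytic-form check); deconvolution
  recovery uses 120 noisy replicates; invariant suites use 100 random
  proteoforms. These sizes give stable pass/fail behavior at fixed seeds
  while keeping the full suite under a minute on a laptop-class machine.

# Known limitations

* No profile-mode peak picking, vendor raw reading, or chromatogram
  handling; inputs are centroided mzML or the documented peak-list text.
* FAIMS compensation voltage is carried as metadata only; spectra at
  different CVs are processed independently.
* No internal fragments, neutral-loss series, ETD/UVPD, or fragment
  intensity prediction; no inter-subunit cross-links beyond intra-chain
  disulfides.
* The intact-mass search trusts the search-space file: a complexoform
  outside the declared modification/stoichiometry bounds can only surface
  as an observed-mass-only record.
* Numbering of modification sites is 1-based on the processed (observed)
  sequence; `canonicalPosition()` maps to canonical coordinates when a
  truncation record is present, which is how a site may legitimately be
  reported as C80 on a Met-cleaved form and C81 canonically.
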