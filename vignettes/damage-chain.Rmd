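---
title: "The strandbreakr damage and repair chain: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The strandbreakr damage and repair chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandbreakr)
```

# Overview

`strandbreakr` is a desk-scale simulation chain for radiation-induced DNA
damage and its repair. It connects five stages, each usable on its own:

1. **Geometry** — a simplified B-DNA double helix on straight chromatin
   segments with histone spheres and ellipsoidal nucleus/cytoplasm
   containers.
2. **Track source** — a stochastic surrogate for track-structure physics
   that produces energy deposits and hydroxyl-radical spawn points for a
   requested dose.
3. **Radical chemistry** — step-by-step Brownian transport of hydroxyl
   radicals with perfect histone scavenging and a hard 5 ns time cut.
4. **Damage scoring and classification** — the direct (linear energy ramp)
   and indirect (Bernoulli per encounter) strand-break models, break
   clustering, DSB pairing, complexity classes (DSB/DSBp/DSBpp) and source
   classes (DSBdir/DSBind/DSBhyb/DSBmix).
5. **Repair kinetics** — a mass-action ODE network for NHEJ, HR, SSA,
   micro-SSA and Alt-NHEJ, with Michaelis–Menten γ-H2AX foci output, plus
   the degree-of-protection analysis that estimates the scavengeable DSB
   fraction.

The chain deliberately replaces full Monte Carlo particle transport and
radiation chemistry with a configurable surrogate: its purpose is to make
the *damage bookkeeping* — scoring rules, clustering, classification,
scavenging logic, repair kinetics — exact, testable and fast, not to
reproduce the absolute yields of a condensed-history or track-structure
code.

# Geometry model

A base pair consists of six molecule sites: two spherical phosphates
(radius 0.228 nm), two spherical deoxyriboses (0.263 nm) and two
ellipsoidal bases (half-axes 0.35 × 0.35 × 0.17 nm). Consecutive base
pairs are rotated by exactly 34° about the fibre axis. Values the
underlying damage model does not constrain are taken from B-DNA
convention and are configurable: helical rise 0.34 nm per bp, backbone
helix radius 1.0 nm, deoxyribose offset 17° from its phosphate, base
centres at 0.3 nm radial offset. Bases are geometry-only — they count for
the radical kill distance ("any DNA molecule centre") but never carry
strand breaks.

Histones are 2.5 nm spheres centred on the fibre axis, one per
`spacing_bp` base pairs (default 200, the nucleosome repeat scale). An
on-axis histone with radius 2.5 nm encloses the backbone (radius 1.0 nm)
over a ±2.3 nm window of fibre — radicals cannot reach those base pairs,
which is the intended perfect-scavenger picture of nucleosome-wrapped
DNA.

Containers are concentric ellipsoids specified by full axis lengths. The
human-fibroblast preset is a 14.2 × 14.2 × 5.0 μm nucleus (≈528 μm³,
0.012 bp/nm³ at 6.4 Gbp) inside a 28.0 × 28.0 × 5.0 μm cytoplasm
(≈2052 μm³). Note the two ellipsoids share the 5.0 μm axis, so
containment is weak (tangent at the poles), and the validator accepts
exactly that. For desk-scale runs, `fibre_container()` wraps a single
fibre in a tight ellipsoid whose volume reproduces a target base-pair
density — 0.012 bp/nm³ in cell mode, one tenth of that in plasmid mode
(plasmids in dilute solution have far lower local DNA density; the exact
factor is a package choice, not a measured value).

Because segments are straight rods along z, the spatial index is a
z-sorted table with binary search and an expanding window — sublinear in
the site count, with no external nearest-neighbour dependency. Ties in
the nearest-backbone-site query go to the lower strand, then the lower bp
index.

# The surrogate track source

Tracks are parallel straight lines along the short container axis with
entry points uniform over the nucleus cross-section. Along each chord,
deposits form a Poisson process with a configurable mean linear density
(default 20 deposits/μm — the "LET-like" knob), displaced radially by a
Gaussian of σ = 2 nm standing in for the secondary-electron penumbra.
Deposit energies are 1 eV plus an exponential tail of scale 45 eV, chosen
so that both sub-5 eV (never breaking) and >37.5 eV (always breaking)
deposits occur; no measured microspectrum is claimed. Hydroxyl radicals
spawn at deposit positions with expected count `energy × G/100 eV`
(default G = 2.5 per 100 eV, the conventional early-time yield).

Tracks are added until the summed deposit energy reaches the target dose
(`Gy = ΣE_eV × 1.602×10⁻¹⁹ / (V_m³ × 1000 kg/m³)`, unit-density water);
the final track is truncated at the first deposit crossing the target, so
the delivered dose overshoots by at most one deposit. At desk scale this
granularity matters: one deposit averages ~46 eV, and 1 Gy in a
10⁴ bp fibre container is only ~5 eV, so meaningful damage statistics
need kGy-scale doses — exactly as in real plasmid irradiation
experiments, where strand-break assays run at hundreds of Gy to kGy. The
within-2% dose postcondition therefore holds whenever the target energy
spans many deposits, and the test suite checks it in that regime.

A zero dose returns empty event lists rather than an error; only negative
doses are rejected.

# Radical chemistry

Radicals born farther than 9 nm from every DNA molecule centre are killed
at creation: 9 nm is the maximum plausible hydroxyl diffusion range
within the chemistry window, since √(6·D·T) = √(6 × 2.8 × 5) ≈ 9.2 nm.
Survivors perform isotropic Gaussian steps (per-axis variance 2·D·Δt,
D = 2.8 nm²/ns, Δt = 0.001 ns) until the first of:

* entry into a histone sphere — scavenged, no event;
* entry into a backbone encounter sphere (site radius + 0.22 nm reaction
  radius) — reacted, exactly one encounter event, the radical is consumed
  whether or not a break results;
* t ≥ T_chem = 5 ns — timed out.

A step landing inside both a histone and an encounter sphere counts as
scavenged (histones take precedence, resolving the otherwise unspecified
same-step race). There is no sub-step root finding; the Δt default makes
the per-axis step ~0.075 nm, small against the ~0.45 nm encounter radii,
and the Brownian mean-squared-displacement test pins the transport law.

Every radical draws from an independent random stream derived from
`(seed, radical id)`. This is what makes paired-arm comparisons exact: in
a histone-free rerun each radical follows its identical path until the
point where a histone would have absorbed it, so removing histones can
only add encounters, never reroute existing ones. The indirect-break
Bernoulli trials reuse the same trick (`(seed, radical id)` hashes), so
the histone-on break set is a subset of the histone-off set, and raising
the break probability can only add breaks at a fixed seed.

# Damage scoring

**Direct.** Each deposit whose nearest backbone site lies within
R_dir = 0.35 nm contributes its full energy to that site; energies are
accumulated over the whole irradiation first, and the phosphate +
deoxyribose of one nucleotide pool into a single sugar-phosphate scoring
unit (the break lives on the moiety, not on one molecule — the
alternative per-molecule reading is not distinguishable from the printed
rules, and pooling is the implemented choice). One Bernoulli trial per
unit uses the linear ramp: probability 0 at or below 5 eV, 1 at or above
37.5 eV, linear between. Per-event scoring (sampling before
accumulation) would be wrong and is not offered.

**Indirect.** Each hydroxyl-backbone encounter breaks the hit nucleotide
with probability 0.405. Duplicate successes on one (segment, bp, strand)
collapse to a single break; a position hit both directly and indirectly
yields one break recorded as direct (direct damage is resolved first — a
deterministic rule the source classification needs).

# Clustering and classification

Breaks sorted along a segment stay in one cluster while the unbroken run
between neighbours is ≤ 100 bp; a strictly longer run splits the cluster.
Within a cluster, opposite-strand breaks within d_DSB = 10 bp pair into
DSBs by a maximum-cardinality matching, realised as the deterministic
two-pointer sweep over position-sorted breaks. (A smallest-gap-first
greedy is *not* maximum — strand 0 at {0, 10} and strand 1 at {10, 20}
admit two DSBs but the Δ=0 pair blocks both — so the sweep is used and an
exhaustive-matching oracle verifies cardinality in the tests.)

Complexity: ≥2 DSBs → DSBpp (three or more DSBs still count as one
DSBpp); one DSB plus ≥1 additional break within d_DSB of either paired
break → DSBp; one DSB → DSB; otherwise SSB cluster. SSBs are counted as
individual unpaired breaks, not clusters. The complex-DSB count is
`N_cDSB = N_DSBp + 2·N_DSBpp`.

Source classes for DSB clusters: all breaks direct → DSBdir; all indirect
→ DSBind; otherwise delete the indirect breaks and re-pair — if no DSB
survives the cluster is DSBhyb ("the DSB does not occur in the absence of
indirect damage", operationalised as a removal test), else DSBmix. The
scavengeable DSB fraction is
`(N_DSBind + N_DSBhyb) / (N_DSBdir + N_DSBmix + N_DSBind + N_DSBhyb)`,
with DSBmix counted non-scavengeable since it cannot be cleanly assigned.

The distant-DSB filter emulates the loss of small fragments in gel
electrophoresis: a left-to-right scan over sorted DSB midpoints (midpoint
= mean of the two paired bp indices) keeps a DSB only if it lies at least
10 kbp after the last retained one.

# Repair kinetics

The repair stage integrates a mass-action network in which `N0`, the
number of unrepaired DSBs (free plus enzyme-bound), feeds five pathway
chains:

* NHEJ: Ku → DNA-PKcs → synapsis → end processing → XRCC4/LigIV →
  ligation (5 complexes, 11 rate constants);
* HR: MRN → resection → RPA → Rad51 → D-loop → synthesis → resolution
  (6 complexes, 13 constants);
* SSA: resection → RPA → Rad52 → flap cleavage → ligation (4, 9);
* micro-SSA: resection → annealing → closure (2, 5);
* Alt-NHEJ: PARP1 → pol θ → LigIII → closure (3, 7);

plus ATM activation/deactivation/autoamplification (3), the
Michaelis–Menten γ-H2AX parameters (2), a phosphorylation/
dephosphorylation relaxation pair (2) and the DSB induction slope α (1):
exactly 53 named constants, validated against the schema by
`validate_rate_table()`.

Complex formation draws on the free pool `N0 − Σ complexes`; only the
terminal step of each pathway removes a DSB from `N0`. This bookkeeping
makes `N0` monotone non-increasing after irradiation while keeping every
intermediate non-negative. Irradiation is instantaneous: the induction
term `α·(dD/dt)·N_cDSB` collapses to the initial condition
`N0(0) = N_ncDSB + N_cDSB` with all intermediates zero. (The printed
induction form has unusual units — a per-Gy slope multiplying a count —
so it is kept behind the α entry of the table rather than reinterpreted;
under the instantaneous convention it never enters the integration.)
`deSolve::lsoda` integrates the system on a 0–25 h grid at 0.1 h steps by
default; integration failure raises an error rather than clamping.

The published values of the 53 constants live in the cited kinetic
modelling literature, not in any table this package could transcribe at
build time, so `default_rate_table()` ships documented pseudo-first-order
defaults (per hour, enzyme pools folded in) that produce fast-dominant
NHEJ, slower HR, a γ-H2AX peak within the first hours and a late plateau.
They are placeholders with sensible dynamics, meant to be replaced via a
JSON table for quantitative work; accordingly every repair test is a
property check (null input, closed-form exponential limit via a reduced
single-step pathway, non-negativity, monotone decay, tolerance-halving
stability, time-rescaling invariance), never a value match against a
published curve.

γ-H2AX is computed from the trajectory: the pooled active DNA-PKcs-bearing
complexes plus active ATM, plus an irreparable component `f·N0(0)` that
permanently retains foci (default `f = N_cDSB/(N_cDSB+N_ncDSB)`), pushed
through the Michaelis–Menten kernel and an asymmetric first-order
relaxation (fast phosphorylation toward the induction level, slower
dephosphorylation away from it). The curve therefore rises over the first
hour, decays as repair proceeds, and plateaus at the f-determined level
— reaching that plateau only after the ATM signal has decayed, which at
the default rates takes longer than 25 h; the plateau test integrates to
100 h for that reason. Ku, DNA-PKcs, RPA and Rad51 curves pool the
obvious complex sets; all curves are scaled to their maxima by default.

# Degree of protection

For survival fractions without (`SF0`) and with (`SFx`) scavenger,
`DP = (ln SF0 − ln SFx)/ln SF0`; the reciprocal regression
`1/DP = k/x + y_inf` extrapolates to infinite scavenger concentration,
and `1/y_inf` estimates the maximum degree of protection, i.e. the
scavengeable damage fraction. The fit is ordinary least squares on the
reciprocal scale, which is also where the parameter-recovery tests place
their Gaussian noise — on that scale the reported standard errors are
exact, whereas noise added to DP itself becomes strongly heteroscedastic
after the reciprocal transform. A non-positive fitted intercept is
flagged `non_physical` with a warning rather than silently inverted.

# What the surrogate does and does not emulate

The track source reproduces: spatial clustering of deposits along
straight tracks, a controllable linear deposit density, dose-targeted
event counts, and radical spawn points co-located with deposits. It does
not reproduce: real proton/photon cross sections, secondary-electron
transport, the LET dependence of track structure, radical species other
than hydroxyl, radical–radical recombination, or bulk scavengers (DMSO
enters only through the analytic degree-of-protection machinery). Passing
tests therefore demonstrate that the damage bookkeeping downstream of the
physics is correct and internally consistent — not that absolute yields
match any particular radiation quality.

# Problem sizes and numerical choices

The test-suite defaults are chosen for a laptop-class single core:
fibres of 10³–10⁵ bp, kGy doses for damage-rich statistics, 400-radical
Brownian checks, 500-cluster pairing oracles, and a 10-replicate
10⁵ bp smoke run — the whole suite completes in well under a minute. Key
tolerances: nearest-site oracle agreement to 10⁻⁹ nm; binomial and
Brownian checks at 3σ; ODE non-negativity at 10⁻⁹ absolute; exponential
limit at 10⁻⁶ relative; tolerance-halving stability at 0.1%.

# Known limitations

* Straight-rod chromatin only: no fractal folding, nucleosome wrapping or
  supercoiled plasmid topology; yields are normalised per Gy per Gbp,
  which keeps the bookkeeping scale-invariant but not geometry-invariant.
* The default rate table is qualitative; quantitative γ-H2AX work needs a
  fitted table.
* Dose granularity at desk scale is one deposit (~46 eV); sub-kGy doses
  on short fibres give sparse, high-variance damage counts.
* The overshoot-free step rule in the Brownian walk carries a small,
  Δt-controlled bias toward late captures; halving Δt is the check.
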