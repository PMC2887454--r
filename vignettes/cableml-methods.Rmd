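---
title: "Models and numerics in cableml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics in cableml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cableml)
```

`cableml` reads, validates, writes and executes neuronal models expressed in
the NeuroML v1.x interchange dialect: Level 1 branched morphologies
(MorphML), Level 2 biophysical cells with ChannelML membrane mechanisms, and
Level 3 networks (NetworkML). This vignette records the scientific models the
package implements, the conventions it fixes where the format leaves room,
and the numerical choices behind the reference simulator.

## The document model and unit systems

A document declares exactly one unit system, `SI` or `Physiological`; mixing
systems inside one file is a validation error. The format names the
Physiological family only loosely (millivolts, milliseconds, centimetre-based
densities), so the package fixes one authoritative table, kept in a single
module constant (`nml_unit_table()`):

| dimension | Physiological | SI |
|---|---|---|
| voltage | mV | V |
| time | ms | s |
| segment geometry | µm | m |
| specific capacitance | µF/cm² | F/m² |
| conductance density | mS/cm² | S/m² |
| absolute conductance | µS | S |
| current | nA | A |
| concentration | mM | mol/m³ |
| axial resistivity | kΩ·cm | Ω·m |

This set was chosen because it is closed under the cable-equation arithmetic
(µS × mV = nA; nF × mV / ms = nA), so the simulator runs without conversion
factors in its inner loop, and because the magnitudes practitioners quote
(nA current steps, pS–nS coupling conductances, mS/cm² channel densities)
are order-one numbers in it. Every conversion is a multiplication by a power
of ten, which is why SI↔Physiological round-trips reproduce magnitudes to
better than one part in 10¹².

One deliberate limitation: *generic* rate-law and `variable_parameter`
expressions are strings in the document and are serialized verbatim. They
are meaningful only in the unit system they were authored in; the writer
does not attempt to rewrite arithmetic. Documents that rely on generic
expressions should therefore be stored in their native system.

Unknown elements are preserved opaquely on round-trip (and surfaced as
warnings), rather than rejected: the format's extension mechanisms
(proprietary subclasses, annotation elements) require that a conforming
reader tolerate material it does not understand.

## Morphologies

Cells are forests of conical frusta (`segment`s) with explicit 3D
proximal/distal points and diameters; unbranched runs are grouped into
`cable`s carrying group labels and a discretisation count
(`internal_divisions`). Conventions fixed here:

* `fraction_along` is 0 at the proximal and 1 at the distal point.
* Path distance is measured from the root segment's proximal point. A
  spherical soma — a single segment whose two points coincide — contributes
  zero path length. This makes the metric unambiguous and testable; the
  ball-and-stick fixture's dendritic tip, five 20 µm segments from the soma,
  is at exactly 100 µm.
* Zero-length segments are tolerated only as spherical somata; anywhere else
  they are integrity findings.

`check_integrity()` reports four defect classes — discontinuities, isolated
elements, zero-length segments and parent-chain cycles. Cycles and isolated
elements are validation *errors* (they break the forest invariant);
discontinuities and zero-length segments are *warnings*, consistent with a
policy of erroring on structure and warning on style.

## Recompartmentalization

Compartmental engines in the GENESIS tradition use cylinders with no
internal structure, so a cable of `n` tapered frusta must be mapped onto
`internal_divisions` equivalent cylinders that conserve total length,
membrane area and series axial resistance. The construction used here:

1. The cable is cut into spans of equal *electrotonic weight*, the integral
   of 1/√r along the arc (the local space-constant density for a cylinder of
   radius r). Both the weight and its inverse have closed forms over a
   linear taper, so cut points are exact.
2. Each compartment reports its span's exact arc length, a radius chosen so
   the cylinder's lateral area (2πrl) equals the span's frusta area, and the
   span's exact integrated axial-resistance factor ∫dx/(πr²) as a separate
   field — the way a GENESIS-style compartment carries its axial resistance
   as an explicit parameter rather than deriving it from geometry.

All three totals are therefore conserved to rounding error (the tests assert
1 part in 10⁹ on randomized tapered cables). A single cylinder cannot in
general realize area and axial resistance through one radius; the relative
gap between the stored axial factor and the cylinder-geometry value is
reported per compartment as `axial_residual` rather than silently absorbed.
For a uniform cylinder the residual is zero and one division returns the
cylinder unchanged.

Spherical somata become spherical compartments: area πd², with the axial
contribution of an equal-diameter cylinder as a documented convention.

## Channels

Distributed conductances follow the ChannelML triad of rate laws, with `A`
in ms⁻¹, `k` in mV⁻¹ and `d` in mV:

* exponential: A·e^{k(v−d)}
* sigmoid: A/(1+e^{k(v−d)})
* linoid (exp-linear): A·k(v−d)/(1−e^{−k(v−d)}), with the removable
  singularity at v = d filled by its limit A inside a guard band of
  10⁻⁷ mV.

Gates carry `instances` (the power in the conductance product), Q10
temperature scaling multiplies rates by factor^{(T−T_exp)/10}, and
ligand-gated (BK/SK-class) rates are expressed through a *generic*
arithmetic form in `v`, `ca` and `celsius`. Generic expressions are parsed
with a dedicated recursive-descent grammar (+, −, ·, /, ^, `exp`, `pow`,
parentheses) and never handed to R's evaluator, so a document cannot execute
host code.

Markov kinetic schemes generalize the two-state gate: occupancies evolve
under the master equation, and the conducting fraction is the summed
occupancy of open states. The propagation step is backward Euler on the
generator matrix, which preserves the probability simplex exactly (the
generator's columns sum to zero, so the implicit update conserves total
occupancy; a final clamp guards rounding). The tests confirm the two-state
scheme tracks the equivalent HH gate within integration tolerance.

Calcium pools are first-order: dc/dt = −(c−c_rest)/τ + φ·i. The influx
scaling φ converts the compartment's total calcium current directly to a
concentration rate (mM per nA·ms). Shell geometry is not part of the v1.x
description, so φ is a *per-compartment* convention here, documented rather
than inferred; inward calcium current raises the concentration.

## Synapses

Conductance waveforms are peak-normalized: g(t) = ḡ·N·(Σᵢ fᵢe^{−t/τ_{d,i}}
− e^{−t/τ_r}) with N chosen once at construction so the peak equals ḡ.
Peak normalization makes ḡ amplitude-interpretable, which is what
voltage-clamp EPSC comparisons need. A zero rise time gives an
instantaneous-rise waveform peaking at t = 0; a rise equal to a lone decay
constant degenerates to the alpha function (t/τ)e^{1−t/τ}.

The NMDA magnesium block is the standard two-parameter exponential
1/(1+η[Mg]e^{−γv}). The defaults (η = 0.33 mM⁻¹, γ = 0.06 mV⁻¹,
[Mg] = 1 mM) are package conventions for fixtures, not fitted values.

Short-term plasticity is the Tsodyks–Markram resource/utilisation scheme.
Between spikes x recovers toward 1 with τ_rec and u decays toward U with
τ_fac; at a spike, facilitation (when τ_fac > 0) first applies
u ← u + U(1−u), the release is u·x, and x ← x − u·x. The zero time
constants are defined as exact special cases — τ_rec = 0 restores x
instantly, τ_fac = 0 pins u at U — so that the control configuration
(both zero) reproduces the base synapse on every spike, the depressing
configuration (τ_rec = 120 ms, τ_fac = 0) yields strictly non-increasing
releases on a fast regular train, and the facilitating one (τ_rec = 0,
τ_fac = 300 ms) non-decreasing ones. Event conductances scale by
release/U.

STDP is the additive Song–Abbott rule implemented with exponential traces.
The per-event contract — a pre-before-post pair at lag Δt potentiates by
A₊e^{−Δt/τ₊}·w_max, post-before-pre depresses by A₋e^{−Δt/τ₋}·w_max, weight
clipped to [0, w_max] after every update — sums over *all* prior opposite
events (trace accumulation), and the tests pin the implementation against a
naive O(n²) pairwise replay. Simulator support for plastic synapses is
intentionally narrow: the rule is integrated only for single-connection
protocols, with the module itself as the reference implementation.

Gap junctions are ohmic: the current into side a is g(v_b − v_a) and the
two sides' currents are exact negatives at every step, a charge-conservation
identity the property tests assert bitwise.

## The reference simulator

The engine discretizes each cell per the recompartmentalization above and
integrates the branched cable equation with a first-order implicit
(backward Euler) voltage solve over the whole tree each step, channel
conductances frozen at the current gate states, followed by staggered
exponential gate updates m ← m_∞ + (m − m_∞)e^{−dt/τ} evaluated at the
just-computed voltages. The exponential update keeps gate states in [0, 1]
unconditionally, and the implicit solve is what makes time steps of order
0.005 ms usable — an explicit exponential-Euler treatment of the voltage
would demand steps several orders of magnitude smaller. A
semi-implicit second-order (trapezoidal) option exists for convergence
studies; the tests verify the expected first- versus second-order error
scaling against the analytic RC charging curve using the passive-membrane
values of the clamp protocols (leak 3.0×10⁻⁹ mS/µm², capacitance
1×10⁻⁸ µF/µm², time constant c/g = 10/3 ms).

Two axial-resistance conventions are implemented, because their
disagreement at coarse discretisation is precisely what cross-simulator
validation must quantify:

* **symmetric** — each compartment's axial resistance is split in half at
  its two ends; the link between neighbours is the sum of the facing
  halves, and the voltage is read at compartment centres;
* **asymmetric** — the full axial resistance sits on one (the proximal)
  side; the voltage is read at the distal node.

The format only says where the resistance sits; the node-placement half of
the convention is fixed here and documented. At branch points axial
conductances simply sum into the junction node; no extra junction
capacitance is introduced beyond the member compartments. Non-uniform
densities are evaluated at each compartment's centre path distance.

Runs are deterministic: identical document, configuration and seed give
bit-identical recordings. Random stimuli draw from a counter-based
Park–Miller stream keyed by (seed, stimulus id), so adding a recording or a
second stimulus never perturbs an existing noise stream — a property a
global RNG cannot give.

Spike detection uses upward threshold crossings with linear interpolation
between samples; the default threshold of 0 mV is a package choice (the
format does not fix a detector) and is configurable. Two runs are compared
by matching spikes in order after a count check and expressing the maximum
timing difference as a percentage of run time; ≤ 0.5 % is the convergence
criterion (spikes at 200 ms may differ by at most 1 ms). When counts
differ the mismatch is *reported*, not resolved: no spike-matching rule for
transient count differences is defined, so the comparison computes the
discrepancy over the common prefix and flags the inequality.

Numerical guards: the voltage solve raises a divergence error naming the
time step if |V| exceeds 1000 mV; the exp-linear singularity uses a
10⁻⁷ mV guard band; conservation assertions run at 10⁻⁹ relative and unit
round-trips at 10⁻¹².

## Networks

Instance-based networks store one cell description per type plus a flat
location list — which is why a homogeneous 10,000-cell population
serializes to one `cell` element and 10,000 `instance` records, and why the
representation stays practical at scale. Template support is deliberately
limited to {box, cylinder} × uniform random placement and three connection
rules (all-to-all, fixed count per source cell, independent probability),
mirroring the narrow template repertoire of v1.x. Instantiation and
connection are pure functions of (template, seed). Minimal-separation
placement uses rejection sampling with a cap of 10⁴ retries per cell and is
*off* by default — nothing in the format forbids overlapping somata, so
enforcing separation is opt-in. `node_id` attributes (parallel-execution
partitioning hints) are parsed and preserved but never affect simulation
semantics. Weights default to 1 and delays to 0 ms when absent.

## Fixtures: what they emulate and what they do not

All test inputs are generated in code. The point cell and ball-and-stick
cell use the classic squid-axon Hodgkin–Huxley kinetics (rates in ms⁻¹ at a
−65 mV resting convention, densities 120/36/0.3 mS/cm²), labelled as such:
they are the canonical textbook parameter set, not values transcribed from
any published figure. The ball-and-stick cell is a 20 µm spherical soma
carrying the active conductances plus a passive 100 µm × 2 µm dendrite of
five segments, 32 internal divisions by default, driven by a 0.3 nA
suprathreshold step for 200 ms — sizes chosen so the two solver conventions
are compared on a genuinely multicompartment problem that still runs in
seconds. The gap-junction pair uses 300 pS coupling and a 0.19 nA step; the
clamp cell uses the passive values above with −80/−20 mV holding
potentials; the STP pair uses U = 0.5 with the three
(τ_rec, τ_fac) configurations; the reduced Layer 2/3 skeleton places
20 + 6 + 10 + 10 + 10 = 56 cells at random in a cylinder with 2.1 nS
electrical coupling within populations and the original random current
drives (0.15–0.25, 0–0.2 and 0–0.02 nA ranges).

Passing tests on these fixtures show that the machinery — parsing,
validation, discretisation, integration, plasticity updates, instantiation
— is correct on exactly specified inputs. They do not show fidelity to real
reconstructed morphologies (thousands of irregular frusta, annotation
noise), nor to the detailed 22-conductance thalamocortical kinetics, which
live in external model files and are out of scope; the network skeleton
deliberately substitutes placeholder integrate-and-fire point cells.

Problem sizes used by the test-suite and acceptance computations: the
convention comparison runs 2 × 40,000 steps on 33 compartments; temporal
convergence sweeps dt ∈ {0.02, 0.01, 0.005, 0.002} ms over 100 ms on the
point cell; the compactness check serializes 10,000 instances. These sizes
exercise every code path at full fidelity while keeping a complete run in
minutes on one core.

## Known limitations

* No HDF5 NetworkML dialect and no generation of simulator-specific
  scripts; the XML dialect plus this simulator is the scope.
* Generic expressions are not unit-converted (above).
* Camera-lucida MorphML extras (`freePoints`, `features`) are preserved
  only as opaque unknown elements.
* Kinetic-scheme synapses, stochastic single-channel gating and
  Nernst/GHK-computed reversal potentials are not modelled.
* The XSD shipped with the package checks element structure; attribute
  ranges and reference integrity are the in-memory validator's job, since
  legal magnitudes depend on the document's unit system.
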