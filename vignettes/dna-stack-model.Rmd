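---
title: "A rule-based kinetic model of a DNA stack data structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rule-based kinetic model of a DNA stack data structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system

A DNA stack records signal strands in last-in first-out order by growing a
nicked-duplex polymer on streptavidin beads, and plays them back by
toehold-mediated strand displacement. The chemistry is operated in stages:
one strand species is added, the reaction is left to equilibrate
(typically 30 min), and the beads are washed. Because every hybridisation
is designed to be irreversible, and the washing purges most unreacted and
off-target material, a well-run protocol keeps the bead-tethered stack
population synchronised with the ideal stack. The interesting regime —
and the reason to simulate — is imperfect washing, where carried-over
strands form off-target complexes, rejoin the stacks, and gradually
destroy that synchrony.

## Species and reaction rules

A complex is a linear token sequence over the nine strands
`{s, p, X, Y, w, r, q, k, z}` with a strict alternation grammar: an
optional bead linker `k`, a start `s`, then (push, signal) pairs with an
optional trailing push. Solution-phase complexes obey the same alternation
without the start (`p.w`, `w.p.w`, ...). Identity is the token sequence
alone; nick positions and hairpin geometry carry no extra information for
any observable the package computes. Ring-closure (intramolecular
cyclisation) is excluded: only intermolecular joins are modelled.

Reactions are instantiated by pattern matching on exposed interfaces. A
complex exposes at most one reactive site at its growing end —
`alpha_open` (a 28 nt A-type domain, presented by a bare start or a
terminal signal), `beta_open` (a 28 nt BC overhang, presented by a
terminal push) or `linker_open` (an unused bead linker). A free complex's
head binds the complementary site. Five rule classes generate every
channel:

1. elongation by push at an `alpha_open` end (rate `k_A`);
2. elongation by signal at a `beta_open` end (rate `k_BC`);
3. read displacement of a terminal signal, yielding an inert signal–read
   duplex (toehold = the exposed A domain, rate `k_A`);
4. pop displacement of a terminal push, yielding an inert push–pop duplex
   (rate `k_BC`);
5. nucleation of start on linker, and release of a whole stack by the
   releaser (rate `k_A`).

Displacement is modelled as a single effective second-order step: with
28 nt toeholds, binding is rate-limiting and completion is irreversible.
There are no reverse reactions anywhere. Inert duplexes (`X.r`, `p.q`,
`k.z`, `s.r`) take part in nothing.

Three degenerate instances are enabled by default and can be switched off
via `rule_options()`: read capping of a bare start (the empty stack
presents the same A-type site as a terminal signal, so a read strand can
permanently cap it), read hybridising a free signal monomer, and pop
hybridising a free push monomer. The latter two follow from free monomers
being fully single-stranded; the free-signal rule also reproduces the
observed insensitivity of strictly alternating record/pop sequences to
carry-over, because leaked signal converts into the *correct* read duplex
at the next pop. Start-headed complexes may nucleate on linkers
(`chain_nucleation`), completing the polymer–polymer join closure.

The rule set lives once, in the compiled just-in-time enumerator; the R
test suite checks it against an independent brute-force oracle on small
states.

## Engine

**Stochastic backend.** The Gillespie direct method runs on integer copy
numbers in a 0.15 pl volume (200 nM linker ≈ 18,066 copies; 300 nM
additions ≈ 27,100 copies). Reaction channels are created lazily: when a
species first acquires positive copy number it is matched against every
live species. Propensities are `k n_i n_j / (V N_A)`, halved for
self-pairs. Channel selection uses block-partial sums so cost grows
sub-linearly with the (hundreds to thousands of) channels a
desynchronised population accumulates. Copy-number conversion rounds
half-to-even.

**Deterministic backend.** Mass-action ODEs on the species set closed
under the rules up to `L_max` monomers per complex, integrated with
`deSolve::lsoda` (`rtol = 1e-8`, `atol = 1e-12` M). Truncation is guarded:
if more than `1e-3` of the monomer token mass ends the interval in
complexes of `L_max - 1` or more monomers, the call aborts rather than
silently distort the kinetics. The default `L_max` is 16; calibration
lanes use 24 because solution-phase push/signal chains under heavy
carry-over follow step-growth statistics with a long tail (at
`phi0 = 0.33` the boundary mass at `L_max = 16` exceeds the guard). For
repeated integrations (grid calibrations) the closed network is built once
with `build_ode_network()` and reused.

The two backends agree within a few percent on stage-end concentrations at
standard conditions, which is also asserted in the tests.

**Washing.** One wash multiplies the bead mass by `(1 - mu)`, thins every
tethered species by `(1 - mu)`, and thins every supernatant species by
`phi_n = phi0 (1 - mu)^n`, where `n` counts washes already performed — the
non-specific carrier is the bead surface, so carry-over decays with bead
mass. The stochastic backend thins binomially (keeping counts integral);
the deterministic backend multiplies exactly. `bead_fraction` is tracked
as the exact scalar `(1 - mu)^n` in both.

## Protocols and observables

`compile_operations()` maps stack operations to stages: a record becomes a
push stage then a signal stage; a pop becomes a read stage and a pop-strand
stage; one start stage is prepended. Every stage adds at `gamma = 300 nM`
(the read stage concentration is separately settable; linker and releaser
use 200 nM), waits `t_w = 30 min`, and washes. A final pop-strand stage is
emitted even when the last read empties the stack — the alternation is
uniform and the extra stage is harmless. Pipetting noise, when enabled,
draws every added concentration from `U(gamma - eta, gamma + eta)`
truncated at zero.

The readout for each pop is taken at the end of its read stage, before the
wash, summing each read duplex over the whole supernatant — including
duplexes carried over from earlier pops, because a downstream circuit (or
a gel lane) sees the supernatant as a whole, not only the freshly popped
material. A pop is correct when `|[Xr] - [Yr]| >= 10 nM` *and* the
majority duplex matches the ideal stack's output; the pop limit counts
consecutive correct pops from the first. Equality at exactly 10 nM counts
as distinguishable, matching the strict-inequality definition of
*indistinguishable* (`< 10 nM`); with continuous concentrations the choice
is immaterial, and with integer copy numbers it affects only a
measure-zero boundary. For single-signal (`w`-only) runs the same scan
uses `[wr] >= 10 nM` as the correctness condition — a documented extension,
since the two-signal definition does not apply. `signals_retrieved()`
additionally counts correct pops without the consecutiveness requirement;
the two differ exactly when a run fails a middle pop but recovers later,
which is how a read strand supplied at 50 nM behaves.

**Benchmark sequences.** `make_seqN()` builds the periodic 40-operation
sequences (N records then N pops, repeated to 20 of each) and `make_seqR()`
the random prefix-valid arrangement, both with seeded balanced X/Y labels
(`|#X - #Y| <= 1`). The specific X/Y arrangement matters — two seq5
arrangements can differ by a couple of pops under W1 — so every generated
arrangement is seeded and recorded, and sequence-level results are
reported as averages over arrangements.

**Gel prediction and calibration.** `band_pattern()` bins a compartment by
total nucleotide content (gel migration is linear in nucleotides for these
nicked duplexes), weights intensity as concentration × nt (stain
proportionality), drops bands below 1000 nM·nt (1 nM of a 1 kb band) and
ranks by intensity. `band_order_error()` compares two rankings as the
fraction of disagreeing band pairs over the union of bands, counting a
pair as maximally disagreeing when either band is missing from one
pattern; it is symmetric, zero exactly on identical orderings, and one on
a full reversal. `fit_wash_params()` grid-searches `(mu, phi0)`,
simulating every lane deterministically per cell and averaging the
ordering error; cells whose simulation fails (truncation overflow at
extreme carry-over) are excluded with a warning. Because the original gel
orderings are not shipped, the calibration is validated by parameter
recovery on synthetic fixtures (`make_fit_fixture()`), which regenerates
rankings at known parameters with optional adjacent-rank swaps; recovery
lands within one grid cell of truth, and survives 10% swap noise within
two cells.

## What the synthetic benchmarks do and do not show

The generated protocols reproduce the study conditions exactly as the
model defines them: volumes, concentrations, waits, washing presets
(`W1 = (0.1, 0.33)`, `W2 = (0.05, 0.15)`, `W3 = (0.02, 0.05)`) and the
40-operation sequence structure. They do not emulate strand-synthesis
impurities (truncated oligos in the long hairpin signals), zero-toehold
leakage displacement, ring polymers, secondary-structure kinetics or
bead-geometry effects — all deliberately outside the chemistry model. A
passing suite therefore validates the rule-based kinetics and the washing
algebra, not the full messiness of a wet-lab run; in particular the model
is expected to *overestimate* achievable pop limits for hairpin-signal
experiments, which is consistent with how the in vitro system behaved.

Two model-level behaviours are worth flagging. First, with 40-operation
sequences under W1 the long-block sequence contributes a pop limit of
zero: its first readout happens after 41 washes, by which point the
tethered population (≈ `200 nM × 0.9^41` ≈ 2.6 nM) is below the 10 nM
detection rule, so the grand mean across the five sequences (≈ 2.7–3.0 in
this implementation) sits below the strictly-alternating sequence's ~6.
Second, under W1 the pipetting-noise curve for seq5 is statistically flat
through `eta = 200 nM` at the replicate counts used (n = 10): the bead
population under `mu = 0.1` falls well below 200 nM within a few washes,
so noisy additions rarely starve the stacks, and a detectable drop only
appears around `eta ≈ 300 nM`. Under W3, where stacks stay near 200 nM,
the curve is flat through 100 nM and collapses between 150 and 200 nM —
the behaviour that motivates the "keep additions above the linker
concentration" rule.

## Numerical choices

* Rate constants `k_A = k_BC = 3e4 /M/s`; strand lengths `X = 107`,
  `Y = 137`, `p = 56` nt (28 nt A domain + 28 nt BC overhang). The
  remaining lengths are not fixed by the domain architecture and are
  package assumptions: two-domain strands (`s`, `w`, `r`, `q`) 56 nt,
  single-domain strands (`k`, `z`) 28 nt. Lengths only affect gel band
  positions, not kinetics.
* Copy-number rounding: round-half-to-even on `c V N_A`.
* SSA block size 64 for partial-propensity sums; block sums are fully
  refreshed every 65,536 firings to cap floating-point drift.
* Ties in band ranking break toward the smaller band size; the majority
  signal at exactly `[Xr] = [Yr]` is called `X` (irrelevant in practice —
  such a pop fails the 10 nM rule anyway).
* Degenerate inputs: an empty operation sequence compiles to the lone
  start stage; a state with no applicable reactions advances only its
  clock; `mu = 1` calibration fixtures are flagged degenerate.

## Problem sizes

The test suite and the acceptance script size their simulations for a
single CPU: five seeded arrangements per sequence for the W1 grand mean
(25 runs), three for the stringent-washing check (15 runs), ten replicates
per noise level (50–70 runs), ten seeds per washing preset for the
monotonicity property, and five- to six-lane subsets with ~20-cell grids
for calibration recovery. These are the package's own defaults for a
desk-scale reproduction; larger grids (the 11 × 13 washing heatmap default
in `sweep_wash()`) match the published sweep geometry and run in minutes
to tens of minutes.

## Known limitations

* The carry-over schedule `phi_n = phi0 (1 - mu)^n` is one concrete
  reading of "transfer scales with bead mass"; other decay laws are
  plausible and would recalibrate `phi0`.
* The exact membership of the full rule set beyond the five principal
  classes is reconstructed by domain-level pattern matching; the three
  degenerate toggles encode the residual uncertainty.
* The band-ordering error is a reconstruction validated by parameter
  recovery, not by comparison with the original fitting surface.
* ODE truncation limits deterministic runs to moderate carry-over;
  stochastic runs have no such limit but are sampled, so distribution
  tails need replicates.
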