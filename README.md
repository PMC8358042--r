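# dnastack

Rule-based kinetic simulation of a last-in first-out (LIFO) stack data
structure implemented in DNA.

## The problem

A DNA stack stores signal strands by hybridisation-driven polymerisation on
streptavidin beads and releases them in reverse order by toehold-mediated
strand displacement. Nine short ssDNA strands operate the device: *linker*
(`k`) anchors complexes to beads, *start* (`s`) nucleates a stack, *push*
(`p`) separates stored signals, hairpin signals `X` (107 nt) and `Y`
(137 nt) — or the linear single-signal variant `w` — carry the information,
*read* (`r`) and *pop* (`q`) peel the last signal and its push off the
stack, and *releaser* (`z`) ejects whole stacks from the beads. Each
operation is a wet-lab stage: add one strand, wait for the reaction to
equilibrate, then wash the beads.

Washing is imperfect, and that imperfection governs the device. Two
parameters describe it:

* `mu` — the fraction of beads lost at each wash;
* `phi0` — the fraction of supernatant species non-specifically carried
  through the first wash. The carry-over fraction decays over successive
  washes as `phi_n = phi0 * (1 - mu)^n`.

This package is for researchers studying dynamic DNA data structures and
strand-displacement chemistry who want to predict how many operations such
a device can sustain, how its performance depends on washing stringency,
strand concentrations, wait times and pipetting accuracy, and how to
calibrate the washing parameters from gel band patterns.

## The model

The chemistry is a rule-based reaction network over linear complexes
(token sequences such as `k.s.p.X.p.Y`). Five principal bimolecular rules
are instantiated by pattern matching on exposed single-stranded interfaces:

* **R1** elongation by push at an exposed A-type (`alpha_open`) end, rate
  `k_A`;
* **R2** elongation by signal at an exposed BC-type (`beta_open`) overhang,
  rate `k_BC`;
* **R3** read displaces the terminal signal, releasing an inert
  signal–read duplex (`k_A`);
* **R4** pop displaces the terminal push as an inert push–pop duplex
  (`k_BC`);
* **R5** start nucleates on a bead linker; releaser ejects a tethered
  stack (`k_A`).

Polymer–polymer joins apply whenever one complex's head matches another's
exposed end, which is how carried-over strands form off-target complexes
(`p.w`, `w.p`, `p.w.p`, ...) that can rejoin bead-tethered stacks. Both
hybridisation rate constants default to `k_A = k_BC = 3e4 /M/s`.

Stack operations compile to staged protocols (record = push stage + signal
stage; pop = read stage + pop stage; every stage: add at 300 nM, wait
30 min, wash). Stages run either under the Gillespie direct stochastic
simulation algorithm in a 0.15 pl volume — with just-in-time reaction
enumeration in compiled code, so the unbounded polymer state space is never
enumerated — or as deterministic mass-action ODEs on a species set
truncated at a maximum complex size.

Performance is summarised by the **pop limit**: the number of consecutive
correct pops before the popped read-duplex concentrations become
indistinguishable (`|[Xr] - [Yr]| < 10 nM`) or the majority signal is
wrong.

## Worked example

Record `X` then `Y`, then pop twice, under the experimentally calibrated
washing preset W1 (`mu = 0.1`, `phi0 = 0.33`):

```r
library(dnastack)
run <- simulate_sequence(parse_ops("X Y q q"), wash = "W1", seed = 7)
run$readouts
#>   pop expected       Xr_nM     Yr_nM wr_nM
#> 1   1        Y  0.02214052 147.94296     0
#> 2   2        X 79.51768080  14.05923     0
pop_limit(run)
#> [1] 2
```

The first pop releases `Yr` at 148 nM against essentially no `Xr` — the
last signal recorded is the first one out. The second pop returns `Xr` at
80 nM, still the clear majority over the 14 nM of carried-over and
off-target `Yr`, so both pops are correct and the pop limit is 2. Longer
runs under W1 desynchronise: benchmark 40-operation sequences average
about three correct pops before readout becomes indistinguishable, while
stringent washing (`mu = 0.02`, `phi0 = 0.01`) recovers all twenty.

Other entry points: `sweep_wash()`, `sweep_conc_wait()` and
`sweep_noise()` for pop-limit heatmaps and pipetting-noise curves;
`band_pattern()` and `fit_wash_params()` for gel band prediction and
`(mu, phi0)` calibration from ranked band orderings (synthetic calibration
fixtures via `make_fit_fixture()`); `inst/cli/dnastack` for a command-line
front-end (`simulate`, `sweep`, `fit`, `fixtures`).

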