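---
title: "A lane-parallel stack VM driving dynamic Bloch-equation MRI simulation"
author: "blochvm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lane-parallel stack VM driving dynamic Bloch-equation MRI simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blochvm)
```

## Why a virtual machine inside a physics simulator

GPU-style simulation kernels are normally compiled statically: the physics is
fixed when the kernel is built, and any quantity that evolves during the
simulation — a relaxation-time map perturbed by an arriving contrast agent, an
off-resonance map perturbed by tissue heating — has to be anticipated in the
kernel's source. `blochvm` explores the alternative architecture: a small,
Turing-complete, stack-based virtual machine whose bytecode can be generated,
loaded and re-run *at simulation time*, so that user-supplied parameter
dynamics execute inside the simulation loop without touching the validated
solver. The package contains the complete chain: the bytecode format and VM,
a compiler for a small C-like language, benchmark programs with independent
oracles, and a spoiled gradient-echo (SPGR) CINE Bloch simulator whose T1 and
off-resonance maps are recomputed each frame either natively or by routines
running on the VM.

## The virtual machine

The execution model is reverse Polish notation: operands are pushed on a
per-lane stack and operations consume them. A program is a triple of aligned
arrays — instructions, operations, values — indexed by a single program
counter. Six instructions exist:

* `OP` — execute the operation in the current slot;
* `VALUE` — push the value in the current slot;
* `JUMP` — pop an absolute instruction index and branch to it;
* `JUMPIFZERO` — pop a target, pop a condition, branch iff the condition is
  exactly `0.0`;
* `SI_VALUE_OP` / `SI_OP_VALUE` — fused pairs performing a push and an
  operation in one dispatch.

The operation library (~60 operations, `op_table()`) is organized in the
categories a GPU-oriented instruction set needs: stack access and pointer
arithmetic, arithmetic/logic, memory management (per-lane heap with an
allocation table: `MALLOC`/`FREE`/`MEMCPY`/`PTR_DEREF`), comparisons, typed
environment I/O (`READ_F64`…`WRITE_CHAR`), math functions (including `ERF`,
required by the heat kernel below), console syscalls, value casts, register
loads (`LDPC`, `LDTID`, `LDSTK_PTR`) and barrier synchronization
(`SYNCWARP`/`SYNCBLOCK`/`SYNCGRID`). A numerical-integration special
operation present in some related instruction sets is deliberately absent
here: no defined semantics were available to implement, so nothing was
guessed.

Design choices that the execution semantics depend on:

* **Aligned arrays.** The operation and value arrays are index-aligned with
  the instruction array and a single program counter indexes all three.  The
  alternative — independent consuming cursors per array — leaves the
  behavior of `JUMP` underdetermined (how would the side cursors
  reposition?), whereas alignment makes jumps trivially consistent.
* **Words.** Stack and heap words are raw 64-bit quantities; nearly every
  operation views them as IEEE doubles.  `DOUBLETOLONGLONG` /
  `LONGLONGTODOUBLE` are *value* conversions (round half away from zero to a
  signed 64-bit integer and back); since words are raw bits, a bit-level
  reinterpretation between the two views is the identity on the word and
  needs no operation of its own.
* **Branch protocol.** `JUMPIFZERO` finds the target on top of the stack and
  the condition beneath it; the compiler always emits condition first, then
  target.  Targets must be exact integers in `[0, n]` (`n` = one past the
  last instruction, the normal halt state); anything else faults the lane.
* **Faults vs IEEE.** Only structural errors fault a lane (stack over/
  underflow, out-of-range addresses or buffer indices, `FREE` of a dead
  handle, invalid jump targets).  Arithmetic follows IEEE semantics —
  division by zero yields ±Inf, NaN propagates — so numerical kernels behave
  exactly as native floating point.  `%` (the `FMOD` operation) is the
  truncated-division remainder `a - trunc(a/b)*b`, computed explicitly in
  those terms.
* **Scheduling.** Lanes emulate GPU threads: deterministic round-robin, one
  instruction per running lane per round.  This fixes the interleaving, so a
  report (`vm_run`) is bit-for-bit reproducible.  Lanes share nothing except
  the named, typed environment buffers — the host↔VM data contract — and
  synchronize through barriers over three scopes: warp (contiguous groups of
  `warp_size` lanes, default 32), block and grid (both the whole launch
  here, since the package models a single launch).  A barrier releases when
  every scope member has arrived; if some members finish while others wait,
  the waiters fault with a barrier deadlock rather than hanging.
* **Limits.** Per-lane stack capacity (4096 words), heap arena (2^16 words)
  and step budget (10^8) are configurable at `vm_load()`.  The step budget
  exists because programs are Turing-complete: tests and the CLI must
  terminate even on runaway inputs.  The heap allocator is a bump allocator
  with a live-allocation table; `FREE` retires an allocation (indices are
  never recycled), which is simple, makes use-after-free detectable, and is
  ample at the package's problem sizes.

## The language and compiler

The compiler (`compile_source()`) implements a deliberately small C-like
language: `let` declarations, 1-D heap arrays (`let a[n];`), `if`/`else`,
`while`, `for` (an undeclared `for`-init variable is declared with loop
scope), user functions with overloading on arity and argument type (`num`
vs `array`), `env` buffer declarations typed `f64`/`f32`/`i32`/`char`,
`print`/`printc`, and built-in math functions that map 1:1 onto math
operations. This is the smallest language that comfortably expresses the
Rule 110 automaton, the Mandelbrot kernel, and the two parameter-update
routines of the MRI application.

Compilation is the classic pipeline: recursive-descent parser to an AST;
semantic analysis (symbol resolution, type checking, overload dispatch, env
binding); code generation; and a peephole fusion pass. Notable decisions:

* **Locals in stack slots.** Every local occupies a reserved stack slot
  addressed by `SREAD`/`SWRITE` relative to the statically tracked stack
  depth; there is no register allocation.  Arrays live on the heap and are
  freed automatically when their scope exits.
* **Calls are inlined.** Overloads are resolved during analysis, and the
  selected definition is expanded at the call site over a hidden result
  slot.  This keeps the calling convention trivial and makes overload
  dispatch free at run time; the costs are code growth and no recursion
  (rejected with a diagnostic).  `return` must be the final statement of a
  function body, which keeps the inline stack unwinding static.
* **Fusion.** `optimize_program()` rewrites every adjacent `VALUE`→`OP` pair
  whose second element is not a jump target into `SI_VALUE_OP` (and
  `OP`→`VALUE` into `SI_OP_VALUE`).  Fusion shifts instruction indices, so
  the compiler records which value slots hold jump addresses
  (`meta$label_slots`) and the optimizer remaps them; a foreign program with
  jumps but no such bookkeeping is returned unchanged rather than risk
  corrupting an address.  Fusion is validated two ways: a completeness check
  (no fusable pair survives) and differential testing — hundreds of randomly
  generated programs must behave identically (console, environment, lane
  statuses) with and without the pass.

## Benchmarks and their oracles

Two classic programs serve as end-to-end correctness probes, each against an
independent brute-force oracle:

* **Rule 110** (`rule110_source()` / `rule110_oracle()`): the elementary
  cellular automaton proven Turing-complete.  The shipped program runs 310
  cells for 100 generations from a single seeded cell at the right edge and
  prints `*`/space rows; the oracle applies the neighborhood truth table
  directly.  Agreement is required character for character.  The boundary
  condition is fixed-zero by default (wrap available), and the single-seed
  initial condition is the conventional choice for this automaton; program
  and oracle always share these settings.
* **Mandelbrot** (`mandelbrot_source()` / `mandelbrot_oracle()`): the
  escape-time algorithm with iteration cap 1500 over the classic viewport
  [−2.5, 1] × [−1, 1], lane-parallel with each lane striding over pixels.
  The oracle mirrors the kernel's operation order exactly (squared-magnitude
  test `zr² + zi² > 4`, same association), so escape counts must agree as
  exact integers — floating-point order sensitivity is part of what the test
  pins down.  The default 256 × 192 grid keeps the interpreted run in the
  tens of seconds on one CPU; the grid is configurable and the equality
  requirement never changes with size.

## The MRI application

The simulator (`simulate_spgr_cine()`) models a T1-weighted SPGR CINE
acquisition on a synthetic 2-D phantom. Defaults follow the acquisition
this package targets: TE = 8 ms, TR = 102 ms, zero delay between frames.

**Phantom.** `make_phantom()` rasterizes tissue classes (ellipses and
rectangles; later primitives overwrite earlier) onto per-voxel maps: T1, T2,
proton density (equilibrium magnetization M0), baseline off-resonance
Δω₀ (rad/s), a unitless tissue field ρ, and integer labels.  The default
"brain-like" phantom is three concentric ellipses with conventional values —
CSF-like (T1 4.5 s, T2 2.2 s), GM-like (1.2 s, 0.1 s), WM-like (0.8 s,
0.07 s) on a 64 × 64, 3 mm grid.  It is a geometric stand-in: it has no
anatomy, no intra-class heterogeneity and no noise, so passing tests show
the *solver and plumbing* are right, not that images look clinical.
Coordinates are centered: voxel i has x = (i − nx/2 + 0.5)·dx, so the
analytic perturbation fields below need no origin bookkeeping.  ρ defaults
to the binary tissue mask (1 in tissue, 0 outside), making the contrast
agent's washout term act only within tissue; it is user-overridable.

**Bloch solver.** Magnetization evolves by symmetric Strang splitting:
relaxation over dt/2, rotation over dt, relaxation over dt/2
(`strang_step()`). Relaxation is the exact exponential operator (mx, my
scaled by e^(−h/T2); mz → M0 + (mz − M0)e^(−h/T1)), and rotation is an
optional RF tip about a transverse axis composed with z-precession by Δω·dt.
The transverse phase convention is M+ ← M+·e^(−iΔω·dt). Each excitation is
idealized SPGR: perfect spoiling (transverse magnetization zeroed), an
instantaneous tip by the flip angle (default 30°, a typical T1-weighted
setting; every quantitative check is against internal closed forms, so the
choice cancels), free evolution to TE where the complex signal mx + i·my is
recorded, then completion of the TR. A "frame" is `lines_per_frame`
excitations (default 8) and its image is the voxel-wise signal at the final
line's echo — single-shot idealization, no Fourier encoding, no noise, no
B1 inhomogeneity. Those are out of scope because every claim the package
makes concerns parameter *dynamics*, not encoding artifacts.

Numerical properties the tests enforce:

* with relaxation disabled the step is a pure rotation and conserves the
  norm to 10⁻¹² per step;
* relaxation-only evolution telescopes to the closed forms exactly (the
  half-step exponentials multiply out), to 10⁻¹²;
* a static phantom converges to the Ernst steady state
  M0·sinα·(1−E1)/(1−E1·cosα)·e^(−TE/T2), E1 = e^(−TR/T1), to 10⁻⁶ relative;
* on a dt-halving ladder against a fine-dt reference the split converges at
  second order.  The ladder drives the step with a *continuous* RF rotation
  and Δω = 0: precession and relaxation commute exactly (both are diagonal
  in the transverse/longitudinal decomposition), so only an RF term that
  mixes mz into the transverse plane exposes the splitting error; with Δω
  present the tip-then-precess composition inside the rotation stage would
  itself add a first-order term and mask the property being measured.

**Dynamic parameter maps.** Two analytic perturbations are built in.

*Contrast agent* — a non-mass-conserving Gaussian propagator

P(x,y,t) = exp(−((x−x₀)² + (y−y₀)²) / (2(σ₀² + 2Dt))) · exp(−λ·ρ(x,y)·t)

rescales the T1 map voxel-wise as T1(t) = T1(0) − A·T1(0)·P(t). Defaults
are σ₀ = 4 mm, D = 0.1, λ = 0.0012 s⁻¹, A = 0.7, (x₀, y₀) = (20, −20) mm.
D is used with units mm²·s⁻¹: it appears inside σ₀² + 2Dt, which is
dimensionally a variance in mm², even though such spread coefficients are
sometimes quoted in mm·s⁻¹; the numeral is taken as-is and the unit is
flagged here. A ≤ 1 is enforced so T1 stays positive. With ρ > 0 the
washout term makes the center-voxel T1 recover monotonically while the
half-maximum radius of P grows — both are tested properties.

*Heating* — a rectangular source diffusing anisotropically,

H(x,y,t) = T₀/4 · [erf((x+a/2)/(2√(kₓt))) − erf((x−a/2)/(2√(kₓt)))] · [same in y],

with the t → 0⁺ limit (T₀ × rectangle indicator; T₀/2 on edge midlines)
used at t ≤ 0, shifts the off-resonance map as Δω(t) = Δω₀ − αγ·H(t).
Defaults: T₀ = 40.3 °C, a × b = 4 cm × 3 cm, kₓ = 0.3, k_y = 0.2 mm² s⁻¹.
α and γ only ever appear as a product, so a single coefficient `c_thermo`
(rad s⁻¹ °C⁻¹) is exposed; its default 2π·0.01·42.58·3 corresponds to a
PRF coefficient of −0.01 ppm/°C at 3 T, and the thermometry round trip is
exact for *any* nonzero value by construction, so the default is a
convention, not a fitted constant.

Maps are recomputed once per frame at the frame's start time. A
per-excitation cadence would be a straightforward flag, but at TR = 102 ms
the fields above change negligibly within a frame and the per-frame cadence
keeps desk-scale runs fast; the update time stamp is recorded per frame so
every downstream check uses exactly the times the simulator used.

**Native vs VM execution.** The update routines exist twice: vectorized R
(`update_t1()`, `update_domega()`) and high-level-language programs
(`t1_update_source()`, `domega_update_source()`) compiled once and re-run
each frame over environment buffers (coordinates, baseline maps, a
parameter block including the clock, and the output map), lanes striding
over voxels. The two paths mirror each other's floating-point operation
order, so frame images are required to agree within 10⁻⁹ relative — in
practice the T1 path is bit-identical and the thermometry path differs only
through the two erf implementations (C library vs the normal-CDF identity),
at the 10⁻¹⁵ level.

**PRF thermometry.** `reconstruct_thermometry()` subtracts the baseline
phase (a run with no heating and Δω₀ = 0), wraps the difference to
(−π, π], and converts with ΔT = Δφ/(c_thermo·TE). No spatial phase
unwrapping is performed; reconstructed values are asserted only on the mask
where the true |Δφ| < π (at the defaults the peak phase is ≈ 2.6 rad, so
wrapping never occurs inside the rectangle anyway). The imposed kernel is
the oracle: per frame, the RMSE of reconstructed minus imposed temperature
on the mask must stay below 1% of T₀.

## Problem sizes and degenerate inputs

The shipped configurations are chosen at desk scale: Rule 110 at 310 × 100,
Mandelbrot at 256 × 192 with cap 1500, physics checks on 64 × 64 phantoms
with 10-frame CINE runs, 10⁴ randomized cases per operation in the fuzz
suite and 200 random programs in the optimizer differential test. Degenerate
inputs are defined rather than accidental: an empty instruction array is a
validation error; an empty source compiles to a single no-op; a zero-PD
voxel produces exactly zero signal; `heat_kernel()` at t ≤ 0 returns the
documented limit; loading with a mismatched buffer length or an undeclared
buffer is a binding error; and `amp > 1` in the contrast model is refused
because it would drive T1 non-positive.

## Known limitations

The VM interprets; it does not JIT, and no actual GPU execution is involved
— lanes emulate the SIMT model deterministically on one CPU. The operation
set is category-complete rather than name-complete against any external
instruction listing. The compiler forbids recursion and closures. The MRI
model is 2-D, noiseless, perfectly spoiled and unencoded; contrast transport
disregards mass conservation by design; phase differences are not spatially
unwrapped. These are the boundaries of what the tests can certify.
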