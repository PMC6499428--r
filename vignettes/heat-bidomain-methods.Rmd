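---
title: "Methods: coupled heat-bidomain simulation of cardiac tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled heat-bidomain simulation of cardiac tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiotherm)
```

## The model

`cardiotherm` simulates the interaction between cardiac electrical activity
and tissue temperature in two space dimensions. Four fields are evolved on a
rectangular sheet: the transmembrane potential $V_m$ (mV), the extracellular
potential $\phi_e$ (mV), a phenomenological recovery/gating variable $W$, and
the tissue temperature $T$ (degC).

The electrics are the classical bidomain equations,

$$\chi C_m \frac{\partial V_m}{\partial t}
  - \nabla\!\cdot\!(G_i \nabla V_m) - \nabla\!\cdot\!(G_i \nabla \phi_e)
  = -\chi\, I(V_m, W, T),$$
$$\nabla\!\cdot\!\big((G_i + G_e)\nabla \phi_e\big)
  = -\nabla\!\cdot\!(G_i \nabla V_m),$$
$$\frac{\partial W}{\partial t} = F(V_m, W, T),$$

with homogeneous Neumann (sealed-tissue) boundaries, membrane
surface-to-volume ratio $\chi = 2000\,\mathrm{cm^{-1}}$, capacitance
$C_m = 1\,\mu\mathrm{F/cm^2}$, and diagonal conductivity tensors
$G_i = \mathrm{diag}(3.0,\,0.315)$, $G_e = \mathrm{diag}(2.0,\,1.35)$ mS/cm
(fibers along the grid x-axis). Under proportional tensors
($G_i = \lambda G_e$) the system reduces to a monodomain equation with
conductivity $G_i/(1+\lambda)$; both forms are implemented
(`coupling_mode` in `solver_config()`).

Heat transfer follows Pennes' bioheat equation with a Joule source generated
by the propagating action potential:

$$\rho c_p \frac{\partial T}{\partial t}
  = \nabla\!\cdot\!(k \nabla T) + b_c (T^{*} - T) + G_i \nabla V_m \cdot \nabla V_m,$$

where $T^{*}$ is the perfusion (arterial blood) temperature, which doubles as
the cooling setpoint of the hypothermia protocols. The simplified source
$G_i\nabla V_m\cdot\nabla V_m$ is used for all production simulations; the
full intra/extracellular form
$G_i\nabla(V_m{+}\phi_e)\cdot\nabla(V_m{+}\phi_e) + G_e\nabla\phi_e\cdot\nabla\phi_e$
is available (`joule_source = "full"`) and reduces to the simplified form
bitwise when $\phi_e \equiv 0$. Electrical power arises in
$\mathrm{mS\,mV^2/cm^3}$; since $1\,\mathrm{mS\,mV^2} = 10^{-9}$ W this is
converted by the fixed factor $10^{-12}$ to $\mathrm{J/(ms\,cm^3)}$
(`joule_unit_conversion()`), which puts the self-heating of a single
wavefront on the micro-degC scale.

Temperature feeds back on the ionic kinetics through two multiplicative
factors,

$$I(V_m, W, T) = A\big(1 + B (T - T_a)\big)\, I_{ion}(V_m, W), \qquad
  F(V_m, W, T) = Q^{(T - T_a)/10}\, F_{ion}(V_m, W),$$

with reference temperature $T_a = 37$ degC and defaults $A = 1$, $Q = 2.4$,
$B = 0.07$ (Mitchell-Schaeffer) or $B = 0.081$ (Aliev-Panfilov) per degC.
Both factors are exactly 1 at 37 degC, so the temperature-coupled solver at
uniform normothermia is bit-equivalent to an isothermal bidomain solver.

## Ionic models

Two dimensional two-variable models are provided, sharing the voltage
scaling $V_{rest} = -85$ mV, $V_{peak} = 40$ mV, $v_{amp} = 125$ mV and the
normalized voltage $u = (V_m - V_{rest})/v_{amp}$.

**Mitchell-Schaeffer** (`ionic_model("ms")`), used for the planar-wave
temperature study:

$$I_{ion} = \frac{v_{amp}}{\tau_{in}} W u^2 (u - 1) + \frac{v_{amp}\,u}{\tau_{out}},
\qquad
F_{ion} = \begin{cases}
 (1 - W)/\tau_{open} & u < v_{gate},\\
 -W/\tau_{close} & u \ge v_{gate},
\end{cases}$$

with $\tau_{in} = 0.05$, $\tau_{out} = 1$, $\tau_{open} = 95$,
$\tau_{close} = 162$ ms and $v_{gate} = 0.13$ (dimensionless; the threshold
is compared against $u$). The repolarizing term is written in the
dimensionally consistent form $(V_m - V_{rest})/\tau_{out}$: the alternative
reading $(V_m-V_{rest})/(\tau_{out} v_{amp})$ would weaken repolarization by
a factor $v_{amp}$ and produce an APD near 1 s, incompatible with the
model's calibration (about 1 ms upstroke, about 0.7 m/s conduction and
about 260 ms APD at 37 degC), all of which the implemented form reproduces.

**Aliev-Panfilov** (`ionic_model("ap")`), used for the spiral-wave
(reentry) experiments, with $k = 8$, $a = 0.15$ (0.1 in the spiral studies),
$\mu_1 = 0.2$, $\mu_2 = 0.3$, $\epsilon_0 = 0.002$:

$$I_{ion} = \frac{1}{12.9}\left(\frac{k}{v_{amp}^2}(V_m - V_{rest})(V_m - v_a)(V_m - V_{peak})
   + (V_m - V_{rest}) W\right),$$
$$F_{ion} = \frac{1}{12.9}\left(\epsilon_0 + \frac{\mu_1 W}{u + \mu_2}\right)
  \big({-W} - k u (u - a - 1)\big),$$

with $v_a = v_{amp} a + V_{rest}$. The factor $1/12.9\ \mathrm{ms^{-1}}$ is
the dimensionalization of the model's single time unit (12.9 ms) and is
applied to *both* equations. This was a genuinely open reading of the
source formulas (which attach it visibly only to the recovery rate). The
whole-model rescaling is the standard dimensionalization, and it is also
forced by the physics: with the factor on the recovery alone, conduction
runs at about 0.35 m/s while the action potential lasts about 490 ms,
giving a reentry wavelength near 17 cm; no spiral can then complete its
first rotation on a 10 cm sheet, and the entire reentry/hypothermia
phenomenology disappears. With the standard rescaling the model conducts at
about 0.11 m/s with a 530 ms APD at 37 degC (wavelength about 5-6 cm), and
a 10 cm sheet sustains a single spiral, and cooling lengthens the
wavelength (APD grows like $Q^{-\Delta T/10}$, conduction slows like
$\sqrt{A(1+B\Delta T)}$).

## Discretization and solver

Space: uniform structured grids (`grid2d()`), second-order 5-point finite
differences for every $\nabla\!\cdot\!(G\nabla\cdot)$ operator, with
mirrored-ghost closure implementing zero co-normal flux. The
volume-weighted form of the operator matrix is symmetric negative
semi-definite with nullspace exactly the constants; the pure-Neumann
extracellular solve is gauge-fixed to zero spatial mean.

Time: the two-level BDF2 (Gear) formula
$(3y^{n+1} - 4y^n + y^{n-1})/(2\Delta t)$, started with a single
backward-Euler step (overall second order is unaffected). Each step solves,
in order:

1. the monolithic nonlinear electrics block for
   $(V_m^{n+1}, \phi_e^{n+1}, W^{n+1})$ with the temperature lagged at
   $T^{(n)}$ inside both thermal factors (no outer fixed-point iteration),
   by Newton iteration;
2. the linear bioheat system for $T^{n+1}$ with the Joule source evaluated
   from the fresh $V_m^{n+1}$ (unconditionally stable).

Newton details: the gating update has no spatial operator and is eliminated
pointwise, leaving a symmetric sparse system in $(V_m, \phi_e)$ whose
off-diagonal blocks are constant stiffness matrices and whose only
state-dependent part is a diagonal. The elliptic block's constant nullspace
is fixed by a diagonal penalty about $10^{-8}$ of the smallest physical
mode (it acts only on the constant mode, since the discrete elliptic
residual always sums to zero); the mean-zero gauge is restored exactly by
re-centering after convergence. Systems are factorized with sparse Cholesky
(supernodal, symbolic analysis reused across refactorizations) and fall
back to sparse LU if a shifted diagonal ever makes the system indefinite.
A factorization is reused across Newton iterations and across steps while
it still halves the residual per sweep; it is rebuilt at the current
iterate otherwise. Convergence demands a relative residual of $10^{-8}$
(scaled per equation block). The Mitchell-Schaeffer gate branch is not
smoothed: it is frozen over each time step at the step's starting state, so
the within-step Newton system is smooth and the gate switches branches
between steps with an $O(\Delta t)$ lag (negligible against the 95-162 ms
gate time constants). As a safety net the iteration also accepts once its
own update is negligible ($<10^{-8}$ mV) after at least a thousand-fold
residual reduction.
Divergence (iteration cap) aborts the run with the simulated time reached.

Default controls (`solver_config()`): $\Delta t = 0.3$ ms (the planar
temperature study uses 0.1 ms; a warning suggests $\Delta t \le 0.1$ ms when
$T^* \ge 43$ degC where the front steepens), Newton cap 20, snapshot stride
30 ms. Grid resolution is a configuration choice; the study configurations
below state the spacings used.

## Protocols

All experiments are declarative `protocol()` objects executed by
`run_simulation()`; everything is deterministic (there is no randomness
anywhere in the model), and the initial temperature always equals the
$t = 0$ setpoint field. The perfusion relaxation time is
$\rho c_p / b_c \approx 50$ s, so over a 1-2 s experiment the bulk tissue
temperature essentially *is* the setpoint; this is why the setpoint change
must be present from the start of a cooling experiment to affect it.

* **planar_q10** - the temperature study: a 10 cm sheet (or an equivalent
  thin strip: the initial condition and boundary conditions make the
  solution uniform across the strip), Mitchell-Schaeffer, 750 ms, an
  excited disc of radius $\sqrt{0.5}$ cm at the center
  ($V_m = 40$ mV inside, $-85$ mV outside), $W = 0.9$, $\phi_e = 0$.
  Probes at (5.5, 5) and (6.5, 5) for conduction velocity and (6, 5) for
  APD and rise time. Setpoints 27-43 degC.
* **single_spiral** - one Aliev-Panfilov spiral ($a = 0.1$) initiated by
  S1-S2 cross-field stimulation, with optional global hypothermia or disc
  cooling (radius 2 cm at the domain center) from $t = 0$.
* **multi_spiral** - three spirals ($a = 0.1$, $\mu_1 = 0.135$,
  $\epsilon_0 = 0.001$), cooling from $t = 600$ ms, 1950 ms duration.
* **domain_size_check** - multi_spiral on a 13 cm sheet.

S1-S2 construction: the S1 conditioning wave is planar and uniform across
the sheet, so its profile is computed once on a thin strip with the same
x-resolution and painted onto the sheet with its repolarization tail at a
prescribed position (fraction `back_frac`, default 0.55, of the domain).
The S2 stimulus then excites the part of the partially recovered wake lying
a distance `s2_gap` (default 0.75 cm) behind the tail, over a stack of
horizontal bands; every *interior* horizontal band edge sheds one free
wavefront end that curls into a spiral during a short settling simulation
(default 90-150 ms). One band covering the lower half of the sheet gives one
spiral; two bands with three interior edges give three. The singularity
count of the produced state is verified with the isopotential-crossing tip
detector and a mismatch is an error carrying the diagnostic snapshot. An S2
covering the whole sheet leaves no free end and is rejected this way. The
delay and geometry constants were calibrated once so that the single-spiral
count is exactly one, and are exposed as arguments.

## Measurements

* `apd()` - time above $-80$ mV at a probe, linearly interpolated
  crossings (sub-step resolution is required: the 37 degC upstroke lasts
  about 1 ms while the planar study samples every 0.1 ms).
* `rise_time()` - interpolated $-80 \to 30$ mV upstroke interval.
* `conduction_velocity()` - probe distance over the difference of first
  interpolated $-80$ mV upcrossings, in m/s, positive by convention.
* `q10()` - $(\mathrm{cold}/\mathrm{warm})^{10/(T_w - T_c)}$ for APD and
  the sign-flipped exponent for conduction velocity.
* `termination_time()` - earliest snapshot time from which max $V_m$
  stays below $-70$ mV (configurable) for the remainder of the run.
* `tip_locations()` - intersections of the $V_m = -22.5$ mV isoline (the
  mid-amplitude level, configurable) with the zero isoline of the one-step
  temporal difference, found per grid cell from the bilinear interpolants;
  nearby duplicates are merged within 3 grid spacings. Snapshots store the
  previous-step potential so the pair is always one $\Delta t$ apart.
* `heat_accumulation()` - the field $T - T^{*}$, its maximum and location;
  near a rotating tip the Joule source lingers, so the maximum tracks the
  tip region.

## Study configurations and what the tests show

The package's own verification uses deliberately scaled-down
configurations chosen to preserve the physics being measured:

* Planar temperature study: a $10 \times 0.08$ cm strip at
  $dx = 0.025$ cm, $dt = 0.1$ ms (the full-sheet solution is y-uniform,
  so the strip is not an approximation but the same 1-D physics). This
  reproduces APD 260/633 ms at 37/27 degC, rise time 1.15 ms and
  Q10(APD) 2.44. Conduction velocity measured with the default probe pair
  gives 0.744 m/s at 37 degC. At 27 degC the same procedure gives
  0.429 m/s: the front-speed temperature scaling of this model class is a
  square-root law in the current factor, $c \propto \sqrt{A(1+B\Delta T)}$
  (ratio $\sqrt{0.3} \approx 0.55$ between 27 and 37 degC; the converged
  steady-state velocities 0.63 and 0.33 m/s confirm it), so Q10(CV) comes
  out near 1.7-1.9. Reported experimental values near 2.2-2.3 would
  require a stronger conduction-temperature coupling than these two scalar
  factors provide; this is a known limitation of the model and is reported
  honestly by the acceptance checks rather than tuned around.
* Spiral/hypothermia study: a $10 \times 10$ cm sheet, heat-bidomain,
  $dt = 0.3$ ms, at $dx = 0.0625$ cm for the production calibration and
  $dx = 0.1$ cm in the routine test suite (the Aliev-Panfilov front is about
  1 mm wide, so both resolve it, marginally at 0.1 cm). The monodomain
  reduction with $\lambda = 1$ has a 1.6x smaller transverse conductivity
  than the bidomain's effective tensor and is used only for initiation
  plumbing and cheap qualitative tests.
* Outcome of the cooling comparison: the S1-S2 spiral persists with exactly
  one phase singularity for the full 1680 ms at uniform 37 degC and under
  disc cooling, as in the modeled study. Under global 30 degC hypothermia it
  also persists in this implementation, on sheets from 6 to 10 cm and at
  every tested placement of the tip. This is a structural property of the
  stated kinetics: the two thermal factors multiply the whole ionic current
  and the whole recovery rate ($f_I = 0.433$, $f_F = 0.542$ at 30 degC), so
  uniform cooling is close to a homogeneous time rescaling - conduction
  velocity scales by $\sqrt{f_I} = 0.66$, APD by $1/f_F = 1.85$, and the
  reentry wavelength grows by only about 22% - and, because the excitatory
  and repolarizing parts of the current share the same factor, the
  excitability balance is temperature-independent and cooling cannot by
  itself produce the conduction block that would terminate reentry. The
  hypothermic-termination experiment therefore reports persistence, and the
  corresponding checks are expected to flag it.
* Temporal accuracy: BDF2 second-order convergence is verified on a
  space-uniform configuration (slope 2 within 0.2 on
  $\Delta t \in \{0.2, 0.1, 0.05, 0.025\}$ ms against a fine-step
  reference); heat relaxation matches the closed-form exponential with
  rate $b_c/(\rho c_p)$ to $10^{-6}$ relative.

The simulated data generated by the protocols emulate the study's
*idealized* tissue: homogeneous, rectangular, fiber-aligned, with two-variable
phenomenological kinetics and temperature entering only through the two
scalar factors. They do not emulate tissue heterogeneity, realistic ionic
currents (and their individual temperature dependences), curved fiber
architecture, 3-D geometry, bath loading, or electromechanical coupling, so
passing tests demonstrate correctness of the stated model, not fidelity to
real myocardium beyond it.

## Known limitations

* The conduction-velocity temperature sensitivity is structurally
  $\sqrt{A(1+B\Delta T)}$, weaker than experimentally reported Q10(CV)
  values (see above).
* Fixed uniform grids: the sharp 37 degC Mitchell-Schaeffer front
  (sub-millimeter) needs $dx \lesssim 0.25$ mm for a few-percent
  conduction-velocity accuracy; adaptive meshing is out of scope.
* Spiral initiation is a calibrated construction; singulariy counts are
  verified, but tip trajectories depend on the initiation geometry, so
  termination times in reentry experiments are reproducible within the
  package yet sensitive to the initiation parameters.
* The bioheat perfusion term uses a single setpoint field as both arterial
  temperature and cooling control, exactly as in the modeled experiments.
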