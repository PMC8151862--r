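---
title: "Models and methods behind erythrosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erythrosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

erythrosim studies how red blood cell (RBC) rigidity and shape influence
the geometry of RBC aggregates and, through it, the erythrocyte
sedimentation rate (ESR). It combines four pieces: a two-dimensional
mesoscopic simulator of aggregating cells, void ("hole") statistics of the
resulting configurations, sub-pixel sedimentation-curve extraction from
Westergren-tube image stacks, and the microfluidic shape phase-diagram
analysis (croissant/slipper transition point, acanthocyte deformability
fits). A synthetic-data module generates every input the analyses need,
with known ground truth. This vignette documents the models, the numerical
choices and their rationale, and what the synthetic tests do and do not
demonstrate about real data.

## The 2D ring-polymer cell model

Each cell is a closed chain of `n_vertices = 50` vertices connected by
springs, with total potential energy

$$E = \sum_i \frac{k_s}{2}\Big(\frac{l_i - l_0}{l_0}\Big)^2
    + k_b \sum_i (1 - \cos\theta_i)
    + \frac{k_a}{2}\Big(\frac{A - A_0}{A_0}\Big)^2 + E_\text{pair},$$

where $l_i$ are bond lengths ($l_0 = L_0/50$, circumference
$L_0 = 24.5\,\mu m$), $\theta_i$ the turning angles between consecutive
bonds, and $A$ the shoelace area of the ring. The area constraint enforces
the discocyte shape at fixed circumference: the reduced area
$s = 4\pi A_0/L_0^2 = 0.48$ reproduces the elongated biconcave-like 2D
cross-section (long axis around 8 um) known from 2D vesicle models. All
energies are in units of $k_BT = 1$.

Cell kinds differ only in stiffness: healthy discocytes have
$k_b = 50\,k_BT$, rigidified discocytes $k_b = 500\,k_BT$, and
acanthocytes — built from the six-lobed polar curve
$r(\theta) = a(1 + b\cos 6\theta)$ with lobe amplitude $b = 0.3$, rescaled
to the same circumference $L_0$ — are fully rigid bodies. Because the
circumference is shared but the enclosed area is not, acanthocytes enclose
about 9% less area than discocytes.

Parameter choices the source material leaves open, with our defaults:

* **Cell size** ($L_0 = 24.5\,\mu m$, $s = 0.48$): gives a discocyte long
  axis of 7–8 um, the physiological value; both configurable.
* **Spring constant** $k_s = 1000\,k_BT$: large enough that membrane
  stretching is negligible (per-bond thermal strain sd ~3%, perimeter sd
  ~0.45%, well within the 1% perimeter-drift tolerance the model assumes)
  while keeping the explicit integrator stable at a usable time step; the
  stability limit scales as $dt < \gamma l_0^2 / (2 k_s)$.
* **Area constant** $k_a = 10^5\,k_BT$: holds the relaxed area within
  0.05% of $A_0$ (bending pressure inflates the ring against the
  constraint) and keeps area excursions under aggregation stress inside
  the 2% band the model tolerates; real RBC area is nearly conserved, so
  a stiff constraint is also the physical choice.
* **Bending discretization**: $k_b(1 - \cos\theta)$ per joint with zero
  spontaneous angle; the quoted bending rigidities are read as the
  discrete joint constants.

## Adhesion and excluded volume

Aggregation is driven by a short-range potential between vertices of
different cells, quoted in the truncated Lennard-Jones form
$U(r) = 4\varepsilon((\sigma/r)^{12} - (\sigma/r)^6)$ with
$\sigma = 0.3\,\mu m$ and $r_\text{cut} = 0.72\,\mu m$ and
$\varepsilon \in [0, 3]\,k_BT$. Taken literally, $\varepsilon = 0$ would
switch off excluded volume along with adhesion and let cells interpenetrate.
We therefore split the interaction:

* an always-on, purely repulsive WCA core of strength
  `eps_rep` $= 1\,k_BT$, cut at $2^{1/6}\sigma$;
* the attractive remainder of the truncated LJ, shifted to zero at
  $r_\text{cut}$ and normalized so its minimum (at $2^{1/6}\sigma$) has
  depth exactly $-\varepsilon_\text{attr}$.

The adhesion strength `eps_attr` is then the single knob for aggregation,
exactly spanning the quoted 0–3 $k_BT$ range, while excluded volume is
preserved throughout. Same-cell vertex pairs more than two ring positions
apart interact through the repulsive core only (no self-adhesion), which
prevents self-crossing without stiffening the ring.

## Langevin dynamics

The integrator is first-order overdamped (Euler–Maruyama) with friction
$\gamma = 1$ per vertex, the standard limit for aggregation kinetics at
this scale:

$$\mathbf{x}_{t+dt} = \mathbf{x}_t + \frac{\mathbf{F}}{\gamma}dt +
  \sqrt{2 k_BT\, dt/\gamma}\; \boldsymbol{\xi}.$$

Rigid cells move as rigid bodies: the net force and torque about the
centroid drive translation with mobility $1/(N\gamma)$ and rotation with
mobility $1/(\gamma I)$, $I = \sum_i |\mathbf{r}_i - \mathbf{r}_{cm}|^2$,
with matching thermal noise, so a rigid cell diffuses exactly like the
centre of mass of its deformable counterpart. Shapes are regenerated from
the body frame each step, so rigid geometry is preserved to machine
precision.

Numerical safeguards:

* The default step $dt = 5\times10^{-5}$ (time unit
  $\gamma\,\mu m^2/k_BT$) sits at ~40% of the spring-stability limit.
* Thermal runs cap each per-step displacement at six standard deviations
  of the free-particle step. A free particle hits the cap with
  probability ~$10^{-8}$ (diffusion statistics are unaffected; the
  measured MSD matches $4Dt$ within a few percent), but the cap prevents
  the rare deep excursions into the $r^{-12}$ core from destabilizing the
  explicit update. An uncapped step larger than $\sigma/2$ is treated as
  an unstable-time-step failure.
* Athermal runs ($k_BT = 0$) use backtracking: a step that would raise
  the energy is retried with half the step, making relaxation
  monotonically non-increasing.
* Pair interactions use a Verlet neighbor list (skin 0.35 um) over
  minimum-image periodic distances; the list is rebuilt when any vertex
  has moved half the skin.
* The noise source is a self-contained xoshiro256++ generator with a
  ziggurat normal sampler, seeded from the user's integer seed, so
  trajectories are bitwise reproducible.

## Initialization at 50% hematocrit

Dense non-overlapping ring configurations cannot be drawn directly:
random placement saturates far below 50% area fraction, and overlapping
rings must never cross (the bond spacing 0.49 um exceeds the repulsive
range 0.337 um, so once two membranes interpenetrate the dynamics cannot
untangle them). `initialize_configuration()` therefore grows the
packing. Shrunken copies of the reference shapes are placed with random
orientations on a jittered hexagonal-offset lattice (the straight
free-space corridors of a square lattice would register across rows and
masquerade as giant voids) and inflated back to full size. During
inflation all cells are treated as rigid bodies relaxed with repulsion
only, softly tethered to their lattice sites so the packing stays
homogeneous; each growth increment is bounded by the currently available
membrane clearance $\sqrt{d_\min^2 - (l_0/2)^2}$, so a rescaling step
can never sweep a membrane segment across another cell's vertex and
crossings are impossible by construction. The packing phase runs at a
tenfold reduced friction (packing is preparation, not physical
dynamics — at the physical friction the slow rigid bodies cannot break
force arches within any reasonable budget) and uses a 1.2x widened
repulsive core so that the final jammed state leaves every inter-cell
vertex pair beyond the physical $\sigma$; occasional small thermal
bursts unlock force-balanced contacts. The final settle keeps all
shapes frozen — the cells are exactly at their relaxed template shapes,
so this is valid — and the dynamics then starts from homogeneous,
overlap-free configurations for every composition. Cell counts follow
largest-remainder rounding of the composition fractions, and the total
reference area matches the requested hematocrit within 2%.

## Hole analysis

Configurations are rasterized on a periodic grid (default 0.3 um): a grid
cell is occupied if its centre falls inside any cell polygon or within
$\sigma/2$ of a vertex (membrane thickness). Free space is labeled with
4-connectivity (8-connectivity for the occupied phase would be the
complementary choice; 4-connectivity for free space avoids checkerboard
leakage through diagonal contacts), and components touching opposite
boundaries are merged under periodicity, so a void straddling the
boundary is counted once.

In two dimensions exactly one phase of a binary pattern can percolate:
once the aggregate network spans the domain, its raw complementary free
space is a single connected plasma void, and raw component labeling
stops carrying information. The compartments seen between aggregated
cells in micrographs are delimited by cells in contact, so before
labeling, the sweep pipeline morphologically closes the occupied phase
(`seal_below`, default $r_\text{cut} - \sigma = 0.42$ um): membranes
within the adhesive interaction range are treated as sealed contacts,
and the compartments become the faces of the aggregate network. Raw
labeling (`seal_below = 0`) remains the default of `label_holes()`
itself and is what the flood-fill equivalence tests exercise.

Void-size distributions of gel-like aggregates are exponential in their
tail, so the **characteristic hole size** is estimated as the scale of a
shifted exponential above a minimum-area cutoff of one discocyte
reference area $A_0 \approx 22.9\,\mu m^2$ (excluding intra-aggregate
slivers and discretization debris). The default estimator is the
mean excess $\hat A = \mathrm{mean}(a_i - a_\text{min})$ — the
maximum-likelihood estimator of the shifted-exponential scale — with one
robustness amendment: compartments larger than 5% of the domain area are
censored as percolation-scale objects, a finite-size artifact of the
desk-scale domain that violates the exponential law and would otherwise
dominate the mean. The uncensored MLE (`"mean_excess"`), a robust
quantile version (`"median_excess"`, $\mathrm{median}/\ln 2$) and the
plain mean of all hole areas (`"mean"`) are labeled alternatives.

Replicated sweeps (5 seeds per condition by default) are compared with
the Shapiro–Wilk normality report per condition, the Kruskal–Wallis
omnibus rank test, and Dunn-style rank comparisons of every condition
against the reference with Holm adjustment (the omnibus test alone cannot
name the smallest affected fraction). The per-run statistic is the
average characteristic size over the last three saved snapshots: the
per-snapshot estimate fluctuates by roughly 10% between adjacent saves,
and the tail mean measures the same late-time state with less noise at
identical simulation cost. A run is flagged non-converged when the
characteristic size at three quarters of the run differs from the
late-time value by more than 5%. At desk scale the gels still coarsen on
the accessible time scale, so these flags are expected and reported
rather than hidden.

## Sedimentation curves

Tube frames are reduced to a 1D intensity profile (row means over the
region of interest), lightly smoothed (3-point moving average). The
interface between bright plasma and the dark packed-cell column is the
most negative central-difference gradient, refined to sub-pixel precision
by a parabola through the extremum and its two neighbours. The extremum
must exceed five times the median absolute deviation of the gradient,
which makes the extraction invariant under affine brightness/contrast
changes and rejects frames without an interface. A threshold-crossing
variant (first crossing of the mid-intensity level) is available behind a
flag. On synthetic stacks with a 3-pixel ramp, 0.05 mm/pixel and noise at
5% of contrast, the maximum extraction error across 50 seeds stays below
0.1 mm — the accuracy the measurement method claims.

Curves report height fallen (mm) relative to the first frame, the
Westergren convention. The 2-hour reading interpolates linearly between
neighbouring samples; the between-visit change is
$100\,(h_\text{during} - h_\text{after})/h_\text{after}$, expressing the
during-treatment ESR relative to the post-treatment baseline (chosen
because the reported values describe treatment readings as an increase
over the later baseline).

## Phase-diagram analysis

Flow records (one row per cell: pressure drop, velocity, shape label) are
grouped by pressure; each group contributes its mean velocity and shape
fractions. The croissant fraction rises and the slipper fraction falls
with velocity; both are fitted with the 3-parameter saturating
exponential $y(v) = y_\infty + (y_0 - y_\infty)e^{-v/v_c}$ — the simplest
family with exponential approach to a finite plateau. The fit runs in a
box-constrained parameterization that keeps the entire curve inside
[0, 1] and enforces the growth/decay direction, with multistart over the
rate constant. Constant fractions leave $v_c$ unidentifiable and are
flagged degenerate rather than fitted.

The **transition point** is the velocity where the fitted croissant and
slipper curves intersect (equal fractions — with equal group sizes this
coincides with equal counts). The difference of the two curves is scanned
on a 512-point grid and the first sign change is polished with Brent's
method; multiple crossings return the smallest with a warning, no
crossing is an error rather than an arbitrary answer. A delta-method
standard error propagates both fits' parameter covariances through the
implicit-function derivative.

The **acanthocyte deformability fit** is nonlinear least squares of
$\varphi_{Ac}(v) = N_0 e^{dv}$ on raw fractions (no log transform, so
zero counts at high velocity are fine). $N_0$ is the undeformed fraction
extrapolated to stasis; $d$ (per mm/s) is the deformability parameter,
negative when flow deforms acanthocytes away from their resting shape;
$|d|$ is the spread statistic used in cohort summaries. Transition points
of two cohorts are compared with Shapiro–Wilk checks followed by an
unpaired two-sided Student's t-test (pooled variance).

**Uncertainty of the fitted quantities.** Group fractions carry binomial
sampling noise whose variance $p(1-p)/n$ changes several-fold across the
velocity grid; unweighted least squares then misstates the parameter
covariance (in simulation, Wald intervals for $N_0$ covered the truth
only ~75% of the time at nominal 95%). Both fitters therefore accept the
per-group cell counts and use inverse-variance weights
$n / (\hat p (1 - \hat p))$; with weights the $N_0$ and $d$ intervals
reach 92–93% coverage at 200 cells per group. The transition point adds
a second subtlety: croissant and slipper fractions are measured on the
same cells, hence negatively correlated, and a delta-method error that
treats the two fits as independent is too small (~85% coverage).
`jackknife_transition_se()` instead refits both curves leaving out one
velocity group at a time, which resamples whole groups and captures the
correlation (~97% coverage in the same simulation).

## Synthetic data: what it emulates and what it does not

* `gen_flow_records()` draws per-group shape labels multinomially from
  the model curves above (defaults: croissant $0.10 \to 0.65$, slipper
  $0.75 \to 0.20$, both $v_c = 2.5$ mm/s; acanthocytes $N_0 = 0.12$,
  $d = -0.35$; 8 velocity groups spanning 0.5–10 mm/s, 200 cells per
  group). The defaults put the croissant/slipper crossing near 2.2 mm/s,
  inside the observed range, and keep all four fractions (with the
  remainder class "other") in [0, 1] everywhere. Per-cell velocities
  jitter by 2% around the group mean.
* `gen_tube_stack()` renders bright-over-dark frames with a 3-pixel
  intensity ramp whose centre follows a logistic fall trajectory, plus
  additive Gaussian noise; ground truth is returned alongside. One frame
  per minute mirrors the acquisition protocol.
* `rbc_cohort_fraction()` implements the treated-cohort model: uniform
  production, a fixed 15-day maturation delay, and a fixed lifespan of
  117.5 days (midpoint of the observed 115–120 d range; the source curve
  is schematic, so a lifespan distribution is deliberately not modeled).
  The result is continuous, piecewise linear and clamped to [0, 1].

These generators reproduce the *statistical structure* the estimators
assume — multinomial label noise, monotone interface trajectories with
pixel noise, exponential void tails. They do not emulate optical
artifacts (menisci, reflections, drift), manual-labeling error,
donor-to-donor heterogeneity, or hydrodynamics; passing the synthetic
suites therefore validates the estimators and the simulator contracts,
not the biology of any particular patient cohort.

## Problem sizes and study conditions

The simulation study conditions follow the source setup where stated
(hematocrit 50%, adhesion 1.5 kBT for composition sweeps, compositions
{0, 20, 40, 60, 80, 100}% abnormal cells, at least 5 seeds per
condition). The composition sweep runs on a 100 x 100 um periodic domain
(the documented scaled-down mode; the full 300 x 300 um domain remains
available through `model_params()`), about 220 cells of 50 vertices
each, integrated for 40,000–50,000 steps (2–2.5 diffusion time units) —
long enough for the gel to form and compartmentalize, short enough that
a full five-seed, six-condition sweep completes in well under half an
hour of desk time. Property-style suites use smaller domains (25–70 um)
so the whole test suite stays desk-scale. Statistical calibration suites
(confidence-interval coverage of the fit parameters) use 200 synthetic
repetitions.

## Known limitations

* 2D geometry; no hydrodynamic interactions, no explicit plasma-protein
  (depletion) physics, no gravity inside the simulator — sedimentation is
  linked to aggregate geometry only through the hole-size statistics.
* The overdamped integrator flavour, friction, time step and run length
  are numerical choices, not measured quantities; aggregate coarsening on
  the accessible time scale is transient, and the convergence flags make
  that visible.
* **Kinetic arrest at desk scale.** On the accessible domain sizes and
  run lengths (of order 100 x 100 um and a few diffusion times), the
  aggregating suspension is in a kinetically arrested, still-coarsening
  regime, not at the steady state of the aggregation process. In this
  regime stronger adhesion and larger rigid-cell fractions tend to
  *freeze a finer compartment structure* (bonds lock before the network
  can compact), so compartment-size orderings measured here can differ
  from — and for some contrasts oppose — orderings expected of
  near-equilibrium dense aggregates. The composition-sweep and
  adhesion-sweep comparisons in the test suite report whatever the
  simulations actually produce under these conditions; they are
  statements about this model at this scale, not about patient data.
* The characteristic-hole-size estimator (cutoff at one cell area,
  censored mean-excess scale) is a documented stand-in for an estimator
  the source literature does not restate at this scale.
* The croissant/slipper fit family and the equal-fraction definition of
  the transition point are modeling choices; with strongly unbalanced
  group sizes, equal fractions and equal counts differ.
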