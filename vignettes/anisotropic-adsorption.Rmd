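---
title: "Facet-resolved analysis of oligomer adsorption on Wulff nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facet-resolved analysis of oligomer adsorption on Wulff nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npadsorb)
```

npadsorb is a desk-scale pipeline for studying how short
poly(lactic-co-glycolic acid) (PLGA) oligomers aggregate in solution and
adsorb anisotropically on faceted gold nanoparticles.  This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the synthetic data generator can and cannot
stand in for.  Units are nm, ps, kJ/mol and K throughout.

## Wulff construction and facet classification

The equilibrium shape of a crystal with fixed mass places each facet family
at a distance from the particle center proportional to its surface energy.
For an FCC metal truncated along the $\{100\}$ and $\{111\}$ families the
shape is controlled by one number, the surface-energy ratio
$\gamma_{111}/\gamma_{100}$, and by the target mass, expressed as the
equivalent spherical diameter $d$ with four atoms per cubic cell:
$N_\mathrm{target} = (\pi/6)\,d^3 / (a^3/4)$.

`build_wulff_nanoparticle()` enumerates lattice sites around a central atom
and keeps those inside the polyhedron $\{x : n\cdot x \le h_n\}$ with
$h_{100} = s$ and $h_{111} = \gamma\, s$.  Because each site enters the
polyhedron at a well-defined scale $s_i = \max(d_{100,i},
d_{111,i}/\gamma)$, sorting the $s_i$ yields the entire staircase of
attainable atom counts at once, and the count nearest the mass target is
selected directly (ties toward the smaller cluster).  This closed-form
solution replaces an iterative bisection on $s$; it finds the same cluster
without an iteration tolerance.  For gold ($a = 0.4078$ nm, a standard bulk
value), $\gamma = 0.96$ and $d = 4$ nm the attainable counts near the
1976.5-atom target are 1709, 1925 and 2441, so the builder returns the
1925-atom particle of equivalent diameter 3.96 nm:

```{r wulff}
np <- build_wulff_nanoparticle(lattice_spec(), wulff_spec(0.96, 4.0))
np
```

Surface atoms are classified by coordination number (CN) within a cutoff
placed at the midpoint of the first and second neighbour shells
($a/\sqrt2$ and $a$): CN 12 is bulk, CN 9 a $\{111\}$ terrace atom, CN 8 a
$\{100\}$ terrace atom, and anything else an edge, corner or step atom.
This is the standard FCC mapping; edge atoms are kept as their own class
rather than being apportioned to a facet.

A second, independent grouping records for every atom which facet family's
*outermost crystal plane* it occupies (`plane_membership()`).  Atoms on the
border between a $\{111\}$ and a $\{100\}$ facet belong to both families.
This grouping exists because facet-exposure histograms need every piece of
surface attributed to a plane family; see below.

## Shrake–Rupley SASA and the edge-attribution conventions

`compute_sasa()` implements Shrake–Rupley quadrature: each atom's van der
Waals sphere is inflated by the probe radius (0.14 nm, water) and covered
with a deterministic golden-spiral point set (960 points by default); a
point is accessible if it lies outside every other inflated sphere, and the
accessible fraction times $4\pi (r+p)^2$ is the atom's area.  Deterministic
points make areas exactly reproducible; doubling the quadrature changes the
1925-atom particle's total by less than 0.5%.  The gold van der Waals
radius defaults to 0.166 nm and coarse adsorbate sites to 0.17 nm; none of
these radii are critical — the facet shares below move by well under a
percentage point across 0.15–0.21 nm.

How edge atoms are attributed decides the headline facet-exposure numbers,
so `per_facet_sasa()` reports three conventions side by side:

* `cn_exclusive` — only CN-labelled terrace areas, edge band excluded;
* `plane_exclusive` — outermost-plane members exclusive to one family;
* `plane_shared` — border atoms count toward **every** family whose
  terminating plane they occupy, which is exactly what overlapping atom
  index groups produce in the standard MD SASA workflow.

On a ~4 nm particle the edge band carries a large share of the accessible
area, so the conventions differ strongly.  The `plane_shared` convention is
the one that reproduces the known 66:34 intrinsic $\{111\}{:}\{100\}$
exposure of the reference particle, and it is what `facet_budget()` and the
acceptance workflow report:

```{r shares}
per_facet_sasa(np)$shares
```

For the shape variants built at $\gamma = 0.7$ ($\{111\}$-dominated) and
$\gamma = 1.4$ ($\{100\}$-dominated), the same pipeline yields $\{111\}$
and $\{100\}$ shares of roughly 81% and 68%.  Published reference values
for such shapes are ~78% and ~74%; the residual gap is a genuine
limitation worth stating: at extreme $\gamma$ the attainable discrete
shapes at fixed mass are sparse (adjacent candidates jump by several
hundred atoms and by 5–10 share points), and the construction tool,
rounding rule and atom-group definitions behind the reference values are
not fully specified, so the shares cannot be pinned more tightly from the
published information alone.

## The synthetic adsorption model

Real trajectories of this system come from all-atom MD.  The package
replaces the MD engine with a kinetic Monte Carlo surrogate
(`simulate_adsorption()`) that reproduces the *statistical structure* the
downstream analyses assume, with ground truth attached:

* oligomers are rigid 69-site point clouds (one site per atom of the
  6 LA + 2 GA chain) of 0.5 nm radius, initially dispersed outside a
  keep-out sphere around the particle;
* free clusters random-walk with a step scaling as $\mathrm{size}^{-1/3}$
  (Stokes-like slowdown of larger aggregates);
* two free clusters merge irreversibly when their centers approach within
  the aggregation radius — aggregation before adsorption, as observed;
* a free cluster whose sites come within the adsorption radius of a
  surface atom binds with probability $p_0\alpha$, $p_0$ or
  $p_0(1+\alpha)/2$ depending on whether the nearest surface atom is a
  $\{111\}$, $\{100\}$ or edge atom.  $\alpha$ is the facet affinity, the
  single knob producing anisotropic coverage;
* every merge and binding (with its anchor facet) is logged.

Defaults mirror the reference conditions: 60 oligomers (45 mM) in a 13 nm
periodic box, 1000 frames of 100 ps (a 100 ns horizon).  The kinetic rates
are not observable in the paper trail, so they were fixed once at values
that reproduce the qualitative phenomenology — aggregation dominating the
first ~20% of the run, adsorption continuing throughout: a monomer rms
step of 0.5 nm/frame, an aggregation radius of 1.0 nm (two cloud radii),
an adsorption radius of 0.45 nm (contact distance plus slack) and
$p_0 = 0.1$ per contact-frame.

What the generator does **not** emulate: solvent structure and
hydrodynamics, force-field energetics, cluster shape relaxation (merged
clusters stay rigid), reversible desorption, and surface crowding (bound
clusters do not block later arrivals).  Tests that pass on this generator
therefore validate the *analysis* machinery — clustering, SASA
bookkeeping, rate estimation — not the physics of any particular polymer.

Parameter recovery closes the loop: `estimate_facet_affinity()` recovers
$\alpha$ as the ratio of facet binding rates per unit bare facet area,
with a binomial confidence interval, and does so across $\alpha \in \{1,
3, 10\}$ in the test suite.  Recovery runs suppress aggregation (tiny
aggregation radius) so each oligomer contributes an independent binding
event, and use a particle with comparable $\{111\}$ and $\{100\}$ areas so
both event counts carry information.

## Cluster kinetics

`count_clusters()` follows the HDBSCAN* recipe to the depth molecular
aggregates need: core distances at `min_samples` = 7 (counting the point
itself), mutual-reachability distances under the minimum-image manhattan
metric, a single-linkage hierarchy (`stats::hclust`), and extraction of
clusters of at least `min_cluster_size` = 60 points from the condensed
tree.  Leaf selection is the default; excess-of-mass stability selection
is available.  Points shed above the selected clusters are noise and are
excluded from counts.  The hyperparameter defaults (7, 60, manhattan,
leaf) are the reference analysis's; 60 sits just below the 69 sites of one
oligomer so a lone free chain still counts as a cluster.  A plain
fixed-radius DBSCAN lives in the test helpers as the independent oracle.

Radial distribution analyses come in the two flavours the coverage story
needs: `rdf_to_reference()` (shell- and density-normalised $g(r)$ of sites
around the particle; peaks just outside the ~2 nm particle radius signal
adsorption) and `pair_distance_distribution()` (shell-normalised only;
its sub-0.3 nm region reflects rigid intra-oligomer geometry and is
time-invariant, while growth between 1–2 nm tracks self-aggregation).

## Umbrella sampling and WHAM

`sample_umbrella_windows()` draws from $\propto \exp[-(U(\xi) +
\tfrac12 k(\xi - \xi_i)^2)/k_BT]$ by Metropolis Monte Carlo with the step
auto-tuned to 30–50% acceptance during burn-in and thinning between
recorded samples.  The default restraint, $k = 10\,000$ kJ mol$^{-1}$
nm$^{-2}$ at 300 K, matches the reference protocol; window spacing is an
open choice (default 0.1 nm).

`wham()` iterates the standard self-consistent equations on binned window
histograms (0.02 nm bins, convergence when no window free energy moves by
more than $10^{-7} k_BT$), reports gaps between non-overlapping adjacent
windows by their centers, and anchors the profile to zero over the
largest-$\xi$ plateau using count-weighted bins (anchoring on a single
fringe bin would inject log-of-small-count noise into the whole profile).
Bins with fewer than 5 samples are dropped from the report for the same
reason.

One statistical point deserves emphasis.  At $k = 10^4$ the biased
distributions have $\sigma = \sqrt{k_BT/k} \approx 0.016$ nm, so windows
spaced 0.1 nm apart overlap only in their far tails; the window-to-window
free-energy matching error is then bounded below by overlap statistics at
roughly $k_BT\sqrt{2/(N\,\Omega)}$ per link ($\Omega \approx e^{-5}$ for
this spacing), and accumulates as a random walk along the profile.  With
11 windows of 5000 samples and three replicas this floor is about 0.8
kJ/mol RMS — the package reaches it, and no estimator can do better from
those samples.  With window spacing chosen for genuine histogram overlap
(0.04 nm or softer restraints), the same code recovers a planted 10 kJ/mol
well to ~0.2 kJ/mol RMSE, which is the regime the test suite demonstrates;
production protocols pairing stiff restraints with wide spacing should
expect the floor, not the overlap regime.

`assemble_polar_fel()` interpolates PMFs measured at several particle
orientations onto a common $\xi$ grid — orientations are generated by
rotating the particle about the axis orthogonal to both facet normals, so
$\theta = 0°$ faces $\{100\}$ and $\theta = 54.7°$ faces $\{111\}$ — and
reports the global minimum, flagging $\theta$-degenerate minima.
`lj_energy_profile()` sums truncated 12-6 Lennard-Jones pair energies
(1 nm cutoff, geometric/arithmetic combining; no force-field values are
hard-coded) as the enthalpy proxy, and `decompose_thermo()` forms
$T\Delta S = \Delta H - \Delta G$ on the shared support of the two curves,
re-anchored at the largest $\xi^* = \xi - R$, so
$\Delta G - \Delta H + T\Delta S = 0$ holds exactly by construction.

## Numerical choices and degenerate inputs

* The classification cutoff must lie strictly between the FCC neighbour
  shells; anything else is refused as ambiguous.
* A mass target below half an atom is an error; exactly one atom yields a
  single EDGE-labelled atom at the origin.
* Coincident adsorbate/particle sites in SASA are skipped with a warning;
  $r = 0$ in a Lennard-Jones sum is an error.
* Metropolis acceptance below 1% after tuning aborts with a step-size
  error rather than returning a frozen chain.
* All randomness flows from one seed through named substreams
  (`substream_seed()`), so adding a stage never shifts another stage's
  stream, and every output file records the package version, seed and a
  hash of the generating parameters.

## Problem sizes in the test suite

The suite exercises the full pipeline at reduced sizes chosen to keep the
whole run in the low minutes while leaving every statistical test with
clear power: recovery runs use 25–40 oligomers of 6–12 sites over a few
hundred to ~1200 frames with 4–8 replicas; clustering oracles run on a few
hundred points; the dispersed-oligomer count check runs at the full study
condition (60 oligomers × 69 sites).  The facet-exposure and
Wulff-construction checks always use the full 4 nm particles — they are
cheap and exact.

## Known limitations

* Only FCC lattices and the $\{100\}/\{111\}$ families are supported; no
  surface reconstruction or relaxation.
* The $\gamma = 0.7$ and $\gamma = 1.4$ facet shares carry the
  discrete-shape ambiguity discussed above.
* The kinetic model's absolute timescales are nominal; only ordering and
  ratios (concentration effects, facet bias) are meaningful.
* WHAM error bars come from replica spread only; no bootstrap.
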