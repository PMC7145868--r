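# memtraj

Analysis toolkit for coarse-grained simulations of membrane proteins that
reorient ("topple") inside the lipid bilayer — in particular the
S-components of ECF-type vitamin transporters, which rotate their membrane
topology by ~90° during the transport cycle while the surrounding membrane
bends and thins around the ECF module. The package is for computational
membrane biophysicists who have trajectories (or umbrella-sampling window
data) and want the standard desk-side analyses of that mechanism without
rerunning any MD:

* **Orientation statistics** — the tilt angle between helix 5 and the
  bilayer normal per frame; classification of the *toppled* state
  (75° ≤ θ ≤ 125°, bounds inclusive); per-replica stability (toppled in
  strictly more than 50% of frames) and the across-replica stable fraction
  p̂ with binomial SD √(p̂(1−p̂)/n).
* **Membrane maps** — per-leaflet least-squares fits of a full bivariate
  degree-4 polynomial z(x, y) to phosphate-bead positions, giving bilayer
  thickness d(x, y) = z⁺(x, y) − z⁻(x, y) and Monge-patch mean curvature
  H = [(1+z_y²)z_xx − 2 z_x z_y z_xy + (1+z_x²)z_yy] / [2(1+z_x²+z_y²)^{3/2}]
  on a grid around the protein, frame-averaged, with the protein footprint
  masked.
* **Lipid fingerprint** — headgroup contacts within 0.7 nm (minimum
  image), the annular-shell census, and the depletion–enrichment index
  D–E(L) = ratio(L)_shell / ratio(L)_bulk per lipid type, plus per-residue
  contact occupancies and binding-site grouping.
* **Free energies** — 1-D potential of mean force from umbrella windows
  (COM–COM reaction coordinate) by the weighted histogram analysis method
  (WHAM), F(x) = −kT ln p(x) anchored at the profile minimum, with
  moving-block bootstrap error bars.
* **Synthetic data** — seeded generators for bilayers with prescribed
  surface/thickness fields, two-state Markov tilt dynamics, prescribed
  annular enrichment, and exact Boltzmann-sampled umbrella windows; every
  analysis stage is validated against these known ground truths.

See the methods vignette (`vignettes/membrane-toppling-analysis.Rmd`) for
the full statistical account and design rationale.

## Worked example

Everything below is generated, analysed and printed by the package itself
(seeds fixed, no external data):

```r
library(memtraj)

# 1. tilt statistics: 15 replicas of two-state toppling dynamics
replicas <- lapply(1:15, function(r)
  make_tilt_trajectory(tilt_spec(
    transition_rates = c(topple = 2e-3, untopple = 2e-4),
    n_frames = 2000, dt = 100, seed = r), replica_id = paste0("rep", r)))
stability_summary(replicas, label = "POPE:POPG:CL 70:25:5")
#> <mt_stability> 'POPE:POPG:CL 70:25:5': 15/15 replicas stable toppled
#>   (fraction 1.000, binomial sd 0.000 on fraction scale)

# 2. membrane maps from a dimpled synthetic bilayer
bl <- make_bilayer_trajectory(bilayer_spec(
  n_lipids_per_leaflet = 1000,
  thickness_field = function(x, y) 4 - 0.4 * exp(-(x^2 + y^2) / 8),
  seed = 7), n_frames = 20)
maps <- membrane_maps(bl$frames, bl$topology, grid = mt_grid(4, 0.2))
maps$thickness
#> <mt_grid_map> thickness (nm): 40 x 40 cells, 20 frame(s), range 3.62..4.037

# 3. lipid fingerprint with prescribed cardiolipin enrichment
sh <- make_enriched_shell_frames(
  bulk_composition  = c(POPE = 0.70, POPG = 0.25, CL = 0.05),
  shell_composition = c(POPE = 0.60, POPG = 0.30, CL = 0.10),
  n_shell = 25, n_bulk = 475, n_frames = 100, seed = 3)
as.data.frame(de_index(shell_census(sh$frames, sh$protein_sel, sh$topology)))
#>   lipid_type de_index         se n_frames
#> 1         CL   2.0000 0.11952769      100
#> 2       POPE   0.8640 0.01524415      100
#> 3       POPG   1.1808 0.03844442      100

# 4. free-energy profile from Boltzmann-sampled umbrella windows
ws <- make_umbrella_samples(potential_spec(
  U = function(x) 0.5 * 100 * x^2, domain = c(-1.6, 1.6),
  centers = seq(-1.2, 1.2, by = 0.1), force_constant = 2500,
  n_per_window = 5000, temperature = 303, seed = 4))
pmf <- bootstrap_pmf(ws, n_boot = 100, seed = 5)
pmf
#> <mt_pmf> 129 bins over -1.290..1.270 nm (width 0.02 nm), T = 303 K
#>   free energy range 0.00..80.86 kJ/mol (anchored at min); 1 iterations
#>   bootstrap errors: median 0.301 kJ/mol
```

Reading the output: all 15 replicas stay toppled, so the stable fraction
is 1 and its binomial SD exactly 0. The thickness map spans ~3.62–4.04 nm,
recovering the prescribed 4.0 nm bulk and 3.6 nm dimple minimum. The D–E
index recovers the prescribed two-fold cardiolipin enrichment (2.00 ±
0.12) with the accompanying POPE depletion. The WHAM profile reproduces
the generating parabola (½·100·x² reaches 80 kJ/mol at |x| ≈ 1.27 nm)
with sub-kJ/mol bootstrap errors.

## Command line

A thin CLI over the same functions ships in `inst/cli/memtraj.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/memtraj.R", package = "memtraj"))')
Rscript $CLI run --seed 1 --out-dir out          # synth -> all four stages
Rscript $CLI pmf --windows win/manifest.tsv --temp 303 --boot 200 --seed 1
```

Subcommands: `run`/`synth`, `orient`, `maps`, `fingerprint`, `pmf`; all
tabular output is TSV with `#`-commented headers naming units. An example
pipeline configuration is in `inst/extdata/example_config.yaml`.

## File formats

* **GRO** (fixed-column, nm, box on the last line) and **PDB** (CRYST1
  box, Å converted to nm); orthorhombic boxes only.
* **Index files**: `[ name ]` headers with 1-based particle indices, plus
  a residue mini-language `select_resid(frame, "resid 69-75,127-133")`.
* **Lipid topology map**: TSV with `residue_name`, `lipid_type`,
  `headgroup_beads`, `phosphate_beads` (comma-separated bead names).
* **Umbrella window files**: `# umbrella_window center=<nm>
  force_constant=<kJ/mol/nm^2>` followed by `time coordinate` rows; a
  manifest TSV lists the window files.
* **Trajectory dialect** (whitespace table), grammar:

```
trajectory  := { comment | frame }
comment     := "#" <anything> NEWLINE
frame       := "FRAME" time_ps box_x box_y box_z NEWLINE { particle }
particle    := index x_nm y_nm z_nm NEWLINE     # exactly N rows, template order
```

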