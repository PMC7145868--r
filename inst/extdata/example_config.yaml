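# Example pipeline configuration for `mt_run()` / the `run` CLI subcommand.
# Any omitted key falls back to default_config(); units: nm, ps, K, kJ/mol.
synth:
  bilayer:
    n_lipids_per_leaflet: 400
    n_frames: 5
    thickness: 4.0        # bulk thickness, nm
    dimple_depth: 0.4     # Gaussian thinning amplitude, nm
    dimple_sigma: 2.0     # thinning width, nm
    noise_sd: 0.1         # phosphate z noise, nm
  tilt:
    n_replicas: 8
    n_frames: 500
    dt: 100               # frame spacing, ps
    model: two_state_markov
    topple_rate: 2.0e-3   # canonical -> toppled, per ps
    untopple_rate: 2.0e-4 # toppled -> canonical, per ps
    mean_toppled: 90
    mean_canonical: 30
    noise_sd: 5           # angle noise, degrees
  shell:
    n_shell: 25
    n_bulk: 400
    n_frames: 50
    bulk:  {POPE: 0.70, POPG: 0.25, CL: 0.05}
    shell: {POPE: 0.60, POPG: 0.30, CL: 0.10}
  umbrella:
    k_harm: 100           # underlying harmonic potential, kJ/mol/nm^2
    centers_from: -1.2
    centers_to: 1.2
    spacing: 0.1          # window spacing, nm
    force_constant: 2500  # restraint, kJ/mol/nm^2
    n_per_window: 500
    temperature: 303
orient:
  band: [75, 125]         # toppled band, degrees (inclusive)
  threshold: 0.5          # strict stable-replica majority rule
maps:
  half_width: 4           # analysis patch half-width, nm
  spacing: 0.2            # grid cell, nm
  what: both
fingerprint:
  cutoff: 0.7             # headgroup contact cutoff, nm
pmf:
  bin_width: 0.02
  tol: 1.0e-7
  n_boot: 50
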