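# membind

Analysis toolkit for molecular-dynamics ensembles of the amyloid-beta(1-40)
peptide binding a mixed POPC/POPS/cholesterol (3:1:1) bilayer — the kind of
system used to study how amyloid peptides damage neuronal membranes. Given a
trajectory, `membind` computes everything a binding-mechanism study needs:

* **PBC-aware contacts** — heavy-atom peptide–bilayer contacts within
  0.5 nm (minimum image, orthorhombic boxes), per frame and per residue,
  with a cell list checked exactly against an O(N²) brute force;
* **distances and insertion depths** — perpendicular COM distance, and per
  residue `depth = |z_res − z_bilayer| − 2.0 nm` (negative = buried);
* **hydrogen bonds** — geometric criterion, donor–acceptor ≤ 0.3 nm and
  D→H/D→A angle ≤ 20°, split by partner (POPC/POPS/CHOL/water/peptide);
* **secondary structure** — DSSP-style Kabsch–Sander assignment into
  E/B/H/G/I/T/C and the grouped fractions C+T+B, E, G+H+I;
* **free-energy landscapes** — `G = −kT ln P` over (distance × contacts),
  basin detection with steepest-descent membership, per-basin landscapes
  over (RMSD × beta content) with microstate extraction;
* **binding-model classification** — the four structural binding modes
  (beta-rich C-terminal anchor; surface-lying helical N-terminus;
  beta-rich deep C-terminal insertion; deeply buried random coil);
* **REST2 diagnostics** — geometric temperature ladders
  (`T_i = T_min·exp(i·ln(T_max/T_min)/(N−1))`) and exchange-log acceptance,
  visitation and round-trip statistics;
* **a synthetic-data generator** — toy peptide+bilayer ensembles with
  planted depths, secondary structure, hydrogen bonds and model labels, so
  the whole pipeline is testable without running any simulation.

The 40-residue sequence `DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV` is split
into the standard regions NT (1–16), CHC (17–21), CL (22–29), CT (30–40).

## Worked example

Generate a 50/50 bound/unbound synthetic ensemble, write it as multi-model
PDB, and run the full pipeline (configs are JSON; every threshold lives
there):

```r
library(membind)
cfg  <- analysis_config(equilibration_discard = 0)   # synthetic: no transient
spec <- synthetic_spec("mixture", n_frames = 120, seed = 1)
ens  <- generate_binding_ensemble(spec)
write_pdb_multimodel(ens$trajectory, "mix.pdb")
rep  <- run_full_pipeline("mix.pdb", cfg, "report")

head(rep$per_frame[, c("frame","distance","n_contacts","bound","beta","model")], 3)
#>   frame distance n_contacts bound  beta   model
#> 1     1 2.965456        384  TRUE 0.375  model1
#> 2     2 2.915941        332  TRUE 0.375  model1
#> 3     3 2.952003        366  TRUE 0.375  model1
mean(rep$per_frame$bound)
#> [1] 0.5                       # exactly the planted bound fraction
rep$microstates[, c("microstate", "mean_beta", "population")]
#>   microstate mean_beta population
#> 1         a2     0.000         60   # unbound coil conformer
#> 2         a1     0.375         60   # bound beta-rich conformer
```

The bound conformer sits ~2.9 nm from the bilayer COM with ~350 atomic
contacts and 37.5 % beta content, so every bound frame classifies as the
beta-rich C-terminal-anchor mode (`model1`); unbound frames sit at ~5 nm
with zero contacts. The per-residue table shows the planted C-terminal
anchoring — CT residues carry the highest membrane contact fractions. With
a more permissive basin filter (`basin_min_depth_kT = 3`) the
distance×contacts landscape resolves the shallow bound-side minima into
separate lettered basins (a at 4.98 nm, then b…i between 2.9–3.1 nm).

A REST2 ladder and its diagnostics:

```r
make_ladder(343, 500, 18)$temperatures[1:5]
#> [1] 343.00 350.69 358.55 366.59 374.81
log <- generate_exchange_log(make_ladder(343, 500, 18), 5000, 0.2, seed = 1)
exchange_rates(log)$mean_rate_pairs
#> [1] 0.1991  # prescribed 0.20
```

## Command line

An installed copy ships `exec/membind` (also callable in-process via
`membind_cli()`):

```sh
membind synth    --model mixture --frames 50 --seed 1 --out traj.pdb --truth truth.json
membind contacts --traj traj.pdb --config cfg.json --out contacts.tsv
membind rest2 ladder --tmin 343 --tmax 500 --nrep 18 --out ladder.tsv
membind run-all  --traj traj.pdb --config cfg.json --out-dir report/
```

Exchange logs are whitespace-delimited text, one attempt per line:
`time_ps i j accepted` with adjacent 0-based rung indices `i`, `j = i+1`
and `accepted` in {0,1}; `#` starts a comment.

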