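# osteoscaffold

Scaffold-guided bone regeneration in a large-animal metaphyseal defect,
as one tested computational chain: parametric lattice scaffolds and
their directional stiffness, a synthetic ovine micro-CT cohort with a
known osteogenic ground truth, segmentation-based bone-ingrowth
quantification, semi-quantitative regional scoring, and the paired
statistics that separate strain-driven from injury-driven osteogenesis.

## The problem

When a porous scaffold is implanted into a trabecular-bone defect, how
much new bone grows into it depends on the scaffold's apparent elastic
modulus (compliant scaffolds transmit strain and stimulate deposition;
stiff ones shield it) and on the host's individual regenerative
capacity. The study design modelled here implants two different
scaffolds, one per femur, in each of 12 ewes, using four designs that
span the stiffness range of trabecular bone:

| design | material (E_s) | architecture | nominal porosity | axial E_app |
|---|---|---|---|---|
| TC | titanium, 100 GPa | octet truss | 0.60 | 7100 MPa |
| TB | titanium, 100 GPa | stochastic, connectivity 4.5 | 0.80 | 1400 MPa |
| PB | polyamide, 2 GPa | octet truss | 0.45 | 220 MPa |
| PC | polyamide, 2 GPa | orthogonal cubic grid | 0.35 | 220 MPa |

The headline quantity is the **bone ingrowth fraction**: segmented bone
volume divided by (defect volume x scaffold porosity), in percent of
the available pore volume. The package implements the whole chain:

* **Lattice generation** — octet (FCC) truss, orthogonal cubic grid,
  and Poisson-disk stochastic networks pruned to a target mean node
  connectivity; strut radii solved by bisection against the nominal
  porosity; trimming to the implant cylinder (16 mm x 15 mm); binary
  STL export.
* **Frame mechanics** — a direct-stiffness solver with 6 DOF per node
  (Timoshenko beam elements; Euler-Bernoulli and pin-jointed limits
  available), apparent modulus E_app = (F/A)/(delta/L) between rigid
  platens, direction sweeps over the hemisphere at 15 degree
  increments of phi and theta, the anisotropy coefficient
  max:min E_app, and modulus extraction from the 20-70%-of-yield
  hysteresis loop of a compression curve.
* **Synthetic cohort** — 12 animals, paired allocation (each design
  used six times), latent truth with an injury-driven peripheral
  component equal in every animal (6.8 pp) and a strain-driven central
  gain awarded to the more compliant scaffold of each pair (strong
  responders mean 14 pp, weak mean 3 pp, one reversed animal); voxel
  phantoms at 27-136 um with titanium beam-hardening halos,
  partial-volume blur and noise; fluorescence interface sections with
  a mineral label band deposited 14 days before endpoint.
* **Quantification** — the polyamide path (global threshold inside the
  delineated defect cylinder) and the titanium path (metal threshold +
  3-kernel dilation, local-adaptive thresholding on every second slice
  with shape interpolation, halo-excluding); virtual sections at 2, 5,
  8, 11 and 14 mm depth.
* **Scoring and statistics** — the 0-4 interface/interior rubric with
  a three-rater consensus rule (rescore when the discrepancy exceeds
  one unit), mineral apposition rate (band offset / 14 days), exact
  paired Wilcoxon signed-rank by full sign enumeration, regression of
  ingrowth on log10 stiffness, and two-means responder classification.

## Worked example

```r
library(osteoscaffold)

## build the polyamide biomimetic octet scaffold and probe its stiffness
b <- build_design_lattice("PB")
b$radius                      # 0.389 (mm) - solved for porosity 0.45
b$porosity                    # 0.448

sw <- direction_sweep(b, increment = 15)
anisotropy_coefficient(sw)    # 1.63  (max:min apparent modulus)
direction_average_modulus(sw) # 266   (MPa)
sw$angles$modulus_MPa[1]      # 210.5 (MPa, axial)

## one synthetic implanted femur: a strong responder's compliant leg
sub <- phantom_substrate("PB", voxel_size = 0.1)
ph  <- build_phantom(sub, latent_total_pp = 20.8, peripheral_pp = 6.8,
                     seed = 3)
quantify_phantom(ph)
#> <ingrowth_result> 21.19% of pore volume (253016 bone / 2653800 defect
#>   voxels, porosity 0.45)

## the full 24-scaffold cohort, one seed (~2.5 min)
res <- run_cohort_analysis(seed = 1)
res$summary$strong_mean_diff  # 13.9 (pp, vs 14 latent)
res$summary$weak_mean_diff    # 3.0  (pp, vs 3 latent)
res$summary$n_strong          # 7
res$regression$slope          # -6.3 (pp per decade of stiffness, p < 0.001)
```

The numbers above are what the code printed for these calls at the
given seeds; stochastic values shift slightly from seed to seed.

## Command line

A thin CLI over the same functions ships in `inst/cli/scaffold.R`:

```sh
Rscript inst/cli/scaffold.R build  --design PB --seed 1 --out designs/
Rscript inst/cli/scaffold.R sweep  --design PC --increment 15 --out pc.csv
Rscript inst/cli/scaffold.R cohort --seed 1 --voxel 100 --out run/
```

See `vignettes/scaffold-ingrowth.Rmd` for the model assumptions,
parameter choices and limitations.
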