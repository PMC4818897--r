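# elbow4d

Four-dimensional (3D + time) simulation of elbow flexion-extension for
planning debridement arthroplasty in degenerative elbow osteoarthritis.
From a *single* CT position — watertight STL surfaces of the distal humerus
and of the forearm (ulna + radius as one rigid body) — the package:

1. **fits the flexion-extension hinge axis** with the *two-rings* method:
   three points are plotted on the trochlea and three on the capitellum, a
   circle (ring) is drawn through each triple, and the axis is the line
   through the two ring centers,
   `axis = line(c_trochlea, c_capitellum)`;
2. **animates the forearm** rigidly about that axis (Rodrigues rotation,
   every pose built from the reference pose at its absolute angle);
3. **quantifies and localizes bony impingement** at any flexion angle as
   the voxelized overlap volume between the bones (cells whose centers lie
   inside both meshes x voxel volume), coloring impinging faces red in
   exported PLY frames; and
4. **estimates the impingement-free arc** from a flexion sweep, plus the
   statistics used to evaluate such simulations: one-way/two-way random
   intraclass correlations ICC(1,1) and ICC(2,1) with 95% CIs for
   duplicate overlap measurements, and cohort mean (±SD) / t-test
   summaries of range-of-motion outcomes.

No patient data is required: a parametric phantom generator builds
hinge-joint meshes with an exactly known axis and osteophytes whose first
contact angle is solved in closed form, so the whole pipeline is testable
offline. It is intended for researchers in musculoskeletal biomechanics
and surgical simulation who want a reproducible, scriptable counterpart to
interactive CAD workflows.

## Worked example

Generate a phantom whose osteophyte is designed to first contact at 120°
of flexion, fit the axis from its landmark file, and sweep:

```r
library(elbow4d)
dir <- file.path(tempdir(), "demo")
cmd_phantom(dir, contact_angle_deg = 120, seed = 1)
axis <- cmd_fit_axis(file.path(dir, "landmarks.json"),
                     file.path(dir, "axis.json"))
#> fit-axis: rings 10.000 / 8.000 mm, centers 40.000 mm apart,
#>           residuals 0.0000 / 0.0000 mm -> .../axis.json
print(axis)
#> <hinge_axis: point (0.000, -0.000, 0.000) mm, direction (1.0000, 0.0000, 0.0000)>
#>   rings: radii 10.000 / 8.000 mm, centers 40.000 mm apart,
#>   normal-axis angles 0.000 / 0.000 deg

profile <- cmd_sweep(file.path(dir, "humerus.stl"),
                     file.path(dir, "forearm.stl"),
                     axis = file.path(dir, "axis.json"),
                     out_dir = file.path(dir, "sweep"),
                     angle_start = 105, angle_stop = 135,
                     angle_step = 1, voxel_size = 0.2)
print(profile)
#> <rom_profile: 31 angles in [105, 135] deg, free arc 15 deg
#>  (extension contact: none, flexion contact: 120 deg)>
```

The fitted rings reproduce the phantom's 10 mm trochlear and 8 mm
capitellar radii with zero residual, the axis is the true hinge, and the
sweep's first flexion contact lands exactly on the designed 120°: overlap
volumes are 0 mm³ through 120° and grow monotonically beyond (0.576 mm³ at
130°, 0.848 mm³ at 135°). `cmd_simulate` additionally writes one frame per
angle (posed forearm STL, both bones as PLY with impinging faces in red)
plus a JSON manifest — the "movie" as a bit-exact frame directory.

Cohort statistics on the bundled 11-patient pre/post range-of-motion
table:

```r
rom <- read_rom_table(system.file("extdata", "cohort_rom.csv",
                                  package = "elbow4d"))
cohort_summary(rom$arc_pre)    #> 101 (±21), n = 11
cohort_summary(rom$arc_post)   #> 124 (±12), n = 11
paired_t(rom$arc_pre, rom$arc_post)
#> $t 3.651437  $df 10  $p 0.004451702  $mean_difference 23.18182
```

The mean flexion-extension arc improves from 101° to 124° (paired t(10) =
3.65, p = 0.004).

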