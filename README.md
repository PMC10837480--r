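# nemadef

Detection and classification of half-integer nematic topological defects
in confluent cell layers, from per-cell centroids and orientations.

## The problem

Confluent tissues — epithelial and endothelial monolayers, dense
bacterial colonies — behave as active nematics: each cell's long axis
defines a head–tail symmetric orientation (a *director*, defined modulo
π), and the local average of these orientations forms a nematic field.
Point singularities of that field, the comet-shaped **+1/2** and
trefoil-shaped **−1/2** topological defects, mediate processes from cell
extrusion to morphogenesis, so locating and classifying them accurately
is a routine need in tissue image analysis.

The classical tool is the **winding number**: the total rotation of the
director around a closed loop, always a multiple of π, giving the defect
charge k = (rotation)/2π ∈ {+1/2, 0, −1/2, …}. It works well when cells
are elongated and the field is well defined everywhere. In epithelial
layers, however, cells can be nearly isotropic: regions of low nematic
order are common and *do not necessarily contain a defect*, and a loop
around such a region can wind to ±1/2 by chance. `nemadef` implements a
pipeline built for exactly this regime:

1. **Director field** — interpolate scattered cell orientations to a fine
   grid and smooth them over a sliding window in double-angle space
   (averaging (cos 2θ, sin 2θ) respects the π-wrap).
2. **Order parameter** — at each node, S = largest eigenvalue of the
   nematic tensor Q = ⟨2û_m û_n − δ_mn⟩, computed in closed form as
   S = √(⟨cos 2θ⟩² + ⟨sin 2θ⟩²); S = 1 for perfect alignment, 0 for an
   isotropic patch.
3. **Candidates** — contiguous regions with S < S_th (default 0.15);
   their centres of mass become candidate defect positions, so detection
   is effectively off-lattice.
4. **Classification** — a 9×9 director region of interest (ROI) around
   each candidate (spanning ~6 cell diameters) is classified as +1/2,
   no defect, or −1/2, either by the boundary winding number or by a
   small convolutional network (two 32-feature 3×3 convolutions, a
   100-unit fully connected layer with 50% dropout, softmax output)
   trained by SGD on rotation/reflection-augmented labelled ROIs. The CNN
   sees the whole patch, not just its perimeter, which is what lets it
   reject defect-free disordered regions that fool the winding number.
5. **Properties** — +1/2 polarity ψ = atan2(p_y, p_x) from the divergence
   of Q, p = (∂xQxx + ∂yQxy, ∂xQxy − ∂yQxx), and oriented ensemble
   averages of the velocity (or director) field around detected defects,
   with a normalized single-point correlation ⟨v_A·v_B⟩ for comparing
   averaged fields.

A seeded synthetic-tissue generator with planted, analytically known
defects (jittered triangular lattices, von Mises angular noise in
double-angle space, planted flow templates) provides ground truth for
training, benchmarking and every test. Precision, sensitivity and
F1 = 2PS/(P+S) are computed per class with class-size-weighted totals.

## Worked example

```r
library(nemadef)

# a 20x20 periodic synthetic tissue (~400 cells) with a planted defect pair
cfg <- synth_config(box = c(20, 20), n_cells = 400,
                    defects = data.frame(x = c(5, 15), y = c(10, 10),
                                         charge = c(0.5, -0.5)),
                    kappa = 8, seed = 42)
sim <- generate_frame(cfg)
rec <- detect_defects(sim$frame, method = "winding")
print(rec, digits = 3)
#>      x    y class charge p_pos p_none p_neg   psi  min_S region_size  method
#> 1  4.9 10.1  +1/2    0.5    NA     NA    NA -3.11 0.0247           5 winding
#> 2 15.1 10.1  -1/2   -0.5    NA     NA    NA    NA 0.0394           5 winding
```

Both planted defects are recovered within a fraction of a cell diameter
of their true cores, with the correct charges; `psi` is the +1/2 comet
axis and `min_S` the deepest order-parameter dip in each candidate
region. Training and evaluating the CNN on synthetic ground truth:

```r
ds    <- augment_rois(generate_labeled_rois(150, kappa = c(16, 6, 2), seed = 1))
model <- train_defect_cnn(ds, train_config(epochs = 10, seed = 2))
test  <- generate_labeled_rois(100, kappa = 6, seed = 3)
classification_report(test$label, predict(model, test), method = "cnn")
#> <defect_metrics> [cnn] n = 300, accuracy = 1.000
#>  class precision sensitivity f1 size
#>   +1/2         1           1  1  100
#>   none         1           1  1  100
#>   -1/2         1           1  1  100
#> weighted: P = 1.000, Sens = 1.000, F1 = 1.000
```

At moderate noise the network separates the three classes perfectly on
this unseen test set, while the winding number misclassifies a few
percent of the disordered no-defect patches (see the methods vignette for
the benchmark design). A command-line interface over the same functions
lives at `inst/cli/nemadef.R`, with subcommands
`simulate | detect | train | evaluate | average-field`.

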