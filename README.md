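# taxofeat

Automatic species identification from single-specimen photographs.

Taxonomic collections hold far more specimens than there are taxonomists to
identify them. `taxofeat` implements a classical morphometric pipeline for
closing part of that gap: a photograph of a single specimen (fish, leaf,
butterfly — anything photographed against a roughly uniform background) is
segmented, reduced to binary, contour and skeleton rasters, summarized by a
fixed 15-dimensional feature vector, and classified to species by a
one-hidden-layer sigmoid neural network trained with backpropagation. The
package is aimed at researchers who want a transparent, fully inspectable
baseline classifier — every feature has a closed-form definition and the
network is small enough to audit weight by weight.

## The feature vector

Each specimen is described by 15 numbers, computed from the binary mask
`I(x, y)`, its contour, and the denoised grayscale restricted to the mask:

**Geometric** (from the mask and its boundary):

| Feature | Definition |
|---|---|
| Area `A` | foreground pixel count |
| Perimeter `P` | boundary pixel count (pixels with a background 8-neighbor) |
| Diameter `D` | `sqrt(4A/pi)` — diameter of the circle of equal area |
| Compatibility `C` | `4*pi*A / P^2` |
| Compactness `Co` | `P^2 / (4*pi*A)` |
| Solidity `S` | `A` / pixel count of the filled convex hull |

**Texture** (first order on the gray-level histogram `h(x)` of the region;
second order on a gray-level co-occurrence matrix `P_δ` at distance 1 pixel
along the −45° diagonal, 16 gray bins):

| Feature | Definition |
|---|---|
| Mean `mu` | `Σ x·h(x)` |
| Variance `var` | `Σ (x−mu)²·h(x)` |
| Uniformity `U` | `ΣΣ P²` |
| Entropy `E` | `−ΣΣ P·log P` |
| Homogeneity `HG` | `ΣΣ P/(1+|x−y|)` |
| Inertia `I` | `ΣΣ P·(x−y)²` |

**Moment invariants** (on the binary mask, central moments `u_pq`):

| Feature | Definition |
|---|---|
| `phi1` | first Hu invariant `(u20+u02)/u00²` |
| `I1` | affine invariant `(u20·u02 − u11²)/u00⁴` |
| `I2` | affine invariant of the third-order central moments, `u00⁻¹⁰`-normalized |

The classifier is a 15-`h`-`m` perceptron with logistic sigmoid activations
throughout, trained by online stochastic gradient descent on squared error
("generations" = individual pattern presentations), with z-score feature
standardization learned on the training set and stored with the model.

## Worked example

The package ships a synthetic specimen generator (parametric perturbed-
ellipse silhouettes with striped, noisy interiors), so the whole pipeline
can be exercised without any image collection:

```r
library(taxofeat)

specs <- benchmark_specs(4)                    # 4 synthetic species
ds    <- generate_dataset(specs, 12, seed = 42)
ft    <- synthetic_feature_table(ds)           # segment + extract features
round(ft[1:3, c("A", "P", "C", "S", "mu", "E", "phi1", "I1")], 4)
#>     A   P      C      S       mu      E   phi1     I1
#> 1 447 106 0.4999 0.9978  94.9485 3.6133 0.2421 0.0063
#> 2 502 104 0.5832 1.0000 103.5299 3.6368 0.2073 0.0063
#> 3 407  98 0.5325 1.0000 102.9631 3.6700 0.2209 0.0063

sp    <- stratified_split(ft, 0.8, seed = 1)
model <- mlp_train(sp$train, train_config(learning_rate = 0.1,
                                          generations = 20000,
                                          hidden = 30, seed = 1))
model
#> mlp_model: 15 - 30 - 4 sigmoid network; 4 species; lr 0.1 ; 20000 generations

sc <- success_rate(model, sp$test)
sprintf("test success rate: %.1f%% on %d held-out specimens", sc$rate, sc$n)
#> "test success rate: 87.5% on 8 held-out specimens"
```

The first row reads: a specimen of 447 px area with a 106-px boundary,
moderately elongated (`C` = 0.50), essentially convex (`S` = 0.998), mean
interior gray level 94.9. The confusion matrix in `sc$confusion` shows
which species absorb the errors — with only 10 training images per species
the two most similar synthetic species trade one misidentification.

A command-line front end with the same verbs
(`preprocess`, `extract`, `train`, `predict`, `evaluate`, `sweep`,
`simulate`) is installed at `inst/cli/taxofeat`.

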