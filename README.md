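# watact

Water-activity prediction for binary aqueous sugar and polyol solutions
from theoretical molecular descriptors.

## The problem

Water activity (a_w) — the ratio of the water vapor pressure over a
solution to that over pure water — controls microbial stability, shelf
life and texture in food, cosmetic and pharmaceutical formulation. For a
binary solution of a nonelectrolyte, the Norrish model describes it with
a single solute-specific parameter, the Norrish constant k_N:

    a_w = x_w · exp(k_N · x_s²),        x_w = 1 − x_s

where x_s is the solute mole fraction. k_N = 0 recovers Raoult's law;
k_N < 0 (the case for sugars and polyols) means the solute depresses
water activity below the ideal line. k_N is normally estimated from
experimental data by minimizing

    Φ(k_N) = Σᵢ (a_w,i^exp − a_w,i^calc)²

`watact` implements the complementary, data-free route: predict k_N from
the solute's molecular structure alone, using two cheap theoretical
descriptors and their combination,

* **I_AC** — information index on atomic composition (constitutional,
  hydrogens included): I_AC = A_tot·log₂A_tot − Σⱼ Aⱼ·log₂Aⱼ over the
  atom-type counts Aⱼ;
* **Z₁** — first Zagreb index (topological): Σ δᵢ² over the vertex
  degrees of the hydrogen-depleted molecular graph;
* **G = I_AC + Z₁** — the global information index, folding composition
  and connectivity into one number.

Five QSPR model forms link k_N to the descriptors (linear and power
forms in (I_AC, Z₁); linear, power and origin-constrained quadratic
forms in G); they are fitted by least squares in k_N space and compared
through the variance statistic φ = Θ/(n − p), where Θ is the sum of
squared k_N errors. On the reference set of eight sugars/polyols the
quadratic single-index model k_N = b₃₁·G + b₃₂·G² attains the minimal φ
and is the recommended form.

The package is aimed at formulation scientists and property-prediction
researchers who need a quick a_w estimate for a hydroxylated solute
before (or instead of) measuring it.

## Worked example

```r
library(watact)

glc <- builtinSolute("glucose")        # glucopyranose, built in
glc
#> Molecule 'glucose': C6H12O6 | 12 heavy atoms, 12 bonds, 1 ring(s)

descriptorTable(list(glc))
#>    solute I_AC Z1  G n_OH
#> 1 glucose   36 58 94    5

fits <- fitReferenceModels()           # five forms, reference data
selectModel(fits)
#> QsprFit 'polyG': b31 = -0.02181, b32 = -7.519e-05 | Theta = 0.3105, ...

(kn <- predictKnFromStructure(glc, fits$polyG))
#> [1] -2.714601

head(activityCurve(kn, xsMax = 0.1, nPoints = 6))
#>    x_s       a_w
#> 1 0.00 1.0000000
#> 2 0.02 0.9789365
#> 3 0.04 0.9558394
#> 4 0.06 0.9308585
#> 5 0.08 0.9041545
#> 6 0.10 0.8758972
```

The predicted k_N = −2.715 for glucose sits within 0.21 of the
experimentally fitted value (−2.920), and the reconstructed curve gives
a_w = 0.876 at x_s = 0.1 versus 0.874 from the experimental constant.

Estimating k_N from (synthetic) activity data instead:

```r
d <- generateActivityDataset(knTrue = -6.777, xsRange = c(0.018, 0.098),
                             nPoints = 10, noiseSigma = 1e-3, seed = 7,
                             solute = "sucrose")
fitNorrish(d)
#> NorrishFit 'sucrose': k_N = -6.7044, Phi_min = 1.354e-05, epsilon = 1.010e-03 (n = 10)
```

A command-line front end with the same capabilities is installed at
`system.file("scripts", "watact", package = "watact")` (subcommands
`descriptors`, `fit-norrish`, `fit-qspr`, `predict`, `curve`,
`simulate`, `reproduce-tables`).

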