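# phenodrift

Clonal populations of *Methylobacterium extorquens* — a methylotroph whose
central metabolism runs through the toxin formaldehyde — contain cells with
continuously distributed formaldehyde tolerance: the frequency of cells
able to grow at ≥ *x* mM falls roughly one order of magnitude per mM, even
though the population is genetically uniform.  Selective plating shows this
distribution shifting under formaldehyde selection and relaxing back during
formaldehyde-free regrowth, at substrate-dependent rates.  phenodrift is an
R package for researchers analysing such CFU tolerance-distribution time
series: it fits a phenotype-structured population model to the data and
asks which phenotype-transition processes the dynamics actually require.

## The model

The density *N*(*x*, *t*) of cells (CFU/mL) whose maximum tolerance is *x*
(mM) evolves by

∂ₜN = r_c N − H(x, F) N + D ∂ₓₓN + v ∂ₓN,
  H(x, F) = α (F − b x) for x < F (else 0),

with growth rate *r_c* (1/h, substrate-specific, fixed from growth-curve
regressions), medium formaldehyde *F* (mM), death coefficient *α*
(1/h/mM), tolerance-protection *b* ∈ [0, 1], phenotypic diffusion *D*
(mM²/h) and advection *v* (mM/h; positive *v* drifts the population toward
lower tolerance).  Zero-flux boundaries at *x* = 0 and at an upper
boundary above the highest observed tolerance.  The PDE is solved by the
method of lines (central-difference diffusion, upwind advection,
`deSolve::lsoda`).

Because plates count every cell at or above the plate concentration, data
are cumulative in tolerance; the package converts between cumulative and
phenotype-density forms, applies the detection-limit extension rule
(~34 CFU/mL floor; one colony ≡ 90.9 CFU/mL), averages replicates, and
builds the model's initial condition from the first sampled distribution
by monotone (Hyman) cubic spline.  Parameters are estimated by maximum
likelihood on the asinh scale (OLS linear-model likelihood of observed on
predicted), with Hessian standard errors, and model structure is chosen by
forward stepwise likelihood-ratio testing over a nested lattice of
variants (death only → +b/+v/+D → …).  A synthetic-data module emulates
the whole observation chain — exponentially declining initial
distributions, forward dynamics, serial-dilution Poisson spot plating —
so estimator quality is quantifiable (`recovery_study()`).

## Worked example

Generate a synthetic 4 mM selection experiment at the best-supported
parameter values, prepare it, and fit the three-parameter model
(death + tolerance-protection + diffusion):

```r
library(phenodrift)
des   <- experiment_design("selection", "methanol")
truth <- model_parameters(r_c = 0.195, alpha = 0.202, b = 0.770,
                          D = 0.019, F = 4)
ds   <- make_synthetic_dataset(truth, des, seed = 1)
prep <- prepare_series(ds$observed_series)
fit  <- fit_tolerance_model(prep, "F3a", r_c = 0.195, F = 4,
                            dx = 0.1, rtol = 1e-6)
fit
#> Tolerance-dynamics fit, variant F3a (selection scenario)
#>   fixed: r_c = 0.195 /h, F = 4 mM; 66 observations
#>   alpha = 0.2011 (SE 0.0161)
#>   b     = 0.7982 (SE 0.0615)
#>   D     = 0.02452 (SE 0.00224)
#>   logLik = -51.873, pseudo-R2 = 0.9857
confint(fit)
#>           2.5 %     97.5 %
#> alpha 0.1695175 0.23267299
#> b     0.6775987 0.91872936
#> D     0.0201325 0.02890158
```

The fit recovers the generating death parameters closely (α within 1 %,
*b* within 4 %) and finds the diffusion signal; `select_model(prep,
scenario = "selection", r_c = 0.195, F = 4, dx = 0.1)` runs the full
stepwise procedure and, on this dataset, picks exactly this variant.
`plot(fit)` overlays the fitted cumulative distributions on the data;
`predict(fit)` returns the paired observed/predicted counts.

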