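# agedrift

Genetic drift and effective population size in age-structured populations.

## What this is for

In populations with overlapping generations, the rate of genetic drift —
and hence the fate of the late-acting, nearly neutral mutations central to
the mutation-accumulation theory of ageing — depends on the survivorship
curve, not just on census size. `agedrift` is for population geneticists
and evolutionary demographers who want to ask how survivorship "type"
(Type-I: late steep senescent decline, as in modern industrialized humans;
Type-II: constant mortality, as in wild chimpanzees; Type-III: heavy
juvenile mortality) and generation time jointly set the rate at which
heterozygosity is lost.

The package provides:

* **Life tables**: construction from counts or survivorship, idealized
  Type-II/Type-III generators, parametric Type-I families
  (modern and pre-industrial), CSV input/output, validation.
* **Demography**: life expectancy e₀, Keyfitz entropy H = e†/e₀, lifespan
  equality ln(1/H), longevity ratio Ω/e₀, net reproductive rate
  R₀ = Σ lₓmₓ, generation time T = Σ x·lₓmₓ / Σ lₓmₓ, and Felsenstein's
  effective size for overlapping generations

      Ne = Nnb·T / (1 + Σₓ lₓ sₓ dₓ v²ₓ₊₁)

  with both readings of sₓ (survival probability Pₓ, the default, or
  stable-age counts) and of the reproductive value vₓ exposed as switches.
* **Projection**: Leslie matrices, stable age distributions, and a
  genotype-resolved projection with Mendelian mating among newborns.
* **Simulation**: a stochastic two-stage drift simulator — a fixed-size
  newborn cohort drawn multinomially at Hardy–Weinberg proportions, then
  a stochastic survival cull between age classes — with optional recessive
  viability selection (P_{x,BB} = Pₓ(1−s) on breeding classes), replicate
  management, notched-boxplot summaries, and effective-size estimation
  from fitted heterozygosity decay H_{t+1} = H_t(1 − 1/2Ne).

## A worked example

```r
library(agedrift)

pops <- study_populations()          # modern, pre-industrial, Type-II
t(vapply(pops, function(lt) {
  s <- demography_summary(lt, gaussian_fecundity(lt))
  unlist(s[c("e0", "H", "shape", "T", "Nnb", "Ne")])
}, numeric(6)))
#>                      e0         H    shape        T       Nnb       Ne
#> modern        70.344380 0.1268446 1.222557 26.95317  14.21578 374.9050
#> preindustrial 41.561417 0.5677224 1.900801 26.79059  24.06078 435.9868
#> type2          9.999761 0.9479902 3.000072 21.86399 100.00239 758.7252
```

At a census of 1000 females, the modern Type-I table admits only ~14
newborns per year (long life expectancy, so most of the census is adults),
while the Type-II table admits ~100 — and the Type-II effective size is
largest despite its short life expectancy.

Shifting the reproductive schedule 20 years earlier or later and
simulating drift (reduced scale: 200 replicates × 300 years, neutral):

```r
cfg <- sim_config(years = 300, replicates = 200, seed = 42)
ex <- run_drift_experiment(pops, shifts = c(-20, 20), s_values = 0,
                           config = cfg)
ex$summary[, c("run", "T", "Nnb", "median", "notch")]
#>                         run         T Nnb   median      notch
#> 1        modern.shift-20.s0  9.173595  14 0.459184 0.01282520
#> 2 preindustrial.shift-20.s0  8.642491  24 0.468750 0.00882523
#> 3         type2.shift-20.s0  6.602836 100 0.486375 0.00362037
#> 4        modern.shift+20.s0 46.863113  14 0.489796 0.00228024
#> 5 preindustrial.shift+20.s0 46.509481  24 0.492188 0.00232754
#> 6         type2.shift+20.s0 41.836991 100 0.481950 0.00501097
```

`median` is the final-time heterozygosity median across replicates and
`notch` the 95% median interval half-width (1.58·IQR/√n). Early breeding
(T−20) costs the Type-I populations significantly more heterozygosity than
late breeding (rows 1–2 vs 4–5: non-overlapping notches), while the two
Type-II regimes are statistically indistinguishable (rows 3 vs 6) — the
Type-II population drifts almost independently of generation time. At
T−20, retained heterozygosity orders Type-II > pre-industrial > modern,
matching the Ne estimates; at T+20 the mean ordering reverses, which the
Ne estimates alone would not predict.

## Scope

Female-only, one-year age classes, single locus, fully recessive viability
effects; no density dependence, mutation, or two-sex projection. See the
methods vignette (`vignettes/age-structured-drift.Rmd`) for the model,
parameter choices, numerical decisions, and known limitations.
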