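# coregonid

Integrative species delimitation for lake whitefish (*Coregonus*)
radiations. Alpine lakes hold young species flocks whose members differ
subtly in body proportions, gill-raker counts and microsatellite allele
frequencies; taxonomic revisions of such flocks rest on several
independent, individually weak lines of evidence. `coregonid` implements
that evidence chain as tested, reusable R functions, for taxonomists and
fish ecologists who want the quantitative half of a revision to be
reproducible:

* **Multivariate ratio analysis** of morphometric characters: two-group
  LDA on log-transformed measurements, exhaustive search for the character
  ratios `x_i / x_j` that best separate two species ranked by the standard
  distance `D(d) = |dᵀ(μ₁ − μ₂)| / sqrt(dᵀ S d)`, and the allometry
  statistic `δ = |⟨w, u⟩|` (unit discriminant `w` against the isometric
  axis `u = 1/√p`; smaller δ = less of the diagnosis is size).
* **Diagnostics**: the asterisk overlap rule for diagnosable ratios,
  dichotomous identification keys as data (with the published Lake
  Lucerne key shipped), and mode/range summaries of meristic frequency
  tables.
* **Population genetics** for microsatellites: GenePop I/O,
  Weir–Cockerham θ with permutation tests, Hardy–Weinberg permutation
  tests, Cavalli-Sforza chord distances `D_CH`, neighbour joining with
  locus-bootstrap supports, and the Evanno ΔK criterion
  `ΔK = mean|L''(K)| / sd(L(K))` fed by an EM mixture surrogate for
  Bayesian clustering runs.
* **Sediment-core chronology**: constant-rate depth↔year conversion for
  dating macrofossil (fish-scale) finds against documented stocking
  history.
* **Synthetic data**: allometric morphometrics, Balding–Nichols
  island-model genotypes and discretized meristic counts, so every stage
  runs and is tested without museum collections or repository downloads.

See `vignette("whitefish-delimitation")` for the full methods account.

## Worked example

Simulate two species that differ only through one planted diagnostic
ratio (a ~22% contrast in caudal-peduncle depth over upper-jaw width,
against 3% residual scatter), then ask the ratio engine to find it:

```r
library(coregonid)

spec <- planted_ratio_spec()          # plants the CD/UJW contrast
tab  <- simulate_morpho(spec, seed = 42)
compare_species_pair(tab)
#> Comparison: A vs. B (n = 20, 20)
#>   CD/UJW *  1.71-1.85 vs. 1.41-1.51  D = 11.46
#>   SL/UJW *  21.8-23 vs. 19.8-20.4  D = 9.35
#>   delta = 0.01
```

The planted pair ranks first: species A's observed CD/UJW range
(1.71–1.85) does not overlap species B's (1.41–1.51), so the ratio earns
the asterisk (usable in a key); `D = 11.46` is the standardized group
separation along that ratio — diagnostic-grade strength — and
`delta = 0.01` says the separation is almost pure shape, not size.

Classify the *C. litoralis* holotype with the shipped Lake Lucerne key,
from its printed measurements (predorsal length 49.9 %SL of 326 mm SL,
eye diameter 20 %HL of 67.5 mm HL, 26 total gill rakers):

```r
key  <- read_key(system.file("extdata", "lucerne_key.yaml",
                             package = "coregonid"))
vals <- c("PreD/ED" = (0.499 * 326) / (0.20 * 67.5), "totalGR" = 26)
classify_with_key(key, vals)
#> [1] "C.litoralis"
```

And the cluster-number pipeline on a simulated four-lake system:

```r
G   <- simulate_genotypes(n_demes = 4, n_per_deme = 60, n_loci = 10,
                          n_alleles = 8, F = 0.15, seed = 1)
res <- select_K(G, K_range = 1:7, n_runs = 10, seed = 1,
                tol = 1e-4, max_iter = 200)
res$selected_K
#> [1] 4
```

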