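# mitodrift

Population-genetic analysis of complete mtDNA genome alignments, built for
surveys of the kind used to study the maternal history of southern-African
populations: many small population samples, haplogroup labels as metadata,
and the key question of whether striking frequency differences between
neighbouring populations require distinct ancestry or are compatible with
shared ancestry plus genetic drift.

The package covers:

* **Curation** — alignment reading, reference-coordinate masking (poly-C
  control-region stretches, indel columns), stringent missing-base
  imputation (a site is filled only when ≥ 2 donors identical at every
  other called position agree on the base), haplotype collapsing, pairwise
  difference matrices with pairwise deletion.
* **Diversity** — Nei's gene diversity `H = n/(n−1)(1 − Σp²)` and per-site
  nucleotide diversity `π`, both with their standard sampling variances;
  segregating sites; haplotype-sharing summaries; exact Clopper–Pearson
  binomial confidence intervals for haplogroup frequencies.
* **Structure** — pairwise Φ\_ST and one/two-level AMOVA from the
  Excoffier-style decomposition of squared distances, with the three
  conventional permutation schemes; mean great-circle distances between
  populations (haversine, R = 6371 km); Mantel tests (via `vegan`).
* **Drift resampling test** — the package's centrepiece: a Wright-Fisher
  simulation in which an ancestral population (N_e = 2000) carrying a focal
  haplogroup at frequency *f* splits into two daughters (N_e = 1000 each,
  hypergeometric partition) that drift independently for 500/1000/2000
  years (25-year generations, binomial resampling); study-sized samples are
  then drawn 100 times per replicate and the probability that **both**
  sample frequencies fall inside their observed 95% confidence intervals
  is averaged over 10,000 replicates. Named presets encode the four
  published Himba/Herero–Damara–Kuvale comparisons (haplogroups L3d and
  L3f), including the optional one-mutation-per-3533-years haplotype clock.
* **Rho dating** — star-genealogy rho statistic (mean distance to a founder
  haplotype, σ = √(ρ/n)) with a linear molecular clock.
* **Synthetic data** — a generator producing alignments + metadata with the
  exact structure the analyses assume (haplogroup frequency vectors,
  starlike Poisson radiation, forced cross-population haplotype sharing,
  injected missing bases), so the whole pipeline is testable without any
  external download.
* **Pipeline** — `run_pipeline()` chains curate → diversity → structure →
  driftsim from one YAML/list config with a seed recorded in a checksummed
  manifest; reruns are bit-identical.

## Worked example

Simulate a two-population survey shaped like the Himba vs Kuvale contrast
(L3f at 31% vs 6%, L3d at 43% vs 0%), curate it, and run the statistics:

```r
library(mitodrift)
set.seed(42)
pops <- data.frame(name = c("Himba", "Kuvale"), size = c(51, 53),
                   language_branch = "WestBantu", subsistence = "pastoralist",
                   lat = c(-18.0, -15.2), lon = c(13.8, 12.5),
                   L3f = c(0.31, 0.06), L3d = c(0.43, 0.00), other = c(0.26, 0.94))
hg <- data.frame(label = c("L3f", "L3d", "other"),
                 divergence = c(8, 8, 12), lambda = c(0.3, 0.3, 1))
d <- generate_dataset(sim_config(pops, hg, length = 2000, missing_rate = 2e-05))
d$alignment
#> mt_alignment: 104 sequences x 2000 columns; 1 missing bases, 0 gap characters

imp <- impute_missing(d$alignment)
imp$report$sites_imputed
#> [1] 1

diversity_table(imp$alignment, d$metadata)
#>   population  N n_hap  S   seq_div seq_div_sd          pi       pi_sd
#> 1      Himba 51    19 47 0.8203922 0.04052332 0.006455686 0.003280494
#> 2     Kuvale 53    35 71 0.8882438 0.04217515 0.002050798 0.001151749
```

The one injected `N` is restored because the sample has unanimous
otherwise-identical donors. `n_hap`, `S`, `H` (`seq_div`) and `π` are the
columns of a standard mtDNA survey table; the Himba-like population has
fewer haplotypes but higher π because two divergent haplogroups segregate
at high frequency.

An exact binomial CI for the realized L3f count in the Himba-like sample
(16 of 51), and the genetic distance between the populations:

```r
k <- sum(d$metadata$haplogroup == "L3f" & d$metadata$population == "Himba")
clopper_pearson_ci(k, 51)
#>    k  n level  estimate    lower     upper
#> 1 16 51  0.95 0.3137255 0.191104 0.4588729

dm <- pairwise_diff_matrix(imp$alignment)
ph <- phi_st_pairwise(dm, setNames(d$metadata$population, d$metadata$sample_id),
                      n_perm = 999)
round(ph$phi_st$values, 3)
#>        Himba Kuvale
#> Himba  0.000  0.547
#> Kuvale 0.547  0.000
ph$p["Himba", "Kuvale"]
#> [1] 0.001
```

Finally, the drift test: could a shared ancestor carrying L3d at 17% have
left L3d at 29–58% in the Himba/Herero yet absent (CI 0–7%) in the Kuvale
after a 2000-year-old split?

```r
set.seed(1)
sc <- drift_preset("d", split_years = 2000)
joint_ci_probability(0.17, sc)
#> $probability
#> [1] 0.033024
#> $mc_se
#> [1] 0.001170909
#> $n_outer
#> [1] 10000
#> $n_inner
#> [1] 100
```

A probability of ~0.03 means drift alone almost never produces that joint
outcome: a shared ancestor carrying L3d is a poor explanation for the
Himba/Herero–Kuvale contrast, whereas the same machinery gives comfortable
probabilities for the shared-L3d-haplotype scenario linking Himba/Herero and
Damara (`drift_preset("a", ...)`).

Full grids over initial frequencies and split times come from
`run_drift_grid()`, and `run_pipeline()` drives everything from one config.

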