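# ecmnet

Extracellular-matrix network analysis for tumour proteomes.

Soft-tissue sarcomas are mesenchymal tumours in which the extracellular
matrix (ECM) is both abundant and poorly characterised. `ecmnet` is for
computational biologists analysing proteome matrices (log2-normalised
protein × sample intensities) of such cohorts who want to ask: which
matrisome and adhesome proteins were detected; which of them form
coregulated networks; how network activity relates to grade, subtype
and survival; and whether gene-set scores — in particular a
proteoglycan (PG) score — carry prognostic information independent of
clinical covariates. It also covers the satellite analyses such studies
use: SAM differential analysis for cell-line contrasts, cell-migration
track metrics, and IHC scoring (H-score, positive pixels, TIL
densities).

## Methods at a glance

- **Annotation filtering** against matrisome/adhesome catalogs with
  matrisome > adhesome precedence for dual-listed genes and per-division
  coverage statistics.
- **Coregulated networks**: pairwise-complete Pearson similarity;
  Monti consensus clustering (average linkage, 80% subsampling) with k
  chosen by PAC stability refined by the consensus-CDF delta-area, and
  SigClust (2-means cluster index against a thresholded-eigenvalue
  Gaussian null) for split significance. Per-sample cluster activity is
  the median of member-protein abundances, with Mann–Whitney /
  Kruskal–Wallis + Dunn clinical associations.
- **Enrichment**: single-sample GSEA, ES(S) = Σ_i [P_in^w(i) −
  P_out(i)] with rank weights |r_i|^0.75, and upper-tail hypergeometric
  overrepresentation with a quantified-proteome universe.
- **Differential abundance**: per-protein Welch t, BH-FDR < 0.01 and
  |Δlog2| ≥ 1; permutation-FDR SAM with d = Δmean/(s + s0).
- **Survival**: Kaplan–Meier, log-rank, Cox PH (Efron ties) via the
  `survival` package, with inclusive-median / tertile score
  stratification, and a two-stage gene-set prognostic screen (log-rank
  filter at p < 0.05, then multivariable Cox retention against
  clinical covariates).
- **Migration**: per-track speed (path length / time) and
  directionality index DI = net / total displacement.
- **IHC**: H-score = 100·(f_weak + 2·f_moderate + 3·f_strong) at
  0.14/0.18/0.23 OD cutpoints, positive-pixel fraction at 0.15 OD, TIL
  densities with preservation adjustment and the 1.274 area factor,
  and `mclust` three-component mixtures of per-case scores.
- **Synthetic cohorts**: block-correlated latent programs with
  subtype/grade structure and exponential survival tied to one program,
  so every stage is testable end-to-end without any download.

The bundled PG gene set (`inst/extdata/pg_score.gmt`) lists ACAN, VCAN,
HSPG2, BGN, DCN, ASPN, FMOD, LUM, PRELP, OGN plus HAPLN1; the first ten
are established small-leucine-rich/hyalectan/basement-membrane-zone
proteoglycans and the eleventh is a reconstructed member, so treat the
file as an editable template rather than a canonical signature. The
annotation snapshot fixture is likewise a miniature example, not a
catalog release.

## Worked example

Generate a 300-sample synthetic cohort, filter to annotated proteins,
discover coregulated networks, and screen gene sets for prognostic
value:

```r
library(ecmnet)

co   <- generate_cohort(cohort_spec(seed = 42))
db   <- synthetic_annotation(co)          # or load_annotation_db("catalog.csv")
filt <- filter_matrix(co$matrix, db)
#> filtered: 240 of 300 proteins

sim <- filter_similarity(correlation_similarity(filt, min_pairs = 10))
#> 60 protein(s) without a correlate at |r| >= 0.4 excluded from network discovery
cc  <- consensus_cluster(sim, k_range = 2:6, n_resamples = 200, seed = 42)
cc
#> consensus_result: chosen k = 3 | PAC: k2=0.000 k3=0.000 k4=0.011 k5=0.014 k6=0.021
```

Three protein clusters are perfectly stable (PAC 0 at k = 2 and 3; the
delta-area rule resolves the coarse/fine tie toward k = 3, which here
matches the three planted programs exactly). Screening gene sets
against overall survival:

```r
sets <- synthetic_gene_sets(co, seed = 42)   # or read_gmt("ecm_sets.gmt")
sr   <- prognostic_screen(filt, sets, co$clinical, endpoints = "OS")
sr$table[sr$table$pass_stage1, ]
#>     set endpoint logrank_p mva_hr mva_ci_lower mva_ci_upper    mva_p retained
#>  PG_set       OS   2.7e-08  0.509        0.368        0.704 4.53e-05     TRUE
```

Only the proteoglycan-like set passes the log-rank filter and stays
significant in the multivariable Cox model: patients in its high-score
stratum have about half the death hazard (HR 0.51, 95% CI 0.37–0.70)
after adjustment for the univariably significant clinical covariates —
the protective direction the generator planted (log-HR −0.7 per SD of
program activity). Decoy sets are not retained.

Track metrics use plain Euclidean geometry; the right-angle
three-point track gives

```r
track_metrics(data.frame(t = c(0, 30, 60), x = c(0, 3, 3), y = c(0, 0, 4)))
#>   speed directionality_index net_distance total_distance duration n_points
#> 1     7               0.7143            5              7        1        3
```

i.e. net 5 µm over a 7 µm path (DI = 5/7) at 7 µm/h.

The full pipeline — filtering, networks, screen, survival tables, with
content-hash stage caching and a JSON run summary — runs from one
config: `run_full_analysis(list(seed = 1, out_dir = "run1"))`.

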