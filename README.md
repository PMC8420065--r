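# emtrn

Enhancer-methylation-mediated target gene regulatory networks.

`emtrn` is an R package for epigenomics groups who want to go from
HM450K-style tumour/normal beta-value matrices and matched expression
profiles to testable hypotheses about enhancer-driven gene
dysregulation: which enhancer regions are differentially methylated,
which lncRNAs and mRNAs they plausibly regulate, how those targets
organise into co-expressed competing-endogenous-RNA (ceRNA) modules,
which modules carry prognostic signal, and which known drug-lncRNA
associations point at actionable nodes.

## The method in brief

* **DMER calling.** Beta values
  (β = I<sub>meth</sub>/(I<sub>meth</sub>+I<sub>unmeth</sub>)) are
  QC-filtered (probes missing in >30% of samples removed), kNN-imputed
  (k = 10), and aggregated over enhancer regions built from ±500 bp
  windows around enhancer CpGs (overlapping windows merged, bookended
  windows kept separate). Regions are tested with an empirical-Bayes
  moderated t (prior estimated by moment matching on log sample
  variances); DMERs satisfy |coef| ≥ 0.01 with BH-adjusted p ≤ 0.05.
* **Target linking.** Genes whose expression is already explained by
  promoter methylation (DPMGs: adjusted p ≤ 0.05, |Δmedian| ≥ 0.1,
  promoter = strand-aware 2 kb upstream of the TSS; then Pearson r < 0,
  p ≤ 0.05 vs own expression) are excluded. Each DMER pairs with genes
  on the same chromosome within 1 Mb of its centre, kept when region
  beta and expression are negatively correlated (p ≤ 0.05).
* **EMTRN assembly.** lncRNA-mRNA pairs sharing ≥2 miRNAs are screened
  by the hypergeometric upper tail P(X ≥ k) (BH FDR ≤ 0.05),
  intersected with DMER targets, and kept when co-expression PCC > 0.5
  with p ≤ 0.05; hypo-/hyper-methylation subnetworks follow the
  endpoint DMER directions, with top-15%-degree hub flags.
* **Modules and survival.** Maximal bicliques (both sides ≥ 2) of the
  hypo-EMTRN are enumerated exactly; per module, a joint Cox model
  (Breslow ties) fitted on a random half of the tumour cohort yields
  risk scores Σ βᵢXᵢ, dichotomised at the training median; modules with
  log-rank p ≤ 0.05 in **both** halves are reported as prognostic.
* **Downstream.** Mann-Whitney AUCs (module score = mean member-gene
  z-score) on an independent validation matrix, Wilcoxon tumour/normal
  comparisons, generic hypergeometric over-representation over any GMT,
  and a drug network of down-regulating associations on hypo-EMTRN
  lncRNAs.

A synthetic-study generator (`simulate_study()`) plants all of this
structure — shifted regions, negatively coupled targets,
positive-coupling decoys, complete-bipartite miRNA-sharing modules with
a latent co-expression factor, one survival-driving module, drug hits —
with machine-readable ground truth, so the full chain is testable
without any external download. See the methods vignette
(`vignettes/emtrn-methods.Rmd`) for the generative model and all design
choices.

## Worked example

```r
library(emtrn)
study <- simulate_study(emtrn_sim_params(), seed = 1)
res   <- run_emtrn_pipeline(study, emtrn_config(seed = 1))

nrow(res$regions)
#> [1] 1887
table(res$dmers$direction)
#> hyper  hypo    ns
#>    11    32  1844
nrow(res$networks$hypo$edges)
#> [1] 21
res$modules[, c("module_id", "n_lnc", "n_mrna")]
#>   module_id n_lnc n_mrna
#> 1  MOD_0001     2      3
#> 2  MOD_0002     2      3
#> 3  MOD_0003     3      3
round(sapply(res$module_auc, `[[`, "module_auc"), 4)
#> MOD_0001 MOD_0002 MOD_0003
#>   0.9750   0.9762   0.9375
res$drug_network$edges[1:3, ]
#>      drug   lncRNA
#> 1 DRUG_01 LNC_0005
#> 2 DRUG_02 LNC_0011
#> 3 DRUG_03 LNC_0018
```

Reading the output: 2,009 enhancer probes collapse into 1,887
non-overlapping regions; 43 are called differentially methylated, with
hypomethylation dominating (32 vs 11) as expected from the planted
design. The 21 surviving network edges are exactly the three planted
biclique modules, each close to perfectly diagnostic on the held-out
validation cohort (AUC 0.94-0.98), and the drug network recovers the
six planted down-regulating associations. At this seed no module clears
the train/test log-rank screen in both halves — the vignette's
"Validation scales" section explains why retention at these cohort
sizes is near a coin flip even for a perfectly scored module.

The same chain is scriptable from a shell:

```sh
Rscript inst/scripts/emtrn.R simulate --out study_dir
Rscript inst/scripts/emtrn.R run --study study_dir --out results_dir
```

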