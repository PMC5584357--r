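# profcor — phylogenetic profiling with distance correlation

`profcor` predicts functional and physical protein–protein interactions
from co-evolution. Proteins that work together tend to be jointly retained
or jointly lost across genomes, so proteins with similar *phylogenetic
profiles* — per-protein vectors describing homolog conservation over a
reference set of genomes — are candidate interaction partners. The package
is aimed at computational biologists who have all-vs-reference alignment
output (BLAST/FASTA 12-column tabular format) and want scored interaction
predictions plus an honest benchmark of how well the scoring works.

## The method

Profiles are graded probabilities derived from the best alignment E-value
per (protein, genome):

    P = -1 / log10(E),   with P = 1 whenever E > 0.1 or there is no hit.

Profile similarity is scored all-vs-all with **distance correlation**: for
each profile, the matrix of absolute pairwise differences
d_kl = |a_k − a_l| is double-centered
(da_kl = d_kl − d̄_k − d̄_l + d̄), and a pair of proteins scores

    dCor_pq = Cov(DA_p, DA_q) / sqrt(Var(DA_p) Var(DA_q)),

the entrywise covariance-to-variance ratio of the centered matrices —
algebraically the square of the classical sample distance correlation
(`root = TRUE` gives the classical scale). Unlike Pearson's correlation,
distance correlation detects non-monotone dependence; both it, Pearson,
and binned mutual information (MI = H(A) + H(B) − H(A,B), natural log, 0.1
bins) are implemented so they can be benchmarked against each other with
pathway-derived gold standards, 0.1-binned ROC curves, trapezoid AUC and
ten-fold cross-validation. A blocked split-apply-combine engine persists
centered distance matrices to an on-disk chunk repository so the all-pairs
computation runs in bounded memory.

See `vignettes/phylogenetic-profiling-dcor.Rmd` for the full model,
numerical conventions and design rationale.

## Worked example

A synthetic study with planted *non-monotone* dependence (each interacting
pair is linked through a latent genome-occupancy vector u via the parabola
4u(1−u) — dependence that linear correlation cannot see), pushed through
the full pipeline from simulated alignment hit tables:

```r
library(profcor)

spec <- simulation_spec(n_proteins = 120, n_genomes = 60, n_modules = 15,
                        module_size = 2, dependence = "non-monotone",
                        strength = 0.9, noise = 0.1, seed = 42)
sim <- simulate_profiles(spec)

tab <- profiles_to_evalue_table(sim$profiles, seed = 42)
pm  <- build_profile_matrix(best_hits(parse_hit_table(tab$lines),
                                      tab$gmap, tab$proteins))
pm
#> Phylogenetic profile matrix: 120 proteins x 60 genomes
#>   values in [0.005, 1]; fraction at 1 (no homolog): 0.393

membership <- simulate_pathways(sim$truth, n_decoy_pathways = 12,
                                chain_length = 6, seed = 42)
gs <- assemble_gold_standard(sim$truth, membership, flavor = "fun")
gs
#> Gold standard (fun): 15 positives, 1203 negatives

reports <- lapply(c("dcor", "pc", "mi"), function(metric) {
  sm <- similarity_matrix(pm, metric)
  sp <- score_pairs(sm, gs)
  ten_fold_cv(sp, seed = 42)
})
compare_metrics(reports)
#> Metric comparison over 10 folds (fun)
#>          dcor     pc     mi
#> min    0.9524 0.1395 0.7976
#> q1     0.9762 0.2480 0.9146
#> median 0.9882 0.4739 0.9882
#> q3     0.9959 0.6667 0.9939
#> max    1.0000 0.9535 0.9940
#> Mean paired difference(s):
#> dcor - pc dcor - mi   pc - mi
#>    0.4930    0.0375   -0.4555
```

The cross-validated AUCs say what the method claims: with non-monotone
dependence planted, distance correlation ranks true pairs almost perfectly
(median fold AUC 0.99) while Pearson's correlation is near chance (0.47);
`plot(compare_metrics(reports))` draws the fold-AUC box plots. With
`dependence = "linear"` all metrics converge, and the gap is the point:
dCor's advantage is specifically on dependence that is not linear.

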