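# pheseq

Gene–disease association prioritization by Bayesian data fusion: per-gene
p-values from sequence analysis (GWAS, differential expression, methylation,
survival screens) are combined with per-gene phenotype-description
embeddings (vectors summarizing textual and network evidence) in one
generative model, yielding a fused posterior probability of association and
a fused p-value per gene.

## The model

For each gene $g$ with embedding $Z_g$ and p-value $P_g$:

$$F_g \sim \mathrm{Beta}(a_g, b_g),\qquad
  T_g \sim \mathrm{Bernoulli}(F_g),\qquad
  P_g \sim T_g\,\mathrm{Beta}(\alpha_g,1) + (1-T_g)\,U(0,1)$$

A latent switch $T_g$ routes the p-value through a significant component
$\mathrm{Beta}(\alpha_g,1)$, $\alpha_g<1$ (mass near zero), or the uniform
null; the association score $F_g$ is the prior switch probability. A neural
perception network maps each gene's embedding to its mixture parameters
$(\alpha_g, a_g, b_g)$, so description evidence shapes the prior while the
p-value supplies the likelihood. Two fitting strategies:

* **Static** (`fit_static`): embeddings fixed; Monte-Carlo maximum
  likelihood with Gibbs-sampled latents and gradient ascent on the network.
* **Dynamic** (`fit_dynamic`): a VAE learns a latent embedding jointly;
  block-coordinate MAP-MLE alternates a closed-form score update
  $F \leftarrow (T+a-1)/(a+b-1)$, reparameterized encoder/decoder gradients,
  and the same network ascent.

The fused posterior is the Gibbs-averaged posterior switch probability; the
fused p-value is one minus it. Significance is called strictly
(Benjamini–Hochberg on the fused p-values) or leniently (fixed cutoff), and
reports compare fused calls with single-omics calls and score recall against
benchmark gene lists. A synthetic-data generator reproduces the assumed
structure so the whole pipeline is testable offline. The model, its
assumptions and all design choices are documented in
`vignettes/pheseq-methods.Rmd`.

## Worked example

```r
library(pheseq)

sim <- simulate_dataset(G = 500, D = 16, seed = 42)   # 10% truly associated
cfg <- pheseq_config(mode = "static", seed = 42, max_iters = 600)
fit <- fit_static(sim$dataset, cfg)
fit
#> pheseq fit (static): 500 genes, 600 iterations (max_iters reached)
#>   final objective: 656.7801
#>   mean fused posterior: 0.1912

results <- call_significance(gene_results(fit), cfg, mode = "strict")
summarize_calls(results)
#> fused vs sequence calls (strict)
#>   background genes 500
#>   fused significant 29 (5.80%)
#>   sequence significant 36 (7.20%)
#>   overlap 29, recalled by fusion only 0
```

The fused posterior ranks the planted associations near the top
(`fused_posterior` ≈ 1 for the strongest genes) and recovers the simulated
truth with balanced accuracy 0.904 in this run. `write_results_table()`,
`export_logp_scatter()` and `summary_report()` write the per-gene table, the
−log10 p scatter coordinates and the JSON summary; `recall_vs_benchmark()`
adds cumulative top-k hit curves against a benchmark gene list.

The same pipeline runs from a shell:

```sh
Rscript exec/pheseq simulate --out-dir data --G 2000 --seed 1
Rscript exec/pheseq fit --pvalues data/sim_pvalues.tsv \
    --embeddings data/sim_embeddings.tsv --mode static --out model.rds
Rscript exec/pheseq report --model model.rds --out-dir report
```

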