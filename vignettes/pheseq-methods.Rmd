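---
title: "Fusing association p-values with phenotype embeddings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing association p-values with phenotype embeddings: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pheseq)
```

## The problem

A sequence-analysis experiment (a GWAS, a differential-expression or
methylation screen, a survival regression) ends in a per-gene p-value. Taken
alone, a hard threshold on those p-values misses genes with real but
sub-threshold signal and keeps genes whose tiny p-value is a fluke. For many
diseases there is a second, independent evidence stream: textual and network
descriptions of how a gene relates to the phenotype, summarized upstream into
a fixed-length embedding vector per gene. `pheseq` fuses the two streams in
one generative model and emits, per gene, a posterior probability of
association and a fused p-value that can be thresholded in the usual ways.

## The generative model

For each gene $g$ of $G$, with embedding $Z_g$ and p-value $P_g$:

$$F_g \sim \mathrm{Beta}(a_g, b_g), \qquad
  T_g \sim \mathrm{Bernoulli}(F_g), \qquad
  P_g \sim T_g\,\mathrm{Beta}(\alpha_g, 1) + (1-T_g)\,U(0,1).$$

$T_g$ is a binary switch: when on, the p-value is drawn from the significant
component $\mathrm{Beta}(\alpha_g,1)$ with $\alpha_g < 1$, whose density
$\alpha p^{\alpha-1}$ piles up near zero; when off, the p-value is uniform.
$F_g \in (0,1)$ is the association score, the prior probability that the
switch is on. The crucial coupling is that $(\alpha_g, a_g, b_g)$ are not
free per-gene constants: a perception network $\Phi$ (two tanh hidden
layers, three constrained output heads) computes them from the gene's
embedding, so genes with similar descriptions share a prior. The fused
output per gene is the posterior mean of $T_g$, and the fused p-value is
one minus it.

The package ships two fitting strategies.

**Static variant** (`fit_static`). Embeddings are used as given. Training
maximizes the expected joint log-probability by stochastic gradient ascent:
latents $(T, F)$ are drawn by Gibbs sweeps of their exact conditionals
($T \mid F$ is Bernoulli with the posterior switch probability;
$F \mid T$ is $\mathrm{Beta}(a + T, b + 1 - T)$), the per-gene gradient
triple

$$\nabla_{\alpha} = T(\log P + 1/\alpha), \quad
  \nabla_a = \Psi(a+b) - \Psi(a) + \log F, \quad
  \nabla_b = \Psi(a+b) - \Psi(b) + \log(1-F)$$

is evaluated at the draw (the Gamma-ratio form of these gradients reduces
algebraically to the digamma differences used here, which are numerically
stable), and the chain rule carries it into $\Phi$.

**Dynamic variant** (`fit_dynamic`). The embedding itself becomes latent: a
VAE encoder maps the description vector $L_g$ to a Gaussian posterior
$q(Z_g \mid L_g) = N(\mu_g, \sigma_g I)$ with a scalar isotropic variance,
and a decoder defines $p(L_g \mid Z_g)$ with unit observation variance. Each
outer iteration alternates: (1) encode and evaluate $\Phi$ at the posterior
mean $\mu_g$; (2) draw the switch from its exact conditional and set the
score by the closed-form MAP update $F \leftarrow (T + a - 1)/(a + b - 1)$;
(3) take a reparameterized ($Z = \mu + \sqrt{\sigma}\,\varepsilon$) gradient
step on encoder and decoder, with the analytic KL terms $-\mu$ and
$K(1-\sigma)/(2\sigma)$ and weight decay on all weights and biases; (4) take
the same chain-rule ascent step on $\Phi$ as the static variant. The
isotropic scalar $\sigma_g$ is the only reading under which the
$K(1-\sigma)/(2\sigma)$ term is the exact derivative of the Gaussian KL, and
the reparameterization must scale the noise by $\sqrt{\sigma}$ for the draw
to have variance $\sigma$.

## Design choices in the optimization, and why they are there

These were genuinely open choices; each was settled by a failure mode we
observed and kept because it removed that failure without touching the model.

* **The $\alpha$ head is capped at 0.5.** As $\alpha \to 1$ the significant
  component degenerates into the uniform null and the switch becomes
  unidentifiable. Under gradient ascent this is not a neutral fact: null
  genes drift toward $\alpha = 1$ and their association scores follow,
  inflating false calls. Capping $\alpha$ keeps the significant branch
  meaningfully concentrated near zero, which is its modeling role.
* **Skeptical head initialization.** Output biases start every gene at
  $\alpha \approx 0.15$, $a$ at 0.3 above its floor, $b \approx 2$ (prior
  score about 0.13 in the static fit). Starting near the null anchors the
  weakly identified majority; genes with real evidence are pulled up by
  their likelihood. Weights are Glorot-uniform from the run seed.
* **Several latent draws per gradient step** (`latent_samples`, default 4).
  Latent sampling is nearly free next to the network passes, so averaging a
  few draws buys a large variance reduction and lets the default step size
  (0.05 on the per-gene-averaged gradient) remain stable. Plain constant-step
  ascent is used throughout; an adaptive per-parameter optimizer was tried
  and rejected because its aggressive early steps jump onto the
  $\alpha \to 1$ degenerate ridge.
* **Gibbs draws, not the MAP point, feed the $(a, b)$ gradients.** Fitting a
  Beta by maximum likelihood to the single MAP coordinate of $F$ makes its
  concentration diverge (the $b$ gradient stays positive and every score
  collapses); the sampled $F$ keeps the target a distribution with finite
  spread. The MAP update is used where it is well-posed: as the coordinate
  the encoder/decoder block conditions on.
* **VAE warm-up** (`vae_warmup`, default 500 iterations of reconstruction
  plus KL, at the separate `vae_learning_rate` 0.2). Until the latent space
  reflects the description structure, $\Phi$ cannot tell genes apart, and
  its early gradient — dominated by the null majority — drives the $a$ head
  into softplus saturation from which gradients cannot recover.
* **A floor on the score along the dynamic block updates**
  (`map_f_floor`, default 0.01). $F$ exactly at the boundary is an absorbing
  state of the block scheme: the switch conditional becomes zero regardless
  of the p-value. The floor keeps every gene minimally open; final posterior
  summaries use the much tighter `f_eps`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 0.05 | ascent step on the per-gene-averaged gradient |
| `latent_samples` | 4 | latent draws averaged per gradient step |
| `mc_samples` (N) | 4 | reparameterized draws in the variational objective |
| `max_iters` | 2000 / 800 | static / dynamic outer iterations |
| `gibbs_sweeps` | 2 | sweeps of the exact conditionals per latent draw |
| `summary_sweeps` (M) | 50 | frozen-parameter sweeps averaged for summaries |
| `embedding_dim` (K) | 16 | VAE latent dimension (dynamic) |
| `hidden_dim` | 64 | width of all hidden layers |
| `weight_decay` | 1e-4 | L2 penalty on encoder/decoder parameters |
| `lenient_alpha` | 0.05 | fixed cutoff of the lenient criterion |
| `strict_fdr_q` | 0.05 | BH level of the strict criterion |
| `p_eps` | 1e-300 | p-value clipping bound (keeps log P finite) |
| `f_eps` | 1e-6 | score clipping margin |

The lenient cutoff follows the common 0.05 convention; a stricter fixed
cutoff (for example 0.005) can be configured where a more conservative
lenient line is wanted.

## Numerical choices

All likelihood ratios are computed in log space with max-subtraction, since
$\alpha p^{\alpha-1}$ overflows for tiny $p$ ($p$ is clipped to
$[10^{-300}, 1]$ so $\log P$ is finite). Convergence is declared when the
largest absolute change of any per-gene $(\alpha, a, b)$ stays below `tol`
for `conv_window` consecutive iterations; under constant-step stochastic
ascent the parameter noise floor usually exceeds any tight tolerance, so
runs are in practice bounded by `max_iters`, and the iteration trace is the
tool for judging a run. The stored trace is the joint log-probability
evaluated at a mean-value latent state (the switch at its conditional
expectation, the score at its conditional mean, and — in the dynamic
variant — $Z$ at the posterior mean): the infinite-replication limit of
common-random-number evaluation, hence a smooth deterministic function of
the parameters that is comparable across iterations. The one-draw ELBO, by
contrast, systematically penalizes sharpness of $\Phi$ under latent noise
and can drift down while the joint probability rises; it is exposed as
`elbo()` for diagnostics but not used as the trace. Ties in the top-k
ranking are broken by ascending sequence p-value, then gene identifier, so
reports are deterministic.

## What the synthetic generator emulates — and what it does not

`simulate_dataset` reproduces the structure the model assumes: a minority
(`frac_assoc`, default 0.1) of genes is truly associated; their p-values are
$\mathrm{Beta}(\alpha_{true}, 1)$ draws (default $\alpha_{true} = 0.1$)
against a uniform null; embeddings are isotropic Gaussian clusters
(dimension 32, within-cluster standard deviation 1) whose means sit
`separation` = 3 apart. The two means are unit-norm whenever the requested
separation permits it (two unit vectors can be at most 2 apart; beyond that
the means sit at radius separation/2). `inject_discordance` then creates the
two disagreement patterns the fusion is meant to arbitrate: associated genes
stripped of their description signal, and null genes given a
lenient-range p-value plus a significant-cluster embedding.

Real phenotype-description embeddings are not Gaussian blobs: they carry
annotation noise, literature-coverage bias (well-studied genes have richer
descriptions), and a continuum of relevance rather than two clusters. Real
p-value sets harbor correlation between neighboring genes and confounding
that the uniform null ignores. Passing the recovery tests here therefore
shows that the inference machinery works when the model's assumptions hold;
it does not certify performance on any particular disease corpus. Missing
embeddings (genes with no description) are zero-imputed and flagged, keeping
the background universe intact for report denominators; zero is the neutral
point of the standard-normal latent prior, but imputed genes necessarily
fall back on their p-value evidence alone.

Problem sizes used in the shipped tests and in `scripts/acceptance.R` —
2,000 genes, 32 embedding dimensions — were chosen so that a full double
fit plus reports completes comfortably on one desktop core; the real case
studies this class of model targets (around 18,000–25,000 genes) are
reachable with the same code and proportionally more iterations of the
same cost per gene.

## Known limitations

* The fused p-value is a posterior probability of non-association, not a
  frequentist tail probability; BH on it controls a posterior-flavored
  criterion, not the classical FDR guarantee.
* Stochastic constant-step ascent leaves seed-to-seed variability of a few
  percentage points in balanced accuracy at the default problem size.
* The dynamic variant's block scheme does not monotonically ascend a single
  scalar objective (MAP and MLE pieces alternate); the joint-probability
  trace rises cleanly at small learning rates but can wander near the
  plateau.
* One disease per fit; no amortization across diseases, no minibatching
  (gene counts in the tens of thousands fit in memory as dense matrices).
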