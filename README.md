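# pancanmil

Pancancer survival modeling from whole-slide histopathology feature bags,
fusing image morphology with routine clinical variables through a
cancer-aware mixture of expert heads.

## The problem

Prognosis models built from digitized H&E slides are usually trained one
cancer type at a time, which fragments already-scarce survival data and
prevents sharing of morphology that is prognostic across cancers (necrosis,
poor differentiation, stromal patterns). `pancanmil` implements a *unified*
pancancer survival model for researchers in computational pathology:

1. **Attention-based multiple instance learning (AMIL).** A slide is a bag
   of patch embeddings `X ∈ R^{N×D}` (from any pluggable patch encoder; a
   foundation-model encoder at 10× with 224×224 patches in practice). Gated
   attention scores `a = softmax((tanh(UW_v) ⊙ σ(UW_u)) w_a)` pool the
   projected patches `U` into one slide summary `H₁ = aᵀU ∈ R^{1×768}`,
   invariant to patch order.
2. **Cross-attention fusion.** `H₁` and the encoded clinical vector
   `C ∈ R^{1×M}` (age/100, sex one-hot, stage I–IV one-hot with an explicit
   stage-missing slot; M = 8) are projected by two symmetric MLPs into a
   shared latent space, split into sub-tokens, and fused by multi-head
   cross-attention in both directions (`A_{c→h}`, `A_{h→c}`), yielding a
   clinically contextualized fused feature.
3. **Cancer-aware expert routing.** The one-hot cancer type becomes a
   control token via a two-layer SiLU network with instance normalization.
   Gate logits (a linear projection of the token) receive an additive
   *logarithmic boost* `ln K` on the patient's own cancer type; the softmax
   is restricted to the top-k experts and renormalized, and the predicted
   log-risk is the gate-weighted sum of cancer-specific expert heads drawn
   from a shared pool.
4. **Joint objective.** Training minimizes `L = L_cox + L_rank`: the Breslow
   Cox partial likelihood (absolute risk) plus a pairwise logistic ranking
   loss over comparable pairs `{(i,j): event_i = 1, t_i < t_j}` (relative
   ordering), with gradient accumulation guaranteeing that risk sets and
   ranking pairs always span the full batch of patients.

The package also provides the slide preprocessing front end (Otsu tissue
masking on the saturation channel, non-overlapping 224-px tiling with
tissue-fraction filtering, pluggable patch encoders), the complete survival
evaluation protocol (Harrell's C-index, IPCW time-dependent AUC averaged
over a grid between the 20th and 81st percentile times, median-risk-split
Kaplan–Meier curves with Greenwood bands, two-sided log-rank, paired
bootstrap z-tests, exact Mann–Whitney fold comparisons), attention heatmaps
(percentile-rank normalization, 0.3-opacity overlays), and a synthetic
multicancer cohort simulator with known ground-truth hazards so the whole
pipeline is testable without any external data. The network forward *and*
backward passes are written in plain R matrix code and verified against
finite differences.

## Worked example

```r
library(pancanmil)

# a 2-cancer synthetic cohort with known ground-truth hazards
cfg <- sim_config(K = 2, n_per_type = 60, D = 16, bag_size_range = c(8, 16))
sim <- simulate_cohort(cfg, seed = 7)

net <- model_config(D = 16, K = 2, d_slide = 32, attn_hidden = 32, d = 32,
                    expert_hidden = 16)
fit <- fit_survival_model(
  sim$cohort, net,
  train_config(lr = 2e-3, epochs = 6, batch_patients = 32, seed = 1),
  k = 3)
glance(fit)
#> # A tibble: 1 × 6
#>   n_patients n_events k_folds epochs final_loss oof_cindex
#>        <int>    <int>   <int>  <int>      <dbl>      <dbl>
#> 1        120       86       3      6       2.47      0.658

report <- aggregate_cv(tidy(fit))
report
#> <pcm_eval_report> n = 120 (86 events)
#>   C-index  0.658
#>   td-AUC   0.709
#>   log-rank chi2 24.25 (p = 8.44e-07)
#>   per-cancer breakdown over 2 type(s)

tidy(report)
#> # A tibble: 3 × 6
#>   cancer_type     n n_events c_index td_auc   logrank_p
#>   <chr>       <int>    <int>   <dbl>  <dbl>       <dbl>
#> 1 BLCA           60       44   0.633  0.677 0.000469
#> 2 BRCA           60       42   0.685  0.726 0.0000561
#> 3 overall       120       86   0.658  0.709 0.000000844

oracle_cindex(sim$truth)   # best achievable under the true hazards
#> [1] 0.7656116
```

The out-of-fold C-index (0.658 here, after six epochs on 80 training
patients per fold) is read against the *oracle* concordance of the true
log-hazards (0.766): under a proportional-hazards generator no risk score
can beat the true hazard ordering, so the gap to the oracle — not the
absolute value — measures how much signal the model recovered. The log-rank
test shows the median-risk split separates survival strongly
(χ² = 24.3, p < 1e-6). `autoplot(report)` draws the two Kaplan–Meier curves
with their 95% Greenwood bands; `autoplot(fit)` shows per-fold training
loss.

A full pipeline (simulate → train → evaluate → heatmap) with on-disk
artifacts is available as `run_pipeline()`, and as a thin command-line
wrapper in `inst/cli/pancanmil.R`.

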