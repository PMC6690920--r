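# tfanet

Transcription-factor activity (TFA) networks from gene-expression compendia.

A transcription factor's regulating activity — the DNA-bound, transcription-
driving fraction of the protein — is hidden: mRNA abundance is a poor proxy
because phosphorylation, cofactors and chromatin state all intervene.
`tfanet` reconstructs a three-layer regulatory network (modulators → TFs →
targets) and estimates each TF's hidden activity from expression data alone,
in three stages:

1. **Pair screening** — Gaussian-kernel mutual information
   MI(X,Y) = E[log p(x,y)/(p₁(x)p₂(y))] for every TF–target pair, with
   upper-tail p-values from a Student-t null fitted to the pooled MI values
   (default cutoff 10⁻⁴).
2. **Modulator detection** — conditional mutual information
   CMI(X,Y|M) = MI(X,Y | M ∈ L⁺ₘ) − MI(X,Y | M ∈ L⁻ₘ), comparing the top and
   bottom 35% of samples by a candidate modulator's expression, with a
   1000-permutation one-sided test (cutoff 0.001) and the rule that a
   cofactor is a modulator of a TF when it is significant for ≥ 50% of that
   TF's targets.
3. **Activity model** — a hierarchical linear-Gaussian model
   P = BQ + ε, E = AP + ε with the activities P hidden, fitted by
   hard-assignment EM: closed-form E-step (solve CP = D), L1-penalized
   ADMM M-step restricted to the stage-1/2 support, closed-form variance
   updates. Triplets whose α and β both survive the penalty form the final
   network.

Downstream tools: three-layer network assembly with degree and betweenness
statistics, a bootstrap test of activity-based vs mRNA-based MI, and a
context-specific rewiring analysis (ten expression bins, 2-means low/high
labelling, 10,000-permutation CMI test). A synthetic-data module generates
ground-truth datasets so every stage is testable without external data.

## Worked example

```r
library(tfanet)

# a ground-truth dataset: 5 TFs, 20 regulators, 60 targets, 400 samples
truth <- generate_tfa_dataset(L = 5, K = 20, N = 60, M = 400, seed = 42)

# Stage 1: screen TF-target pairs (truncated empirical null for a small pool)
screen <- screen_pairs(truth$expr, truth$tf_ids, trim = 0.75)
screen
#> MI screen: 375 TF-target pairs scored; 52 selected at p < 1e-04
#> t null (mle): mu = 0.0625, s = 0.0074, df = 1000000.00

# Stage 3: fit the activity model on the true support
fit <- fit_tfa(truth_draft(truth), Q = truth$Q, E = truth$E, lambda = 0)
median(abs(sapply(1:5, function(l) cor(fit$P[l, ], truth$P_true[l, ]))))
#> [1] 0.9997994

# a modulator-gated triplet and its rewiring signature
tr <- generate_modulated_triplet(1000, gate_strength = 1, noise_sd = 0.3, seed = 7)
expr <- rbind(x = tr$x, y = tr$y, m = tr$m)
colnames(expr) <- paste0("s", 1:1000)
rewiring_analysis(expr, "x", "y", "m", n_perm = 10000, seed = 1)
#> rewiring of (x, y) along m: CMI = 0.9260 (MI high 0.9917, low 0.0657), p = 9.999e-05 [10000 perms]
#> bin categories: low low low low low high high high high high
```

The screen recovers the planted regulatory pairs; the fitted activities
correlate almost perfectly with the hidden truth at the preset noise level;
and the gated pair shows the canonical rewiring signature — no correlation
in the five low-modulator bins, strong correlation in the five high bins,
with the smallest attainable permutation p-value.

The full pipeline (simulate → pairs → triplets → fit → network) runs from a
single config:

```r
run_pipeline(list(out_dir = "run1", seed = 5))
```

or from a shell via the thin wrapper `inst/scripts/tfanet.R`
(`tfanet.R run --config config.yaml`). Each run writes TSV artifacts and a
JSON manifest; reruns with the same config are bit-identical.

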