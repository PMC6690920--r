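#' Generate a ground-truth dataset from the hierarchical activity model
#'
#' Draws a dataset with exactly the statistical structure the activity model
#' assumes: regulator expression `Q` (K x M) i.i.d. standard normal, hidden
#' activities `P = B_true Q + noise_P`, and target expression
#' `E = A_true P + noise_E`.  The first `L` regulators are the TFs' own mRNA,
#' and every TF keeps a forced self edge in `B_true`.  Remaining support
#' entries are Bernoulli(`support_density`); nonzero weights are uniform in
#' `+/-[0.5, 1.5]` so "nonzero" is unambiguous for support-recovery checks.
#'
#' @param L Number of TFs.
#' @param K Number of regulators (>= L; TFs first, then cofactors).
#' @param N Number of target genes.
#' @param M Number of samples.
#' @param support_density Probability of a non-forced support entry, in (0, 1].
#' @param noise_sd_P,noise_sd_E Gaussian noise standard deviations.
#' @param seed Integer seed; output is bit-reproducible given it.
#' @return List of class `synthetic_truth`: matrices `Q`, `E`, `P_true`,
#'   `A_true`, `B_true`, an `expr` genes-by-samples matrix stacking Q over E,
#'   ID vectors, the `gated_triplets` tibble (modulator, tf, target for every
#'   non-self modulation crossed with the TF's targets), and the parameters.
#' @export
generate_tfa_dataset <- function(L = 5, K = 20, N = 60, M = 400,
                                 support_density = 0.2, noise_sd_P = 0.1,
                                 noise_sd_E = 0.1, seed = 1L) {
  stopifnot(K >= L, L >= 1, N >= 1, M >= 1)
  if (support_density <= 0 || support_density > 1)
    stop("support_density must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  tf_ids <- sprintf("TF%02d", seq_len(L))
  cf_ids <- if (K > L) sprintf("CF%02d", seq_len(K - L)) else character()
  regulator_ids <- c(tf_ids, cf_ids)
  target_ids <- sprintf("TG%03d", seq_len(N))
  sample_ids <- sprintf("S%04d", seq_len(M))

  rand_weights <- function(n) (2 * (runif(n) < 0.5) - 1) * runif(n, 0.5, 1.5)

  Q <- matrix(rnorm(K * M), K, M, dimnames = list(regulator_ids, sample_ids))
  B_true <- matrix(0, L, K, dimnames = list(tf_ids, regulator_ids))
  off_b <- matrix(runif(L * K) < support_density, L, K)
  off_b[cbind(seq_len(L), seq_len(L))] <- FALSE
  B_true[off_b] <- rand_weights(sum(off_b))
  B_true[cbind(seq_len(L), seq_len(L))] <- rand_weights(L) # forced self edges
  A_true <- matrix(0, N, L, dimnames = list(target_ids, tf_ids))
  on_a <- matrix(runif(N * L) < support_density, N, L)
  A_true[on_a] <- rand_weights(sum(on_a))

  P_true <- B_true %*% Q + noise_sd_P * matrix(rnorm(L * M), L, M)
  rownames(P_true) <- tf_ids
  E <- A_true %*% P_true + noise_sd_E * matrix(rnorm(N * M), N, M)
  dimnames(E) <- list(target_ids, sample_ids)

  gated <- purrr::map_dfr(seq_len(L), function(l) {
    mods <- regulator_ids[which(B_true[l, ] != 0 & seq_len(K) != l)]
    tgs <- target_ids[which(A_true[, l] != 0)]
    if (!length(mods) || !length(tgs))
      return(tibble::tibble(modulator = character(), tf = character(),
                            target = character()))
    tidyr::expand_grid(modulator = mods, target = tgs) |>
      dplyr::mutate(tf = tf_ids[l], .after = "modulator")
  })

  structure(list(Q = Q, E = E, P_true = P_true, A_true = A_true,
                 B_true = B_true, expr = rbind(Q, E),
                 tf_ids = tf_ids, regulator_ids = regulator_ids,
                 target_ids = target_ids, gated_triplets = gated,
                 noise_sd_P = noise_sd_P, noise_sd_E = noise_sd_E,
                 support_density = support_density, seed = seed),
            class = "synthetic_truth")
}

#' True-support draft network of a synthetic dataset
#'
#' @param truth A [generate_tfa_dataset()] result.
#' @return [draft_network()] whose supports equal the generator's.
#' @export
truth_draft <- function(truth) {
  idx_a <- which(truth$A_true != 0, arr.ind = TRUE)
  pairs <- tibble::tibble(tf = colnames(truth$A_true)[idx_a[, 2L]],
                          target = rownames(truth$A_true)[idx_a[, 1L]])
  draft_network(pairs, truth$gated_triplets, tf_ids = truth$tf_ids)
}

#' Generate one modulator-gated triplet
#'
#' `m` and `x` are i.i.d. standard normal and the target is
#' `y = gate_strength * x * 1[m > median(m)] + noise`: the TF-target
#' dependency exists only in the high-modulator half.  `gate_strength = 0`
#' gives a null triplet.  The generator gates at the median even though
#' detection uses 35% tails — detection is never told the generator's split.
#'
#' @param M_samples Number of samples (>= 40).
#' @param gate_strength Regulation strength in the high-modulator state.
#' @param noise_sd Noise standard deviation on `y`.
#' @param seed Integer seed.
#' @return List with numeric vectors `m`, `x`, `y`.
#' @export
generate_modulated_triplet <- function(M_samples = 500, gate_strength = 1,
                                       noise_sd = 0.3, seed = 1L) {
  stopifnot(M_samples >= 40)
  set.seed(seed)
  m <- rnorm(M_samples)
  x <- rnorm(M_samples)
  y <- gate_strength * x * (m > median(m)) + noise_sd * rnorm(M_samples)
  list(m = m, x = x, y = y)
}

#' Generate an all-independent expression matrix
#'
#' Every entry i.i.d. standard normal; the null input for type-I-error
#' calibration of the screening and modulation tests.
#'
#' @param G Number of genes (>= 2).
#' @param M Number of samples (>= 2).
#' @param seed Integer seed.
#' @return Genes-by-samples matrix with synthesized IDs.
#' @export
generate_null_matrix <- function(G, M, seed = 1L) {
  stopifnot(G >= 2, M >= 2)
  set.seed(seed)
  expression_matrix(matrix(rnorm(G * M), G, M,
                           dimnames = list(sprintf("G%04d", seq_len(G)),
                                           sprintf("S%04d", seq_len(M)))))
}
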