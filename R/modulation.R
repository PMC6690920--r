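#' Split samples by a modulator's expression level
#'
#' Returns the indices of the bottom and top `floor(fraction * M)` samples by
#' modulator expression.  Ties are broken by sample position (stable sort), so
#' the split is deterministic.
#'
#' @param m_expr Numeric vector of the modulator's expression (length >= 20).
#' @param fraction Tail fraction in (0, 0.5]; default 0.35 (bottom/top 35%).
#' @return List with integer vectors `low_idx` and `high_idx` (each sorted
#'   ascending, disjoint).
#' @export
split_by_modulator <- function(m_expr, fraction = 0.35) {
  if (length(m_expr) < 20L) stop("need at least 20 samples to split", call. = FALSE)
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]", call. = FALSE)
  if (sd(m_expr) == 0) stop("constant modulator: split meaningless", call. = FALSE)
  n_tail <- floor(fraction * length(m_expr))
  ord <- order(m_expr, seq_along(m_expr)) # stable: ties by sample order
  list(low_idx = sort(ord[seq_len(n_tail)]),
       high_idx = sort(ord[seq.int(length(m_expr) - n_tail + 1L, length(m_expr))]))
}

#' Conditional mutual information given a modulator
#'
#' The MINDy-style approximation: the TF-target MI on the samples where the
#' modulator is highly expressed minus the MI on the samples where it is lowly
#' expressed, `CMI = MI(X,Y | M high) - MI(X,Y | M low)`.  Each subset MI is a
#' clamped-nonnegative kernel estimate, so the CMI may be negative.
#'
#' @param x,y Numeric vectors (TF and target expression).
#' @param m Modulator expression, same length.
#' @param fraction Tail fraction for the split (default 0.35).
#' @return Tibble with one row: `mi_low`, `mi_high`, `cmi`.
#' @export
conditional_mi <- function(x, y, m, fraction = 0.35) {
  if (length(unique(c(length(x), length(y), length(m)))) != 1L)
    stop("x, y, m must have equal length", call. = FALSE)
  sp <- split_by_modulator(m, fraction)
  mi_low <- .kernel_mi_subset_cpp(as.numeric(x), as.numeric(y), sp$low_idx)
  mi_high <- .kernel_mi_subset_cpp(as.numeric(x), as.numeric(y), sp$high_idx)
  tibble::tibble(mi_low = mi_low, mi_high = mi_high, cmi = mi_high - mi_low)
}

#' Conditional MI from the two subset MI scores
#'
#' The CMI statistic is by definition the high-modulator subset MI minus the
#' low-modulator subset MI; this helper applies that definition to already
#' computed subset scores (e.g. reported values).
#'
#' @param mi_low,mi_high Subset MI scores.
#' @return `mi_high - mi_low`.
#' @export
cmi_from_subset_mi <- function(mi_low, mi_high) mi_high - mi_low

# Low/high index matrices for n_perm random permutations of m (columns are
# replicates).  Shared across a cofactor's targets: permuting m induces the
# same split whatever the (x, y) pair.
perm_splits <- function(m, n_perm, fraction) {
  n <- length(m)
  n_tail <- floor(fraction * n)
  low <- matrix(0L, n_tail, n_perm)
  high <- matrix(0L, n_tail, n_perm)
  for (r in seq_len(n_perm)) {
    # x and y stay in place; the permuted modulator value at position i is
    # m[perm[i]], so the split sets are positions ranked by m[perm]
    perm <- sample.int(n)
    ord <- order(m[perm], seq_len(n))
    low[, r] <- sort(ord[seq_len(n_tail)])
    high[, r] <- sort(ord[seq.int(n - n_tail + 1L, n)])
  }
  list(low = low, high = high)
}

#' Permutation p-value for a modulation triplet
#'
#' Permutes the modulator vector, recomputes the CMI for each permutation, and
#' returns the one-sided (gain of dependency) add-one p-value
#' `(1 + #\{perm CMI >= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams conditional_mi
#' @param n_perm Number of permutations (>= 1; default 1000).
#' @param seed Integer seed; the result is deterministic given it.
#' @return p-value in `[1/(n_perm+1), 1]`.
#' @export
permutation_pvalue <- function(x, y, m, fraction = 0.35, n_perm = 1000L,
                               seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs <- conditional_mi(x, y, m, fraction)$cmi
  set.seed(seed)
  sp <- perm_splits(m, n_perm, fraction)
  perm_cmi <- .cmi_splits_cpp(as.numeric(x), as.numeric(y), sp$low, sp$high)[, 3L]
  (1 + sum(perm_cmi >= obs)) / (1 + n_perm)
}

#' Call modulators of a TF from its candidate cofactors
#'
#' Step 2 of the pipeline.  For each cofactor (linkage neighbour of the TF) a
#' permutation CMI p-value is computed against every Step-1 target of the TF;
#' the cofactor is called a modulator when the fraction of targets with
#' `p < p_cutoff` is at least `majority` (the >= 50%-of-targets rule).  One
#' set of permuted splits is drawn per cofactor and shared across its targets,
#' since permuting the modulator induces the same sample split for every
#' target.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param tf TF gene ID.
#' @param targets Character vector: the TF's significant Step-1 targets.
#' @param cofactors Candidate modulators (typically linkage neighbours of the
#'   TF present in `expr`); the TF itself is excluded.
#' @param fraction Tail fraction for the modulator split (default 0.35).
#' @param n_perm Permutations per cofactor (default 1000).
#' @param p_cutoff Per-target significance cutoff (default 0.001).
#' @param majority Minimum fraction of significant targets (default 0.5).
#' @param seed Integer seed.
#' @return Tibble of triplets (modulator, tf, target, mi_low, mi_high, cmi,
#'   p_value) for called modulators, restricted to their significant targets.
#' @export
call_modulators <- function(expr, tf, targets, cofactors, fraction = 0.35,
                            n_perm = 1000L, p_cutoff = 0.001, majority = 0.5,
                            seed = 1L) {
  expr <- expression_matrix(expr)
  empty <- tibble::tibble(modulator = character(), tf = character(),
                          target = character(), mi_low = numeric(),
                          mi_high = numeric(), cmi = numeric(),
                          p_value = numeric())
  targets <- intersect(targets, rownames(expr))
  if (!length(targets)) {
    warning("TF ", tf, " has no Step-1 targets in the matrix; nothing to test")
    return(empty)
  }
  cofactors <- setdiff(intersect(cofactors, rownames(expr)), tf)
  if (!length(cofactors)) return(empty)

  set.seed(seed)
  out <- vector("list", length(cofactors))
  for (ci in seq_along(cofactors)) {
    cf <- cofactors[[ci]]
    m <- expr[cf, ]
    sp_perm <- perm_splits(m, n_perm, fraction)
    recs <- purrr::map(targets, function(tg) {
      obs <- conditional_mi(expr[tf, ], expr[tg, ], m, fraction)
      perm_cmi <- .cmi_splits_cpp(as.numeric(expr[tf, ]),
                                  as.numeric(expr[tg, ]),
                                  sp_perm$low, sp_perm$high)[, 3L]
      obs$p_value <- (1 + sum(perm_cmi >= obs$cmi)) / (1 + n_perm)
      obs
    }) |> dplyr::bind_rows()
    recs <- dplyr::mutate(recs, modulator = cf, tf = tf, target = targets,
                          .before = 1L)
    sig_frac <- mean(recs$p_value < p_cutoff)
    if (sig_frac >= majority) {
      out[[ci]] <- dplyr::filter(recs, .data$p_value < p_cutoff)
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) empty else res
}
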