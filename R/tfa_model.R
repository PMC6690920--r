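#' Build the draft network structure for the activity model
#'
#' The draft network fixes the allowed support of the two strength matrices:
#' `A` (targets x TFs, regulatory strengths alpha) may be nonzero only where a
#' Step-1 pair exists, and `B` (TFs x regulators, modulation strengths beta)
#' only on each TF's own-mRNA self edge plus its Step-2 modulators.
#' Regulators are ordered TFs first, then the remaining modulators.
#'
#' @param pairs Tibble with columns `tf`, `target` (Step-1 output).
#' @param triplets Optional tibble with columns `modulator`, `tf`, `target`
#'   (Step-2 output).
#' @param tf_ids Optional explicit TF ordering; defaults to the TFs seen in
#'   `pairs`/`triplets`.
#' @return Object of class `draft_network` with the index vectors, logical
#'   support matrices `A_support` (N x L) and `B_support` (L x K), and the
#'   input tables.
#' @export
draft_network <- function(pairs, triplets = NULL, tf_ids = NULL) {
  stopifnot(all(c("tf", "target") %in% names(pairs)))
  if (is.null(triplets))
    triplets <- tibble::tibble(modulator = character(), tf = character(),
                               target = character())
  if (is.null(tf_ids))
    tf_ids <- unique(c(pairs$tf, triplets$tf))
  tf_ids <- as.character(tf_ids)
  if (!all(triplets$tf %in% tf_ids))
    stop("triplet TFs missing from tf_ids", call. = FALSE)
  target_ids <- unique(as.character(pairs$target))
  regulator_ids <- c(tf_ids, setdiff(unique(as.character(triplets$modulator)), tf_ids))
  L <- length(tf_ids); K <- length(regulator_ids); N <- length(target_ids)
  if (L < 1L || N < 1L) stop("draft network needs >= 1 TF and >= 1 target", call. = FALSE)

  A_support <- matrix(FALSE, N, L, dimnames = list(target_ids, tf_ids))
  A_support[cbind(match(pairs$target, target_ids), match(pairs$tf, tf_ids))] <- TRUE
  B_support <- matrix(FALSE, L, K, dimnames = list(tf_ids, regulator_ids))
  B_support[cbind(seq_len(L), seq_len(L))] <- TRUE # self mRNA edge, always allowed
  if (nrow(triplets))
    B_support[cbind(match(triplets$tf, tf_ids),
                    match(triplets$modulator, regulator_ids))] <- TRUE

  structure(list(tf_ids = tf_ids, regulator_ids = regulator_ids,
                 target_ids = target_ids, A_support = A_support,
                 B_support = B_support, pairs = pairs, triplets = triplets),
            class = "draft_network")
}

#' @export
print.draft_network <- function(x, ...) {
  cat("draft network:", length(x$tf_ids), "TFs,", length(x$regulator_ids),
      "regulators,", length(x$target_ids), "targets;",
      sum(x$A_support), "regulation and", sum(x$B_support),
      "modulation support entries\n")
  invisible(x)
}

# Subset a named matrix to the draft's row order; pass-through when unnamed
# (caller guarantees alignment then).
align_rows <- function(x, ids, what) {
  if (is.null(rownames(x))) {
    if (nrow(x) != length(ids))
      stop(what, " has ", nrow(x), " rows but the draft indexes ",
           length(ids), call. = FALSE)
    return(x)
  }
  miss <- setdiff(ids, rownames(x))
  if (length(miss))
    stop(what, " is missing draft rows: ", paste(head(miss, 10L), collapse = ", "),
         call. = FALSE)
  x[ids, , drop = FALSE]
}

# Restricted least squares of one response row on the supported regressor
# rows: returns full-length coefficients, zeros off support.  Rank-deficient
# designs are handled by pivoting (aliased coefficients set to 0).
ls_row <- function(X_rows, y, support) {
  beta <- numeric(length(support))
  s <- which(support)
  if (!length(s)) return(beta)
  fit <- stats::lm.fit(t(X_rows[s, , drop = FALSE]), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  beta[s] <- cf
  beta
}

#' Initialize the activity model
#'
#' Each TF's activity starts at its own mRNA row of `Q`; `B` starts as the
#' identity on the self edges; `A` is the per-target restricted least squares
#' of `E` on the initial activities; variances come from the initial
#' residuals (floored at 1e-8).
#'
#' @param draft A [draft_network()].
#' @param Q Regulators-by-samples matrix (rows named, covering
#'   `draft$regulator_ids`).
#' @param E Targets-by-samples matrix (rows named, covering
#'   `draft$target_ids`).
#' @param lambda Nonnegative L1 penalty carried by the model.
#' @return Object of class `tfa_model`.
#' @export
init_model <- function(draft, Q, E, lambda = 0) {
  stopifnot(inherits(draft, "draft_network"))
  miss <- c(setdiff(draft$regulator_ids, rownames(Q)),
            setdiff(draft$target_ids, rownames(E)))
  if (length(miss))
    stop("draft references genes absent from Q/E: ",
         paste(head(miss, 10L), collapse = ", "), call. = FALSE)
  Q <- Q[draft$regulator_ids, , drop = FALSE]
  E <- E[draft$target_ids, , drop = FALSE]
  L <- length(draft$tf_ids); K <- length(draft$regulator_ids)
  N <- length(draft$target_ids); M <- ncol(Q)

  P <- Q[seq_len(L), , drop = FALSE]
  rownames(P) <- draft$tf_ids
  B <- matrix(0, L, K, dimnames = dimnames(draft$B_support))
  B[cbind(seq_len(L), seq_len(L))] <- 1
  A <- matrix(0, N, L, dimnames = dimnames(draft$A_support))
  for (n in seq_len(N)) A[n, ] <- ls_row(P, E[n, ], draft$A_support[n, ])

  model <- structure(list(A = A, B = B, P = P,
                          sigma2_P = rep(1, L), sigma2_E = rep(1, N),
                          lambda = lambda, draft = draft,
                          objective_trace = numeric(), n_iter = 0L,
                          converged = FALSE),
                     class = "tfa_model")
  v <- update_variances(model, P, Q, E)
  # The initial activities are exactly representable by the self edges, so the
  # raw activity-layer residual is degenerate at zero; starting that variance
  # at the marginal scale (1 on z-scored data) lets the first E-step blend
  # prior and target information instead of pinning P to B Q.
  model$sigma2_P <- pmax(v$sigma2_P, 1)
  model$sigma2_E <- v$sigma2_E
  model
}

#' Hard-assignment E-step: solve for the hidden activities
#'
#' With the strengths and variances fixed, the activities maximizing the
#' likelihood solve the linear system `C P = D` columnwise, where
#' `C = t(A) diag(1/sigma2_E) A + diag(1/sigma2_P)` (sample-independent) and
#' each sample's right-hand side is
#' `D = diag(1/sigma2_P) B q + t(A) diag(1/sigma2_E) e`.  The variance floor
#' keeps `C` positive definite.
#'
#' @param model A `tfa_model`.
#' @param Q,E Aligned regulator and target matrices.
#' @return Activity matrix `P` (TFs x samples).
#' @export
e_step <- function(model, Q, E) {
  Q <- align_rows(Q, model$draft$regulator_ids, "Q")
  E <- align_rows(E, model$draft$target_ids, "E")
  A <- model$A; B <- model$B
  w_e <- 1 / model$sigma2_E
  w_p <- 1 / model$sigma2_P
  C <- crossprod(A, A * w_e)
  diag(C) <- diag(C) + w_p
  D <- (B %*% Q) * w_p + crossprod(A, E * w_e)
  P <- solve(C, D)
  rownames(P) <- rownames(B)
  P
}

#' Dense M-step via restricted least squares (pseudo-inverse)
#'
#' The unpenalized M-step: `A = E P^+` and `B = P Q^+`, computed row by row
#' restricted to the draft support (off-support coefficients stay 0).  Errors
#' when `P` or `Q` is row-rank-deficient, in which case the sparse M-step must
#' be used instead.
#'
#' @param P Activities (TFs x samples).
#' @param Q,E Aligned regulator and target matrices.
#' @param draft The [draft_network()].
#' @return List with matrices `A` and `B`.
#' @export
m_step_dense <- function(P, Q, E, draft) {
  P <- align_rows(P, draft$tf_ids, "P")
  Q <- align_rows(Q, draft$regulator_ids, "Q")
  E <- align_rows(E, draft$target_ids, "E")
  if (qr(t(P))$rank < nrow(P) || qr(t(Q))$rank < nrow(Q))
    stop("P or Q is row-rank-deficient: use the sparse (L1/ADMM) M-step",
         call. = FALSE)
  N <- nrow(E); L <- nrow(P); K <- nrow(Q)
  A <- matrix(0, N, L, dimnames = dimnames(draft$A_support))
  for (n in seq_len(N)) A[n, ] <- ls_row(P, E[n, ], draft$A_support[n, ])
  B <- matrix(0, L, K, dimnames = dimnames(draft$B_support))
  for (l in seq_len(L)) B[l, ] <- ls_row(Q, P[l, ], draft$B_support[l, ])
  list(A = A, B = B)
}

#' Smallest L1 penalty with an all-zero lasso solution
#'
#' For the row problem `min ||y - w' X_rows||^2 / (2 sigma2) + lambda ||w||_1`
#' the zero vector is optimal exactly when
#' `lambda >= max |X_rows y| / sigma2`.
#'
#' @param X_rows Regressors-by-samples matrix.
#' @param y Response vector.
#' @param sigma2 Residual variance weight (default 1).
#' @return The threshold penalty.
#' @export
lambda_max <- function(X_rows, y, sigma2 = 1) {
  max(abs(X_rows %*% y)) / sigma2
}

# ADMM for min 1/2 ||X w - y||^2 + mu ||w||_1 (lasso with exact zeros from
# the soft-thresholded copy).  Standard scaled-dual form with over-relaxation.
admm_lasso <- function(X, y, mu, rho = 1, abs_tol = 1e-6, rel_tol = 1e-4,
                       max_iter = 500L, relax = 1.5) {
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  R <- chol(XtX + rho * diag(p))
  w <- z <- u <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- backsolve(R, forwardsolve(t(R), Xty + rho * (z - u)))
    w_hat <- relax * w + (1 - relax) * z
    z_old <- z
    v <- w_hat + u
    z <- sign(v) * pmax(abs(v) - mu / rho, 0)
    u <- u + w_hat - z
    r_pri <- sqrt(sum((w - z)^2))
    r_dual <- rho * sqrt(sum((z - z_old)^2))
    eps_pri <- sqrt(p) * abs_tol + rel_tol * max(sqrt(sum(w^2)), sqrt(sum(z^2)))
    eps_dual <- sqrt(p) * abs_tol + rel_tol * rho * sqrt(sum(u^2))
    if (r_pri <= eps_pri && r_dual <= eps_dual) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ADMM did not converge within ", max_iter,
            " iterations; returning best iterate")
  drop(z)
}

#' Sparse M-step via L1-regularized least squares (ADMM)
#'
#' The penalized M-step is separable into one lasso problem per target row of
#' `A` and per TF row of `B`; each is solved by ADMM over the support-
#' restricted coefficients.  Residuals are weighted by the corresponding
#' conditional variance so the update minimizes the penalized negative
#' log-likelihood; with unit variances (the default) the problem is the plain
#' `||E - A P||^2 + ||P - B Q||^2 + lambda (||A||_1 + ||B||_1)` objective, and
#' with `lambda = 0` the solution matches [m_step_dense()].
#'
#' @inheritParams m_step_dense
#' @param lambda Nonnegative L1 penalty.
#' @param sigma2_P,sigma2_E Variance weights (defaults 1).
#' @param admm_params List overriding `rho`, `abs_tol`, `rel_tol`, `max_iter`,
#'   `relax`.
#' @return List with matrices `A` and `B`.
#' @export
m_step_sparse <- function(P, Q, E, draft, lambda = 0, sigma2_P = NULL,
                          sigma2_E = NULL, admm_params = list()) {
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  P <- align_rows(P, draft$tf_ids, "P")
  Q <- align_rows(Q, draft$regulator_ids, "Q")
  E <- align_rows(E, draft$target_ids, "E")
  N <- nrow(E); L <- nrow(P); K <- nrow(Q)
  if (is.null(sigma2_P)) sigma2_P <- rep(1, L)
  if (is.null(sigma2_E)) sigma2_E <- rep(1, N)
  ap <- utils::modifyList(list(rho = 1, abs_tol = 1e-6, rel_tol = 1e-4,
                               max_iter = 500L, relax = 1.5), admm_params)
  solve_row <- function(X_rows, y, support, s2) {
    beta <- numeric(length(support))
    s <- which(support)
    if (!length(s)) return(beta)
    sig <- sqrt(s2)
    beta[s] <- admm_lasso(t(X_rows[s, , drop = FALSE]) / sig, y / sig, lambda,
                          rho = ap$rho, abs_tol = ap$abs_tol,
                          rel_tol = ap$rel_tol, max_iter = ap$max_iter,
                          relax = ap$relax)
    beta
  }
  A <- matrix(0, N, L, dimnames = dimnames(draft$A_support))
  for (n in seq_len(N))
    A[n, ] <- solve_row(P, E[n, ], draft$A_support[n, ], sigma2_E[n])
  B <- matrix(0, L, K, dimnames = dimnames(draft$B_support))
  for (l in seq_len(L))
    B[l, ] <- solve_row(Q, P[l, ], draft$B_support[l, ], sigma2_P[l])
  list(A = A, B = B)
}

#' Closed-form variance updates
#'
#' Per-TF and per-target mean squared residuals,
#' `sigma2_P[l] = mean((p_l - beta_l Q)^2)` and
#' `sigma2_E[n] = mean((e_n - alpha_n P)^2)`, floored at 1e-8.
#'
#' @param model A `tfa_model` (supplies `A`, `B`).
#' @param P Activities.
#' @param Q,E Aligned matrices.
#' @return List with `sigma2_P` and `sigma2_E`.
#' @export
update_variances <- function(model, P, Q, E) {
  Q <- align_rows(Q, model$draft$regulator_ids, "Q")
  E <- align_rows(E, model$draft$target_ids, "E")
  rp <- P - model$B %*% Q
  re <- E - model$A %*% P
  list(sigma2_P = pmax(rowMeans(rp^2), 1e-8),
       sigma2_E = pmax(rowMeans(re^2), 1e-8))
}

#' Penalized negative log-likelihood of the activity model
#'
#' Sum over the activity and expression layers of
#' `0.5 * M * log(2 pi sigma2) + RSS / (2 sigma2)`, plus
#' `lambda * (||A||_1 + ||B||_1)`.  The marginal terms of the observed
#' regulator rows carry no information about the strengths and are omitted.
#'
#' @param model A `tfa_model`.
#' @param Q,E Aligned matrices.
#' @param P Optional activities (defaults to `model$P`).
#' @return Finite scalar; EM iterations never increase it.
#' @export
penalized_objective <- function(model, Q, E, P = NULL) {
  if (is.null(P)) P <- model$P
  Q <- align_rows(Q, model$draft$regulator_ids, "Q")
  E <- align_rows(E, model$draft$target_ids, "E")
  M <- ncol(Q)
  rp <- P - model$B %*% Q
  re <- E - model$A %*% P
  obj_p <- sum(0.5 * M * log(2 * pi * model$sigma2_P) +
                 rowSums(rp^2) / (2 * model$sigma2_P))
  obj_e <- sum(0.5 * M * log(2 * pi * model$sigma2_E) +
                 rowSums(re^2) / (2 * model$sigma2_E))
  obj_p + obj_e + model$lambda * (sum(abs(model$A)) + sum(abs(model$B)))
}

# Per-row penalized objective pieces used by the monotone M-step safeguard.
row_objective_A <- function(a_row, P, e, s2, lambda) {
  sum((e - drop(a_row %*% P))^2) / (2 * s2) + lambda * sum(abs(a_row))
}
row_objective_B <- function(b_row, Q, p, s2, lambda) {
  sum((p - drop(b_row %*% Q))^2) / (2 * s2) + lambda * sum(abs(b_row))
}

#' Fit the hierarchical activity model by hard-assignment EM
#'
#' Alternates the closed-form E-step (activities from `C P = D`) with the
#' sparse M-step (per-row ADMM lasso) and the variance updates until the
#' relative change of the penalized objective falls below `tol` or `max_iter`
#' is reached.  A per-row monotone safeguard keeps the previous strengths
#' whenever the ADMM iterate would increase that row's penalized objective,
#' so the recorded objective trace is non-increasing.
#'
#' Variance updates are damped: a conditional variance may shrink by at most
#' a factor of `var_shrink_cap` per iteration.  Without the cap the
#' activity-layer variance collapses to the floor within a few iterations on
#' low-noise data (the activities are almost exactly representable by the
#' regulators early on), which pins the activities to `B Q` under a wrong
#' `B` — a degenerate local optimum of hard EM.  The cap only limits the
#' shrink rate, not the fixed points, and preserves monotone descent (the
#' capped update is still the constrained minimizer over the allowed
#' variance range).
#'
#' @param draft A [draft_network()].
#' @param expr Optional genes-by-samples matrix from which `Q` (regulator
#'   rows) and `E` (target rows) are extracted; alternatively pass `Q` and
#'   `E` directly.
#' @param Q,E Aligned matrices (used when `expr` is NULL).
#' @param lambda Nonnegative L1 penalty on the strengths.
#' @param max_iter,tol EM stopping rule (default 100 iterations, relative
#'   objective change 1e-6).
#' @param standardize Z-score the rows of `Q` and `E` before fitting
#'   (default TRUE).
#' @param var_shrink_cap Maximum per-iteration shrink factor of each
#'   conditional variance (default 1.3; `Inf` disables damping).
#' @param admm_params Passed to [m_step_sparse()].
#' @return A fitted `tfa_model` with `A`, `B`, `P`, variances,
#'   `objective_trace`, `n_iter`, `converged`.
#' @export
fit_tfa <- function(draft, expr = NULL, Q = NULL, E = NULL, lambda = 0,
                    max_iter = 100L, tol = 1e-6, standardize = TRUE,
                    var_shrink_cap = 1.3, admm_params = list()) {
  if (!is.null(expr)) {
    expr <- expression_matrix(expr)
    miss <- setdiff(c(draft$regulator_ids, draft$target_ids), rownames(expr))
    if (length(miss))
      stop("draft references genes absent from the matrix: ",
           paste(head(miss, 10L), collapse = ", "), call. = FALSE)
    Q <- expr[draft$regulator_ids, , drop = FALSE]
    E <- expr[draft$target_ids, , drop = FALSE]
  }
  Q <- align_rows(Q, draft$regulator_ids, "Q")
  E <- align_rows(E, draft$target_ids, "E")
  if (standardize) {
    Q <- zscore_rows(Q)
    E <- zscore_rows(E)
  }
  model <- init_model(draft, Q, E, lambda = lambda)
  obj <- penalized_objective(model, Q, E)
  trace <- obj
  L <- nrow(model$B); N <- nrow(model$A)
  for (it in seq_len(max_iter)) {
    model$P <- e_step(model, Q, E)
    ms <- m_step_sparse(model$P, Q, E, draft, lambda = lambda,
                        sigma2_P = model$sigma2_P, sigma2_E = model$sigma2_E,
                        admm_params = admm_params)
    # monotone safeguard: per-row, keep the better of old/new coefficients
    for (n in seq_len(N)) {
      if (row_objective_A(ms$A[n, ], model$P, E[n, ], model$sigma2_E[n], lambda) <=
          row_objective_A(model$A[n, ], model$P, E[n, ], model$sigma2_E[n], lambda))
        model$A[n, ] <- ms$A[n, ]
    }
    for (l in seq_len(L)) {
      if (row_objective_B(ms$B[l, ], Q, model$P[l, ], model$sigma2_P[l], lambda) <=
          row_objective_B(model$B[l, ], Q, model$P[l, ], model$sigma2_P[l], lambda))
        model$B[l, ] <- ms$B[l, ]
    }
    v <- update_variances(model, model$P, Q, E)
    model$sigma2_P <- pmax(v$sigma2_P, model$sigma2_P / var_shrink_cap)
    model$sigma2_E <- pmax(v$sigma2_E, model$sigma2_E / var_shrink_cap)
    obj_new <- penalized_objective(model, Q, E)
    trace <- c(trace, obj_new)
    model$n_iter <- it
    if (abs(obj - obj_new) < tol * max(1, abs(obj))) {
      model$converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  model$objective_trace <- trace
  model
}

zscore_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0] <- 1
  (x - mu) / s
}

#' Triplets surviving the fitted model
#'
#' A draft triplet (modulator m, TF t, target g) is active when both its
#' modulation strength `B[t, m]` and its regulatory strength `A[g, t]` are
#' nonzero after ADMM thresholding (|.| > 1e-10).
#'
#' @param model Fitted `tfa_model`.
#' @param draft Optional draft (defaults to the one stored in the model).
#' @return Tibble: the subset of draft triplets that are active.
#' @export
select_active_triplets <- function(model, draft = model$draft) {
  tr <- draft$triplets
  if (!nrow(tr)) return(tr)
  keep <- abs(model$B[cbind(match(tr$tf, rownames(model$B)),
                            match(tr$modulator, colnames(model$B)))]) > 1e-10 &
    abs(model$A[cbind(match(tr$target, rownames(model$A)),
                      match(tr$tf, colnames(model$A)))]) > 1e-10
  tr[keep, , drop = FALSE]
}

#' @export
print.tfa_model <- function(x, ...) {
  cat("TFA model:", nrow(x$B), "TFs,", ncol(x$B), "regulators,",
      nrow(x$A), "targets,", ncol(x$P), "samples\n")
  cat(sprintf("lambda = %g; %d EM iteration(s); %sconverged; objective %.4f\n",
              x$lambda, x$n_iter, if (x$converged) "" else "NOT ",
              tail(x$objective_trace, 1L)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tfa_model <- function(x, ...) {
  A <- x$A; B <- x$B
  reg <- tibble::tibble(
    source = rep(colnames(A), each = nrow(A)),
    target = rep(rownames(A), times = ncol(A)),
    edge_type = "regulation",
    estimate = as.vector(A),
    in_support = as.vector(x$draft$A_support))
  mod <- tibble::tibble(
    source = rep(colnames(B), each = nrow(B)),
    target = rep(rownames(B), times = ncol(B)),
    edge_type = "modulation",
    estimate = as.vector(B),
    in_support = as.vector(x$draft$B_support))
  dplyr::filter(dplyr::bind_rows(reg, mod), .data$in_support) |>
    dplyr::select(-"in_support")
}

#' @exportS3Method generics::glance
glance.tfa_model <- function(x, ...) {
  tibble::tibble(
    n_tfs = nrow(x$B), n_regulators = ncol(x$B), n_targets = nrow(x$A),
    n_samples = ncol(x$P), lambda = x$lambda, n_iter = x$n_iter,
    converged = x$converged, objective = tail(x$objective_trace, 1L),
    nnz_A = sum(abs(x$A) > 1e-10), nnz_B = sum(abs(x$B) > 1e-10))
}

#' @exportS3Method ggplot2::autoplot
autoplot.tfa_model <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "EM iteration", y = "penalized negative log-likelihood",
                  title = "EM objective trace")
}
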