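make_instance <- function(L = 3, K = 6, N = 8, M = 40, density = 0.5,
                          noise = 0.2, seed = 1) {
  truth <- generate_tfa_dataset(L, K, N, M, density, noise, noise, seed)
  list(truth = truth, draft = truth_draft(truth))
}

test_that("draft network indexes TFs first and always allows self edges", {
  pairs <- tibble::tibble(tf = c("T1", "T2"), target = c("G1", "G2"))
  trip <- tibble::tibble(modulator = c("M1", "T1"), tf = c("T1", "T2"),
                         target = c("G1", "G2"))
  d <- draft_network(pairs, trip)
  expect_identical(d$tf_ids, c("T1", "T2"))
  expect_identical(d$regulator_ids, c("T1", "T2", "M1"))
  expect_true(all(diag(d$B_support[, 1:2])))       # self mRNA edges
  expect_true(d$B_support["T1", "M1"])
  expect_true(d$B_support["T2", "T1"])             # a TF can modulate a TF
  expect_true(d$A_support["G1", "T1"] && d$A_support["G2", "T2"])
  expect_identical(sum(d$A_support), 2L)
  expect_error(draft_network(pairs, trip, tf_ids = "T1"), "missing")
})

test_that("initialization seeds activities with the TF's own mRNA and is deterministic", {
  inst <- make_instance(seed = 2)
  tr <- inst$truth
  m1 <- init_model(inst$draft, tr$Q, tr$E)
  m2 <- init_model(inst$draft, tr$Q, tr$E)
  expect_identical(m1, m2)
  expect_equal(m1$P, tr$Q[inst$draft$tf_ids, ], tolerance = 1e-15)
  expect_true(all(m1$B[cbind(1:3, 1:3)] == 1))
  expect_true(all(m1$A[!inst$draft$A_support] == 0))
  expect_true(all(m1$sigma2_E >= 1e-8))
  bad <- inst$draft
  bad$regulator_ids <- c(bad$regulator_ids, "GHOST")
  expect_error(init_model(bad, tr$Q, tr$E), "GHOST")
})

test_that("the E-step solves C P = D exactly and reduces to B Q when A = 0", {
  for (s in 1:20) {
    inst <- make_instance(L = 3, K = 4, N = 5, M = 10, density = 0.8, seed = s)
    tr <- inst$truth
    model <- init_model(inst$draft, tr$Q, tr$E)
    set.seed(s)
    model$A[inst$draft$A_support] <- rnorm(sum(inst$draft$A_support))
    model$B[inst$draft$B_support] <- rnorm(sum(inst$draft$B_support))
    model$sigma2_P <- runif(3, 0.1, 2)
    model$sigma2_E <- runif(nrow(model$A), 0.1, 2)
    P <- e_step(model, tr$Q, tr$E)
    Qd <- tr$Q[inst$draft$regulator_ids, ]
    Ed <- tr$E[inst$draft$target_ids, ]
    C <- crossprod(model$A, model$A / model$sigma2_E) + diag(1 / model$sigma2_P)
    D <- (model$B %*% Qd) / model$sigma2_P +
      crossprod(model$A, Ed / model$sigma2_E)
    expect_lt(max(abs(P - solve(C, D))), 1e-10)
    # gradient of the per-sample quadratic objective vanishes at the solution
    expect_lt(max(abs(C %*% P - D)), 1e-8)
    # A = 0: the prior mean is the exact solution
    model$A[] <- 0
    expect_lt(max(abs(e_step(model, tr$Q, tr$E) - model$B %*% Qd)), 1e-8)
  }
})

test_that("the E-step returns B Q on noiseless consistent data", {
  inst <- make_instance(noise = 0, M = 60, seed = 3)
  tr <- inst$truth
  model <- init_model(inst$draft, tr$Q, tr$E)
  model$A <- tr$A_true[inst$draft$target_ids, ]
  model$B <- tr$B_true[, inst$draft$regulator_ids]
  BQ <- model$B %*% tr$Q[inst$draft$regulator_ids, ]
  expect_lt(max(abs(e_step(model, tr$Q, tr$E) - BQ)), 1e-8)
})

test_that("the dense M-step is exact least squares on the draft support", {
  inst <- make_instance(L = 3, K = 6, N = 8, M = 50, density = 1,
                        noise = 0, seed = 4)
  tr <- inst$truth
  ms <- m_step_dense(tr$P_true, tr$Q, tr$E, inst$draft)
  expect_lt(max(abs(ms$A - tr$A_true[inst$draft$target_ids, ])), 1e-8)

  # orthonormal activity rows: pseudo-inverse is the transpose
  set.seed(5)
  P <- qr.Q(qr(matrix(rnorm(50 * 3), 50, 3)))[, 1:3]
  P <- t(P); rownames(P) <- inst$draft$tf_ids
  E <- matrix(rnorm(8 * 50), 8, 50,
              dimnames = list(inst$draft$target_ids, NULL))
  mso <- m_step_dense(P, tr$Q, E, inst$draft)
  expect_lt(max(abs(mso$A - E %*% t(P))), 1e-8)

  # noisy instance vs normal equations
  inst2 <- make_instance(L = 3, K = 6, N = 8, M = 50, density = 0.6,
                         noise = 0.5, seed = 6)
  tr2 <- inst2$truth
  ms2 <- m_step_dense(tr2$P_true, tr2$Q, tr2$E, inst2$draft)
  for (n in seq_along(inst2$draft$target_ids)) {
    s <- inst2$draft$A_support[n, ]
    if (!any(s)) next
    X <- t(tr2$P_true[s, , drop = FALSE])
    beta <- solve(crossprod(X), crossprod(X, tr2$E[inst2$draft$target_ids[n], ]))
    expect_lt(max(abs(ms2$A[n, s] - beta)), 1e-8)
  }

  # rank-deficient P directs to the sparse path
  Pdef <- tr$P_true; Pdef[2, ] <- Pdef[1, ]
  expect_error(m_step_dense(Pdef, tr$Q, tr$E, inst$draft), "sparse")
})

test_that("the ADMM M-step matches restricted least squares at lambda 0 and a CD oracle otherwise", {
  inst <- make_instance(L = 3, K = 6, N = 8, M = 50, density = 0.6,
                        noise = 0.3, seed = 7)
  tr <- inst$truth
  dense <- m_step_dense(tr$P_true, tr$Q, tr$E, inst$draft)
  sparse0 <- m_step_sparse(tr$P_true, tr$Q, tr$E, inst$draft, lambda = 0)
  expect_lt(max(abs(dense$A - sparse0$A)), 1e-6)
  expect_lt(max(abs(dense$B - sparse0$B)), 1e-6)

  # per-coefficient agreement with coordinate descent at lambda > 0
  lam <- 3
  sp <- m_step_sparse(tr$P_true, tr$Q, tr$E, inst$draft, lambda = lam)
  for (n in 1:3) {
    s <- inst$draft$A_support[n, ]
    if (!any(s)) next
    X <- t(tr$P_true[s, , drop = FALSE])
    w <- oracle_cd_lasso(X, tr$E[inst$draft$target_ids[n], ], lam)
    expect_lt(max(abs(sp$A[n, s] - w)), 1e-4)
  }
  expect_error(m_step_sparse(tr$P_true, tr$Q, tr$E, inst$draft, lambda = -1),
               "nonnegative")
})

test_that("penalties at or above lambda_max zero out a row", {
  inst <- make_instance(seed = 8)
  tr <- inst$truth
  n <- 1
  s <- which(inst$draft$A_support[n, ])
  y <- tr$E[inst$draft$target_ids[n], ]
  lmax <- lambda_max(tr$P_true[s, , drop = FALSE], y)
  sp <- suppressWarnings(
    m_step_sparse(tr$P_true, tr$Q, tr$E, inst$draft, lambda = lmax * 1.001))
  expect_true(all(abs(sp$A[n, ]) <= 1e-10))
})

test_that("variance updates are the floored mean squared residuals", {
  inst <- make_instance(seed = 9)
  tr <- inst$truth
  model <- init_model(inst$draft, tr$Q, tr$E)
  Qd <- tr$Q[inst$draft$regulator_ids, ]
  Ed <- tr$E[inst$draft$target_ids, ]
  v <- update_variances(model, tr$P_true, tr$Q, tr$E)
  expect_equal(v$sigma2_P,
               pmax(rowMeans((tr$P_true - model$B %*% Qd)^2), 1e-8),
               tolerance = 1e-12)
  expect_equal(v$sigma2_E,
               pmax(rowMeans((Ed - model$A %*% tr$P_true)^2), 1e-8),
               tolerance = 1e-12)
  # exact fit hits the floor
  model$B[] <- 0; model$B[cbind(1:3, 1:3)] <- 1
  v0 <- update_variances(model, Qd[1:3, ], tr$Q, tr$E)
  expect_equal(unname(v0$sigma2_P), rep(1e-8, 3))
})

test_that("the penalized objective matches a direct evaluation and its closed form", {
  inst <- make_instance(seed = 10)
  tr <- inst$truth
  model <- init_model(inst$draft, tr$Q, tr$E, lambda = 2)
  Qd <- tr$Q[inst$draft$regulator_ids, ]
  Ed <- tr$E[inst$draft$target_ids, ]
  M <- ncol(Qd)
  direct <- sum(0.5 * M * log(2 * pi * model$sigma2_P) +
                  rowSums((model$P - model$B %*% Qd)^2) / (2 * model$sigma2_P)) +
    sum(0.5 * M * log(2 * pi * model$sigma2_E) +
          rowSums((Ed - model$A %*% model$P)^2) / (2 * model$sigma2_E)) +
    2 * (sum(abs(model$A)) + sum(abs(model$B)))
  expect_equal(penalized_objective(model, tr$Q, tr$E), direct,
               tolerance = 1e-12)

  # doubling the expression-layer residuals at fixed variances increases it
  E_worse <- 2 * Ed - model$A %*% model$P
  rownames(E_worse) <- rownames(Ed)
  expect_gt(penalized_objective(model, tr$Q, E_worse),
            penalized_objective(model, tr$Q, tr$E))

  # all-zero model on population-z-scored data: closed-form constant
  zpop <- function(x) (x - rowMeans(x)) / sqrt(rowMeans((x - rowMeans(x))^2))
  L <- 3; N <- length(inst$draft$target_ids)
  m0 <- model
  m0$A[] <- 0; m0$B[] <- 0
  m0$P <- matrix(0, L, M, dimnames = list(inst$draft$tf_ids, colnames(Qd)))
  m0$sigma2_P <- rep(1, L); m0$sigma2_E <- rep(1, N); m0$lambda <- 0
  obj0 <- penalized_objective(m0, zpop(Qd), zpop(Ed))
  expect_equal(obj0, 0.5 * M * (N * (1 + log(2 * pi)) + L * log(2 * pi)),
               tolerance = 1e-9)
})

test_that("EM fits noiseless realizable data essentially exactly", {
  truth <- generate_tfa_dataset(L = 3, K = 8, N = 15, M = 100,
                                support_density = 0.4, noise_sd_P = 0,
                                noise_sd_E = 0, seed = 3)
  d <- truth_draft(truth)
  fit <- fit_tfa(d, Q = truth$Q, E = truth$E, lambda = 0, max_iter = 400,
                 tol = 0)
  Qz <- zrows(truth$Q[d$regulator_ids, ])
  Ez <- zrows(truth$E[d$target_ids, ])
  expect_lt(mean((Ez - fit$A %*% fit$P)^2), 1e-6)
  expect_lt(mean((fit$P - fit$B %*% Qz)^2), 1e-6)
  expect_lt(max(abs(Ez - fit$A %*% fit$P)), 1e-4)
})

test_that("EM recovers true strengths on noiseless data up to the per-TF scale", {
  # (A, B) are identified only up to a diagonal rescaling of the hidden
  # activities: A diag(c) and diag(1/c) B give the same likelihood, so the
  # recovery checks are the scale-invariant product A B and the per-TF
  # activity correlations.
  truth <- generate_tfa_dataset(L = 3, K = 8, N = 15, M = 100,
                                support_density = 0.4, noise_sd_P = 0,
                                noise_sd_E = 0, seed = 12)
  d <- truth_draft(truth)
  fit <- fit_tfa(d, Q = truth$Q, E = truth$E, lambda = 0, max_iter = 500,
                 tol = 0, standardize = FALSE)
  AB_true <- truth$A_true[d$target_ids, ] %*% truth$B_true[, d$regulator_ids]
  expect_lt(max(abs(fit$A %*% fit$B - AB_true)), 1e-4)
  for (l in 1:3)
    expect_gt(abs(cor(fit$P[l, ], truth$P_true[l, ])), 1 - 1e-6)
})

test_that("EM descends monotonically, preserves support and is deterministic", {
  truth <- generate_tfa_dataset(L = 4, K = 10, N = 20, M = 120,
                                support_density = 0.3, seed = 13)
  d <- truth_draft(truth)
  f1 <- suppressWarnings(fit_tfa(d, Q = truth$Q, E = truth$E, lambda = 5,
                                 max_iter = 40))
  f2 <- suppressWarnings(fit_tfa(d, Q = truth$Q, E = truth$E, lambda = 5,
                                 max_iter = 40))
  expect_identical(f1$A, f2$A)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_true(all(diff(f1$objective_trace) <= 1e-9))
  expect_true(all(f1$A[!d$A_support] == 0))
  expect_true(all(f1$B[!d$B_support] == 0))
})

test_that("the number of surviving coefficients is non-increasing in lambda", {
  truth <- generate_tfa_dataset(L = 4, K = 10, N = 20, M = 120,
                                support_density = 0.3, noise_sd_P = 0.2,
                                noise_sd_E = 0.2, seed = 6)
  d <- truth_draft(truth)
  nnz <- sapply(c(0, 5, 20, 60, 200), function(lam) {
    f <- suppressWarnings(fit_tfa(d, Q = truth$Q, E = truth$E, lambda = lam,
                                  max_iter = 30))
    sum(abs(f$A) > 1e-10) + sum(abs(f$B) > 1e-10)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("active triplets are exactly those with nonzero strengths on both legs", {
  truth <- generate_tfa_dataset(L = 4, K = 10, N = 20, M = 120,
                                support_density = 0.3, noise_sd_P = 0.2,
                                noise_sd_E = 0.2, seed = 14)
  d <- truth_draft(truth)
  # scan for a penalty that zeroes part of the support (prefer one that
  # keeps some triplets alive so both branches of the rule are exercised)
  f <- f_partial <- NULL
  for (lam in c(60, 70, 80, 90, 100, 110, 120, 150, 200, 300, 500)) {
    cand <- suppressWarnings(fit_tfa(d, Q = truth$Q, E = truth$E,
                                     lambda = lam, max_iter = 30))
    n_act <- nrow(select_active_triplets(cand))
    if (n_act < nrow(d$triplets)) {
      if (is.null(f)) f <- cand
      if (n_act > 0) { f_partial <- cand; break }
    }
  }
  if (!is.null(f_partial)) f <- f_partial
  expect_false(is.null(f))
  act <- select_active_triplets(f)
  expect_lt(nrow(act), nrow(d$triplets))
  manual <- purrr::pmap_lgl(d$triplets, function(modulator, tf, target, ...) {
    abs(f$B[tf, modulator]) > 1e-10 && abs(f$A[target, tf]) > 1e-10
  })
  expect_identical(nrow(act), sum(manual))
  expect_true(all(purrr::pmap_lgl(act, function(modulator, tf, target, ...) {
    abs(f$B[tf, modulator]) > 1e-10 && abs(f$A[target, tf]) > 1e-10
  })))
})

test_that("tidy and glance summarize a fitted model", {
  inst <- make_instance(seed = 15)
  f <- fit_tfa(inst$draft, Q = inst$truth$Q, E = inst$truth$E, lambda = 0,
               max_iter = 15)
  td <- tidy(f)
  expect_setequal(unique(td$edge_type), c("regulation", "modulation"))
  expect_identical(nrow(td),
                   sum(inst$draft$A_support) + sum(inst$draft$B_support))
  g <- glance(f)
  expect_identical(g$n_tfs, 3L)
  expect_equal(g$objective, tail(f$objective_trace, 1))
})
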