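#' Run the full inference pipeline
#'
#' Chains the stages simulate (or load) -> pair screening -> modulator
#' detection -> activity-model fit -> network assembly (optionally a rewiring
#' analysis), writing each stage's tab-delimited outputs and a JSON run
#' manifest into `out_dir`.  Every random stage consumes a seed derived
#' deterministically from the global seed and the stage order, so a rerun
#' with the same configuration reproduces identical files.
#'
#' @param config Either a YAML file path or a list.  Recognized entries:
#'   `out_dir`, `seed`, and per-stage lists `simulate` (passed to
#'   [generate_tfa_dataset()]), `pairs` (`p_cutoff`), `triplets` (`fraction`,
#'   `n_perm`, `p_cutoff`, `majority`), `fit` (`lambda`, `max_iter`, `tol`),
#'   and optional `rewire` (`gene_a`, `gene_b`, `modulator`, `n_bins`,
#'   `n_perm`).  Alternatively `expr`, `tfs` and `linkage` paths replace the
#'   simulate stage.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stage_seed <- function(i) (seed * 131L + i * 7919L) %% .Machine$integer.max

  # --- inputs: simulate, or load from paths -------------------------------
  if (!is.null(config$expr)) {
    if (!file.exists(config$expr))
      stop("expression file not found: ", config$expr, call. = FALSE)
    expr <- read_expression(config$expr)
    tf_ids <- readLines(config$tfs)
    linkage <- read_linkage(config$linkage)
    truth <- NULL
  } else {
    sim <- utils::modifyList(list(L = 5, K = 20, N = 60, M = 400,
                                  support_density = 0.2, noise_sd_P = 0.1,
                                  noise_sd_E = 0.1),
                             config$simulate %||% list())
    truth <- generate_tfa_dataset(sim$L, sim$K, sim$N, sim$M,
                                  sim$support_density, sim$noise_sd_P,
                                  sim$noise_sd_E, seed = stage_seed(1L))
    expr <- expression_matrix(truth$expr)
    tf_ids <- truth$tf_ids
    # candidate cofactors: every regulator is linked to every TF, so true
    # modulators and decoys alike enter the Step-2 screen
    linkage <- tidyr::expand_grid(gene_a = tf_ids,
                                  gene_b = truth$regulator_ids) |>
      dplyr::filter(.data$gene_a != .data$gene_b) |>
      dplyr::mutate(score = NA_real_)
    write_expression(expr, file.path(out_dir, "expression.tsv"))
    readr::write_tsv(linkage[c("gene_a", "gene_b")],
                     file.path(out_dir, "linkage.tsv"), col_names = FALSE)
    jsonlite::write_json(
      list(A_support = which(truth$A_true != 0, arr.ind = TRUE),
           B_support = which(truth$B_true != 0, arr.ind = TRUE),
           tf_ids = truth$tf_ids, regulator_ids = truth$regulator_ids,
           target_ids = truth$target_ids,
           noise_sd_P = truth$noise_sd_P, noise_sd_E = truth$noise_sd_E,
           seed = truth$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  }

  # --- Step 1: pair screening --------------------------------------------
  # the pipeline's candidate pools are small and signal-rich, so the Step-1
  # null uses the truncated-t empirical-null fit (see ?screen_pairs)
  pcfg <- utils::modifyList(list(p_cutoff = 1e-4, trim = 0.75),
                            config$pairs %||% list())
  screen <- screen_pairs(expr, tf_ids, target_ids = config$targets,
                         p_cutoff = pcfg$p_cutoff, trim = pcfg$trim)
  write_pairs(screen$pairs, file.path(out_dir, "pairs.tsv"))

  # --- Step 2: modulator detection ---------------------------------------
  tcfg <- utils::modifyList(list(fraction = 0.35, n_perm = 1000L,
                                 p_cutoff = 0.001, majority = 0.5),
                            config$triplets %||% list())
  triplets <- purrr::imap_dfr(split(screen$pairs$target, screen$pairs$tf),
    function(targets, tf) {
      call_modulators(expr, tf, targets,
                      cofactors = linkage_neighbors(linkage, tf),
                      fraction = tcfg$fraction, n_perm = tcfg$n_perm,
                      p_cutoff = tcfg$p_cutoff, majority = tcfg$majority,
                      seed = stage_seed(2L) + match(tf, tf_ids))
    })
  if (!nrow(triplets))
    triplets <- tibble::tibble(modulator = character(), tf = character(),
                               target = character(), mi_low = numeric(),
                               mi_high = numeric(), cmi = numeric(),
                               p_value = numeric())
  write_triplets(triplets, file.path(out_dir, "triplets.tsv"))
  write_network(screen$pairs, triplets, file.path(out_dir, "draft_network.tsv"))

  # --- Step 3: activity model --------------------------------------------
  # default penalty pilot-calibrated so roughly half the draft support
  # survives on the synthetic preset (see the methods vignette)
  fcfg <- utils::modifyList(list(lambda = 250, max_iter = 100L, tol = 1e-6),
                            config$fit %||% list())
  draft <- draft_network(screen$pairs, triplets, tf_ids = tf_ids)
  model <- fit_tfa(draft, expr = expr, lambda = fcfg$lambda,
                   max_iter = fcfg$max_iter, tol = fcfg$tol)
  write_expression(model$P, file.path(out_dir, "activities.tsv"))
  tidy(model) |>
    dplyr::filter(abs(.data$estimate) > 1e-10) |>
    readr::write_tsv(file.path(out_dir, "strengths.tsv"))
  active <- select_active_triplets(model)
  if (nrow(active)) write_triplets(active, file.path(out_dir, "active_triplets.tsv"))

  # --- network assembly ---------------------------------------------------
  net <- assemble_three_layer(screen$pairs, active)
  readr::write_tsv(net$nodes, file.path(out_dir, "network_nodes.tsv"))
  readr::write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
  readr::write_tsv(degree_summary(net), file.path(out_dir, "degrees.tsv"))
  readr::write_tsv(node_betweenness(net), file.path(out_dir, "betweenness.tsv"))

  # --- optional rewiring --------------------------------------------------
  rewiring <- NULL
  if (!is.null(config$rewire)) {
    r <- config$rewire
    rewiring <- rewiring_analysis(expr, r$gene_a, r$gene_b, r$modulator,
                                  n_bins = r$n_bins %||% 10L,
                                  n_perm = r$n_perm %||% 10000L,
                                  seed = stage_seed(5L))
    readr::write_tsv(tidy(rewiring), file.path(out_dir, "rewiring_bins.tsv"))
    readr::write_tsv(glance(rewiring), file.path(out_dir, "rewiring.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tfanet")),
    seed = seed,
    parameters = list(pairs = pcfg, triplets = tcfg, fit = fcfg),
    n_pairs = nrow(screen$pairs), n_triplets = nrow(triplets),
    n_active_triplets = nrow(active),
    files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(truth = truth, expr = expr, screen = screen,
                 triplets = triplets, draft = draft, model = model,
                 active_triplets = active, network = net,
                 rewiring = rewiring, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
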