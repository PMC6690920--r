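#' Assemble the three-layer activity network
#'
#' Builds the modulators -> TFs -> targets graph: regulation edges (tf ->
#' target) from the Step-1 pairs and modulation edges (modulator -> tf) from
#' the (active) triplets.  A gene may hold several roles.  Duplicate
#' (source, target, type) edges are collapsed.
#'
#' @param pairs Tibble with columns `tf`, `target` (optionally `mi`).
#' @param triplets Tibble with columns `modulator`, `tf` (optionally `cmi`);
#'   may have zero rows.
#' @return Object of class `tfa_network`: tibbles `nodes` (id, roles) and
#'   `edges` (source, target, edge_type, weight) plus the igraph object.
#' @export
assemble_three_layer <- function(pairs, triplets = NULL) {
  if (is.null(triplets))
    triplets <- tibble::tibble(modulator = character(), tf = character())
  reg <- tibble::tibble(source = as.character(pairs$tf),
                        target = as.character(pairs$target),
                        edge_type = "regulation",
                        weight = if ("mi" %in% names(pairs)) pairs$mi else NA_real_)
  mod <- tibble::tibble(source = as.character(triplets$modulator),
                        target = as.character(triplets$tf),
                        edge_type = "modulation",
                        weight = if ("cmi" %in% names(triplets)) triplets$cmi else NA_real_)
  edges <- dplyr::distinct(dplyr::bind_rows(mod, reg),
                           .data$source, .data$target, .data$edge_type,
                           .keep_all = TRUE)
  roles <- dplyr::bind_rows(
    tibble::tibble(id = unique(c(pairs$tf, triplets$tf)), role = "tf"),
    tibble::tibble(id = unique(as.character(pairs$target)), role = "target"),
    tibble::tibble(id = unique(as.character(triplets$modulator)), role = "modulator"))
  nodes <- roles |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(roles = paste(sort(unique(.data$role)), collapse = ";"),
                     .groups = "drop")
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target", "edge_type", "weight")],
    directed = TRUE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "tfa_network")
}

#' @export
print.tfa_network <- function(x, ...) {
  counts <- table(x$edges$edge_type)
  has_role <- function(r) sum(grepl(r, x$nodes$roles, fixed = TRUE))
  cat("three-layer network:", nrow(x$nodes), "nodes (",
      has_role("modulator"), "modulators,", has_role("tf"), "TFs,",
      has_role("target"), "targets );",
      sum(x$edges$edge_type == "modulation"), "modulation and",
      sum(x$edges$edge_type == "regulation"), "regulation edges\n")
  invisible(counts)
}

#' @exportS3Method generics::tidy
tidy.tfa_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.tfa_network <- function(x, ...) {
  has_role <- function(r) sum(grepl(r, x$nodes$roles, fixed = TRUE))
  tibble::tibble(n_nodes = nrow(x$nodes),
                 n_modulators = has_role("modulator"),
                 n_tfs = has_role("tf"),
                 n_targets = has_role("target"),
                 n_modulation_edges = sum(x$edges$edge_type == "modulation"),
                 n_regulation_edges = sum(x$edges$edge_type == "regulation"))
}

#' Shortest-path node betweenness
#'
#' Unnormalized betweenness (number of shortest paths through each node, with
#' the usual fractional credit for tied shortest paths).  Edges are treated as
#' directed by default, matching the modulation/regulation edge semantics;
#' `restrict_to_tfs` first takes the induced subgraph on TF-role nodes, the
#' "core" network of the hub analysis.
#'
#' @param net A `tfa_network` or an igraph object.
#' @param restrict_to_tfs Restrict to TF-role nodes first (default FALSE).
#' @param directed Treat edges as directed (default TRUE).
#' @return Tibble (node, betweenness), sorted decreasing.
#' @export
node_betweenness <- function(net, restrict_to_tfs = FALSE, directed = TRUE) {
  if (inherits(net, "tfa_network")) {
    g <- net$graph
    if (restrict_to_tfs) {
      tfs <- net$nodes$id[grepl("tf", net$nodes$roles, fixed = TRUE)]
      g <- igraph::induced_subgraph(g, tfs)
    }
  } else {
    g <- net
  }
  if (igraph::vcount(g) == 0L)
    return(tibble::tibble(node = character(), betweenness = numeric()))
  b <- igraph::betweenness(g, directed = directed, weights = NA)
  tibble::tibble(node = names(b), betweenness = unname(b)) |>
    dplyr::arrange(dplyr::desc(.data$betweenness))
}

#' Per-node degrees split by edge type
#'
#' @param net A `tfa_network`.
#' @return Tibble (node, edge_type, in_degree, out_degree), with zero rows
#'   filled in for every node x type combination.
#' @export
degree_summary <- function(net) {
  edges <- net$edges
  outd <- edges |> dplyr::count(node = .data$source, .data$edge_type,
                                name = "out_degree")
  ind <- edges |> dplyr::count(node = .data$target, .data$edge_type,
                               name = "in_degree")
  tidyr::expand_grid(node = net$nodes$id,
                     edge_type = c("modulation", "regulation")) |>
    dplyr::left_join(outd, by = c("node", "edge_type")) |>
    dplyr::left_join(ind, by = c("node", "edge_type")) |>
    dplyr::mutate(in_degree = dplyr::coalesce(.data$in_degree, 0L),
                  out_degree = dplyr::coalesce(.data$out_degree, 0L))
}

#' Bootstrap test of activity-based vs mRNA-based mutual information
#'
#' Computes the target's MI with the TF's mRNA and with its estimated
#' activity, then bootstrap-resamples the samples (jointly for all three
#' vectors) `n_boot` times and reports the add-one fraction of replicates in
#' which the activity MI fails to beat the mRNA MI — a one-sided p-value for
#' the improvement.  Exact ties (e.g. when the activity simply equals the
#' mRNA) count half, so an exchangeable comparison is centred at 0.5 rather
#' than degenerating to 1.
#'
#' @param tf_mrna,tfa,target Aligned numeric vectors.
#' @param n_boot Bootstrap replicates (>= 1; default 1000).
#' @param seed Integer seed.
#' @return Tibble: `mi_mrna`, `mi_tfa`, `improvement`, `p_value`.
#' @export
mi_improvement_test <- function(tf_mrna, tfa, target, n_boot = 1000L,
                                seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (length(unique(c(length(tf_mrna), length(tfa), length(target)))) != 1L)
    stop("vectors must be aligned", call. = FALSE)
  n <- length(target)
  mi_mrna <- kernel_mi(tf_mrna, target)
  mi_tfa <- kernel_mi(tfa, target)
  set.seed(seed)
  worse <- 0
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    bm <- .kernel_mi_cpp(tf_mrna[idx], target[idx])
    bt <- .kernel_mi_cpp(tfa[idx], target[idx])
    worse <- worse + if (bt < bm) 1 else if (bt == bm) 0.5 else 0
  }
  tibble::tibble(mi_mrna = mi_mrna, mi_tfa = mi_tfa,
                 improvement = mi_tfa - mi_mrna,
                 p_value = (1 + worse) / (1 + n_boot))
}

#' Context-specific rewiring of a gene pair along a modulator
#'
#' Sorts the samples by the modulator's expression, splits them into
#' `n_bins` equal-size groups (remainder to the last bin), computes the
#' Pearson correlation of the pair in each bin, labels the bins "low"/"high"
#' by 1-D 2-means with deterministic extremes initialization, and tests the
#' modulator dependence with the conditional-MI statistic (35% tails) against
#' `n_perm` modulator permutations (one-sided gain, add-one p-value).
#'
#' @param expr Genes-by-samples expression matrix.
#' @param gene_a,gene_b The gene pair.
#' @param modulator The conditioning gene.
#' @param n_bins Number of expression bins (default 10).
#' @param n_perm Permutations (default 10000).
#' @param fraction Tail fraction for the CMI statistic (default 0.35).
#' @param seed Integer seed.
#' @return Object of class `rewiring_result`: tibble `bins` (bin, pcc,
#'   category) plus `cmi`, `p_value` and the identifiers.
#' @export
rewiring_analysis <- function(expr, gene_a, gene_b, modulator, n_bins = 10L,
                              n_perm = 10000L, fraction = 0.35, seed = 1L) {
  expr <- expression_matrix(expr)
  ids <- c(gene_a, gene_b, modulator)
  miss <- setdiff(ids, rownames(expr))
  if (length(miss)) stop("genes absent from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  a <- expr[gene_a, ]; b <- expr[gene_b, ]; m <- expr[modulator, ]
  if (sd(m) == 0) stop("constant modulator", call. = FALSE)
  M <- length(m)
  ord <- order(m, seq_len(M))
  base <- floor(M / n_bins)
  sizes <- rep(base, n_bins)
  sizes[n_bins] <- sizes[n_bins] + (M - base * n_bins) # remainder to last bin
  bin_of <- rep(seq_len(n_bins), times = sizes)
  pcc <- vapply(seq_len(n_bins), function(k) {
    idx <- ord[bin_of == k]
    if (sd(a[idx]) == 0 || sd(b[idx]) == 0) {
      warning("bin ", k, " has constant gene values; PCC recorded as 0")
      return(0)
    }
    cor(a[idx], b[idx])
  }, numeric(1L))
  category <- kmeans_low_high(pcc)

  cm <- conditional_mi(a, b, m, fraction)
  set.seed(seed)
  sp <- perm_splits(m, n_perm, fraction)
  perm_cmi <- .cmi_splits_cpp(as.numeric(a), as.numeric(b),
                              sp$low, sp$high)[, 3L]
  p <- (1 + sum(perm_cmi >= cm$cmi)) / (1 + n_perm)

  structure(list(gene_a = gene_a, gene_b = gene_b, modulator = modulator,
                 bins = tibble::tibble(bin = seq_len(n_bins), pcc = pcc,
                                       category = category),
                 mi_low = cm$mi_low, mi_high = cm$mi_high, cmi = cm$cmi,
                 p_value = p, n_perm = n_perm),
            class = "rewiring_result")
}

# Deterministic 1-D 2-means: centroids initialized at the min and max,
# Lloyd iterations; ties go to the nearer centroid then the lower label.
# "high" is the cluster with the larger mean.
kmeans_low_high <- function(x) {
  if (max(x) == min(x)) return(rep("low", length(x)))
  c_lo <- min(x); c_hi <- max(x)
  lab <- NULL
  for (it in 1:100) {
    new_lab <- ifelse(abs(x - c_hi) < abs(x - c_lo), "high", "low")
    if (identical(new_lab, lab)) break
    lab <- new_lab
    if (any(lab == "low")) c_lo <- mean(x[lab == "low"])
    if (any(lab == "high")) c_hi <- mean(x[lab == "high"])
  }
  lab
}

#' @export
print.rewiring_result <- function(x, ...) {
  cat(sprintf("rewiring of (%s, %s) along %s: CMI = %.4f (MI high %.4f, low %.4f), p = %.4g [%d perms]\n",
              x$gene_a, x$gene_b, x$modulator, x$cmi, x$mi_high, x$mi_low,
              x$p_value, x$n_perm))
  cat("bin categories:", paste(x$bins$category, collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rewiring_result <- function(x, ...) x$bins

#' @exportS3Method generics::glance
glance.rewiring_result <- function(x, ...) {
  tibble::tibble(gene_a = x$gene_a, gene_b = x$gene_b,
                 modulator = x$modulator, mi_low = x$mi_low,
                 mi_high = x$mi_high, cmi = x$cmi, p_value = x$p_value,
                 n_high_bins = sum(x$bins$category == "high"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rewiring_result <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = factor(.data$bin), y = .data$pcc,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(low = "steelblue", high = "darkorange")) +
    ggplot2::labs(x = sprintf("%s expression bin (low to high)", object$modulator),
                  y = sprintf("PCC(%s, %s)", object$gene_a, object$gene_b),
                  title = sprintf("Rewiring along %s: CMI = %.3f, p = %.3g",
                                  object$modulator, object$cmi, object$p_value))
}
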