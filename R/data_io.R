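#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is an ordinary numeric matrix whose rownames are gene
#' IDs and colnames are sample IDs.  IDs must be unique and every value must
#' be finite.  All downstream functions index this matrix by ID, never by
#' position.
#'
#' @param values Numeric matrix with rownames (genes) and colnames (samples).
#' @return The validated matrix, invisibly classed for printing.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  g <- rownames(values)
  s <- colnames(values)
  if (is.null(g) || is.null(s))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  dup_g <- g[duplicated(g)]
  if (length(dup_g))
    stop("duplicate gene ID(s): ", paste(unique(dup_g), collapse = ", "), call. = FALSE)
  dup_s <- s[duplicated(s)]
  if (length(dup_s))
    stop("duplicate sample ID(s): ", paste(unique(dup_s), collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  values
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample IDs, gene IDs in the first column, and a
#' strictly numeric body (no missing cells, no placeholder "." entries).
#' Row and column order are preserved as read.
#'
#' @param path Path to a TSV file.
#' @return A genes-by-samples numeric matrix with ID dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  ncol_expect <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_expect)) {
    bad <- which(widths != ncol_expect)[1L]
    stop("ragged row at line ", bad + 1L, ": expected ", ncol_expect,
         " fields, found ", widths[bad], call. = FALSE)
  }
  genes <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    row_chr <- body[[i]][-1L]
    row_num <- suppressWarnings(as.numeric(row_chr))
    bad <- which(is.na(row_num) | row_chr == "" | row_chr == ".")
    if (length(bad))
      stop("non-numeric cell at line ", i + 1L, ", column ", bad[1L] + 1L,
           " (gene ", genes[i], ", sample ", samples[bad[1L]], "): '",
           row_chr[bad[1L]], "'", call. = FALSE)
    vals[i, ] <- row_num
  }
  expression_matrix(vals)
}

#' Write an expression matrix as TSV
#'
#' @param expr Genes-by-samples numeric matrix with ID dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- expression_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes mapping to more than one gene are removed outright.  When several
#' probes map to one gene, each sample gets the maximum expression value over
#' that gene's probes.  Probes absent from the map are dropped.
#'
#' @param probe_matrix Probes-by-samples matrix (probe IDs as rownames).
#' @param probe_map Data frame with columns `probe` and `gene`; a probe may
#'   appear on several rows (multimap).
#' @return Genes-by-samples matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  probe_matrix <- expression_matrix(probe_matrix)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  probe_map <- dplyr::distinct(tibble::as_tibble(probe_map[c("probe", "gene")]))
  missing <- setdiff(probe_map$probe, rownames(probe_matrix))
  if (length(missing))
    stop("probe_map references probes absent from the matrix: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  multi <- probe_map |>
    dplyr::count(.data$probe) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull("probe")
  keep <- dplyr::filter(probe_map, !.data$probe %in% multi)
  if (nrow(keep) == 0L)
    stop("no probes left after removing multi-gene probes", call. = FALSE)
  genes <- unique(keep$gene)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  probes_by_gene <- split(keep$probe, keep$gene)
  for (g in genes) {
    rows <- probe_matrix[probes_by_gene[[g]], , drop = FALSE]
    out[g, ] <- apply(rows, 2L, max)
  }
  expression_matrix(out)
}

#' Read a functional-linkage edge list
#'
#' Two or three tab-separated columns per line: gene_a, gene_b, optional
#' numeric score.  Edges are undirected: each unordered pair is stored once,
#' self-loops are dropped (a message reports how many).
#'
#' @param path Path to the edge-list file.
#' @return Tibble with columns `gene_a`, `gene_b` (sorted within row) and
#'   `score` (NA when absent).
#' @export
read_linkage <- function(path) {
  if (!file.exists(path)) stop("linkage file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          score = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  bad <- which(widths < 2L | widths > 3L)
  if (length(bad))
    stop("malformed linkage line ", bad[1L], ": expected 2-3 fields, found ",
         widths[bad[1L]], call. = FALSE)
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  score <- vapply(fields, function(f) {
    if (length(f) < 3L) return(NA_real_)
    v <- suppressWarnings(as.numeric(f[[3L]]))
    if (is.na(v)) stop("non-numeric linkage score: '", f[[3L]], "'", call. = FALSE)
    v
  }, numeric(1L))
  self <- a == b
  if (any(self)) message("dropped ", sum(self), " self-loop(s) from linkage file")
  tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b), score = score) |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
}

#' Linkage neighbours of a gene
#'
#' @param linkage Tibble from [read_linkage()] (or with the same columns).
#' @param gene Gene ID.
#' @return Character vector of neighbouring gene IDs.
#' @export
linkage_neighbors <- function(linkage, gene) {
  unique(c(linkage$gene_b[linkage$gene_a == gene],
           linkage$gene_a[linkage$gene_b == gene]))
}

#' Write / read Step-1 pair and Step-2 triplet tables
#'
#' Pairs are written with columns (tf, target, mi, p_value); triplets with
#' (modulator, tf, target, mi_low, mi_high, cmi, p_value).  Zero rows yield a
#' header-only file.  `write_network()` additionally writes a single merged
#' edge list with an `edge_type` column (`regulation` / `modulation`) for
#' graph-viewer import.
#'
#' @param pairs Tibble of TF-target pairs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("tf", "target", "mi", "p_value")
  stopifnot(all(cols %in% names(pairs)))
  readr::write_tsv(pairs[cols], path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(tf = "c", target = "c",
                                          mi = "d", p_value = "d"))
}

#' @rdname write_pairs
#' @param triplets Tibble of modulator-TF-target triplets.
#' @export
write_triplets <- function(triplets, path) {
  cols <- c("modulator", "tf", "target", "mi_low", "mi_high", "cmi", "p_value")
  stopifnot(all(cols %in% names(triplets)))
  readr::write_tsv(triplets[cols], path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_triplets <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(modulator = "c", tf = "c",
                                          target = "c", mi_low = "d",
                                          mi_high = "d", cmi = "d",
                                          p_value = "d"))
}

#' @rdname write_pairs
#' @export
write_network <- function(pairs, triplets, path) {
  reg <- tibble::tibble(source = as.character(pairs$tf),
                        target = as.character(pairs$target),
                        edge_type = "regulation",
                        weight = pairs$mi)
  mod <- tibble::tibble(source = as.character(triplets$modulator),
                        target = as.character(triplets$tf),
                        edge_type = "modulation",
                        weight = triplets$cmi)
  merged <- dplyr::distinct(dplyr::bind_rows(reg, mod),
                            .data$source, .data$target, .data$edge_type,
                            .keep_all = TRUE)
  readr::write_tsv(merged, path)
  invisible(path)
}
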