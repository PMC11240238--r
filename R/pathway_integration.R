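# Cross-omics pathway integration: aggregate each layer's features to
# shared KO/EC function ids, compute fold-change-normalized log2 ratios of
# group mean abundance per id, and assemble pathway split-node tables
# (one column per omics layer) plus heatmap exports.

#' Aggregate a feature matrix to KO/EC function ids
#'
#' Feature counts are scatter-added into every KO and EC id the feature is
#' annotated with (a feature carrying k ids contributes its full abundance
#' to each — the KEGG-mapper convention; set `split_weights = TRUE` to
#' divide it equally instead). Unannotated features are dropped and
#' tallied.
#'
#' @param m an [abundance_matrix()] whose annotations carry `ko` and/or
#'   `ec` list columns.
#' @param split_weights divide a feature's abundance over its ids instead
#'   of full multi-assignment.
#' @return An [abundance_matrix()] keyed by function id, with attributes
#'   `n_features` (supporting-feature count per id) and `n_unannotated`.
#' @export
aggregate_to_function <- function(m, split_weights = FALSE) {
  ann <- m$annotations
  if (is.null(ann) || !any(c("ko", "ec") %in% colnames(ann)))
    mox_stop("matrix has no ko/ec annotations", "metaomix_value_error")
  ids_per_feature <- lapply(rownames(m$values), function(f) {
    ids <- character(0)
    if ("ko" %in% colnames(ann)) ids <- c(ids, ann[f, "ko"][[1]])
    if ("ec" %in% colnames(ann)) ids <- c(ids, ann[f, "ec"][[1]])
    unique(ids)
  })
  k <- lengths(ids_per_feature)
  if (all(k == 0))
    mox_stop("no annotated features to aggregate", "metaomix_value_error")
  rows <- rep(seq_len(nrow(m$values)), k)
  ids <- unlist(ids_per_feature, use.names = FALSE)
  w <- if (split_weights) 1 / k[rows] else rep(1, length(rows))
  agg <- rowsum(m$values[rows, , drop = FALSE] * w, group = ids, reorder = TRUE)
  out <- abundance_matrix(agg, layer = m$layer)
  attr(out, "n_features") <- vapply(split(rows, ids), function(r)
    length(unique(r)), integer(1))[rownames(agg)]
  attr(out, "n_unannotated") <- sum(k == 0)
  out
}

#' Per-layer log2 ratios of group mean abundance
#'
#' The function-level matrix is total-sum scaled per sample (so ratios are
#' library-size invariant), then for each id
#' `log2((mean over groupB + eps) / (mean over groupA + eps))`. The
#' pseudocount `eps` defaults to half the smallest nonzero normalized
#' value in the layer, guaranteeing finite ratios.
#'
#' @param m_fn function-keyed [abundance_matrix()] (from
#'   [aggregate_to_function()]).
#' @param meta a [sample_metadata()]; groups are levels of its phenotype.
#' @param groupA,groupB phenotype levels (ratio is B vs A).
#' @param pseudocount numeric eps, or NULL for the half-min default.
#' @return A `layer_ratios` object: data.frame `ratios` (id, log2_ratio,
#'   n_features) plus layer and group labels.
#' @export
layer_log2_ratio <- function(m_fn, meta, groupA, groupB, pseudocount = NULL) {
  groups <- as.character(meta$data[colnames(m_fn$values), meta$phenotype])
  for (g in c(groupA, groupB)) if (!g %in% groups)
    mox_stop(sprintf("no samples in group '%s'", g), "metaomix_value_error")
  x <- sweep(m_fn$values, 2, colSums(m_fn$values), "/")
  eps <- pseudocount
  if (is.null(eps)) {
    nz <- x[x > 0]
    eps <- if (length(nz)) min(nz) / 2 else 1e-6
  }
  mA <- rowMeans(x[, groups == groupA, drop = FALSE])
  mB <- rowMeans(x[, groups == groupB, drop = FALSE])
  nf <- attr(m_fn, "n_features")
  ratios <- data.frame(
    id = rownames(x),
    log2_ratio = log2((mB + eps) / (mA + eps)),
    n_features = if (is.null(nf)) NA_integer_ else unname(nf[rownames(x)]),
    row.names = rownames(x), stringsAsFactors = FALSE)
  structure(list(ratios = ratios, layer = m_fn$layer,
                 groupA = groupA, groupB = groupB, pseudocount = eps),
            class = "layer_ratios")
}

#' Assemble a pathway split-node table across omics layers
#'
#' For each pathway node and each layer, the cell is `combine` applied to
#' the ratios of the node's KO/EC ids that have a ratio in that layer
#' (default mean; `"max_abs"` keeps the single largest-magnitude ratio).
#' A cell is NA exactly when none of the node's ids is present in the
#' layer.
#'
#' @param pathway a [pathway_definition()].
#' @param layers list of [layer_log2_ratio()] results (named or labeled by
#'   their `layer` field).
#' @param combine `"mean"` or `"max_abs"`.
#' @return A `split_node_table`: `values` (node x layer matrix of log2
#'   ratios), node labels, matched ids per cell, and the pathway id.
#' @export
assemble_split_nodes <- function(pathway, layers, combine = c("mean", "max_abs")) {
  combine <- match.arg(combine)
  stopifnot(inherits(pathway, "pathway_definition"))
  if (length(layers) == 0)
    mox_stop("need at least one layer", "metaomix_value_error")
  if (nrow(pathway$nodes) == 0)
    mox_stop("empty pathway", "metaomix_value_error")
  layer_names <- vapply(seq_along(layers), function(i) {
    nm <- names(layers)[i]
    if (!is.null(nm) && nzchar(nm)) nm else layers[[i]]$layer
  }, character(1))
  nodes <- pathway$nodes$node
  vals <- matrix(NA_real_, nrow = length(nodes), ncol = length(layers),
                 dimnames = list(nodes, layer_names))
  matched <- vector("list", length(nodes) * length(layers))
  dim(matched) <- c(length(nodes), length(layers))
  dimnames(matched) <- dimnames(vals)
  for (i in seq_along(nodes)) {
    node_ids <- unique(c(pathway$nodes$ko[[i]], pathway$nodes$ec[[i]]))
    for (j in seq_along(layers)) {
      rt <- layers[[j]]$ratios
      hit <- node_ids[node_ids %in% rt$id]
      matched[[i, j]] <- hit
      if (length(hit)) {
        r <- rt[hit, "log2_ratio"]
        vals[i, j] <- if (combine == "mean") mean(r) else r[which.max(abs(r))]
      }
    }
  }
  structure(list(pathway_id = pathway$pathway_id, values = vals,
                 labels = stats::setNames(pathway$nodes$label, nodes),
                 matched = matched, combine = combine),
            class = "split_node_table")
}

#' @export
print.split_node_table <- function(x, ...) {
  cat(sprintf("<split_node_table> pathway %s: %d nodes x %d layers\n",
              x$pathway_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Export a split-node table as heatmap figure + TSV
#'
#' The figure is a node x layer heatmap on a diverging palette centered at
#' 0, red = up in group B, green = down (matching the KEGG-map coloring
#' convention). The TSV companion stores the exact values (full precision,
#' round-trippable with [read_split_node_tsv()]).
#'
#' @param table a [assemble_split_nodes()] result.
#' @param prefix output prefix: writes `<prefix>.tsv` and `<prefix>.pdf`.
#' @return `prefix`, invisibly.
#' @export
export_split_heatmap <- function(table, prefix) {
  vals <- table$values
  df <- data.frame(node = rownames(vals),
                   label = unname(table$labels[rownames(vals)]),
                   stringsAsFactors = FALSE)
  for (j in colnames(vals)) df[[j]] <- format_full(vals[, j])
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long <- data.frame(
    node = factor(rep(rownames(vals), ncol(vals)), levels = rev(rownames(vals))),
    layer = rep(colnames(vals), each = nrow(vals)),
    log2_ratio = as.vector(vals))
  lim <- max(abs(vals), 1e-9, na.rm = TRUE)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = layer, y = node,
                                          fill = log2_ratio)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_gradient2(low = "#1a9850", mid = "grey95",
                                  high = "#d73027", midpoint = 0,
                                  limits = c(-lim, lim), na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 ratio",
                  title = table$pathway_id) +
    ggplot2::theme_minimal()
  grDevices::pdf(paste0(prefix, ".pdf"), width = 5, height = 6)
  print(p)
  grDevices::dev.off()
  invisible(prefix)
}

#' Read back a split-node TSV companion
#' @param path TSV written by [export_split_heatmap()].
#' @return node x layer numeric matrix.
#' @export
read_split_node_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(colnames(df), c("node", "label")), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$node
  vals
}
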