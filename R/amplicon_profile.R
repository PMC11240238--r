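# Amplicon-profile stage: aggregate ASV counts to a taxonomic rank, rank
# taxa by abundance and produce top-n selections and stacked-barplot data.

#' Aggregate an ASV count table to a taxonomic rank
#'
#' Each ASV's counts are credited to the ancestor of its assigned taxon at
#' the requested rank. ASVs whose lineage lacks that rank are pooled into a
#' feature named `"Unclassified"`. Per-sample totals are conserved exactly.
#'
#' @param asv an [abundance_matrix()] whose annotations carry a `taxon`
#'   column mapping each ASV to a taxonomy node.
#' @param tax a [taxonomy_tree()].
#' @param rank target rank (e.g. `"genus"`).
#' @return An [abundance_matrix()] whose features are taxon names at `rank`;
#'   annotations keep the taxonomy node id per feature.
#' @export
aggregate_to_rank <- function(asv, tax, rank) {
  stopifnot(inherits(asv, "abundance_matrix"), inherits(tax, "taxonomy_tree"))
  if (is.null(asv$annotations) || !"taxon" %in% colnames(asv$annotations))
    mox_stop("ASV matrix needs a 'taxon' annotation column", "metaomix_value_error")
  taxa <- asv$annotations[rownames(asv$values), "taxon"]
  unknown <- rownames(asv$values)[!taxa %in% tax$nodes$id]
  if (length(unknown))
    mox_stop(sprintf("ASV(s) mapped to unknown taxonomy node: %s",
                     join_semicolon(unknown)), "metaomix_value_error")
  anc <- vapply(taxa, function(t) tax_ancestor_at_rank(tax, t, rank), character(1))
  label <- ifelse(is.na(anc), "Unclassified", tax$nodes[anc, "name"])
  node <- ifelse(is.na(anc), NA_character_, anc)
  agg <- rowsum(asv$values, group = label, reorder = TRUE)
  ann <- data.frame(taxon = tapply(node, label, function(x) x[1])[rownames(agg)],
                    row.names = rownames(agg), stringsAsFactors = FALSE)
  abundance_matrix(agg, layer = asv$layer, annotations = ann)
}

#' Convert counts to per-sample relative abundances (total-sum scaling)
#'
#' @param m an [abundance_matrix()].
#' @return The same matrix with every column summing to 1.
#' @export
relative_abundance <- function(m) {
  totals <- colSums(m$values)
  zero <- colnames(m$values)[totals == 0]
  if (length(zero))
    mox_stop(sprintf("sample(s) with zero total: %s", join_semicolon(zero)),
             "metaomix_value_error")
  abundance_matrix(sweep(m$values, 2, totals, "/"), layer = m$layer,
                   annotations = m$annotations)
}

#' Rank taxa by abundance and select the top n
#'
#' Taxa are scored either by the mean of per-sample relative abundances
#' (default; robust to library-size differences) or by total raw counts.
#' Ties are broken lexicographically by taxon name for determinism. The
#' `"Unclassified"` pool never enters the ranking.
#'
#' @param m an [abundance_matrix()] of counts at the target rank.
#' @param n number of taxa to select (>= 1).
#' @param rank_by scoring rule: `"mean_relative"` or `"total_count"`.
#' @return A `ranked_taxa` object: data.frame `entries` (taxon, abundance,
#'   descending), selection size `n`, and the scoring rule used.
#' @export
rank_taxa <- function(m, n, rank_by = c("mean_relative", "total_count")) {
  rank_by <- match.arg(rank_by)
  stopifnot(n >= 1)
  keep <- setdiff(rownames(m$values), "Unclassified")
  if (length(keep) == 0)
    mox_stop("no classified taxa to rank", "metaomix_value_error")
  score <- if (rank_by == "mean_relative") {
    rowMeans(relative_abundance(m)$values[keep, , drop = FALSE])
  } else {
    tot <- rowSums(m$values[keep, , drop = FALSE])
    tot / sum(m$values)   # report on a relative scale for comparability
  }
  ord <- order(-score, names(score))
  if (n > length(keep)) {
    warning(sprintf("n = %d exceeds the %d available taxa; returning all",
                    n, length(keep)))
    n <- length(keep)
  }
  entries <- data.frame(taxon = names(score)[ord][seq_len(n)],
                        abundance = unname(score[ord][seq_len(n)]),
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, n = n, rank_by = rank_by),
            class = "ranked_taxa")
}

#' @export
print.ranked_taxa <- function(x, ...) {
  cat(sprintf("<ranked_taxa> top %d by %s\n", x$n, x$rank_by))
  print(utils::head(x$entries, 10))
  invisible(x)
}

#' Long-format composition data for stacked barplots
#'
#' Relative abundances per sample for the top-n taxa, with everything else
#' (including the Unclassified pool) summed into `"Other"`. Per-sample
#' values sum to 1.
#'
#' @param m an [abundance_matrix()] of counts at the target rank.
#' @param n number of taxa to keep un-pooled.
#' @return data.frame with columns `sample`, `taxon`, `abundance`.
#' @export
composition_plot_data <- function(m, n) {
  rel <- relative_abundance(m)$values
  top <- rank_taxa(m, n)$entries$taxon
  rest <- setdiff(rownames(rel), top)
  rows <- rel[top, , drop = FALSE]
  if (length(rest)) {
    other <- colSums(rel[rest, , drop = FALSE])
    rows <- rbind(rows, Other = other)
  }
  out <- data.frame(
    sample = rep(colnames(rows), each = nrow(rows)),
    taxon = rep(rownames(rows), times = ncol(rows)),
    abundance = as.vector(rows),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Stacked-bar composition plot
#' @param plot_data output of [composition_plot_data()].
#' @return A ggplot object.
#' @export
plot_composition <- function(plot_data) {
  ggplot2::ggplot(plot_data,
                  ggplot2::aes(x = sample, y = abundance,
                               fill = taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
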