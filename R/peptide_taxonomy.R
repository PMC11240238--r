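# Peptide-level taxonomy: in-silico tryptic digestion of the constructed
# database, a peptide -> provenance index, lowest-common-ancestor (LCA)
# assignment, and per-sample peptide/taxon abundance tables.
#
# Assignment runs against the database the pipeline itself constructed, so
# peptide taxonomy is self-consistent with the metaproteomics search space
# (database content drives metaproteomics outcomes).

#' Digestion parameters
#'
#' Trypsin cleaves C-terminal of K or R except when the next residue is P.
#' Defaults (2 missed cleavages, length 7-45, I/L equated) reflect common
#' mass-spectrometry practice; I and L are isobaric and indistinguishable
#' by mass, hence the default collapse.
#'
#' @param missed_cleavages maximum internal cleavage sites per peptide.
#' @param min_len,max_len peptide length bounds (residues).
#' @param equate_il collapse I and L when indexing peptides.
#' @return A `digest_params` object.
#' @export
digest_params <- function(missed_cleavages = 2L, min_len = 7L, max_len = 45L,
                          equate_il = TRUE) {
  stopifnot(missed_cleavages >= 0, min_len >= 1, min_len <= max_len)
  structure(list(missed_cleavages = as.integer(missed_cleavages),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 equate_il = isTRUE(equate_il)),
            class = "digest_params")
}

#' Tryptic digest of one protein sequence
#'
#' Products are emitted in position order and, within a start position, by
#' increasing number of missed cleavages; duplicates are retained.
#'
#' @param sequence amino-acid string.
#' @param params a [digest_params()].
#' @return Character vector of peptides (possibly empty).
#' @export
digest <- function(sequence, params = digest_params()) {
  sequence <- toupper(sequence)
  if (!is_valid_sequence(sequence))
    mox_stop("invalid amino-acid sequence", "metaomix_value_error")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # cleavage after position i: K/R at i, and residue i+1 is not P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)            # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nfrag <- length(starts)
  out <- character(0)
  for (i in seq_len(nfrag)) {
    for (k in 0:params$missed_cleavages) {
      j <- i + k
      if (j > nfrag) break
      len <- ends[j] - starts[i] + 1L
      if (len >= params$min_len && len <= params$max_len)
        out <- c(out, substr(sequence, starts[i], ends[j]))
    }
  }
  out
}

#' Collapse I/L in peptide keys
#' @noRd
il_collapse <- function(x, params) {
  if (params$equate_il) gsub("I", "L", x, fixed = TRUE) else x
}

#' Build the peptide -> provenance index for a protein database
#'
#' Each digested peptide maps to the union, over all proteins containing
#' it, of protein ids, source taxa (including duplicate-collapse taxa),
#' EC numbers and KO ids. Index keys are I/L-collapsed when
#' `params$equate_il`.
#'
#' @param db a [protein_db()].
#' @param params a [digest_params()].
#' @return A `peptide_index` object.
#' @export
build_index <- function(db, params = digest_params()) {
  if (nrow(db) == 0)
    mox_stop("cannot index an empty database", "metaomix_value_error")
  pep_per_protein <- lapply(db$sequence, function(s)
    unique(il_collapse(digest(s, params), params)))
  counts <- lengths(pep_per_protein)
  long_pep <- unlist(pep_per_protein, use.names = FALSE)
  long_row <- rep(seq_len(nrow(db)), counts)
  by_pep <- split(long_row, long_pep)
  peptides <- names(by_pep)
  entry <- function(field) lapply(by_pep, function(rows)
    unique(unlist(db[[field]][rows], use.names = FALSE)))
  tab <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  tab$proteins <- lapply(by_pep, function(rows) db$id[rows])
  tab$taxa <- entry("taxa")
  tab$ec <- entry("ec")
  tab$ko <- entry("ko")
  rownames(tab) <- peptides
  structure(list(table = tab, params = params), class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index> %d peptides (mc=%d, len %d-%d, equate_il=%s)\n",
              nrow(x$table), x$params$missed_cleavages, x$params$min_len,
              x$params$max_len, x$params$equate_il))
  invisible(x)
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every taxon in the set,
#' computed as the last shared element of the root-paths.
#'
#' @param tree a [taxonomy_tree()].
#' @param taxa character vector of node ids (nonempty).
#' @return A single node id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (length(taxa) == 0)
    mox_stop("LCA of an empty taxon set", "metaomix_value_error")
  path <- tax_path(tree, taxa[1])
  for (t in taxa[-1]) {
    other <- tax_path(tree, t)
    k <- min(length(path), length(other))
    same <- path[seq_len(k)] == other[seq_len(k)]
    depth <- if (all(same)) k else which(!same)[1] - 1L
    path <- path[seq_len(depth)]
  }
  path[length(path)]
}

#' Assign a peptide's LCA taxon
#'
#' @param peptide peptide string (I/L collapse applied automatically to
#'   match the index keys).
#' @param index a [build_index()] result.
#' @param tax a [taxonomy_tree()].
#' @return The LCA node id, or `NA_character_` for a peptide absent from
#'   the index (the "unmapped" marker — not an error).
#' @export
assign_lca <- function(peptide, index, tax) {
  key <- il_collapse(toupper(peptide), index$params)
  if (!key %in% rownames(index$table)) return(NA_character_)
  lca(tax, index$table[key, "taxa"][[1]])
}

#' Aggregate per-sample peptide identifications into a peptide table
#'
#' @param ids data.frame with columns `sample`, `peptide`, `count`
#'   (positive integer spectral counts). Duplicate (sample, peptide) rows
#'   are summed with a warning.
#' @param index optional [build_index()] result: attaches provenance.
#' @param tax optional [taxonomy_tree()]: attaches LCA assignments.
#' @return A `peptide_table`: list with `matrix` (MP [abundance_matrix()],
#'   peptides x samples) and `peptide_info` (data.frame with `lca`,
#'   `mapped`, and `ec`/`ko` list columns).
#' @export
aggregate_peptides <- function(ids, index = NULL, tax = NULL) {
  stopifnot(all(c("sample", "peptide", "count") %in% colnames(ids)))
  if (any(ids$count <= 0) || any(ids$count != round(ids$count)))
    mox_stop("spectral counts must be positive integers", "metaomix_value_error")
  key <- paste(ids$sample, ids$peptide, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (sample, peptide) rows summed")
    ids <- stats::aggregate(count ~ sample + peptide, data = ids, FUN = sum)
  }
  samples <- unique(ids$sample)
  peptides <- sort(unique(ids$peptide))
  mat <- matrix(0, nrow = length(peptides), ncol = length(samples),
                dimnames = list(peptides, samples))
  mat[cbind(match(ids$peptide, peptides), match(ids$sample, samples))] <- ids$count
  info <- data.frame(peptide = peptides, row.names = peptides,
                     stringsAsFactors = FALSE)
  if (!is.null(index)) {
    keys <- il_collapse(peptides, index$params)
    hit <- match(keys, rownames(index$table))
    info$mapped <- !is.na(hit)
    info$ec <- ifelse_list(hit, index$table$ec)
    info$ko <- ifelse_list(hit, index$table$ko)
    if (!is.null(tax))
      info$lca <- vapply(seq_along(peptides), function(i)
        if (is.na(hit[i])) NA_character_ else
          lca(tax, index$table$taxa[[hit[i]]]), character(1))
  }
  ann <- if (!is.null(index)) info else NULL
  structure(list(matrix = abundance_matrix(mat, layer = "MP", annotations = ann),
                 peptide_info = info),
            class = "peptide_table")
}

ifelse_list <- function(hit, source) {
  lapply(hit, function(h) if (is.na(h)) character(0) else source[[h]])
}

#' Taxon abundance table from a peptide table
#'
#' Each peptide's spectral counts are credited to the `rank`-level ancestor
#' of its LCA. Peptides whose LCA sits above `rank` (or that are unmapped)
#' are pooled into `"Unclassified_at_<rank>"`. Per-sample totals are
#' conserved.
#'
#' @param pt a [aggregate_peptides()] result carrying LCA assignments.
#' @param tax a [taxonomy_tree()].
#' @param rank target rank.
#' @return An MP-layer [abundance_matrix()] of taxa x samples.
#' @export
taxon_table_from_peptides <- function(pt, tax, rank) {
  if (is.null(pt$peptide_info$lca))
    mox_stop("peptide table lacks LCA assignments; pass index and tax to aggregate_peptides",
             "metaomix_value_error")
  bucket <- sprintf("Unclassified_at_%s", rank)
  lab <- vapply(pt$peptide_info$lca, function(l) {
    if (is.na(l)) return(bucket)
    anc <- tax_ancestor_at_rank(tax, l, rank)
    if (is.na(anc)) bucket else tax$nodes[anc, "name"]
  }, character(1))
  agg <- rowsum(pt$matrix$values, group = lab, reorder = TRUE)
  abundance_matrix(agg, layer = "MP")
}
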