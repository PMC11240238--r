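# Domain containers and plain-text readers/writers.
#
# All omics layers share three core containers: a protein database (the
# metaproteomics search space), an abundance matrix (features x samples for
# any layer), and a taxonomy tree (the backbone for rank aggregation and
# peptide LCA assignment). Everything is read from and written to plain TSV
# or FASTA so runs are fully inspectable.

# Ordered taxonomic ranks; "root" and "unranked" are allowed outside the order.
RANK_LEVELS <- c("domain", "kingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Construct a protein database
#'
#' A protein database is a data frame with one row per protein record:
#' `id` (unique), `taxon` (primary source taxon), `sequence` (uppercase
#' amino acids, `X` allowed), `ec` and `ko` (list columns of annotation
#' sets) and `taxa` (list column: all taxa the sequence was observed in,
#' which grows beyond `taxon` when exact duplicates from several taxa are
#' collapsed — the peptide LCA stage needs the full set).
#'
#' @param id,taxon,sequence character vectors of equal length.
#' @param ec,ko list of character vectors (or NULL for all-empty).
#' @param taxa list of character vectors; defaults to `as.list(taxon)`.
#' @return A `protein_db` data frame.
#' @export
protein_db <- function(id, taxon, sequence, ec = NULL, ko = NULL, taxa = NULL) {
  n <- length(id)
  if (is.null(ec)) ec <- rep(list(character(0)), n)
  if (is.null(ko)) ko <- rep(list(character(0)), n)
  if (is.null(taxa)) taxa <- as.list(taxon)
  stopifnot(length(taxon) == n, length(sequence) == n,
            length(ec) == n, length(ko) == n, length(taxa) == n)
  if (n > 0) {
    if (anyDuplicated(id))
      mox_stop(sprintf("duplicate protein ids: %s",
                       join_semicolon(unique(id[duplicated(id)]))),
               "metaomix_duplicate_error")
    if (any(!nzchar(id)))
      mox_stop("empty protein id", "metaomix_value_error")
    sequence <- toupper(sequence)
    bad <- which(!is_valid_sequence(sequence))
    if (length(bad))
      mox_stop(sprintf("invalid or empty sequence in record(s): %s",
                       join_semicolon(id[bad])), "metaomix_value_error")
    all_ec <- unlist(ec, use.names = FALSE)
    if (length(all_ec) && any(!is_valid_ec(all_ec)))
      mox_stop(sprintf("malformed EC number(s): %s",
                       join_semicolon(all_ec[!is_valid_ec(all_ec)])),
               "metaomix_value_error")
  }
  out <- data.frame(id = as.character(id), taxon = as.character(taxon),
                    sequence = as.character(sequence),
                    stringsAsFactors = FALSE)
  out$ec <- ec
  out$ko <- ko
  out$taxa <- taxa
  class(out) <- c("protein_db", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Headers follow the package's self-describing dialect:
#' `>id taxon=<t1[;t2...]>[ ec=<ec;ec>][ ko=<ko;ko>]`. The first taxon is
#' the record's primary taxon; additional semicolon-separated taxa carry
#' duplicate provenance from redundancy removal. Absent `ec=`/`ko=` tags
#' give empty annotation sets. Sequences are uppercased on read.
#'
#' @param path path to a FASTA file.
#' @return A [protein_db()] data frame in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    mox_stop(sprintf("file not found: %s", path), "metaomix_io_error")
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0)
    return(protein_db(character(0), character(0), character(0)))
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  ids <- character(length(aa))
  taxon <- character(length(aa)); taxa <- vector("list", length(aa))
  ec <- vector("list", length(aa)); ko <- vector("list", length(aa))
  for (i in seq_along(headers)) {
    tok <- strsplit(trimws(headers[i]), "\\s+")[[1]]
    ids[i] <- tok[1]
    tags <- tok[-1]
    get_tag <- function(tag) {
      hit <- grep(sprintf("^%s=", tag), tags, value = TRUE)
      if (length(hit) == 0) return(NULL)
      split_semicolon(sub(sprintf("^%s=", tag), "", hit[1]))
    }
    tx <- get_tag("taxon")
    if (is.null(tx) || length(tx) == 0)
      mox_stop(sprintf("record '%s': missing taxon= tag in FASTA header", ids[i]),
               "metaomix_parse_error")
    taxon[i] <- tx[1]
    taxa[[i]] <- tx
    ec[[i]] <- get_tag("ec") %||% character(0)
    ko[[i]] <- get_tag("ko") %||% character(0)
    if (!nzchar(seqs[i]))
      mox_stop(sprintf("record '%s': empty sequence", ids[i]),
               "metaomix_parse_error")
  }
  protein_db(ids, taxon, seqs, ec, ko, taxa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a protein database as FASTA
#'
#' Emits the header dialect documented in [read_fasta()], with sequences
#' wrapped at 60 columns. Output is deterministic given record order.
#'
#' @param records a [protein_db()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (anyDuplicated(records$id))
    mox_stop("duplicate protein ids", "metaomix_duplicate_error")
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  headers <- vapply(seq_len(nrow(records)), function(i) {
    h <- sprintf("%s taxon=%s", records$id[i], join_semicolon(records$taxa[[i]]))
    if (length(records$ec[[i]])) h <- sprintf("%s ec=%s", h, join_semicolon(records$ec[[i]]))
    if (length(records$ko[[i]])) h <- sprintf("%s ko=%s", h, join_semicolon(records$ko[[i]]))
    h
  }, character(1))
  aa <- Biostrings::BStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Construct an abundance matrix
#'
#' Features x samples nonnegative values for one omics layer, with an
#' optional feature-annotation side table (`taxon` character column and
#' `ec`/`ko` list columns, row-aligned with features).
#'
#' @param values numeric matrix with unique row (feature) and column
#'   (sample) names; all values must be >= 0 and finite.
#' @param layer one of "AS", "MG", "MT", "MP".
#' @param annotations optional data.frame keyed by feature id (rownames).
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, layer = c("AS", "MG", "MT", "MP"),
                             annotations = NULL) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    mox_stop("abundance matrix needs feature rownames and sample colnames",
             "metaomix_value_error")
  if (anyDuplicated(rownames(values)))
    mox_stop("duplicate feature ids", "metaomix_duplicate_error")
  if (anyDuplicated(colnames(values)))
    mox_stop("duplicate sample ids", "metaomix_duplicate_error")
  if (any(!is.finite(values)) || any(values < 0))
    mox_stop("abundance values must be finite and nonnegative",
             "metaomix_value_error")
  if (!is.null(annotations)) {
    if (!all(rownames(values) %in% rownames(annotations)))
      mox_stop("annotations missing for some features", "metaomix_value_error")
    annotations <- annotations[rownames(values), , drop = FALSE]
  }
  structure(list(values = values, layer = layer, annotations = annotations),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> layer=%s  %d features x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Read a features-x-samples TSV matrix
#'
#' First column = feature id; header row = sample ids (order preserved).
#'
#' @param path TSV path.
#' @param layer omics layer label.
#' @param annotations optional annotation data.frame passed through.
#' @return An [abundance_matrix()].
#' @export
read_matrix <- function(path, layer = "AS", annotations = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    mox_stop("matrix TSV needs a feature column plus >=1 sample column",
             "metaomix_parse_error")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    mox_stop(sprintf("duplicate feature ids: %s",
                     join_semicolon(unique(ids[duplicated(ids)]))),
             "metaomix_duplicate_error")
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(is.na(vals)))
    mox_stop("non-numeric or missing values in matrix", "metaomix_parse_error")
  if (any(vals < 0))
    mox_stop("negative values in abundance matrix", "metaomix_value_error")
  rownames(vals) <- ids
  abundance_matrix(vals, layer = layer, annotations = annotations)
}

#' Write an abundance matrix as TSV
#' @param m an [abundance_matrix()].
#' @param path output path.
#' @param id_column name for the feature-id column.
#' @export
write_matrix <- function(m, path, id_column = "feature") {
  df <- data.frame(rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample metadata table
#'
#' @param data data.frame with unique rownames = sample ids.
#' @param phenotype name of the designated phenotype column.
#' @param covariates character vector of covariate column names.
#' @return A `sample_metadata` object.
#' @export
sample_metadata <- function(data, phenotype, covariates = character(0)) {
  if (anyDuplicated(rownames(data)))
    mox_stop("duplicate sample ids in metadata", "metaomix_duplicate_error")
  missing_cols <- setdiff(c(phenotype, covariates), colnames(data))
  if (length(missing_cols))
    mox_stop(sprintf("metadata columns not found: %s",
                     join_semicolon(missing_cols)), "metaomix_value_error")
  structure(list(data = data, phenotype = phenotype, covariates = covariates),
            class = "sample_metadata")
}

#' Read sample metadata from TSV (first column = sample id)
#' @param path TSV path.
#' @param phenotype designated phenotype column.
#' @param covariates covariate column names.
#' @export
read_metadata <- function(path, phenotype, covariates = character(0)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    mox_stop("duplicate sample ids in metadata", "metaomix_duplicate_error")
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  sample_metadata(df, phenotype, covariates)
}

#' Construct a taxonomy tree
#'
#' Rooted tree given as a node table. Exactly one node is its own parent
#' (the root); every other node must reach the root by following parents.
#'
#' @param nodes data.frame with columns `id`, `name`, `rank`, `parent`.
#' @return A `taxonomy_tree` object with fields `nodes` and `root`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("id", "name", "rank", "parent") %in% colnames(nodes)))
  nodes$id <- as.character(nodes$id); nodes$parent <- as.character(nodes$parent)
  if (anyDuplicated(nodes$id))
    mox_stop("duplicate taxonomy node ids", "metaomix_duplicate_error")
  bad_rank <- setdiff(unique(nodes$rank), c(RANK_LEVELS, "root", "unranked"))
  if (length(bad_rank))
    mox_stop(sprintf("unknown taxonomic rank(s): %s", join_semicolon(bad_rank)),
             "metaomix_value_error")
  roots <- nodes$id[nodes$id == nodes$parent]
  if (length(roots) != 1)
    mox_stop(sprintf("taxonomy must have exactly one root, found %d",
                     length(roots)), "metaomix_value_error")
  unknown_parent <- setdiff(nodes$parent, nodes$id)
  if (length(unknown_parent))
    mox_stop(sprintf("parent(s) not in node table: %s",
                     join_semicolon(unknown_parent)), "metaomix_value_error")
  parent <- stats::setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {  # cycle check: every node must reach the root
    seen <- character(0); cur <- id
    while (cur != roots) {
      if (cur %in% seen)
        mox_stop(sprintf("cycle in taxonomy involving node '%s'", cur),
                 "metaomix_cycle_error")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  rownames(nodes) <- nodes$id
  structure(list(nodes = nodes, root = roots), class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, root='%s'\n", nrow(x$nodes), x$root))
  invisible(x)
}

#' Path from the root to a node (inclusive)
#' @param tree a [taxonomy_tree()].
#' @param id node id.
#' @return Character vector of node ids, root first.
#' @export
tax_path <- function(tree, id) {
  if (!id %in% tree$nodes$id)
    mox_stop(sprintf("unknown taxon '%s'", id), "metaomix_value_error")
  path <- id
  while (path[1] != tree$root) path <- c(tree$nodes[path[1], "parent"], path)
  path
}

#' Ancestor (or self) of a node at a given rank
#' @param tree a [taxonomy_tree()].
#' @param id node id.
#' @param rank target rank.
#' @return Node id at `rank`, or `NA_character_` if the lineage lacks it.
#' @export
tax_ancestor_at_rank <- function(tree, id, rank) {
  path <- tax_path(tree, id)
  hit <- path[tree$nodes[path, "rank"] == rank]
  if (length(hit)) hit[length(hit)] else NA_character_
}

#' Read a taxonomy from TSV
#'
#' Expects columns `child`, `parent`, `name`, `rank` (header required).
#' The root is the row whose child equals its parent.
#' @param path TSV path.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "name", "rank") %in% colnames(df)))
  taxonomy_tree(data.frame(id = df$child, name = df$name, rank = df$rank,
                           parent = df$parent, stringsAsFactors = FALSE))
}

#' Write a taxonomy tree as TSV (child/parent/name/rank)
#' @param tree a [taxonomy_tree()].
#' @param path output path.
#' @export
write_taxonomy <- function(tree, path) {
  df <- data.frame(child = tree$nodes$id, parent = tree$nodes$parent,
                   name = tree$nodes$name, rank = tree$nodes$rank)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rank-prefix map used by SILVA/GTDB-style lineage strings
LINEAGE_PREFIXES <- c(d = "domain", k = "kingdom", p = "phylum", c = "class",
                      o = "order", f = "family", g = "genus", s = "species")

#' Build a taxonomy tree from rank-prefixed lineage strings
#'
#' Accepts lineages such as `"d__Bacteria;p__Firmicutes;g__Veillonella"`.
#' Nodes are identified by their prefixed token (e.g. `"g__Veillonella"`),
#' all placed under a synthetic `"root"` node. A token appearing under two
#' different parents is an error.
#'
#' @param lineages character vector of lineage strings, optionally named by
#'   the feature (e.g. ASV) they classify.
#' @return list with `tree` (a [taxonomy_tree()]) and `leaf` (named vector
#'   mapping each input lineage to its deepest node id).
#' @export
taxonomy_from_lineages <- function(lineages) {
  nodes <- data.frame(id = "root", name = "root", rank = "root",
                      parent = "root", stringsAsFactors = FALSE)
  leaf <- character(length(lineages))
  for (i in seq_along(lineages)) {
    toks <- split_semicolon(lineages[i])
    parent <- "root"
    for (tok in toks) {
      pre <- sub("__.*$", "", tok)
      if (!pre %in% names(LINEAGE_PREFIXES))
        mox_stop(sprintf("unknown rank prefix in lineage token '%s'", tok),
                 "metaomix_parse_error")
      nm <- sub("^.__", "", tok)
      if (tok %in% nodes$id) {
        if (nodes[nodes$id == tok, "parent"] != parent)
          mox_stop(sprintf("lineage token '%s' appears under two parents", tok),
                   "metaomix_parse_error")
      } else {
        nodes <- rbind(nodes, data.frame(
          id = tok, name = nm, rank = LINEAGE_PREFIXES[[pre]],
          parent = parent, stringsAsFactors = FALSE))
      }
      parent <- tok
    }
    leaf[i] <- parent
  }
  names(leaf) <- names(lineages)
  list(tree = taxonomy_tree(nodes), leaf = leaf)
}

#' Construct a pathway definition
#'
#' @param pathway_id pathway identifier.
#' @param nodes data.frame with columns `node`, `label` and list columns
#'   `ko`, `ec`; every node needs at least one KO or EC id.
#' @return A `pathway_definition` object.
#' @export
pathway_definition <- function(pathway_id, nodes) {
  stopifnot(all(c("node", "label", "ko", "ec") %in% colnames(nodes)))
  if (anyDuplicated(nodes$node))
    mox_stop("duplicate pathway node ids", "metaomix_duplicate_error")
  empty <- vapply(seq_len(nrow(nodes)),
                  function(i) length(nodes$ko[[i]]) + length(nodes$ec[[i]]) == 0,
                  logical(1))
  if (any(empty))
    mox_stop(sprintf("pathway node(s) without any KO/EC id: %s",
                     join_semicolon(nodes$node[empty])), "metaomix_value_error")
  rownames(nodes) <- nodes$node
  structure(list(pathway_id = pathway_id, nodes = nodes),
            class = "pathway_definition")
}

#' Read a pathway node map from TSV
#'
#' Columns: `node`, `label`, `ko` (semicolon list), `ec` (semicolon list).
#' @param path TSV path.
#' @param pathway_id identifier for the pathway (default: file stem).
#' @export
read_pathway <- function(path, pathway_id = NULL) {
  if (is.null(pathway_id))
    pathway_id <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("node", "label", "ko", "ec") %in% colnames(df)))
  nodes <- data.frame(node = df$node, label = df$label, stringsAsFactors = FALSE)
  nodes$ko <- lapply(df$ko, split_semicolon)
  nodes$ec <- lapply(df$ec, split_semicolon)
  pathway_definition(pathway_id, nodes)
}

#' Write a pathway definition as TSV
#' @param pathway a [pathway_definition()].
#' @param path output path.
#' @export
write_pathway <- function(pathway, path) {
  df <- data.frame(node = pathway$nodes$node, label = pathway$nodes$label,
                   ko = vapply(pathway$nodes$ko, join_semicolon, character(1)),
                   ec = vapply(pathway$nodes$ec, join_semicolon, character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
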