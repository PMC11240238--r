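# Protein-database construction: collect proteomes for the top-n taxa,
# remove exact sequence redundancy, optionally merge a host proteome, and
# report the counts at each stage.

#' Local-directory proteome source
#'
#' A proteome source is the lookup contract used by [collect_proteomes()]:
#' `lookup(taxon)` returns a named list `genome id -> protein_db` (genomes
#' sorted by id, records in file order), or `NULL` when the taxon is not
#' available. This implementation serves a directory laid out as
#' `<root>/<taxon>/<genome_id>.faa`. A remote (e.g. NCBI) source satisfying
#' the same contract can be supplied via [proteome_source()]; none is
#' bundled because lookups there depend on database snapshots and are not
#' reproducible.
#'
#' @param root directory containing one subdirectory per taxon.
#' @return A `proteome_source` object.
#' @export
proteome_source_local <- function(root) {
  if (!dir.exists(root))
    mox_stop(sprintf("proteome directory not found: %s", root),
             "metaomix_io_error")
  proteome_source(function(taxon) {
    dir <- file.path(root, taxon)
    if (!dir.exists(dir)) return(NULL)
    files <- sort(list.files(dir, pattern = "\\.faa$", full.names = TRUE))
    if (length(files) == 0) return(list())
    stats::setNames(lapply(files, read_fasta),
                    tools::file_path_sans_ext(basename(files)))
  }, description = sprintf("local:%s", root))
}

#' Wrap a lookup function as a proteome source
#' @param lookup function(taxon) -> named list of [protein_db()] per genome,
#'   or NULL if the taxon is unavailable; must be deterministic and ordered.
#' @param description human-readable label for reports.
#' @export
proteome_source <- function(lookup, description = "custom") {
  stopifnot(is.function(lookup))
  structure(list(lookup = lookup, description = description),
            class = "proteome_source")
}

#' Collect proteomes for ranked taxa
#'
#' Records are concatenated in ranked-taxon order, then genome order, then
#' record order, each record tagged with its source taxon. Taxa the source
#' cannot resolve are skipped with a warning and recorded as gaps.
#'
#' @param taxa a `ranked_taxa` object (or character vector of taxon names).
#' @param source a [proteome_source()].
#' @return list with `records` ([protein_db()]), `genome_counts`
#'   (data.frame taxon/genomes/proteins) and `missing` (character).
#' @export
collect_proteomes <- function(taxa, source) {
  if (inherits(taxa, "ranked_taxa")) taxa <- taxa$entries$taxon
  stopifnot(inherits(source, "proteome_source"))
  pieces <- list(); counts <- list(); missing <- character(0)
  for (taxon in taxa) {
    genomes <- source$lookup(taxon)
    if (is.null(genomes) || length(genomes) == 0) {
      warning(sprintf("no proteomes found for taxon '%s'; skipping", taxon))
      missing <- c(missing, taxon)
      counts[[taxon]] <- data.frame(taxon = taxon, genomes = 0L, proteins = 0L)
      next
    }
    nprot <- 0L
    for (g in names(genomes)) {
      rec <- genomes[[g]]
      rec$taxon <- taxon          # tag with the taxon it was collected for
      rec$taxa <- as.list(rec$taxon)
      pieces[[length(pieces) + 1L]] <- rec
      nprot <- nprot + nrow(rec)
    }
    counts[[taxon]] <- data.frame(taxon = taxon, genomes = length(genomes),
                                  proteins = nprot)
  }
  records <- if (length(pieces)) bind_protein_dbs(pieces) else
    protein_db(character(0), character(0), character(0))
  list(records = records,
       genome_counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
       missing = missing)
}

# rbind protein_db pieces, disambiguating duplicate ids across genomes
bind_protein_dbs <- function(pieces) {
  out <- do.call(rbind, lapply(pieces, function(p) { class(p) <- "data.frame"; p }))
  if (anyDuplicated(out$id))
    out$id <- make.unique(out$id, sep = "_dup")
  class(out) <- c("protein_db", "data.frame")
  rownames(out) <- NULL
  out
}

#' Drop records with empty or invalid amino-acid sequences
#' @param records a [protein_db()].
#' @return list with cleaned `records` and `dropped` ids.
#' @export
clean_records <- function(records) {
  ok <- is_valid_sequence(toupper(records$sequence))
  list(records = records[ok, , drop = FALSE], dropped = records$id[!ok])
}

#' Remove exact sequence redundancy
#'
#' Records with identical full-length amino-acid sequences are collapsed to
#' one: the FIRST record in input order survives. The survivor's EC/KO sets
#' become the union over its duplicates, and the full set of source taxa is
#' preserved in the `taxa` list column (discarding it would corrupt
#' downstream lowest-common-ancestor assignment).
#'
#' @param records a [protein_db()].
#' @return A deduplicated [protein_db()] in first-occurrence order.
#' @export
deduplicate <- function(records) {
  if (nrow(records) <= 1) return(records)
  grp <- match(records$sequence, records$sequence)  # index of first occurrence
  keep <- which(!duplicated(records$sequence))
  out <- records[keep, , drop = FALSE]
  if (length(keep) < nrow(records)) {
    idx <- split(seq_len(nrow(records)), grp)
    for (j in seq_along(keep)) {
      members <- idx[[as.character(keep[j])]]
      if (length(members) > 1) {
        out$ec[[j]] <- unique(unlist(records$ec[members], use.names = FALSE))
        out$ko[[j]] <- unique(unlist(records$ko[members], use.names = FALSE))
        out$taxa[[j]] <- unique(unlist(records$taxa[members], use.names = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Merge a host proteome into the database
#'
#' Host records are appended after the microbial ones and a second exact
#' deduplication pass runs over the merged set, so a host protein identical
#' to a microbial one collapses into the earlier (microbial) record while
#' keeping both taxa.
#'
#' @param records microbial [protein_db()].
#' @param host_proteome host [protein_db()] (records tagged with the host
#'   taxon).
#' @return Merged, deduplicated [protein_db()].
#' @export
add_host <- function(records, host_proteome) {
  if (is.null(host_proteome) || nrow(host_proteome) == 0) return(records)
  deduplicate(bind_protein_dbs(list(records, host_proteome)))
}

#' Build the metaproteomics protein database from an ASV profile
#'
#' Runs the full construction: aggregate ASV counts to `rank`, select the
#' top `n` taxa, collect their proteomes from `source`, drop invalid
#' records, remove exact redundancy, and merge the host proteome if given.
#'
#' @param asv ASV [abundance_matrix()] with taxon annotations.
#' @param taxonomy a [taxonomy_tree()].
#' @param rank taxonomic rank for selection (e.g. "genus").
#' @param n number of top taxa.
#' @param source a [proteome_source()].
#' @param host optional host [protein_db()].
#' @param out_fasta optional path: write the final database FASTA.
#' @param report_prefix optional path prefix: write `<prefix>.tsv` and
#'   `<prefix>.json` build reports.
#' @param rank_by passed to [rank_taxa()].
#' @return list with `database` ([protein_db()]), `report` (build counts)
#'   and `ranked` (the selected taxa).
#' @export
build_database <- function(asv, taxonomy, rank, n, source, host = NULL,
                           out_fasta = NULL, report_prefix = NULL,
                           rank_by = "mean_relative") {
  agg <- aggregate_to_rank(asv, taxonomy, rank)
  ranked <- rank_taxa(agg, n, rank_by = rank_by)
  got <- collect_proteomes(ranked, source)
  cleaned <- clean_records(got$records)
  nr <- deduplicate(cleaned$records)
  final <- add_host(nr, host)
  report <- list(
    rank = rank, n = ranked$n,
    per_taxon = got$genome_counts,
    missing_taxa = got$missing,
    dropped_invalid = length(cleaned$dropped),
    raw_count = nrow(got$records),
    nonredundant_count = nrow(nr),
    host_count = if (is.null(host)) 0L else nrow(host),
    total = nrow(final))
  if (!is.null(out_fasta)) write_fasta(final, out_fasta)
  if (!is.null(report_prefix)) write_build_report(report, report_prefix)
  list(database = final, report = report, ranked = ranked)
}

#' Write a build report as TSV + JSON
#' @param report the `report` element of [build_database()].
#' @param prefix output path prefix.
#' @export
write_build_report <- function(report, prefix) {
  utils::write.table(report$per_taxon, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report[setdiff(names(report), "per_taxon")],
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
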