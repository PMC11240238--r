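# Deterministic synthetic-data generators. They emulate the structure of
# the real study designs the pipeline targets — two-group cohorts with
# covariates, overdispersed compositional counts, peptides drawn from
# taxon proteomes in proportion to abundance, planted KO-level fold
# changes — so every stage runs and is scored against truth files with no
# downloads. Protein sequences are uniform random over the 20 amino acids:
# adequate for digestion/LCA logic, with no biological realism claimed.

#' Specification of a synthetic microbial community
#'
#' @param seed RNG seed; everything downstream is fully determined by it.
#' @param n_taxa number of genera.
#' @param genomes_per_taxon genomes per genus.
#' @param proteins_per_genome proteins per genome.
#' @param protein_length min/max protein length (residues).
#' @param duplicate_fraction fraction of proteins overwritten with a copy
#'   of another taxon's protein (planted cross-taxon redundancy), in [0,1).
#' @param host include a host proteome.
#' @param host_proteins number of host proteins.
#' @return A `community_spec` list.
#' @export
community_spec <- function(seed = 1, n_taxa = 6, genomes_per_taxon = 2,
                           proteins_per_genome = 20,
                           protein_length = c(80, 200),
                           duplicate_fraction = 0.1, host = TRUE,
                           host_proteins = 30) {
  stopifnot(n_taxa >= 1, genomes_per_taxon >= 1, proteins_per_genome >= 1,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  structure(list(seed = seed, n_taxa = n_taxa,
                 genomes_per_taxon = genomes_per_taxon,
                 proteins_per_genome = proteins_per_genome,
                 protein_length = protein_length,
                 duplicate_fraction = duplicate_fraction,
                 host = host, host_proteins = host_proteins),
            class = "community_spec")
}

#' Specification of a two-group study design with planted effects
#'
#' Counts follow a Dirichlet-multinomial: per-sample proportions drawn
#' around the base composition with the given concentration (default 50,
#' a typical overdispersion for stool-like communities), then multinomial
#' sampling at a uniform random depth. Effects are multiplicative log2
#' fold changes applied to the affected features in group B.
#'
#' @param seed RNG seed.
#' @param n_per_group samples per group (groups "A" and "B").
#' @param concentration Dirichlet concentration parameter.
#' @param depth_range sequencing-depth range (counts per sample).
#' @param effects named numeric vector: feature/taxon/KO id -> log2 fold
#'   change in group B (empty = null design).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(seed = 1, n_per_group = 20, concentration = 50,
                        depth_range = c(20000, 50000),
                        effects = numeric(0)) {
  stopifnot(n_per_group >= 2, concentration > 0, all(depth_range > 0),
            all(is.finite(effects)))
  structure(list(seed = seed, n_per_group = n_per_group,
                 concentration = concentration, depth_range = depth_range,
                 effects = effects),
            class = "effect_spec")
}

rand_protein <- function(len) {
  paste(sample(AA_ALPHABET[AA_ALPHABET != "X"], len, replace = TRUE),
        collapse = "")
}

#' Generate a synthetic community: taxonomy, proteome directory, host
#'
#' Builds a genus-level taxonomy (domain > phylum > family > genus), writes
#' a [proteome_source_local()] directory layout of random proteomes with
#' planted cross-taxon duplicate sequences, an optional host FASTA, and a
#' truth table of the planted duplicates.
#'
#' @param spec a [community_spec()].
#' @param dir output directory (created); proteomes under `dir/proteomes`.
#' @return list: `tree` ([taxonomy_tree()]), `genera` (ids), `source_dir`,
#'   `host` ([protein_db()] or NULL), `host_fasta`, `duplicates` (truth
#'   data.frame), `records` (all microbial records, collection order).
#' @export
make_community <- function(spec, dir) {
  with_seed(spec$seed, {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    genera <- sprintf("Genus_%02d", seq_len(spec$n_taxa))
    n_fam <- max(1, ceiling(spec$n_taxa / 2))
    n_phy <- max(1, ceiling(n_fam / 2))
    fam_of <- rep(seq_len(n_fam), each = 2)[seq_len(spec$n_taxa)]
    phy_of <- rep(seq_len(n_phy), each = 2)[seq_len(n_fam)]
    nodes <- data.frame(id = "root", name = "root", rank = "root",
                        parent = "root", stringsAsFactors = FALSE)
    nodes <- rbind(nodes, data.frame(id = "d__Bacteria", name = "Bacteria",
                                     rank = "domain", parent = "root"))
    for (p in seq_len(n_phy))
      nodes <- rbind(nodes, data.frame(
        id = sprintf("p__Phylum_%02d", p), name = sprintf("Phylum_%02d", p),
        rank = "phylum", parent = "d__Bacteria"))
    for (f in seq_len(n_fam))
      nodes <- rbind(nodes, data.frame(
        id = sprintf("f__Family_%02d", f), name = sprintf("Family_%02d", f),
        rank = "family", parent = sprintf("p__Phylum_%02d", phy_of[f])))
    for (i in seq_len(spec$n_taxa))
      nodes <- rbind(nodes, data.frame(
        id = paste0("g__", genera[i]), name = genera[i], rank = "genus",
        parent = sprintf("f__Family_%02d", fam_of[i])))
    host_taxon <- NULL
    if (spec$host) {
      nodes <- rbind(nodes,
        data.frame(id = "d__Eukaryota", name = "Eukaryota", rank = "domain",
                   parent = "root"),
        data.frame(id = "g__Host", name = "Host", rank = "genus",
                   parent = "d__Eukaryota"))
      host_taxon <- "g__Host"
    }
    tree <- taxonomy_tree(nodes)

    src <- file.path(dir, "proteomes")
    lens <- spec$protein_length
    all_recs <- list()
    for (i in seq_len(spec$n_taxa)) {
      for (g in seq_len(spec$genomes_per_taxon)) {
        gid <- sprintf("%s_gen%02d", genera[i], g)
        n <- spec$proteins_per_genome
        seqs <- vapply(sample(lens[1]:lens[2], n, replace = TRUE),
                       rand_protein, character(1))
        all_recs[[gid]] <- data.frame(
          id = sprintf("%s_p%03d", gid, seq_len(n)), taxon = genera[i],
          genome = gid, sequence = seqs, stringsAsFactors = FALSE)
      }
    }
    pool <- do.call(rbind, c(all_recs, list(make.row.names = FALSE)))
    n_dup <- round(spec$duplicate_fraction * nrow(pool))
    duplicates <- data.frame(id = character(0), source_id = character(0))
    if (n_dup > 0) {
      targets <- sample(nrow(pool), n_dup)
      sources <- vapply(targets, function(t) {
        cand <- which(pool$taxon != pool$taxon[t] &
                        !seq_len(nrow(pool)) %in% targets)
        sample(cand, 1)
      }, integer(1))
      pool$sequence[targets] <- pool$sequence[sources]
      duplicates <- data.frame(id = pool$id[targets],
                               source_id = pool$id[sources],
                               stringsAsFactors = FALSE)
    }
    for (gid in unique(pool$genome)) {
      sub <- pool[pool$genome == gid, ]
      tdir <- file.path(src, sub$taxon[1])
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(protein_db(sub$id, sub$taxon, sub$sequence),
                  file.path(tdir, paste0(gid, ".faa")))
    }
    utils::write.table(duplicates, file.path(dir, "truth_duplicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    host <- NULL; host_fasta <- NULL
    if (spec$host) {
      seqs <- vapply(sample(lens[1]:lens[2], spec$host_proteins, replace = TRUE),
                     rand_protein, character(1))
      host <- protein_db(sprintf("host_p%03d", seq_len(spec$host_proteins)),
                         rep("Host", spec$host_proteins), seqs)
      host_fasta <- file.path(dir, "host.faa")
      write_fasta(host, host_fasta)
    }
    records <- protein_db(pool$id, pool$taxon, pool$sequence)
    list(tree = tree, genera = genera, source_dir = src, host = host,
         host_fasta = host_fasta, host_taxon = host_taxon,
         duplicates = duplicates, records = records)
  })
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a two-group ASV count table with planted taxon effects
#'
#' Base genus proportions follow a geometric abundance series; each genus
#' is split over `asvs_per_taxon` ASVs. Group-B samples apply the planted
#' multiplicative effects before renormalization; counts are
#' Dirichlet-multinomial. Metadata carries group, age (numeric) and sex
#' (2-level).
#'
#' @param community a [make_community()] result.
#' @param effects an [effect_spec()]; `effects` names must be genus names
#'   (e.g. `"Genus_03"`).
#' @param asvs_per_taxon ASVs per genus.
#' @return list: `asv` (AS [abundance_matrix()] with taxon annotations),
#'   `meta` ([sample_metadata()]), `truth` (planted log2 effects),
#'   `truth_transformed` (per-genus expected group difference of mean log2
#'   relative abundance under the Dirichlet model — the scale a log-TSS
#'   linear model estimates), `base_proportions` (genus-level).
#' @export
make_asv_counts <- function(community, effects, asvs_per_taxon = 3) {
  with_seed(effects$seed, {
    genera <- community$genera
    stopifnot(all(names(effects$effects) %in% genera))
    base <- 0.6^seq_along(genera)
    base <- base / sum(base)
    names(base) <- genera
    n_asv <- asvs_per_taxon * length(genera)
    asv_tax <- rep(genera, each = asvs_per_taxon)
    split_w <- unlist(lapply(genera, function(g) rdirichlet1(rep(2, asvs_per_taxon))))
    asv_base <- base[asv_tax] * split_w
    asv_ids <- sprintf("ASV_%03d", seq_len(n_asv))

    n <- 2 * effects$n_per_group
    groups <- rep(c("A", "B"), each = effects$n_per_group)
    samples <- sprintf("S%02d_%s", seq_len(n), groups)
    fc <- rep(1, n_asv)
    mult <- 2^effects$effects
    counts <- matrix(0L, nrow = n_asv, ncol = n,
                     dimnames = list(asv_ids, samples))
    depths <- sample(effects$depth_range[1]:effects$depth_range[2], n,
                     replace = TRUE)
    for (s in seq_len(n)) {
      p <- asv_base
      if (groups[s] == "B" && length(mult))
        p[asv_tax %in% names(mult)] <-
          p[asv_tax %in% names(mult)] * mult[asv_tax[asv_tax %in% names(mult)]]
      p <- p / sum(p)
      ps <- rdirichlet1(effects$concentration * p)
      counts[, s] <- stats::rmultinom(1, depths[s], ps)
    }
    # exact expected group difference of mean log2 relative abundance under
    # the Dirichlet model (closure + Jensen effects included):
    # E[log p_i] = digamma(alpha_i) - digamma(alpha_0)
    pB <- base
    if (length(mult)) pB[names(mult)] <- pB[names(mult)] * mult
    pB <- pB / sum(pB)
    truth_transformed <- (digamma(effects$concentration * pB) -
                            digamma(effects$concentration * base)) / log(2)
    ann <- data.frame(taxon = paste0("g__", asv_tax), row.names = asv_ids,
                      stringsAsFactors = FALSE)
    md <- data.frame(group = groups,
                     age = round(stats::rnorm(n, 45, 10), 1),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     row.names = samples, stringsAsFactors = FALSE)
    list(asv = abundance_matrix(counts, layer = "AS", annotations = ann),
         meta = sample_metadata(md, phenotype = "group",
                                covariates = c("age", "sex")),
         truth = effects$effects, truth_transformed = truth_transformed,
         base_proportions = base)
  })
}

#' Generate per-sample peptide identifications from a community
#'
#' Peptides are sampled from the in-silico tryptic digests of each taxon's
#' proteome with probability proportional to the taxon's relative
#' abundance in the sample, emulating spectral counting against the
#' community. The truth table records the generating taxon of every PSM.
#'
#' @param community a [make_community()] result.
#' @param abundance genus-level relative-abundance matrix (genera x
#'   samples), e.g. from the aggregated ASV table; rownames are genus
#'   names.
#' @param n_psms spectral counts per sample.
#' @param seed RNG seed.
#' @param params a [digest_params()].
#' @param include_host sample host peptides too (at a fixed 10% share).
#' @return list: `ids` (long data.frame sample/peptide/count), `truth`
#'   (sample/peptide/taxon draws), `pools` (peptides per taxon).
#' @export
make_peptide_ids <- function(community, abundance, n_psms = 300, seed = 1,
                             params = digest_params(), include_host = FALSE) {
  with_seed(seed, {
    taxa <- community$genera
    pools <- lapply(taxa, function(tx) {
      recs <- community$records[community$records$taxon == tx, ]
      unique(unlist(lapply(recs$sequence, digest, params = params),
                    use.names = FALSE))
    })
    names(pools) <- taxa
    if (include_host && !is.null(community$host))
      pools$Host <- unique(unlist(lapply(community$host$sequence, digest,
                                         params = params), use.names = FALSE))
    ids <- list(); truth <- list()
    for (s in colnames(abundance)) {
      w <- stats::setNames(abundance[taxa, s], taxa)
      w <- w / sum(w)
      if (include_host && "Host" %in% names(pools))
        w <- c(w * 0.9, Host = 0.1)
      tx_draw <- sample(names(w), n_psms, replace = TRUE, prob = w)
      pep_draw <- vapply(tx_draw, function(tx) sample(pools[[tx]], 1),
                         character(1))
      tab <- table(pep_draw)
      ids[[s]] <- data.frame(sample = s, peptide = names(tab),
                             count = as.integer(tab), stringsAsFactors = FALSE)
      truth[[s]] <- data.frame(sample = s, peptide = pep_draw, taxon = tx_draw,
                               stringsAsFactors = FALSE)
    }
    list(ids = do.call(rbind, c(ids, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         pools = pools)
  })
}

#' Generate annotated multi-layer matrices with planted KO fold changes
#'
#' Emits MG/MT/MP feature matrices (log-normal abundances around
#' feature-specific baselines), each feature annotated with one KO (and an
#' EC number for half of the KOs), plus a pathway definition over the KOs
#' and a truth table of the planted per-layer log2 ratios.
#'
#' @param effects an [effect_spec()]; its `effects` field is ignored here.
#' @param planted named list per layer (`MG`, `MT`, `MP`): named numeric
#'   vectors KO id -> log2 ratio planted in group B.
#' @param n_kos number of KO ids.
#' @param features_per_ko features annotated to each KO, per layer.
#' @param n_pathway_nodes nodes in the generated pathway definition.
#' @return list: `layers` (named list of [abundance_matrix()]), `meta`,
#'   `pathway` ([pathway_definition()]), `truth` (data.frame
#'   layer/ko/log2_ratio), `ko_ec` (KO -> EC map).
#' @export
make_layer_matrices <- function(effects, planted = list(), n_kos = 30,
                                features_per_ko = 2, n_pathway_nodes = 12) {
  with_seed(effects$seed, {
    kos <- sprintf("K%05d", seq_len(n_kos))
    ecs <- stats::setNames(rep(NA_character_, n_kos), kos)
    half <- seq_len(floor(n_kos / 2))
    ecs[half] <- sprintf("1.1.%d.%d", (half - 1) %/% 10 + 1, (half - 1) %% 10 + 1)
    n <- 2 * effects$n_per_group
    groups <- rep(c("A", "B"), each = effects$n_per_group)
    samples <- sprintf("S%02d_%s", seq_len(n), groups)
    layers <- list(); truth <- list()
    for (layer in c("MG", "MT", "MP")) {
      nf <- n_kos * features_per_ko
      fid <- sprintf("%s_f%03d", layer, seq_len(nf))
      fko <- rep(kos, each = features_per_ko)
      basel <- stats::rlnorm(nf, meanlog = 5, sdlog = 1)
      vals <- matrix(0, nrow = nf, ncol = n, dimnames = list(fid, samples))
      eff <- planted[[layer]]
      for (s in seq_len(n)) {
        mu <- basel
        if (groups[s] == "B" && length(eff))
          mu[fko %in% names(eff)] <-
            mu[fko %in% names(eff)] * 2^eff[fko[fko %in% names(eff)]]
        vals[, s] <- stats::rlnorm(nf, meanlog = log(mu), sdlog = 0.2)
      }
      ann <- data.frame(row.names = fid, stringsAsFactors = FALSE)
      ann$ko <- lapply(fko, function(k) k)
      ann$ec <- lapply(fko, function(k)
        if (is.na(ecs[[k]])) character(0) else ecs[[k]])
      layers[[layer]] <- abundance_matrix(vals, layer = layer,
                                          annotations = ann)
      planted_r <- if (length(eff))
        ifelse(kos %in% names(eff), unname(eff[kos]), 0) else rep(0, n_kos)
      truth[[layer]] <- data.frame(layer = layer, ko = kos,
                                   log2_ratio = planted_r,
                                   stringsAsFactors = FALSE)
    }
    n_nodes <- min(n_pathway_nodes, n_kos)
    pool <- kos[seq_len(min(n_kos, n_nodes * 3))]
    node_kos <- split(pool, rep(seq_len(n_nodes), length.out = length(pool)))
    nodes <- data.frame(node = sprintf("node%02d", seq_len(n_nodes)),
                        label = sprintf("Step %d", seq_len(n_nodes)),
                        stringsAsFactors = FALSE)
    nodes$ko <- lapply(seq_len(n_nodes), function(i) unname(node_kos[[i]]))
    nodes$ec <- lapply(seq_len(n_nodes), function(i) {
      e <- ecs[node_kos[[i]]]
      unname(e[!is.na(e)])
    })
    md <- data.frame(group = groups,
                     age = round(stats::rnorm(n, 45, 10), 1),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     row.names = samples, stringsAsFactors = FALSE)
    list(layers = layers,
         meta = sample_metadata(md, "group", c("age", "sex")),
         pathway = pathway_definition("synthetic_pathway", nodes),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         ko_ec = ecs)
  })
}
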