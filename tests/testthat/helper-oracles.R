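# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately written from first principles (enumeration, set operations)
# and never call the implementation paths they check.

# small fixed taxonomy: root -> d1 -> {p1 -> {g1, g2}, p2 -> g3}
tiny_tree <- function() {
  taxonomy_tree(data.frame(
    id     = c("root", "d1", "p1", "p2", "g1", "g2", "g3"),
    name   = c("root", "Bacteria", "Phy1", "Phy2", "GenA", "GenB", "GenC"),
    rank   = c("root", "domain", "phylum", "phylum", "genus", "genus", "genus"),
    parent = c("root", "root", "d1", "d1", "p1", "p1", "p2"),
    stringsAsFactors = FALSE))
}

# random rooted tree: node i attaches to a uniformly chosen earlier node
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- c("root", sprintf("n%02d", seq_len(n_nodes - 1)))
  parent <- c("root",
              vapply(seq_len(n_nodes - 1), function(i)
                ids[sample(i, 1)], character(1)))
  taxonomy_tree(data.frame(id = ids, name = ids,
                           rank = c("root", rep("unranked", n_nodes - 1)),
                           parent = parent, stringsAsFactors = FALSE))
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

random_protein_db <- function(n, seed, len = c(20, 60)) {
  set.seed(seed)
  protein_db(sprintf("p%03d", seq_len(n)),
             sample(c("t1", "t2", "t3"), n, replace = TRUE),
             vapply(sample(len[1]:len[2], n, replace = TRUE), random_aa,
                    character(1)))
}

random_counts <- function(nf, ns, seed, max = 100) {
  set.seed(seed)
  matrix(sample(0:max, nf * ns, replace = TRUE), nrow = nf,
         dimnames = list(sprintf("f%02d", seq_len(nf)),
                         sprintf("s%02d", seq_len(ns))))
}

# ---- oracles -------------------------------------------------------------

# tryptic digest oracle: enumerate every substring and keep those whose
# ends coincide with cleavage boundaries and whose internal cleavage-site
# count is within the missed-cleavage budget
oracle_digest <- function(seq, params) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  is_site <- function(p)
    p >= 1 && p < n && chars[p] %in% c("K", "R") && chars[p + 1] != "P"
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!(i == 1 || is_site(i - 1))) next
      if (!(j == n || is_site(j))) next
      len <- j - i + 1
      if (len < params$min_len || len > params$max_len) next
      internal <- sum(vapply(i:(j - 1), is_site, logical(1)))
      if (j == i) internal <- 0
      if (internal > params$missed_cleavages) next
      out <- c(out, substr(seq, i, j))
    }
  }
  out
}

# LCA oracle: intersect root-path node sets, take the deepest survivor
# (walks parents itself, independent of tax_path)
oracle_lca <- function(tree, taxa) {
  walk <- function(id) {
    path <- id
    while (path[1] != tree$root)
      path <- c(tree$nodes[path[1], "parent"], path)
    path
  }
  paths <- lapply(unique(taxa), walk)
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(x) length(walk(x)), integer(1))
  common[which.max(depths)]
}

# split-node oracle: plain nested loops over nodes, layers and ids
oracle_split_nodes <- function(pathway, layers, combine = "mean") {
  nodes <- pathway$nodes$node
  out <- matrix(NA_real_, length(nodes), length(layers),
                dimnames = list(nodes, names(layers)))
  for (i in seq_along(nodes)) {
    ids <- unique(c(pathway$nodes$ko[[i]], pathway$nodes$ec[[i]]))
    for (j in seq_along(layers)) {
      vals <- c()
      for (id in ids) {
        rt <- layers[[j]]$ratios
        if (id %in% rt$id) vals <- c(vals, rt[rt$id == id, "log2_ratio"])
      }
      if (length(vals))
        out[i, j] <- if (combine == "mean") mean(vals) else
          vals[which.max(abs(vals))]
    }
  }
  out
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
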