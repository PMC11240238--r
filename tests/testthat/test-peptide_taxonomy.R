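test_that("tryptic digest applies the K/R-not-before-P rule", {
  p <- digest_params(missed_cleavages = 0, min_len = 3, max_len = 45,
                     equate_il = FALSE)
  expect_equal(digest("AAAKGGGRCCC", p), c("AAAK", "GGGR", "CCC"))
  expect_equal(digest("AAKPAA", p), "AAKPAA")        # no cleavage before P
  # missed cleavages emitted in position order, then increasing span
  p1 <- digest_params(missed_cleavages = 1, min_len = 3, max_len = 45,
                      equate_il = FALSE)
  expect_equal(digest("AAAKGGGRCCC", p1),
               c("AAAK", "AAAKGGGR", "GGGR", "GGGRCCC", "CCC"))
  # length bounds filter
  p2 <- digest_params(missed_cleavages = 0, min_len = 4, max_len = 45)
  expect_equal(digest("AAAKGGGRCCC", p2), c("AAAK", "GGGR"))
})

test_that("digest equals the brute-force substring oracle on random sequences", {
  set.seed(17)
  for (i in 1:40) {
    seq <- random_aa(sample(20:60, 1))
    p <- digest_params(missed_cleavages = sample(0:2, 1),
                       min_len = sample(3:6, 1), max_len = sample(15:30, 1),
                       equate_il = FALSE)
    expect_equal(sort(digest(seq, p)), sort(oracle_digest(seq, p)),
                 info = sprintf("seq %d: %s", i, seq))
  }
})

test_that("digest yield is monotone nondecreasing in missed cleavages", {
  set.seed(19)
  for (i in 1:10) {
    seq <- random_aa(60)
    counts <- vapply(0:3, function(mc)
      length(digest(seq, digest_params(missed_cleavages = mc, min_len = 3,
                                       max_len = 60))), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("peptide index unions provenance over containing proteins", {
  db <- protein_db(c("pA", "pB"), c("tA", "tB"),
                   c("GGGGGGGKAAAAAAAK", "CCCCCCCKAAAAAAAK"),
                   ec = list("1.1.1.1", "2.2.2.2"),
                   ko = list("K00001", character(0)))
  idx <- build_index(db, digest_params(missed_cleavages = 0, min_len = 7))
  shared <- idx$table["AAAAAAAK", ]
  expect_setequal(shared$taxa[[1]], c("tA", "tB"))
  expect_setequal(shared$proteins[[1]], c("pA", "pB"))
  expect_setequal(shared$ec[[1]], c("1.1.1.1", "2.2.2.2"))
  expect_equal(idx$table["GGGGGGGK", "taxa"][[1]], "tA")
  # single protein: every peptide maps to its taxon
  one <- build_index(db[1, ], digest_params())
  expect_true(all(vapply(one$table$taxa, identical, logical(1), "tA")))
})

test_that("index agrees with per-protein digestion + dictionary merge oracle", {
  db <- random_protein_db(15, seed = 23, len = c(30, 80))
  params <- digest_params(missed_cleavages = 1, min_len = 5, max_len = 30)
  idx <- build_index(db, params)
  oracle <- new.env()
  for (i in seq_len(nrow(db))) {
    peps <- unique(gsub("I", "L", digest(db$sequence[i], params)))
    for (pep in peps)
      assign(pep, unique(c(if (exists(pep, oracle)) get(pep, oracle),
                           db$taxon[i])), envir = oracle)
  }
  expect_setequal(rownames(idx$table), ls(oracle))
  for (pep in ls(oracle))
    expect_setequal(idx$table[pep, "taxa"][[1]], get(pep, oracle))
})

test_that("I/L collapse never increases the number of index keys", {
  for (seed in c(3, 8)) {
    db <- random_protein_db(10, seed = seed, len = c(40, 80))
    p_il <- digest_params(equate_il = TRUE, min_len = 5)
    p_no <- digest_params(equate_il = FALSE, min_len = 5)
    expect_lte(nrow(build_index(db, p_il)$table),
               nrow(build_index(db, p_no)$table))
  }
})

test_that("LCA follows the tree and equals the path-intersection oracle", {
  tree <- tiny_tree()
  expect_equal(lca(tree, "g1"), "g1")                 # singleton
  expect_equal(lca(tree, c("g1", "g2")), "p1")        # siblings -> parent
  expect_equal(lca(tree, c("g1", "g3")), "d1")
  expect_equal(lca(tree, c("g1", "g2", "g3")), "d1")
  expect_equal(lca(tree, c("g1", "p1")), "p1")        # ancestor-or-self
  expect_equal(lca(tree, c("g2", "g1")), lca(tree, c("g1", "g2")))
})

test_that("LCA equals brute force on 200+ random tree/subset cases", {
  cases <- 0
  for (seed in 1:12) {
    tree <- random_tree(sample(8:25, 1), seed = seed)
    set.seed(seed + 100)
    for (j in 1:20) {
      taxa <- sample(tree$nodes$id, sample(1:5, 1))
      expect_equal(lca(tree, taxa), oracle_lca(tree, taxa))
      cases <- cases + 1
    }
  }
  expect_gte(cases, 200)
})

test_that("assign_lca returns the unmapped marker for unknown peptides", {
  db <- protein_db("pA", "g1", "GGGGGGGKAAAAAAAK")
  idx <- build_index(db, digest_params(missed_cleavages = 0))
  tree <- tiny_tree()
  expect_equal(assign_lca("AAAAAAAK", idx, tree), "g1")
  expect_true(is.na(assign_lca("WWWWWWWK", idx, tree)))
})

test_that("aggregate_peptides builds the count matrix and tallies match", {
  ids <- data.frame(sample = c("s1", "s1", "s2"),
                    peptide = c("AAAAAAAK", "CCCCCCCK", "AAAAAAAK"),
                    count = c(3L, 2L, 5L), stringsAsFactors = FALSE)
  pt <- aggregate_peptides(ids)
  expect_equal(dim(pt$matrix$values), c(2L, 2L))
  expect_equal(pt$matrix$values["CCCCCCCK", "s2"], 0)  # absent -> 0
  expect_equal(colSums(pt$matrix$values), c(s1 = 5, s2 = 5))
  dup <- rbind(ids, ids[1, ])
  expect_warning(pt2 <- aggregate_peptides(dup), "summed")
  expect_equal(pt2$matrix$values["AAAAAAAK", "s1"], 6)
  expect_error(aggregate_peptides(transform(ids, count = c(1, -2, 3))),
               class = "metaomix_value_error")
  # row/column sums match input tallies on a random fixture
  set.seed(31)
  rnd <- data.frame(sample = sample(paste0("s", 1:4), 50, replace = TRUE),
                    peptide = sample(vapply(rep(10, 12), random_aa,
                                            character(1)), 50, replace = TRUE),
                    count = sample(1:9, 50, replace = TRUE))
  rnd <- stats::aggregate(count ~ sample + peptide, rnd, sum)
  pt3 <- aggregate_peptides(rnd)
  expect_equal(sum(pt3$matrix$values), sum(rnd$count))
  ss <- sort(unique(rnd$sample))
  expect_equal(as.numeric(colSums(pt3$matrix$values)[ss]),
               as.numeric(tapply(rnd$count, rnd$sample, sum)[ss]))
})

test_that("taxon tables credit rank ancestors and conserve totals", {
  tree <- tiny_tree()
  db <- protein_db(c("p1", "p2", "p3"), c("g1", "g2", "g3"),
                   c("GGGGGGGKAAAAAAAK",   # GGGGGGGK unique to g1
                     "AAAAAAAKCCCCCCCK",   # AAAAAAAK shared g1/g2 -> LCA p1
                     "WWYYWWYYK"))
  idx <- build_index(db, digest_params(missed_cleavages = 0))
  ids <- data.frame(sample = "s1",
                    peptide = c("GGGGGGGK", "AAAAAAAK", "WWYYWWYYK"),
                    count = c(4L, 2L, 1L), stringsAsFactors = FALSE)
  pt <- aggregate_peptides(ids, idx, tree)
  expect_equal(pt$peptide_info["AAAAAAAK", "lca"], "p1")
  tt <- taxon_table_from_peptides(pt, tree, "genus")
  expect_equal(tt$values["GenA", "s1"], 4)
  expect_equal(tt$values["GenC", "s1"], 1)
  # LCA above genus pools into the rank-specific unclassified bucket
  expect_equal(tt$values["Unclassified_at_genus", "s1"], 2)
  expect_equal(sum(tt$values), sum(pt$matrix$values))  # conservation
  # at phylum rank the shared peptide is classified
  tp <- taxon_table_from_peptides(pt, tree, "phylum")
  expect_equal(tp$values["Phy1", "s1"], 6)
})

test_that("peptides from taxon-unique proteins get consistent LCAs end-to-end", {
  set.seed(55)
  tree <- tiny_tree()
  dbs <- lapply(c("g1", "g2", "g3"), function(tx)
    protein_db(sprintf("%s_p%d", tx, 1:4), rep(tx, 4),
               vapply(rep(60, 4), random_aa, character(1))))
  db <- do.call(rbind, lapply(dbs, function(d) { class(d) <- "data.frame"; d }))
  class(db) <- c("protein_db", "data.frame")
  idx <- build_index(db, digest_params())
  for (tx in c("g1", "g2", "g3")) {
    sub <- db[db$taxon == tx, ]
    peps <- unique(unlist(lapply(sub$sequence, digest, params = digest_params())))
    for (pep in utils::head(peps, 10)) {
      got <- assign_lca(pep, idx, tree)
      # generating taxon must be the LCA itself or a descendant of it
      expect_true(got %in% tax_path(tree, tx))
    }
  }
})
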