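two_group_meta <- function(n_per_group, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  md <- data.frame(group = rep(c("A", "B"), each = n_per_group),
                   age = rnorm(n, 45, 10),
                   row.names = sprintf("s%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  sample_metadata(md, "group", character(0))
}

test_that("prevalence filter matches a brute-force predicate scan", {
  cfg <- da_config("group", min_prevalence = 0.1)
  set.seed(2)
  vals <- random_counts(30, 20, seed = 2, max = 3)   # sparse
  m <- abundance_matrix(vals)
  res <- filter_features(m, cfg)
  brute_keep <- rownames(vals)[rowMeans(vals > 0) >= 0.1]
  expect_equal(rownames(res$matrix$values), brute_keep)
  expect_setequal(res$ledger$feature, setdiff(rownames(vals), brute_keep))
  # min_prevalence = 0 is the identity
  cfg0 <- da_config("group", min_prevalence = 0)
  expect_equal(filter_features(m, cfg0)$matrix$values, vals)
  # feature present in 1/20 samples is removed at 0.1
  one <- vals; one["f01", ] <- 0; one["f01", 3] <- 5
  res1 <- filter_features(abundance_matrix(one), cfg)
  expect_true("f01" %in% res1$ledger$feature)
})

test_that("TSS, log and CLR transforms behave as defined", {
  cfg_tss <- da_config("group", normalization = "TSS", transform = "none")
  m <- abundance_matrix(matrix(c(2, 2), 2, dimnames = list(c("f1", "f2"), "s1")))
  expect_equal(normalize_transform(m, cfg_tss)[, 1], c(f1 = 0.5, f2 = 0.5))
  # CLR column means are zero
  cfg_clr <- da_config("group", normalization = "none", transform = "CLR")
  x <- abundance_matrix(random_counts(10, 6, seed = 4) + 1)
  clr <- normalize_transform(x, cfg_clr)
  expect_true(all(abs(colMeans(clr)) < 1e-10))
  # strictly positive data: log transform is the plain log2
  cfg_log <- da_config("group", normalization = "none", transform = "log")
  expect_equal(normalize_transform(x, cfg_log), log2(x$values))
  # with zeros: half the smallest nonzero value is added first
  xz <- x$values; xz[1, 1] <- 0
  direct <- log2(xz + 0.5 * min(xz[xz > 0]))
  expect_equal(normalize_transform(abundance_matrix(xz), cfg_log), direct)
  # zero-total sample under TSS errors with the sample name
  z <- abundance_matrix(matrix(c(1, 0), 1, 2,
                               dimnames = list("f1", c("ok", "empty"))))
  expect_error(normalize_transform(z, cfg_tss), "empty",
               class = "metaomix_value_error")
})

test_that("BH adjustment matches hand computation and propagates NaN", {
  expect_equal(bh_adjust(0.2), 0.2)                       # single p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, NA, 0.04, 0.9)
  q <- bh_adjust(p)
  expect_true(is.nan(q[2]))
  expect_equal(q[-2], p.adjust(p[-2], "BH"))              # NA excluded from m
  set.seed(6)
  ps <- runif(50)
  qs <- bh_adjust(ps)
  expect_true(all(diff(qs[order(ps)]) >= -1e-15))         # monotone in p order
  expect_error(bh_adjust(c(0.5, 1.2)), class = "metaomix_value_error")
})

test_that("two-group fit reproduces the classical equal-variance t-test", {
  meta <- two_group_meta(15, seed = 7)
  set.seed(8)
  vals <- matrix(rnorm(40 * 30, mean = 10), nrow = 40,
                 dimnames = list(sprintf("f%02d", 1:40), rownames(meta$data)))
  m <- abundance_matrix(vals)
  cfg <- da_config("group", normalization = "none", transform = "none",
                   min_prevalence = 0)
  fit <- fit_models(m, meta, cfg)
  res <- fit$results[fit$results$term == "groupB", ]
  for (f in rownames(vals)) {
    tt <- t.test(vals[f, meta$data$group == "B"],
                 vals[f, meta$data$group == "A"], var.equal = TRUE)
    expect_equal(res$p_value[res$feature == f], tt$p.value, tolerance = 1e-12)
    expect_equal(res$estimate[res$feature == f],
                 unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("noiseless group effect gives the exact coefficient and p ~ 0", {
  meta <- two_group_meta(10)
  vals <- matrix(5, nrow = 2, ncol = 20,
                 dimnames = list(c("flat", "hit"), rownames(meta$data)))
  vals["hit", meta$data$group == "B"] <- 8
  set.seed(9)
  vals["flat", ] <- runif(20, 1, 9)
  cfg <- da_config("group", normalization = "none", transform = "none",
                   min_prevalence = 0)
  fit <- fit_models(abundance_matrix(vals), meta, cfg)
  hit <- fit$results[fit$results$feature == "hit" &
                       fit$results$term == "groupB", ]
  expect_equal(hit$estimate, 3)
  expect_lt(hit$p_value, 1e-12)
})

test_that("a confounder carrying the whole effect zeroes the phenotype term", {
  set.seed(10)
  n <- 60
  z <- rnorm(n)                       # confounder
  grp <- ifelse(z + rnorm(n, sd = 0.3) > 0, "B", "A")
  y <- matrix(rep(3 * z, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), sprintf("s%02d", 1:n)))
  y <- y + matrix(rnorm(2 * n, sd = 0.05), nrow = 2)
  md <- data.frame(group = grp, z = z, row.names = colnames(y))
  m <- abundance_matrix(y - min(y) + 1)
  cfg_adj <- da_config("group", covariates = "z", normalization = "none",
                       transform = "none", min_prevalence = 0)
  cfg_raw <- da_config("group", normalization = "none", transform = "none",
                       min_prevalence = 0)
  fit_adj <- fit_models(m, sample_metadata(md, "group", "z"), cfg_adj)
  fit_raw <- fit_models(m, sample_metadata(md, "group"), cfg_raw)
  est_adj <- fit_adj$results$estimate[fit_adj$results$term == "groupB"]
  est_raw <- fit_raw$results$estimate[fit_raw$results$term == "groupB"]
  expect_true(all(abs(est_adj) < 0.2))
  expect_true(all(abs(est_raw) > 1))        # unadjusted fit is badly biased
})

test_that("degenerate designs and features are reported, not silently fit", {
  meta <- two_group_meta(10)
  md <- meta$data
  md$copy <- ifelse(md$group == "A", 0, 1)  # exact duplicate of phenotype
  vals <- abundance_matrix(random_counts(5, 20, seed = 11) + 1)
  colnames(vals$values) <- rownames(md)
  cfg <- da_config("group", covariates = "copy", normalization = "none",
                   transform = "none", min_prevalence = 0)
  expect_error(fit_models(vals, sample_metadata(md, "group", "copy"), cfg),
               "copy", class = "metaomix_value_error")
  # constant feature is skipped with a ledger entry
  vals$values[1, ] <- 7
  cfg2 <- da_config("group", normalization = "none", transform = "none",
                    min_prevalence = 0)
  fit <- fit_models(vals, meta, cfg2)
  expect_true(rownames(vals$values)[1] %in% fit$ledger$feature)
  expect_false(rownames(vals$values)[1] %in% fit$results$feature)
})

test_that("planted effects are recovered with q-value support", {
  set.seed(12)
  n <- 40; nf <- 60
  meta <- two_group_meta(n / 2, seed = 12)
  delta <- 1.5
  vals <- matrix(rnorm(nf * n, mean = 8), nrow = nf,
                 dimnames = list(sprintf("f%02d", 1:nf), rownames(meta$data)))
  hits <- sprintf("f%02d", 1:6)
  vals[hits, meta$data$group == "B"] <- vals[hits, meta$data$group == "B"] + delta
  cfg <- da_config("group", normalization = "none", transform = "none",
                   min_prevalence = 0)
  fit <- fit_models(abundance_matrix(vals - min(vals) + 1), meta, cfg)
  res <- fit$results[fit$results$term == "groupB", ]
  expect_true(all(res$q_value[res$feature %in% hits] < 0.05))
  expect_equal(mean(res$estimate[res$feature %in% hits]), delta,
               tolerance = 0.15)
})

test_that("da_plot_data returns group-wise abundances for one feature", {
  meta <- two_group_meta(3)
  m <- abundance_matrix(random_counts(4, 6, seed = 13) + 1)
  colnames(m$values) <- rownames(meta$data)
  pd <- da_plot_data(m, meta, "f02")
  expect_equal(nrow(pd), 6)
  expect_equal(pd$abundance, unname(m$values["f02", pd$sample]))
  expect_equal(sort(unique(pd$group)), c("A", "B"))
  expect_error(da_plot_data(m, meta, "nope"), class = "metaomix_value_error")
})
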