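# Per-feature linear-model differential abundance: prevalence filtering,
# normalization/transform, ordinary-least-squares fits of transformed
# abundance on phenotype + covariates, and Benjamini-Hochberg correction
# across features within each model term.

#' Differential-abundance configuration
#'
#' Defaults follow common microbiome practice: total-sum scaling, log2
#' transform with a pseudocount of half the smallest nonzero value (the
#' `pseudocount` argument is the multiplier on that smallest nonzero
#' value, so 0.5 = "half-min"; it is only applied when the matrix contains
#' zeros), and a 10% prevalence gate.
#'
#' @param phenotype metadata column tested.
#' @param covariates metadata columns adjusted for.
#' @param normalization `"TSS"` or `"none"`.
#' @param transform `"log"` (log2), `"CLR"` or `"none"`.
#' @param pseudocount multiplier on the smallest nonzero value, added
#'   before log/CLR when zeros are present; must be > 0.
#' @param min_prevalence minimum fraction of samples in which a feature
#'   must exceed `min_abundance`.
#' @param min_abundance abundance threshold defining "present".
#' @param reference optional named list: reference level per categorical
#'   metadata column.
#' @return A `da_config` object.
#' @export
da_config <- function(phenotype, covariates = character(0),
                      normalization = c("TSS", "none"),
                      transform = c("log", "CLR", "none"),
                      pseudocount = 0.5, min_prevalence = 0.1,
                      min_abundance = 0, reference = NULL) {
  stopifnot(pseudocount > 0, min_prevalence >= 0, min_prevalence <= 1)
  structure(list(phenotype = phenotype, covariates = covariates,
                 normalization = match.arg(normalization),
                 transform = match.arg(transform),
                 pseudocount = pseudocount, min_prevalence = min_prevalence,
                 min_abundance = min_abundance, reference = reference),
            class = "da_config")
}

#' Prevalence/abundance feature filter
#'
#' Keeps features whose abundance exceeds `min_abundance` in at least
#' `min_prevalence` of samples; removals are recorded in a ledger.
#'
#' @param m an [abundance_matrix()].
#' @param cfg a [da_config()].
#' @return list with filtered `matrix` and `ledger` (data.frame
#'   feature/reason).
#' @export
filter_features <- function(m, cfg) {
  prev <- rowMeans(m$values > cfg$min_abundance)
  keep <- prev >= cfg$min_prevalence
  if (!any(keep))
    mox_stop("all features removed by the prevalence filter; lower min_prevalence or min_abundance",
             "metaomix_value_error")
  ledger <- data.frame(
    feature = rownames(m$values)[!keep],
    reason = sprintf("prevalence %.3f < %.3f", prev[!keep], cfg$min_prevalence),
    stringsAsFactors = FALSE)
  ann <- if (is.null(m$annotations)) NULL else
    m$annotations[keep, , drop = FALSE]
  list(matrix = abundance_matrix(m$values[keep, , drop = FALSE],
                                 layer = m$layer, annotations = ann),
       ledger = ledger)
}

#' Normalize and transform an abundance matrix
#'
#' TSS scales each sample to sum 1. The log transform is log2; CLR is
#' per-sample log2 values minus their mean (column means of the result are
#' 0). When zeros are present, `pseudocount * min(nonzero)` is added to
#' the whole matrix first; on strictly positive data no pseudocount is
#' added.
#'
#' @param m an [abundance_matrix()] or numeric matrix.
#' @param cfg a [da_config()].
#' @return Numeric matrix (same dimnames) on the transformed scale.
#' @export
normalize_transform <- function(m, cfg) {
  x <- if (inherits(m, "abundance_matrix")) m$values else as.matrix(m)
  if (cfg$normalization == "TSS") {
    totals <- colSums(x)
    zero <- colnames(x)[totals == 0]
    if (length(zero))
      mox_stop(sprintf("zero-total sample(s) under TSS: %s",
                       join_semicolon(zero)), "metaomix_value_error")
    x <- sweep(x, 2, totals, "/")
  }
  if (cfg$transform %in% c("log", "CLR")) {
    if (any(x == 0)) {
      nz <- x[x > 0]
      if (length(nz) == 0)
        mox_stop("all-zero matrix cannot be log-transformed", "metaomix_value_error")
      x <- x + cfg$pseudocount * min(nz)
    }
    x <- log2(x)
    if (cfg$transform == "CLR") x <- sweep(x, 2, colMeans(x), "-")
  }
  x
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment across the non-missing p-values; NaN/NA
#' p-values propagate as NaN and do not count toward the number of tests.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA/NaN allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    mox_stop("p-values must lie in [0, 1]", "metaomix_value_error")
  q <- rep(NaN, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Fit per-feature linear models
#'
#' Applies the configured prevalence filter and normalization/transform,
#' then fits one ordinary-least-squares model per feature of transformed
#' abundance on phenotype + covariates. Coefficients get two-sided t-tests;
#' q-values are Benjamini-Hochberg within each model term across features.
#' Features with zero variance after transformation are skipped and
#' recorded in the ledger.
#'
#' @param m an [abundance_matrix()] (features x samples).
#' @param meta a [sample_metadata()] covering the matrix's samples.
#' @param cfg a [da_config()].
#' @return A `da_result`: `results` (data.frame feature/term/estimate/
#'   std_error/p_value/q_value/n), `ledger` (removed features and why),
#'   and the design info.
#' @export
fit_models <- function(m, meta, cfg) {
  stopifnot(inherits(m, "abundance_matrix"), inherits(meta, "sample_metadata"))
  samples <- colnames(m$values)
  if (!all(samples %in% rownames(meta$data)))
    mox_stop("metadata missing for some samples", "metaomix_value_error")
  md <- meta$data[samples, , drop = FALSE]
  for (col in c(cfg$phenotype, cfg$covariates)) {
    if (is.character(md[[col]])) md[[col]] <- factor(md[[col]])
    if (is.factor(md[[col]]) && !is.null(cfg$reference[[col]]))
      md[[col]] <- stats::relevel(md[[col]], ref = cfg$reference[[col]])
  }
  form <- stats::reformulate(c(cfg$phenotype, cfg$covariates))
  X <- stats::model.matrix(form, data = md)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    mox_stop(sprintf("design matrix rank deficient; collinear term(s): %s",
                     join_semicolon(dropped)), "metaomix_value_error")
  }
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 3)
    mox_stop(sprintf("only %d residual degrees of freedom (need >= 3)", df_resid),
             "metaomix_value_error")

  filt <- filter_features(m, cfg)
  Y <- normalize_transform(filt$matrix, cfg)

  const <- apply(Y, 1, function(r) stats::var(r) == 0)
  ledger <- filt$ledger
  if (any(const))
    ledger <- rbind(ledger, data.frame(
      feature = rownames(Y)[const],
      reason = "constant after transformation", stringsAsFactors = FALSE))
  Y <- Y[!const, , drop = FALSE]
  if (nrow(Y) == 0)
    mox_stop("no variable features left to model", "metaomix_value_error")

  yt <- t(Y)                                   # samples x features
  coefs <- qr.coef(qrX, yt)                    # terms x features
  resid <- yt - X %*% coefs
  sigma2 <- colSums(resid^2) / df_resid
  xtx_inv_diag <- diag(solve(crossprod(X)))    # diag of (X'X)^-1
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df = df_resid)

  terms <- colnames(X)
  res <- do.call(rbind, lapply(seq_along(terms), function(j) {
    data.frame(feature = rownames(Y), term = terms[j],
               estimate = coefs[j, ], std_error = se[j, ],
               p_value = pval[j, ], q_value = bh_adjust(pval[j, ]),
               n = nrow(X), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  structure(list(results = res, ledger = ledger, formula = form,
                 terms = terms, df_resid = df_resid, cfg = cfg),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("<da_result> %d features x %d terms (%d filtered)\n",
              length(unique(x$results$feature)), length(x$terms),
              nrow(x$ledger)))
  invisible(x)
}

#' Group-wise abundance data for one feature (boxplot-ready)
#'
#' @param m an [abundance_matrix()] (typically relative abundances).
#' @param meta a [sample_metadata()].
#' @param feature feature id.
#' @return data.frame with columns `sample`, `group`, `abundance`.
#' @export
da_plot_data <- function(m, meta, feature) {
  if (!feature %in% rownames(m$values))
    mox_stop(sprintf("unknown feature '%s'", feature), "metaomix_value_error")
  samples <- colnames(m$values)
  data.frame(sample = samples,
             group = as.character(meta$data[samples, meta$phenotype]),
             abundance = m$values[feature, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a da_result as TSVs
#' @param result a [fit_models()] result.
#' @param prefix output path prefix (`<prefix>_results.tsv`,
#'   `<prefix>_filtered.tsv`).
#' @export
write_da_result <- function(result, prefix) {
  utils::write.table(result$results, paste0(prefix, "_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$ledger, paste0(prefix, "_filtered.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
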