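# Joint multi-block ordination: all omics layers on a single ordination
# plot. Each block is CLR-transformed, feature-centered, scaled to unit
# total variance, concatenated, and decomposed by SVD. This is a
# transparent multi-block principal-component ordination — methodologically
# different from model-based compositional integration (e.g. the combi
# estimator) but serving the same joint-visualization role.

#' Multi-block ordination of omics layers
#'
#' Per block: transform (CLR by default, with a half-min pseudocount when
#' zeros are present), center each feature across samples, scale the block
#' to unit total variance so no layer dominates, concatenate along
#' features, then SVD. Sample scores are the left singular vectors scaled
#' by the singular values; loadings are split back per block. Axis signs
#' are fixed by making the largest-magnitude loading on each axis
#' positive.
#'
#' @param layers named list of [abundance_matrix()] objects (or plain
#'   features x samples matrices) sharing a sample set; the intersection
#'   is taken with a warning when they differ.
#' @param meta optional [sample_metadata()]; numeric covariates get
#'   correlation arrows, categorical ones level centroids.
#' @param d number of ordination axes (default 2).
#' @param transform per-block transform: `"CLR"`, `"log"`, or `"none"`.
#' @param scale_blocks scale each block to unit total variance.
#' @return An `ordination_result`: `scores` (samples x d), `loadings`
#'   (per-block list, features x d), `block_weights`,
#'   `explained_variance` (fractions, all axes), `covariates` (arrows and
#'   centroids), `singular_values`.
#' @export
multiblock_ordinate <- function(layers, meta = NULL, d = 2,
                                transform = c("CLR", "log", "none"),
                                scale_blocks = TRUE) {
  transform <- match.arg(transform)
  stopifnot(length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("block", seq_along(layers))
  mats <- lapply(layers, function(l)
    if (inherits(l, "abundance_matrix")) l$values else as.matrix(l))
  shared <- Reduce(intersect, lapply(mats, colnames))
  if (any(vapply(mats, ncol, integer(1)) != length(shared)))
    warning(sprintf("layers differ in samples; using the %d shared samples",
                    length(shared)))
  if (length(shared) < 3)
    mox_stop("need at least 3 shared samples", "metaomix_value_error")
  if (any(vapply(mats, nrow, integer(1)) < 2))
    mox_stop("each block needs at least 2 features", "metaomix_value_error")
  n <- length(shared)
  blocks <- list(); weights <- numeric(0)
  for (b in names(mats)) {
    x <- mats[[b]][, shared, drop = FALSE]
    if (transform %in% c("CLR", "log")) {
      if (any(x == 0)) {
        nzmin <- min(x[x > 0])
        x <- x + nzmin / 2
      }
      x <- log2(x)
      if (transform == "CLR") x <- sweep(x, 2, colMeans(x), "-")
    }
    xs <- t(x)                                   # samples x features
    xs <- sweep(xs, 2, colMeans(xs), "-")        # center each feature
    w <- 1
    if (scale_blocks) {
      tv <- sum(xs^2) / (n - 1)                  # total variance of block
      if (tv > 0) w <- 1 / sqrt(tv)
    }
    blocks[[b]] <- xs * w
    weights[b] <- w
  }
  X <- do.call(cbind, blocks)
  sv <- svd(X)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  d_eff <- min(d, r)
  U <- sv$u[, seq_len(d_eff), drop = FALSE]
  V <- sv$v[, seq_len(d_eff), drop = FALSE]
  dv <- sv$d[seq_len(d_eff)]
  for (j in seq_len(d_eff)) {                    # deterministic sign
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(dv, nrow = d_eff)
  dimnames(scores) <- list(shared, paste0("axis", seq_len(d_eff)))
  feat_ids <- unlist(lapply(blocks, colnames), use.names = FALSE)
  rownames(V) <- feat_ids
  colnames(V) <- paste0("axis", seq_len(d_eff))
  offsets <- cumsum(c(0, vapply(blocks, ncol, integer(1))))
  loadings <- stats::setNames(lapply(seq_along(blocks), function(i)
    V[(offsets[i] + 1):offsets[i + 1], , drop = FALSE]), names(blocks))
  expl <- sv$d[seq_len(r)]^2 / sum(sv$d[seq_len(r)]^2)
  covs <- project_covariates(meta, scores)
  structure(list(scores = scores, loadings = loadings,
                 block_weights = weights, explained_variance = expl,
                 covariates = covs, singular_values = sv$d[seq_len(r)],
                 d = d_eff, transform = transform),
            class = "ordination_result")
}

project_covariates <- function(meta, scores) {
  if (is.null(meta)) return(NULL)
  cols <- unique(c(meta$phenotype, meta$covariates))
  md <- meta$data[rownames(scores), cols, drop = FALSE]
  arrows <- list(); centroids <- list()
  for (col in cols) {
    v <- md[[col]]
    if (is.numeric(v)) {
      arrows[[col]] <- data.frame(
        covariate = col, t(stats::cor(v, scores)), stringsAsFactors = FALSE)
    } else {
      cen <- apply(scores, 2, function(ax) tapply(ax, as.character(v), mean))
      centroids[[col]] <- data.frame(
        covariate = col, level = rownames(cen), cen,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  list(arrows = if (length(arrows)) do.call(rbind, c(arrows, list(make.row.names = FALSE))) else NULL,
       centroids = if (length(centroids)) do.call(rbind, c(centroids, list(make.row.names = FALSE))) else NULL)
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d blocks, d=%d (%.1f%% + %.1f%% variance)\n",
              nrow(x$scores), length(x$loadings), x$d,
              100 * x$explained_variance[1],
              if (length(x$explained_variance) > 1) 100 * x$explained_variance[2] else 0))
  invisible(x)
}

#' Biplot-ready tables from an ordination
#'
#' @param result a [multiblock_ordinate()] result.
#' @param top_k number of features kept per block, by loading norm (all
#'   features when `top_k` exceeds the block size).
#' @param meta optional [sample_metadata()] to attach a phenotype `group`
#'   column to the sample table.
#' @return list of data.frames: `samples`, `features` (with `block`
#'   column), `arrows`, `centroids`.
#' @export
biplot_data <- function(result, top_k = 10, meta = NULL) {
  samples <- data.frame(sample = rownames(result$scores), result$scores,
                        row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(meta))
    samples$group <- as.character(meta$data[samples$sample, meta$phenotype])
  feats <- do.call(rbind, lapply(names(result$loadings), function(b) {
    L <- result$loadings[[b]]
    norms <- sqrt(rowSums(L^2))
    ord <- order(-norms, rownames(L))
    keep <- ord[seq_len(min(top_k, nrow(L)))]
    data.frame(block = b, feature = rownames(L)[keep], L[keep, , drop = FALSE],
               norm = norms[keep], row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(samples = samples, features = feats,
       arrows = result$covariates$arrows,
       centroids = result$covariates$centroids)
}

#' Joint ordination biplot
#' @param result a [multiblock_ordinate()] result.
#' @param meta optional [sample_metadata()] for group coloring.
#' @param top_k features labeled per block.
#' @return A ggplot object.
#' @export
plot_ordination <- function(result, meta = NULL, top_k = 5) {
  bd <- biplot_data(result, top_k = top_k, meta = meta)
  sc <- max(abs(bd$samples$axis1), abs(bd$samples$axis2)) /
    max(abs(bd$features$axis1), abs(bd$features$axis2), 1e-12)
  p <- ggplot2::ggplot(bd$samples, ggplot2::aes(x = axis1, y = axis2))
  p <- if (!is.null(bd$samples$group))
    p + ggplot2::geom_point(ggplot2::aes(color = group)) else
    p + ggplot2::geom_point()
  p + ggplot2::geom_text(data = bd$features, size = 2.5,
                         ggplot2::aes(x = axis1 * sc * 0.8,
                                      y = axis2 * sc * 0.8,
                                      label = feature)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * result$explained_variance[1]),
      y = sprintf("Axis 2 (%.1f%%)",
                  100 * result$explained_variance[min(2, length(result$explained_variance))])) +
    ggplot2::theme_minimal()
}
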