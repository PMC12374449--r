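# Species x gene Pearson correlation between bacterial presence and host
# expression, reduced by PCA; component scores, loadings and top gene
# contributions.

#' Correlation between bacterial presence and gene expression
#'
#' Pearson correlation between the binary presence of each species
#' (same exposure definition as the risk screen: at least one read) and the
#' normalized expression of each gene, across spots. Restrict to CD spots
#' before calling (use [cd_spots()]); entries where either vector is
#' constant are undefined and masked.
#'
#' @param expr genes x spots normalized matrix.
#' @param exposure spots x species logical (or count) matrix aligned with
#'   the columns of `expr`.
#' @return list of class `sb_correlation`: `r` (species x genes Pearson
#'   matrix, `NA` where undefined) and `mask` (logical matrix of undefined
#'   entries).
#' @export
presence_expression_correlation <- function(expr, exposure) {
  stopifnot(nrow(exposure) == ncol(expr))
  if (ncol(expr) < 3) stop("need at least 3 spots to correlate")
  presence <- (as.matrix(exposure) > 0) * 1
  r <- suppressWarnings(cor(presence, t(expr)))  # species x genes
  mask <- is.na(r)
  structure(list(r = r, mask = mask), class = "sb_correlation")
}

#' PCA of the presence-expression correlation matrix
#'
#' Masked (undefined) correlations are imputed as 0 -- the no-association
#' neutral value -- gene columns are centered (no rescaling: entries are
#' already on the common correlation scale) and the matrix is decomposed by
#' SVD. Component signs follow a deterministic convention: the gene loading
#' with the largest absolute value is made positive on every component.
#'
#' @param corr an `sb_correlation` (or a plain species x genes matrix).
#' @param n_components number of components to keep (clipped with a warning
#'   if it exceeds the matrix rank limit).
#' @param top_genes number of top-contributing genes (largest absolute
#'   loading) reported per component (default 20).
#' @return list of class `sb_pca`: `scores` (species x components),
#'   `loadings` (genes x components), `explained_variance_ratio`,
#'   `top_contributions` (tibble: component, rank, gene, loading,
#'   abs_loading), `center` (gene means used for centering).
#' @export
pca_on_correlations <- function(corr, n_components = 10, top_genes = 20) {
  x <- if (inherits(corr, "sb_correlation")) corr$r else as.matrix(corr)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 species and 2 genes")
  x[is.na(x)] <- 0
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax) {
    warning(sprintf("n_components clipped from %d to %d", n_components, kmax))
    n_components <- kmax
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  # deterministic sign convention
  for (j in k) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  top <- do.call(rbind, lapply(k, function(j) {
    ord <- order(-abs(loadings[, j]))[seq_len(min(top_genes, nrow(loadings)))]
    tibble::tibble(component = paste0("PC", j),
                   rank = seq_along(ord),
                   gene = rownames(loadings)[ord],
                   loading = unname(loadings[ord, j]),
                   abs_loading = unname(abs(loadings[ord, j])))
  }))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[k],
                 top_contributions = top, center = pc$center),
            class = "sb_pca")
}

#' @export
print.sb_pca <- function(x, ...) {
  cat(sprintf("<sb_pca> %d species x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Do principal components separate beneficial from pathogenic species?
#'
#' For every component: group means of the species scores and a two-sided
#' rank-sum p-value comparing the two label groups, with the
#' best-separating component flagged. Groups with fewer than 2 members make
#' separation not computable.
#'
#' @param pca an `sb_pca` from [pca_on_correlations()].
#' @param labels named character vector over (a subset of) the scored
#'   species with values `"beneficial"` or `"pathogenic"`; unlabeled
#'   species are ignored.
#' @return tibble: component, n_beneficial, n_pathogenic, mean_beneficial,
#'   mean_pathogenic, z, p, best (logical; `NA` p never flagged).
#' @export
component_separation_report <- function(pca, labels) {
  labels <- labels[names(labels) %in% rownames(pca$scores)]
  ben <- names(labels)[labels == "beneficial"]
  pat <- names(labels)[labels == "pathogenic"]
  computable <- length(ben) >= 2 && length(pat) >= 2
  if (!computable)
    message("component_separation_report: a group has < 2 members; p-values not computed")
  out <- lapply(seq_len(ncol(pca$scores)), function(j) {
    sb <- pca$scores[ben, j]; sp <- pca$scores[pat, j]
    t <- if (computable) rank_sum_test(sb, sp) else list(z = NA_real_, p = NA_real_)
    tibble::tibble(component = colnames(pca$scores)[j],
                   n_beneficial = length(ben), n_pathogenic = length(pat),
                   mean_beneficial = if (length(ben)) mean(sb) else NA_real_,
                   mean_pathogenic = if (length(pat)) mean(sp) else NA_real_,
                   z = t$z, p = t$p)
  })
  out <- do.call(rbind, out)
  out$best <- FALSE
  if (any(!is.na(out$p)))
    out$best[which.min(out$p)] <- TRUE
  out
}
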