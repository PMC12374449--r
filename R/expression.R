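# Per-species differential gene expression by bacterial exposure,
# cross-species consistency scoring, and the beneficial-versus-pathogenic
# pair comparison.

#' Depth-normalize and log-transform host expression
#'
#' Scales each spot's gene counts to a common target sum and applies
#' `log(1 + x)`. Genes expressed (count > 0) in fewer than `min_spots`
#' spots are dropped, as are spots with zero total counts (with a warning).
#'
#' @param dataset an [sb_dataset] (QC-filtered).
#' @param target_sum common per-spot depth after scaling (default 1e4).
#' @param min_spots minimum number of expressing spots for a gene to be
#'   kept (default 10).
#' @param include_mito whether mitochondrial genes enter the normalized
#'   matrix (default `FALSE`: they are QC metrics, not response genes).
#' @return genes x spots dense numeric matrix with attributes
#'   `dropped_genes` and `dropped_spots`.
#' @export
normalize_expression <- function(dataset, target_sum = 1e4, min_spots = 10,
                                 include_mito = FALSE) {
  counts <- dataset$host_counts
  if (!include_mito)
    counts <- counts[!dataset$genes$is_mito, , drop = FALSE]
  totals <- Matrix::colSums(counts)
  drop_spots <- totals == 0
  if (any(drop_spots)) {
    warning(sprintf("dropping %d spot(s) with zero total counts", sum(drop_spots)))
    counts <- counts[, !drop_spots, drop = FALSE]
    totals <- totals[!drop_spots]
  }
  n_expressing <- Matrix::rowSums(counts > 0)
  drop_genes <- n_expressing < min_spots
  if (any(drop_genes))
    message(sprintf("normalize_expression: dropping %d gene(s) expressed in < %d spots",
                    sum(drop_genes), min_spots))
  counts <- counts[!drop_genes, , drop = FALSE]
  mat <- as.matrix(counts)
  mat <- mat * rep(target_sum / totals, each = nrow(mat))
  mat <- log1p(mat)
  attr(mat, "dropped_genes") <- names(which(drop_genes))
  attr(mat, "dropped_spots") <- names(which(drop_spots))
  mat
}

#' Per-gene differential expression by bacterial exposure
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test per gene between exposed
#' and unexposed spots, with BH correction across genes. `z` is the signed
#' standard-normal-scale statistic, positive when expression is higher in
#' exposed spots. The comparison is skipped (returns `NULL` with a message)
#' when either group has fewer than `min_group_size` spots.
#'
#' @param expr genes x spots normalized matrix ([normalize_expression()]).
#' @param exposed logical vector over the columns of `expr`.
#' @param min_group_size minimum spots per group (default 10).
#' @return tibble (gene, z, p, q), or `NULL` if skipped.
#' @export
dge_by_exposure <- function(expr, exposed, min_group_size = 10) {
  stopifnot(length(exposed) == ncol(expr))
  n1 <- sum(exposed); n0 <- sum(!exposed)
  if (n1 < min_group_size || n0 < min_group_size) {
    message(sprintf("dge_by_exposure: skipped (%d exposed vs %d unexposed; need >= %d each)",
                    n1, n0, min_group_size))
    return(NULL)
  }
  i1 <- which(exposed); i0 <- which(!exposed)
  res <- apply(expr, 1, function(v) {
    t <- rank_sum_test(v[i1], v[i0])
    c(t$z, t$p)
  })
  out <- tibble::tibble(gene = rownames(expr), z = unname(res[1, ]),
                        p = unname(res[2, ]))
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Cross-species consistency of expression responses
#'
#' Runs [dge_by_exposure()] once per species and summarizes, per gene, how
#' consistently the species elicit the same response: `consistency_rate` is
#' the fraction of tested species in which the gene is significant
#' (q < `fdr`), and `direction_agreement` the fraction of those significant
#' results sharing the majority sign. Genes with
#' `consistency_rate >= r_min`, `direction_agreement >= d_min` and a
#' positive (negative) majority sign form the consistently-up
#' (consistently-down) lists.
#'
#' @param expr genes x spots normalized matrix.
#' @param exposure spots x species logical (or count) matrix aligned with
#'   the columns of `expr`.
#' @param species species to test (default: all columns of `exposure`).
#' @param min_group_size minimum spots per group per species.
#' @param fdr per-species significance threshold on q (default 0.05).
#' @param r_min,d_min consistency-call thresholds (defaults 0.5 and 0.9).
#' @return list of class `sb_response_matrix`: `z` and `significant`
#'   (genes x species matrices), `gene_stats` (tibble: gene,
#'   n_species_tested, consistency_rate, direction_agreement,
#'   majority_sign), `consistently_up`, `consistently_down`,
#'   `skipped_species`.
#' @export
consistency_screen <- function(expr, exposure, species = NULL,
                               min_group_size = 10, fdr = 0.05,
                               r_min = 0.5, d_min = 0.9) {
  species <- species %||% colnames(exposure)
  stopifnot(nrow(exposure) == ncol(expr))
  if (length(species) < 2) stop("consistency_screen needs >= 2 species")
  z <- sig <- matrix(NA_real_, nrow(expr), length(species),
                     dimnames = list(rownames(expr), species))
  skipped <- character()
  for (s in species) {
    d <- suppressMessages(
      dge_by_exposure(expr, exposure[, s] > 0, min_group_size))
    if (is.null(d)) { skipped <- c(skipped, s); next }
    z[, s] <- d$z
    sig[, s] <- as.numeric(d$q < fdr)
  }
  tested <- setdiff(species, skipped)
  if (length(tested) < 2) stop("fewer than 2 species evaluable")
  n_sig <- rowSums(sig[, tested, drop = FALSE], na.rm = TRUE)
  consistency_rate <- n_sig / length(tested)
  sign_mat <- sign(z[, tested, drop = FALSE]) * sig[, tested, drop = FALSE]
  n_pos <- rowSums(sign_mat > 0, na.rm = TRUE)
  n_neg <- rowSums(sign_mat < 0, na.rm = TRUE)
  majority_sign <- ifelse(n_sig == 0, NA_real_, sign(n_pos - n_neg))
  direction_agreement <- ifelse(n_sig == 0, NA_real_,
                                pmax(n_pos, n_neg) / pmax(1, n_sig))
  gene_stats <- tibble::tibble(
    gene = rownames(expr),
    n_species_tested = length(tested),
    consistency_rate = unname(consistency_rate),
    direction_agreement = unname(direction_agreement),
    majority_sign = unname(majority_sign))
  up <- gene_stats$gene[!is.na(direction_agreement) &
                          consistency_rate >= r_min &
                          direction_agreement >= d_min & majority_sign > 0]
  down <- gene_stats$gene[!is.na(direction_agreement) &
                            consistency_rate >= r_min &
                            direction_agreement >= d_min & majority_sign < 0]
  structure(list(z = z, significant = sig, gene_stats = gene_stats,
                 consistently_up = up, consistently_down = down,
                 skipped_species = skipped),
            class = "sb_response_matrix")
}

#' @export
print.sb_response_matrix <- function(x, ...) {
  cat(sprintf("<sb_response_matrix> %d genes x %d species (%d skipped)\n",
              nrow(x$z), ncol(x$z), length(x$skipped_species)))
  cat(sprintf("  consistently up: %d | consistently down: %d\n",
              length(x$consistently_up), length(x$consistently_down)))
  invisible(x)
}

#' Beneficial-versus-pathogenic expression pair comparison
#'
#' Enumerates every (beneficial, pathogenic) species pair -- always
#' `|beneficial| * |pathogenic|` pairs -- and for each pair compares spots
#' exposed to the beneficial species but not the pathogenic one against
#' spots exposed to the pathogenic but not the beneficial one
#' (doubly-exposed and unexposed spots are excluded). Per gene and pair a
#' two-sided rank-sum test is run as in [dge_by_exposure()]; positive `z`
#' means higher expression with beneficial exposure. The per-gene
#' pair-consistency rate is the fraction of evaluable pairs in which the
#' gene is significant.
#'
#' @param expr genes x spots normalized matrix.
#' @param exposure spots x species logical (or count) matrix.
#' @param beneficial,pathogenic non-empty species label sets.
#' @param min_group_size minimum spots per group per pair.
#' @param fdr per-pair significance threshold on q.
#' @return list of class `sb_pair_comparison`: `pairs` (tibble: beneficial,
#'   pathogenic, n_beneficial_spots, n_pathogenic_spots, evaluated), `z`
#'   and `significant` (genes x pairs), `gene_stats` (tibble: gene,
#'   n_pairs_evaluated, pair_consistency_rate, direction_agreement,
#'   majority_sign).
#' @export
pair_comparison <- function(expr, exposure, beneficial, pathogenic,
                            min_group_size = 10, fdr = 0.05) {
  if (!length(beneficial) || !length(pathogenic))
    stop("both species sets must be non-empty")
  stopifnot(all(c(beneficial, pathogenic) %in% colnames(exposure)),
            nrow(exposure) == ncol(expr))
  pairs <- expand.grid(beneficial = beneficial, pathogenic = pathogenic,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  pair_id <- paste(pairs$beneficial, pairs$pathogenic, sep = "|")
  z <- sig <- matrix(NA_real_, nrow(expr), nrow(pairs),
                     dimnames = list(rownames(expr), pair_id))
  nb <- np <- integer(nrow(pairs))
  evaluated <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    eb <- exposure[, pairs$beneficial[k]] > 0
    ep <- exposure[, pairs$pathogenic[k]] > 0
    g1 <- which(eb & !ep); g0 <- which(ep & !eb)
    nb[k] <- length(g1); np[k] <- length(g0)
    if (length(g1) < min_group_size || length(g0) < min_group_size) next
    res <- apply(expr, 1, function(v) {
      t <- rank_sum_test(v[g1], v[g0])
      c(t$z, t$p)
    })
    z[, k] <- res[1, ]
    sig[, k] <- as.numeric(p.adjust(res[2, ], method = "BH") < fdr)
    evaluated[k] <- TRUE
  }
  if (!any(evaluated))
    stop("all pairs skipped: no pair had enough singly-exposed spots")
  ev <- which(evaluated)
  n_sig <- rowSums(sig[, ev, drop = FALSE], na.rm = TRUE)
  sign_mat <- sign(z[, ev, drop = FALSE]) * sig[, ev, drop = FALSE]
  n_pos <- rowSums(sign_mat > 0, na.rm = TRUE)
  n_neg <- rowSums(sign_mat < 0, na.rm = TRUE)
  gene_stats <- tibble::tibble(
    gene = rownames(expr),
    n_pairs_evaluated = length(ev),
    pair_consistency_rate = unname(n_sig / length(ev)),
    direction_agreement = unname(ifelse(n_sig == 0, NA_real_,
                                        pmax(n_pos, n_neg) / pmax(1, n_sig))),
    majority_sign = unname(ifelse(n_sig == 0, NA_real_, sign(n_pos - n_neg))))
  structure(list(
    pairs = tibble::tibble(beneficial = pairs$beneficial,
                           pathogenic = pairs$pathogenic,
                           n_beneficial_spots = nb, n_pathogenic_spots = np,
                           evaluated = evaluated),
    z = z, significant = sig, gene_stats = gene_stats),
    class = "sb_pair_comparison")
}

#' @export
print.sb_pair_comparison <- function(x, ...) {
  cat(sprintf("<sb_pair_comparison> %d genes x %d pairs (%d evaluated)\n",
              nrow(x$z), nrow(x$pairs), sum(x$pairs$evaluated)))
  invisible(x)
}

#' Write ranked gene lists for external enrichment tools
#'
#' Exports the per-gene consistency summary ranked by consistency rate (and
#' the consistently-up/down calls) as plain TSV that any enrichment tool
#' accepts. Gene set enrichment itself is out of scope here.
#'
#' @param response an `sb_response_matrix` from [consistency_screen()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_gene_lists <- function(response, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ranked <- response$gene_stats[order(-response$gene_stats$consistency_rate), ]
  write.table(ranked, file.path(dir, "genes_ranked_by_consistency.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(response$consistently_up, file.path(dir, "consistently_up.txt"))
  writeLines(response$consistently_down, file.path(dir, "consistently_down.txt"))
  invisible(dir)
}
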