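# Bacterial load quantification: per spot, per group, per cell-type area,
# per patient, and species-by-cell-type colocalization.

#' Total bacterial load per spot, in CPM
#'
#' Sums counts-per-million over the (retained) species for every spot.
#' Visium-style spots contain multiple cells, so load is reported per spot.
#'
#' @param dataset an [sb_dataset] (typically after [decontaminate()]).
#' @param species optional species subset.
#' @param variant human-read-removal variant (default `"single"`).
#' @return named numeric vector of per-spot total bacterial CPM.
#' @export
per_spot_load <- function(dataset, species = NULL, variant = "single") {
  cpm <- sb_cpm(dataset, variant = variant, species = species)
  rowSums(cpm)
}

#' Compare bacterial load between groups
#'
#' Mean load, standard error of the mean, and two-sided Wilcoxon-Mann-Whitney
#' rank-sum p-values for every pair of groups, with the star annotation
#' thresholds 0.05 / 0.005 / 0.0005. Groups with zero spots are excluded
#' with a warning; the SEM is reported as `NA` for groups with fewer than 2
#' spots.
#'
#' @param loads numeric vector of per-spot loads (e.g. [per_spot_load()]).
#' @param groups vector of group or area labels, one per spot.
#' @return list of class `sb_group_summary`: `summary` (tibble: group,
#'   n_spots, mean_cpm, sem) and `pairwise` (tibble: group1, group2, z, p,
#'   stars).
#' @export
group_compare <- function(loads, groups) {
  stopifnot(length(loads) == length(groups))
  if (is.factor(groups)) {
    empty <- setdiff(levels(groups), as.character(unique(groups)))
    if (length(empty))
      warning("excluding group(s) with zero spots: ", paste(empty, collapse = ", "))
  }
  groups <- as.character(groups)
  keep <- !is.na(groups)
  loads <- loads[keep]; groups <- groups[keep]
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("group_compare needs at least 2 non-empty groups")
  split_loads <- split(loads, groups)
  summary <- tibble::tibble(
    group = lv,
    n_spots = vapply(split_loads[lv], length, integer(1), USE.NAMES = FALSE),
    mean_cpm = vapply(split_loads[lv], mean, numeric(1), USE.NAMES = FALSE),
    sem = vapply(split_loads[lv], function(x)
      if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_,
      numeric(1), USE.NAMES = FALSE))
  pairs <- utils::combn(lv, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    t <- rank_sum_test(split_loads[[g1]], split_loads[[g2]])
    tibble::tibble(group1 = g1, group2 = g2, z = t$z, p = t$p)
  })
  pw <- do.call(rbind, pw)
  pw$stars <- stars_from_p(pw$p)
  structure(list(summary = summary, pairwise = pw), class = "sb_group_summary")
}

#' @export
print.sb_group_summary <- function(x, ...) {
  cat("<sb_group_summary>\n")
  print(x$summary)
  print(x$pairwise)
  invisible(x)
}

#' Per-patient bacterial load and prognosis table
#'
#' Averages the per-spot bacterial load within each patient and joins the
#' patient-level prognosis metadata (time to relapse in months, Rutgeerts
#' endoscopic score). Spearman rank correlations of mean load versus the
#' Rutgeerts score (all patients with a score) and versus time to relapse
#' (relapse patients only) are attached; a correlation with fewer than 3
#' complete pairs is reported as not computable (`NA`).
#'
#' @param loads named per-spot loads, aligned with `dataset$spots`.
#' @param dataset an [sb_dataset] carrying spot and patient metadata.
#' @return list with `table` (tibble: patient_id, group, n_spots, mean_cpm,
#'   time_to_relapse, rutgeerts) and `correlations` (tibble: variable, n,
#'   rho, p).
#' @export
patient_prognosis_table <- function(loads, dataset) {
  stopifnot(length(loads) == nrow(dataset$spots))
  by_patient <- split(loads, dataset$spots$patient_id)
  tab <- tibble::tibble(
    patient_id = names(by_patient),
    n_spots = vapply(by_patient, length, integer(1)),
    mean_cpm = vapply(by_patient, mean, numeric(1)))
  tab <- merge(tab, dataset$patients, by = "patient_id", all.x = TRUE)
  tab <- tibble::as_tibble(tab[order(tab$patient_id),
                               c("patient_id", "group", "n_spots", "mean_cpm",
                                 "time_to_relapse", "rutgeerts")])
  spearman <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(c(n = sum(ok), rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    c(n = sum(ok), rho = unname(ct$estimate), p = ct$p.value)
  }
  c1 <- spearman(tab$mean_cpm, tab$rutgeerts)
  c2 <- spearman(tab$mean_cpm, tab$time_to_relapse)
  correlations <- tibble::tibble(
    variable = c("rutgeerts", "time_to_relapse"),
    n = unname(c(c1["n"], c2["n"])),
    rho = unname(c(c1["rho"], c2["rho"])),
    p = unname(c(c1["p"], c2["p"])))
  list(table = tab, correlations = correlations)
}

#' Species-by-cell-type colocalization
#'
#' Co-existence weights between each bacterial species and each deconvolved
#' cell type, computed by multiplying cell-type fractions with bacterial
#' counts per spot and summing over spots:
#' `weight[s, c] = sum_i fractions[i, c] * counts[i, s]`. Because fraction
#' rows sum to 1, each species' weights sum exactly to its total read count.
#' The probability variant divides each species row by its sum (rows of
#' species with zero reads are `NA`).
#'
#' When beneficial and pathogenic species sets are supplied, a per-cell-type
#' comparison is added: log2 fold change of the mean colocalization
#' probability (beneficial over pathogenic; zeros are offset by half the
#' smallest positive probability to avoid infinities) and a two-sided
#' rank-sum p-value comparing the two species groups, BH-adjusted across
#' cell types.
#'
#' @param dataset an [sb_dataset] with cell-type fractions.
#' @param species optional species subset (default: all current species).
#' @param beneficial,pathogenic optional species label sets for the group
#'   comparison.
#' @return list with `weights` (species x cell-type matrix), `probability`
#'   (row-normalized variant) and, when label sets are given, `group_fc`
#'   (tibble: cell_type, log2_fc, z, p, q).
#' @export
colocalization <- function(dataset, species = NULL, beneficial = NULL,
                           pathogenic = NULL) {
  if (is.null(dataset$fractions)) stop("dataset has no cell-type fractions")
  counts <- dataset$bacteria$single
  if (!is.null(species)) counts <- counts[, species, drop = FALSE]
  weights <- t(counts) %*% dataset$fractions  # species x cell types
  weights <- as.matrix(weights)
  rs <- rowSums(weights)
  probability <- weights / rs
  probability[rs == 0, ] <- NA_real_
  out <- list(weights = weights, probability = probability)
  if (!is.null(beneficial) && !is.null(pathogenic)) {
    stopifnot(all(c(beneficial, pathogenic) %in% rownames(probability)))
    pb <- probability[beneficial, , drop = FALSE]
    pp <- probability[pathogenic, , drop = FALSE]
    pos <- probability[probability > 0 & !is.na(probability)]
    eps <- if (length(pos)) min(pos) / 2 else 0.5
    fc <- vapply(colnames(probability), function(ct) {
      log2((mean(pb[, ct], na.rm = TRUE) + eps) /
           (mean(pp[, ct], na.rm = TRUE) + eps))
    }, numeric(1))
    tests <- lapply(colnames(probability), function(ct)
      rank_sum_test(pb[, ct], pp[, ct]))
    group_fc <- tibble::tibble(
      cell_type = colnames(probability),
      log2_fc = unname(fc),
      z = vapply(tests, `[[`, numeric(1), "z"),
      p = vapply(tests, `[[`, numeric(1), "p"))
    group_fc$q <- p.adjust(group_fc$p, method = "BH")
    out$group_fc <- group_fc
  }
  out
}
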