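# Four-rule stepwise decontamination of species-level spatial microbiome
# counts. All rules use strict inequalities exactly as printed:
#   1. spatial floor:  fail iff total spatial reads  < 50
#   2. bulk floor:     fail iff total bulk reads     < 50
#   3. share ratio:    fail iff spatial% / bulk%     > 1.5
#   4. survival:       fail iff double/single reads  < 2%
# Rules are conjunctive; all four are evaluated for every species so the
# report supports audit, and the verdict is their conjunction.

#' Rule 1: spatial read floor
#'
#' A species fails when its total read count across all spatial microbiome
#' spots (all samples pooled) is strictly below `min_reads`.
#'
#' @param totals named numeric vector of per-species total spatial reads.
#' @param min_reads threshold (default 50).
#' @return named logical vector, `TRUE` = pass.
#' @export
rule_spatial_floor <- function(totals, min_reads = 50) {
  !(totals < min_reads)
}

#' Rule 2: bulk metagenome read floor
#'
#' A species fails when its total read count in the bulk metagenome
#' sequencing of the same tissues is strictly below `min_reads`. Species
#' absent from the bulk table count as 0 reads (fail).
#'
#' @param totals named numeric vector of per-species total bulk reads
#'   (use 0 for species missing from the bulk table).
#' @param min_reads threshold (default 50).
#' @return named logical vector, `TRUE` = pass.
#' @export
rule_bulk_floor <- function(totals, min_reads = 50) {
  !(totals < min_reads)
}

#' Rule 3: spatial/bulk read-share ratio
#'
#' Read shares are each species' percentage of all classified bacterial
#' reads within its technology (spatial vs bulk). A species fails when its
#' spatial share divided by its bulk share strictly exceeds `max_ratio`.
#' A species with spatial reads but zero bulk share fails (ratio +Inf);
#' a species with zero share in both passes this rule (its read floors
#' already fail) and its ratio is reported as `NA`.
#'
#' @param spatial_pct,bulk_pct per-species read shares (any common scale;
#'   proportions and percentages give the same ratio).
#' @param max_ratio threshold (default 1.5).
#' @return named logical vector, `TRUE` = pass, with the ratio in
#'   attribute `"ratio"`.
#' @export
rule_spatial_bulk_ratio <- function(spatial_pct, bulk_pct, max_ratio = 1.5) {
  ratio <- ifelse(bulk_pct > 0, spatial_pct / bulk_pct,
                  ifelse(spatial_pct > 0, Inf, NA_real_))
  pass <- !(ratio > max_ratio)
  pass[is.na(ratio)] <- TRUE
  attr(pass, "ratio") <- ratio
  pass
}

#' Rule 4: double human-read-removal survival
#'
#' A species is a potential human-read false positive when its total reads
#' after double removal (Bowtie2 + BWA) drop strictly below `min_survival`
#' (default 2 percent) of its single-removal total. Species with a
#' single-removal total of 0 cannot be evaluated (they already fail the
#' spatial floor); their survival is `NA` and they pass this rule.
#'
#' @param single_totals,double_totals named per-species totals under the two
#'   removal variants.
#' @param min_survival threshold survival proportion (default 0.02).
#' @return named logical vector, `TRUE` = pass, with the survival ratio in
#'   attribute `"survival"`.
#' @export
rule_double_removal_survival <- function(single_totals, double_totals,
                                         min_survival = 0.02) {
  survival <- ifelse(single_totals > 0, double_totals / single_totals, NA_real_)
  pass <- !(survival < min_survival)
  pass[is.na(survival)] <- TRUE
  attr(pass, "survival") <- survival
  pass
}

#' Build a decontamination report from per-species totals
#'
#' Vector-level core of [decontaminate()]: evaluates all four rules on
#' pooled per-species totals and returns the audit report.
#'
#' @param spatial_totals named per-species total spatial reads.
#' @param bulk_counts named per-species bulk reads; species missing from
#'   this vector are treated as 0 (and reported).
#' @param double_totals named per-species totals after double human-read
#'   removal, or `NULL` if the double-removal table is unavailable (rule 4
#'   is then skipped with a warning and passes vacuously).
#' @param min_spatial_reads,min_bulk_reads,max_spatial_bulk_ratio,min_double_survival
#'   rule thresholds.
#' @param spatial_pct optional per-species spatial read shares overriding
#'   the pooled shares computed from `spatial_totals` (used for the
#'   per-sample-mean share mode).
#' @return tibble with one row per species: totals, shares, ratio, survival,
#'   the four pass flags, `verdict` (retained/excluded) and `failing_rule`
#'   (first failing rule in rule order, `NA` if retained).
#' @export
decontamination_report <- function(spatial_totals, bulk_counts,
                                   double_totals = NULL,
                                   min_spatial_reads = 50,
                                   min_bulk_reads = 50,
                                   max_spatial_bulk_ratio = 1.5,
                                   min_double_survival = 0.02,
                                   spatial_pct = NULL) {
  species <- names(spatial_totals)
  if (length(spatial_totals) > 0L && is.null(species))
    stop("spatial_totals must be named by species")
  if (length(spatial_totals) == 0L)
    return(tibble::tibble(species = character(), total_spatial_reads = numeric(),
                          total_bulk_reads = numeric(), spatial_pct = numeric(),
                          bulk_pct = numeric(), spatial_bulk_ratio = numeric(),
                          double_single_survival = numeric(),
                          pass_spatial_floor = logical(), pass_bulk_floor = logical(),
                          pass_spatial_bulk_ratio = logical(),
                          pass_double_survival = logical(),
                          verdict = character(), failing_rule = character()))

  missing_bulk <- setdiff(species, names(bulk_counts))
  if (length(missing_bulk))
    message(sprintf("decontamination: %d species absent from bulk table treated as 0 reads: %s",
                    length(missing_bulk), paste(missing_bulk, collapse = ", ")))
  bulk <- stats::setNames(rep(0, length(species)), species)
  bulk[intersect(species, names(bulk_counts))] <-
    bulk_counts[intersect(species, names(bulk_counts))]

  s_share <- if (!is.null(spatial_pct)) spatial_pct[species] else {
    if (sum(spatial_totals) > 0) spatial_totals / sum(spatial_totals)
    else rep(0, length(species))
  }
  b_share <- if (sum(bulk) > 0) bulk / sum(bulk) else stats::setNames(rep(0, length(species)), species)

  p1 <- rule_spatial_floor(spatial_totals, min_spatial_reads)
  p2 <- rule_bulk_floor(bulk, min_bulk_reads)
  p3 <- rule_spatial_bulk_ratio(s_share, b_share, max_spatial_bulk_ratio)
  if (is.null(double_totals)) {
    warning("double-removal table unavailable: survival rule skipped (passes vacuously)")
    p4 <- stats::setNames(rep(TRUE, length(species)), species)
    survival <- rep(NA_real_, length(species))
  } else {
    p4 <- rule_double_removal_survival(spatial_totals, double_totals[species],
                                       min_double_survival)
    survival <- attr(p4, "survival")
  }

  flags <- cbind(p1, p2, as.logical(p3), as.logical(p4))
  verdict <- ifelse(rowSums(!flags) == 0, "retained", "excluded")
  rule_ids <- c("spatial_floor", "bulk_floor", "spatial_bulk_ratio", "double_survival")
  failing <- apply(flags, 1, function(f) if (all(f)) NA_character_ else rule_ids[which(!f)[1]])

  tibble::tibble(
    species = species,
    total_spatial_reads = unname(spatial_totals),
    total_bulk_reads = unname(bulk),
    spatial_pct = unname(s_share),
    bulk_pct = unname(b_share),
    spatial_bulk_ratio = unname(attr(p3, "ratio")),
    double_single_survival = unname(survival),
    pass_spatial_floor = unname(p1),
    pass_bulk_floor = unname(p2),
    pass_spatial_bulk_ratio = as.logical(unname(p3)),
    pass_double_survival = as.logical(unname(p4)),
    verdict = unname(verdict),
    failing_rule = unname(failing))
}

#' Apply the decontamination cascade to a dataset
#'
#' Pools counts across all spots of all samples (CD and control alike),
#' evaluates the four rules and removes excluded species from the dataset.
#' Downstream analyses use the single-removal counts of the retained
#' species, since double removal also depresses genuine gut-residing
#' species.
#'
#' @param dataset an [sb_dataset].
#' @param min_spatial_reads,min_bulk_reads,max_spatial_bulk_ratio,min_double_survival
#'   rule thresholds (defaults 50, 50, 1.5, 0.02).
#' @param pct_mode how to compute the spatial read share for rule 3:
#'   `"pooled"` (share of all classified spatial bacterial reads, pooled
#'   across samples; default) or `"per_sample_mean"` (mean over samples of
#'   the within-sample share).
#' @return list with `dataset` (retained species only) and `report`
#'   (the [decontamination_report()] tibble over all species).
#' @examples
#' fx <- worked_fixture()
#' dec <- decontaminate(fx$dataset)
#' table(dec$report$verdict)
#' @export
decontaminate <- function(dataset,
                          min_spatial_reads = 50,
                          min_bulk_reads = 50,
                          max_spatial_bulk_ratio = 1.5,
                          min_double_survival = 0.02,
                          pct_mode = c("pooled", "per_sample_mean")) {
  pct_mode <- match.arg(pct_mode)
  single <- dataset$bacteria$single
  spatial_totals <- colSums(single)
  double_totals <- if (!is.null(dataset$bacteria$double))
    colSums(dataset$bacteria$double) else NULL
  spatial_pct <- NULL
  if (pct_mode == "per_sample_mean") {
    shares <- vapply(split(seq_len(nrow(single)), dataset$spots$sample_id),
                     function(idx) {
                       tot <- colSums(single[idx, , drop = FALSE])
                       if (sum(tot) > 0) tot / sum(tot) else tot * 0
                     }, numeric(ncol(single)))
    spatial_pct <- rowMeans(shares)
  }
  report <- decontamination_report(
    spatial_totals, dataset$bulk_counts, double_totals,
    min_spatial_reads = min_spatial_reads, min_bulk_reads = min_bulk_reads,
    max_spatial_bulk_ratio = max_spatial_bulk_ratio,
    min_double_survival = min_double_survival, spatial_pct = spatial_pct)
  retained <- report$species[report$verdict == "retained"]
  list(dataset = subset_species(dataset, retained), report = report)
}
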