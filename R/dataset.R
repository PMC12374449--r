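#' Joined spatial host-microbiome dataset
#'
#' The central container of the package: per-spot host gene counts, bacterial
#' species counts under single and double human-read removal, bulk metagenome
#' species counts, deconvolved cell-type fractions and spot/patient metadata,
#' all aligned on spot barcodes.
#'
#' @section Components:
#' \describe{
#'   \item{spots}{tibble with one row per spot: `barcode`, `sample_id`,
#'     `patient_id`, `group` (control / CD_noninflamed / CD_inflamed),
#'     `x`, `y`, `total_sequencing_reads`, `total_gene_counts`,
#'     `mito_fraction`, `area_label`.}
#'   \item{genes}{tibble: `gene`, `is_mito`.}
#'   \item{host_counts}{sparse genes x spots count matrix.}
#'   \item{bacteria}{list of spots x species count matrices, elements
#'     `single` and `double` (human-read removal variants).}
#'   \item{bulk_counts}{named numeric vector of bulk metagenome read counts
#'     per species.}
#'   \item{fractions}{spots x cell-types matrix of deconvolved cell-type
#'     fractions (rows sum to 1).}
#'   \item{patients}{tibble: `patient_id`, `group`, `time_to_relapse`
#'     (months, NA for patients without relapse), `rutgeerts` (i0-i4 coded
#'     0-4, NA for controls).}
#' }
#'
#' @param spots,genes,host_counts,bacteria,bulk_counts,fractions,patients
#'   components as described above.
#' @return An object of class `sb_dataset`.
#' @export
sb_dataset <- function(spots, genes, host_counts, bacteria, bulk_counts,
                       fractions, patients) {
  x <- structure(
    list(spots = spots, genes = genes, host_counts = host_counts,
         bacteria = bacteria, bulk_counts = bulk_counts,
         fractions = fractions, patients = patients),
    class = "sb_dataset")
  validate_sb_dataset(x)
}

validate_sb_dataset <- function(x) {
  bc <- x$spots$barcode
  if (anyDuplicated(paste(x$spots$sample_id, bc)))
    stop("barcodes must be unique within a sample")
  if (!is.null(x$host_counts)) {
    stopifnot(ncol(x$host_counts) == length(bc))
    if (any(x$host_counts@x < 0)) stop("negative host counts")
  }
  for (v in names(x$bacteria)) {
    m <- x$bacteria[[v]]
    if (is.null(m)) next
    stopifnot(nrow(m) == length(bc))
    if (any(m < 0)) stop(sprintf("negative bacterial counts in `%s` table", v))
  }
  if (!is.null(x$fractions)) {
    stopifnot(nrow(x$fractions) == length(bc))
    if (any(x$fractions < 0)) stop("negative cell-type fractions")
    rs <- rowSums(x$fractions)
    if (any(abs(rs - 1) > 1e-6))
      stop("cell-type fraction rows must sum to 1 (tolerance 1e-6)")
  }
  x
}

#' @export
print.sb_dataset <- function(x, ...) {
  cat(sprintf("<sb_dataset> %d spots | %d samples | %d genes | %d species\n",
              nrow(x$spots), length(unique(x$spots$sample_id)),
              nrow(x$genes), ncol(x$bacteria$single)))
  cat(sprintf("  groups: %s\n",
              paste(names(table(x$spots$group)), table(x$spots$group),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  bacterial variants: %s | bulk species: %d | cell types: %d\n",
              paste(names(x$bacteria), collapse = "/"),
              length(x$bulk_counts),
              if (is.null(x$fractions)) 0L else ncol(x$fractions)))
  invisible(x)
}

#' Bacterial counts per million for a dataset
#'
#' CPM of species `s` in spot `i` is the raw read count divided by the spot's
#' total sequencing reads, times 1e6. Spots with zero total reads get 0.
#'
#' @param dataset an [sb_dataset].
#' @param variant which human-read-removal variant to use (`"single"`, the
#'   default used by all downstream analyses, or `"double"`).
#' @param species optional character vector restricting the columns.
#' @return spots x species numeric matrix of CPM values.
#' @export
sb_cpm <- function(dataset, variant = c("single", "double"), species = NULL) {
  variant <- match.arg(variant)
  m <- dataset$bacteria[[variant]]
  if (is.null(m)) stop(sprintf("no `%s` bacterial count table in dataset", variant))
  if (!is.null(species)) {
    missing <- setdiff(species, colnames(m))
    if (length(missing))
      stop("unknown species: ", paste(missing, collapse = ", "))
    m <- m[, species, drop = FALSE]
  }
  cpm_from_counts(m, dataset$spots$total_sequencing_reads)
}

# Subset every aligned component to the given spot index/logical vector.
subset_spots <- function(dataset, keep) {
  dataset$spots <- dataset$spots[keep, , drop = FALSE]
  if (!is.null(dataset$host_counts))
    dataset$host_counts <- dataset$host_counts[, keep, drop = FALSE]
  for (v in names(dataset$bacteria))
    if (!is.null(dataset$bacteria[[v]]))
      dataset$bacteria[[v]] <- dataset$bacteria[[v]][keep, , drop = FALSE]
  if (!is.null(dataset$fractions))
    dataset$fractions <- dataset$fractions[keep, , drop = FALSE]
  dataset
}

# Subset bacterial tables (and bulk vector) to a species set.
subset_species <- function(dataset, species) {
  for (v in names(dataset$bacteria))
    if (!is.null(dataset$bacteria[[v]]))
      dataset$bacteria[[v]] <-
        dataset$bacteria[[v]][, intersect(species, colnames(dataset$bacteria[[v]])),
                              drop = FALSE]
  dataset$bulk_counts <- dataset$bulk_counts[intersect(species, names(dataset$bulk_counts))]
  dataset
}

#' Restrict a dataset to spots from Crohn's disease samples
#'
#' The viability risk and correlation analyses are performed exclusively on
#' spots from participants with CD; this helper subsets to the
#' `CD_noninflamed` and `CD_inflamed` groups.
#'
#' @param dataset an [sb_dataset].
#' @return the subsetted dataset.
#' @export
cd_spots <- function(dataset) {
  subset_spots(dataset, dataset$spots$group %in% c("CD_noninflamed", "CD_inflamed"))
}
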