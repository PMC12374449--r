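# Reading and writing the pipeline's on-disk formats.
#
# Layout written by write_dataset() and read by load_dataset():
#   host/matrix.mtx, host/features.tsv, host/barcodes.tsv   (10x-style triplet)
#   species_single.tsv, species_double.tsv    (barcode, species, count; long)
#   bulk_species.tsv                          (species, count)
#   cell_type_fractions.tsv                   (barcode + one column per type)
#   spots.csv, patients.csv                   (metadata)

#' Write a dataset to a directory of standard-format files
#'
#' Host counts are written as an MTX triplet (matrix.mtx, features.tsv,
#' barcodes.tsv), bacterial counts as long-format TSV (one per human-read
#' removal variant), bulk counts and cell-type fractions as TSV, and spot and
#' patient metadata as CSV.
#'
#' @param dataset an [sb_dataset].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "host"), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dataset$host_counts, file.path(dir, "host", "matrix.mtx"))
  write.table(dataset$genes, file.path(dir, "host", "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(dataset$host_counts), file.path(dir, "host", "barcodes.tsv"))
  for (v in names(dataset$bacteria)) {
    m <- dataset$bacteria[[v]]
    idx <- which(m > 0, arr.ind = TRUE)
    long <- data.frame(barcode = rownames(m)[idx[, 1]],
                       species = colnames(m)[idx[, 2]],
                       count = m[idx])
    long <- long[order(long$barcode, long$species), ]
    write.table(long, file.path(dir, sprintf("species_%s.tsv", v)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(species = names(dataset$bulk_counts),
                         count = unname(dataset$bulk_counts)),
              file.path(dir, "bulk_species.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- data.frame(barcode = rownames(dataset$fractions),
                   dataset$fractions, check.names = FALSE)
  write.table(fr, file.path(dir, "cell_type_fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(dataset$spots[, setdiff(names(dataset$spots),
                                    c("total_gene_counts", "mito_fraction"))],
            file.path(dir, "spots.csv"), row.names = FALSE)
  write.csv(dataset$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  invisible(dir)
}

read_species_long <- function(path, barcodes) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "species", "count") %in% names(long)))
    stop(sprintf("%s: expected columns barcode, species, count", basename(path)))
  if (nrow(long) && any(long$count < 0))
    stop(sprintf("%s: negative counts", basename(path)))
  species <- sort(unique(long$species))
  m <- matrix(0L, length(barcodes), length(species),
              dimnames = list(barcodes, species))
  keep <- long$barcode %in% barcodes
  if (nrow(long))
    m[cbind(long$barcode[keep], long$species[keep])] <- as.integer(long$count[keep])
  if (sum(!keep) > 0)
    message(sprintf("load_dataset: %s: %d row(s) with unmatched barcodes dropped",
                    basename(path), sum(!keep)))
  m
}

#' Load a dataset from a directory of standard-format files
#'
#' Reads the layout written by [write_dataset()], recomputes each spot's
#' mitochondrial read fraction from the host counts, and joins all tables on
#' spot barcodes. Barcodes present in one table but not in the host matrix
#' are reported and dropped; if more than half of the metadata barcodes are
#' missing from the host matrix the pairing is considered wrong and loading
#' fails.
#'
#' @param dir input directory.
#' @param mito_prefix prefix (case-insensitive) identifying mitochondrial
#'   gene symbols; ignored when `mito_genes` is given.
#' @param mito_genes optional explicit character vector of mitochondrial
#'   gene names, overriding the prefix rule.
#' @return an [sb_dataset].
#' @export
load_dataset <- function(dir, mito_prefix = "MT-", mito_genes = NULL) {
  need <- c(file.path("host", c("matrix.mtx", "features.tsv", "barcodes.tsv")),
            "species_single.tsv", "bulk_species.tsv",
            "cell_type_fractions.tsv", "spots.csv", "patients.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  host <- methods::as(Matrix::readMM(file.path(dir, "host", "matrix.mtx")),
                      "CsparseMatrix")
  genes <- tibble::as_tibble(read.delim(file.path(dir, "host", "features.tsv"),
                                        stringsAsFactors = FALSE))
  barcodes <- readLines(file.path(dir, "host", "barcodes.tsv"))
  dimnames(host) <- list(genes$gene, barcodes)
  if (any(host@x < 0)) stop("host count matrix contains negative counts")

  is_mito <- if (!is.null(mito_genes)) {
    genes$gene %in% mito_genes
  } else {
    startsWith(tolower(genes$gene), tolower(mito_prefix))
  }
  genes$is_mito <- is_mito

  spots <- tibble::as_tibble(read.csv(file.path(dir, "spots.csv"),
                                      stringsAsFactors = FALSE))
  n_meta <- nrow(spots)
  matched <- spots$barcode %in% barcodes
  if (n_meta > 0 && mean(matched) < 0.5)
    stop(sprintf(
      "barcode mismatch: only %d of %d metadata barcodes match the host matrix; wrong file pairing?",
      sum(matched), n_meta))
  dropped <- n_meta - sum(matched)
  if (dropped > 0)
    message(sprintf("load_dataset: dropping %d metadata barcode(s) absent from host matrix", dropped))
  spots <- spots[matched, , drop = FALSE]
  host <- host[, spots$barcode, drop = FALSE]

  totals <- Matrix::colSums(host)
  mito <- Matrix::colSums(host[is_mito, , drop = FALSE])
  spots$total_gene_counts <- unname(as.integer(totals))
  spots$mito_fraction <- unname(ifelse(totals > 0, mito / totals, 0))
  if (!"area_label" %in% names(spots)) spots$area_label <- NA_character_

  single <- read_species_long(file.path(dir, "species_single.tsv"), spots$barcode)
  double_path <- file.path(dir, "species_double.tsv")
  double <- NULL
  if (file.exists(double_path)) {
    double <- read_species_long(double_path, spots$barcode)
    # align species sets across variants (absent = 0 reads)
    species <- sort(union(colnames(single), colnames(double)))
    pad <- function(m) {
      out <- matrix(0L, nrow(m), length(species),
                    dimnames = list(rownames(m), species))
      out[, colnames(m)] <- m
      out
    }
    single <- pad(single); double <- pad(double)
  }
  bulk_tab <- read.delim(file.path(dir, "bulk_species.tsv"), stringsAsFactors = FALSE)
  if (nrow(bulk_tab) && any(bulk_tab$count < 0)) stop("bulk_species.tsv: negative counts")
  bulk <- stats::setNames(as.numeric(bulk_tab$count), bulk_tab$species)

  fr <- read.delim(file.path(dir, "cell_type_fractions.tsv"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  fractions <- as.matrix(fr[, -1, drop = FALSE])
  rownames(fractions) <- fr$barcode
  keep_fr <- rownames(fractions) %in% spots$barcode
  if (any(!keep_fr))
    message(sprintf("load_dataset: dropping %d fraction row(s) with unmatched barcodes",
                    sum(!keep_fr)))
  fractions <- fractions[spots$barcode, , drop = FALSE]

  patients <- tibble::as_tibble(read.csv(file.path(dir, "patients.csv"),
                                         stringsAsFactors = FALSE))

  bacteria <- list(single = single)
  if (!is.null(double)) bacteria$double <- double
  sb_dataset(spots = spots, genes = genes, host_counts = host,
             bacteria = bacteria, bulk_counts = bulk,
             fractions = fractions, patients = patients)
}

#' Quality-control filter on the mitochondrial read fraction
#'
#' Removes low-quality spots whose mitochondrial read fraction strictly
#' exceeds the threshold (default 40 percent); a spot at exactly the
#' threshold is retained.
#'
#' @param dataset an [sb_dataset].
#' @param mito_threshold maximum tolerated mitochondrial fraction.
#' @return the filtered dataset, with a `qc_report` attribute: a tibble of
#'   removed barcodes with their sample and mitochondrial fraction.
#' @export
qc_filter_spots <- function(dataset, mito_threshold = 0.40) {
  if (!is.numeric(mito_threshold) || length(mito_threshold) != 1L ||
      is.na(mito_threshold) || mito_threshold < 0 || mito_threshold > 1)
    stop_param("mito_threshold", "must be a proportion in [0, 1]")
  remove <- dataset$spots$mito_fraction > mito_threshold
  report <- tibble::tibble(barcode = dataset$spots$barcode[remove],
                           sample_id = dataset$spots$sample_id[remove],
                           mito_fraction = dataset$spots$mito_fraction[remove])
  out <- subset_spots(dataset, !remove)
  attr(out, "qc_report") <- report
  out
}

# Default aggregation of fine cell types into named tissue areas.
default_area_map <- function() {
  c(enterocyte = "enterocyte-rich", goblet = "goblet cell-rich",
    M_cell = "M cell-rich", immune_T = "immune cell-rich",
    immune_B = "immune cell-rich", myeloid = "immune cell-rich",
    stromal = "stromal-rich", tuft = "tuft cell-rich")
}

#' Label each spot by its dominant cell-type-enriched area
#'
#' Aggregates fine cell-type fractions into named areas (summing fractions
#' within an area) and labels each spot by the area with the largest
#' aggregated fraction. Ties are broken deterministically in favour of the
#' lexicographically first area name (and reported via a message).
#'
#' @param dataset an [sb_dataset] with cell-type fractions.
#' @param area_map named character vector mapping each cell type to an area
#'   name; may also be a two-column data frame (`cell_type`, `area`), in
#'   which case a cell type mapped to two different areas is a
#'   configuration error. Cell types absent from the map form their own
#'   `<type>-rich` area.
#' @return the dataset with `spots$area_label` filled in.
#' @export
assign_area_labels <- function(dataset, area_map = NULL) {
  if (is.null(dataset$fractions)) stop("dataset has no cell-type fractions")
  if (is.null(area_map)) area_map <- default_area_map()
  if (is.data.frame(area_map)) {
    dup <- unique(area_map$cell_type[duplicated(area_map$cell_type)])
    conflicting <- vapply(dup, function(ct)
      length(unique(area_map$area[area_map$cell_type == ct])) > 1, logical(1))
    if (any(conflicting))
      stop_param("area_map", paste("cell type(s) mapped to more than one area:",
                                   paste(dup[conflicting], collapse = ", ")))
    area_map <- stats::setNames(area_map$area, area_map$cell_type)[!duplicated(area_map$cell_type)]
  }
  types <- colnames(dataset$fractions)
  areas <- ifelse(types %in% names(area_map), area_map[types],
                  paste0(types, "-rich"))
  area_names <- sort(unique(areas))
  agg <- sapply(area_names, function(a)
    rowSums(dataset$fractions[, areas == a, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(dataset$fractions),
                dimnames = list(rownames(dataset$fractions), area_names))
  # argmax with lexicographic tie-break: columns already sorted, take first max
  best <- max.col(agg, ties.method = "first")
  row_max <- agg[cbind(seq_len(nrow(agg)), best)]
  n_tie <- sum(rowSums(agg == row_max) > 1)
  if (n_tie > 0)
    message(sprintf("assign_area_labels: %d tie(s) broken lexicographically", n_tie))
  dataset$spots$area_label <- area_names[best]
  dataset
}
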