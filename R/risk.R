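# Per-species relative risk of reduced cell viability, Katz confidence
# intervals, BH multiplicity correction and population attributable risk
# percent (PARP).
#
# The 2x2 table per species, over spots:
#               damaged   viable
#   exposed        a         b
#   unexposed      c         d
#
#   RR  = (a / (a + b)) / (c / (c + d))
#   95% CI (Katz log method): exp(log RR +/- 1.96 * SE),
#     SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))
#   PARP(%) = 100 * P * (RR - 1) / (P * (RR - 1) + 1),  P = (a+b)/(a+b+c+d)

#' Classify spots as viable or damaged from the mitochondrial fraction
#'
#' Spots with a mitochondrial read fraction of at most the cutoff (default
#' 10 percent) are viable; spots strictly above it are damaged. Run after
#' QC filtering (the 40 percent exclusion), since spots above the QC
#' threshold are dropped, not classified.
#'
#' @param dataset an [sb_dataset].
#' @param mito_cutoff viability cutoff on the mitochondrial fraction.
#' @return named logical vector: `TRUE` = damaged.
#' @export
classify_viability <- function(dataset, mito_cutoff = 0.10) {
  if (!is.numeric(mito_cutoff) || length(mito_cutoff) != 1L ||
      is.na(mito_cutoff) || mito_cutoff < 0 || mito_cutoff > 1)
    stop_param("mito_cutoff", "must be a proportion in [0, 1]")
  stats::setNames(dataset$spots$mito_fraction > mito_cutoff,
                  dataset$spots$barcode)
}

#' Relative risk of damage given exposure, with Katz confidence interval
#'
#' Tabulates the 2x2 exposure-by-damage table and evaluates the relative
#' risk formula with a Katz log-normal confidence interval and a two-sided
#' p-value from the z statistic `log(RR) / SE`. When a zero damaged cell
#' (`a = 0` or `c = 0`) makes the log RR degenerate, the Haldane-Anscombe
#' 0.5 continuity correction is applied to all four cells and flagged.
#' A species with no exposed or no unexposed spots is not evaluable.
#'
#' @param exposed,damaged logical vectors of equal length, one element per
#'   spot.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return one-row tibble: a, b, c, d, rr, ci_low, ci_high, p,
#'   continuity_corrected, evaluable.
#' @examples
#' relative_risk(rep(c(TRUE, FALSE), c(100, 200)),
#'               rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 20, 180)))
#' @export
relative_risk <- function(exposed, damaged, conf_level = 0.95) {
  stopifnot(length(exposed) == length(damaged))
  a <- sum(exposed & damaged); b <- sum(exposed & !damaged)
  cc <- sum(!exposed & damaged); d <- sum(!exposed & !damaged)
  out <- rr_from_cells(a, b, cc, d, conf_level)
  tibble::tibble(a = a, b = b, c = cc, d = d,
                 rr = out$rr, ci_low = out$ci_low, ci_high = out$ci_high,
                 p = out$p, continuity_corrected = out$corrected,
                 evaluable = out$evaluable)
}

# Vectorized core over per-species cell counts.
rr_from_cells <- function(a, b, cc, d, conf_level = 0.95) {
  n_exp <- a + b
  n_une <- cc + d
  evaluable <- n_exp > 0 & n_une > 0
  corrected <- evaluable & (a == 0 | cc == 0)
  a2 <- a + 0.5 * corrected; b2 <- b + 0.5 * corrected
  c2 <- cc + 0.5 * corrected; d2 <- d + 0.5 * corrected
  rr <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci_low <- exp(log(rr) - zq * se)
  ci_high <- exp(log(rr) + zq * se)
  z <- log(rr) / se
  p <- 2 * pnorm(-abs(z))
  p[se == 0] <- 1
  rr[!evaluable] <- NA_real_; ci_low[!evaluable] <- NA_real_
  ci_high[!evaluable] <- NA_real_; p[!evaluable] <- NA_real_
  list(rr = rr, ci_low = ci_low, ci_high = ci_high, p = p,
       corrected = corrected, evaluable = evaluable)
}

#' Population attributable risk percent
#'
#' `PARP = 100 * P * (RR - 1) / (P * (RR - 1) + 1)`, where `P` is the
#' exposure prevalence. Zero at RR = 1, negative for protective species
#' (RR < 1), positive for harmful ones (RR > 1).
#'
#' @param rr relative risk (positive).
#' @param p exposure prevalence in (0, 1).
#' @return PARP, in percent. Vectorized over `rr` and `p`.
#' @examples
#' parp(3, 0.5)     # 50
#' parp(0.54, 0.1)  # -4.82...
#' @export
parp <- function(rr, p) {
  if (any(rr <= 0, na.rm = TRUE)) stop_param("rr", "must be positive")
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) stop_param("p", "must be in (0, 1)")
  x <- p * (rr - 1)
  if (any(x <= -1, na.rm = TRUE))
    stop("PARP undefined: P * (RR - 1) <= -1")  # cannot occur for RR>0, P<1
  100 * x / (x + 1)
}

# Shared screen over a spots x labels count matrix.
risk_screen_matrix <- function(counts, damaged, exposure_min_count = 1,
                               fdr = 0.05, conf_level = 0.95) {
  stopifnot(nrow(counts) == length(damaged))
  exposed <- counts >= exposure_min_count
  a <- as.vector(crossprod(exposed, damaged))
  n_exp <- colSums(exposed)
  b <- n_exp - a
  cc <- sum(damaged) - a
  d <- (nrow(counts) - n_exp) - cc
  res <- rr_from_cells(a, b, cc, d, conf_level)
  n <- nrow(counts)
  prevalence <- n_exp / n
  parp_val <- rep(NA_real_, length(a))
  ok <- res$evaluable & prevalence > 0 & prevalence < 1 & !is.na(res$rr)
  parp_val[ok] <- parp(res$rr[ok], prevalence[ok])
  q <- rep(NA_real_, length(a))
  q[res$evaluable] <- p.adjust(res$p[res$evaluable], method = "BH")
  direction <- rep(NA_character_, length(a))
  sig <- !is.na(q) & q < fdr & res$rr != 1
  direction[sig] <- ifelse(res$rr[sig] < 1, "beneficial", "pathogenic")
  tibble::tibble(
    species = colnames(counts),
    a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
    rr = unname(res$rr), ci_low = unname(res$ci_low),
    ci_high = unname(res$ci_high),
    p = unname(res$p), q = unname(q),
    prevalence = unname(prevalence), parp = unname(parp_val),
    continuity_corrected = unname(res$corrected),
    evaluable = unname(res$evaluable),
    direction = unname(direction))
}

#' Screen all species for association with reduced cell viability
#'
#' For every species: the 2x2 exposure-by-damage table (exposure = at least
#' `exposure_min_count` reads in the spot), relative risk with Katz
#' confidence interval, BH-adjusted q-values over the evaluable species,
#' exposure prevalence and PARP. Species with `q < fdr` are labelled
#' beneficial (RR < 1) or pathogenic (RR > 1). The analysis population is
#' restricted to spots from CD samples by default.
#'
#' @param dataset an [sb_dataset], QC-filtered and decontaminated.
#' @param species optional species subset.
#' @param mito_cutoff viability cutoff (default 0.10).
#' @param exposure_min_count minimum read count defining exposure.
#' @param fdr false discovery rate for the direction labels (default 0.05).
#' @param population `"cd_only"` (default) or `"all"` spots.
#' @return tibble of class `sb_risk_table`, one row per species.
#' @examples
#' fx <- worked_fixture()
#' dec <- decontaminate(qc_filter_spots(fx$dataset))
#' head(risk_screen(dec$dataset))
#' @export
risk_screen <- function(dataset, species = NULL, mito_cutoff = 0.10,
                        exposure_min_count = 1, fdr = 0.05,
                        population = c("cd_only", "all")) {
  population <- match.arg(population)
  if (population == "cd_only") dataset <- cd_spots(dataset)
  counts <- dataset$bacteria$single
  if (!is.null(species)) counts <- counts[, species, drop = FALSE]
  if (ncol(counts) == 0L || nrow(counts) == 0L)
    return(risk_screen_matrix(matrix(0L, 0, 0,
                                     dimnames = list(NULL, character())),
                              logical(0)))
  damaged <- classify_viability(dataset, mito_cutoff)
  out <- risk_screen_matrix(counts, damaged,
                            exposure_min_count = exposure_min_count, fdr = fdr)
  class(out) <- c("sb_risk_table", class(out))
  out
}

#' Strain-level relative risk screen
#'
#' Runs the identical risk computation on a strain-resolved count table
#' (same schema as the species table, labels are strain identifiers) and
#' reports the fraction of species-level reads that are resolved to strain
#' level.
#'
#' @param dataset an [sb_dataset] providing the damage classification and
#'   the species-level read total.
#' @param strain_counts spots x strains count matrix, rows named by the
#'   dataset's barcodes (missing spots count as unexposed).
#' @inheritParams risk_screen
#' @return tibble as [risk_screen()], with attribute `resolved_fraction`.
#' @export
strain_level_screen <- function(dataset, strain_counts, mito_cutoff = 0.10,
                                exposure_min_count = 1, fdr = 0.05,
                                population = c("cd_only", "all")) {
  population <- match.arg(population)
  if (population == "cd_only") dataset <- cd_spots(dataset)
  bc <- dataset$spots$barcode
  m <- matrix(0L, length(bc), ncol(strain_counts),
              dimnames = list(bc, colnames(strain_counts)))
  common <- intersect(rownames(strain_counts), bc)
  m[common, ] <- as.matrix(strain_counts[common, , drop = FALSE])
  damaged <- classify_viability(dataset, mito_cutoff)
  out <- risk_screen_matrix(m, damaged,
                            exposure_min_count = exposure_min_count, fdr = fdr)
  total_species <- sum(dataset$bacteria$single)
  attr(out, "resolved_fraction") <-
    if (total_species > 0) sum(m) / total_species else NA_real_
  low <- colSums(m >= exposure_min_count) <= 1
  out$low_exposure <- unname(low)
  class(out) <- c("sb_risk_table", class(out))
  out
}
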