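# Synthetic-data generator: every pipeline input with planted ground truth.

MITO_GENE_NAMES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                     "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                     "MT-ND5", "MT-ND6", "MT-CYB")

DEFAULT_CELL_TYPES <- c("enterocyte", "goblet", "M_cell", "immune_T",
                        "immune_B", "myeloid", "stromal", "tuft")

CONTAMINANT_RULES <- c("spatial_floor", "bulk_floor", "spatial_bulk_ratio",
                       "double_survival")
CONTAMINANT_NAMES <- c("contam_low_reads", "contam_low_bulk",
                       "contam_high_ratio", "contam_low_survival")

#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: sample and
#' spot counts, negative-binomial host expression, sparse per-spot bacterial
#' exposure, planted per-species relative risks of reduced cell viability,
#' planted expression responses to bacterial presence, planted contaminant
#' species (one decontamination rule each), Dirichlet cell-type fractions
#' with an M-cell-enriched stratum of elevated bacterial exposure, and the
#' mitochondrial-fraction link between true spot damage and the observable
#' QC metric.
#'
#' @param n_samples number of tissue samples (one patient per sample).
#' @param n_spots_per_sample spots per sample.
#' @param n_genes total host genes, including mitochondrial genes.
#' @param n_mito_genes number of mitochondrial (`MT-` prefixed) genes.
#' @param n_species total bacterial species including planted contaminants.
#' @param n_contaminant_species number of planted contaminants; contaminant
#'   `k` is constructed to violate decontamination rule `((k-1) mod 4) + 1`
#'   and nothing else.
#' @param planted_rr named numeric vector (names are genuine species) of
#'   planted relative risks of spot damage given exposure; unnamed species
#'   default to 1 (no effect). Values below 1 plant beneficial species,
#'   above 1 pathogenic ones.
#' @param planted_log_fold_change data frame with columns `species`, `gene`,
#'   `lfc`: log2 fold change of the gene's expected expression in spots
#'   exposed to the species (effects of co-exposures add on the log2 scale).
#' @param baseline_damage_rate probability that an unexposed spot is damaged.
#'   Exposure to species `s` multiplies the damage probability by
#'   `planted_rr[s]`; multipliers combine multiplicatively across species and
#'   the product is capped at probability 1.
#' @param exposure_rate scalar or named per-species probability that a spot
#'   in a reference (CD non-inflamed, non-M-cell) stratum is exposed.
#' @param group_exposure_mult named multipliers of the exposure rate per
#'   tissue group (bacterial infiltration is elevated in inflamed tissue).
#' @param m_cell_stratum_frac fraction of spots planted in an M-cell-enriched
#'   stratum; `m_cell_exposure_mult` multiplies their exposure rate.
#' @param m_cell_exposure_mult exposure multiplier of the M-cell stratum.
#' @param dirichlet_alpha named positive vector of Dirichlet concentration
#'   parameters over cell types (default symmetric over 8 types).
#' @param nb_mean mean of the per-gene lognormal baseline expression means.
#' @param nb_dispersion negative-binomial size (dispersion) parameter.
#' @param mean_extra_reads_per_exposed mean additional reads (beyond the
#'   first) in an exposed spot; per-spot counts are `1 + Poisson(this)`.
#' @param bulk_depth_factor expected bulk metagenome reads per spatial read
#'   for genuine species (bulk counts are Poisson around
#'   `bulk_depth_factor` times the species' spatial total).
#' @param mito_mean_damaged,mito_conc_damaged,mito_mean_viable,mito_conc_viable
#'   Beta mean/concentration of the target mitochondrial read fraction for
#'   truly damaged and truly viable spots. Defaults put damaged spots well
#'   above and viable spots well below the 10 percent viability cutoff while
#'   the two distributions still overlap, so downstream classification has
#'   realistic (small) error.
#' @param groups character vector of tissue groups per sample, recycled to
#'   `n_samples`; default cycles control, CD_noninflamed, CD_inflamed.
#' @param seed integer seed; the same configuration always generates
#'   byte-identical outputs.
#' @return An object of class `sb_simulation_config` (a validated list).
#' @seealso [simulate_dataset()], [worked_fixture()]
#' @export
simulation_config <- function(n_samples = 9L,
                              n_spots_per_sample = 250L,
                              n_genes = 300L,
                              n_mito_genes = 13L,
                              n_species = 20L,
                              n_contaminant_species = 4L,
                              planted_rr = NULL,
                              planted_log_fold_change = NULL,
                              baseline_damage_rate = 0.05,
                              exposure_rate = 0.12,
                              group_exposure_mult = c(control = 0.25,
                                                      CD_noninflamed = 1,
                                                      CD_inflamed = 2),
                              m_cell_stratum_frac = 0.15,
                              m_cell_exposure_mult = 3,
                              dirichlet_alpha = NULL,
                              nb_mean = 8,
                              nb_dispersion = 2,
                              mean_extra_reads_per_exposed = 3,
                              bulk_depth_factor = 1,
                              mito_mean_damaged = 0.30,
                              mito_conc_damaged = 40,
                              mito_mean_viable = 0.03,
                              mito_conc_viable = 120,
                              groups = NULL,
                              seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  n_spots_per_sample <- check_count(n_spots_per_sample, "n_spots_per_sample", min = 1L)
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_mito_genes <- check_count(n_mito_genes, "n_mito_genes", min = 1L)
  if (n_mito_genes >= n_genes)
    stop_param("n_mito_genes", "must be smaller than n_genes")
  n_species <- check_count(n_species, "n_species", min = 0L)
  n_contaminant_species <- check_count(n_contaminant_species, "n_contaminant_species")
  if (n_contaminant_species > n_species)
    stop_param("n_contaminant_species", "cannot exceed n_species")
  check_prob(baseline_damage_rate, "baseline_damage_rate")
  check_prob(exposure_rate, "exposure_rate")
  check_prob(m_cell_stratum_frac, "m_cell_stratum_frac")
  check_positive(m_cell_exposure_mult, "m_cell_exposure_mult")
  check_positive(nb_mean, "nb_mean")
  check_positive(nb_dispersion, "nb_dispersion")
  check_positive(bulk_depth_factor, "bulk_depth_factor")
  check_positive(mean_extra_reads_per_exposed, "mean_extra_reads_per_exposed")
  check_prob(mito_mean_damaged, "mito_mean_damaged")
  check_prob(mito_mean_viable, "mito_mean_viable")
  seed <- check_count(abs(seed), "seed")

  if (is.null(dirichlet_alpha))
    dirichlet_alpha <- stats::setNames(rep(1, length(DEFAULT_CELL_TYPES)),
                                       DEFAULT_CELL_TYPES)
  check_positive(dirichlet_alpha, "dirichlet_alpha")
  if (is.null(names(dirichlet_alpha)) || anyDuplicated(names(dirichlet_alpha)))
    stop_param("dirichlet_alpha", "must be a uniquely named vector over cell types")
  if (!"M_cell" %in% names(dirichlet_alpha) && m_cell_stratum_frac > 0)
    stop_param("dirichlet_alpha",
               "must include an `M_cell` type when m_cell_stratum_frac > 0")

  groups <- groups %||% c("control", "CD_noninflamed", "CD_inflamed")
  if (!all(groups %in% c("control", "CD_noninflamed", "CD_inflamed")))
    stop_param("groups", "must be control, CD_noninflamed or CD_inflamed")
  groups <- rep_len(groups, n_samples)
  if (!all(names(group_exposure_mult) %in% c("control", "CD_noninflamed", "CD_inflamed")))
    stop_param("group_exposure_mult", "names must be tissue groups")
  check_positive(group_exposure_mult, "group_exposure_mult")

  n_genuine <- n_species - n_contaminant_species
  genuine <- if (n_genuine > 0) sprintf("species_%02d", seq_len(n_genuine)) else character()
  contam <- contaminant_labels(n_contaminant_species)

  rr <- stats::setNames(rep(1, n_genuine), genuine)
  if (!is.null(planted_rr)) {
    if (is.null(names(planted_rr)) || !all(names(planted_rr) %in% genuine))
      stop_param("planted_rr", "must be named by genuine species labels")
    check_positive(planted_rr, "planted_rr")
    rr[names(planted_rr)] <- planted_rr
  }

  exposure <- if (length(exposure_rate) == 1L) {
    stats::setNames(rep(exposure_rate, n_genuine), genuine)
  } else {
    if (is.null(names(exposure_rate)) || !all(genuine %in% names(exposure_rate)))
      stop_param("exposure_rate", "must be scalar or named for every genuine species")
    exposure_rate[genuine]
  }

  if (!is.null(planted_log_fold_change)) {
    planted_log_fold_change <- as.data.frame(planted_log_fold_change)
    if (!all(c("species", "gene", "lfc") %in% names(planted_log_fold_change)))
      stop_param("planted_log_fold_change",
                 "must have columns species, gene, lfc")
    if (!all(planted_log_fold_change$species %in% genuine))
      stop_param("planted_log_fold_change", "species must be genuine species labels")
  }

  structure(list(
    n_samples = n_samples, n_spots_per_sample = n_spots_per_sample,
    n_genes = n_genes, n_mito_genes = n_mito_genes,
    n_species = n_species, n_contaminant_species = n_contaminant_species,
    genuine_species = genuine, contaminant_species = contam,
    planted_rr = rr, planted_log_fold_change = planted_log_fold_change,
    baseline_damage_rate = baseline_damage_rate,
    exposure_rate = exposure,
    group_exposure_mult = group_exposure_mult,
    m_cell_stratum_frac = m_cell_stratum_frac,
    m_cell_exposure_mult = m_cell_exposure_mult,
    dirichlet_alpha = dirichlet_alpha,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    mean_extra_reads_per_exposed = mean_extra_reads_per_exposed,
    bulk_depth_factor = bulk_depth_factor,
    mito_mean_damaged = mito_mean_damaged, mito_conc_damaged = mito_conc_damaged,
    mito_mean_viable = mito_mean_viable, mito_conc_viable = mito_conc_viable,
    groups = groups, seed = seed
  ), class = "sb_simulation_config")
}

contaminant_labels <- function(k) {
  if (k == 0L) return(character())
  base <- CONTAMINANT_NAMES[(seq_len(k) - 1L) %% 4L + 1L]
  cycle <- (seq_len(k) - 1L) %/% 4L
  ifelse(cycle == 0L, base, paste0(base, "_", cycle + 1L))
}

contaminant_rule_for <- function(k) CONTAMINANT_RULES[(seq_len(k) - 1L) %% 4L + 1L]

#' Simulate a complete spatial host-microbiome dataset with ground truth
#'
#' Generates every input the pipeline consumes: negative-binomial host gene
#' counts with a mitochondrial gene subset, sparse per-spot bacterial counts
#' under single and double human-read removal, bulk metagenome species
#' counts, Dirichlet cell-type fractions and spot/patient metadata -- plus a
#' ground-truth sidecar recording the planted contaminants (one
#' decontamination rule each), the planted beneficial/pathogenic species and
#' the true per-spot damage state.
#'
#' The generative model, in order: spots are assigned to samples and groups;
#' an M-cell-enriched stratum is planted with elevated bacterial exposure;
#' per-spot exposure to each genuine species is Bernoulli with a rate scaled
#' by group and stratum; the damage probability of a spot is the baseline
#' rate times the product of `planted_rr` over the species it is exposed to,
#' capped at 1; damaged spots draw their mitochondrial read fraction from a
#' Beta distribution centred above the 10 percent viability cutoff, viable
#' spots below it; host counts are negative binomial with planted log2 fold
#' changes applied in exposed spots; bulk counts are Poisson around
#' spatial-proportional expectations; double-removal counts are a thinned
#' copy of single-removal counts with per-species survival factors (at least
#' 0.55 for genuine species, below 0.02 for the planted human-read-artifact
#' contaminant).
#'
#' @param config an [simulation_config()] object.
#' @return list with elements `dataset` (an [sb_dataset]) and `ground_truth`
#'   (contaminants and their rules, beneficial/pathogenic label sets, the
#'   planted relative risks, per-spot true damage states, M-cell stratum
#'   barcodes, per-species double-removal survival factors).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_samples = 3,
#'   n_spots_per_sample = 40, n_genes = 50, n_species = 8,
#'   n_contaminant_species = 4, seed = 7))
#' sim$dataset
#' sim$ground_truth$contaminants
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sb_simulation_config"))
    stop_param("config", "must be created by simulation_config()")
  set.seed(config$seed)

  n_samples <- config$n_samples
  n_per <- config$n_spots_per_sample
  n_spots <- n_samples * n_per
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  patient_ids <- sprintf("P%02d", seq_len(n_samples))
  groups <- config$groups

  spot_sample <- rep(sample_ids, each = n_per)
  spot_group <- rep(groups, each = n_per)
  spot_patient <- rep(patient_ids, each = n_per)
  barcodes <- paste0(spot_sample, "_", sprintf("%05d", rep(seq_len(n_per), n_samples)))
  grid_w <- ceiling(sqrt(n_per))
  xy <- cbind(x = ((seq_len(n_per) - 1L) %% grid_w) + 1L,
              y = ((seq_len(n_per) - 1L) %/% grid_w) + 1L)
  xy <- xy[rep(seq_len(n_per), n_samples), , drop = FALSE]

  cell_types <- names(config$dirichlet_alpha)
  in_mcell <- runif(n_spots) < config$m_cell_stratum_frac
  alpha <- matrix(config$dirichlet_alpha, n_spots, length(cell_types), byrow = TRUE)
  if (any(in_mcell))
    alpha[in_mcell, cell_types == "M_cell"] <-
      alpha[in_mcell, cell_types == "M_cell"] * 8
  fractions <- matrix(rgamma(n_spots * length(cell_types), shape = alpha),
                      n_spots, length(cell_types))
  fractions <- fractions / rowSums(fractions)
  dimnames(fractions) <- list(barcodes, cell_types)

  # --- bacterial exposure and single-removal counts ----------------------
  genuine <- config$genuine_species
  contam <- config$contaminant_species
  contam_rule <- contaminant_rule_for(length(contam))
  species <- c(genuine, contam)
  mult <- unname(config$group_exposure_mult[spot_group]) *
    ifelse(in_mcell, config$m_cell_exposure_mult, 1)

  single <- matrix(0L, n_spots, length(species),
                   dimnames = list(barcodes, species))
  draw_exposure_counts <- function(rate) {
    p <- pmin(0.95, rate * mult)
    exposed <- runif(n_spots) < p
    counts <- integer(n_spots)
    counts[exposed] <- 1L + rpois(sum(exposed), config$mean_extra_reads_per_exposed)
    counts
  }
  for (s in genuine)
    single[, s] <- draw_exposure_counts(config$exposure_rate[[s]])
  # rule-4 contaminants look genuine in the single-removal table
  rate_ref <- if (length(genuine)) mean(config$exposure_rate) else 0.1
  for (j in which(contam_rule == "double_survival"))
    single[, contam[j]] <- draw_exposure_counts(rate_ref)

  bulk <- stats::setNames(numeric(length(species)), species)
  ok_bulk <- c(genuine, contam[contam_rule == "double_survival"])
  bulk[ok_bulk] <- rpois(length(ok_bulk),
                         config$bulk_depth_factor * colSums(single[, ok_bulk, drop = FALSE]))
  # genuine species must clear the bulk read floor; keep Poisson noise but
  # guard the lower tail so low-abundance genuine species stay retainable
  bulk[ok_bulk] <- pmax(bulk[ok_bulk], 55)

  scatter_reads <- function(n_reads) {
    counts <- integer(n_spots)
    if (n_reads > 0) {
      idx <- sample.int(n_spots, n_reads, replace = TRUE)
      tab <- tabulate(idx, nbins = n_spots)
      counts <- as.integer(tab)
    }
    counts
  }
  # rule-1 contaminants: exactly 49 spatial reads (just below the floor),
  # healthy bulk representation so no other rule fires
  for (j in which(contam_rule == "spatial_floor")) {
    single[, contam[j]] <- scatter_reads(49L)
    bulk[contam[j]] <- 100 + rpois(1, 25)
  }
  stot_ref <- sum(single)
  btot_ref <- max(1, sum(bulk))
  # rule-2 contaminants: bulk reads just below the floor; spatial total
  # scaled so the spatial/bulk share ratio stays clearly below 1.5
  for (j in which(contam_rule == "bulk_floor")) {
    b2 <- 45L
    n2 <- max(55L, as.integer(round(1.2 * b2 * stot_ref / btot_ref)))
    single[, contam[j]] <- scatter_reads(n2)
    bulk[contam[j]] <- b2
  }
  # rule-3 contaminants: overrepresented spatially (share ratio ~2.5) while
  # clearing both read floors
  for (j in which(contam_rule == "spatial_bulk_ratio")) {
    b3 <- max(55L, as.integer(round(0.016 * btot_ref)))
    n3 <- as.integer(round(2.5 * b3 * stot_ref / btot_ref))
    single[, contam[j]] <- scatter_reads(n3)
    bulk[contam[j]] <- b3
  }

  # --- double-removal counts --------------------------------------------
  survival <- stats::setNames(runif(length(species), 0.55, 0.95), species)
  survival[contam[contam_rule == "double_survival"]] <- 0.015
  double <- single
  for (s in species) {
    tot <- sum(single[, s])
    if (tot == 0) next
    if (s %in% contam[contam_rule == "double_survival"]) {
      # deterministic thinning: keep floor(0.015 * total) reads, guaranteeing
      # realized survival below the 2 percent cutoff
      target <- as.integer(floor(0.015 * tot))
      reads <- rep.int(seq_len(n_spots), single[, s])
      keep <- if (target > 0) sample(reads, target) else integer()
      double[, s] <- as.integer(tabulate(keep, nbins = n_spots))
    } else {
      double[, s] <- rbinom(n_spots, single[, s], survival[[s]])
    }
  }

  # --- true damage state and mitochondrial fraction ----------------------
  log_rr <- log(config$planted_rr)
  risk_mult <- if (length(genuine)) {
    exp(as.vector((single[, genuine, drop = FALSE] > 0) %*% log_rr))
  } else rep(1, n_spots)
  p_damage <- pmin(1, config$baseline_damage_rate * risk_mult)
  damaged <- runif(n_spots) < p_damage
  shape_d <- c(config$mito_mean_damaged, 1 - config$mito_mean_damaged) * config$mito_conc_damaged
  shape_v <- c(config$mito_mean_viable, 1 - config$mito_mean_viable) * config$mito_conc_viable
  mito_target <- ifelse(damaged,
                        rbeta(n_spots, shape_d[1], shape_d[2]),
                        rbeta(n_spots, shape_v[1], shape_v[2]))
  mito_target <- pmin(mito_target, 0.9)

  # --- host expression ---------------------------------------------------
  n_mito <- config$n_mito_genes
  n_nonmito <- config$n_genes - n_mito
  gene_names <- sprintf("GENE_%04d", seq_len(n_nonmito))
  mito_names <- if (n_mito <= length(MITO_GENE_NAMES)) {
    MITO_GENE_NAMES[seq_len(n_mito)]
  } else {
    c(MITO_GENE_NAMES, sprintf("MT-G%02d", seq_len(n_mito - length(MITO_GENE_NAMES))))
  }
  mu_g <- rlnorm(n_nonmito, meanlog = log(config$nb_mean) - 0.245, sdlog = 0.7)
  log2fac <- NULL
  lfc_tab <- config$planted_log_fold_change
  if (!is.null(lfc_tab) && nrow(lfc_tab)) {
    lfc_species <- unique(lfc_tab$species)
    lfc_mat <- matrix(0, length(lfc_species), n_nonmito,
                      dimnames = list(lfc_species, gene_names))
    bad <- setdiff(unique(lfc_tab$gene), gene_names)
    if (length(bad))
      stop_param("planted_log_fold_change",
                 paste("unknown genes:", paste(bad, collapse = ", ")))
    lfc_mat[cbind(lfc_tab$species, lfc_tab$gene)] <- lfc_tab$lfc
    log2fac <- (single[, lfc_species, drop = FALSE] > 0) %*% lfc_mat  # spots x genes
  }
  mu <- matrix(mu_g, n_nonmito, n_spots)  # genes x spots
  if (!is.null(log2fac)) mu <- mu * 2^t(log2fac)
  host_nonmito <- matrix(rnbinom(n_nonmito * n_spots, mu = mu,
                                 size = config$nb_dispersion),
                         n_nonmito, n_spots)
  s_tot <- colSums(host_nonmito)
  m_tot <- as.integer(round(mito_target / (1 - mito_target) * s_tot))
  mito_weights <- runif(n_mito, 0.5, 1.5)
  mito_weights <- mito_weights / sum(mito_weights)
  host_mito <- vapply(seq_len(n_spots), function(i) {
    if (m_tot[i] == 0) return(integer(n_mito))
    as.integer(rmultinom(1, m_tot[i], mito_weights))
  }, integer(n_mito))
  host_mito <- matrix(host_mito, n_mito, n_spots)
  host <- rbind(host_nonmito, host_mito)
  dimnames(host) <- list(c(gene_names, mito_names), barcodes)
  host <- methods::as(Matrix::Matrix(host, sparse = TRUE), "CsparseMatrix")

  total_gene_counts <- s_tot + m_tot
  mito_fraction <- ifelse(total_gene_counts > 0, m_tot / total_gene_counts, 0)
  total_reads <- as.integer(round(total_gene_counts * runif(n_spots, 2, 3))) +
    rowSums(single)

  # --- patient metadata --------------------------------------------------
  rutgeerts <- rep(NA_integer_, n_samples)
  rutgeerts[groups == "CD_noninflamed"] <- sample(0:2, sum(groups == "CD_noninflamed"), TRUE)
  rutgeerts[groups == "CD_inflamed"] <- sample(2:4, sum(groups == "CD_inflamed"), TRUE)
  relapse_p <- c(control = 0, CD_noninflamed = 0.3, CD_inflamed = 0.7)
  relapse <- runif(n_samples) < relapse_p[groups]
  ttr <- rep(NA_real_, n_samples)
  ttr[relapse] <- pmax(1, round(runif(sum(relapse), 6, 30) - 3 * rutgeerts[relapse]))
  patients <- tibble::tibble(patient_id = patient_ids, group = groups,
                             time_to_relapse = ttr, rutgeerts = rutgeerts)

  spots <- tibble::tibble(
    barcode = barcodes, sample_id = spot_sample, patient_id = spot_patient,
    group = spot_group, x = xy[, "x"], y = xy[, "y"],
    total_sequencing_reads = total_reads,
    total_gene_counts = total_gene_counts,
    mito_fraction = mito_fraction,
    area_label = NA_character_)
  genes <- tibble::tibble(gene = rownames(host),
                          is_mito = startsWith(tolower(rownames(host)), "mt-"))

  dataset <- sb_dataset(
    spots = spots, genes = genes, host_counts = host,
    bacteria = list(single = single, double = double),
    bulk_counts = bulk, fractions = fractions, patients = patients)

  rr <- config$planted_rr
  ground_truth <- structure(list(
    contaminants = tibble::tibble(species = contam, rule = contam_rule),
    beneficial_species = names(rr)[rr < 1],
    pathogenic_species = names(rr)[rr > 1],
    planted_rr = rr,
    planted_log_fold_change = lfc_tab,
    true_damage = stats::setNames(damaged, barcodes),
    m_cell_spots = barcodes[in_mcell],
    survival_factors = survival,
    seed = config$seed
  ), class = "sb_ground_truth")

  list(dataset = dataset, ground_truth = ground_truth)
}

#' A small deterministic worked dataset
#'
#' A fixed 180-spot, 20-species, 120-gene simulation used in documentation
#' examples and tests: 4 planted contaminants (one per decontamination rule,
#' with the spatial-floor contaminant at exactly 49 reads), 6 beneficial
#' species (planted RR 0.4), 6 pathogenic species (planted RR 2.5), 4
#' neutral species, and two three-gene expression programs responding in
#' opposite directions to beneficial and pathogenic exposure.
#'
#' @return list with `dataset` and `ground_truth`, as [simulate_dataset()].
#' @examples
#' fx <- worked_fixture()
#' fx$dataset
#' @export
worked_fixture <- function() {
  beneficial <- sprintf("species_%02d", 1:6)
  pathogenic <- sprintf("species_%02d", 7:12)
  lfc <- rbind(
    expand.grid(species = beneficial, gene = sprintf("GENE_%04d", 1:3),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    expand.grid(species = pathogenic, gene = sprintf("GENE_%04d", 4:6),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  lfc$lfc <- 1.5
  # programs: genes 1-3 up with beneficial, genes 4-6 up with pathogenic,
  # genes 11-13 down with beneficial, genes 14-16 down with pathogenic
  down <- rbind(
    expand.grid(species = beneficial, gene = sprintf("GENE_%04d", 11:13),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    expand.grid(species = pathogenic, gene = sprintf("GENE_%04d", 14:16),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  down$lfc <- -1.5
  config <- simulation_config(
    n_samples = 3L, n_spots_per_sample = 60L,
    n_genes = 120L, n_mito_genes = 10L,
    n_species = 20L, n_contaminant_species = 4L,
    planted_rr = stats::setNames(c(rep(0.4, 6), rep(2.5, 6)),
                                 c(beneficial, pathogenic)),
    planted_log_fold_change = rbind(lfc, down),
    exposure_rate = 0.15,
    seed = 20260921L)
  simulate_dataset(config)
}

#' Write the ground-truth sidecar of a simulation
#'
#' Ground truth is written as a JSON sidecar that the analysis pipeline
#' never reads; it exists so tests and audits can compare recovered results
#' against the planted truth.
#'
#' @param ground_truth the `ground_truth` element of [simulate_dataset()].
#' @param path output JSON file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$true_damage <- list(barcode = names(gt$true_damage),
                         damaged = unname(gt$true_damage))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
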