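test_that("normalization scales to target depth then log1p", {
  fx <- get_fixture()
  d <- fx$dataset
  # hand spot: counts (2, 0, 8) at target 10 stay (2, 0, 8)
  m <- matrix(0, nrow(d$host_counts), 3,
              dimnames = list(rownames(d$host_counts), c("s1", "s2", "s3")))
  m[1:3, 1] <- c(2, 0, 8)
  m[1:3, 2] <- c(1, 1, 2)
  m[4, 3] <- 4
  d$host_counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  d$spots <- d$spots[1:3, ]
  expr <- suppressMessages(normalize_expression(d, target_sum = 10, min_spots = 0))
  expect_equal(unname(expr[1:3, "s1"]), log1p(c(2, 0, 8)))
  expect_equal(unname(expr[1:3, "s2"]), log1p(c(2.5, 2.5, 5)))
  # oracle recomputation across the worked fixture
  fxd <- fx$dataset
  expr2 <- suppressMessages(normalize_expression(fxd, min_spots = 5))
  j <- 10
  counts <- as.matrix(fxd$host_counts[!fxd$genes$is_mito, ])
  depth_j <- sum(counts[, j])  # depth over all non-mito genes, pre-drop
  expect_equal(expr2[, j],
               log1p(counts[rownames(expr2), j] / depth_j * 1e4))
})

test_that("all-zero genes and zero-count spots are dropped", {
  fx <- get_fixture()
  d <- fx$dataset
  hc <- as.matrix(d$host_counts)
  hc["GENE_0050", ] <- 0
  hc[, 5] <- 0
  d$host_counts <- methods::as(Matrix::Matrix(hc, sparse = TRUE), "CsparseMatrix")
  expect_warning(
    expect_message(expr <- normalize_expression(d), "dropping"),
    "zero total")
  expect_false("GENE_0050" %in% rownames(expr))
  expect_false(d$spots$barcode[5] %in% colnames(expr))
})

test_that("dge on identical distributions is null; labels swap antisymmetrically", {
  set.seed(23)
  expr <- matrix(rnorm(50 * 60), 50, 60,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  exposed <- rep(c(TRUE, FALSE), each = 30)
  d1 <- dge_by_exposure(expr, exposed)
  expect_lt(max(abs(d1$z)), 4)
  expect_gt(min(d1$q), 0.2)
  d2 <- dge_by_exposure(expr, !exposed)
  expect_equal(d2$z, -d1$z)
  expect_equal(d2$p, d1$p)
  # too-small group is skipped with a message
  expect_message(res <- dge_by_exposure(expr, rep(c(TRUE, FALSE), c(3, 57))),
                 "skipped")
  expect_null(res)
})

test_that("dge p-values are exact for small untied groups", {
  set.seed(9)
  expr <- matrix(rnorm(10 * 14), 10, 14,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  exposed <- rep(c(TRUE, FALSE), c(6, 8))
  d <- dge_by_exposure(expr, exposed, min_group_size = 3)
  for (i in c(1, 5, 10)) {
    expect_equal(d$p[i], oracle_ranksum_p(expr[i, exposed], expr[i, !exposed]),
                 tolerance = 1e-12)
  }
  # a gene entirely higher in the exposed group attains the extreme tail
  expr[1, exposed] <- 100 + seq_len(6)
  d2 <- dge_by_exposure(expr, exposed, min_group_size = 3)
  expect_equal(d2$p[1], 2 / choose(14, 6))
  expect_gt(d2$z[1], 0)
})

test_that("planted expression responses are recovered with correct sign", {
  lfc <- data.frame(species = "species_01",
                    gene = c("GENE_0001", "GENE_0002"),
                    lfc = c(1.2, -1.2))
  sim <- flat_sim(n_samples = 2, n_spots_per_sample = 400, seed = 41,
                  n_species = 4, n_contaminant_species = 0, n_genes = 60,
                  n_mito_genes = 5, planted_log_fold_change = lfc,
                  exposure_rate = 0.2)
  d <- qc_filter_spots(sim$dataset)
  expr <- suppressMessages(normalize_expression(d))
  dg <- dge_by_exposure(expr, d$bacteria$single[, "species_01"] > 0)
  up <- dg[dg$gene == "GENE_0001", ]
  down <- dg[dg$gene == "GENE_0002", ]
  expect_lt(up$q, 0.05); expect_gt(up$z, 0)
  expect_lt(down$q, 0.05); expect_lt(down$z, 0)
})

test_that("consistency screen calls pan-species signature genes", {
  species <- sprintf("species_%02d", 1:5)
  lfc <- rbind(
    expand.grid(species = species, gene = c("GENE_0001", "GENE_0002"),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    expand.grid(species = species, gene = "GENE_0003",
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  lfc$lfc <- rep(c(1.2, -1.2), c(10, 5))
  sim <- flat_sim(n_samples = 2, n_spots_per_sample = 500, seed = 43,
                  n_species = 5, n_contaminant_species = 0, n_genes = 80,
                  n_mito_genes = 5, planted_log_fold_change = lfc,
                  exposure_rate = 0.2)
  d <- qc_filter_spots(sim$dataset)
  expr <- suppressMessages(normalize_expression(d))
  cs <- consistency_screen(expr, d$bacteria$single, species)
  expect_true(all(c("GENE_0001", "GENE_0002") %in% cs$consistently_up))
  expect_true("GENE_0003" %in% cs$consistently_down)
  stats <- cs$gene_stats
  expect_equal(stats$consistency_rate[stats$gene == "GENE_0001"], 1)
  expect_equal(stats$direction_agreement[stats$gene == "GENE_0001"], 1)
  expect_true(all(stats$consistency_rate >= 0 & stats$consistency_rate <= 1))
  ok <- !is.na(stats$direction_agreement)
  expect_true(all(stats$direction_agreement[ok] >= 0 &
                    stats$direction_agreement[ok] <= 1))
})

test_that("a gene split across opposite signs is not called consistent", {
  # synthetic z/significance pattern via a constructed expression matrix:
  # gene responds +- across species exposed to disjoint spot sets
  set.seed(77)
  n <- 200
  expo <- cbind(sA = rep(c(TRUE, FALSE, FALSE), length.out = n),
                sB = rep(c(FALSE, TRUE, FALSE), length.out = n))
  expr <- matrix(rnorm(2 * n, sd = 0.1), 2, n,
                 dimnames = list(c("gSplit", "gNull"), NULL))
  expr["gSplit", expo[, "sA"]] <- expr["gSplit", expo[, "sA"]] + 3
  expr["gSplit", expo[, "sB"]] <- expr["gSplit", expo[, "sB"]] - 3
  cs <- consistency_screen(expr, expo)
  stats <- cs$gene_stats[cs$gene_stats$gene == "gSplit", ]
  expect_equal(stats$consistency_rate, 1)
  expect_equal(stats$direction_agreement, 0.5)
  expect_false("gSplit" %in% cs$consistently_up)
  expect_false("gSplit" %in% cs$consistently_down)
})

test_that("pair comparison enumerates |B| x |P| pairs and is antisymmetric", {
  fx <- get_fixture()
  dec <- decontaminate(fx$dataset)
  d <- qc_filter_spots(dec$dataset)
  expr <- suppressMessages(normalize_expression(d, min_spots = 5))
  gt <- fx$ground_truth
  pc <- pair_comparison(expr, d$bacteria$single,
                        gt$beneficial_species, gt$pathogenic_species,
                        min_group_size = 3)
  expect_identical(nrow(pc$pairs),
                   length(gt$beneficial_species) * length(gt$pathogenic_species))
  pc_swap <- pair_comparison(expr, d$bacteria$single,
                             gt$pathogenic_species, gt$beneficial_species,
                             min_group_size = 3)
  # swapping the sets negates every evaluated z (pair grid is transposed)
  for (k in which(pc$pairs$evaluated)[1:5]) {
    id <- paste(pc$pairs$pathogenic[k], pc$pairs$beneficial[k], sep = "|")
    expect_equal(pc_swap$z[, id], -pc$z[, k])
  }
  # the planted beneficial program gene is higher with beneficial exposure
  gstat <- pc$gene_stats[pc$gene_stats$gene == "GENE_0001", ]
  expect_gt(mean(pc$z["GENE_0001", pc$pairs$evaluated]), 0)
})

test_that("degenerate pair sets are skipped or error out", {
  fx <- get_fixture()
  dec <- decontaminate(fx$dataset)
  d <- qc_filter_spots(dec$dataset)
  expr <- suppressMessages(normalize_expression(d, min_spots = 5))
  # same singleton on both sides: zero singly-exposed spots, all skipped
  expect_error(pair_comparison(expr, d$bacteria$single,
                               "species_01", "species_01", min_group_size = 3),
               "all pairs skipped")
  expect_error(pair_comparison(expr, d$bacteria$single,
                               character(), "species_01"),
               "non-empty")
})
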