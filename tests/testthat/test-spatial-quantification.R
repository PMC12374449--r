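test_that("per-spot load is the row sum of CPM over retained species", {
  fx <- get_fixture()
  dec <- decontaminate(fx$dataset)
  loads <- per_spot_load(dec$dataset)
  # brute force for a handful of spots
  d <- dec$dataset
  for (i in c(1, 25, 90)) {
    expect_equal(loads[[i]],
                 sum(d$bacteria$single[i, ] / d$spots$total_sequencing_reads[i] * 1e6))
  }
  zero <- rowSums(d$bacteria$single) == 0
  if (any(zero)) expect_true(all(loads[zero] == 0))
  # 5 reads at 1e6 total reads is 5 CPM
  d$bacteria$single[1, ] <- 0L
  d$bacteria$single[1, 1] <- 5L
  d$spots$total_sequencing_reads[1] <- 1e6L
  expect_equal(per_spot_load(d)[[1]], 5)
})

test_that("group_compare recovers exact rank-sum tails and exchangeability", {
  # {0,0,0} vs {10,10,10}: most extreme assignment of 3+3
  gc <- group_compare(c(0, 0, 0, 10, 10, 10), rep(c("a", "b"), each = 3))
  expect_equal(gc$summary$mean_cpm, c(0, 10))
  expect_equal(gc$pairwise$p, 2 / choose(6, 3))  # = 0.1, exact enumeration
  expect_identical(gc$pairwise$stars, "ns")
  # identical distributions: maximal p
  gc2 <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gte(gc2$pairwise$p, 1)
  # relabeling groups permutes, not changes, the summary
  set.seed(1)
  x <- rnorm(60)
  g <- rep(c("g1", "g2", "g3"), each = 20)
  a <- group_compare(x, g)
  swap <- c(g1 = "g2", g2 = "g1", g3 = "g3")
  b <- group_compare(x, unname(swap[g]))
  expect_equal(a$summary$mean_cpm[a$summary$group == "g1"],
               b$summary$mean_cpm[b$summary$group == "g2"])
  pa <- a$pairwise[a$pairwise$group1 == "g1" & a$pairwise$group2 == "g2", ]
  pb <- b$pairwise[b$pairwise$group1 == "g1" & b$pairwise$group2 == "g2", ]
  expect_equal(pa$p, pb$p)
})

test_that("rank-sum p-values match the exact-enumeration oracle", {
  set.seed(5)
  for (i in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    t <- rank_sum_test(x, y)
    expect_equal(t$p, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("planted group ordering is recovered on the fixture", {
  fx <- get_fixture()
  dec <- decontaminate(fx$dataset)
  loads <- per_spot_load(dec$dataset)
  gc <- group_compare(loads, dec$dataset$spots$group)
  m <- gc$summary$mean_cpm[match(c("control", "CD_noninflamed", "CD_inflamed"),
                                 gc$summary$group)]
  expect_true(all(diff(m) > 0))
})

test_that("patient table equals brute-force per-patient means", {
  fx <- get_fixture()
  d <- fx$dataset
  loads <- per_spot_load(d)
  pt <- patient_prognosis_table(loads, d)
  for (p in pt$table$patient_id) {
    expect_equal(pt$table$mean_cpm[pt$table$patient_id == p],
                 mean(loads[d$spots$patient_id == p]))
  }
  expect_identical(nrow(pt$table), nrow(d$patients))
})

test_that("prognosis correlations handle extremes and tiny n", {
  fx <- get_fixture()
  d <- fx$dataset
  # perfectly anti-monotone time-to-relapse fixture
  loads <- per_spot_load(d)
  pt0 <- patient_prognosis_table(loads, d)
  d$patients$time_to_relapse <- nrow(d$patients) + 1 - rank(pt0$table$mean_cpm)
  pt <- patient_prognosis_table(loads, d)
  rho <- pt$correlations$rho[pt$correlations$variable == "time_to_relapse"]
  expect_equal(rho, -1)
  # single patient: correlations not computable
  one <- d
  keep <- d$spots$patient_id == d$patients$patient_id[1]
  one$spots <- d$spots[keep, ]
  one$bacteria$single <- d$bacteria$single[keep, , drop = FALSE]
  one$bacteria$double <- d$bacteria$double[keep, , drop = FALSE]
  one$host_counts <- d$host_counts[, keep]
  one$fractions <- d$fractions[keep, , drop = FALSE]
  pt1 <- patient_prognosis_table(per_spot_load(one), one)
  expect_identical(nrow(pt1$table), 1L)
  expect_true(all(is.na(pt1$correlations$rho)))
})

test_that("colocalization reduces to the identity on a 2x2 hand example", {
  fx <- get_fixture()
  d <- fx$dataset
  d$spots <- d$spots[1:2, ]
  d$bacteria$single <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                              dimnames = list(d$spots$barcode, c("sA", "sB")))
  d$bacteria$double <- d$bacteria$single
  d$host_counts <- d$host_counts[, 1:2]
  d$fractions <- matrix(c(1, 0, 0, 1), 2, 2,
                        dimnames = list(d$spots$barcode, c("ct1", "ct2")))
  co <- colocalization(d)
  expect_equal(unname(co$weights), diag(2))
  expect_equal(unname(co$probability), diag(2))
})

test_that("colocalization weights conserve species totals exactly", {
  fx <- get_fixture()
  co <- colocalization(fx$dataset)
  expect_equal(rowSums(co$weights),
               colSums(fx$dataset$bacteria$single)[rownames(co$weights)])
  # probability rows sum to 1 for species with any reads
  has <- colSums(fx$dataset$bacteria$single) > 0
  expect_equal(unname(rowSums(co$probability[has, ])),
               rep(1, sum(has)))
})

test_that("fractions concentrated on one type put all probability there", {
  fx <- get_fixture()
  d <- fx$dataset
  d$fractions[] <- 0
  d$fractions[, "goblet"] <- 1
  co <- colocalization(d)
  has <- rowSums(co$weights) > 0
  expect_true(all(co$probability[has, "goblet"] == 1))
})

test_that("the planted M-cell association shows up in colocalization", {
  fx <- get_fixture()
  dec <- decontaminate(fx$dataset)
  gt <- fx$ground_truth
  co <- colocalization(dec$dataset,
                       beneficial = gt$beneficial_species,
                       pathogenic = gt$pathogenic_species)
  # exposed species co-localize with M cells above the Dirichlet background
  # share (1/8 of mass under symmetric alpha)
  expect_gt(mean(co$probability[, "M_cell"], na.rm = TRUE), 1 / 8)
  expect_true(is.data.frame(co$group_fc))
  expect_identical(nrow(co$group_fc), ncol(fx$dataset$fractions))
})
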