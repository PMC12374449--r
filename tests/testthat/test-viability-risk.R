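test_that("viability classification boundary is inclusive at the cutoff", {
  fx <- get_fixture()
  d <- fx$dataset
  d$spots$mito_fraction[1:3] <- c(0.10, 0.101, 0)
  dam <- classify_viability(d)
  expect_identical(unname(dam[1:3]), c(FALSE, TRUE, FALSE))
  expect_error(classify_viability(d, mito_cutoff = -1), "mito_cutoff",
               class = "spotbiome_param_error")
})

test_that("relative risk evaluates the 2x2 formula directly", {
  rr <- relative_risk(rep(c(TRUE, FALSE), c(100, 200)),
                      rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 20, 180)))
  expect_equal(rr$rr, 3)  # (30/100) / (20/200)
  expect_identical(c(rr$a, rr$b, rr$c, rr$d), c(30L, 70L, 20L, 180L))
  expect_false(rr$continuity_corrected)
  # equal damage rates in both arms
  rr1 <- relative_risk(rep(c(TRUE, FALSE), each = 100),
                       rep(rep(c(TRUE, FALSE), c(20, 80)), 2))
  expect_equal(rr1$rr, 1)
  expect_true(rr1$ci_low <= 1 && 1 <= rr1$ci_high)
})

test_that("relative risk matches a brute-force oracle on random tables", {
  set.seed(11)
  for (i in 1:200) {
    cells <- rmultinom(1, sample(50:400, 1), runif(4, 0.05, 1))
    exposed <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    damaged <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    got <- relative_risk(exposed, damaged)
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    if (a + b == 0 || cc + d == 0) {
      expect_false(got$evaluable)
      next
    }
    if (a == 0 || cc == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    want_rr <- (a / (a + b)) / (cc / (cc + d))
    se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
    expect_equal(got$rr, want_rr, tolerance = 1e-12)
    expect_equal(got$ci_low, exp(log(want_rr) - qnorm(0.975) * se), tolerance = 1e-12)
    expect_equal(got$ci_high, exp(log(want_rr) + qnorm(0.975) * se), tolerance = 1e-12)
    expect_true(got$ci_low <= got$rr && got$rr <= got$ci_high)
  }
})

test_that("zero cells trigger the flagged continuity correction", {
  rr <- relative_risk(rep(c(TRUE, FALSE), c(50, 50)),
                      rep(c(FALSE, TRUE, FALSE), c(50, 10, 40)))
  expect_true(rr$continuity_corrected)
  expect_true(is.finite(rr$rr) && rr$rr > 0)
  # no exposed spots: not evaluable
  rr2 <- relative_risk(rep(FALSE, 100), rep(c(TRUE, FALSE), 50))
  expect_false(rr2$evaluable)
  expect_true(is.na(rr2$rr))
})

test_that("PARP matches hand values and is monotone in prevalence", {
  expect_identical(parp(1, 0.3), 0)
  expect_identical(parp(1, 0.9), 0)
  expect_equal(parp(3, 0.5), 50)
  expect_equal(parp(0.54, 0.1), 100 * 0.1 * (0.54 - 1) / (0.1 * (0.54 - 1) + 1))
  expect_equal(round(parp(0.54, 0.1), 2), -4.82)
  grid <- seq(0.01, 0.99, length.out = 99)
  for (rr in c(0.2, 0.54, 1.5, 3)) {
    v <- parp(rr, grid)
    if (rr > 1) expect_true(all(diff(v) > 0)) else expect_true(all(diff(v) < 0))
    expect_true(all(sign(v) == sign(rr - 1)))
  }
  expect_error(parp(-1, 0.5), "rr", class = "spotbiome_param_error")
  expect_error(parp(2, 1), "p", class = "spotbiome_param_error")
})

test_that("BH adjustment equals an independent step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))  # hand application of step-up
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("risk_screen restricts to CD spots and labels directions", {
  fx <- get_fixture()
  dec <- decontaminate(fx$dataset)
  d <- qc_filter_spots(dec$dataset)
  rs <- risk_screen(d)
  n_cd <- sum(d$spots$group != "control")
  expect_true(all(rs$a + rs$b + rs$c + rs$d == n_cd))
  rs_all <- risk_screen(d, population = "all")
  expect_true(all(rs_all$a + rs_all$b + rs_all$c + rs_all$d == nrow(d$spots)))
  expect_true(all(rs$direction[!is.na(rs$direction)] %in%
                    c("beneficial", "pathogenic")))
  # q is BH over evaluable p
  ev <- rs$evaluable
  expect_equal(rs$q[ev], oracle_bh(rs$p[ev]))
})

test_that("planted risk effects are recovered at moderate scale", {
  rr_true <- stats::setNames(c(0.4, 0.5, 2, 2.5, 1, 1),
                             sprintf("species_%02d", 1:6))
  sim <- flat_sim(n_samples = 4, n_spots_per_sample = 1500, seed = 31,
                  n_species = 6, n_contaminant_species = 0, n_genes = 30,
                  n_mito_genes = 5, planted_rr = rr_true,
                  baseline_damage_rate = 0.06, exposure_rate = 0.15)
  d <- qc_filter_spots(sim$dataset)
  rs <- risk_screen(d)
  covered <- rs$ci_low <= rr_true[rs$species] & rr_true[rs$species] <= rs$ci_high
  expect_gte(mean(covered), 5 / 6)
  sig <- !is.na(rs$direction)
  expect_true(all(sign(rs$rr[sig] - 1) == sign(rr_true[rs$species][sig] - 1)))
  planted_effect <- rr_true != 1
  expect_gt(sum(sig & planted_effect[rs$species]), 2)
})

test_that("strain screen is the species computation relabelled", {
  fx <- get_fixture()
  dec <- decontaminate(fx$dataset)
  d <- qc_filter_spots(dec$dataset)
  strains <- d$bacteria$single
  colnames(strains) <- paste0(colnames(strains), "_strain1")
  ss <- strain_level_screen(d, strains)
  rs <- risk_screen(d)
  expect_equal(ss$rr, rs$rr)
  expect_equal(ss$q, rs$q)
  expect_equal(attr(ss, "resolved_fraction"), 1)
  # a strain present in one spot is flagged low-exposure with a wide CI
  one <- matrix(0L, nrow(d$spots), 1,
                dimnames = list(d$spots$barcode, "rare_strain"))
  one[which(cd_spots(d)$spots$barcode[1] == rownames(one)), 1] <- 3L
  ss1 <- strain_level_screen(d, one)
  expect_true(ss1$low_exposure)
  if (ss1$evaluable) expect_gt(ss1$ci_high / ss1$ci_low, 3)
})

test_that("null-species CIs cover RR = 1 at close to nominal rate", {
  set.seed(17)
  hits <- replicate(300, {
    e <- runif(1500) < 0.25
    dmg <- runif(1500) < 0.2
    r <- relative_risk(e, dmg)
    r$ci_low <= 1 && 1 <= r$ci_high
  })
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})
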