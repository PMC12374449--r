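# Shared fixtures and independent oracles. The worked fixture is generated
# once per test run and reused.

.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fx_cache$fx)) .fx_cache$fx <- worked_fixture()
  .fx_cache$fx
}

# Small homogeneous-exposure simulation used by several recovery tests.
flat_sim <- function(n_samples = 4, n_spots_per_sample = 250, seed = 101, ...) {
  simulate_dataset(simulation_config(
    n_samples = n_samples, n_spots_per_sample = n_spots_per_sample,
    groups = rep(c("CD_noninflamed", "CD_inflamed"), length.out = n_samples),
    group_exposure_mult = c(CD_noninflamed = 1, CD_inflamed = 1),
    m_cell_exposure_mult = 1, seed = seed, ...))
}

# --- independent oracles -------------------------------------------------

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (no ties assumed).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  obs <- sum(rank(all_v)[seq_len(n1)])
  combos <- utils::combn(length(all_v), n1)
  r <- rank(all_v)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) * length(x) / (length(x) - 1)
}

# The four decontamination inequalities re-evaluated independently.
oracle_decontam_verdict <- function(spatial, bulk, double,
                                    min_sp = 50, min_bk = 50,
                                    max_ratio = 1.5, min_surv = 0.02) {
  sp_share <- spatial / sum(spatial)
  bk_share <- bulk / sum(bulk)
  sapply(seq_along(spatial), function(i) {
    f1 <- spatial[i] < min_sp
    f2 <- bulk[i] < min_bk
    f3 <- if (bk_share[i] == 0) sp_share[i] > 0 else sp_share[i] / bk_share[i] > max_ratio
    f4 <- if (spatial[i] > 0) double[i] / spatial[i] < min_surv else FALSE
    if (f1 || f2 || f3 || f4) "excluded" else "retained"
  })
}
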