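# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parameter error that names the offending field (classed so tests can catch it).
stop_param <- function(field, msg) {
  stop(structure(
    class = c("spotbiome_param_error", "error", "condition"),
    list(message = sprintf("invalid parameter `%s`: %s", field, msg),
         call = sys.call(-1), field = field)
  ))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_param(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_param(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stop_param(field, "must be positive")
  invisible(x)
}

# Symmetric-capable Dirichlet sampler via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n, ncol = k)
  x / rowSums(x)
}

#' Two-sample Wilcoxon-Mann-Whitney rank-sum test
#'
#' Shared rank test used for group comparisons, per-gene differential
#' expression and PCA score separation. Returns a signed standard-normal-scale
#' statistic (positive when `x` tends to exceed `y`) from the tie-corrected
#' normal approximation, and a two-sided p-value: exact (enumeration of the
#' Mann-Whitney U null distribution) when both groups have at most
#' `exact_max_n` observations and there are no ties, otherwise from the
#' normal approximation.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max_n maximum per-group size for the exact p-value.
#' @return list with `z` (signed statistic), `p` (two-sided), `n1`, `n2`.
#' @examples
#' rank_sum_test(c(4, 5, 6), c(1, 2, 3))
#' @export
rank_sum_test <- function(x, y, exact_max_n = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(list(z = NA_real_, p = NA_real_, n1 = n1, n2 = n2))
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(z = 0, p = 1, n1 = n1, n2 = n2))
  z <- (u - mu) / sqrt(sigma2)
  if (n1 <= exact_max_n && n2 <= exact_max_n) {
    if (tie_term == 0) {
      # exact null distribution of U for untied data
      p <- if (u > mu) 2 * (1 - pwilcox(u - 1, n1, n2)) else 2 * pwilcox(u, n1, n2)
    } else {
      # ties: enumerate all group assignments of the midranks
      w_mu <- n1 * (n + 1) / 2
      w_obs <- sum(r[seq_len(n1)])
      sums <- utils::combn(n, n1, function(idx) sum(r[idx]))
      p <- mean(abs(sums - w_mu) >= abs(w_obs - w_mu) - 1e-9)
    }
    p <- min(1, p)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  list(z = z, p = p, n1 = n1, n2 = n2)
}

# Significance stars at the thresholds used in the figures.
stars_from_p <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.0005, "***",
      ifelse(p < 0.005, "**",
        ifelse(p < 0.05, "*", "ns"))))
}

# Counts-per-million given per-spot total sequencing reads.
cpm_from_counts <- function(counts, total_reads) {
  stopifnot(nrow(counts) == length(total_reads))
  out <- counts / total_reads * 1e6
  out[total_reads == 0, ] <- 0
  out
}
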