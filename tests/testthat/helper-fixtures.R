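# shared fixtures and independent oracles for the suite

toy_params <- function() rcr_params(a = 0.4, b = 0.8, c = 1.2)

# draw valid random RCR parameter triples (a > 0 so integrals converge)
random_params <- function(n, seed = 1) {
  withr::with_seed(seed, purrr::map(seq_len(n), function(i) {
    rcr_params(a = stats::runif(1, 0.1, 1.5),
               b = stats::runif(1, 0, 2),
               c = stats::runif(1, 0.6, 3))
  }))
}

# brute-force oracle: first dose on a dense grid where survival crosses s
grid_scan_dose <- function(params, s_target, d_max = 50, step = 1e-4) {
  d <- seq(0, d_max, by = step)
  s <- rcr_survival(params, d)
  i <- which(s <= s_target)[1]
  d[i]
}

# per-gene one-way ANOVA F by explicit lm/anova, the slow reference path
anova_f_oracle <- function(expr, groups) {
  apply(expr, 1, function(y) {
    stats::anova(stats::lm(y ~ groups))[1, "F value"]
  })
}

# enumerate all 2-subset partitions and minimise total within-cluster SS
best_two_partition <- function(x) {
  n <- length(x)
  best <- NULL
  best_ss <- Inf
  for (mask in 1:(2^n - 2)) {
    in1 <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    ss <- sum((x[in1] - mean(x[in1]))^2) + sum((x[!in1] - mean(x[!in1]))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- in1
    }
  }
  best
}

# Table-like five-line endpoint RBE records used by the summary tests
printed_rbe_records <- function() {
  tibble::tibble(
    endpoint = rep(c("sf10", "dbar_param", "dbar_auc", "d0"), each = 5),
    cell_line = rep(c("SCC9", "HN5", "UMSCC1", "SqCC/Y1", "HN31"), times = 4),
    rbe = c(2.11, 2.27, 1.83, 2.08, 1.92,
            2.55, 2.61, 2.09, 2.58, 2.14,
            2.55, 2.56, 2.07, 2.57, 2.12,
            1.51, 1.93, 1.50, 1.51, 1.61))
}
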