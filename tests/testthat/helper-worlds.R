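# Small simulated worlds shared across tests. All fixtures are generated in
# code; sizes are kept small so the whole suite stays fast.

small_world <- function(seed = 1, n = 120, n_events = 150, frac = 0.2,
                        noise_sd = 0.3, n_hidden_factors = 0, ...) {
  cfg <- sim_config(n_individuals = n, n_events = n_events,
                    frac_age_assoc = frac, noise_sd = noise_sd,
                    n_hidden_factors = n_hidden_factors, seed = seed, ...)
  co <- simulate_cohort(cfg)
  ps <- simulate_psi(co, cfg)
  list(cfg = cfg, cohort = co, psi = ps$psi, truth = ps$truth)
}

# brute-force BH oracle: q_i = min over candidate thresholds t >= p_i of
# m * t / #{p <= t} — a different formulation from the package's sorted
# cummin implementation
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# exact two-sided rank-sum p by enumerating all group assignments
ranksum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# naive position-by-position IUPAC scanner (independent of count_iupac)
naive_motif_count <- function(seq, consensus) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(consensus, "")[[1]]
  m <- length(p)
  if (length(s) < m) return(0L)
  hits <- 0L
  for (i in seq_len(length(s) - m + 1)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      if (!(s[i + k - 1] %in% codes[[p[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# exact two-sided Fisher p by enumerating all tables with the observed
# margins and summing the probabilities of tables at most as likely
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
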