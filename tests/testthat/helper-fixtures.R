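# Shared fixture builders and independent oracles used across test files.

# Small planted cohort used by several end-to-end tests.
small_cohort_config <- function(seed = 1L, ...) {
  sim_config(
    n_pairs = 8L, n_cpgs = 4000L, n_genes = 60L,
    chrom_lengths = c(chr1 = 60e6, chr2 = 60e6, chr5 = 181e6),
    planted_sets = data.frame(set = "GS01", direction = "hypo",
                              delta_beta = 0.2),
    seed = seed, ...)
}

# A tiny hand-buildable intensity matrix.
toy_intensities <- function(n_probes = 20, n_samples = 4, seed = 42) {
  set.seed(seed)
  ids <- sprintf("cg%06d", seq_len(n_probes))
  samples <- sprintf("s%d", seq_len(n_samples))
  meth <- matrix(rlnorm(n_probes * n_samples, log(5000), 0.3),
                 n_probes, n_samples, dimnames = list(ids, samples))
  unmeth <- matrix(rlnorm(n_probes * n_samples, log(5000), 0.3),
                   n_probes, n_samples, dimnames = list(ids, samples))
  detp <- matrix(1e-6, n_probes, n_samples, dimnames = list(ids, samples))
  intensity_matrix(meth, unmeth, detp)
}

# Brute-force weighted-KS running sum: the independent ES oracle.
es_oracle <- function(stats_sorted, member_pos, weight_p = 1) {
  n <- length(stats_sorted)
  m <- length(member_pos)
  is_hit <- seq_len(n) %in% member_pos
  w <- abs(stats_sorted)^weight_p
  hit_w <- w * is_hit
  if (sum(hit_w) == 0) hit_w <- is_hit / m
  inc <- ifelse(is_hit, hit_w / sum(hit_w),
                if (n > m) -1 / (n - m) else 0)
  run <- cumsum(inc)
  mx <- max(run); mn <- min(run)
  # positive preference on (numerical) ties, as in the implementation
  if (mx + mn >= -1e-9) mx else mn
}

# Straight-line reimplementation of the variance-prior moment equations,
# independent of the package's Newton solver (uses stats::uniroot).
prior_oracle <- function(s2, df) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  target <- var(e) - trigamma(df / 2)
  if (target <= 0) return(list(d0 = Inf, s02 = exp(mean(e))))
  half_d0 <- uniroot(function(x) trigamma(x) - target,
                     lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  list(d0 = 2 * half_d0,
       s02 = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}

# Exhaustive hypergeometric upper tail by enumeration (N small).
hyper_tail_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Fixture with overlapping removal rules: 1000 probes, 37 failing detection
# in >= 1 sample, 13 SNP-flagged (3 of them among the 37), 50 on a sex
# chromosome (disjoint from both). Set arithmetic: 37 + 13 - 3 + 50 = 97
# removed, 903 retained.
filter_fixture <- function() {
  n <- 1000
  ids <- sprintf("cg%06d", 1:n)
  samples <- sprintf("s%d", 1:4)
  meth <- matrix(1000, n, 4, dimnames = list(ids, samples))
  unmeth <- matrix(1000, n, 4, dimnames = list(ids, samples))
  detp <- matrix(1e-8, n, 4, dimnames = list(ids, samples))
  fail <- 1:37
  detp[cbind(fail, rep_len(1:4, 37))] <- 0.5
  snp <- c(35:37, 101:110)                      # 13 flagged, 3 overlap detection
  sex <- 201:250                                # 50, no overlap
  ann <- data.frame(probe_id = ids,
                    snp_flag = seq_len(n) %in% snp,
                    sex_flag = seq_len(n) %in% sex)
  list(int = intensity_matrix(meth, unmeth, detp), ann = ann,
       expected_retained = ids[-c(fail, snp, sex)])
}

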