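# Shared fixtures and independent oracles for the test suite.

# A small, fast simulation configuration.
quick_config <- function(n = 40, depth = 600, seed = 42, ...) {
  sim_config(n_transcripts = n, depth_per_transcript = depth,
             n_spikes = 4, spike_depth = 300, seed = seed, ...)
}

# Fixed-step 4th-order Runge-Kutta integration of the two-pool ODE
#   old' = -kdeg_new * old,  old(0) = ksyn / kdeg_old
#   new' = ksyn_new - kdeg_new * new,  new(0) = 0
# with step <= 1e-4 h; vectorized over parameter sets.
rk4_pools <- function(ksyn, kd_old, kd_new, ks_new, t_end, step = 1e-4) {
  n_steps <- max(ceiling(t_end / step))
  h <- t_end / n_steps
  old <- ksyn / kd_old
  new <- rep(0, length(old))
  f_old <- function(y) -kd_new * y
  f_new <- function(y) ks_new - kd_new * y
  for (s in seq_len(n_steps)) {
    k1o <- f_old(old);              k1n <- f_new(new)
    k2o <- f_old(old + h / 2 * k1o); k2n <- f_new(new + h / 2 * k1n)
    k3o <- f_old(old + h / 2 * k2o); k3n <- f_new(new + h / 2 * k2n)
    k4o <- f_old(old + h * k3o);     k4n <- f_new(new + h * k3n)
    old <- old + h / 6 * (k1o + 2 * k2o + 2 * k3o + k4o)
    new <- new + h / 6 * (k1n + 2 * k2n + 2 * k3n + k4n)
  }
  list(old = old, new = new)
}

# Dense grid-search maximizer of the mixture likelihood: the independent
# oracle for the EM fit.
grid_theta_hat <- function(n_t, k_tc, count, pnew, pbg, resolution = 1e-4) {
  keep <- n_t > 0 & count > 0
  n <- n_t[keep]; k <- k_tc[keep]; cnt <- count[keep]
  f1 <- dbinom(k, n, pnew)
  f0 <- dbinom(k, n, pbg)
  thetas <- seq(0, 1, by = resolution)
  ll <- vapply(thetas, function(th) {
    mix <- th * f1 + (1 - th) * f0
    mix[mix <= 0] <- .Machine$double.xmin
    sum(cnt * log(mix))
  }, numeric(1))
  thetas[which.max(ll)]
}

# Random conversion histogram under the mixture model.
random_histogram <- function(n_reads, theta, pnew, pbg, read_len = 50,
                             u = 0.25) {
  n_t <- rbinom(n_reads, read_len, u)
  new <- runif(n_reads) < theta
  k <- rbinom(n_reads, n_t, ifelse(new, pnew, pbg))
  agg <- aggregate(list(count = rep(1L, n_reads)),
                   by = list(n_t = n_t, k = k), FUN = sum)
  agg
}

# Brute-force two-sample KS D: max CDF gap evaluated at every sample point.
brute_ks_d <- function(x, y) {
  pts <- c(x, y)
  fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(fx - fy))
}

# Brute-force sliding-window codon counter (checks in-frame positions only
# via the stride).
brute_codon_counts <- function(cds) {
  s <- toupper(chartr("Uu", "Tt", cds))
  n <- nchar(s)
  codons <- vapply(seq(1, n - 2, by = 3), function(i) {
    substr(s, i, i + 2)
  }, character(1))
  if (codons[length(codons)] %in% c("TAA", "TAG", "TGA")) {
    codons <- codons[-length(codons)]
  }
  codons <- codons[!grepl("N", codons)]
  tab <- table(codons)
  setNames(as.integer(tab), names(tab))
}

# Tiny hand-built conversion table (valid schema).
toy_conversion_table <- function() {
  data.frame(
    sample_id = rep(c("untreated_rep1", "untreated_rep2"), each = 3),
    condition = "untreated",
    replicate = rep(1:2, each = 3),
    transcript_id = "tx_0001",
    n_T = c(0, 2, 2, 0, 2, 2),
    k_TC = c(0, 0, 1, 0, 0, 2),
    n_A = c(10, 40, 12, 8, 36, 10),
    k_AG = c(0, 1, 0, 0, 0, 0),
    read_count = c(5, 80, 15, 4, 70, 20),
    stringsAsFactors = FALSE)
}
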