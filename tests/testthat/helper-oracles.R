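# Independent oracles and small fixture builders used across the suite.

# all permutations of 1:n (recursive; n <= 8 only)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# brute-force minimum-cost bipartite matching between equal-size samples:
# the transport-distance oracle the sorted pairing must equal in 1-D
brute_force_emd <- function(x, z) {
  n <- length(x)
  perms <- all_perms(n)
  costs <- vapply(seq_len(nrow(perms)), function(i)
    sum(abs(x[perms[i, ]] - z)), numeric(1))
  min(costs)
}

# Wasserstein-1 by direct Riemann integration of |F_x - F_z| over the
# knots of the two empirical CDFs (independent of the package's merged
# cumulative-step implementation)
w1_ecdf_oracle <- function(x, z) {
  k <- sort(unique(c(x, z)))
  if (length(k) < 2) return(0)
  fx <- stats::ecdf(x); fz <- stats::ecdf(z)
  mid <- k[-length(k)]
  sum(abs(fx(mid) - fz(mid)) * diff(k))
}

# write a small measurement table to a temp file and return the path
write_fixture_table <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# a minimal well-formed three-condition record set
tiny_records <- function() {
  mass_records(
    mass = c(55, 60, 65, 58, 62, 66, 70, 75, 80),
    particle_class = "intact",
    condition_id = rep(c("REF", "CTL", "drugA"), each = 3),
    role = rep(c("reference", "control", "test"), each = 3),
    t_meas = rep(c(0, 7200, 3600), each = 3))
}

# small inference config for fast tests
fast_config <- function(...) {
  inference_config(N = 400, R_ci = 400, R_test = 99, ...)
}
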