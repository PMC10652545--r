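# Small in-code fixtures shared across the suite.

# tiny two-group dataset for fast end-to-end runs
tiny_sim <- function(seed = 1L, n = 12L, p = 6L, hub = 3L,
                     rho_a = 0.2, rho_b = 0.8) {
  simulate_two_group(synthetic_scenario(
    n_per_group = c(n, n), p = p, hub_size = hub,
    base_rho = rho_a, perturbed_rho = rho_b, seed = seed))
}

# write a samples x genes matrix as the TSV dialect read_expression expects
write_expr_tsv <- function(m, path = tempfile(fileext = ".tsv")) {
  write_expression(m, path)
  path
}

write_pheno_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- data.frame(sample = rownames(df), df,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force plug-in MI over a joint bin table, independent of the
# crossprod-based implementation
mi_bruteforce <- function(dx, dy, b) {
  n <- length(dx)
  total <- 0
  for (u in seq_len(b)) {
    for (v in seq_len(b)) {
      nuv <- sum(dx == u & dy == v)
      if (nuv > 0) {
        total <- total + nuv / n * log(nuv * n / (sum(dx == u) * sum(dy == v)))
      }
    }
  }
  total
}

# exhaustive triplet-enumeration DPI oracle
dpi_oracle <- function(w, eps = 0) {
  p <- ncol(w)
  out <- w
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      for (k in seq_len(p)) {
        if (k == i || k == j) next
        if (w[i, j] < min(w[i, k], w[k, j]) - eps - 1e-12) out[i, j] <- 0
      }
    }
  }
  out
}

# independent step-up BH implementation: sort, scale, cumulative min
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}
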