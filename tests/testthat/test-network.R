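test_that("empirical MI matches closed forms: identical columns give log(b), constants give 0", {
  x <- c(0.3, 1.2, 2.2, 3.1, 4.7, 5.0, 6.3, 7.9, 8.1)
  m <- cbind(g1 = x, g2 = x, g3 = rep(2.5, 9))
  rownames(m) <- paste0("s", 1:9)
  cfg <- net_config(estimator = "empirical", n_bins = 3)
  mim <- build_mi_matrix(m, cfg)
  expect_equal(mim["g1", "g2"], log(3), tolerance = 1e-12)
  expect_equal(unname(mim["g3", ]), c(0, 0, 0))
  # bits instead of nats
  cfg2 <- net_config(estimator = "empirical", n_bins = 3, log_base = 2)
  expect_equal(build_mi_matrix(m, cfg2)["g1", "g2"], log2(3), tolerance = 1e-12)
  # auto bins at n = 9 is floor(sqrt(9)) = 3
  expect_equal(build_mi_matrix(m, net_config(estimator = "empirical"))["g1", "g2"],
               log(3), tolerance = 1e-12)
})

test_that("empirical MI agrees with a brute-force joint-histogram oracle", {
  set.seed(11)
  n <- 24L; b <- 4L
  m <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  rownames(m) <- paste0("s", seq_len(n))
  mim <- build_mi_matrix(m, net_config(estimator = "empirical", n_bins = b))
  disc <- apply(m, 2, function(col) {
    r <- integer(n); r[order(col)] <- seq_len(n)
    as.integer(floor((r - 1L) * b / n)) + 1L
  })
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(mim[i, j], mi_bruteforce(disc[, i], disc[, j], b),
                   tolerance = 1e-12)
    }
  }
})

test_that("both MI estimators are invariant under strictly monotone transforms", {
  set.seed(12)
  m <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), c("a", "b")))
  m2 <- m
  m2[, 1] <- exp(m2[, 1])        # strictly increasing
  m2[, 2] <- m2[, 2]^3           # strictly increasing
  for (est in c("gaussian_rank", "empirical")) {
    cfg <- net_config(estimator = est)
    expect_equal(build_mi_matrix(m, cfg), build_mi_matrix(m2, cfg))
  }
})

test_that("gaussian-rank MI matches its closed form and zeroes constant genes", {
  set.seed(13)
  m <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), c("a", "b", "c")))
  m[, 3] <- 7  # constant
  mim <- build_mi_matrix(m, net_config())
  rho <- cor(rank(m[, 1]), rank(m[, 2]))
  expect_equal(mim["a", "b"], -0.5 * log(1 - rho^2), tolerance = 1e-12)
  expect_equal(unname(mim["c", ]), c(0, 0, 0))
})

test_that("DPI prunes the weak leg of a triangle and respects boundary cases", {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- w["b", "a"] <- 0.9
  w["a", "c"] <- w["c", "a"] <- 0.8
  w["b", "c"] <- w["c", "b"] <- 0.5
  out <- apply_dpi(w, 0)
  expect_equal(out["b", "c"], 0)
  expect_equal(out["a", "b"], 0.9)
  expect_equal(out["a", "c"], 0.8)

  # p = 2: no third node, identity
  w2 <- w[1:2, 1:2]
  expect_identical(apply_dpi(w2, 0), w2)

  # epsilon at least the max weight: identity
  expect_identical(apply_dpi(w, 1), w)

  expect_error(apply_dpi(matrix(c(0, 1, 2, 0), 2, 2), 0), "symmetric")
})

test_that("DPI agrees with the exhaustive triplet oracle and never raises an edge", {
  set.seed(14)
  for (rep in 1:20) {
    p <- sample(3:6, 1)
    w <- matrix(0, p, p)
    w[upper.tri(w)] <- sample(seq(0.1, 0.9, by = 0.1), p * (p - 1) / 2, replace = TRUE)
    w <- w + t(w)
    eps <- sample(c(0, 0.05, 0.2), 1)
    out <- apply_dpi(w, eps)
    expect_equal(out, dpi_oracle(w, eps))
    expect_true(all(out <= w + 1e-15))
    expect_true(all(out[w == 0] == 0))
  }
})

test_that("degree centrality equals brute-force marginal sums and conserves total weight", {
  expect_equal(unname(degree_centrality(matrix(0, 4, 4))), rep(0, 4))
  w3 <- matrix(0.5, 3, 3); diag(w3) <- 0
  expect_equal(unname(degree_centrality(w3)), rep(1, 3))

  set.seed(15)
  w <- matrix(0, 6, 6)
  w[upper.tri(w)] <- runif(15)
  w <- w + t(w)
  theta <- degree_centrality(w)
  loop <- sapply(1:6, function(k) { s <- 0; for (j in 1:6) if (j != k) s <- s + w[k, j]; s })
  expect_equal(unname(theta), loop)
  expect_equal(sum(theta), 2 * sum(w[upper.tri(w)]))
})

test_that("group network estimation is deterministic and separates hub connectivity", {
  sim <- tiny_sim(seed = 21, n = 30, p = 10, hub = 4, rho_a = 0.1, rho_b = 0.85)
  al <- align_and_split(sim$expr, sim$pheno)
  xa <- al$expr[al$assignment$group_a, , drop = FALSE]
  xb <- al$expr[al$assignment$group_b, , drop = FALSE]
  na <- estimate_group_network(xa)
  nb <- estimate_group_network(xb)
  expect_length(na$theta, 10L)
  expect_identical(estimate_group_network(xa), na)  # bit-identical rerun
  # perturbed hub genes are more connected in group B
  hub <- sim$truth
  bg <- setdiff(colnames(sim$expr), hub)
  expect_gt(mean(nb$theta[hub] - na$theta[hub]),
            mean(nb$theta[bg] - na$theta[bg]))
})

test_that("mean off-diagonal MI of independent genes shrinks as n grows", {
  # the empirical plug-in bias is ~(b-1)^2/(2n), so consistency requires a
  # fixed bin count; the rank estimator has no bin parameter
  mean_mi <- function(n, seed, cfg) {
    set.seed(seed)
    m <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("g", 1:8)))
    rownames(m) <- paste0("s", seq_len(n))
    mim <- build_mi_matrix(m, cfg)
    mean(mim[upper.tri(mim)])
  }
  cfg_rank <- net_config()
  expect_lt(mean_mi(500, 31, cfg_rank), mean_mi(50, 31, cfg_rank))
  cfg_emp <- net_config(estimator = "empirical", n_bins = 4)
  expect_lt(mean_mi(500, 31, cfg_emp), mean_mi(50, 31, cfg_emp))
})

test_that("edge-list export writes sorted nonzero upper-triangle edges", {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("b", "a", "c")), 2))
  w["b", "a"] <- w["a", "b"] <- 0.4
  w["a", "c"] <- w["c", "a"] <- 0.2
  f <- tempfile(fileext = ".tsv")
  export_edge_list(w, f)
  got <- utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(got$gene_i, c("a", "b"))
  expect_equal(got$weight, c(0.2, 0.4))
})
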