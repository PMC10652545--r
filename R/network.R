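#' Network estimation settings
#'
#' @param estimator Mutual-information estimator. `"gaussian_rank"`
#'   (default) computes MI through the Gaussian copula on ranks,
#'   `mim = -0.5 * log(1 - rho_s^2)` with `rho_s` the Spearman rank
#'   correlation: smooth in the data and nearly bias-free, which both the
#'   jackknife variance estimator and the degree signal-to-noise benefit
#'   from. `"empirical"` is the plug-in estimator on equal-frequency bins
#'   (classic discrete ARACNE input); its `(b-1)^2/(2n)` bias is shared
#'   across gene pairs and grows quickly with the bin count.
#' @param n_bins `"auto"` (equal-frequency bins, `floor(sqrt(n))`) or an
#'   integer >= 2 pinning the bin count; `"empirical"` estimator only.
#' @param log_base Base of the logarithm for mutual information; `exp(1)`
#'   (nats, default) or 2 (bits).
#' @param epsilon Data-processing-inequality tolerance, >= 0. An edge (i, j)
#'   is pruned when `w[i,j] < min(w[i,k], w[k,j]) - epsilon` for some third
#'   gene k. The default 0.1 sits in the tolerance range the ARACNE authors
#'   recommend to absorb MI estimation error; strict pruning (0) reduces a
#'   tightly co-expressed module to a spanning tree and discards most of
#'   its degree signal.
#' @param loo_rediscretize In leave-one-out re-estimation, re-derive the
#'   equal-frequency bins from the reduced sample (`TRUE`) instead of
#'   pinning the full-group bin assignments (default `FALSE`). Pinning
#'   keeps the degree statistic a smooth functional of the data, which the
#'   jackknife variance estimator requires; see the methods vignette.
#' @param loo_reprune In leave-one-out re-estimation, re-run DPI pruning on
#'   each reduced network (`TRUE`) instead of freezing the full-group edge
#'   set and recomputing only the surviving MI weights (default `FALSE`).
#'   Same smoothness rationale as `loo_rediscretize`.
#' @param recompute_bins_loo When `loo_rediscretize = TRUE` and
#'   `n_bins = "auto"`, recompute the bin count from the reduced sample
#'   size (default) rather than keeping the full-group count.
#' @return A list of class `"net_config"`.
#' @export
net_config <- function(estimator = c("gaussian_rank", "empirical"),
                       n_bins = "auto", log_base = exp(1), epsilon = 0.1,
                       loo_rediscretize = FALSE, loo_reprune = FALSE,
                       recompute_bins_loo = TRUE) {
  estimator <- match.arg(estimator)
  if (!identical(n_bins, "auto")) {
    n_bins <- as.integer(n_bins)
    if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be 'auto' or an integer >= 2")
  }
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(estimator = estimator,
                 n_bins = n_bins, log_base = log_base, epsilon = epsilon,
                 loo_rediscretize = isTRUE(loo_rediscretize),
                 loo_reprune = isTRUE(loo_reprune),
                 recompute_bins_loo = isTRUE(recompute_bins_loo)),
            class = "net_config")
}

auto_bins <- function(n) max(2L, as.integer(floor(sqrt(n))))

effective_bins <- function(n, config) {
  b <- if (identical(config$n_bins, "auto")) auto_bins(n) else config$n_bins
  min(b, n)
}

# Equal-frequency discretization of one column. Ties are broken by a stable
# order on (value, original position) so bin assignment is deterministic.
# Constant columns collapse to a single occupied bin (zero entropy), which
# makes their MI against anything exactly 0 downstream.
discretize_ef <- function(x, b) {
  n <- length(x)
  if (length(unique(x)) == 1L) return(rep(1L, n))
  r <- integer(n)
  r[order(x)] <- seq_len(n)  # order() is stable: ties by original position
  as.integer(floor((r - 1L) * b / n)) + 1L
}

discretize_matrix <- function(expr, b) {
  disc <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (j in seq_len(ncol(expr))) disc[, j] <- discretize_ef(expr[, j], b)
  disc
}

# Empirical plug-in MI for every gene pair from pre-binned data. All
# pairwise joint histograms come from one crossprod of the stacked one-hot
# indicator matrix Z (n x p*b): block (i, j) of t(Z)Z is the b x b joint
# count table of genes i and j.
mi_from_discrete <- function(disc, b, log_base = exp(1)) {
  n <- nrow(disc); p <- ncol(disc)
  Z <- matrix(0, n, p * b)
  Z[cbind(rep(seq_len(n), p), (rep(seq_len(p), each = n) - 1L) * b + as.vector(disc))] <- 1
  C <- crossprod(Z)
  marg <- diag(C)
  lb <- log(log_base)
  mim <- matrix(0, p, p, dimnames = list(colnames(disc), colnames(disc)))
  for (i in seq_len(p - 1L)) {
    ri <- (i - 1L) * b + seq_len(b)
    ni <- marg[ri]
    for (j in (i + 1L):p) {
      cj <- (j - 1L) * b + seq_len(b)
      J <- C[ri, cj]
      nz <- J > 0
      mi <- sum(J[nz] / n * log(J[nz] * n / (outer(ni, marg[cj])[nz]))) / lb
      mim[i, j] <- mim[j, i] <- max(mi, 0)
    }
  }
  mim
}

# Gaussian-copula rank MI: -0.5 * log(1 - rho_s^2) per pair, in the
# configured log base. Constant columns (zero rank variance) get MI 0.
mi_gaussian_rank <- function(expr, log_base = exp(1)) {
  rk <- apply(expr, 2L, rank)
  sds <- apply(rk, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(rk))
  r[!is.finite(r)] <- 0
  r[, sds == 0] <- 0
  r[sds == 0, ] <- 0
  r2 <- pmin(r^2, 1 - 1e-15)
  mim <- -0.5 * log(1 - r2) / log(log_base)
  diag(mim) <- 0
  dimnames(mim) <- list(colnames(expr), colnames(expr))
  mim
}

#' Mutual-information association matrix
#'
#' With the default `"gaussian_rank"` estimator, each off-diagonal entry is
#' the Gaussian-copula mutual information `-0.5 * log(1 - rho_s^2)` of the
#' two genes' rank profiles. With `"empirical"`, it is the plug-in mutual
#' information of the two genes' equal-frequency-discretized profiles.
#' Both depend on the data only through ranks, so the matrix is invariant
#' under strictly monotone transformations of any gene's values. Constant
#' genes get zero MI against everything (zero entropy), not an error, so
#' leave-one-out subsets that accidentally flatten a gene do not abort the
#' jackknife.
#'
#' @param expr Samples x genes numeric matrix (one group's rows).
#' @param config A [net_config()].
#' @return Symmetric p x p matrix, zero diagonal, nonnegative entries, gene
#'   ids as dimnames.
#' @export
build_mi_matrix <- function(expr, config = net_config()) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expr must be a numeric matrix")
  n <- nrow(expr)
  if (n < 2L) stop("need at least 2 samples for MI estimation")
  if (config$estimator == "gaussian_rank") {
    mi_gaussian_rank(expr, config$log_base)
  } else {
    b <- effective_bins(n, config)
    mi_from_discrete(discretize_matrix(expr, b), b, config$log_base)
  }
}

#' ARACNE data-processing-inequality pruning
#'
#' For every triplet (i, j, k) the edge (i, j) is scheduled for removal when
#' `w[i,j] < min(w[i,k], w[k,j]) - epsilon`; removal decisions are computed
#' against the input matrix and applied simultaneously, so the result does
#' not depend on triplet iteration order. Removed edges are set to 0;
#' survivors keep their MI weight. A strict-inequality tolerance of 1e-12
#' absorbs float noise.
#'
#' @param mim Symmetric nonnegative association matrix, zero diagonal.
#' @param epsilon DPI tolerance >= 0 (default 0).
#' @return Pruned association matrix of the same shape.
#' @export
apply_dpi <- function(mim, epsilon = 0) {
  if (!isSymmetric(unname(mim), tol = 1e-10)) stop("association matrix must be symmetric")
  if (any(mim < 0)) stop("association matrix must be nonnegative")
  p <- ncol(mim)
  if (p < 3L) return(mim)
  # strongest indirect path: max_k min(w[i,k], w[k,j]); the zero diagonal
  # makes k = i and k = j harmless (min is then 0)
  indirect <- matrix(0, p, p)
  for (k in seq_len(p)) {
    indirect <- pmax(indirect, pmin(matrix(mim[, k], p, p),
                                    matrix(mim[k, ], p, p, byrow = TRUE)))
  }
  out <- mim
  out[mim < indirect - epsilon - 1e-12] <- 0
  out
}

#' Weighted degree centrality (total connectivity)
#'
#' The marginal sum of each gene's association-matrix row, i.e. the sum of
#' its surviving MI edge weights. No binarization threshold is applied.
#'
#' @param adj Symmetric nonnegative association matrix, zero diagonal.
#' @return Named numeric vector of length p.
#' @export
degree_centrality <- function(adj) {
  if (any(adj < 0)) stop("association matrix must be nonnegative")
  rowSums(adj)
}

#' Estimate one group's association network and degree vector
#'
#' Composition [build_mi_matrix()] -> [apply_dpi()] -> [degree_centrality()];
#' fully deterministic for a fixed input and configuration.
#'
#' @param expr_group Samples x genes matrix restricted to one group's rows.
#' @param config A [net_config()].
#' @return List with elements `adjacency` (pruned association matrix) and
#'   `theta` (named degree vector).
#' @export
estimate_group_network <- function(expr_group, config = net_config()) {
  mim <- build_mi_matrix(expr_group, config)
  adj <- apply_dpi(mim, config$epsilon)
  list(adjacency = adj, theta = degree_centrality(adj))
}

# Precomputed full-group state shared by all leave-one-out fits: bin count,
# bin assignments, MI matrix, pruned adjacency, surviving-edge mask, theta.
group_network_state <- function(expr_group, config = net_config()) {
  n <- nrow(expr_group)
  if (config$estimator == "gaussian_rank") {
    b <- NA_integer_
    disc <- NULL
    mim <- mi_gaussian_rank(expr_group, config$log_base)
  } else {
    b <- effective_bins(n, config)
    disc <- discretize_matrix(expr_group, b)
    mim <- mi_from_discrete(disc, b, config$log_base)
  }
  adj <- apply_dpi(mim, config$epsilon)
  list(n = n, b = b, disc = disc, mim = mim, adj = adj,
       mask = adj > 0, theta = degree_centrality(adj))
}

# Leave-one-out degree from a precomputed state. By default the full-group
# bin assignments and DPI edge set are pinned and only the MI weights are
# recomputed on the reduced sample, keeping the statistic smooth so the
# jackknife variance estimator stays consistent. Config switches restore
# full re-estimation per subset.
loo_theta_from_state <- function(state, expr_group, i, config = net_config()) {
  if (config$estimator == "gaussian_rank") {
    mim_i <- mi_gaussian_rank(expr_group[-i, , drop = FALSE], config$log_base)
    return(if (config$loo_reprune) {
      degree_centrality(apply_dpi(mim_i, config$epsilon))
    } else {
      rowSums(mim_i * state$mask)
    })
  }
  if (config$loo_rediscretize) {
    x <- expr_group[-i, , drop = FALSE]
    b <- if (identical(config$n_bins, "auto") && !config$recompute_bins_loo) {
      state$b
    } else {
      effective_bins(nrow(x), config)
    }
    disc_i <- discretize_matrix(x, b)
  } else {
    b <- state$b
    disc_i <- state$disc[-i, , drop = FALSE]
  }
  mim_i <- mi_from_discrete(disc_i, b, config$log_base)
  if (config$loo_reprune) {
    degree_centrality(apply_dpi(mim_i, config$epsilon))
  } else {
    rowSums(mim_i * state$mask)
  }
}

#' Leave-one-out degree centrality
#'
#' Re-estimates the group's degree vector from the expression data with one
#' sample's row deleted. Under the default configuration the full-group
#' equal-frequency bin assignments and DPI edge set are pinned and only the
#' MI weights are recomputed (see [net_config()]); with
#' `loo_rediscretize = TRUE` and `loo_reprune = TRUE` the whole network is
#' re-estimated from scratch on the reduced sample.
#'
#' @param expr_group One group's samples x genes matrix (>= 4 rows).
#' @param i Row index of the sample to leave out.
#' @param config A [net_config()].
#' @return Named numeric vector of length p.
#' @export
loo_degree <- function(expr_group, i, config = net_config()) {
  n <- nrow(expr_group)
  if (i < 1L || i > n) stop("sample index ", i, " out of range 1..", n)
  state <- group_network_state(expr_group, config)
  loo_theta_from_state(state, expr_group, i, config)
}

#' Export an association matrix as a three-column edge list
#'
#' Writes `gene_i`, `gene_j`, `weight` (upper triangle, nonzero edges only)
#' as TSV for external network viewers.
#'
#' @param adj Association matrix with gene dimnames.
#' @param path Output TSV path.
#' @export
export_edge_list <- function(adj, path) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  df <- data.frame(gene_i = rownames(adj)[idx[, 1L]],
                   gene_j = colnames(adj)[idx[, 2L]],
                   weight = adj[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_i, df$gene_j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
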