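#' Multiplicity-adjustment settings
#'
#' @param method `"ebs"` (empirical Bayes screening, default) or `"bh"`
#'   (Benjamini-Hochberg).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param ebs_bandwidth Kernel bandwidth for the probit-scale density
#'   estimate, or `"auto"` (Silverman's rule via [stats::bw.nrd0()]).
#' @param pi0_cap Upper cap for the estimated null proportion, in (0, 1].
#' @return A list of class `"adjust_config"`.
#' @export
adjust_config <- function(method = c("ebs", "bh"), alpha = 0.05,
                          ebs_bandwidth = "auto", pi0_cap = 1) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (pi0_cap <= 0 || pi0_cap > 1) stop("pi0_cap must lie in (0, 1]")
  if (!identical(ebs_bandwidth, "auto") && ebs_bandwidth <= 0) {
    stop("ebs_bandwidth must be 'auto' or positive")
  }
  structure(list(method = method, alpha = alpha,
                 ebs_bandwidth = ebs_bandwidth, pi0_cap = pi0_cap),
            class = "adjust_config")
}

check_pvals <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  p
}

#' Empirical Bayes screening of p-values
#'
#' Models the p-values as a two-group mixture
#' `f(p) = pi0 * 1 + (1 - pi0) * f1(p)` and returns, for each p, the
#' estimated posterior null probability `min(1, pi0 / f(p))`. The marginal
#' density `f` is estimated by Gaussian kernel density estimation on the
#' probit scale (`z = qnorm(p)`), back-transformed with the Jacobian
#' `dnorm(z)`; `pi0` is the median of the fitted density over p in
#' [0.95, 1], capped at `pi0_cap`. A final isotonic-regression pass makes
#' the adjusted values monotone non-decreasing in p.
#'
#' With fewer than 10 p-values, or a degenerate (all-identical) input, the
#' density estimate is meaningless and [bh_adjust()] is used instead, with
#' a warning.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @param config An [adjust_config()].
#' @return Adjusted values in [0, 1], same length and order as `pvals`.
#' @export
ebs_adjust <- function(pvals, config = adjust_config()) {
  check_pvals(pvals)
  m <- length(pvals)
  if (m < 10L) {
    warning("fewer than 10 p-values; falling back to Benjamini-Hochberg")
    return(bh_adjust(pvals))
  }
  if (length(unique(pvals)) == 1L) {
    warning("all p-values identical; falling back to Benjamini-Hochberg")
    return(bh_adjust(pvals))
  }
  eps <- 1e-10
  p_clip <- pmin(pmax(pvals, eps), 1 - eps)
  z <- stats::qnorm(p_clip)
  bw <- if (identical(config$ebs_bandwidth, "auto")) stats::bw.nrd0(z) else config$ebs_bandwidth

  # marginal density of p at arbitrary points, via the probit-scale KDE
  f_p <- function(p) {
    zz <- stats::qnorm(pmin(pmax(p, eps), 1 - eps))
    fz <- vapply(zz, function(z0) mean(stats::dnorm((z0 - z) / bw)) / bw, numeric(1L))
    fz / stats::dnorm(zz)
  }

  # density-based null proportion, guarded from below by the Storey
  # count-based estimate: with no p-value mass near 1 the KDE extrapolates
  # f toward 0 there, which would drive every posterior null probability
  # to 0; the tail-count bound keeps pi0 honest in that regime
  pi0_dens <- stats::median(f_p(seq(0.95, 1 - eps, length.out = 51L)))
  pi0_storey <- (1 + sum(pvals > 0.5)) / (m * 0.5)
  pi0 <- min(max(pi0_dens, pi0_storey), config$pi0_cap)
  adj <- pmin(1, pi0 / f_p(pvals))

  ord <- order(p_clip, adj)
  adj[ord] <- stats::isoreg(adj[ord])$yf
  pmin(pmax(adj, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (`p * m / rank`, cumulative minimum from the
#' largest rank, clipped at 1), delegated to [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  check_pvals(pvals)
  stats::p.adjust(pvals, method = "BH")
}

#' Fill in adjusted p-values on a fitted result set
#'
#' Each predictor's family of p gene-level p-values is adjusted separately
#' (column-wise), so the output keeps the genes x predictors shape.
#'
#' @param results A `dn_result` from [fit_all_genes()].
#' @param config An [adjust_config()].
#' @return The `dn_result` with `adj_pvalues` filled.
#' @export
adjust_results <- function(results, config = adjust_config()) {
  adj_fun <- switch(config$method,
                    ebs = function(p) ebs_adjust(p, config),
                    bh = bh_adjust)
  adj <- apply(results$pvalues, 2L, adj_fun)
  dimnames(adj) <- dimnames(results$pvalues)
  attr(adj, "method") <- config$method
  results$adj_pvalues <- adj
  results
}

#' Significantly differentially connected genes
#'
#' Genes whose adjusted p-value for the group predictor falls strictly
#' below `alpha`, sorted by gene id for determinism.
#'
#' @param results A `dn_result` with adjusted p-values.
#' @param group_predictor Predictor whose adjusted p-values are screened;
#'   defaults to the result's group predictor.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with columns `gene_id` and `adj_pvalue`.
#' @export
sig_dc_genes <- function(results, group_predictor = results$group_predictor,
                         alpha = 0.05) {
  adj <- extract(results, "adjpval", group_predictor)
  hit <- which(adj[[2L]] < alpha)
  out <- adj[hit, , drop = FALSE]
  names(out) <- c("gene_id", "adj_pvalue")
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Names of significantly differentially connected genes
#'
#' @inheritParams sig_dc_genes
#' @return Character vector of gene ids (sorted).
#' @export
sig_dc_gene_names <- function(results, group_predictor = results$group_predictor,
                              alpha = 0.05) {
  sig_dc_genes(results, group_predictor, alpha)$gene_id
}

#' Extract a slice of a differential-connectivity result
#'
#' @param results A `dn_result`.
#' @param what `"adjpval"`, `"pval"`, or `"coeff"`.
#' @param predictor A predictor name, or `"all"` (default) for the full
#'   genes x predictors table.
#' @return `data.frame` with `gene_id` first, then the requested column(s).
#' @export
extract <- function(results, what = c("adjpval", "pval", "coeff"),
                    predictor = "all") {
  what <- match.arg(what)
  tab <- switch(what,
                adjpval = results$adj_pvalues,
                pval = results$pvalues,
                coeff = results$coefficients)
  if (is.null(tab)) stop("adjusted p-values not filled; run adjust_results() first")
  if (!identical(predictor, "all")) {
    if (!predictor %in% results$predictors) {
      stop("unknown predictor '", predictor, "'; available: ",
           paste(results$predictors, collapse = ", "))
    }
    tab <- tab[, predictor, drop = FALSE]
  }
  data.frame(gene_id = results$gene_ids, tab,
             check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}
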