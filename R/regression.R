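#' Build the per-gene regression design matrix
#'
#' Columns are: intercept, the binary group indicator (0 = Group A,
#' 1 = Group B), then every non-group phenotype column in table order.
#' Categorical covariates are treatment-coded with the lexicographically
#' first level as reference.
#'
#' @param pheno Aligned phenotype `data.frame` (from [align_and_split()]).
#' @param assignment The matching `group_assignment`.
#' @param covariates Character vector of phenotype columns to adjust for,
#'   or `"all"` (default) for every non-group column.
#' @return Numeric n x (1 + q') matrix of full column rank with rownames =
#'   sample ids; attribute `predictors` holds the non-intercept column
#'   names (group first).
#' @export
build_design <- function(pheno, assignment, covariates = "all") {
  gv <- attr(pheno, "group_variable")
  if (is.null(gv)) stop("phenotype table lacks a group_variable attribute")
  covs <- setdiff(colnames(pheno), gv)
  if (!identical(covariates, "all")) {
    missing <- setdiff(covariates, covs)
    if (length(missing)) {
      stop("unknown covariate(s): ", paste(missing, collapse = ", "),
           "; available: ", paste(covs, collapse = ", "))
    }
    covs <- covs[covs %in% covariates]
  }
  n <- nrow(pheno)
  group <- integer(n)
  group[assignment$group_b] <- 1L
  cols <- list("(Intercept)" = rep(1, n))
  cols[[gv]] <- group
  for (v in covs) {
    x <- pheno[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      lev <- sort(unique(as.character(x)))
      la <- unique(as.character(x)[assignment$group_a])
      lb <- unique(as.character(x)[assignment$group_b])
      only <- c(setdiff(lev, lb), setdiff(lev, la))
      if (length(only)) {
        warning("covariate '", v, "' level(s) ", paste(unique(only), collapse = ", "),
                " present in one group only; group effect partially confounded")
      }
      for (l in lev[-1L]) {  # reference = lexicographically first level
        cols[[paste0(v, l)]] <- as.numeric(as.character(x) == l)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(pheno)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  attr(X, "predictors") <- colnames(X)[-1L]
  X
}

#' Robust MM regression of one gene's pseudo-values
#'
#' Fits an MM-type robust linear model (high-breakdown initial S-estimate of
#' scale followed by an iteratively reweighted M-step with Tukey bisquare
#' psi tuned for 95% asymptotic Gaussian efficiency, via
#' [MASS::rlm()] with `method = "MM"`). Two-sided p-values use a t
#' reference with `df = n - ncol(X)` on coefficient / robust-SE.
#'
#' Degenerate cases never abort a run: a perfect (zero-residual-scale) fit
#' returns the interpolating coefficients with p = 0 for nonzero
#' coefficients and 1 otherwise (`flag = "perfect_fit"`); non-convergence
#' falls back to ordinary least squares (`flag = "ols_fallback"`).
#'
#' @param y Numeric response of length n.
#' @param X Design matrix from [build_design()] (includes the intercept).
#' @param max_iter Maximum IRLS iterations (default 200).
#' @param tol Coefficient-change convergence tolerance (default 1e-8).
#' @return List with `coefficients`, `std_errors`, `pvalues` (all named,
#'   intercept included) and `flag` (`"ok"`, `"perfect_fit"`, or
#'   `"ols_fallback"`).
#' @export
fit_robust <- function(y, X, max_iter = 200L, tol = 1e-8) {
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("need more observations (", n, ") than design columns (", k, ")")
  df <- n - k

  ols <- stats::lm.fit(X, y)
  scale_y <- max(abs(y), 1)
  if (max(abs(ols$residuals)) < 1e-8 * scale_y) {
    beta <- ols$coefficients
    pv <- ifelse(abs(beta) > 1e-12, 0, 1)
    return(list(coefficients = beta,
                std_errors = stats::setNames(rep(0, k), colnames(X)),
                pvalues = stats::setNames(pv, colnames(X)),
                flag = "perfect_fit"))
  }

  fit <- tryCatch(
    suppressWarnings(
      MASS::rlm(X, y, method = "MM", psi = MASS::psi.bisquare,
                maxit = max_iter, acc = tol)),
    error = function(e) NULL)

  if (is.null(fit) || !isTRUE(fit$converged) ||
      !is.finite(fit$s) || fit$s <= 0) {
    # OLS fallback with classical standard errors
    beta <- ols$coefficients
    sigma2 <- sum(ols$residuals^2) / df
    XtXinv <- chol2inv(qr.R(ols$qr))
    se <- sqrt(sigma2 * diag(XtXinv))
    tval <- beta / se
    return(list(coefficients = stats::setNames(beta, colnames(X)),
                std_errors = stats::setNames(se, colnames(X)),
                pvalues = stats::setNames(2 * stats::pt(-abs(tval), df), colnames(X)),
                flag = "ols_fallback"))
  }

  beta <- stats::coef(fit)
  se <- summary(fit, method = "XtWX")$coefficients[, "Std. Error"]
  tval <- beta / se
  list(coefficients = stats::setNames(beta, colnames(X)),
       std_errors = stats::setNames(se, colnames(X)),
       pvalues = stats::setNames(2 * stats::pt(-abs(tval), df), colnames(X)),
       flag = "ok")
}

#' Fit the robust regression for every gene
#'
#' One robust fit per gene of the pseudo-value column on the shared design.
#' The initial S-estimate inside MM estimation involves random subsampling;
#' each gene's fit runs under a deterministic seed derived from `seed` and
#' the gene index, so results are bit-identical across reruns and worker
#' counts and equivariant under gene permutation.
#'
#' @param psv n x p pseudo-value matrix (rows aligned with `X`).
#' @param X Design matrix from [build_design()].
#' @param seed Integer seed for the robust fits' subsampling.
#' @param jobs Worker count ([parallel::mclapply()] when > 1).
#' @return A `dn_result` list: `gene_ids`, `predictors`, and p x q' matrices
#'   `coefficients` and `pvalues` (intercept excluded, group first),
#'   per-gene `flags`, and `adj_pvalues = NULL` (filled by
#'   [adjust_results()]).
#' @export
fit_all_genes <- function(psv, X, seed = 1L, jobs = 1L) {
  if (nrow(psv) != nrow(X)) stop("pseudo-value rows must match design rows")
  genes <- colnames(psv)
  preds <- attr(X, "predictors")
  gene_seed <- function(k) (as.integer(seed) + 7919L * k) %% .Machine$integer.max
  one <- function(k) {
    withr::with_seed(gene_seed(k), fit_robust(psv[, k], X))
  }
  fits <- if (jobs > 1L) {
    parallel::mclapply(seq_along(genes), one, mc.cores = jobs)
  } else {
    lapply(seq_along(genes), one)
  }
  coefs <- do.call(rbind, lapply(fits, function(f) f$coefficients[-1L]))
  pvals <- do.call(rbind, lapply(fits, function(f) f$pvalues[-1L]))
  dimnames(coefs) <- dimnames(pvals) <- list(genes, preds)
  flags <- vapply(fits, `[[`, character(1L), "flag")
  names(flags) <- genes
  n_flagged <- sum(flags != "ok")
  if (n_flagged > 0L) {
    message(n_flagged, " gene fit(s) flagged: ",
            paste(names(flags)[flags != "ok"], flags[flags != "ok"],
                  sep = "=", collapse = ", "))
  }
  structure(list(gene_ids = genes, predictors = preds,
                 coefficients = coefs, pvalues = pvals,
                 adj_pvalues = NULL, flags = flags,
                 group_predictor = preds[1L]),
            class = "dn_result")
}

#' @export
print.dn_result <- function(x, ...) {
  cat("Differential connectivity result:", length(x$gene_ids), "genes x",
      length(x$predictors), "predictors\n")
  cat("Predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("Group predictor:", x$group_predictor, "\n")
  if (!is.null(x$adj_pvalues)) {
    cat("Adjustment:", attr(x$adj_pvalues, "method"), "\n")
  }
  invisible(x)
}
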