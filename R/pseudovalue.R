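#' Jackknife pseudo-values of degree centrality for one group
#'
#' For each sample i and gene k computes the first-order jackknife
#' pseudo-value
#' \deqn{\tilde\theta_{ik} = n_z \hat\theta_k - (n_z - 1) \hat\theta_k^{(-i)},}
#' where \eqn{\hat\theta} is the full-group degree and
#' \eqn{\hat\theta^{(-i)}} the leave-one-out degree (see [loo_degree()] for
#' how the leave-one-out networks are re-estimated). The leave-one-out fits
#' are pure functions of the reduced data, so parallel scheduling cannot
#' change the result.
#'
#' @param expr_group One group's samples x genes matrix (>= 4 rows).
#' @param config A [net_config()].
#' @param jobs Worker count for the leave-one-out fits (forked via
#'   [parallel::mclapply()] when > 1).
#' @param stat_fn Optional statistic `function(expr_matrix, config)`
#'   returning a length-p vector, replacing the ARACNE degree pipeline
#'   (used to verify the jackknife algebra with stub statistics). When
#'   given, both the full-group and leave-one-out statistics are plain
#'   evaluations of `stat_fn`.
#' @return n_z x p matrix of pseudo-values with the group's sample ids as
#'   rownames and gene ids as colnames.
#' @export
jackknife_pseudovalues <- function(expr_group, config = net_config(),
                                   jobs = 1L, stat_fn = NULL) {
  n <- nrow(expr_group)
  if (n < 4L) stop("each group needs >= 4 samples for leave-one-out re-estimation")
  if (is.null(stat_fn)) {
    state <- group_network_state(expr_group, config)
    theta_full <- state$theta
    one <- function(i) loo_theta_from_state(state, expr_group, i, config)
  } else {
    theta_full <- stat_fn(expr_group, config)
    one <- function(i) stat_fn(expr_group[-i, , drop = FALSE], config)
  }
  loo <- if (jobs > 1L) {
    parallel::mclapply(seq_len(n), one, mc.cores = jobs)
  } else {
    lapply(seq_len(n), one)
  }
  psv <- matrix(NA_real_, n, ncol(expr_group), dimnames = dimnames(expr_group))
  for (i in seq_len(n)) {
    psv[i, ] <- n * theta_full - (n - 1) * loo[[i]]
  }
  if (any(!is.finite(psv))) stop("non-finite pseudo-values")
  psv
}

#' Assemble per-group pseudo-value blocks into analysis order
#'
#' Interleaves the two group blocks back into the original sample order of
#' the aligned dataset so the rows line up with the regression design
#' matrix.
#'
#' @param block_a,block_b Pseudo-value matrices from
#'   [jackknife_pseudovalues()] for Group A and Group B.
#' @param assignment A `group_assignment` from [align_and_split()].
#' @return n x p pseudo-value matrix in aligned sample order.
#' @export
assemble_pseudovalues <- function(block_a, block_b, assignment) {
  if (!identical(colnames(block_a), colnames(block_b))) {
    stop("gene ids differ between the two pseudo-value blocks")
  }
  n <- length(assignment$group_a) + length(assignment$group_b)
  if (nrow(block_a) != length(assignment$group_a) ||
      nrow(block_b) != length(assignment$group_b)) {
    stop("block row counts do not match the group assignment")
  }
  psv <- matrix(NA_real_, n, ncol(block_a))
  rn <- character(n)
  psv[assignment$group_a, ] <- block_a
  psv[assignment$group_b, ] <- block_b
  rn[assignment$group_a] <- rownames(block_a)
  rn[assignment$group_b] <- rownames(block_b)
  dimnames(psv) <- list(rn, colnames(block_a))
  psv
}
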