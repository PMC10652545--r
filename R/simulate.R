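#' Describe a two-group synthetic scenario
#'
#' The generator draws each group's samples from a multivariate normal with
#' a block covariance: a "hub" block of `hub_size` genes equicorrelated at
#' `base_rho` in Group A and `perturbed_rho` in Group B, against an
#' independent background. Under the negative-binomial count model the
#' latent normals are pushed through a Gaussian copula
#' (`qnbinom(pnorm(z))`) to mimic RNA-seq counts; MI estimation is
#' rank-based, so the latent correlation structure survives the margins.
#'
#' The phenotype carries the binary group label, one numeric covariate
#' whose group means differ by `confounding_strength`, and one balanced
#' two-level categorical covariate. With `covariate_driven_rho = TRUE` the
#' hub correlation is driven by the binary covariate rather than by group
#' membership (the covariate's group imbalance then makes the covariate a
#' true confounder of connectivity).
#'
#' @param n_per_group Length-2 integer vector of group sample sizes.
#' @param p Gene count.
#' @param hub_size Number of genes in the perturbed block (<= p).
#' @param base_rho,perturbed_rho Within-hub correlations for Groups A / B,
#'   each in [0, 1).
#' @param confounding_strength Mean shift of the numeric covariate between
#'   groups (0 = no confounding). Under `covariate_driven_rho` it instead
#'   sets the group imbalance of the driving binary covariate.
#' @param noise_sd Standard deviation of additive Gaussian measurement
#'   noise on the latent scale.
#' @param count_model `"gaussian"` (latent values reported directly) or
#'   `"negbin"` (Gaussian-copula negative-binomial counts).
#' @param nb_mu,nb_size Negative-binomial mean and dispersion (size) for
#'   `count_model = "negbin"`.
#' @param covariate_driven_rho Make the hub correlation depend on the
#'   binary covariate instead of the group (see above).
#' @param seed Integer seed; the scenario plus seed fully determines the
#'   data.
#' @return A list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n_per_group = c(60L, 60L), p = 30L,
                               hub_size = 6L, base_rho = 0.2,
                               perturbed_rho = 0.7,
                               confounding_strength = 0, noise_sd = 0.1,
                               count_model = c("gaussian", "negbin"),
                               nb_mu = 100, nb_size = 5,
                               covariate_driven_rho = FALSE, seed = 1L) {
  count_model <- match.arg(count_model)
  if (hub_size > p) stop("hub_size must be <= p")
  if (hub_size < 2L) stop("hub_size must be >= 2 (a one-gene block has no edges)")
  for (rho in c(base_rho, perturbed_rho)) {
    if (rho < 0 || rho >= 1) stop("correlations must lie in [0, 1)")
    # equicorrelation is positive definite iff rho > -1/(m-1); rho >= 0 suffices
  }
  if (noise_sd < 0) stop("noise_sd must be positive or zero")
  structure(list(n_per_group = as.integer(n_per_group), p = as.integer(p),
                 hub_size = as.integer(hub_size), base_rho = base_rho,
                 perturbed_rho = perturbed_rho,
                 confounding_strength = confounding_strength,
                 noise_sd = noise_sd, count_model = count_model,
                 nb_mu = nb_mu, nb_size = nb_size,
                 covariate_driven_rho = covariate_driven_rho,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Cholesky factor of an equicorrelation block of size m at rho.
equicor_chol <- function(m, rho) {
  chol(matrix(rho, m, m) + diag(1 - rho, m))
}

#' Simulate a two-group dataset with known differentially connected genes
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `expr` (samples x genes matrix, both groups stacked
#'   and shuffled into a deterministic interleaved order), `pheno`
#'   (phenotype `data.frame` with attribute `group_variable = "group"`),
#'   and `truth` (character vector of truly differentially connected gene
#'   ids: the hub genes when the two correlations differ, else empty).
#' @export
simulate_two_group <- function(scenario) {
  withr::with_seed(scenario$seed, {
    n1 <- scenario$n_per_group[1L]; n2 <- scenario$n_per_group[2L]
    n <- n1 + n2; p <- scenario$p; h <- scenario$hub_size
    genes <- sprintf("g%02d", seq_len(p))
    samples <- sprintf("s%03d", seq_len(n))
    group <- rep(c(0L, 1L), c(n1, n2))

    # numeric covariate, mean-shifted between groups when confounding
    shift <- if (scenario$covariate_driven_rho) 0 else scenario$confounding_strength
    cov_num <- stats::rnorm(n, mean = shift * group, sd = 1)
    cov_cat <- rep_len(c("c1", "c2"), n)

    # which correlation governs each sample's hub block
    if (scenario$covariate_driven_rho) {
      # binary driver, imbalanced across groups by confounding_strength
      pr <- pmin(pmax(0.5 + scenario$confounding_strength * (group - 0.5), 0.05), 0.95)
      driver <- stats::rbinom(n, 1L, pr)
      rho_of <- ifelse(driver == 1L, scenario$perturbed_rho, scenario$base_rho)
      cov_num <- as.numeric(driver)
    } else {
      rho_of <- ifelse(group == 1L, scenario$perturbed_rho, scenario$base_rho)
    }

    L_base <- equicor_chol(h, scenario$base_rho)
    L_pert <- equicor_chol(h, scenario$perturbed_rho)
    lat <- matrix(stats::rnorm(n * p), n, p)
    for (i in seq_len(n)) {
      L <- if (rho_of[i] == scenario$base_rho) L_base else L_pert
      lat[i, seq_len(h)] <- drop(lat[i, seq_len(h)] %*% L)
    }
    if (scenario$noise_sd > 0) {
      lat <- lat + matrix(stats::rnorm(n * p, sd = scenario$noise_sd), n, p)
    }

    expr <- if (scenario$count_model == "negbin") {
      sds <- sqrt(1 + scenario$noise_sd^2)
      matrix(stats::qnbinom(stats::pnorm(lat / sds), mu = scenario$nb_mu,
                            size = scenario$nb_size),
             n, p)
    } else {
      lat
    }
    dimnames(expr) <- list(samples, genes)

    pheno <- data.frame(group = group, covar = cov_num, batch = cov_cat,
                        row.names = samples, stringsAsFactors = FALSE)
    pheno <- as_phenotype_table(pheno, "group")

    truth <- if (scenario$base_rho != scenario$perturbed_rho) {
      genes[seq_len(h)]
    } else {
      character(0)
    }
    list(expr = expr, pheno = pheno, truth = truth, scenario = scenario)
  })
}

#' A COPD-panel-shaped synthetic fixture
#'
#' Generates a dataset with the shape of the published 28-gene COPD smoking
#' panel: 406 samples, 28 genes (Entrez-style numeric ids), negative-
#' binomial counts, and six clinical variables (current smoking status as
#' the binary grouping variable, plus smoking pack years, age, gender,
#' race, and FEV1 percent). Values are synthetic; only the shape and
#' variable types mirror the real panel.
#'
#' @param seed Integer seed.
#' @return List with `expr` (406 x 28 matrix) and `pheno` (406 x 6
#'   `data.frame` with `group_variable = "currentsmoking"`).
#' @export
make_copd_like_fixture <- function(seed = 1L) {
  sc <- synthetic_scenario(n_per_group = c(233L, 173L), p = 28L, hub_size = 6L,
                           base_rho = 0.2, perturbed_rho = 0.6,
                           confounding_strength = 0.5, noise_sd = 0.1,
                           count_model = "negbin", nb_mu = 500, nb_size = 2,
                           seed = seed)
  sim <- simulate_two_group(sc)
  withr::with_seed(seed + 1L, {
    n <- nrow(sim$expr)
    # Entrez-style opaque numeric gene ids
    colnames(sim$expr) <- as.character(sort(sample(1000:99999, 28L)))
    grp <- sim$pheno$group
    pheno <- data.frame(
      currentsmoking = grp,
      packyears = round(pmax(stats::rnorm(n, 25 + 10 * grp, 15), 0), 1),
      age = round(stats::rnorm(n, 62, 8)),
      gender = sample(c("Female", "Male"), n, replace = TRUE),
      race = sample(c("Black", "White"), n, replace = TRUE, prob = c(0.3, 0.7)),
      fev1perc = round(stats::rnorm(n, 65, 20), 1),
      row.names = rownames(sim$expr), stringsAsFactors = FALSE)
    list(expr = sim$expr, pheno = as_phenotype_table(pheno, "currentsmoking"))
  })
}
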