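make_pheno <- function(n, seed = 1) {
  set.seed(seed)
  as_phenotype_table(data.frame(
    grp = rep(c(0, 1), each = n / 2),
    age = rnorm(n, 60, 8),
    sex = sample(c("F", "M"), n, replace = TRUE),
    row.names = sprintf("s%03d", 1:n)), "grp")
}

make_assignment <- function(n) {
  structure(list(group_a = 1:(n / 2), group_b = (n / 2 + 1):n,
                 levels = c("0", "1")), class = "group_assignment")
}

test_that("design matrix has intercept, group, then treatment-coded covariates", {
  ph <- make_pheno(20)
  X <- build_design(ph, make_assignment(20))
  expect_identical(colnames(X)[1:2], c("(Intercept)", "grp"))
  expect_identical(attr(X, "predictors"), c("grp", "age", "sexM"))
  expect_setequal(unique(X[, "grp"]), c(0, 1))

  # 3-level categorical expands to two indicators, reference dropped
  ph3 <- ph
  ph3$site <- rep(c("a", "b", "c"), length.out = 20)
  attr(ph3, "group_variable") <- "grp"
  X3 <- build_design(ph3, make_assignment(20))
  expect_true(all(c("siteb", "sitec") %in% colnames(X3)))
  expect_false("sitea" %in% colnames(X3))

  # duplicated covariate -> rank deficiency error naming the column
  phd <- ph
  phd$age2 <- phd$age
  attr(phd, "group_variable") <- "grp"
  expect_error(build_design(phd, make_assignment(20)), "age2")

  # covariate subsetting
  Xs <- build_design(ph, make_assignment(20), covariates = "age")
  expect_identical(attr(Xs, "predictors"), c("grp", "age"))
  expect_error(build_design(ph, make_assignment(20), covariates = "typo"),
               "unknown covariate")
})

test_that("robust fit tracks least squares on clean Gaussian data", {
  set.seed(101)
  n <- 200
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rnorm(n))
  attr(X, "predictors") <- c("x1", "x2")
  y <- 1 + 2 * X[, "x1"] - 0.5 * X[, "x2"] + rnorm(n)
  fit <- fit_robust(y, X)
  ols <- lm.fit(X, y)$coefficients
  expect_identical(fit$flag, "ok")
  expect_true(all(abs(fit$coefficients - ols) <= 2 * fit$std_errors))
})

test_that("gross outliers leave the robust slope near truth while least squares departs", {
  set.seed(102)
  n <- 200
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- 1 + 2 * X[, "x"] + rnorm(n)
  clean <- fit_robust(y, X)
  y_out <- y
  idx <- sample(n, n / 10)
  y_out[idx] <- y_out[idx] + 50
  rob <- fit_robust(y_out, X)
  ols <- lm.fit(X, y_out)$coefficients
  expect_lte(abs(rob$coefficients["x"] - clean$coefficients["x"]),
             2 * rob$std_errors["x"])
  expect_gt(abs(ols["x"] - clean$coefficients["x"]), 2 * rob$std_errors["x"])
})

test_that("perfect fits are flagged with the interpolating solution and degenerate p-values", {
  X <- cbind("(Intercept)" = 1, x = c(1, 2, 3, 4, 5, 6))
  y <- 3 + 0 * X[, "x"]
  fit <- fit_robust(y, X)
  expect_identical(fit$flag, "perfect_fit")
  expect_equal(unname(fit$coefficients), c(3, 0))
  expect_equal(unname(fit$pvalues), c(0, 1))  # nonzero coef -> 0, zero -> 1

  # near-noiseless data: robust and OLS coincide tightly
  set.seed(103)
  X2 <- cbind("(Intercept)" = 1, x = rnorm(30))
  y2 <- 2 - X2[, "x"] + rnorm(30, sd = 1e-6)
  fit2 <- fit_robust(y2, X2)
  expect_equal(unname(fit2$coefficients), unname(lm.fit(X2, y2)$coefficients),
               tolerance = 1e-4)
})

test_that("per-gene fitting is equivariant under gene permutation and survives constants", {
  sim <- tiny_sim(seed = 104, n = 10, p = 5, hub = 2)
  al <- align_and_split(sim$expr, sim$pheno)
  asg <- al$assignment
  psv <- assemble_pseudovalues(
    jackknife_pseudovalues(al$expr[asg$group_a, , drop = FALSE]),
    jackknife_pseudovalues(al$expr[asg$group_b, , drop = FALSE]), asg)
  X <- build_design(al$pheno, asg)
  res <- fit_all_genes(psv, X, seed = 5)
  expect_identical(dim(res$coefficients), c(5L, length(res$predictors)))
  expect_true(all(res$pvalues >= 0 & res$pvalues <= 1))

  perm <- c(3, 1, 5, 2, 4)
  res_p <- fit_all_genes(psv[, perm], X, seed = 5)
  expect_equal(res_p$coefficients, res$coefficients[perm, ])
  expect_equal(res_p$pvalues, res$pvalues[perm, ])

  # constant pseudo-value column is flagged, run continues
  psv_c <- psv
  psv_c[, 2] <- 4
  expect_message(res_c <- fit_all_genes(psv_c, X, seed = 5), "perfect_fit")
  expect_identical(unname(res_c$flags[2]), "perfect_fit")
  expect_equal(res_c$coefficients[-2, ], res$coefficients[-2, ])
})

test_that("genes made more connected in group B get positive group coefficients", {
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    sim <- tiny_sim(seed = 200 + s, n = 30, p = 10, hub = 4,
                    rho_a = 0.1, rho_b = 0.8)
    res <- run_analysis(sim$expr, sim$pheno, run_config(seed = s))
    hits <- hits + sum(res$coefficients[sim$truth, "group"] > 0)
    total <- total + length(sim$truth)
  }
  expect_gt(hits / total, 0.75)
})
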