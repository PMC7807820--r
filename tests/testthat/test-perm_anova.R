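test_that("cell-means fit reproduces hand-computed OLS quantities", {
  cf <- factor(c("g1", "g1", "g2", "g2"))
  fit <- fit_cell_means(c(1, 3, 5, 7), cf)
  expect_equal(unname(fit$means), c(2, 6))
  expect_equal(fit$mse, 2)            # pooled within-cell variance
  expect_equal(fit$df_resid, 2L)
  # constant response
  fit0 <- fit_cell_means(rep(4, 6), factor(rep(c("a", "b"), 3)))
  expect_equal(unname(fit0$means), c(4, 4))
  expect_equal(fit0$mse, 0)
  # invariance to sample order
  o <- c(3, 1, 4, 2)
  fit_o <- fit_cell_means(c(1, 3, 5, 7)[o], cf[o])
  expect_equal(fit_o$means, fit$means)
  expect_error(fit_cell_means(1:3, factor(c("a", "b", "c"))),
               "residual degrees")
})

test_that("1-df contrast F equals the squared pooled t statistic", {
  withr::local_seed(2)
  y <- rnorm(30)
  g <- rep(c("g1", "g2"), each = 15)
  fit <- fit_cell_means(y, factor(g))
  con <- make_contrast("d", c(g1 = 1, g2 = -1))
  fs <- f_statistic(fit, con)
  tt <- t.test(y[g == "g1"], y[g == "g2"], var.equal = TRUE)
  expect_equal(fs$f, unname(tt$statistic)^2)
  expect_equal(fs$f, (fs$estimate / fs$se)^2)
  # equal cell means give F = 0; scaling y leaves F unchanged
  expect_equal(f_statistic(fit_cell_means(rep(c(2, 2), 10),
                                          factor(rep(c("g1", "g2"), 10))),
                           con)$f, 0)
  fs_k <- f_statistic(fit_cell_means(7 * y, factor(g)), con)
  expect_equal(fs_k$f, fs$f)
})

test_that("standard contrasts carry the correct cell weights", {
  meta <- design_fixture()
  sc <- standard_contrasts(meta)
  w <- sc$farm$weights
  a_cells <- grepl("^A\\.", names(w))
  expect_equal(unname(w[a_cells]), rep(1 / 8, 8))
  expect_equal(unname(w[!a_cells]), rep(-1 / 4, 4))
  for (con in sc) {
    expect_equal(sum(con$weights), 0)
    expect_equal(sum(abs(con$weights[con$weights > 0])), 1)
  }
  expect_true(all(sc$antibiotic_within_B$weights[a_cells] == 0))
  expect_true(all(sc$feeding_within_B$weights[a_cells] == 0))
  # interaction contrast: zero-sum difference of within-farm feeding effects
  ic <- interaction_contrast(meta)
  expect_equal(sum(ic$weights), 0)
})

test_that("contrasts touching unobserved cells are rejected", {
  fit <- fit_cell_means(rnorm(8), factor(rep(c("g1", "g2"), 4)))
  con <- make_contrast("bad", c(g1 = 1, g3 = -1))
  expect_error(f_statistic(fit, con), "unobserved cell")
  expect_error(make_contrast("x", c(a = 1, b = -0.5)), "sum to zero")
  expect_error(make_contrast("x", c(a = 0.7, b = -0.2, c = -0.5)),
               "sum to one")
})

test_that("permutation p-values follow the counting definition", {
  cf <- factor(rep(c("g1", "g2"), each = 10))
  con <- make_contrast("d", c(g1 = 1, g2 = -1))
  # constant response: every permuted F equals the observed 0, p = 1
  expect_equal(permutation_pvalue(rep(5, 20), cf, con, n_perm = 50,
                                  seed = 1), 1)
  withr::local_seed(3)
  y <- rnorm(20)
  p1 <- permutation_pvalue(y, cf, con, n_perm = 99, seed = 7)
  # affine transforms of the response leave the p-value unchanged
  expect_equal(permutation_pvalue(3 * y + 10, cf, con, n_perm = 99,
                                  seed = 7), p1)
  # add-one variant never reaches zero
  p_add <- permutation_pvalue(y, cf, con, n_perm = 99, seed = 7,
                              add_one = TRUE)
  expect_gte(p_add, 1 / 100)
  expect_equal(p_add, (99 * p1 + 1) / 100)
})

test_that("permutation p agrees with the classical F test on Gaussian data", {
  withr::local_seed(11)
  cf <- factor(rep(c("g1", "g2"), each = 20))
  con <- make_contrast("d", c(g1 = 1, g2 = -1))
  y <- rnorm(40) + 0.5 * (cf == "g1")
  fit <- fit_cell_means(y, cf)
  fs <- f_statistic(fit, con)
  p_classical <- pf(fs$f, 1, fit$df_resid, lower.tail = FALSE)
  p_perm <- permutation_pvalue(y, cf, con, n_perm = 4000, seed = 5)
  expect_lt(abs(p_perm - p_classical), 0.03)
})

test_that("add-one permutation p-values are uniform under the null", {
  cf <- factor(rep(c("g1", "g2"), each = 12))
  con <- make_contrast("d", c(g1 = 1, g2 = -1))
  withr::local_seed(19)
  pvals <- replicate(500, permutation_pvalue(rnorm(24), cf, con,
                                             n_perm = 99,
                                             seed = sample.int(1e6, 1),
                                             add_one = TRUE))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pvals) - 0.5), 0.05)
})

test_that("interaction test flags differential feeding effects across farms", {
  meta <- toy_metadata(10)
  withr::local_seed(23)
  base <- rnorm(nrow(meta), sd = 0.5)
  # same feeding effect in both farms: interaction null
  y_null <- base + 2 * (meta$feeding == "R")
  expect_gt(interaction_test(y_null, meta, n_perm = 400, seed = 3)$p_emp,
            0.05)
  # feeding effect only in farm A
  y_alt <- base + 4 * (meta$feeding == "R") * (meta$farm == "A")
  expect_lt(interaction_test(y_alt, meta, n_perm = 400, seed = 3)$p_emp,
            0.01)
  # constant response: p = 1
  expect_equal(interaction_test(rep(1, nrow(meta)), meta, n_perm = 100,
                                seed = 1)$p_emp, 1)
})

test_that("BH adjustment matches an exhaustive step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  withr::local_seed(29)
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.8, 1)
  for (len in c(2:8)) {
    for (rep in 1:20) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_fdr(p), bh_oracle(p))
    }
  }
})

test_that("differential abundance recovers a farm-exclusive taxon", {
  meta <- toy_metadata(12)
  withr::local_seed(31)
  p <- 20
  values <- matrix(abs(rnorm(p * nrow(meta), mean = 5)), p, nrow(meta),
                   dimnames = list(sprintf("OTU%02d", 1:p), meta$sample_id))
  values["OTU01", meta$farm == "B"] <- 0   # present only in farm A
  res <- run_differential_abundance(values, meta, n_perm = 200, seed = 7)
  tab <- res$table
  row <- tab[tab$taxon == "OTU01" & tab$contrast == "farm", ]
  expect_gt(row$estimate, 0)
  expect_true(row$significant)
  expect_equal(mean(values["OTU01", meta$farm == "B"]), 0)
  # p_fdr >= p_emp everywhere
  expect_true(all(tab$p_fdr >= tab$p_emp - 1e-12))
  # per-taxon streams: results identical when rows are processed in
  # reverse order
  res_rev <- run_differential_abundance(values[rev(rownames(values)), ],
                                        meta, n_perm = 200, seed = 7)
  merged <- merge(tab, res_rev$table, by = c("taxon", "contrast"))
  expect_equal(merged$p_emp.x, merged$p_emp.y)
  expect_equal(merged$estimate.x, merged$estimate.y)
})

test_that("sample/metadata misalignment is caught", {
  meta <- toy_metadata(2)
  values <- matrix(1, 2, 3,
                   dimnames = list(c("a", "b"), c("S001", "S002", "zz")))
  expect_error(run_differential_abundance(values, meta, n_perm = 10),
               "align")
})
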