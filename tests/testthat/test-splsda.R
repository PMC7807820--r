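test_that("dense fit reduces to PLS-DA and matches the SVD oracle", {
  inst <- separable_instance()
  fit <- splsda(inst$X, inst$classes, ncomp = 1, keepX = ncol(inst$X))
  Y <- scale(stats::model.matrix(~ inst$classes - 1))
  v <- svd(crossprod(Y, scale(inst$X)))$v[, 1]
  expect_lt(max(abs(abs(fit$x_loadings[, 1]) - abs(v))), 1e-8)
  expect_equal(sqrt(sum(fit$x_loadings[, 1]^2)), 1)
})

test_that("keepX controls the exact support size of each component", {
  inst <- separable_instance()
  fit <- splsda(inst$X, inst$classes, ncomp = 2, keepX = c(1, 3))
  expect_equal(colSums(fit$x_loadings != 0), c(1, 3))
  fit5 <- splsda(inst$X, inst$classes, ncomp = 1, keepX = 5)
  expect_setequal(selected_variables(fit5)$comp1, inst$signal)
  expect_error(splsda(inst$X, inst$classes, keepX = 999), "keepX")
})

test_that("score columns are orthogonal and explained variance is bounded", {
  inst <- separable_instance(p = 40)
  fit <- splsda(inst$X, inst$classes, ncomp = 3, keepX = c(10, 10, 10))
  G <- crossprod(fit$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  expect_true(all(fit$explained_variance >= 0))
  expect_lte(sum(fit$explained_variance), 1)
})

test_that("prediction is nearest-centroid with a deterministic tie break", {
  # perfectly symmetric two-feature instance: the second feature carries no
  # class signal, so centroids sit at exactly +/- s on component 1
  X <- cbind(rep(c(-1, 1), each = 4), rep(c(1, -1), 4))
  cls <- rep(c("zeta", "alpha"), each = 4)
  fit <- splsda(X, cls, ncomp = 1, keepX = 2, scale = FALSE)
  expect_equal(as.character(predict(fit, X)), cls)
  # the exact midpoint of the centroids ties: lexicographically smallest
  mid <- matrix(colMeans(X), 1, 2)
  expect_equal(as.character(predict(fit, mid)), "alpha")
})

test_that("training-set predictions recover separable labels, equivariantly", {
  inst <- separable_instance()
  fit <- splsda(inst$X, inst$classes, ncomp = 2, keepX = c(5, 5))
  expect_equal(predict(fit, inst$X), inst$classes, ignore_attr = TRUE)
  # permuting the class labels permutes predictions identically
  swapped <- factor(ifelse(inst$classes == "A", "B", "A"))
  fit_sw <- splsda(inst$X, swapped, ncomp = 2, keepX = c(5, 5))
  pr <- predict(fit_sw, inst$X)
  expect_equal(as.character(pr),
               ifelse(as.character(predict(fit, inst$X)) == "A", "B", "A"))
  expect_error(predict(fit, inst$X[, 1:3]), "feature")
})

test_that("the sparse fit agrees with the mixOmics reference on selection", {
  skip_if_not_installed("mixOmics")
  inst <- separable_instance(n_per_class = 25, p = 40, seed = 3)
  fit <- splsda(inst$X, inst$classes, ncomp = 1, keepX = 5)
  ref <- mixOmics::splsda(inst$X, inst$classes, ncomp = 1, keepX = 5)
  ref_sel <- mixOmics::selectVar(ref, comp = 1)$name
  expect_setequal(selected_variables(fit)$comp1, ref_sel)
  ours <- fit$x_loadings[ref_sel, 1]
  theirs <- ref$loadings$X[ref_sel, 1]
  expect_gt(abs(cor(ours, theirs)), 0.99)
})

test_that("tuning selects sparsity by cross-validated BER", {
  inst <- separable_instance()
  single <- tune_splsda(inst$X, inst$classes, keepX_grid = 7,
                        max_ncomp = 1, repeats = 2, seed = 4)
  expect_equal(single$keepX, 7L)
  expect_equal(single$ncomp, 1L)
  tuned <- tune_splsda(inst$X, inst$classes, keepX_grid = c(1, 5, 10),
                       max_ncomp = 2, repeats = 3, seed = 4)
  expect_equal(tuned$ber, 0)
  tuned2 <- tune_splsda(inst$X, inst$classes, keepX_grid = c(1, 5, 10),
                        max_ncomp = 2, repeats = 3, seed = 4)
  expect_identical(tuned, tuned2)
  expect_error(tune_splsda(inst$X, inst$classes, keepX_grid = numeric(0)),
               "grid")
})

test_that("cross-validated BER is zero on separable and ~0.5 on random labels", {
  inst <- separable_instance()
  perf <- evaluate_splsda(inst$X, inst$classes, ncomp = 1, keepX = 5,
                          repeats = 20, seed = 5)
  expect_equal(unname(perf$overall_ber[["mean"]]), 0)
  expect_equal(unname(perf$overall_ber[["sd"]]), 0)
  # every fold selects the same 5 strong features: stability 1
  expect_equal(unname(perf$stability[inst$signal, 1]), rep(1, 5))
  expect_setequal(perf$stable_variables$comp1, inst$signal)

  withr::local_seed(6)
  X0 <- matrix(rnorm(50 * 30), 50, 30)
  cls0 <- factor(rep(c("A", "B"), 25))
  perf0 <- evaluate_splsda(X0, cls0, ncomp = 1, keepX = 5, repeats = 30,
                           seed = 7)
  expect_lt(abs(perf0$overall_ber[["mean"]] - 0.5), 0.07)
})

test_that("BER is invariant to class relabeling and feature order", {
  inst <- separable_instance(n_per_class = 15, p = 20)
  perf_a <- evaluate_splsda(inst$X, inst$classes, ncomp = 1, keepX = 5,
                            repeats = 10, seed = 8)
  relab <- factor(ifelse(inst$classes == "A", "grp2", "grp1"))
  perf_b <- evaluate_splsda(inst$X, relab, ncomp = 1, keepX = 5,
                            repeats = 10, seed = 8)
  expect_equal(perf_a$overall_ber, perf_b$overall_ber)
  o <- rev(seq_len(ncol(inst$X)))
  perf_c <- evaluate_splsda(inst$X[, o], inst$classes, ncomp = 1, keepX = 5,
                            repeats = 10, seed = 8)
  expect_equal(perf_a$overall_ber, perf_c$overall_ber)
})
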