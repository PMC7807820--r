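# Sparse partial least squares discriminant analysis, from first
# principles: dummy-coded classes, alternating power iterations on the
# X'Y cross-covariance with soft-thresholded X-loadings (exactly keepX
# nonzeros per component), regression-mode deflation, centroid-distance
# prediction, and repeated stratified cross-validation for tuning (balanced
# error rate) and selection-stability scoring.

# Soft-threshold u to exactly keepX nonzero entries by magnitude, ties
# broken by feature order.
.soft_keep <- function(u, keepX) {
  p <- length(u)
  if (keepX >= p) return(u)
  ord <- order(-abs(u), seq_along(u))
  kept <- ord[seq_len(keepX)]
  lambda <- max(abs(u[ord[(keepX + 1L):p]]))
  out <- numeric(p)
  shrunk <- abs(u[kept]) - lambda
  # a tie at the threshold would shrink a kept entry to zero; keep it
  # nonzero at negligible magnitude so the support size is exact
  shrunk[shrunk <= 0] <- lambda * 1e-8 + 1e-300
  out[kept] <- sign(u[kept]) * shrunk
  out
}

.scale_training <- function(X, scale) {
  cm <- colMeans(X)
  Xc <- sweep(X, 2L, cm)
  csd <- rep(1, ncol(X))
  if (scale) {
    csd <- apply(Xc, 2L, stats::sd)
    zero <- csd < .Machine$double.eps^0.5
    if (any(zero)) csd[zero] <- 1  # zero-variance: centered column stays 0
    Xc <- sweep(Xc, 2L, csd, "/")
  }
  list(X = Xc, center = cm, scale = csd)
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Classes are dummy coded and X is centered (and by default unit-variance
#' scaled).  Each component extracts the leading pair of singular vectors of
#' the deflated cross-covariance \eqn{X^T Y} by alternating iteration, with
#' the X-loading soft-thresholded at the (keepX+1)-th largest magnitude and
#' renormalized, so exactly \code{keepX[h]} variables carry component
#' \eqn{h}.  X and Y are deflated by regression on the component score;
#' class centroids are the class means of the training scores.
#'
#' @param X sample x feature numeric matrix.
#' @param classes factor (or coercible) of class labels, one per row of X.
#' @param ncomp number of components (at most 4 in this analysis).
#' @param keepX integer vector of variables to retain per component
#'   (recycled to \code{ncomp}).
#' @param scale unit-variance scale X (default TRUE).
#' @param max_iter,tol alternating-iteration controls.
#' @param warn_zero_var warn when zero-variance features are dropped
#'   (silenced by the cross-validation drivers, where refitting on folds
#'   makes the condition routine).
#' @return Object of class \code{splsda_fit} with loadings, scores,
#'   centroids, per-component explained X-variance and the centering/scaling
#'   vectors used for prediction.
#' @export
splsda <- function(X, classes, ncomp = 2L, keepX = ncol(X), scale = TRUE,
                   max_iter = 500L, tol = 1e-9, warn_zero_var = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  classes <- factor(classes)
  if (nlevels(classes) < 2) stop("need at least two classes")
  if (nrow(X) != length(classes)) stop("X rows and classes differ in length")
  ncomp <- as.integer(ncomp)
  keepX <- as.integer(rep_len(keepX, ncomp))
  if (any(keepX < 1) || any(keepX > ncol(X)))
    stop("keepX must lie in 1..ncol(X)")
  zero_var <- apply(X, 2L, stats::sd) < .Machine$double.eps^0.5
  if (any(zero_var)) {
    if (warn_zero_var)
      warning("dropping ", sum(zero_var), " zero-variance feature(s)")
    X <- X[, !zero_var, drop = FALSE]
    if (any(keepX > ncol(X))) stop("keepX exceeds remaining features")
  }
  n <- nrow(X); p <- ncol(X); K <- nlevels(classes)
  sx <- .scale_training(X, scale)
  Y <- stats::model.matrix(~ classes - 1)
  colnames(Y) <- levels(classes)
  sy <- .scale_training(Y, scale = TRUE)
  Xh <- sx$X; Yh <- sy$X
  total_var <- sum(Xh^2)
  loadings <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  reg_loadings <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  scores <- matrix(0, n, ncomp)
  expl <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)                       # p x K
    sv <- svd(M, nu = 1L, nv = 1L)
    v <- sv$v[, 1L]
    u <- numeric(p)
    for (iter in seq_len(max_iter)) {
      u_new <- .soft_keep(drop(M %*% v), keepX[[h]])
      nrm <- sqrt(sum(u_new^2))
      if (nrm < .Machine$double.eps) break
      u_new <- u_new / nrm
      v_new <- drop(crossprod(M, u_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (sum((u_new - u)^2) < tol) { u <- u_new; v <- v_new; break }
      u <- u_new; v <- v_new
    }
    t_h <- drop(Xh %*% u)
    tt <- sum(t_h^2)
    if (tt < .Machine$double.eps) {
      warning("component ", h, " degenerate; truncating at ", h - 1L,
              " component(s)")
      ncomp <- h - 1L
      loadings <- loadings[, seq_len(ncomp), drop = FALSE]
      reg_loadings <- reg_loadings[, seq_len(ncomp), drop = FALSE]
      scores <- scores[, seq_len(ncomp), drop = FALSE]
      expl <- expl[seq_len(ncomp)]
      keepX <- keepX[seq_len(ncomp)]
      break
    }
    c_h <- drop(crossprod(Xh, t_h)) / tt
    e_h <- drop(crossprod(Yh, t_h)) / tt
    expl[[h]] <- sum((tcrossprod(t_h, c_h))^2) / total_var
    Xh <- Xh - tcrossprod(t_h, c_h)
    Yh <- Yh - tcrossprod(t_h, e_h)
    loadings[, h] <- u
    reg_loadings[, h] <- c_h
    scores[, h] <- t_h
  }
  if (ncomp < 1L) stop("no usable component")
  centroids <- rowsum(scores, classes) / as.vector(table(classes))
  structure(list(ncomp = ncomp, keepX = keepX, scale = scale,
                 x_loadings = loadings, reg_loadings = reg_loadings,
                 scores = scores, classes = classes,
                 class_levels = levels(classes), centroids = centroids,
                 x_center = sx$center, x_scale = sx$scale,
                 explained_variance = expl),
            class = "splsda_fit")
}

#' Variables selected on each component
#'
#' @param fit an \code{splsda_fit}.
#' @return Named list, per component, of the feature names with nonzero
#'   loadings.
#' @export
selected_variables <- function(fit) {
  stopifnot(inherits(fit, "splsda_fit"))
  out <- lapply(seq_len(fit$ncomp), function(h)
    rownames(fit$x_loadings)[fit$x_loadings[, h] != 0])
  names(out) <- paste0("comp", seq_len(fit$ncomp))
  out
}

#' @export
print.splsda_fit <- function(x, ...) {
  cat(sprintf("sPLS-DA fit: %d classes, %d components (keepX: %s)\n",
              length(x$class_levels), x$ncomp,
              paste(x$keepX, collapse = ", ")))
  cat(sprintf("Explained X variance per component: %s\n",
              paste(sprintf("%.2f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}

#' Predict classes by nearest centroid in score space
#'
#' New samples are centered/scaled with the training parameters, projected
#' through the training loadings with the same deflation, and assigned to
#' the class whose training centroid is nearest (Euclidean distance); exact
#' ties go to the lexicographically smallest class label.
#'
#' @param object an \code{splsda_fit}.
#' @param newdata sample x feature matrix with the training features.
#' @param ... unused.
#' @return Factor of predicted classes (attribute \code{scores} holds the
#'   projected coordinates).
#' @export
predict.splsda_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  feats <- rownames(object$x_loadings)
  if (!is.null(colnames(newdata))) {
    if (!all(feats %in% colnames(newdata)))
      stop("newdata is missing training feature(s)")
    newdata <- newdata[, feats, drop = FALSE]
  } else if (ncol(newdata) != length(feats)) {
    stop("newdata feature count does not match the training features")
  }
  Xh <- sweep(sweep(newdata, 2L, object$x_center), 2L, object$x_scale, "/")
  n <- nrow(Xh)
  scores <- matrix(0, n, object$ncomp)
  for (h in seq_len(object$ncomp)) {
    t_h <- drop(Xh %*% object$x_loadings[, h])
    scores[, h] <- t_h
    Xh <- Xh - tcrossprod(t_h, object$reg_loadings[, h])
  }
  d2 <- outer(rowSums(scores^2), rowSums(object$centroids^2), "+") -
    2 * tcrossprod(scores, object$centroids)
  # ties resolved toward the lexicographically smallest class label
  ord <- order(rownames(object$centroids))
  d2o <- d2[, ord, drop = FALSE]
  pred <- rownames(object$centroids)[ord][max.col(-d2o, ties.method = "first")]
  structure(factor(pred, levels = object$class_levels), scores = scores)
}

#' @export
plot.splsda_fit <- function(x, comps = c(1L, 2L), ...) {
  comps <- comps[comps <= x$ncomp]
  if (length(comps) < 2) stop("need two fitted components to plot")
  cls <- as.integer(x$classes)
  graphics::plot(x$scores[, comps[[1L]]], x$scores[, comps[[2L]]],
                 col = cls, pch = cls,
                 xlab = sprintf("Component %d (%.2f%%)", comps[[1L]],
                                100 * x$explained_variance[[comps[[1L]]]]),
                 ylab = sprintf("Component %d (%.2f%%)", comps[[2L]],
                                100 * x$explained_variance[[comps[[2L]]]]),
                 ...)
  graphics::legend("topright", legend = x$class_levels,
                   col = seq_along(x$class_levels),
                   pch = seq_along(x$class_levels), bty = "n")
  invisible(x)
}

# Stratified k-fold partition: within each class, shuffled indices are dealt
# round-robin so every fold holds ~1/folds (20% for 5 folds) of each class.
.stratified_folds <- function(classes, folds) {
  assignment <- integer(length(classes))
  for (cl in levels(classes)) {
    idx <- sample(which(classes == cl))
    assignment[idx] <- rep_len(sample.int(folds), length(idx))
  }
  lapply(seq_len(folds), function(k) which(assignment == k))
}

# Balanced error rate: unweighted mean of per-class misclassification rates
# over the classes present in the truth.
.ber <- function(truth, pred) {
  per_class <- vapply(levels(truth), function(cl) {
    sel <- truth == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] != cl)
  }, 0)
  mean(per_class, na.rm = TRUE)
}

#' Tune sPLS-DA sparsity by repeated cross-validation
#'
#' Forward per-component selection: with earlier components fixed, every
#' grid value is scored by mean balanced error rate (BER) over
#' \code{repeats} stratified \code{folds}-fold cross-validations, and the
#' minimizer is kept (ties to the smallest keepX).  Components are added
#' while the mean BER improves, up to \code{max_ncomp}.
#'
#' @param X sample x feature matrix.
#' @param classes class labels.
#' @param keepX_grid candidate numbers of variables per component.
#' @param max_ncomp maximum components (default 4).
#' @param folds,repeats cross-validation design (default 5-fold x 10).
#' @param seed integer seed.
#' @param scale passed to \code{\link{splsda}}.
#' @return List with \code{ncomp}, \code{keepX}, and \code{ber_path}, the
#'   per-component grid of mean BERs.
#' @export
tune_splsda <- function(X, classes, keepX_grid = c(1, 5, 10, 25, 50, 70),
                        max_ncomp = 4L, folds = 5L, repeats = 10L,
                        seed = 1L, scale = TRUE) {
  X <- as.matrix(X); classes <- factor(classes)
  keepX_grid <- sort(unique(as.integer(keepX_grid)))
  keepX_grid <- keepX_grid[keepX_grid >= 1 & keepX_grid <= ncol(X)]
  if (!length(keepX_grid)) stop("empty keepX grid")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chosen <- integer(0)
  best_ber <- Inf
  ber_path <- list()
  for (h in seq_len(max_ncomp)) {
    grid_ber <- vapply(keepX_grid, function(k) {
      bers <- replicate(repeats, {
        fold_idx <- .stratified_folds(classes, folds)
        preds <- factor(rep(NA_character_, length(classes)),
                        levels = levels(classes))
        for (val in fold_idx) {
          if (!length(val)) next
          if (nlevels(droplevels(classes[-val])) < nlevels(classes)) {
            warning("training fold lost a class; fold skipped")
            next
          }
          fit <- splsda(X[-val, , drop = FALSE], classes[-val],
                        ncomp = h, keepX = c(chosen, k), scale = scale,
                        warn_zero_var = FALSE)
          preds[val] <- predict(fit, X[val, , drop = FALSE])
        }
        ok <- !is.na(preds)
        .ber(droplevels(classes[ok]), preds[ok])
      })
      mean(bers)
    }, 0)
    names(grid_ber) <- keepX_grid
    ber_path[[h]] <- grid_ber
    k_best <- keepX_grid[[which.min(grid_ber)]]
    if (min(grid_ber) < best_ber - 1e-12 || h == 1L) {
      chosen <- c(chosen, k_best)
      best_ber <- min(grid_ber)
    } else break
    if (best_ber <= 0) break  # perfect classification; nothing to improve
  }
  list(ncomp = length(chosen), keepX = chosen, ber_path = ber_path,
       ber = best_ber)
}

#' Evaluate sPLS-DA classification performance
#'
#' Repeated stratified 5-fold cross-validation at fixed sparsity: each
#' repeat partitions every class across the folds (20% of each class per
#' validation set), fits on the training folds and classifies the
#' validation fold; performance is the overall and per-class balanced error
#' rate (mean and sd over repeats), plus the selection frequency (stability)
#' of every variable on every component across all fold fits; variables with
#' stability above 0.9 are flagged.
#'
#' @param X sample x feature matrix.
#' @param classes class labels.
#' @param ncomp,keepX model sparsity (e.g. from \code{\link{tune_splsda}}).
#' @param folds,repeats cross-validation design (default 5-fold x 1000).
#' @param seed integer seed.
#' @param scale passed to \code{\link{splsda}}.
#' @return Object of class \code{splsda_cv}: \code{overall_ber} (mean, sd),
#'   \code{per_class_ber}, \code{stability} (feature x component matrix),
#'   \code{stable_variables}.
#' @export
evaluate_splsda <- function(X, classes, ncomp, keepX, folds = 5L,
                            repeats = 1000L, seed = 1L, scale = TRUE) {
  X <- as.matrix(X); classes <- factor(classes)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  K <- nlevels(classes)
  rep_ber <- numeric(repeats)
  rep_class <- matrix(NA_real_, repeats, K,
                      dimnames = list(NULL, levels(classes)))
  sel_count <- matrix(0, ncol(X), ncomp,
                      dimnames = list(colnames(X),
                                      paste0("comp", seq_len(ncomp))))
  n_fits <- 0L
  for (r in seq_len(repeats)) {
    fold_idx <- .stratified_folds(classes, folds)
    preds <- factor(rep(NA_character_, length(classes)),
                    levels = levels(classes))
    for (val in fold_idx) {
      if (!length(val)) next
      if (nlevels(droplevels(classes[-val])) < K) {
        warning("training fold lost a class; fold skipped")
        next
      }
      fit <- splsda(X[-val, , drop = FALSE], classes[-val], ncomp = ncomp,
                    keepX = keepX, scale = scale, warn_zero_var = FALSE)
      preds[val] <- predict(fit, X[val, , drop = FALSE])
      sel <- fit$x_loadings != 0
      sel_count[rownames(fit$x_loadings), seq_len(fit$ncomp)] <-
        sel_count[rownames(fit$x_loadings), seq_len(fit$ncomp)] + sel
      n_fits <- n_fits + 1L
    }
    ok <- !is.na(preds)
    for (cl in levels(classes)) {
      sel_cl <- classes == cl & ok
      if (any(sel_cl)) rep_class[r, cl] <- mean(preds[sel_cl] != cl)
    }
    rep_ber[[r]] <- mean(rep_class[r, ], na.rm = TRUE)
  }
  stability <- sel_count / n_fits
  stable <- lapply(seq_len(ncomp), function(h)
    rownames(stability)[stability[, h] > 0.9])
  names(stable) <- colnames(stability)
  structure(list(
    overall_ber = c(mean = mean(rep_ber), sd = stats::sd(rep_ber)),
    per_class_ber = rbind(mean = colMeans(rep_class, na.rm = TRUE),
                          sd = apply(rep_class, 2L, stats::sd, na.rm = TRUE)),
    stability = stability, stable_variables = stable,
    folds = folds, repeats = repeats, ncomp = ncomp, keepX = keepX),
    class = "splsda_cv")
}

#' @export
print.splsda_cv <- function(x, ...) {
  cat(sprintf(
    "sPLS-DA cross-validation: %d-fold x %d repeats, ncomp %d (keepX: %s)\n",
    x$folds, x$repeats, x$ncomp, paste(x$keepX, collapse = ", ")))
  cat(sprintf("Overall BER: %.2f (%.2f)\n",
              x$overall_ber[["mean"]], x$overall_ber[["sd"]]))
  cat("Per-class BER (mean, sd):\n")
  print(round(x$per_class_ber, 3))
  n_stable <- vapply(x$stable_variables, length, 1L)
  cat("Variables with stability > 0.9 per component: ",
      paste(n_stable, collapse = ", "), "\n", sep = "")
  invisible(x)
}
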