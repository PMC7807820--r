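# Per-taxon permutation analysis of variance over the combined design
# factor.  The model is a one-way cell-means fit on the 12 observed cells of
# farm x batch x antibiotic x feeding; management effects are zero-sum
# contrasts of unweighted cell means, tested with an F statistic whose null
# distribution is obtained by permuting the response over samples.

#' Combined design factor
#'
#' One factor whose levels are the observed cells of
#' farm x batch x antibiotic x feeding.
#'
#' @param meta validated metadata data.frame.
#' @return A factor of cell labels (\code{farm.batch.antibiotic.feeding}),
#'   one per sample, named by sample_id.
#' @export
combined_factor <- function(meta) {
  validate_metadata(meta)
  lab <- paste(meta$farm, meta$batch, meta$antibiotic, meta$feeding,
               sep = ".")
  stats::setNames(factor(lab), meta$sample_id)
}

#' Fit the one-way cell-means model
#'
#' Ordinary least squares on the combined factor: cell means are within-cell
#' sample means and the residual mean square is the pooled within-cell
#' variance.
#'
#' @param y numeric response, one value per sample.
#' @param cf combined factor from \code{\link{combined_factor}}.
#' @return An object of class \code{cell_means_fit}: \code{means},
#'   \code{n_g}, \code{mse}, \code{df_resid}, \code{cells}.
#' @export
fit_cell_means <- function(y, cf) {
  cf <- droplevels(as.factor(cf))
  if (length(y) != length(cf)) stop("y and cf lengths differ")
  n_g <- tabulate(cf)
  if (any(n_g == 0)) stop("empty design cell")
  n <- length(y)
  if (n - nlevels(cf) < 1) stop("no residual degrees of freedom")
  S <- rowsum(y, cf)
  means <- drop(S) / n_g
  sse <- sum(y^2) - sum(drop(S)^2 / n_g)
  structure(list(means = stats::setNames(means, levels(cf)),
                 n_g = stats::setNames(n_g, levels(cf)),
                 mse = max(sse, 0) / (n - nlevels(cf)),
                 df_resid = n - nlevels(cf),
                 cells = levels(cf)),
            class = "cell_means_fit")
}

#' @export
print.cell_means_fit <- function(x, ...) {
  cat(sprintf("Cell-means fit: %d cells, residual df %d, residual MS %.4g\n",
              length(x$means), x$df_resid, x$mse))
  print(round(rbind(mean = x$means, n = x$n_g), 3))
  invisible(x)
}

#' @export
coef.cell_means_fit <- function(object, ...) object$means

#' Construct a cell-means contrast
#'
#' @param name contrast label.
#' @param weights either a named numeric vector (1 df; names are cell
#'   labels, weights sum to zero with positive and negative parts summing to
#'   one in absolute value) or a numeric matrix with one such row per degree
#'   of freedom (rows need not be normalized).
#' @return Object of class \code{cell_contrast}.
#' @export
make_contrast <- function(name, weights) {
  if (is.matrix(weights)) {
    if (is.null(colnames(weights))) stop("contrast matrix needs cell names")
    if (any(abs(rowSums(weights)) > 1e-8))
      stop("contrast rows must sum to zero")
    df <- nrow(weights)
  } else {
    if (is.null(names(weights))) stop("contrast weights need cell names")
    if (abs(sum(weights)) > 1e-8) stop("contrast weights must sum to zero")
    if (abs(sum(weights[weights > 0]) - 1) > 1e-8 ||
        abs(sum(weights[weights < 0]) + 1) > 1e-8)
      stop("positive and negative parts must each sum to one")
    df <- 1L
  }
  structure(list(name = name, weights = weights, df = df),
            class = "cell_contrast")
}

# Align a contrast with the cells of a fit; error on unobserved cells.
.contrast_matrix <- function(contrast, cells) {
  w <- contrast$weights
  if (!is.matrix(w)) w <- matrix(w, nrow = 1L, dimnames = list(NULL, names(w)))
  touched <- colnames(w)[colSums(w != 0) > 0]
  missing <- setdiff(touched, cells)
  if (length(missing))
    stop("contrast '", contrast$name, "' touches unobserved cell(s): ",
         paste(missing, collapse = ", "))
  C <- matrix(0, nrow = nrow(w), ncol = length(cells),
              dimnames = list(NULL, cells))
  C[, colnames(w)[colnames(w) %in% cells]] <-
    w[, colnames(w) %in% cells, drop = FALSE]
  C
}

#' Contrast F statistic from a cell-means fit
#'
#' For a 1-df contrast \eqn{F = (\sum_g w_g m_g)^2 / (MSE \sum_g w_g^2/n_g)}
#' (the square of the pooled t statistic); multi-df contrasts use the
#' general linear hypothesis form.
#'
#' @param fit a \code{cell_means_fit}.
#' @param contrast a \code{cell_contrast}.
#' @return A list: \code{f}, \code{estimate} and \code{se} (1-df contrasts;
#'   \code{NA} otherwise), \code{df}.
#' @export
f_statistic <- function(fit, contrast) {
  C <- .contrast_matrix(contrast, fit$cells)
  est <- drop(C %*% fit$means)
  M <- C %*% (t(C) / fit$n_g)   # C diag(1/n_g) C'
  if (contrast$df == 1L) {
    denom <- fit$mse * drop(M)
    f <- if (denom > 0) est^2 / denom else if (abs(est) < 1e-12) 0 else Inf
    list(f = f, estimate = est, se = sqrt(max(denom, 0)),
         df = 1L)
  } else {
    q <- drop(t(est) %*% solve(M, est))
    denom <- contrast$df * fit$mse
    f <- if (denom > 0) q / denom else if (q < 1e-12) 0 else Inf
    list(f = f, estimate = NA_real_, se = NA_real_, df = contrast$df)
  }
}

#' Standard management contrasts for the study design
#'
#' Builds the reported comparisons as unweighted averages of cell means:
#' farm (A minus B), feeding regime within each farm and averaged over farms
#' (restricted minus ad libitum), and antibiotic within farm B (without
#' minus with).
#'
#' @param meta metadata defining the observed cells.
#' @return Named list of \code{cell_contrast} objects.
#' @export
standard_contrasts <- function(meta) {
  validate_metadata(meta)
  cells <- unique(data.frame(farm = meta$farm, batch = meta$batch,
                             antibiotic = meta$antibiotic,
                             feeding = meta$feeding,
                             stringsAsFactors = FALSE))
  lab <- paste(cells$farm, cells$batch, cells$antibiotic, cells$feeding,
               sep = ".")
  zero <- stats::setNames(numeric(length(lab)), lab)
  avg <- function(sel) {
    w <- zero
    if (!any(sel)) stop("contrast touches no observed cell")
    w[sel] <- 1 / sum(sel)
    w
  }
  diffc <- function(name, plus, minus)
    make_contrast(name, avg(plus) - avg(minus))
  out <- list(
    farm = diffc("farm", cells$farm == "A", cells$farm == "B"),
    feeding_within_A = diffc("feeding_within_A",
                             cells$farm == "A" & cells$feeding == "R",
                             cells$farm == "A" & cells$feeding == "AL"),
    feeding_within_B = diffc("feeding_within_B",
                             cells$farm == "B" & cells$feeding == "R",
                             cells$farm == "B" & cells$feeding == "AL"))
  out$feeding <- make_contrast("feeding",
    (out$feeding_within_A$weights + out$feeding_within_B$weights) / 2)
  if (any(cells$antibiotic == "without"))
    out$antibiotic_within_B <- diffc(
      "antibiotic_within_B",
      cells$farm == "B" & cells$antibiotic == "without",
      cells$farm == "B" & cells$antibiotic == "with")
  out
}

#' Feeding-by-farm interaction contrast
#'
#' The difference of within-farm feeding effects (difference of
#' differences); its significance decides whether feeding is reported
#' nested within farm or averaged over farms.
#'
#' @param meta metadata defining the observed cells.
#' @return A 1-df \code{cell_contrast}.
#' @export
interaction_contrast <- function(meta) {
  sc <- standard_contrasts(meta)
  w <- sc$feeding_within_A$weights - sc$feeding_within_B$weights
  structure(list(name = "feeding_x_farm", weights = w / 2, df = 1L),
            class = "cell_contrast")
}

#' Permutation test of a factor-by-factor interaction
#'
#' Tests equality of the feeding effect across farms by permuting the
#' response globally and recomputing the interaction F statistic.
#'
#' @param y numeric response.
#' @param meta metadata for the same samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with \code{f} and \code{p_emp}.
#' @export
interaction_test <- function(y, meta, n_perm = 1000L, seed = 1L) {
  cf <- combined_factor(meta)
  ic <- interaction_contrast(meta)
  fit <- fit_cell_means(y, cf)
  list(f = f_statistic(fit, ic)$f,
       p_emp = permutation_pvalue(y, cf, ic, n_perm = n_perm, seed = seed))
}

# Vectorized permutation machinery.  Cell means and residual mean squares
# of all permuted responses are computed once (one matrix product) and can
# then be scored against any number of contrasts.
.perm_moments <- function(y, cf, perm_idx) {
  cf <- droplevels(as.factor(cf))
  ind <- stats::model.matrix(~ cf - 1)
  n_g <- tabulate(cf)
  n <- length(y); G <- nlevels(cf)
  Pm <- matrix(y[perm_idx], nrow = n)        # one permuted y per column
  S <- crossprod(Pm, ind)                    # n_perm x G cell sums
  means <- sweep(S, 2L, n_g, "/")
  sse <- sum(y^2) - rowSums(sweep(S^2, 2L, n_g, "/"))
  list(means = means, mse = pmax(sse, 0) / (n - G), n_g = n_g)
}

.f_from_moments <- function(mom, C) {
  est <- mom$means %*% t(C)                  # n_perm x q
  M <- C %*% (t(C) / mom$n_g)
  if (nrow(C) == 1L) {
    denom <- mom$mse * drop(M)
    ifelse(denom > 0, drop(est)^2 / denom,
           ifelse(abs(drop(est)) < 1e-12, 0, Inf))
  } else {
    half <- chol(solve(M))
    qf <- rowSums((est %*% t(half))^2)
    denom <- nrow(C) * mom$mse
    ifelse(denom > 0, qf / denom, ifelse(qf < 1e-12, 0, Inf))
  }
}

.perm_f <- function(y, cf, C, perm_idx) {
  .f_from_moments(.perm_moments(y, cf, perm_idx), C)
}

# Deterministic 31-bit string hash (for taxon-keyed permutation streams).
.hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

# Draw a permutation index matrix (n x n_perm, one permutation per column)
# under a local seed.
.perm_indices <- function(n, n_perm, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
}

#' Empirical permutation p-value for a contrast F statistic
#'
#' Permutes the response over samples (globally, without replacement),
#' recomputes the contrast F statistic each round, and returns the
#' proportion of rounds with \eqn{F^* \ge F_{obs}}.  With
#' \code{add_one = TRUE} the add-one estimator
#' \eqn{(1 + \#)/(1 + n_{perm})} is returned instead.
#'
#' @param y numeric response.
#' @param cf combined factor.
#' @param contrast a \code{cell_contrast}.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param add_one use the add-one estimator.
#' @return p-value in [0, 1].
#' @export
permutation_pvalue <- function(y, cf, contrast, n_perm = 1000L, seed = 1L,
                               add_one = FALSE) {
  stopifnot(n_perm >= 1)
  cf <- droplevels(as.factor(cf))
  fit <- fit_cell_means(y, cf)
  C <- .contrast_matrix(contrast, fit$cells)
  f_obs <- f_statistic(fit, contrast)$f
  f_perm <- .perm_f(y, cf, C, .perm_indices(length(y), n_perm, seed))
  hits <- sum(f_perm >= f_obs - 1e-12)
  if (add_one) (1 + hits) / (1 + n_perm) else hits / n_perm
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone, capped at one),
#' delegated to \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-taxon permutation ANOVA over the combined design factor
#'
#' For every taxon (row of the normalized matrix) and every management
#' contrast: ordinary least squares estimate and standard error on the
#' cell-means model, contrast F statistic, empirical permutation p-value,
#' and Benjamini-Hochberg adjustment across taxa within each contrast.  A
#' feeding-by-farm interaction permutation test per taxon decides whether
#' the feeding comparison is reported nested within farm (interaction
#' significant at \code{alpha}) or averaged over farms.
#'
#' @param normalized a \code{css_table}, a percentage matrix from
#'   \code{\link{collapse_taxa}}, or any taxon x sample numeric matrix.
#' @param meta metadata covering every sample column.
#' @param n_perm permutations per test (default 1000).
#' @param alpha significance threshold for the FDR-adjusted p-values.
#' @param seed master seed; per-taxon permutation streams are derived from
#'   it up front so results do not depend on processing order.
#' @param contrasts named list of \code{cell_contrast}s (default
#'   \code{\link{standard_contrasts}}).
#' @param share_permutations reuse one permutation stream for all taxa
#'   (faster; default \code{FALSE} draws an independent stream per taxon).
#' @param add_one use add-one permutation p-values.
#' @return Object of class \code{diff_abundance}: a long results data.frame
#'   (\code{$table}) with one row per taxon x contrast plus the per-taxon
#'   interaction test (\code{$interaction}).
#' @export
run_differential_abundance <- function(normalized, meta, n_perm = 1000L,
                                       alpha = 0.05, seed = 1L,
                                       contrasts = NULL,
                                       share_permutations = FALSE,
                                       add_one = FALSE) {
  values <- if (is.list(normalized)) normalized$values else normalized
  validate_metadata(meta)
  if (is.null(colnames(values)) ||
      !all(colnames(values) %in% meta$sample_id))
    stop("sample columns do not align with metadata")
  meta <- meta[match(colnames(values), meta$sample_id), ]
  cf <- combined_factor(meta)
  if (is.null(contrasts)) contrasts <- standard_contrasts(meta)
  ic <- interaction_contrast(meta)
  n <- ncol(values); p <- nrow(values)
  taxa <- rownames(values)
  if (is.null(taxa)) taxa <- sprintf("row%04d", seq_len(p))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # streams keyed by (master seed, taxon name): independent of row order
  base_seed <- sample.int(.Machine$integer.max, 1L)
  taxon_seeds <- vapply(taxa, function(nm)
    as.integer((base_seed + .hash_string(nm)) %% 2147483647), 1L)

  cfd <- droplevels(as.factor(cf))
  cells <- levels(cfd)
  G <- length(cells)
  ind <- stats::model.matrix(~ cfd - 1)
  n_g <- tabulate(cfd)
  # geometry of every contrast is fixed across taxa; precompute it
  Cmats <- lapply(contrasts, .contrast_matrix, cells = cells)
  Cint <- .contrast_matrix(ic, cells)
  geom <- lapply(c(Cmats, list(.int = Cint)), function(C) {
    M <- C %*% (t(C) / n_g)
    list(C = C, m = if (nrow(C) == 1L) drop(M) else NA_real_,
         half = if (nrow(C) > 1L) chol(solve(M)) else NULL)
  })
  shared_idx <- if (share_permutations)
    .perm_indices(n, n_perm, taxon_seeds[[1L]]) else NULL

  K <- length(contrasts)
  cn <- names(contrasts)
  est_m <- se_m <- f_m <- pe_m <- matrix(NA_real_, p, K,
                                         dimnames = list(taxa, cn))
  inter <- data.frame(taxon = taxa, f = NA_real_, p_emp = NA_real_)
  p_hat <- function(hits) if (add_one) (1 + hits) / (1 + n_perm) else
    hits / n_perm
  f_obs_1df <- function(est, mse, m)
    if (mse * m > 0) est^2 / (mse * m) else if (abs(est) < 1e-12) 0 else Inf
  for (i in seq_len(p)) {
    y <- values[i, ]
    S <- drop(rowsum(y, cfd))
    means <- S / n_g
    mse <- max(sum(y^2) - sum(S^2 / n_g), 0) / (n - G)
    idx <- if (share_permutations) shared_idx else
      .perm_indices(n, n_perm, taxon_seeds[[i]])
    Pm <- matrix(y[idx], nrow = n)
    Sp <- crossprod(Pm, ind)
    means_p <- sweep(Sp, 2L, n_g, "/")
    mse_p <- pmax(sum(y^2) - rowSums(sweep(Sp^2, 2L, n_g, "/")), 0) /
      (n - G)
    mom <- list(means = means_p, mse = mse_p, n_g = n_g)
    for (k in seq_len(K)) {
      gk <- geom[[k]]
      if (nrow(gk$C) == 1L) {
        est <- drop(gk$C %*% means)
        f_obs <- f_obs_1df(est, mse, gk$m)
        est_m[i, k] <- est
        se_m[i, k] <- sqrt(mse * gk$m)
        fp <- ifelse(mse_p * gk$m > 0,
                     drop(mom$means %*% t(gk$C))^2 / (mse_p * gk$m), 0)
      } else {  # general linear hypothesis for multi-df contrasts
        lam <- drop(gk$C %*% means)
        qf <- sum((gk$half %*% lam)^2)
        denom <- nrow(gk$C) * mse
        f_obs <- if (denom > 0) qf / denom else if (qf < 1e-12) 0 else Inf
        fp <- .f_from_moments(mom, gk$C)
      }
      f_m[i, k] <- f_obs
      pe_m[i, k] <- p_hat(sum(fp >= f_obs - 1e-12))
    }
    gi <- geom[[".int"]]
    est_i <- drop(gi$C %*% means)
    f_int <- f_obs_1df(est_i, mse, gi$m)
    inter$f[[i]] <- f_int
    fp_i <- ifelse(mse_p * gi$m > 0,
                   drop(mom$means %*% t(gi$C))^2 / (mse_p * gi$m), 0)
    inter$p_emp[[i]] <- p_hat(sum(fp_i >= f_int - 1e-12))
  }
  tab <- data.frame(taxon = rep(taxa, each = K),
                    contrast = rep(cn, times = p),
                    estimate = as.vector(t(est_m)),
                    se = as.vector(t(se_m)),
                    f = as.vector(t(f_m)),
                    p_emp = as.vector(t(pe_m)),
                    stringsAsFactors = FALSE)
  tab$p_fdr <- NA_real_
  for (nm in unique(tab$contrast)) {
    sel <- tab$contrast == nm
    tab$p_fdr[sel] <- bh_fdr(tab$p_emp[sel])
  }
  tab$significant <- tab$p_fdr <= alpha
  # nested-versus-averaged feeding reporting, per taxon
  nested <- stats::setNames(inter$p_emp <= alpha, inter$taxon)
  tab$reported <- TRUE
  is_nested_row <- tab$contrast %in% c("feeding_within_A", "feeding_within_B")
  is_avg_row <- tab$contrast == "feeding"
  tab$reported[is_nested_row] <- nested[tab$taxon[is_nested_row]]
  tab$reported[is_avg_row] <- !nested[tab$taxon[is_avg_row]]
  rownames(tab) <- NULL
  structure(list(table = tab, interaction = inter, alpha = alpha,
                 n_perm = n_perm, seed = seed,
                 contrasts = names(contrasts)),
            class = "diff_abundance")
}

#' @export
print.diff_abundance <- function(x, ...) {
  cat(sprintf(
    "Permutation ANOVA differential abundance: %d taxa, %d permutations\n",
    length(unique(x$table$taxon)), x$n_perm))
  sig <- x$table[x$table$significant & x$table$reported, ]
  counts <- table(factor(sig$contrast, levels = x$contrasts))
  cat(sprintf("Significant at FDR %.2f (reported contrasts):\n", x$alpha))
  for (nm in names(counts))
    cat(sprintf("  %-22s %d\n", nm, counts[[nm]]))
  invisible(x)
}

#' @export
summary.diff_abundance <- function(object, contrast = NULL, ...) {
  tab <- object$table
  if (!is.null(contrast)) tab <- tab[tab$contrast %in% contrast, ]
  tab <- tab[order(tab$contrast, tab$p_fdr, tab$p_emp), ]
  rownames(tab) <- NULL
  tab
}
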