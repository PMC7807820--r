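# Alpha diversity on the rarefied table and its contrasts over the combined
# design factor.  Shannon uses natural-log units by default (the convention
# of the vegan/phyloseq route used for these indices).

#' Observed number of OTUs in a sample
#'
#' @param x numeric count vector for one sample.
#' @return Number of OTUs with a positive count.
#' @export
observed_otus <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  sum(x > 0)
}

#' Shannon diversity index of a sample
#'
#' \eqn{H = -\sum_i p_i \log p_i} over OTUs with positive counts, with
#' \eqn{p_i} the within-sample proportions.  Delegates to
#' \code{vegan::diversity}.
#'
#' @param x numeric count vector for one sample (positive total).
#' @param base logarithm base (default \code{exp(1)}, natural log).
#' @return Shannon index.
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  if (sum(x) <= 0) stop("sample total must be positive")
  unname(vegan::diversity(x, index = "shannon", base = base))
}

#' Alpha diversity table
#'
#' Computes observed OTUs and the Shannon index for every sample of a
#' (typically rarefied) count table.
#'
#' @param counts OTU x sample count matrix.
#' @param base logarithm base for Shannon.
#' @return data.frame with columns \code{sample_id}, \code{observed_otus},
#'   \code{shannon}.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  validate_count_table(counts)
  data.frame(sample_id = colnames(counts),
             observed_otus = apply(counts, 2L, observed_otus),
             shannon = apply(counts, 2L, shannon_index, base = base),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group contrasts on alpha diversity indices
#'
#' Fits the one-way cell-means model on the combined design factor to each
#' index and tests the management contrasts with classical (theoretical
#' null) F tests; p-values are Benjamini-Hochberg adjusted across the
#' contrast family within each index.
#'
#' @param div alpha diversity data.frame from \code{\link{alpha_diversity}}.
#' @param meta metadata covering every sample.
#' @param contrasts named list of \code{cell_contrast}s (default
#'   \code{\link{standard_contrasts}}).
#' @param alpha significance threshold on the adjusted p-values.
#' @return data.frame with one row per index x contrast: estimate, se, f,
#'   p, p_fdr, significant.
#' @export
alpha_contrasts <- function(div, meta, contrasts = NULL, alpha = 0.05) {
  validate_metadata(meta)
  if (!all(div$sample_id %in% meta$sample_id))
    stop("metadata is missing sample(s) present in the diversity table")
  meta <- meta[match(div$sample_id, meta$sample_id), ]
  cf <- combined_factor(meta)
  if (is.null(contrasts)) contrasts <- standard_contrasts(meta)
  out <- list()
  for (index in c("observed_otus", "shannon")) {
    fit <- fit_cell_means(div[[index]], cf)
    rows <- lapply(names(contrasts), function(nm) {
      fs <- f_statistic(fit, contrasts[[nm]])
      p <- stats::pf(fs$f, fs$df, fit$df_resid, lower.tail = FALSE)
      data.frame(index = index, contrast = nm, estimate = fs$estimate,
                 se = fs$se, f = fs$f, p = p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- bh_fdr(tab$p)
    out[[index]] <- tab
  }
  res <- do.call(rbind, out)
  res$significant <- res$p_fdr <= alpha
  rownames(res) <- NULL
  res
}
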