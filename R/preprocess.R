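# Filtering, normalization and summarization of OTU count tables:
# low-depth sample removal, doubleton removal, the joint prevalence/abundance
# filter, cumulative sum scaling (CSS), rarefaction, taxonomy collapse to
# percentage tables, and average daily gain from weekly weights.

#' Drop samples with low sequencing depth
#'
#' Removes samples whose total count is strictly below \code{min_depth}
#' (the study discarded samples with fewer than 5000 final sequences).
#'
#' @param counts OTU x sample count matrix.
#' @param min_depth minimum total count a sample must reach to be kept.
#' @return The count matrix restricted to retained samples.
#' @export
remove_low_depth_samples <- function(counts, min_depth = 5000) {
  validate_count_table(counts)
  stopifnot(min_depth >= 0)
  keep <- colSums(counts) >= min_depth
  if (!any(keep)) stop("all samples fall below min_depth")
  counts[, keep, drop = FALSE]
}

#' Remove doubleton (and rarer) OTUs
#'
#' Drops OTUs whose total count across all samples is at most
#' \code{max_total} (default 2: doubletons and singletons).
#'
#' @param counts OTU x sample count matrix.
#' @param max_total largest total count that is still removed.
#' @return The count matrix restricted to retained OTUs.
#' @export
remove_doubletons <- function(counts, max_total = 2) {
  validate_count_table(counts)
  counts[rowSums(counts) > max_total, , drop = FALSE]
}

#' Joint prevalence and abundance filter
#'
#' Keeps OTUs detected in at least \code{min_prevalence} of the samples
#' (inclusive, on the ceiling of the sample count) AND whose total count
#' exceeds \code{min_total_fraction} of the grand total (strict), the
#' two-part rule applied before the per-taxon analyses.
#'
#' @param counts OTU x sample count matrix.
#' @param min_prevalence minimum fraction of samples with a nonzero count.
#' @param min_total_fraction minimum fraction of the grand total (strict).
#' @return The filtered count matrix.
#' @export
prevalence_abundance_filter <- function(counts, min_prevalence = 0.05,
                                        min_total_fraction = 1e-4) {
  validate_count_table(counts)
  stopifnot(min_prevalence > 0, min_prevalence < 1,
            min_total_fraction > 0, min_total_fraction < 1)
  n <- ncol(counts)
  prev_ok <- rowSums(counts > 0) >= ceiling(min_prevalence * n)
  abund_ok <- rowSums(counts) > min_total_fraction * sum(counts)
  counts[prev_ok & abund_ok, , drop = FALSE]
}

# Per-sample quantiles of the nonzero count distribution at probabilities p.
.nonzero_quantiles <- function(counts, p) {
  apply(counts, 2L, function(x) stats::quantile(x[x > 0], probs = p,
                                                names = FALSE, type = 7))
}

#' Choose the CSS quantile adaptively
#'
#' Scans quantile levels of the per-sample nonzero-count distributions and
#' returns the smallest level at which the median absolute deviation of the
#' sample quantiles around the across-sample reference (the median) changes
#' by at least \code{rel_threshold} relative to the next level, floored at
#' 0.5.  This is the instability criterion of the cumulative-sum-scaling
#' method.
#'
#' @param counts OTU x sample count matrix.
#' @param rel_threshold relative-change threshold (default 0.1).
#' @param grid_size number of quantile levels scanned.
#' @return A quantile level in [0.5, 1).
#' @export
css_quantile <- function(counts, rel_threshold = 0.1, grid_size = 100L) {
  probs <- seq_len(grid_size - 1L) / grid_size
  qs <- .nonzero_quantiles(counts, probs)           # levels x samples
  ref <- apply(qs, 1L, stats::median)
  devs <- apply(abs(qs - ref), 1L, stats::median)   # MAD around reference
  rel <- abs(diff(devs)) / devs[-1L]
  rel[!is.finite(rel)] <- 0
  hit <- which(rel >= rel_threshold)
  if (!length(hit)) {
    warning("CSS instability criterion never met; falling back to quantile 0.5")
    return(0.5)
  }
  max(probs[hit[[1L]]], 0.5)
}

#' Cumulative sum scaling normalization
#'
#' Scales each sample by its cumulative count up to a quantile of its
#' nonzero-count distribution: \eqn{s_j} is the sum of the counts in sample
#' \eqn{j} that are at most the chosen quantile of sample \eqn{j}'s nonzero
#' counts, and normalized values are \code{counts / s_j * scale_constant}.
#' When \code{quantile} is omitted it is chosen by \code{\link{css_quantile}}.
#'
#' @param counts OTU x sample count matrix; every sample needs a nonzero
#'   count.
#' @param quantile quantile level in (0,1), or \code{NULL} for adaptive
#'   selection.
#' @param scale_constant rescaling constant applied after division.
#' @return A list of class \code{css_table}: \code{values} (normalized
#'   matrix), \code{scaling_factors}, \code{quantile_used},
#'   \code{scale_constant}.
#' @export
css_normalize <- function(counts, quantile = NULL, scale_constant = 1000) {
  validate_count_table(counts)
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  stopifnot(scale_constant > 0)
  q <- if (is.null(quantile)) css_quantile(counts) else quantile
  stopifnot(q > 0, q < 1)
  qv <- .nonzero_quantiles(counts, q)
  s <- vapply(seq_len(ncol(counts)),
              function(j) sum(counts[counts[, j] <= qv[[j]], j]), 0)
  if (any(s <= 0)) stop("non-positive CSS scaling factor")
  values <- sweep(counts, 2L, s, "/") * scale_constant
  structure(list(values = values,
                 scaling_factors = stats::setNames(s, colnames(counts)),
                 quantile_used = q, scale_constant = scale_constant),
            class = "css_table")
}

#' @export
print.css_table <- function(x, ...) {
  cat(sprintf("CSS-normalized table: %d OTUs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  quantile %.2f, scale constant %g, scaling factors %g-%g\n",
              x$quantile_used, x$scale_constant,
              min(x$scaling_factors), max(x$scaling_factors)))
  invisible(x)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample without replacement to exactly \code{depth}
#' sequences (multivariate hypergeometric); samples whose total is below the
#' depth are dropped with a message.  Delegates the draw to
#' \code{vegan::rrarefy}.
#'
#' @param counts OTU x sample count matrix.
#' @param depth target depth per sample.
#' @param seed integer seed.
#' @return Rarefied count matrix (every column sums to \code{depth}).
#' @export
rarefy <- function(counts, depth = 10000, seed = 1L) {
  validate_count_table(counts)
  stopifnot(depth >= 1)
  totals <- colSums(counts)
  drop <- totals < depth
  if (all(drop)) stop("all samples fall below the rarefaction depth")
  if (any(drop))
    message("rarefy: dropping ", sum(drop), " sample(s) below depth ", depth)
  kept <- counts[, !drop, drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # vegan warns whenever the smallest nonzero count exceeds one; that is
  # expected for these tables, so the advisory is muffled
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(kept), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(kept)
  out
}

#' Collapse a normalized table to relative abundances at a taxonomic rank
#'
#' Sums CSS-normalized values within each taxon at the requested rank, pools
#' OTUs unassigned at that rank into an \code{"unclassified"} bucket, and
#' rescales each sample to percentages.
#'
#' @param normalized a \code{css_table} (or any list with a \code{values}
#'   matrix) or a bare numeric matrix.
#' @param taxonomy taxonomy data.frame covering every OTU in the table.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @param include_unclassified keep the pooled unassigned bucket (default
#'   TRUE; percentages sum to 100 only when it is kept).
#' @return A taxon x sample matrix of percentages.
#' @export
collapse_taxa <- function(normalized, taxonomy, rank = "phylum",
                          include_unclassified = TRUE) {
  values <- if (is.list(normalized)) normalized$values else normalized
  rank <- match.arg(rank, TAX_RANKS)
  idx <- match(rownames(values), taxonomy$otu_id)
  if (anyNA(idx))
    stop("taxonomy is missing OTU(s): ",
         paste(utils::head(rownames(values)[is.na(idx)], 3), collapse = ", "))
  label <- taxonomy[[rank]][idx]
  label[is.na(label)] <- "unclassified"
  agg <- rowsum(values, group = label)
  agg <- sweep(agg, 2L, colSums(agg), "/") * 100
  if (!include_unclassified)
    agg <- agg[rownames(agg) != "unclassified", , drop = FALSE]
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Average daily gain from weekly body weights
#'
#' The within-animal ordinary least squares slope of body weight on age,
#' in g/day.
#'
#' @param age_days integer ages (at least two distinct values).
#' @param body_weight_g body weights in grams.
#' @return The OLS slope.
#' @export
compute_adg <- function(age_days, body_weight_g) {
  ok <- !is.na(age_days) & !is.na(body_weight_g)
  age_days <- age_days[ok]; body_weight_g <- body_weight_g[ok]
  if (length(unique(age_days)) < 2)
    stop("need at least two distinct ages to fit a growth slope")
  unname(stats::coef(stats::lm(body_weight_g ~ age_days))[["age_days"]])
}

#' Average daily gain for every animal in a metadata table
#'
#' @param meta metadata with \code{bw_<age>} columns (see
#'   \code{\link{generate_weights}}).
#' @return Named numeric vector of ADG (g/day) keyed by sample_id.
#' @export
adg_by_sample <- function(meta) {
  bw_cols <- grep("^bw_[0-9]+$", names(meta), value = TRUE)
  if (length(bw_cols) < 2) stop("metadata has fewer than two bw_<age> columns")
  ages <- as.numeric(sub("^bw_", "", bw_cols))
  adg <- vapply(seq_len(nrow(meta)), function(i)
    compute_adg(ages, as.numeric(meta[i, bw_cols])), 0, USE.NAMES = FALSE)
  stats::setNames(adg, meta$sample_id)
}
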