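# Synthetic OTU tables with the statistical structure the downstream
# analysis assumes: the 12-cell management design, log-normal library sizes
# truncated at the study minimum, a heavy-tailed base composition, and
# Dirichlet-multinomial counts with planted multiplicative group effects.

EFFECT_FACTORS <- c("farm", "feeding_within_A", "feeding_within_B",
                    "antibiotic_within_B")

#' Specify planted differential-abundance effects
#'
#' One row per (OTU, factor) pair.  The log2 fold change multiplies the
#' expected relative abundance of the OTU in the factor's first-named level:
#' \code{farm} scales farm A samples (A vs B), \code{feeding_within_A} and
#' \code{feeding_within_B} scale AL samples within the farm, and
#' \code{antibiotic_within_B} scales antibiotic-free samples within farm B.
#'
#' @param otu_id character vector of OTU identifiers.
#' @param factor one of \code{"farm"}, \code{"feeding_within_A"},
#'   \code{"feeding_within_B"}, \code{"antibiotic_within_B"} (recycled).
#' @param log2_fold_change finite numeric fold changes on the log2 scale.
#' @return data.frame with columns \code{otu_id}, \code{factor},
#'   \code{log2_fold_change}.
#' @export
effect_spec <- function(otu_id, factor, log2_fold_change) {
  spec <- data.frame(otu_id = as.character(otu_id),
                     factor = as.character(factor),
                     log2_fold_change = as.numeric(log2_fold_change),
                     stringsAsFactors = FALSE)
  bad <- setdiff(unique(spec$factor), EFFECT_FACTORS)
  if (length(bad))
    stop("unknown effect factor(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(spec$log2_fold_change)))
    stop("log2_fold_change must be finite")
  if (anyDuplicated(spec[c("otu_id", "factor")]))
    stop("one effect per (otu, factor) pair")
  spec
}

#' Simulation parameters for the synthetic OTU table generator
#'
#' Defaults emulate the study scale: 963 OTUs over the 425-animal design,
#' library sizes log-normal with median ~20,000 reads truncated below at the
#' study minimum of 10,157, a heavy-tailed log-normal base composition, and
#' moderate Dirichlet-multinomial overdispersion (concentration 200).
#'
#' @param n_otus number of OTUs.
#' @param design metadata data.frame (default \code{\link{design_fixture}()}).
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @param min_depth truncation floor for library sizes (reads).
#' @param base_meanlog,base_sdlog log-normal base-abundance parameters over
#'   OTUs (only relative values matter; composition is renormalized).
#' @param base_abundance optional explicit base composition (positive vector
#'   of length \code{n_otus}, renormalized); overrides the log-normal draw.
#' @param concentration Dirichlet concentration scalar; larger is closer to
#'   plain multinomial sampling.
#' @param effects effect data.frame from \code{\link{effect_spec}}, or
#'   \code{NULL} for the null model.
#' @param seed integer seed governing every draw.
#' @return A validated parameter list of class \code{sim_params}.
#' @export
sim_params <- function(n_otus = 963L, design = design_fixture(),
                       lib_meanlog = log(20000), lib_sdlog = 1,
                       min_depth = 10157L,
                       base_meanlog = 0, base_sdlog = 2,
                       base_abundance = NULL,
                       concentration = 200,
                       effects = NULL, seed = 1L) {
  stopifnot(n_otus >= 1, lib_sdlog > 0, base_sdlog >= 0,
            concentration > 0, min_depth >= 1)
  if (!is.null(base_abundance)) {
    stopifnot(length(base_abundance) == n_otus, all(base_abundance > 0))
    base_abundance <- base_abundance / sum(base_abundance)
  }
  validate_metadata(design)
  if (!is.null(effects))
    effects <- effect_spec(effects$otu_id, effects$factor,
                           effects$log2_fold_change)
  structure(list(n_otus = as.integer(n_otus), design = design,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
                 min_depth = as.integer(min_depth),
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 base_abundance = base_abundance,
                 concentration = concentration, effects = effects,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a nested synthetic taxonomy
#'
#' Assigns every OTU a phylum and, for a stated fraction, a genus nested
#' consistently within its phylum.  Defaults mirror the taxonomic breadth of
#' the real tables: 8 phyla and 28 genera.
#'
#' @param n_otus number of OTUs.
#' @param n_phyla,n_genera number of distinct phylum / genus names.
#' @param frac_genus_unassigned fraction of OTUs left unassigned at genus
#'   level (and below).
#' @param seed integer seed.
#' @return Taxonomy data.frame (see \code{\link{read_taxonomy}}).
#' @export
generate_taxonomy <- function(n_otus, n_phyla = 8L, n_genera = 28L,
                              frac_genus_unassigned = 0.15, seed = 1L) {
  if (n_phyla < 1 || n_genera < n_phyla)
    stop("need n_genera >= n_phyla >= 1")
  if (n_otus < n_genera)
    stop("need n_otus >= n_genera so every genus can be observed")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  phyla <- sprintf("Phylum%02d", seq_len(n_phyla))
  # nest genera within phyla: each genus belongs to one phylum
  genus_phylum <- sort(c(seq_len(n_phyla),
                         sample(n_phyla, n_genera - n_phyla, replace = TRUE)))
  genera <- sprintf("Genus%02d", seq_len(n_genera))
  # guarantee every genus (hence every phylum) appears at least once
  g_idx <- c(seq_len(n_genera),
             sample(n_genera, n_otus - n_genera, replace = TRUE))
  g_idx <- sample(g_idx)  # shuffle so coverage is not positional
  unassigned <- runif(n_otus) < frac_genus_unassigned
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  tax <- data.frame(otu_id = otu_ids,
                    kingdom = "Bacteria",
                    phylum = phyla[genus_phylum[g_idx]],
                    class = sprintf("Class%02d", genus_phylum[g_idx]),
                    order = sprintf("Order%02d", genus_phylum[g_idx]),
                    family = sprintf("Family%02d", g_idx),
                    genus = genera[g_idx],
                    species = NA_character_,
                    stringsAsFactors = FALSE)
  tax[unassigned, c("family", "genus")] <- NA_character_
  validate_taxonomy(tax)
  tax
}

#' Balanced two-farm benchmark design
#'
#' A minimal two-class design for classifier benchmarking: equal numbers of
#' farm A (batch 1) and farm B (batch 5) samples, all on the same
#' antibiotic-supplemented ad libitum regime, so farm is the only varying
#' factor.
#'
#' @param n_per_class samples per farm (default 60).
#' @return A metadata data.frame with \code{2 * n_per_class} rows.
#' @export
two_class_design <- function(n_per_class = 60L) {
  n <- 2L * n_per_class
  meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     farm = rep(c("A", "B"), each = n_per_class),
                     batch = rep(c("1", "5"), each = n_per_class),
                     antibiotic = "with", feeding = "AL",
                     stringsAsFactors = FALSE)
  validate_metadata(meta)
  meta
}

# Which samples an effect factor scales (the factor's first-named level).
effect_applies <- function(factor, design) {
  switch(factor,
         farm = design$farm == "A",
         feeding_within_A = design$farm == "A" & design$feeding == "AL",
         feeding_within_B = design$farm == "B" & design$feeding == "AL",
         antibiotic_within_B = design$farm == "B" &
           design$antibiotic == "without",
         stop("unknown effect factor: ", factor))
}

#' Generate a synthetic OTU count table
#'
#' For each sample: draw a truncated log-normal library size, scale the base
#' composition by \code{2^log2_fold_change} for every planted effect that
#' applies to the sample's design cell, renormalize, and draw a
#' Dirichlet-multinomial count vector.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return A list with \code{counts} (integer OTU x sample matrix),
#'   \code{taxonomy} = \code{NULL} (generate separately), and
#'   \code{effects}, the effect table actually applied (ground truth).
#' @export
generate_counts <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  design <- params$design
  n <- nrow(design)
  p <- params$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(p))
  base <- if (!is.null(params$base_abundance)) params$base_abundance else
    stats::rlnorm(p, params$base_meanlog, params$base_sdlog)
  base <- base / sum(base)
  # library sizes: log-normal truncated below at min_depth (resampling)
  libs <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- round(stats::rlnorm(length(todo), params$lib_meanlog,
                                params$lib_sdlog))
    ok <- draw >= params$min_depth
    libs[todo[ok]] <- as.integer(draw[ok])
    todo <- todo[!ok]
  }
  # per-cell expected composition
  lfc <- matrix(0, nrow = p, ncol = n, dimnames = list(otu_ids, NULL))
  eff <- params$effects
  if (!is.null(eff) && nrow(eff)) {
    miss <- setdiff(eff$otu_id, otu_ids)
    if (length(miss)) stop("effects reference unknown OTUs: ",
                           paste(miss, collapse = ", "))
    for (k in seq_len(nrow(eff))) {
      applies <- effect_applies(eff$factor[[k]], design)
      lfc[eff$otu_id[[k]], applies] <-
        lfc[eff$otu_id[[k]], applies] + eff$log2_fold_change[[k]]
    }
  }
  counts <- matrix(0L, nrow = p, ncol = n,
                   dimnames = list(otu_ids, design$sample_id))
  for (j in seq_len(n)) {
    prob <- base * 2^lfc[, j]
    prob <- prob / sum(prob)
    alpha <- params$concentration * prob
    g <- stats::rgamma(p, shape = alpha, rate = 1)
    if (all(g == 0)) g[which.max(prob)] <- 1  # degenerate underflow guard
    counts[, j] <- stats::rmultinom(1L, size = libs[[j]], prob = g / sum(g))
  }
  list(counts = counts,
       effects = if (is.null(eff)) effect_spec(character(), character(),
                                               numeric()) else eff,
       library_sizes = stats::setNames(libs, design$sample_id))
}

#' Generate weekly body weights and attach them to metadata
#'
#' Body weight grows linearly within animal: weight = intercept + ADG x age
#' plus Gaussian noise, recorded at the stated ages.  The intercept places
#' each animal at ~700 g at weaning (32 days).
#'
#' @param design metadata data.frame.
#' @param base_adg_by_cell named numeric vector of average daily gains
#'   (g/day) keyed by \code{farm.feeding} (e.g. \code{"A.AL"}), or a single
#'   number used for all cells.
#' @param noise_sd standard deviation of the weighing error (g).
#' @param ages ages in days at weighing; strictly increasing.
#' @param weaning_weight body weight at 32 days used for the intercept (g).
#' @param seed integer seed.
#' @return \code{design} with added numeric columns \code{bw_<age>}.
#' @export
generate_weights <- function(design, base_adg_by_cell = 45, noise_sd = 10,
                             ages = c(32L, 39L, 46L, 53L, 60L),
                             weaning_weight = 700, seed = 1L) {
  validate_metadata(design)
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  key <- paste(design$farm, design$feeding, sep = ".")
  if (length(base_adg_by_cell) == 1L && is.null(names(base_adg_by_cell))) {
    adg <- rep(as.numeric(base_adg_by_cell), nrow(design))
  } else {
    if (!all(key %in% names(base_adg_by_cell)))
      stop("base_adg_by_cell must name every farm.feeding combination")
    adg <- as.numeric(base_adg_by_cell[key])
  }
  for (i in seq_along(ages)) {
    mu <- weaning_weight + adg * (ages[[i]] - ages[[1L]])
    design[[paste0("bw_", ages[[i]])]] <-
      mu + stats::rnorm(nrow(design), 0, noise_sd)
  }
  design
}

# RNG bookkeeping: generators restore the caller's random stream so that
# seeded synthesis does not perturb surrounding simulations.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
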