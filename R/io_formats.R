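# Containers --------------------------------------------------------------
#
# A count table is an integer matrix, OTUs as rows, samples as columns, with
# unique dimnames.  Metadata is a data.frame keyed by sample_id.  Taxonomy is
# a data.frame with one row per OTU and one column per rank.  Plain base
# containers are used throughout (as in vegan) so objects compose with
# standard matrix/data.frame tooling.

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
TAX_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__",
                  species = "s__")

FARM_LEVELS <- c("A", "B")
BATCH_LEVELS <- as.character(1:5)
ANTIBIOTIC_LEVELS <- c("with", "without")
FEEDING_LEVELS <- c("AL", "R")

#' Validate an OTU count table
#'
#' Checks the container invariants: a numeric matrix of non-negative integral
#' counts with unique, non-missing OTU row names and sample column names.
#'
#' @param counts matrix to validate.
#' @return The matrix, invisibly, with storage mode coerced to integer-valued
#'   numeric.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count table must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must carry OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU identifiers in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count table")
  if (anyNA(counts) || any(counts < 0))
    stop("count table contains missing or negative values")
  if (any(counts != round(counts)))
    stop("count table contains non-integral values")
  invisible(counts)
}

#' Read a QIIME classic OTU table
#'
#' Parses the tab-separated "classic" OTU table dialect: a header line whose
#' first cell is \code{#OTU ID}, one row per OTU, integer counts, and an
#' optional trailing \code{taxonomy} column holding Greengenes-style lineage
#' strings.
#'
#' @param path path to a tab-separated OTU table.
#' @return A list with elements \code{counts} (integer matrix, OTUs x
#'   samples) and \code{taxonomy} (a taxonomy data.frame, or \code{NULL} when
#'   the file has no taxonomy column).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^# Constructed", lines)]
  if (!length(lines)) stop("empty OTU table: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (header[[1]] != "#OTU ID")
    stop("not a classic OTU table (first header cell must be '#OTU ID')")
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  sample_ids <- header[-1]
  if (has_tax) sample_ids <- sample_ids[-length(sample_ids)]
  if (!length(sample_ids)) stop("OTU table has no sample columns")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_expect <- length(header)
  if (any(vapply(body, length, 1L) != ncol_expect))
    stop("ragged OTU table: row lengths differ from header")
  otu_ids <- vapply(body, `[[`, "", 1L)
  cells <- vapply(body, function(x) x[2:(1 + length(sample_ids))],
                  character(length(sample_ids)))
  cells <- matrix(suppressWarnings(as.numeric(cells)),
                  nrow = length(sample_ids))
  if (anyNA(cells)) stop("non-numeric count cell in OTU table")
  counts <- t(cells)
  dimnames(counts) <- list(otu_ids, sample_ids)
  validate_count_table(counts)
  storage.mode(counts) <- "integer"
  taxonomy <- NULL
  if (has_tax) {
    lineages <- vapply(body, function(x) x[[ncol_expect]], "")
    taxonomy <- parse_lineages(otu_ids, lineages)
  }
  list(counts = counts, taxonomy = taxonomy)
}

#' Write a QIIME classic OTU table
#'
#' @param counts integer OTU x sample matrix.
#' @param path output path.
#' @param taxonomy optional taxonomy data.frame; when supplied, written as a
#'   trailing \code{taxonomy} column of lineage strings.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(counts, path, taxonomy = NULL) {
  validate_count_table(counts)
  header <- c("#OTU ID", colnames(counts))
  rows <- apply(counts, 1L, function(x) paste(format(x, scientific = FALSE,
                                                     trim = TRUE),
                                              collapse = "\t"))
  rows <- paste(rownames(counts), rows, sep = "\t")
  if (!is.null(taxonomy)) {
    lin <- format_lineages(taxonomy)
    idx <- match(rownames(counts), taxonomy$otu_id)
    if (anyNA(idx)) stop("taxonomy is missing OTUs present in the table")
    header <- c(header, "taxonomy")
    rows <- paste(rows, lin[idx], sep = "\t")
  }
  writeLines(c(paste(header, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

# Metadata ----------------------------------------------------------------

#' Validate sample metadata
#'
#' Enforces the study-design invariants: known factor levels, batches 1-4 in
#' farm A and batch 5 in farm B, and antibiotic-supplemented feed for every
#' farm A animal.
#'
#' @param meta data.frame with columns \code{sample_id}, \code{farm},
#'   \code{batch}, \code{antibiotic}, \code{feeding}.
#' @return \code{meta}, invisibly, with factor columns normalized to
#'   character.
#' @export
validate_metadata <- function(meta) {
  req <- c("sample_id", "farm", "batch", "antibiotic", "feeding")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$farm <- as.character(meta$farm)
  meta$batch <- as.character(meta$batch)
  meta$antibiotic <- as.character(meta$antibiotic)
  meta$feeding <- as.character(meta$feeding)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x), levels)
    if (length(bad))
      stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "))
  }
  check_levels(meta$farm, FARM_LEVELS, "farm")
  check_levels(meta$batch, BATCH_LEVELS, "batch")
  check_levels(meta$antibiotic, ANTIBIOTIC_LEVELS, "antibiotic")
  check_levels(meta$feeding, FEEDING_LEVELS, "feeding")
  farm_from_batch <- ifelse(meta$batch == "5", "B", "A")
  if (any(farm_from_batch != meta$farm))
    stop("batch/farm inconsistency: batches 1-4 belong to farm A, batch 5 to farm B")
  if (any(meta$farm == "A" & meta$antibiotic != "with"))
    stop("farm A animals all received antibiotic-supplemented feed")
  invisible(meta)
}

#' Read sample metadata
#'
#' Reads a tab-separated metadata table with columns \code{sample_id},
#' \code{farm}, \code{batch}, \code{antibiotic}, \code{feeding} and optional
#' weekly body-weight columns named \code{bw_<age_days>}.
#'
#' @param path path to a metadata TSV.
#' @return A data.frame of validated metadata; body-weight columns, when
#'   present, are kept as numeric \code{bw_<age>} columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE)
  validate_metadata(meta)
  for (cn in grep("^bw_[0-9]+$", names(meta), value = TRUE))
    meta[[cn]] <- as.numeric(meta[[cn]])
  meta$farm <- as.character(meta$farm)
  meta$batch <- as.character(meta$batch)
  meta
}

#' Write sample metadata
#'
#' @param meta validated metadata data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Taxonomy ----------------------------------------------------------------

parse_lineages <- function(otu_ids, lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  tax <- matrix(NA_character_, nrow = length(otu_ids),
                ncol = length(TAX_RANKS),
                dimnames = list(NULL, TAX_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    if (length(p) > length(TAX_RANKS))
      stop("lineage has more than ", length(TAX_RANKS), " ranks: ",
           lineages[[i]])
    for (j in seq_along(p)) {
      pref <- TAX_PREFIXES[[j]]
      if (substr(p[[j]], 1, 3) != pref)
        stop("malformed lineage (expected prefix '", pref, "'): ",
             lineages[[i]])
      name <- substring(p[[j]], 4)
      tax[i, j] <- if (nzchar(name)) name else NA_character_
    }
  }
  tax_df <- data.frame(otu_id = otu_ids, tax, stringsAsFactors = FALSE)
  validate_taxonomy(tax_df)
  tax_df
}

format_lineages <- function(taxonomy) {
  vapply(seq_len(nrow(taxonomy)), function(i) {
    paste0(TAX_PREFIXES,
           ifelse(is.na(unlist(taxonomy[i, TAX_RANKS])), "",
                  unlist(taxonomy[i, TAX_RANKS])),
           collapse = "; ")
  }, "")
}

#' Validate a taxonomy map
#'
#' Checks hierarchical consistency: an assigned rank may not follow an
#' unassigned one (an OTU with unknown phylum cannot have a known genus).
#'
#' @param taxonomy data.frame with columns \code{otu_id} and the seven ranks
#'   kingdom..species; \code{NA} marks an unassigned rank.
#' @return \code{taxonomy}, invisibly.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (!all(c("otu_id", TAX_RANKS) %in% names(taxonomy)))
    stop("taxonomy must have columns otu_id and ", paste(TAX_RANKS, collapse = ", "))
  if (anyDuplicated(taxonomy$otu_id)) stop("duplicate otu_id in taxonomy")
  assigned <- !is.na(as.matrix(taxonomy[, TAX_RANKS]))
  # after the first unassigned rank everything deeper must be unassigned
  ok <- apply(assigned, 1L, function(a) all(diff(a) <= 0) || all(a))
  if (!all(ok))
    stop("non-hierarchical taxonomy: assigned rank follows an unassigned one")
  invisible(taxonomy)
}

#' Read a taxonomy map
#'
#' Two tab-separated columns: OTU identifier and a Greengenes-style lineage
#' string (\code{k__Bacteria; p__Firmicutes; ...}); an empty name after a
#' rank prefix marks the rank unassigned.
#'
#' @param path path to a taxonomy TSV (no header).
#' @return Taxonomy data.frame with columns \code{otu_id}, kingdom..species.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("otu_id", "lineage"))
  parse_lineages(raw$otu_id, raw$lineage)
}

#' Write a taxonomy map
#'
#' @param taxonomy taxonomy data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  validate_taxonomy(taxonomy)
  writeLines(paste(taxonomy$otu_id, format_lineages(taxonomy), sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

# Design fixture ----------------------------------------------------------

#' The 425-animal study design
#'
#' Returns the per-animal metadata of the study design: 336 rabbits raised in
#' farm A over batches 1-4 (all on antibiotic-supplemented feed) and 89 in
#' farm B, batch 5, of which 23 received antibiotic-free feed; within every
#' farm/batch/antibiotic cell animals were split between ad libitum (AL) and
#' restricted (R) feeding, giving 12 design cells.
#'
#' @return A metadata data.frame with 425 rows and generated sample
#'   identifiers \code{S001..S425}.
#' @export
design_fixture <- function() {
  cells <- data.frame(
    farm       = c(rep("A", 8), rep("B", 4)),
    batch      = c("1", "1", "2", "2", "3", "3", "4", "4", "5", "5", "5", "5"),
    antibiotic = c(rep("with", 10), "without", "without"),
    feeding    = rep(c("AL", "R"), 6),
    n          = c(27L, 30L, 35L, 41L, 61L, 53L, 57L, 32L, 32L, 34L, 12L, 11L),
    stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), cells$n)
  meta <- cells[idx, c("farm", "batch", "antibiotic", "feeding")]
  meta <- data.frame(sample_id = sprintf("S%03d", seq_along(idx)), meta,
                     row.names = NULL, stringsAsFactors = FALSE)
  validate_metadata(meta)
  meta
}
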