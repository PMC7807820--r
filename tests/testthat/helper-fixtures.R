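# Programmatic fixtures shared across the suite.

# Small deterministic count table with named OTUs/samples.
toy_counts <- function(nrow = 5L, ncol = 3L, seed = 42L, lambda = 30) {
  withr::local_seed(seed)
  m <- matrix(rpois(nrow * ncol, lambda), nrow, ncol,
              dimnames = list(sprintf("OTU%d", seq_len(nrow)),
                              sprintf("S%d", seq_len(ncol))))
  storage.mode(m) <- "integer"
  m
}

# A compact valid design: two farm-A cells and two farm-B cells.
toy_metadata <- function(n_per_cell = 6L) {
  cells <- data.frame(
    farm = c("A", "A", "B", "B"),
    batch = c("1", "1", "5", "5"),
    antibiotic = c("with", "with", "with", "without"),
    feeding = c("AL", "R", "AL", "R"),
    stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
  meta <- cells[idx, ]
  meta <- data.frame(sample_id = sprintf("S%03d", seq_along(idx)), meta,
                     row.names = NULL, stringsAsFactors = FALSE)
  meta
}

# Brute-force CSS oracle: per sample, the chosen quantile of the sorted
# nonzero counts, the cumulative sum of counts up to it, then rescale.
css_oracle <- function(counts, q, scale_constant = 1000) {
  out <- counts * NA_real_
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    nz <- sort(x[x > 0])
    qv <- stats::quantile(nz, probs = q, names = FALSE, type = 7)
    s <- 0
    for (i in seq_along(x)) if (x[[i]] <= qv) s <- s + x[[i]]
    out[, j] <- x / s * scale_constant
  }
  out
}

# Exhaustive Benjamini-Hochberg step-up, written independently: for each i,
# adjusted p = min over j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[[i]] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-class, strongly separated feature matrix for sPLS-DA tests.
separable_instance <- function(n_per_class = 20L, p = 30L, n_signal = 5L,
                               shift = 4, seed = 7L) {
  withr::local_seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%d", seq_len(n)),
                              sprintf("f%d", seq_len(p))))
  cls <- factor(rep(c("A", "B"), each = n_per_class))
  X[cls == "A", seq_len(n_signal)] <- X[cls == "A", seq_len(n_signal)] + shift
  list(X = X, classes = cls, signal = sprintf("f%d", seq_len(n_signal)))
}
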