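test_that("low-depth sample removal uses a strict threshold", {
  m <- toy_counts(4, 2, seed = 1)
  m[, 1] <- c(4999L, 0L, 0L, 0L)
  m[, 2] <- c(5000L, 0L, 0L, 0L)
  out <- remove_low_depth_samples(m)
  expect_equal(colnames(out), "S2")
  expect_equal(nrow(out), 4L)  # OTU set unchanged

  m3 <- toy_counts(3, 3, seed = 2)
  m3[] <- 0L
  m3[1, ] <- c(100L, 6000L, 7000L)
  expect_equal(ncol(remove_low_depth_samples(m3)), 2L)
  big <- toy_counts(3, 3, seed = 3, lambda = 3000)
  expect_identical(remove_low_depth_samples(big), big)
  expect_error(remove_low_depth_samples(m3, min_depth = 1e7), "all samples")
})

test_that("doubleton removal drops OTUs with total <= 2", {
  m <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  expect_equal(rownames(remove_doubletons(m)), "c")
  big <- toy_counts(10, 4, seed = 4)
  expect_identical(remove_doubletons(big), big)
  mixed <- rbind(big, low1 = c(1L, 0L, 0L, 0L), low2 = c(1L, 1L, 0L, 0L),
                 low3 = c(0L, 2L, 0L, 0L), low4 = c(0L, 0L, 1L, 1L))
  expect_equal(nrow(remove_doubletons(mixed)), 10L)
})

test_that("prevalence/abundance filter applies both printed rules", {
  # 100 samples; inclusive prevalence at ceil(5% * 100) = 5 samples
  n <- 100L
  m <- matrix(0L, 3, n,
              dimnames = list(c("rare4", "edge5", "common"),
                              sprintf("S%d", 1:n)))
  m["rare4", 1:4] <- 1000L
  m["edge5", 1:5] <- 1000L
  m["common", ] <- 1000L
  out <- prevalence_abundance_filter(m)
  expect_setequal(rownames(out), c("edge5", "common"))

  # strict abundance rule at 0.01% of the grand total
  m2 <- matrix(0L, 2, 100, dimnames = list(c("at", "above"),
                                           sprintf("S%d", 1:100)))
  m2["at", 1:50] <- 2L        # total 100
  m2["above", 1:50] <- 2L
  m2["above", 51] <- 1L       # total 101
  filler <- matrix(9998L, 1, 100, dimnames = list("filler", colnames(m2)))
  m2 <- rbind(m2, filler)          # grand total 1,000,001
  out2 <- prevalence_abundance_filter(m2, min_total_fraction = 1e-4)
  expect_setequal(rownames(out2), c("above", "filler"))  # 100 !> 100.0001

  # constructed table: direct evaluation of both rules agrees
  withr::local_seed(10)
  m3 <- matrix(rpois(20 * 40, 2), 20, 40,
               dimnames = list(sprintf("O%d", 1:20), sprintf("S%d", 1:40)))
  m3[1:7, ] <- 0L
  m3[1:7, 1] <- 1L  # 7 OTUs fail prevalence
  storage.mode(m3) <- "integer"
  keep_manual <- rowSums(m3 > 0) >= ceiling(0.05 * 40) &
    rowSums(m3) > 1e-4 * sum(m3)
  expect_equal(rownames(prevalence_abundance_filter(m3)),
               rownames(m3)[keep_manual])
  expect_equal(sum(keep_manual), 13L)
})

test_that("filters are idempotent and commute with reordering", {
  m <- toy_counts(12, 8, seed = 6, lambda = 2)
  f <- function(x) prevalence_abundance_filter(
    remove_doubletons(remove_low_depth_samples(x, min_depth = 5)),
    min_prevalence = 0.3, min_total_fraction = 0.01)
  once <- f(m)
  expect_identical(f(once), once)
  withr::local_seed(1)
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  reord <- f(perm)
  expect_identical(once[rownames(reord), colnames(reord)], reord)
})

test_that("CSS normalization matches the brute-force oracle", {
  withr::local_seed(3)
  m <- matrix(rpois(5 * 8, 40) + 1L, 5, 8,
              dimnames = list(sprintf("O%d", 1:5), sprintf("S%d", 1:8)))
  storage.mode(m) <- "integer"
  nt <- css_normalize(m, quantile = 0.5)
  expect_lt(max(abs(nt$values - css_oracle(m, 0.5)) /
                  pmax(css_oracle(m, 0.5), 1e-12)), 1e-10)
  # zeros stay zero, for any quantile
  m[2, 3] <- 0L
  for (q in c(0.25, 0.5, 0.75))
    expect_equal(css_normalize(m, quantile = q)$values[2, 3], 0)
  # identical samples get identical scaling factors
  same <- matrix(rep(c(5L, 10L, 20L, 40L), 3), 4, 3,
                 dimnames = list(letters[1:4], c("S1", "S2", "S3")))
  nts <- css_normalize(same, quantile = 0.5)
  expect_equal(length(unique(nts$scaling_factors)), 1L)
  expect_error(css_normalize(cbind(same, S4 = c(0L, 0L, 0L, 0L))),
               "all-zero")
})

test_that("CSS is scale-equivariant within a sample", {
  withr::local_seed(4)
  m <- matrix(rpois(6 * 4, 30) + 1L, 6, 4,
              dimnames = list(sprintf("O%d", 1:6), sprintf("S%d", 1:4)))
  storage.mode(m) <- "integer"
  m2 <- m
  m2[, 2] <- m2[, 2] * 7L
  a <- css_normalize(m, quantile = 0.5)$values
  b <- css_normalize(m2, quantile = 0.5)$values
  expect_equal(a[, 2], b[, 2])
})

test_that("adaptive CSS quantile selection stays in [0.5, 1)", {
  params <- sim_params(n_otus = 150, design = toy_metadata(10), seed = 2,
                       lib_meanlog = log(5000), min_depth = 1000)
  g <- generate_counts(params)
  q <- css_quantile(g$counts)
  expect_gte(q, 0.5)
  expect_lt(q, 1)
  nt <- css_normalize(g$counts)
  expect_equal(nt$quantile_used, q)
})

test_that("rarefaction conserves depth and couples to the original counts", {
  params <- sim_params(n_otus = 30, design = toy_metadata(3), seed = 4,
                       lib_meanlog = log(3000), min_depth = 1500)
  g <- generate_counts(params)
  r <- rarefy(g$counts, depth = 1000, seed = 5)
  expect_true(all(colSums(r) == 1000))
  expect_true(all(r <= g$counts))
  expect_identical(rarefy(g$counts, depth = 1000, seed = 5), r)
  # a sample already at depth is returned unchanged
  ex <- matrix(c(600L, 400L), 2, 1, dimnames = list(c("a", "b"), "S1"))
  expect_equal(rarefy(ex, depth = 1000, seed = 1), ex)
  # under-depth samples are dropped with a message
  both <- cbind(ex, S2 = c(300L, 300L))
  expect_message(out <- rarefy(both, depth = 1000, seed = 1), "dropping")
  expect_equal(colnames(out), "S1")
  expect_error(rarefy(both, depth = 5000, seed = 1), "all samples")
})

test_that("rarefied counts match the hypergeometric mean", {
  x <- matrix(c(50L, 30L, 20L), 3, 1, dimnames = list(c("a", "b", "c"), "S"))
  draws <- sapply(1:1000, function(s) rarefy(x, depth = 10, seed = s))
  expected <- 10 * c(50, 30, 20) / 100
  expect_true(all(abs(rowMeans(draws) - expected) / expected < 0.02))
})

test_that("taxonomy collapse yields percentages that sum to 100", {
  m <- toy_counts(6, 4, seed = 9)
  tax <- generate_taxonomy(6, n_phyla = 2, n_genera = 3,
                           frac_genus_unassigned = 0.4, seed = 12)
  tax$otu_id <- rownames(m)
  nt <- css_normalize(m, quantile = 0.5)
  pct <- collapse_taxa(nt, tax, "phylum")
  expect_equal(unname(colSums(pct)), rep(100, 4))
  pg <- collapse_taxa(nt, tax, "genus")
  expect_equal(unname(colSums(pg)), rep(100, 4))
  # two OTUs 30/70 in one sample, different phyla
  two <- matrix(c(30L, 70L), 2, 1, dimnames = list(c("x", "y"), "S1"))
  tax2 <- data.frame(otu_id = c("x", "y"), kingdom = "Bacteria",
                     phylum = c("P1", "P2"), class = NA, order = NA,
                     family = NA, genus = NA, species = NA,
                     stringsAsFactors = FALSE)
  p2 <- collapse_taxa(two, tax2, "phylum")
  expect_equal(unname(p2[, 1]), c(30, 70))
  # single phylum: 100% everywhere
  tax2$phylum <- "P1"
  expect_equal(unname(collapse_taxa(two, tax2, "phylum")[1, ]), 100)
  expect_error(collapse_taxa(two, tax2[1, ], "phylum"), "missing OTU")
})

test_that("average daily gain is the within-animal OLS slope", {
  expect_equal(compute_adg(c(32, 39, 46, 53, 60),
                           c(700, 1000, 1300, 1600, 1900)), 300 / 7)
  expect_equal(compute_adg(c(32, 60), c(700, 1400)), 25)
  ages <- c(32, 39, 46, 53, 60)
  w <- 500 + 42 * ages
  o <- sample(5)
  expect_equal(compute_adg(ages[o], w[o]), compute_adg(ages, w))
  expect_error(compute_adg(c(32, 32), c(700, 710)), "distinct ages")
})
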