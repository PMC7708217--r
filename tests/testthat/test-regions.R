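# helper: region whose site columns have prescribed pairwise correlation
corr_region <- function(cors = 1, n_sites = 5, spacing = 100, n_subj = 10,
                        seed = 1) {
  withr::with_seed(seed, {
    base <- runif(n_subj)
    vals <- if (identical(cors, 1))
      matrix(rep(scale01(base), n_sites), ncol = n_sites)
    else matrix(runif(n_subj * n_sites), ncol = n_sites)
    region_matrix("chr1", seq(1, by = spacing, length.out = n_sites), vals)
  })
}
scale01 <- function(v) (v - min(v)) / (max(v) - min(v)) * 0.8 + 0.1

test_that("uncorrelated sites are never merged", {
  withr::with_seed(2, {
    vals <- matrix(runif(200), nrow = 20) # independent columns
  })
  rm <- region_matrix("chr1", seq(1, by = 100, length.out = 10), vals)
  out <- cluster_adjacent(rm, min_corr = 0.99)
  expect_equal(nrow(out), 10)
  expect_equal(attr(out, "site_region"), 1:10)
})

test_that("perfectly correlated nearby sites collapse into one region", {
  rm <- corr_region(cors = 1, n_sites = 5, spacing = 100)
  out <- cluster_adjacent(rm)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_sites, 5)
  expect_equal(attr(out, "site_region"), rep(1, 5))
})

test_that("the distance gate blocks merging of far-apart correlated sites", {
  rm <- corr_region(cors = 1, n_sites = 2, spacing = 5000)
  out <- cluster_adjacent(rm)
  expect_equal(nrow(out), 2)
})

test_that("adjacent clustering output partitions and orders the sites", {
  withr::with_seed(9, {
    n <- 30
    block <- rep(1:6, each = 5)
    base <- matrix(runif(15 * 6), 15, 6)
    vals <- base[, block] + matrix(runif(15 * n, 0, 0.15), 15, n)
    vals <- vals / max(vals)
  })
  rm <- region_matrix("chr1", seq(1, by = 200, length.out = 30), vals)
  out <- cluster_adjacent(rm)
  sr <- attr(out, "site_region")
  expect_true(all(diff(sr) >= 0))          # ordered
  expect_equal(sort(unique(sr)), seq_len(nrow(out))) # exactly one region each
  expect_equal(sum(out$n_sites), 30)
})

test_that("fixed windows split CpGs as specified, dropping remainders", {
  rm <- region_matrix("chr1", seq(1, by = 10, length.out = 2500),
                      matrix(0.5, 1, 2500))
  w <- sliding_windows(rm, 50)
  expect_equal(nrow(w), 50)
  rm2 <- region_matrix("chr1", seq(1, by = 10, length.out = 120),
                       matrix(0.5, 1, 120))
  expect_warning(w2 <- sliding_windows(rm2, 50), "remainder")
  expect_equal(nrow(w2), 2)
  expect_equal(sum(attr(w2, "site_window") == 0), 20)
  rm3 <- region_matrix("chr1", seq(1, by = 10, length.out = 50),
                       matrix(0.5, 1, 50))
  expect_equal(nrow(sliding_windows(rm3, 50)), 1)
})

test_that("promoter pruning keeps the nearest flank CpGs around the TSS", {
  rm <- region_matrix("chr1", seq(10, by = 10, length.out = 100),
                      matrix(0.5, 2, 100))
  tss <- 510 # 50 CpGs below, 51 at/above
  out <- prune_promoter(rm, tss, flank_cpgs = 25)
  expect_equal(length(out$positions), 50)
  expect_equal(sum(out$positions < tss), 25)
  expect_equal(sum(out$positions >= tss), 25)
  # scarce upstream: keep what exists and flag
  rm_up <- region_matrix("chr1", seq(10, by = 10, length.out = 40),
                         matrix(0.5, 2, 40))
  out2 <- prune_promoter(rm_up, 110, flank_cpgs = 25) # 10 upstream only
  expect_equal(sum(out2$positions < 110), 10)
  expect_true(isTRUE(attr(out2, "short_flank")))
  expect_error(prune_promoter(rm, 5000), "outside")
})

test_that("region filters reject constant and alternating profiles", {
  # constant region: variance gate
  const <- region_matrix("chr1", seq(1, by = 10, length.out = 20),
                         matrix(0.5, 20, 20))
  rep1 <- filter_region(const)
  expect_false(rep1$passed)
  expect_match(paste(rep1$failure_reasons, collapse = " "), "variance")

  # alternating 0/1 profile over 50 CpGs: 50 runs
  alt <- region_matrix("chr1", seq(1, by = 10, length.out = 50),
                       matrix(rep(c(0, 1), 25), 20, 50, byrow = TRUE))
  rep2 <- filter_region(alt)
  expect_equal(rep2$n_runs, 50)
  expect_false(rep2$passed)
  expect_match(paste(rep2$failure_reasons, collapse = " "), "runs")

  # a block-patterned, variable region with 16 subjects passes every gate
  withr::with_seed(4, {
    prof <- rep(c(0.1, 0.9), each = 25)
    vals <- matrix(prof, 16, 50, byrow = TRUE) +
      matrix(rnorm(16 * 50, 0, 0.05), 16, 50)
    vals[vals < 0] <- 0; vals[vals > 1] <- 1
  })
  good <- region_matrix("chr1", seq(1, by = 10, length.out = 50), vals)
  rep3 <- filter_region(good)
  expect_true(rep3$passed)
  expect_equal(rep3$n_subjects_available, 16)
  expect_identical(rep3$failure_reasons, character(0))

  # monotone: raising min_var can only shrink the passing set
  expect_false(filter_region(good, min_var = 10)$passed)

  # empty region
  empty <- region_matrix("chr1", c(1, 11), matrix(NA_real_, 2, 2),
                         mask = matrix(FALSE, 2, 2))
  expect_false(filter_region(empty)$passed)
  expect_equal(filter_region(empty)$failure_reasons, "no data")
})

test_that("skewness matches the adjusted Fisher-Pearson estimator", {
  withr::with_seed(6, v <- runif(200)^3)
  rm <- region_matrix("chr1", seq(1, by = 5, length.out = 20),
                      matrix(v, 10, 20))
  expect_equal(filter_region(rm)$skewness, e1071::skewness(v, type = 2))
})

test_that("regions map to every promoter window they overlap", {
  regions <- data.frame(region_id = c("rA", "rB", "rC"), chrom = "chr1",
                        start = c(1000, 8000, 30000),
                        end = c(2000, 9000, 31000))
  tss <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    tss = c(1500, 4500), strand = c("+", "-"))
  hits <- map_to_promoters(regions, tss, flank_bp = 5000)
  # rA overlaps both promoter windows, rB only g2's, rC neither
  expect_setequal(hits$gene[hits$region_id == "rA"], c("g1", "g2"))
  expect_equal(hits$gene[hits$region_id == "rB"], "g2")
  expect_false("rC" %in% hits$region_id)
  expect_warning(map_to_promoters(regions, tss[, 1:3]), "strand")
})
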