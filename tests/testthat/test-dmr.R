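toy_annot <- function(pos, chrom = "1") {
  data.frame(probe_id = sprintf("cg%03d", seq_along(pos)),
             chromosome = chrom, position = pos,
             stringsAsFactors = FALSE)
}

test_that("probe clustering splits on gaps and chromosomes", {
  cl <- cluster_probes(toy_annot(c(100L, 300L, 2000L)), max_gap_bp = 500)
  expect_identical(cl$cluster, c(1L, 1L, 2L))

  far <- cluster_probes(toy_annot(c(0L, 5000L, 10000L)), max_gap_bp = 1000)
  expect_identical(far$cluster, 1:3)

  two_chrom <- cluster_probes(
    data.frame(probe_id = c("a", "b"), chromosome = c("1", "2"),
               position = c(100L, 150L)), max_gap_bp = 1000)
  expect_identical(two_chrom$cluster, 1:2)

  expect_error(cluster_probes(
    data.frame(probe_id = c("a", "b"), chromosome = "1",
               position = c(5L, 5L))), "duplicate")
})

test_that("clustering agrees with a brute-force gap scan", {
  set.seed(14)
  for (i in 1:10) {
    n <- 200
    annot <- data.frame(
      probe_id = sprintf("cg%04d", 1:n),
      chromosome = sort(sample(c("1", "2", "3"), n, replace = TRUE)),
      position = 0L, stringsAsFactors = FALSE)
    for (ch in unique(annot$chromosome)) {
      k <- sum(annot$chromosome == ch)
      annot$position[annot$chromosome == ch] <-
        cumsum(sample(c(50:400, 1500:2500), k, replace = TRUE))
    }
    mine <- cluster_probes(annot, max_gap_bp = 1000)
    orac <- oracle_cluster(annot, 1000)
    expect_identical(mine$probe_id, orac$probe_id)
    # same partition (ids may differ in labeling, not here by construction)
    expect_identical(mine$cluster, orac$cluster)
  }
})

test_that("running-mean smoothing truncates at cluster edges", {
  expect_equal(smooth_coefficients(c(0, 0, 3, 0, 0), rep(1L, 5)),
               c(0, 1, 1, 1, 0))
  expect_equal(smooth_coefficients(rep(2, 6), rep(1L, 6)), rep(2, 6))
  expect_equal(smooth_coefficients(5, 1L), 5)
  # cluster boundaries are respected: no bleed across clusters
  sm <- smooth_coefficients(c(9, 9, 0, 0), c(1L, 1L, 2L, 2L))
  expect_equal(sm, c(9, 9, 0, 0))
  # loess-like smoothing leaves constants unchanged too
  expect_equal(
    smooth_coefficients(rep(1, 8), rep(1L, 8),
                        positions = (1:8) * 100, method = "loess"),
    rep(1, 8), tolerance = 1e-8)
})

test_that("bump finding matches a brute-force run scan", {
  set.seed(15)
  for (rep in 1:8) {
    n <- 300
    pos <- cumsum(sample(c(100:800, 1500:2000), n, replace = TRUE))
    annot <- toy_annot(pos)
    cl <- cluster_probes(annot, max_gap_bp = 1000)
    sm <- rnorm(n, sd = 0.5)
    cutoff <- quantile(abs(sm), 0.9, type = 7, names = FALSE)
    mine <- find_bumps(sm, cl, min_probes = 2L, cutoff = cutoff)
    orac <- oracle_bumps(sm, cl$cluster, cutoff, 2L)
    expect_identical(nrow(mine), nrow(orac))
    if (nrow(orac)) {
      orac$start <- cl$position[orac$idx_start]
      o1 <- orac[order(-orac$area), ]
      expect_equal(mine$start, o1$start)
      expect_equal(mine$area, o1$area)
      expect_equal(mine$n_probes, o1$n_probes)
      expect_equal(mine$sign, o1$sign)
    }
  }
})

test_that("no exceedance means no candidate regions", {
  cl <- cluster_probes(toy_annot(c(100L, 200L, 300L)))
  out <- find_bumps(c(0.1, 0.1, 0.1), cl, cutoff = 1)
  expect_identical(nrow(out), 0L)
})

test_that("a planted run becomes exactly one region with its span", {
  pos <- seq(1000L, by = 200L, length.out = 20L)
  cl <- cluster_probes(toy_annot(pos))
  sm <- rep(0.01, 20)
  sm[8:13] <- 0.9
  out <- find_bumps(sm, cl, cutoff = 0.5, min_probes = 5L)
  expect_identical(nrow(out), 1L)
  expect_identical(out$n_probes, 6L)
  expect_identical(out$start, pos[8])
  expect_identical(out$end, pos[13])
  expect_equal(out$area, sum(0.9 - 0.5) * 6)
})

test_that("permutation p-values follow the pooled +1 convention", {
  sr <- small_residuals()
  cl <- cluster_probes(sr$annot)
  R <- sr$R[match(cl$probe_id, rownames(sr$R)), ]
  attr(R, "design") <- NULL
  sl <- pestewas:::probe_slopes(R, sr$copper)
  sm <- smooth_coefficients(sl, cl)
  regions <- find_bumps(sm, cl, cutoff_quantile = 0.95, min_probes = 2L)
  skip_if(nrow(regions) == 0, "no candidate regions in fixture")
  dmr <- permutation_pvalues(R, sr$copper, regions, cl, B = 20L,
                             seed = 17L)
  n_null <- attr(dmr, "n_null")
  expect_true(all(dmr$p_perm > 0 & dmr$p_perm <= 1))
  # identity permutation sanity: observed areas reproduce themselves
  sl2 <- pestewas:::probe_slopes(R, sr$copper)
  sm2 <- smooth_coefficients(sl2, cl)
  obs <- pestewas:::exceedance_runs(sm2, cl$cluster,
                                    attr(regions, "cutoff"))
  expect_true(all(regions$area %in% obs$area))
  # a region beating every null area gets 1/(1+n_null)
  fake <- regions[1, , drop = FALSE]
  fake$area <- 1e9
  attr(fake, "cutoff") <- attr(regions, "cutoff")
  p_best <- permutation_pvalues(R, sr$copper, fake, cl, B = 20L,
                                seed = 17L)
  expect_equal(p_best$p_perm, 1 / (1 + attr(p_best, "n_null")))
})

test_that("region output is invariant to probe input order", {
  sr <- small_residuals()
  set.seed(19)
  perm <- sample(nrow(sr$R))
  Rp <- sr$R[perm, ]
  attr(Rp, "design") <- attr(sr$R, "design")  # subsetting drops attributes
  d1 <- run_dmr(sr$R, sr$annot, sr$copper, B = 5L, seed = 3L,
                cutoff_quantile = 0.95, min_probes = 2L)
  d2 <- run_dmr(Rp, sr$annot[perm, ], sr$copper, B = 5L,
                seed = 3L, cutoff_quantile = 0.95, min_probes = 2L)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("regions never span cluster boundaries and match probe spans", {
  sr <- small_residuals()
  d <- run_dmr(sr$R, sr$annot, sr$copper, B = 5L, seed = 3L,
               cutoff_quantile = 0.95, min_probes = 2L)
  skip_if(nrow(d) == 0, "no regions called in fixture")
  cl <- cluster_probes(sr$annot)
  probes <- attr(d, "probes")
  for (i in seq_len(nrow(d))) {
    member <- cl[match(probes[[i]], cl$probe_id), ]
    expect_identical(length(unique(member$cluster)), 1L)
    expect_identical(min(member$position), d$start[i])
    expect_identical(max(member$position), d$end[i])
  }
})

test_that("BED export converts to 0-based half-open intervals", {
  d <- structure(
    data.frame(chromosome = "3", start = 1001L, end = 1500L,
               n_probes = 5L, area = 1, sign = 1L, p_perm = 0.01),
    class = c("dmr_table", "data.frame"))
  path <- tempfile(fileext = ".bed")
  dmr_to_bed(d, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V2, 1000L)
  expect_identical(bed$V3, 1500L)
  expect_equal(bed$V5, 2)
})
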