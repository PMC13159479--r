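test_that("GMT files round-trip", {
  sets <- simulate_gene_sets(sprintf("G%03d", 1:200), n_sets = 12L,
                             seed = 4L)
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), names(sets))
  for (id in names(sets)) expect_identical(back[[id]], sets[[id]])
  expect_identical(unname(attr(back, "category")),
                   unname(attr(sets, "category")))
  expect_error(read_gmt({
    p <- tempfile(); writeLines("ONLYID\tdesc", p); p
  }), "fewer than 3")
})

test_that("probe-to-gene mapping de-duplicates and drops intergenic", {
  annot <- data.frame(
    probe_id = sprintf("cg%02d", 1:6),
    gene = c("A", "A", "B", "", "C", "c"),
    stringsAsFactors = FALSE)
  mp <- map_cpgs_to_genes(c("cg01", "cg02"), annot)
  expect_identical(mp$selected, "A")
  expect_setequal(mp$universe, c("A", "B", "C"))
  expect_identical(unname(mp$cpgs_per_gene[c("A", "B", "C")]),
                   c(2L, 1L, 2L))
  # selecting everything selects the whole universe
  expect_message(
    mp_all <- map_cpgs_to_genes(annot$probe_id, annot), "dropped")
  expect_setequal(mp_all$selected, mp_all$universe)
  expect_error(map_cpgs_to_genes(character(), annot), "empty")
})

test_that("mapping at scale equals brute-force grouping", {
  st <- small_study()
  fl <- filter_probes(st$beta, st$annotation)
  set.seed(30)
  sel <- sample(fl$annot$probe_id, 100)
  mine <- suppressMessages(map_cpgs_to_genes(sel, fl$annot))
  orac <- oracle_map_genes(sel, fl$annot)
  expect_identical(mine$selected, orac$selected)
  expect_identical(mine$universe, orac$universe)
  expect_identical(unname(mine$cpgs_per_gene[orac$universe]),
                   unname(orac$cpgs_per_gene))
})

test_that("bias weights are flat when selection ignores CpG counts", {
  set.seed(5)
  genes <- sprintf("G%05d", 1:5000)
  cpgs <- setNames(rnbinom(5000, size = 1.2, mu = 8) + 1L, genes)
  sel <- sample(genes, 400)
  w <- estimate_bias_weights(sel, genes, cpgs)
  expect_lt(max(abs(w - 1)), 0.2)
  expect_equal(mean(w), 1, tolerance = 1e-12)
})

test_that("bias weights rise when selection tracks CpG counts", {
  set.seed(5)
  genes <- sprintf("G%05d", 1:5000)
  cpgs <- setNames(rnbinom(5000, size = 1.2, mu = 8) + 1L, genes)
  sel <- genes[runif(5000) < pmin(cpgs / sum(cpgs) * 500, 1)]
  w <- estimate_bias_weights(sel, genes, cpgs)
  bins <- cut(cpgs, quantile(cpgs, 0:5 / 5), include.lowest = TRUE)
  expect_false(is.unsorted(tapply(w, bins, mean)))
  expect_gt(max(w) / min(w), 1.5)
})

test_that("degenerate weight situations return uniform weights", {
  genes <- sprintf("G%02d", 1:50)
  cpgs <- setNames(rep(4L, 50), genes)  # a single count bin
  expect_warning(w <- estimate_bias_weights(genes[1:10], genes, cpgs),
                 "100")
  expect_true(all(w == 1))
  expect_warning(
    expect_warning(w2 <- estimate_bias_weights(genes, genes, cpgs),
                   "all genes"),
    "fewer than 100")
  expect_true(all(w2 == 1))
})

test_that("Wallenius reduces to Fisher under uniform weights", {
  set.seed(16)
  for (i in 1:10) {
    N <- sample(100:400, 1)
    genes <- sprintf("G%04d", 1:N)
    sel <- sample(genes, sample(20:60, 1))
    st <- sample(genes, sample(10:40, 1))
    res <- wallenius_test(st, sel, genes, weights = NULL)
    fisher <- phyper(res$k - 1, res$m1, N - res$m1, res$n,
                     lower.tail = FALSE)
    expect_lt(abs(res$p - fisher), 1e-6)
  }
})

test_that("Wallenius tail matches the integral oracle on small
           universes", {
  set.seed(17)
  for (i in 1:50) {
    N <- sample(20:60, 1)
    m1 <- sample(5:(N %/% 2), 1)
    n <- sample(5:(N - 5), 1)
    w <- exp(runif(1, -1, 1.2))
    genes <- sprintf("G%03d", 1:N)
    set_genes <- genes[1:m1]
    sel <- sample(genes, n)
    weights <- setNames(c(rep(w, m1), rep(1, N - m1)), genes)
    res <- wallenius_test(set_genes, sel, genes, weights)
    expect_identical(res$method, "wallenius")
    orac <- if (res$k == 0) 1 else
      oracle_wallenius_tail(res$k, m1, N - m1, n, res$odds)
    expect_lt(abs(res$p - orac), 1e-8)
  }
})

test_that("zero overlap gives p = 1 and disjoint sets are skipped", {
  genes <- sprintf("G%03d", 1:100)
  res <- wallenius_test(genes[1:10], genes[50:60], genes)
  expect_equal(res$p, 1)
  annot <- data.frame(probe_id = sprintf("cg%03d", 1:100),
                      gene = rep(genes[1:50], each = 2),
                      stringsAsFactors = FALSE)
  sets <- list(IN = genes[1:10], OUT = c("ZZZ1", "ZZZ2"))
  attr(sets, "category") <- c(IN = "BP", OUT = "BP")
  suppressWarnings(expect_message(
    et <- run_enrichment(annot$probe_id[1:20], annot, sets),
    "no overlap"))   # small-universe weight warning is expected here
  expect_identical(et$set_id, "IN")
})

test_that("a strongly enriched set tops the table", {
  set.seed(13)
  genes <- sprintf("G%04d", 1:1500)
  annot <- data.frame(
    probe_id = sprintf("cg%05d", 1:6000),
    gene = sample(rep(genes, times = 4)),
    stringsAsFactors = FALSE)
  target <- genes[1:40]
  sel_probes <- c(
    annot$probe_id[annot$gene %in% target][1:60],
    sample(annot$probe_id[!(annot$gene %in% target)], 60))
  sets <- c(list(TARGET = target),
            setNames(lapply(1:30, function(i) sample(genes, 40)),
                     sprintf("NULL%02d", 1:30)))
  attr(sets, "category") <- setNames(rep("BP", 31), names(sets))
  et <- run_enrichment(sel_probes, annot, sets)
  expect_identical(et$set_id[1], "TARGET")
  expect_lt(et$fdr[1], 0.05)
})

test_that("an empty selection yields an empty table with a notice", {
  annot <- data.frame(probe_id = "cg1", gene = "A",
                      stringsAsFactors = FALSE)
  sets <- list(S = "A")
  expect_message(et <- run_enrichment(character(), annot, sets),
                 "no selected")
  expect_identical(nrow(et), 0L)
})

test_that("null p-values are approximately uniform across sets", {
  # heterogeneous set sizes: the mixture of discrete supports smooths the
  # tail p-value distribution toward uniformity
  set.seed(31)
  genes <- sprintf("G%04d", 1:2000)
  cpgs <- rnbinom(2000, size = 1.5, mu = 6) + 1L
  annot <- data.frame(
    probe_id = sprintf("cg%05d", seq_len(sum(cpgs))),
    gene = rep(genes, times = cpgs), stringsAsFactors = FALSE)
  sel <- sample(annot$probe_id, 600)
  sizes <- sample(30:400, 1000, replace = TRUE)
  sets <- setNames(lapply(sizes, function(k) sample(genes, k)),
                   sprintf("S%04d", seq_along(sizes)))
  attr(sets, "category") <- setNames(rep("BP", length(sets)), names(sets))
  et <- suppressMessages(run_enrichment(sel, annot, sets))
  ks <- suppressWarnings(ks.test(et$p_wallenius, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
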