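# Gene-set overrepresentation with correction for the number of CpG probes
# per gene: probe->gene mapping, probability-weighting-function bias
# weights, and Wallenius' noncentral hypergeometric tail test.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`,
#' member gene symbols. Symbols are uppercased.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with attributes `description`
#'   and `category` (category is the description when it is one of
#'   BP/CC/MF/pathway, otherwise `"set"`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT", call. = FALSE)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  attr(sets, "category") <- setNames(
    ifelse(desc %in% c("BP", "CC", "MF", "pathway"), desc, "set"), ids)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (attributes `description`
#'   and `category` used when present; category is written as the
#'   description field when it is informative).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "category")
  if (is.null(desc)) desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("set", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map selected CpG probes to genes
#'
#' Builds the gene universe (all genes with at least one surviving probe),
#' the selected gene list (genes containing at least one selected probe),
#' and the per-gene surviving CpG counts used for bias correction. Probes
#' with an empty gene annotation are dropped (with a message).
#'
#' @param selected_probes Character vector of selected probe ids
#'   (non-empty).
#' @param annot Filtered probe annotation (`probe_id`, `gene`).
#' @return List with `selected` (gene symbols), `universe`,
#'   `cpgs_per_gene` (named integer vector over the universe).
#' @export
map_cpgs_to_genes <- function(selected_probes, annot) {
  if (length(selected_probes) == 0L)
    stop("empty probe selection", call. = FALSE)
  gene <- toupper(ifelse(is.na(annot$gene), "", annot$gene))
  has_gene <- nzchar(gene)
  n_drop <- sum(!has_gene & annot$probe_id %in% selected_probes)
  if (n_drop)
    message("map_cpgs_to_genes: ", n_drop,
            " selected probe(s) without gene annotation dropped")
  ann <- annot[has_gene, , drop = FALSE]
  gene <- gene[has_gene]
  counts <- table(gene)
  universe <- names(counts)
  selected <- sort(unique(gene[ann$probe_id %in% selected_probes]))
  list(selected = selected, universe = universe,
       cpgs_per_gene = setNames(as.integer(counts), universe))
}

#' Probability-weighting bias weights per gene
#'
#' Estimates the probability that a gene is selected as a function of its
#' CpG probe count: genes are binned by CpG count (equal-frequency bins),
#' the per-bin selection proportion is made monotone by isotonic
#' regression, floored at a small epsilon, and returned on a relative-odds
#' scale normalized to mean 1.
#'
#' @param selected Selected gene symbols.
#' @param universe Gene universe.
#' @param cpgs_per_gene Named CpG counts over the universe.
#' @param n_bins Target number of bins (default 10).
#' @param eps Weight floor (default 1e-3).
#' @param monotone Apply isotonic regression across bins (default TRUE).
#' @return Named per-gene weight vector over the universe, mean 1.
#' @export
estimate_bias_weights <- function(selected, universe, cpgs_per_gene,
                                  n_bins = 10L, eps = 1e-3,
                                  monotone = TRUE) {
  if (length(universe) < 100)
    warning("fewer than 100 genes in the universe; bias weights are noisy")
  cnt <- cpgs_per_gene[universe]
  sel <- universe %in% selected
  if (all(sel)) {
    warning("all genes selected; returning uniform weights")
    return(setNames(rep(1, length(universe)), universe))
  }
  qs <- unique(quantile(cnt, probs = seq(0, 1, length.out = n_bins + 1L),
                        type = 7, names = FALSE))
  if (length(qs) < 3L) {
    # degenerate: effectively a single bin of counts
    return(setNames(rep(1, length(universe)), universe))
  }
  bin <- cut(cnt, breaks = qs, include.lowest = TRUE, labels = FALSE)
  prop <- tapply(sel, bin, mean)
  xmid <- tapply(cnt, bin, mean)
  if (monotone && length(prop) > 1L) {
    iso <- isoreg(xmid, prop)
    prop <- iso$yf[order(order(xmid))]
  }
  w <- pmax(as.vector(prop)[bin], eps)
  w <- w / mean(w)
  setNames(w, universe)
}

# Exact Wallenius noncentral hypergeometric distribution of the number of
# "set" genes among n sequential weighted draws without replacement, by the
# standard forward recursion over (draws, successes): with two weight
# classes the remaining urn composition depends only on the success count.
wallenius_distribution <- function(m1, m2, n, odds) {
  stopifnot(n <= m1 + m2, odds > 0)
  kmax <- min(n, m1)
  p <- numeric(kmax + 1L)
  p[1] <- 1
  for (j in seq_len(n)) {
    x <- 0:min(j - 1L, kmax)
    wr <- odds * (m1 - x)              # remaining set weight
    ww <- pmax(m2 - (j - 1L - x), 0)   # remaining non-set weight
    d <- wr + ww
    pr <- ifelse(d > 0, wr / d, 0)     # P(draw a set gene | x)
    pnew <- numeric(kmax + 1L)
    pnew[x + 1L] <- p[x + 1L] * (1 - pr)
    adv <- x + 2L
    ok <- adv <= kmax + 1L
    pnew[adv[ok]] <- pnew[adv[ok]] + p[x[ok] + 1L] * pr[ok]
    p <- pnew
  }
  p
}

#' Wallenius noncentral hypergeometric overrepresentation test
#'
#' Upper-tail probability of observing at least the seen number of
#' set-member genes among the selected genes, when genes are drawn without
#' replacement with unequal odds. The odds are the mean bias weight of the
#' set's genes over the mean weight of the non-set genes, and the
#' distribution is evaluated by the exact sequential-draw recursion. On
#' numerical failure the central hypergeometric is used, with a flag.
#'
#' @param set_genes Gene symbols of the set.
#' @param selected Selected gene symbols.
#' @param universe Gene universe.
#' @param weights Per-gene weights over the universe (see
#'   [estimate_bias_weights()]); `NULL` for uniform.
#' @return List: `p`, `k` (selected in set), `m1` (set genes in universe),
#'   `n` (genes selected), `odds`, `method` (`"wallenius"` or
#'   `"hypergeometric"`).
#' @export
wallenius_test <- function(set_genes, selected, universe, weights = NULL) {
  set_u <- intersect(toupper(set_genes), universe)
  if (length(set_u) == 0L)
    stop("set has no overlap with the universe", call. = FALSE)
  m1 <- length(set_u)
  m2 <- length(universe) - m1
  n <- length(intersect(selected, universe))
  k <- length(intersect(selected, set_u))
  if (is.null(weights)) {
    odds <- 1
  } else {
    w_in <- mean(weights[set_u])
    w_out <- if (m2 > 0) mean(weights[setdiff(universe, set_u)]) else w_in
    odds <- w_in / w_out
  }
  if (k == 0L)
    return(list(p = 1, k = 0L, m1 = m1, n = n, odds = odds,
                method = "wallenius"))
  pv <- tryCatch({
    d <- wallenius_distribution(m1, m2, n, odds)
    tail_p <- sum(d[(k + 1L):length(d)])
    if (!is.finite(tail_p) || tail_p < -1e-8 || tail_p > 1 + 1e-8)
      stop("unstable")
    min(max(tail_p, .Machine$double.xmin), 1)
  }, error = function(e) NA_real_)
  if (is.na(pv)) {
    warning("Wallenius evaluation failed; central hypergeometric fallback")
    return(list(p = phyper(k - 1L, m1, m2, n, lower.tail = FALSE),
                k = k, m1 = m1, n = n, odds = odds,
                method = "hypergeometric"))
  }
  list(p = pv, k = k, m1 = m1, n = n, odds = odds, method = "wallenius")
}

#' Run gene-set overrepresentation
#'
#' Maps the selected probes (significant probes for `source = "dmp"`,
#' region-member probes for `source = "dmr"`) to genes, estimates
#' CpG-count bias weights, runs the Wallenius test per set, and adjusts
#' p-values by Benjamini-Hochberg within each category label.
#'
#' @param selected_probes Character vector of selected probe ids (e.g.
#'   `ewas$probe_id[ewas$significant]` or
#'   `unlist(attr(dmr, "probes"))`).
#' @param annot Filtered probe annotation.
#' @param sets Gene sets from [read_gmt()] or [simulate_gene_sets()].
#' @param correct_bias Use CpG-count bias weights (default TRUE); FALSE
#'   reduces the engine to Fisher-style central enrichment.
#' @param min_overlap Sets whose universe overlap is below this are
#'   dropped with a message (default 1).
#' @return Data frame of class `enrichment_table`, sorted by p:
#'   `set_id`, `name`, `category`, `n_genes_in_set`, `n_selected_in_set`,
#'   `expected`, `odds`, `p_wallenius`, `fdr`, `method`.
#' @export
run_enrichment <- function(selected_probes, annot, sets,
                           correct_bias = TRUE, min_overlap = 1L) {
  empty <- data.frame(set_id = character(), name = character(),
                      category = character(), n_genes_in_set = integer(),
                      n_selected_in_set = integer(), expected = numeric(),
                      odds = numeric(), p_wallenius = numeric(),
                      fdr = numeric(), method = character())
  class(empty) <- c("enrichment_table", "data.frame")
  if (length(selected_probes) == 0L) {
    message("run_enrichment: no selected probes; returning empty table")
    return(empty)
  }
  mp <- map_cpgs_to_genes(selected_probes, annot)
  if (length(mp$selected) == 0L) {
    message("run_enrichment: selection maps to no genes")
    return(empty)
  }
  w <- if (correct_bias)
    estimate_bias_weights(mp$selected, mp$universe, mp$cpgs_per_gene)
  else NULL
  desc <- attr(sets, "description")
  categ <- attr(sets, "category")
  ids <- names(sets)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set_u <- intersect(toupper(sets[[i]]), mp$universe)
    if (length(set_u) < min_overlap) {
      message("run_enrichment: set ", ids[i],
              " has no overlap with the universe; skipped")
      next
    }
    res <- wallenius_test(set_u, mp$selected, mp$universe, w)
    exp_k <- res$n * res$m1 * res$odds /
      (res$m1 * res$odds + (length(mp$universe) - res$m1))
    rows[[i]] <- data.frame(
      set_id = ids[i],
      name = if (!is.null(desc)) desc[[ids[i]]] else ids[i],
      category = if (!is.null(categ)) categ[[ids[i]]] else "set",
      n_genes_in_set = res$m1, n_selected_in_set = res$k,
      expected = exp_k, odds = res$odds, p_wallenius = res$p,
      fdr = NA_real_, method = res$method)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  for (cat_l in unique(out$category)) {
    sel <- out$category == cat_l
    out$fdr[sel] <- bh_adjust(out$p_wallenius[sel])
  }
  out <- out[order(out$p_wallenius), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
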