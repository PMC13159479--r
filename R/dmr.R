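# Bump-hunting detection of differentially methylated regions: position
# clustering, within-cluster smoothing of per-probe exposure coefficients,
# cutoff exceedance runs, and pooled permutation p-values.

#' Cluster probes by genomic position
#'
#' Greedy single-pass clustering: a new cluster starts whenever the gap to
#' the previous probe exceeds `max_gap_bp` or the chromosome changes.
#'
#' @param annot Probe annotation (`probe_id`, `chromosome`, `position`).
#' @param max_gap_bp Maximum within-cluster gap in bp (default 1000).
#' @return Data frame sorted by (chromosome, position) with columns
#'   `probe_id`, `chromosome`, `position`, `cluster` (integer id).
#' @export
cluster_probes <- function(annot, max_gap_bp = 1000) {
  key <- paste(annot$chromosome, annot$position)
  if (anyDuplicated(key))
    stop("duplicate (chromosome, position) in annotation", call. = FALSE)
  ord <- order(annot$chromosome, annot$position)
  a <- annot[ord, c("probe_id", "chromosome", "position")]
  new_chrom <- c(TRUE, a$chromosome[-1] != a$chromosome[-nrow(a)])
  gap <- c(Inf, diff(a$position))
  gap[new_chrom] <- Inf
  a$cluster <- cumsum(new_chrom | gap > max_gap_bp)
  rownames(a) <- NULL
  a
}

#' Smooth per-probe coefficients within clusters
#'
#' `method = "runmean"`: running mean over a centered window of `window`
#' probes, truncated at cluster edges; clusters smaller than the window
#' pass through unchanged (the edge truncation already reduces to the
#' identity for singletons). `method = "loess"`: local linear fit on
#' position with tricube weights, per cluster, falling back to the running
#' mean for clusters too small to fit.
#'
#' @param coefs Numeric coefficient vector, one per probe, in cluster
#'   order.
#' @param clusters Cluster assignment from [cluster_probes()] (either the
#'   data frame or its `cluster` column), aligned with `coefs`.
#' @param positions Probe positions (required for `method = "loess"`).
#' @param method `"runmean"` (default) or `"loess"`.
#' @param window Running-mean window in probes (odd, default 3).
#' @param span Loess span (default 0.75).
#' @return Smoothed coefficient vector of the same length.
#' @export
smooth_coefficients <- function(coefs, clusters, positions = NULL,
                                method = c("runmean", "loess"),
                                window = 3L, span = 0.75) {
  method <- match.arg(method)
  if (is.data.frame(clusters)) {
    if (is.null(positions)) positions <- clusters$position
    clusters <- clusters$cluster
  }
  stopifnot(length(coefs) == length(clusters), window >= 1L)
  n <- length(coefs)
  if (n == 0L) return(coefs)
  if (method == "runmean") {
    h <- (window - 1L) %/% 2L
    # vectorized truncated running mean respecting cluster boundaries
    cs <- c(0, cumsum(coefs))
    idx <- seq_len(n)
    cstart <- ave(idx, clusters, FUN = min)
    cend <- ave(idx, clusters, FUN = max)
    lo <- pmax(idx - h, cstart)
    hi <- pmin(idx + h, cend)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else {
    if (is.null(positions)) stop("loess smoothing needs positions",
                                 call. = FALSE)
    out <- coefs
    for (cl in split(seq_len(n), clusters)) {
      if (length(cl) < 4L) {
        out[cl] <- smooth_coefficients(coefs[cl], rep(1L, length(cl)),
                                       method = "runmean", window = window)
        next
      }
      fit <- tryCatch(
        stats::predict(stats::loess(y ~ x, degree = 1, span = span,
                                    family = "symmetric",
                                    data = data.frame(x = positions[cl],
                                                      y = coefs[cl]))),
        error = function(e) coefs[cl])
      out[cl] <- fit
    }
    out
  }
}

# Maximal same-sign exceedance runs of a smoothed coefficient vector.
# Returns one row per run with its area; min_probes filters short runs.
exceedance_runs <- function(smoothed, clusters, cutoff, min_probes = 1L) {
  state <- integer(length(smoothed))
  state[smoothed > cutoff] <- 1L
  state[smoothed < -cutoff] <- -1L
  # run breaks at state change or cluster change
  brk <- c(TRUE, state[-1] != state[-length(state)] |
             clusters[-1] != clusters[-length(clusters)])
  run_id <- cumsum(brk)
  keep <- state != 0L
  if (!any(keep))
    return(data.frame(idx_start = integer(), idx_end = integer(),
                      n_probes = integer(), area = numeric(),
                      sign = integer(), cluster = integer()))
  rid <- run_id[keep]
  idx <- which(keep)
  first <- !duplicated(rid)
  last <- !duplicated(rid, fromLast = TRUE)
  areas <- tapply(abs(smoothed[keep]) - cutoff, rid, sum)
  out <- data.frame(
    idx_start = idx[first], idx_end = idx[last],
    n_probes = as.vector(table(rid)[as.character(rid[first])]),
    area = as.vector(areas[as.character(rid[first])]),
    sign = state[idx[first]],
    cluster = clusters[idx[first]])
  out[out$n_probes >= min_probes, , drop = FALSE]
}

#' Find candidate differentially methylated regions
#'
#' Pools all smoothed coefficients genome-wide, sets the exceedance cutoff
#' at `cutoff_quantile` of their absolute values, and reports every maximal
#' run of consecutive probes within one cluster whose smoothed values all
#' exceed +cutoff (or all fall below -cutoff) and that contains at least
#' `min_probes` probes. The area of a region is the summed exceedance
#' \eqn{\sum (|value| - cutoff)}.
#'
#' @param smoothed Smoothed coefficient vector.
#' @param clusters Cluster data frame from [cluster_probes()] aligned with
#'   `smoothed` (supplies positions and probe ids).
#' @param cutoff_quantile Quantile of pooled |smoothed| defining the
#'   cutoff (default 0.99); ignored when `cutoff` is given.
#' @param min_probes Minimum probes per region (default 5).
#' @param cutoff Optional explicit cutoff.
#' @return Data frame of candidate regions (`chromosome`, `start`, `end`,
#'   `n_probes`, `area`, `sign`), with the cutoff in attribute `"cutoff"`
#'   and member probe ids in attribute `"probes"` (a list).
#' @export
find_bumps <- function(smoothed, clusters, cutoff_quantile = 0.99,
                       min_probes = 5L, cutoff = NULL) {
  stopifnot(length(smoothed) == nrow(clusters))
  if (is.null(cutoff))
    cutoff <- quantile(abs(smoothed), cutoff_quantile, type = 7,
                       names = FALSE)
  runs <- exceedance_runs(smoothed, clusters$cluster, cutoff,
                          min_probes = min_probes)
  out <- data.frame(
    chromosome = clusters$chromosome[runs$idx_start],
    start = clusters$position[runs$idx_start],
    end = clusters$position[runs$idx_end],
    n_probes = runs$n_probes, area = runs$area, sign = runs$sign)
  probes <- mapply(function(i, j) clusters$probe_id[i:j],
                   runs$idx_start, runs$idx_end, SIMPLIFY = FALSE)
  if (nrow(out)) {
    ord <- order(-out$area)
    out <- out[ord, , drop = FALSE]
    probes <- probes[ord]
    rownames(out) <- NULL
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "probes") <- probes
  out
}

# per-probe simple-regression slopes of the residual matrix on an exposure
probe_slopes <- function(residuals, exposure) {
  xc <- exposure - mean(exposure)
  as.vector((residuals - rowMeans(residuals)) %*% xc) / sum(xc^2)
}

#' Permutation p-values for candidate regions
#'
#' For each of `B` seeded permutations of the exposure vector, recomputes
#' per-probe slopes, smooths them, and collects the areas of all maximal
#' exceedance runs at the observed cutoff (no length filter, pooled across
#' permutations). Each observed region's p-value is
#' \eqn{(1 + \#\{null\ areas \ge observed\ area\}) / (1 + total\ null\ runs)}.
#'
#' @param residuals Probes x samples residual matrix, rows aligned with
#'   `clusters`.
#' @param exposure Exposure vector.
#' @param regions Candidate regions from [find_bumps()] (carries the
#'   cutoff).
#' @param clusters Cluster data frame aligned with the residual rows.
#' @param B Number of permutations (default 250).
#' @param seed Permutation seed.
#' @param method,window,span Smoothing parameters, as in
#'   [smooth_coefficients()].
#' @return `regions` with a `p_perm` column, sorted by `p_perm`, of class
#'   `dmr_table`; total null-run count in attribute `"n_null"`.
#' @export
permutation_pvalues <- function(residuals, exposure, regions, clusters,
                                B = 250L, seed = 1L,
                                method = "runmean", window = 3L,
                                span = 0.75) {
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  cutoff <- attr(regions, "cutoff")
  if (is.null(cutoff)) stop("regions must carry a cutoff attribute",
                            call. = FALSE)
  null_areas <- with_seed(derive_seed(seed, 171L), {
    unlist(lapply(seq_len(B), function(b) {
      xp <- sample(exposure)
      sl <- probe_slopes(residuals, xp)
      sm <- smooth_coefficients(sl, clusters, method = method,
                                window = window, span = span)
      exceedance_runs(sm, clusters$cluster, cutoff)$area
    }))
  })
  n_null <- length(null_areas)
  p <- vapply(regions$area, function(a)
    (1 + sum(null_areas >= a)) / (1 + n_null), numeric(1))
  out <- regions
  out$p_perm <- p
  ord <- order(out$p_perm, -out$area)
  probes <- attr(regions, "probes")[ord]
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "probes") <- probes
  attr(out, "n_null") <- n_null
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Run the full bump-hunting DMR analysis
#'
#' Clusters probes, computes per-probe slopes of the residuals on the
#' exposure, smooths within clusters, finds candidate regions, and assigns
#' pooled permutation p-values.
#'
#' @param residuals Probes x samples residual matrix.
#' @param annot Annotation covering the residual rows.
#' @param exposure Exposure vector.
#' @param max_gap_bp Cluster gap (default 1000).
#' @param cutoff_quantile Genome-wide cutoff quantile (default 0.99).
#' @param min_probes Minimum probes per region (default 5).
#' @param B Permutations (default 250).
#' @param seed Permutation seed.
#' @param method,window,span Smoothing parameters.
#' @param adjust_exposure Adjust the exposure for the residual matrix's
#'   covariate design before computing slopes (default TRUE; see
#'   [run_ewas()]).
#' @return `dmr_table` of regions with permutation p-values.
#' @export
run_dmr <- function(residuals, annot, exposure, max_gap_bp = 1000,
                    cutoff_quantile = 0.99, min_probes = 5L, B = 250L,
                    seed = 1L, method = "runmean", window = 3L,
                    span = 0.75, adjust_exposure = TRUE) {
  exposure <- adjust_exposure_to_design(residuals, exposure,
                                        adjust_exposure)$exposure
  cl <- cluster_probes(annot[annot$probe_id %in% rownames(residuals), ],
                       max_gap_bp = max_gap_bp)
  R <- residuals[match(cl$probe_id, rownames(residuals)), , drop = FALSE]
  attr(R, "design") <- NULL
  sl <- probe_slopes(R, exposure)
  sm <- smooth_coefficients(sl, cl, method = method, window = window,
                            span = span)
  regions <- find_bumps(sm, cl, cutoff_quantile = cutoff_quantile,
                        min_probes = min_probes)
  permutation_pvalues(R, exposure, regions, cl, B = B, seed = seed,
                      method = method, window = window, span = span)
}

#' Export regions to BED
#'
#' Writes regions as BED (0-based half-open): name = region id, score =
#' \eqn{-log10(p)} capped at 1000.
#'
#' @param dmr `dmr_table` from [permutation_pvalues()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
dmr_to_bed <- function(dmr, path) {
  bed <- data.frame(chrom = paste0("chr", dmr$chromosome),
                    start = dmr$start - 1L,
                    end = dmr$end,
                    name = sprintf("dmr_%04d", seq_len(nrow(dmr))),
                    score = round(pmin(-log10(dmr$p_perm), 1000), 4))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
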