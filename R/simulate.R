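# Synthetic study generator: pesticide application records, a two-wave
# case-control cohort with address histories, and a methylation beta matrix
# with planted probe- and region-level exposure effects plus ground truth.

# Persistent agricultural hotspots shared by the application process and the
# address generator. Application intensity of BOTH chemical groups loads on
# the same per-hotspot activity, which is what makes copper and OP exposure
# positively correlated across participants.
region_hotspots <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 11L), {
    u <- rnorm(cfg$n_hotspots, 0, 0.8)
    # OP intensity is a noisy linear function of local copper intensity,
    # so exposures correlate without being collinear
    v <- 0.55 * u + rnorm(cfg$n_hotspots, 0, 0.75)
    data.frame(
      hotspot = seq_len(cfg$n_hotspots),
      x = runif(cfg$n_hotspots, 0, cfg$region_extent),
      y = runif(cfg$n_hotspots, 0, cfg$region_extent),
      activity_cu = exp(u), activity_op = exp(v))
  })
}

#' Generate pesticide application records
#'
#' Simulates annual application events in the style of California's
#' Pesticide Use Reporting system: each event carries a CADPR chemical
#' code, year, pounds applied, treated acres, and a planar location.
#' Events concentrate around persistent spatial hotspots whose activity is
#' shared between the copper and organophosphate chemical groups, so
#' participant-level copper and OP exposures are positively correlated.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `chemical_code`, `year`, `pounds`,
#'   `acres`, `x`, `y`.
#' @export
generate_applications <- function(config) {
  validate_sim_config(config)
  empty <- data.frame(chemical_code = integer(), year = integer(),
                      pounds = numeric(), acres = numeric(),
                      x = numeric(), y = numeric())
  if (config$n_applications_per_year == 0L) return(empty)
  hs <- region_hotspots(config)
  chems <- config_chemicals(config)
  with_seed(derive_seed(config$seed, 23L), {
    # chemical "popularity" is heterogeneous but fixed over years, and each
    # chemical is only in use at a subset of hotspots (crop specificity),
    # which keeps per-chemical exposure prevalence realistic
    pop_cu <- rexp(length(chems$copper)) + 0.2
    pop_op <- rexp(length(chems$op)) + 0.2
    all_codes <- c(chems$copper, chems$op)
    used_at <- lapply(seq_along(all_codes), function(i) {
      s <- which(runif(nrow(hs)) < 0.3)
      if (!length(s)) sample.int(nrow(hs), 1L) else s
    })
    names(used_at) <- as.character(all_codes)
    years <- seq(config$years[1], config$years[2])
    n_year <- config$n_applications_per_year
    n <- n_year * length(years)
    year <- rep(years, each = n_year)
    is_cu <- runif(n) < 0.35
    code <- integer(n)
    code[is_cu] <- sample(chems$copper, sum(is_cu), replace = TRUE,
                          prob = pop_cu)
    code[!is_cu] <- sample(chems$op, sum(!is_cu), replace = TRUE,
                           prob = pop_op)
    h <- integer(n)
    for (cc in unique(code)) {
      sel <- code == cc
      spots <- used_at[[as.character(cc)]]
      act <- if (cc %in% chems$copper) hs$activity_cu else hs$activity_op
      h[sel] <- spots[sample.int(length(spots), sum(sel), replace = TRUE,
                                 prob = act[spots])]
    }
    x <- pmin(pmax(hs$x[h] + rnorm(n, 0, 150), 0), config$region_extent)
    y <- pmin(pmax(hs$y[h] + rnorm(n, 0, 150), 0), config$region_extent)
    data.frame(chemical_code = code, year = year,
               pounds = rlnorm(n, log(50), 1),
               acres = rlnorm(n, log(10), 0.7),
               x = x, y = y)
  })
}

#' Generate a synthetic case-control cohort
#'
#' Produces participant covariates and lifetime address histories for a
#' two-wave study. Cases are slightly older than controls and more often
#' male; smoking, ancestry and blood cell-type fractions follow realistic
#' marginal distributions; every participant's residential history covers
#' 1974 through the blood-draw year, and a subset additionally holds a
#' workplace address.
#'
#' @param config A [sim_config()].
#' @return A list with `covariates` (one row per participant) and
#'   `addresses` (one row per address interval, columns `participant_id`,
#'   `x`, `y`, `start_year`, `end_year`, `kind`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  hs <- region_hotspots(config)
  n <- config$n_cases + config$n_controls
  yr <- config$years
  with_seed(derive_seed(config$seed, 37L), {
    id <- sprintf("P%05d", seq_len(n))
    pd <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))
    wave <- ifelse(runif(n) < 0.6, "PEG1", "PEG2")
    w1 <- max(yr[1], yr[2] - 15L):max(yr[1], yr[2] - 9L)
    w2 <- max(yr[1], yr[2] - 5L):yr[2]
    draw <- ifelse(wave == "PEG1",
                   w1[sample.int(length(w1), n, replace = TRUE)],
                   w2[sample.int(length(w2), n, replace = TRUE)])
    age <- ifelse(pd == 1L, rnorm(n, 70.5, 9.8), rnorm(n, 67.4, 12.8))
    age <- round(pmin(pmax(age, 35), 95), 1)
    sex <- ifelse(runif(n) < ifelse(pd == 1L, 0.626, 0.532), "M", "F")
    ancestry <- rbinom(n, 1L, 0.86)
    smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                      prob = c(0.493, 0.454, 0.053))
    alpha <- c(cd8t = 0.08, cd4t = 0.15, nk = 0.06, bcell = 0.07,
               mono = 0.08, gran = 0.56) * 60
    g <- matrix(rgamma(n * 6L, shape = rep(alpha, each = n)), nrow = n)
    cells <- g / rowSums(g)
    colnames(cells) <- names(alpha)
    covariates <- data.frame(participant_id = id, pd_status = pd,
                             age = age, sex = sex, ancestry = ancestry,
                             smoking = smoking, wave = wave,
                             blood_draw_year = draw, cells)

    draw_location <- function(k, p_near = 0.55) {
      near <- runif(k) < p_near
      h <- sample.int(nrow(hs), k, replace = TRUE)
      x <- ifelse(near, hs$x[h] + rnorm(k, 0, 350),
                  runif(k, 0, config$region_extent))
      y <- ifelse(near, hs$y[h] + rnorm(k, 0, 350),
                  runif(k, 0, config$region_extent))
      cbind(pmin(pmax(x, 0), config$region_extent),
            pmin(pmax(y, 0), config$region_extent))
    }
    addr <- vector("list", n)
    for (i in seq_len(n)) {
      first <- min(1974L, yr[1])
      n_moves <- min(rpois(1L, 0.7), max(draw[i] - first - 1L, 0L))
      breaks <- if (n_moves > 0L)
        sort(sample((first + 1L):(draw[i] - 1L), n_moves)) else integer()
      starts <- c(first, breaks)
      ends <- c(breaks - 1L, draw[i])
      k <- length(starts)
      # cases live slightly closer to agricultural hotspots on average
      loc <- draw_location(k, p_near = if (pd[i] == 1L) 0.60 else 0.50)
      res <- data.frame(participant_id = covariates$participant_id[i],
                        x = loc[, 1], y = loc[, 2],
                        start_year = starts, end_year = ends,
                        kind = "residential")
      if (runif(1) < 0.35 && draw[i] - first >= 6L) {
        ws <- sample(first:(draw[i] - 5L), 1L)
        we <- sample(ws:(draw[i]), 1L)
        wl <- draw_location(1L)
        res <- rbind(res, data.frame(
          participant_id = covariates$participant_id[i],
          x = wl[, 1], y = wl[, 2], start_year = ws, end_year = we,
          kind = "workplace"))
      }
      addr[[i]] <- res
    }
    list(covariates = covariates, addresses = do.call(rbind, addr))
  })
}

# Empirically measured inflation factor compensating attenuation from the
# logit->beta curvature and 5/95 winsorization between the logit-scale
# planting and the beta-scale association (single calibration run; see the
# methods vignette).
.plant_calibration <- 1.06

# Chromosome layout weights (rough relative genome share; X sizable, Y small)
.chrom_weights <- c(8.0, 7.8, 6.4, 6.2, 5.8, 5.5, 5.1, 4.7, 4.5, 4.3,
                    4.3, 4.3, 3.7, 3.4, 3.2, 2.9, 2.6, 2.5, 1.9, 2.0,
                    1.5, 1.6, 5.0, 0.9)

# Build the probe annotation: chromosome/position layout with configurable
# median gap, gene blocks, QC flags, and planted DMR blocks at requested
# coordinates. Returns annotation plus bookkeeping on planted blocks.
simulate_annotation <- function(config) {
  chroms <- c(as.character(1:22), "X", "Y")
  specs <- config$dmr_specs
  spec_chrom <- vapply(specs, `[[`, character(1), "chromosome")
  if (anyDuplicated(spec_chrom))
    stop("dmr_specs: at most one planted region per chromosome", call. = FALSE)
  if (!all(spec_chrom %in% as.character(1:22)))
    stop("dmr_specs: planted regions must be autosomal", call. = FALSE)
  with_seed(derive_seed(config$seed, 53L), {
    n_chrom <- pmax(1L, round(config$n_probes * .chrom_weights /
                                sum(.chrom_weights)))
    # pad/trim the largest chromosome so counts sum exactly
    n_chrom[1] <- n_chrom[1] + config$n_probes - sum(n_chrom)
    for (s in specs) {
      i <- match(s$chromosome, chroms)
      need <- s$n_probes + 10L
      if (n_chrom[i] < need) {
        n_chrom[1] <- n_chrom[1] - (need - n_chrom[i])
        n_chrom[i] <- need
      }
    }
    if (any(n_chrom < 1L))
      stop("n_probes too small for the requested layout", call. = FALSE)
    rate <- log(2) / config$median_gap_bp
    out <- vector("list", length(chroms))
    planted <- list()
    for (ci in seq_along(chroms)) {
      m <- n_chrom[ci]
      gaps <- pmax(2, round(rexp(m, rate)))
      spec <- specs[spec_chrom == chroms[ci]]
      block_idx <- integer()
      if (length(spec) == 1L) {
        s <- spec[[1]]
        i0 <- if (m - s$n_probes - 5L >= 5L)
          sample(5L:(m - s$n_probes - 5L), 1L) else 1L
        block_idx <- i0:(i0 + s$n_probes - 1L)
        if (s$n_probes > 1L) gaps[block_idx[-1]] <- 100
      }
      pos <- cumsum(gaps) + 50000
      if (length(block_idx)) {
        off <- spec[[1]]$start - pos[block_idx[1]]
        pos <- pos + off
        if (pos[1] < 1) pos <- pos - pos[1] + 1
      }
      out[[ci]] <- data.frame(chromosome = chroms[ci], position = pos)
      if (length(block_idx))
        planted[[length(planted) + 1L]] <- list(
          chromosome = chroms[ci], idx_in_chrom = block_idx,
          shift = spec[[1]]$shift)
    }
    annot <- do.call(rbind, out)
    annot$probe_id <- sprintf("cg%08d", seq_len(nrow(annot)))
    rownames(annot) <- NULL

    # gene blocks: runs of consecutive probes share a symbol; ~15% of
    # blocks are intergenic (empty symbol)
    gene <- character(nrow(annot))
    gi <- 0L
    i <- 1L
    while (i <= nrow(annot)) {
      size <- rnbinom(1L, size = 1.2, mu = 8) + 1L
      j <- min(i + size - 1L, nrow(annot))
      # a gene never spans chromosomes
      j <- i + sum(annot$chromosome[i:j] == annot$chromosome[i]) - 1L
      if (runif(1) < 0.85) {
        gi <- gi + 1L
        gene[i:j] <- sprintf("GENE%05d", gi)
      }
      i <- j + 1L
    }
    annot$gene <- gene

    # resolve planted blocks to probe ids
    planted_rows <- lapply(planted, function(p) {
      rows <- which(annot$chromosome == p$chromosome)[p$idx_in_chrom]
      list(chromosome = p$chromosome, rows = rows, shift = p$shift)
    })
    protected <- unlist(lapply(planted_rows, `[[`, "rows"))

    # QC flags: every sex-chromosome probe is flagged; autosomal probes are
    # flagged at the rate needed to reach the overall flag fraction
    flags <- character(nrow(annot))
    on_xy <- annot$chromosome %in% c("X", "Y")
    flags[on_xy] <- "sex_chromosome"
    auto <- which(!on_xy)
    auto <- setdiff(auto, protected)
    p_extra <- max(0, (config$flag_fraction * nrow(annot) - sum(on_xy)) /
                     length(auto))
    hit <- auto[runif(length(auto)) < p_extra]
    flags[hit] <- sample(c("cross_reactive", "snp", "non_cpg"),
                         length(hit), replace = TRUE,
                         prob = c(0.55, 0.35, 0.10))
    annot$flags <- flags
    annot <- annot[, c("probe_id", "chromosome", "position", "gene", "flags")]
    list(annotation = annot, planted_rows = planted_rows)
  })
}

#' Generate a methylation beta matrix with planted exposure effects
#'
#' Methylation is generated on the logit (M-value) scale as probe baseline +
#' per-probe covariate effects + planted exposure effects + heteroskedastic
#' noise, then mapped through the inverse logit so every beta value lies
#' strictly in (0, 1). Planted probe effects are calibrated so that the
#' partial correlation between adjusted methylation and the copper count,
#' after covariate removal, matches `config$effect_size_r`; planted regions
#' receive a coordinated shift across consecutive probes.
#'
#' @param config A [sim_config()].
#' @param counts Data frame with `participant_id`, `copper_count`,
#'   `op_count` (see [copper_op_counts()]).
#' @param covariates Cohort covariate table from [generate_cohort()].
#' @return A list with `beta` (probes x samples matrix), `annotation`, and
#'   `truth` (planted probe ids, per-probe true slopes, planted regions).
#' @export
generate_beta_matrix <- function(config, counts, covariates) {
  validate_sim_config(config)
  if (!all(covariates$participant_id %in% counts$participant_id))
    stop("counts and covariates must cover the same participants",
         call. = FALSE)
  counts <- counts[match(covariates$participant_id, counts$participant_id), ]
  lay <- simulate_annotation(config)
  annot <- lay$annotation
  n_p <- nrow(annot)
  n_s <- nrow(covariates)
  cov2 <- covariates
  cov2$op_count <- counts$op_count
  Z <- design_matrix(cov2, drop_cell = "gran")[, -1, drop = FALSE]
  Z <- scale(Z)
  Z[is.nan(Z)] <- 0
  tau <- covariate_slope_sds(config$covariate_effect_sizes, colnames(Z))
  x <- counts$copper_count
  with_seed(derive_seed(config$seed, 71L), {
    planted_rows_dmr <- lay$planted_rows
    dmr_idx <- unlist(lapply(planted_rows_dmr, `[[`, "rows"))
    eligible <- which(!(annot$chromosome %in% c("X", "Y")) &
                        annot$flags == "" &
                        !(seq_len(n_p) %in% dmr_idx))
    if (config$effect_probes > length(eligible))
      stop("not enough unflagged autosomal probes to plant effects",
           call. = FALSE)
    planted_idx <- sort(sample(eligible, config$effect_probes))

    mu <- rnorm(n_p, -0.8, 1.6)
    mid <- c(planted_idx, dmr_idx)
    mu[mid] <- rnorm(length(mid), 0, 0.8)
    sigma <- config$noise_sd * sqrt(20 / rchisq(n_p, df = 20))

    # partial SD of the exposure given the covariate design
    qz <- qr(cbind(1, Z))
    x_res <- qr.resid(qz, x)
    sd_x <- sd(x_res)
    r <- config$effect_size_r
    slope <- numeric(n_p)
    if (length(planted_idx) && isTRUE(sd_x > 0)) {
      sgn <- sample(c(-1, 1), length(planted_idx), replace = TRUE)
      slope[planted_idx] <- .plant_calibration * sgn * r / sqrt(1 - r^2) *
        sigma[planted_idx] / sd_x
    } else if (length(planted_idx)) {
      warning("exposure has no residual variance; effects not planted")
      planted_idx <- integer()
    }
    regions <- list()
    for (p in planted_rows_dmr) {
      sh <- p$shift
      sgn <- sample(c(-1, 1), 1L)
      if (is.na(sh)) {
        if (!isTRUE(sd_x > 0)) next
        sh <- sgn * .plant_calibration * r / sqrt(1 - r^2) *
          mean(sigma[p$rows]) / sd_x
      }
      slope[p$rows] <- sh
      regions[[length(regions) + 1L]] <- data.frame(
        chromosome = p$chromosome,
        start = min(annot$position[p$rows]),
        end = max(annot$position[p$rows]),
        n_probes = length(p$rows), shift = sh)
    }

    gamma <- matrix(rnorm(n_p * ncol(Z)), n_p, ncol(Z)) *
      rep(tau, each = n_p)
    M <- mu + gamma %*% t(Z) + outer(slope, x) +
      matrix(rnorm(n_p * n_s), n_p, n_s) * sigma
    beta <- plogis(M)
    dimnames(beta) <- list(annot$probe_id, covariates$participant_id)

    truth <- list(
      planted_probe_ids = annot$probe_id[planted_idx],
      true_slope = setNames(slope[c(planted_idx, dmr_idx)],
                            annot$probe_id[c(planted_idx, dmr_idx)]),
      planted_regions = if (length(regions)) do.call(rbind, regions)
                        else data.frame(chromosome = character(),
                                        start = integer(), end = integer(),
                                        n_probes = integer(),
                                        shift = numeric()),
      dmr_probe_ids = annot$probe_id[dmr_idx],
      effect_size_r = r, sd_x_partial = sd_x)
    list(beta = beta, annotation = annot, truth = truth)
  })
}

# map the named covariate_effect_sizes vector onto design-matrix columns
covariate_slope_sds <- function(es, cols) {
  if (is.null(names(es))) es <- c(age = es[[1]], sex = es[[1]],
                                  ancestry = es[[1]], smoking = es[[1]],
                                  wave = es[[1]], cells = es[[1]],
                                  op_count = es[[1]])
  pick <- function(col) {
    if (grepl("^age", col)) es[["age"]]
    else if (grepl("^sex", col)) es[["sex"]]
    else if (grepl("^ancestry", col)) es[["ancestry"]]
    else if (grepl("^smoking", col)) es[["smoking"]]
    else if (grepl("^wave", col)) es[["wave"]]
    else if (grepl("^op_count", col)) es[["op_count"]]
    else es[["cells"]]
  }
  vapply(cols, pick, numeric(1))
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator chain: application records, cohort, buffer-based
#' annual exposures, window averages, copper/OP counts, and the beta matrix
#' with planted effects. The returned ground truth records planted probes
#' and regions together with the realized exposure scores, so recovery
#' tests never re-derive it.
#'
#' @param config A [sim_config()].
#' @param radius_m Buffer radius in meters passed to
#'   [annual_buffer_exposure()] (default 500).
#' @return A list with `applications`, `addresses`, `covariates` (including
#'   `op_count`), `profiles`, `counts`, `beta`, `annotation`, `truth`, and
#'   the `config` used.
#' @export
simulate_study <- function(config, radius_m = 500) {
  validate_sim_config(config)
  applications <- generate_applications(config)
  cohort <- generate_cohort(config)
  annual <- annual_buffer_exposure(applications, cohort$addresses,
                                   radius_m = radius_m)
  draw <- cohort$covariates[, c("participant_id", "blood_draw_year")]
  profiles <- average_window(annual, draw)
  control_ids <- cohort$covariates$participant_id[
    cohort$covariates$pd_status == 0L]
  counts <- copper_op_counts(profiles, control_ids,
                             copper_codes = config_chemicals(config)$copper,
                             op_codes = config_chemicals(config)$op)
  covariates <- cohort$covariates
  covariates$op_count <- counts$op_count[
    match(covariates$participant_id, counts$participant_id)]
  bm <- generate_beta_matrix(config, counts, covariates)
  truth <- bm$truth
  truth$copper_count <- setNames(counts$copper_count, counts$participant_id)
  truth$op_count <- setNames(counts$op_count, counts$participant_id)
  list(applications = applications, addresses = cohort$addresses,
       covariates = covariates, profiles = profiles, counts = counts,
       beta = bm$beta, annotation = bm$annotation, truth = truth,
       config = config)
}

#' Simulate gene-set definitions
#'
#' Draws random gene sets from a gene universe, each labelled with a
#' category (biological process, cellular component, molecular function or
#' pathway), for use by the overrepresentation engine.
#'
#' @param universe Character vector of gene symbols to draw from.
#' @param n_sets Number of sets.
#' @param size_range Inclusive range of set sizes.
#' @param seed Random seed.
#' @return A named list of character vectors with attributes `description`
#'   and `category` (named character vectors), as returned by [read_gmt()].
#' @export
simulate_gene_sets <- function(universe, n_sets = 200L,
                               size_range = c(10L, 80L), seed = 1L) {
  universe <- unique(toupper(universe[nzchar(universe)]))
  with_seed(derive_seed(seed, 91L), {
    sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(universe, min(k, length(universe))))
    ids <- sprintf("SET%04d", seq_len(n_sets))
    names(sets) <- ids
    cat_lab <- sample(c("BP", "CC", "MF", "pathway"), n_sets,
                      replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2))
    attr(sets, "description") <- setNames(sprintf("synthetic set %d",
                                                  seq_len(n_sets)), ids)
    attr(sets, "category") <- setNames(cat_lab, ids)
    sets
  })
}
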