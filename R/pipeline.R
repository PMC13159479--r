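# End-to-end orchestration: simulate -> exposure -> preprocess -> ewas
# (total + strata) -> dmr -> enrich, against a single configuration, with
# per-stage derived seeds, file round-trips and a structured run report.

#' Pipeline configuration
#'
#' One structured configuration for [run_pipeline()]. Every enabled stage
#' reads its inputs from `output_dir` (written by the preceding stage) and
#' writes its outputs there, so each stage is independently re-runnable.
#' All randomness flows from the single root `seed` via per-stage derived
#' seeds.
#'
#' @param output_dir Directory for all stage artifacts.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "exposure", "preprocess", "ewas", "dmr", "enrich")`.
#' @param sim [sim_config()] used by the simulate stage (its seed is
#'   derived from `seed`).
#' @param seed Root seed (mandatory when any stochastic stage is enabled).
#' @param radius_m Exposure buffer radius (meters).
#' @param winsor Lower/upper winsorization quantiles.
#' @param mode Residualization mode, `"ols"` or `"eb"`.
#' @param threshold EWAS significance threshold on the unadjusted p.
#' @param strata Strata to run the EWAS in, subset of
#'   `c("all", "cases", "controls")`.
#' @param max_gap_bp,cutoff_quantile,min_probes,B DMR parameters.
#' @param gmt Path to a GMT file of gene sets; `NULL` simulates sets from
#'   the annotation's gene universe.
#' @param enrich_source `"dmp"` or `"dmr"`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            stages = c("simulate", "exposure",
                                       "preprocess", "ewas", "dmr",
                                       "enrich"),
                            sim = sim_config(n_cases = 200L,
                                             n_controls = 100L),
                            seed = 1L,
                            radius_m = 500,
                            winsor = c(0.05, 0.95),
                            mode = "ols",
                            threshold = 1e-7,
                            strata = c("all", "cases", "controls"),
                            max_gap_bp = 1000,
                            cutoff_quantile = 0.99,
                            min_probes = 5L,
                            B = 100L,
                            gmt = NULL,
                            enrich_source = c("dmp", "dmr")) {
  all_stages <- c("simulate", "exposure", "preprocess", "ewas", "dmr",
                  "enrich")
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "),
         call. = FALSE)
  if (length(stages) && is.null(seed))
    stop("seed is mandatory when any stage is enabled", call. = FALSE)
  cfg <- list(output_dir = output_dir, stages = stages, sim = sim,
              seed = as.integer(seed), radius_m = radius_m,
              winsor = winsor, mode = mode, threshold = threshold,
              strata = match.arg(strata, several.ok = TRUE),
              max_gap_bp = max_gap_bp, cutoff_quantile = cutoff_quantile,
              min_probes = as.integer(min_probes), B = as.integer(B),
              gmt = gmt, enrich_source = match.arg(enrich_source))
  class(cfg) <- "pipeline_config"
  cfg
}

# hash of the scientific configuration; volatile paths excluded so the
# same analysis in two directories hashes identically
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(cfg)
  x$output_dir <- NULL
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_log <- function(...) message("[pestewas] ", ...)

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate, exposure, preprocess,
#' ewas, dmr, enrich), writing every artifact under
#' `config$output_dir` and a structured `run_report.json`. Any stage
#' failure aborts with an error naming the stage. Identical configuration
#' and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report (a list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config_hash = config_hash(config), stages = list())
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_log(sprintf("stage %-10s done in %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 1L)

  if ("simulate" %in% config$stages) {
    report$stages$simulate <- run_stage("simulate", function() {
      study <- simulate_study(sim, radius_m = config$radius_m)
      write_study(study, dir)
      if (is.null(config$gmt)) {
        genes <- unique(study$annotation$gene)
        sets <- simulate_gene_sets(genes[nzchar(genes)],
                                   seed = derive_seed(config$seed, 2L))
        write_gmt(sets, file.path(dir, "genesets.gmt"))
      }
      list(n_applications = nrow(study$applications),
           n_participants = nrow(study$covariates),
           n_probes = nrow(study$beta),
           n_planted_probes = length(study$truth$planted_probe_ids),
           n_planted_regions = nrow(study$truth$planted_regions))
    })
  }

  if ("exposure" %in% config$stages) {
    report$stages$exposure <- run_stage("exposure", function() {
      inp <- read_study_tables(dir)
      annual <- annual_buffer_exposure(inp$applications, inp$addresses,
                                       radius_m = config$radius_m)
      profiles <- average_window(
        annual, inp$covariates[, c("participant_id", "blood_draw_year")])
      controls <- inp$covariates$participant_id[
        inp$covariates$pd_status == 0L]
      counts <- copper_op_counts(profiles, controls)
      write.csv(profiles, file.path(dir, "exposure_profiles.csv"),
                row.names = FALSE)
      write.csv(counts, file.path(dir, "counts.csv"), row.names = FALSE)
      list(n_profiles = nrow(profiles),
           mean_copper_count = mean(counts$copper_count),
           mean_op_count = mean(counts$op_count),
           copper_op_cor = cor(counts$copper_count, counts$op_count))
    })
  }

  if ("preprocess" %in% config$stages) {
    report$stages$preprocess <- run_stage("preprocess", function() {
      beta <- read_matrix_tsv(file.path(dir, "beta.tsv"))
      annot <- read.csv(file.path(dir, "annotation.csv"),
                        stringsAsFactors = FALSE)
      annot$flags[is.na(annot$flags)] <- ""
      covar <- read.csv(file.path(dir, "covariates.csv"),
                        stringsAsFactors = FALSE)
      counts <- read.csv(file.path(dir, "counts.csv"),
                         stringsAsFactors = FALSE)
      covar$op_count <- counts$op_count[
        match(covar$participant_id, counts$participant_id)]
      fl <- filter_probes(beta, annot)
      wz <- winsorize(fl$beta, config$winsor[1], config$winsor[2])
      write_matrix_tsv(wz, file.path(dir, "beta_winsorized.tsv"))
      write.csv(fl$annot, file.path(dir, "annotation_filtered.csv"),
                row.names = FALSE)
      R <- residualize(wz, covar, mode = config$mode)
      write_matrix_tsv(R, file.path(dir, "residuals.tsv"))
      jsonlite::write_json(fl$report, file.path(dir, "filter_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(fl$report, list(mode = config$mode))
    })
  }

  if ("ewas" %in% config$stages) {
    report$stages$ewas <- run_stage("ewas", function() {
      wz <- read_matrix_tsv(file.path(dir, "beta_winsorized.tsv"))
      annot <- read.csv(file.path(dir, "annotation_filtered.csv"),
                        stringsAsFactors = FALSE)
      covar <- read.csv(file.path(dir, "covariates.csv"),
                        stringsAsFactors = FALSE)
      counts <- read.csv(file.path(dir, "counts.csv"),
                         stringsAsFactors = FALSE)
      covar$op_count <- counts$op_count[
        match(covar$participant_id, counts$participant_id)]
      copper <- setNames(counts$copper_count, counts$participant_id)
      out <- list()
      inflation <- list()
      for (st in config$strata) {
        keep <- switch(st,
                       all = rep(TRUE, nrow(covar)),
                       cases = covar$pd_status == 1L,
                       controls = covar$pd_status == 0L)
        cv <- covar[keep, , drop = FALSE]
        bw <- wz[, cv$participant_id, drop = FALSE]
        R <- residualize(bw, cv, mode = config$mode)
        tab <- run_ewas(R, annot, copper[cv$participant_id],
                        threshold = config$threshold)
        z <- z_from_p(tab$p, sign(tab$slope))
        enc <- empirical_null_correct(z,
                                      seed = derive_seed(config$seed, 5L))
        suffix <- if (st == "all") "" else paste0("_", st)
        write_ewas_tsv(tab, file.path(dir,
                                      paste0("ewas_results", suffix,
                                             ".tsv")))
        inflation[[st]] <- list(
          lambda_raw = attr(tab, "lambda"),
          null_mean = enc$null_mean, null_sd = enc$null_sd,
          null_prop = enc$null_prop,
          lambda_corrected = enc$lambda_corrected)
        out[[st]] <- list(n_significant = sum(tab$significant),
                          lambda_raw = attr(tab, "lambda"),
                          lambda_corrected = enc$lambda_corrected,
                          top_probe = tab$probe_id[which.min(tab$p)],
                          top_p = min(tab$p))
      }
      jsonlite::write_json(inflation, file.path(dir, "inflation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out
    })
  }

  if ("dmr" %in% config$stages) {
    report$stages$dmr <- run_stage("dmr", function() {
      R <- read_matrix_tsv(file.path(dir, "residuals.tsv"))
      annot <- read.csv(file.path(dir, "annotation_filtered.csv"),
                        stringsAsFactors = FALSE)
      counts <- read.csv(file.path(dir, "counts.csv"),
                         stringsAsFactors = FALSE)
      copper <- counts$copper_count[
        match(colnames(R), counts$participant_id)]
      dmr <- run_dmr(R, annot, copper, max_gap_bp = config$max_gap_bp,
                     cutoff_quantile = config$cutoff_quantile,
                     min_probes = config$min_probes, B = config$B,
                     seed = derive_seed(config$seed, 7L))
      tab <- as.data.frame(dmr)
      tab$probes <- vapply(attr(dmr, "probes"), paste, character(1),
                           collapse = ";")
      write.table(tab, file.path(dir, "dmrs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      dmr_to_bed(dmr, file.path(dir, "dmrs.bed"))
      list(n_regions = nrow(dmr),
           n_significant = sum(dmr$p_perm < 0.05),
           top_region = if (nrow(dmr)) sprintf(
             "chr%s:%d-%d", dmr$chromosome[1], dmr$start[1], dmr$end[1])
             else NA)
    })
  }

  if ("enrich" %in% config$stages) {
    report$stages$enrich <- run_stage("enrich", function() {
      annot <- read.csv(file.path(dir, "annotation_filtered.csv"),
                        stringsAsFactors = FALSE)
      gmt_path <- if (is.null(config$gmt)) file.path(dir, "genesets.gmt")
                  else config$gmt
      sets <- read_gmt(gmt_path)
      selected <- if (config$enrich_source == "dmp") {
        ew <- read.delim(file.path(dir, "ewas_results.tsv"),
                         stringsAsFactors = FALSE)
        ew$probe_id[ew$significant]
      } else {
        dm <- read.delim(file.path(dir, "dmrs.tsv"),
                         stringsAsFactors = FALSE)
        unlist(strsplit(dm$probes, ";", fixed = TRUE))
      }
      et <- run_enrichment(selected, annot, sets)
      write.table(as.data.frame(et), file.path(dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_sets_tested = nrow(et),
           n_fdr_05 = if (nrow(et)) sum(et$fdr < 0.05) else 0L,
           top_set = if (nrow(et)) et$set_id[1] else NA)
    })
  }

  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
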