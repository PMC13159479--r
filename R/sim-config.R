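#' CADPR chemical codes for copper-based pesticides
#'
#' The 15 California Department of Pesticide Regulation (CADPR) chemical
#' codes for copper-based active ingredients (copper carbonate, copper
#' hydroxide, copper sulfates, oxychlorides, amine complexes, ...).
#'
#' @return Integer vector of 15 CADPR chemical codes.
#' @export
copper_chem_codes <- function() {
  c(60L, 151L, 155L, 156L, 158L, 161L, 162L, 164L, 175L, 714L,
    753L, 1615L, 1789L, 3550L, 3551L)
}

#' CADPR chemical codes for organophosphate pesticides
#'
#' The 40 CADPR chemical codes for organophosphate (OP) active ingredients
#' historically applied in California's Central Valley (diazinon,
#' chlorpyrifos, malathion, parathion, ...).
#'
#' @return Integer vector of 40 CADPR chemical codes.
#' @export
op_chem_codes <- function() {
  c(52L, 70L, 72L, 88L, 110L, 181L, 187L, 190L, 192L, 198L, 216L, 230L,
    253L, 254L, 268L, 293L, 314L, 335L, 367L, 382L, 394L, 404L, 418L,
    459L, 478L, 479L, 480L, 482L, 558L, 566L, 577L, 1626L, 1676L, 1685L,
    1689L, 1697L, 1799L, 1857L, 2006L, 2042L)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study generator: cohort size,
#' pesticide application process, methylation array layout, planted
#' probe-level and region-level exposure effects, covariate effects and
#' noise. Defaults reproduce the scale and structure of a two-wave
#' population-based Parkinson's disease case-control study in an
#' agricultural region: 569 cases and 237 controls, applications of 15
#' copper and 40 organophosphate chemicals recorded annually from 1974,
#' with spatially clustered application intensity so that copper and OP
#' exposures are positively correlated across participants.
#'
#' @param n_cases Number of cases (default 569).
#' @param n_controls Number of controls (default 237).
#' @param n_probes Number of methylation probes on the simulated array.
#' @param n_chemicals_copper Number of copper chemicals (default 15; the
#'   first `n` CADPR copper codes are used, synthetic codes beyond 15).
#' @param n_chemicals_op Number of organophosphate chemicals (default 40).
#' @param years Inclusive year range of application records, default
#'   `c(1974, 2015)`.
#' @param region_extent Side, in meters, of the flat square study region.
#' @param n_applications_per_year Expected number of application events per
#'   calendar year.
#' @param effect_probes Number of planted exposure-associated CpGs.
#' @param effect_size_r Target partial correlation (after covariate
#'   removal) between adjusted methylation and copper count at planted
#'   probes; must lie in (0, 1).
#' @param dmr_specs List of planted region specifications, each a list with
#'   elements `chromosome`, `start`, `n_probes` and `shift` (per-unit-
#'   exposure shift on the logit scale; `NA` means calibrate to
#'   `effect_size_r`). See [dmr_spec()].
#' @param covariate_effect_sizes Named numeric vector of across-probe SDs of
#'   per-probe covariate slopes on the logit scale (recycled if length 1).
#' @param noise_sd Median residual SD on the logit (M-value) scale.
#' @param flag_fraction Expected fraction of probes carrying at least one QC
#'   flag (cross-reactive, SNP-overlapping, sex-chromosome, non-CpG);
#'   default 0.28.
#' @param median_gap_bp Median inter-probe gap in bp (default 500).
#' @param n_hotspots Number of persistent agricultural hotspots over which
#'   application intensity concentrates.
#' @param seed Root random seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cases = 569L,
                       n_controls = 237L,
                       n_probes = 20000L,
                       n_chemicals_copper = 15L,
                       n_chemicals_op = 40L,
                       years = c(1974L, 2015L),
                       region_extent = 10000,
                       n_applications_per_year = 200L,
                       effect_probes = 0L,
                       effect_size_r = 0.3,
                       dmr_specs = list(),
                       covariate_effect_sizes = c(
                         age = 0.10, sex = 0.10, ancestry = 0.05,
                         smoking = 0.05, wave = 0.10, cells = 0.10,
                         op_count = 0.05),
                       noise_sd = 0.35,
                       flag_fraction = 0.28,
                       median_gap_bp = 500,
                       n_hotspots = 40L,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_probes = as.integer(n_probes),
    n_chemicals_copper = as.integer(n_chemicals_copper),
    n_chemicals_op = as.integer(n_chemicals_op),
    years = as.integer(years), region_extent = region_extent,
    n_applications_per_year = as.integer(n_applications_per_year),
    effect_probes = as.integer(effect_probes),
    effect_size_r = effect_size_r, dmr_specs = dmr_specs,
    covariate_effect_sizes = covariate_effect_sizes,
    noise_sd = noise_sd, flag_fraction = flag_fraction,
    median_gap_bp = median_gap_bp, n_hotspots = as.integer(n_hotspots),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Planted region specification
#'
#' @param chromosome Chromosome label, e.g. `"1"`.
#' @param start 1-based bp start position of the region.
#' @param n_probes Number of consecutive probes in the region.
#' @param shift Per-unit-exposure shift on the logit scale applied to every
#'   probe in the region; `NA` (default) calibrates the shift so each probe
#'   reaches the configuration's `effect_size_r`.
#' @return A list usable inside `sim_config(dmr_specs = ...)`.
#' @export
dmr_spec <- function(chromosome, start, n_probes = 10L, shift = NA_real_) {
  list(chromosome = as.character(chromosome), start = as.integer(start),
       n_probes = as.integer(n_probes), shift = shift)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_cases, cfg$n_controls, cfg$n_probes,
              cfg$n_chemicals_copper, cfg$n_chemicals_op, cfg$n_hotspots)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("sim_config: all counts must be positive", call. = FALSE)
  if (cfg$n_applications_per_year < 0)
    stop("sim_config: n_applications_per_year must be >= 0", call. = FALSE)
  if (length(cfg$years) != 2L || cfg$years[1] > cfg$years[2])
    stop("sim_config: years must be an inclusive range c(first, last)",
         call. = FALSE)
  if (!is.finite(cfg$effect_size_r) ||
      cfg$effect_size_r <= 0 || cfg$effect_size_r >= 1)
    stop("sim_config: effect_size_r must lie in (0, 1)", call. = FALSE)
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("sim_config: noise_sd must be > 0", call. = FALSE)
  if (cfg$effect_probes < 0)
    stop("sim_config: effect_probes must be >= 0", call. = FALSE)
  n_dmr <- sum(vapply(cfg$dmr_specs, function(s) s$n_probes, integer(1)))
  if (cfg$effect_probes + n_dmr > cfg$n_probes)
    stop("sim_config: effect_probes + DMR probes exceed n_probes",
         call. = FALSE)
  invisible(cfg)
}

# Chemical code lists actually used for a config (padded with synthetic
# codes when more chemicals are requested than the catalogue holds).
config_chemicals <- function(cfg) {
  pad <- function(codes, n, base) {
    if (n <= length(codes)) codes[seq_len(n)]
    else c(codes, base + seq_len(n - length(codes)))
  }
  list(copper = pad(copper_chem_codes(), cfg$n_chemicals_copper, 9000L),
       op = pad(op_chem_codes(), cfg$n_chemicals_op, 9500L))
}
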