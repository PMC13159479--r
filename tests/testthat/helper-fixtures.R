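# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small complete study: 120 samples, 2000 probes, 30 planted CpGs
small_study <- function() {
  cached("small_study", function() {
    cfg <- sim_config(n_cases = 80L, n_controls = 40L, n_probes = 2000L,
                      effect_probes = 30L,
                      n_applications_per_year = 120L, seed = 42L)
    simulate_study(cfg)
  })
}

# residual matrix + aligned copper count for the small study
small_residuals <- function() {
  cached("small_residuals", function() {
    st <- small_study()
    fl <- filter_probes(st$beta, st$annotation)
    wz <- winsorize(fl$beta)
    R <- residualize(wz, st$covariates)
    list(study = st, annot = fl$annot, R = R,
         copper = st$counts$copper_count[
           match(colnames(R), st$counts$participant_id)])
  })
}

# random application/address fixture for exposure oracle comparisons
random_exposure_fixture <- function(seed = 7L, n_apps = 200L,
                                    n_participants = 5L) {
  set.seed(seed)
  applications <- data.frame(
    chemical_code = sample(c(60L, 151L, 187L), n_apps, replace = TRUE),
    year = sample(1990:1999, n_apps, replace = TRUE),
    pounds = runif(n_apps, 1, 100),
    acres = runif(n_apps, 0.5, 20),
    x = runif(n_apps, 0, 3000), y = runif(n_apps, 0, 3000))
  addresses <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    k <- sample(1:3, 1)
    brk <- sort(sample(1991:1998, k - 1))
    data.frame(participant_id = sprintf("P%02d", i),
               x = runif(k, 0, 3000), y = runif(k, 0, 3000),
               start_year = c(1990L, brk),
               end_year = c(brk - 1L, 1999L),
               kind = "residential")
  }))
  list(applications = applications, addresses = addresses)
}
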