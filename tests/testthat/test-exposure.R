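test_that("buffer sums include only in-radius applications, boundary in", {
  addr <- data.frame(participant_id = "P1", x = 0, y = 0,
                     start_year = 1990L, end_year = 1999L,
                     kind = "residential")
  apps <- data.frame(chemical_code = 60L, year = 1995L,
                     pounds = c(10, 5), acres = c(2, 1),
                     x = c(300, 600), y = c(0, 0))
  out <- annual_buffer_exposure(apps, addr)
  expect_identical(nrow(out), 1L)
  expect_equal(out$exposure, 5.0)   # only the 300 m event: 10 lbs / 2 ac

  apps_edge <- data.frame(chemical_code = 60L, year = 1995L, pounds = 8,
                          acres = 4, x = 500, y = 0)
  out_edge <- annual_buffer_exposure(apps_edge, addr)
  expect_equal(out_edge$exposure, 2.0)  # exactly 500.0 m is included
})

test_that("residential and workplace buffers add within a year", {
  addr <- data.frame(participant_id = "P1",
                     x = c(0, 5000), y = c(0, 0),
                     start_year = c(1990L, 1994L),
                     end_year = c(1999L, 1996L),
                     kind = c("residential", "workplace"))
  apps <- data.frame(chemical_code = 60L, year = c(1995L, 1995L),
                     pounds = c(10, 6), acres = c(2, 2),
                     x = c(100, 5100), y = c(0, 0))
  out <- annual_buffer_exposure(apps, addr)
  expect_equal(out$exposure, 5 + 3)
})

test_that("buffer exposure equals the brute-force double loop", {
  fx <- random_exposure_fixture()
  mine <- annual_buffer_exposure(fx$applications, fx$addresses)
  orac <- oracle_buffer_exposure(fx$applications, fx$addresses)
  expect_equal(nrow(mine), nrow(orac))
  expect_equal(mine$participant_id, orac$participant_id)
  expect_equal(mine$chemical_code, orac$chemical_code)
  expect_equal(mine$year, orac$year)
  expect_equal(mine$exposure, orac$exposure)
})

test_that("exposure output is invariant to record order", {
  fx <- random_exposure_fixture(seed = 9L)
  base <- annual_buffer_exposure(fx$applications, fx$addresses)
  set.seed(1)
  perm <- annual_buffer_exposure(
    fx$applications[sample(nrow(fx$applications)), ],
    fx$addresses[sample(nrow(fx$addresses)), ])
  expect_equal(base, perm, ignore_attr = TRUE)
})

test_that("window averages divide by all years from 1974", {
  annual <- data.frame(participant_id = "P1", chemical_code = 60L,
                       year = 1974L, exposure = 2.0)
  draw <- data.frame(participant_id = "P1", blood_draw_year = 1975L)
  expect_equal(average_window(annual, draw)$avg_exposure, 1.0)

  # all-zero exposure participants appear with 0
  draw2 <- data.frame(participant_id = c("P1", "P2"),
                      blood_draw_year = c(1975L, 1980L))
  out <- average_window(annual, draw2)
  expect_equal(out$avg_exposure[out$participant_id == "P2"], 0)
  expect_error(average_window(annual,
                              data.frame(participant_id = "P1",
                                         blood_draw_year = 1970L)),
               "before the start")
  # years after the blood draw never count
  annual3 <- data.frame(participant_id = "P1",
                        chemical_code = c(60L, 60L),
                        year = c(1974L, 1990L), exposure = c(2, 100))
  expect_equal(average_window(annual3, draw)$avg_exposure, 1.0)
})

test_that("window averages match a hand-computed spreadsheet", {
  fx <- random_exposure_fixture()
  annual <- annual_buffer_exposure(fx$applications, fx$addresses)
  draw <- data.frame(participant_id = sprintf("P%02d", 1:5),
                     blood_draw_year = c(1995L, 1999L, 1996L, 1999L,
                                         1998L))
  out <- average_window(annual, draw)
  for (r in sample(nrow(out), min(25, nrow(out)))) {
    id <- out$participant_id[r]; cc <- out$chemical_code[r]
    dy <- draw$blood_draw_year[draw$participant_id == id]
    rows <- annual[annual$participant_id == id &
                     annual$chemical_code == cc & annual$year <= dy, ]
    expect_equal(out$avg_exposure[r], sum(rows$exposure) / (dy - 1974 + 1))
  }
})

test_that("dichotomization is strict-greater at the control median", {
  profiles <- data.frame(
    participant_id = c(sprintf("C%d", 1:5), "X1", "X2"),
    chemical_code = 60L,
    avg_exposure = c(0, 0, 1, 2, 3, 2, 1))
  dc <- dichotomize_and_count(profiles, sprintf("C%d", 1:5), 60L)
  expect_equal(unname(dc$thresholds), 1)
  expect_identical(unname(dc$count["X1"]), 1L)  # 2 > 1
  expect_identical(unname(dc$count["X2"]), 0L)  # 1 is not > 1 (tie -> 0)
})

test_that("counts sum indicators and respect group bounds", {
  st <- small_study()
  controls <- st$covariates$participant_id[st$covariates$pd_status == 0L]
  dc <- dichotomize_and_count(st$profiles, controls, copper_chem_codes())
  expect_true(all(dc$count >= 0 & dc$count <= 15))
  expect_identical(unname(dc$count),
                   as.integer(rowSums(dc$indicators)))
  # brute-force recomputation from raw profile values
  for (id in sample(names(dc$count), 10)) {
    sub <- st$profiles[st$profiles$participant_id == id &
                         st$profiles$chemical_code %in%
                           copper_chem_codes(), ]
    expect_identical(
      unname(dc$count[id]),
      sum(as.integer(sub$avg_exposure[
        order(sub$chemical_code)] > dc$thresholds)))
  }
  # a participant above threshold everywhere reaches the full count
  prof_hi <- expand.grid(participant_id = c("C1", "C2", "HI"),
                         chemical_code = copper_chem_codes(),
                         stringsAsFactors = FALSE)
  prof_hi$avg_exposure <- ifelse(prof_hi$participant_id == "HI", 100, 0.1)
  dh <- dichotomize_and_count(prof_hi, c("C1", "C2"), copper_chem_codes())
  expect_identical(unname(dh$count["HI"]), 15L)
})

test_that("counts are monotone in any single exposure", {
  fx <- random_exposure_fixture(seed = 21L)
  annual <- annual_buffer_exposure(fx$applications, fx$addresses)
  draw <- data.frame(participant_id = sprintf("P%02d", 1:5),
                     blood_draw_year = rep(1999L, 5))
  prof <- average_window(annual, draw)
  chems <- unique(prof$chemical_code)
  base <- dichotomize_and_count(prof, c("P01", "P02"), chems)
  bumped <- prof
  i <- which(bumped$participant_id == "P03" &
               bumped$chemical_code == chems[1])
  bumped$avg_exposure[i] <- bumped$avg_exposure[i] + 10
  up <- dichotomize_and_count(bumped, c("P01", "P02"), chems)
  expect_gte(up$count[["P03"]], base$count[["P03"]])
})

test_that("at most half the controls exceed their own median", {
  st <- small_study()
  controls <- st$covariates$participant_id[st$covariates$pd_status == 0L]
  dc <- dichotomize_and_count(st$profiles, controls, copper_chem_codes())
  ctrl_ind <- dc$indicators[controls, , drop = FALSE]
  expect_true(all(colMeans(ctrl_ind) <= 0.5))
})

test_that("empty controls or unknown controls are rejected", {
  profiles <- data.frame(participant_id = "P1", chemical_code = 60L,
                         avg_exposure = 1)
  expect_error(dichotomize_and_count(profiles, character(), 60L),
               "non-empty")
  expect_error(dichotomize_and_count(profiles, "NOPE", 60L), "subset")
})
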