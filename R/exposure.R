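# Buffer-based ambient exposure scoring: application records + address
# histories -> per-participant per-chemical annual exposures -> window
# averages -> control-median dichotomized chemical counts.

#' Annual exposure within a circular buffer around each address
#'
#' For every participant-year, sums pounds-per-acre (or raw pounds) over all
#' applications of each chemical in that year whose location falls within
#' `radius_m` (Euclidean, boundary inclusive) of an address active that
#' year. When both a residential and a workplace address are active in the
#' same year their buffer sums are added.
#'
#' @param applications Data frame of application records (`chemical_code`,
#'   `year`, `pounds`, `acres`, `x`, `y`).
#' @param addresses Data frame of address intervals (`participant_id`, `x`,
#'   `y`, `start_year`, `end_year`, `kind`).
#' @param radius_m Buffer radius in meters (default 500).
#' @param value Exposure unit: `"per_acre"` sums pounds/acres per event
#'   (default), `"pounds"` sums raw pounds.
#' @return Sparse long data frame (`participant_id`, `chemical_code`,
#'   `year`, `exposure`); absent combinations mean zero. Participants whose
#'   address history is empty are excluded with a warning and recorded in
#'   the `"excluded"` attribute.
#' @export
annual_buffer_exposure <- function(applications, addresses, radius_m = 500,
                                   value = c("per_acre", "pounds")) {
  value <- match.arg(value)
  stopifnot(all(c("chemical_code", "year", "pounds", "acres", "x", "y")
                %in% names(applications)),
            all(c("participant_id", "x", "y", "start_year", "end_year")
                %in% names(addresses)))
  if (any(addresses$start_year > addresses$end_year))
    stop("address interval with start_year > end_year", call. = FALSE)
  empty <- data.frame(participant_id = character(),
                      chemical_code = integer(), year = integer(),
                      exposure = numeric())
  if (nrow(applications) == 0L || nrow(addresses) == 0L) {
    attr(empty, "excluded") <- unique(as.character(addresses$participant_id))
    return(empty)
  }
  amount <- if (value == "per_acre")
    applications$pounds / applications$acres else applications$pounds

  pieces <- vector("list", nrow(addresses))
  for (i in seq_len(nrow(addresses))) {
    a <- addresses[i, ]
    in_years <- applications$year >= a$start_year &
      applications$year <= a$end_year
    if (!any(in_years)) next
    d2 <- (applications$x[in_years] - a$x)^2 +
      (applications$y[in_years] - a$y)^2
    hit <- d2 <= radius_m^2
    if (!any(hit)) next
    idx <- which(in_years)[hit]
    pieces[[i]] <- data.frame(
      participant_id = as.character(a$participant_id),
      chemical_code = applications$chemical_code[idx],
      year = applications$year[idx],
      exposure = amount[idx])
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- if (length(pieces)) {
    long <- do.call(rbind, pieces)
    aggregate(exposure ~ participant_id + chemical_code + year,
              data = long, FUN = sum)
  } else empty
  out <- out[order(out$participant_id, out$chemical_code, out$year), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- character()
  out
}

#' Average annual exposure over the study window
#'
#' Averages each participant's annual exposure per chemical over calendar
#' years 1974 through the blood-draw year inclusive, counting
#' zero-exposure years in the denominator (denominator =
#' `blood_draw_year - 1974 + 1`).
#'
#' @param annual Long data frame from [annual_buffer_exposure()].
#' @param draw_years Data frame with `participant_id` and
#'   `blood_draw_year`; defines the participant universe of the output.
#' @param window_start First year of the averaging window (default 1974).
#' @return Long data frame (`participant_id`, `chemical_code`,
#'   `avg_exposure`) containing every participant in `draw_years` crossed
#'   with every chemical present in `annual` (zero averages included).
#' @export
average_window <- function(annual, draw_years, window_start = 1974L) {
  stopifnot(all(c("participant_id", "blood_draw_year") %in%
                  names(draw_years)))
  if (any(draw_years$blood_draw_year < window_start))
    stop("blood_draw_year before the start of the exposure window (",
         window_start, ")", call. = FALSE)
  ids <- as.character(draw_years$participant_id)
  chems <- sort(unique(annual$chemical_code))
  out <- expand.grid(participant_id = ids, chemical_code = chems,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$avg_exposure <- 0
  if (nrow(annual)) {
    draw <- setNames(draw_years$blood_draw_year, ids)
    keep <- annual$year >= window_start &
      annual$year <= draw[as.character(annual$participant_id)] &
      as.character(annual$participant_id) %in% ids
    ann <- annual[keep, , drop = FALSE]
    if (nrow(ann)) {
      tot <- aggregate(exposure ~ participant_id + chemical_code,
                       data = ann, FUN = sum)
      key <- paste(out$participant_id, out$chemical_code)
      m <- match(paste(as.character(tot$participant_id),
                       tot$chemical_code), key)
      denom <- draw[as.character(tot$participant_id)] - window_start + 1
      out$avg_exposure[m] <- tot$exposure / denom
    }
  }
  out <- out[order(out$participant_id, out$chemical_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dichotomize window averages at control medians and count chemicals
#'
#' Per chemical, the threshold is the median window-average among control
#' participants (midpoint convention for even counts); a participant's
#' indicator for that chemical is 1 iff their average is strictly greater
#' than the threshold. The count score is the number of chemicals in the
#' group with indicator 1.
#'
#' @param profiles Long data frame from [average_window()].
#' @param control_ids Participant ids of the controls (non-empty, subset of
#'   `profiles`).
#' @param chemical_codes Chemical codes in the group to count over.
#' @return A list with `count` (named integer vector per participant),
#'   `indicators` (participants x chemicals 0/1 matrix) and `thresholds`
#'   (named per-chemical control medians).
#' @export
dichotomize_and_count <- function(profiles, control_ids, chemical_codes) {
  control_ids <- as.character(control_ids)
  if (length(control_ids) == 0L)
    stop("control_ids must be non-empty", call. = FALSE)
  ids <- unique(as.character(profiles$participant_id))
  if (!all(control_ids %in% ids))
    stop("control_ids must be a subset of the participants in profiles",
         call. = FALSE)
  chemical_codes <- as.integer(chemical_codes)
  avg <- matrix(0, nrow = length(ids), ncol = length(chemical_codes),
                dimnames = list(ids, as.character(chemical_codes)))
  sub <- profiles[profiles$chemical_code %in% chemical_codes, , drop = FALSE]
  if (nrow(sub))
    avg[cbind(match(as.character(sub$participant_id), ids),
              match(sub$chemical_code, chemical_codes))] <- sub$avg_exposure
  thresholds <- apply(avg[control_ids, , drop = FALSE], 2, median)
  flat <- apply(avg, 2, function(v) length(unique(v)) == 1L)
  if (any(flat))
    message("dichotomize_and_count: ", sum(flat),
            " chemical(s) with no exposure variation; indicators set to 0")
  indicators <- sweep(avg, 2, thresholds, `>`) * 1L
  indicators[, flat] <- 0L
  count <- as.integer(rowSums(indicators))
  list(count = setNames(count, ids), indicators = indicators,
       thresholds = thresholds)
}

#' Copper and organophosphate count scores
#'
#' Convenience wrapper running [dichotomize_and_count()] for the copper and
#' OP chemical groups and returning one row per participant.
#'
#' @param profiles Long data frame from [average_window()].
#' @param control_ids Control participant ids.
#' @param copper_codes,op_codes Chemical code vectors defining the groups.
#' @return Data frame with `participant_id`, `copper_count`, `op_count`.
#' @export
copper_op_counts <- function(profiles, control_ids,
                             copper_codes = copper_chem_codes(),
                             op_codes = op_chem_codes()) {
  cu <- dichotomize_and_count(profiles, control_ids, copper_codes)
  op <- dichotomize_and_count(profiles, control_ids, op_codes)
  data.frame(participant_id = names(cu$count),
             copper_count = as.integer(cu$count),
             op_count = as.integer(op$count[names(cu$count)]))
}
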