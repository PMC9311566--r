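#' Cumulative weight-weaned records
#'
#' One WtW record per breeding exposure: the weaning weight of the calf
#' resulting from that breeding (zero if none) plus the sum of all previous
#' calves' weaning weights. Ages are the intended calving ages carried by
#' the event log, starting with the exposure intended to calve at age 2.
#'
#' @param events event data.frame (`cow_id`, `age`, `preg`, `calf_sex`,
#'   `wean_wt`, `cow_wt`) or a `herd_events` object.
#' @return data.frame of trait records: `cow_id`, `trait` ("WtW"),
#'   `value_kg`, `age_yr`, `cum_calf_sex`.
#' @export
build_wtw_records <- function(events) {
  ev <- event_frame(events)
  if (any(ev$wean_wt < 0)) stop("negative weaning weight")
  if (anyDuplicated(ev[c("cow_id", "age")])) {
    stop("duplicate (cow, age) exposure")
  }
  parts <- lapply(split(ev, ev$cow_id), function(d) {
    d <- d[order(d$age), , drop = FALSE]
    data.frame(cow_id = d$cow_id, trait = rep("WtW", nrow(d)),
               value_kg = cumsum(d$wean_wt), age_yr = d$age,
               cum_calf_sex = cum_calf_sex_vec(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(cow_id = character(0), trait = character(0),
                      value_kg = numeric(0), age_yr = numeric(0),
                      cum_calf_sex = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Cow-weight records
#'
#' One CW record per pregnancy test with a non-missing weight; ages are
#' coded identically to WtW records. The number of skipped (missing-weight)
#' tests is attached as attribute `n_skipped`.
#'
#' @inheritParams build_wtw_records
#' @return data.frame of trait records: `cow_id`, `trait` ("CW"),
#'   `value_kg`, `age_yr`.
#' @export
build_cw_records <- function(events) {
  ev <- event_frame(events)
  n_skip <- sum(is.na(ev$cow_wt))
  keep <- !is.na(ev$cow_wt)
  out <- data.frame(cow_id = ev$cow_id[keep],
                    trait = rep("CW", sum(keep)),
                    value_kg = ev$cow_wt[keep], age_yr = ev$age[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$cow_id, out$age_yr), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skip
  out
}

event_frame <- function(events) {
  if (inherits(events, "herd_events")) events <- events$events
  stopifnot(is.data.frame(events),
            all(c("cow_id", "age", "wean_wt") %in% names(events)))
  events
}

cum_calf_sex_vec <- function(d) {
  weaned <- d$wean_wt > 0
  if (any(weaned & is.na(d$calf_sex))) {
    stop("weaned calf with unknown sex")
  }
  inc <- ifelse(weaned, ifelse(d$calf_sex == "M", 1L, -1L), 0L)
  inc[is.na(inc)] <- 0L
  cumsum(inc)
}

#' Cumulative calf-sex covariate
#'
#' Running count of males minus females over calves weaned up to and
#' including each exposure's outcome; used as a covariate in the WtW
#' analysis only.
#'
#' @inheritParams build_wtw_records
#' @return integer vector, one entry per exposure in age order within cow.
#' @export
cumulative_calf_sex <- function(events) {
  ev <- event_frame(events)
  ord <- order(ev$cow_id, ev$age)
  evo <- ev[ord, , drop = FALSE]
  f <- factor(evo$cow_id, levels = unique(evo$cow_id))
  vals <- unlist(lapply(split(evo, f), cum_calf_sex_vec),
                 use.names = FALSE)
  out <- integer(nrow(ev))
  out[ord] <- vals
  out
}

#' Opportunity-group code from breed composition and birth season
#'
#' Concatenates the birth-season index with the maximum single-breed
#' composition bin: `<50`, `50-<75`, `75-<87.5`, `>=87.5` (bins closed on
#' the left; the `<50` bin covers advanced-generation crosses whose largest
#' breed fraction falls below one half).
#'
#' @param composition named numeric vector or matrix row of breed
#'   fractions summing to 1, or a matrix (one row per animal).
#' @param birth_season integer birth-season index (half-year resolution).
#' @return character group code(s).
#' @export
assign_opportunity_group <- function(composition, birth_season) {
  if (is.matrix(composition)) {
    mx <- apply(composition, 1, max)
  } else {
    mx <- max(composition)
  }
  bin <- ifelse(mx >= 0.875, ">=87.5",
         ifelse(mx >= 0.75, "75-<87.5",
         ifelse(mx >= 0.5, "50-<75", "<50")))
  paste0("S", birth_season, ":", bin)
}

#' Build analysis-ready trait records for a herd
#'
#' Convenience wrapper combining [build_cw_records()] and
#' [build_wtw_records()] and attaching each cow's opportunity-group code
#' from the pedigree's composition and birth season.
#'
#' @param events a `herd_events` or event data.frame.
#' @param pedigree the `herd_pedigree` the cows belong to.
#' @return list with elements `cw` and `wtw`, each a record data.frame
#'   with columns `cow_id`, `trait`, `value_kg`, `age_yr`, `opp_group`
#'   (and `cum_calf_sex` for WtW).
#' @export
build_records <- function(events, pedigree) {
  comp <- breed_composition(pedigree)
  season <- stats::setNames(pedigree$season, pedigree$id)
  opp <- stats::setNames(
    assign_opportunity_group(comp, season[rownames(comp)]),
    rownames(comp))
  cw <- build_cw_records(events)
  cw$opp_group <- unname(opp[cw$cow_id])
  wtw <- build_wtw_records(events)
  wtw$opp_group <- unname(opp[wtw$cow_id])
  list(cw = cw, wtw = wtw)
}
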