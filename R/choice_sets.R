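# Cohort inclusion filters, hospital-year choice sets, and preferred-network
# classification by cumulative prior-year volume share.

#' Apply the cohort inclusion and exclusion filters
#'
#' Retains discharges of adults (age >= 18) admitted to a SNF within one day
#' of hospital discharge, with no SNF stay in the prior year, whose chosen
#' SNF lies in the same state as the discharging hospital, and with complete
#' geocoding for the home, hospital, and chosen facility. Filters are applied
#' in that order and each rule's removals are counted.
#'
#' @param discharges,facilities,hospitals Linked tables as produced by
#'   [generate_population()].
#' @return A list with `kept` (the filtered discharge table) and
#'   `exclusion_log`, a data frame with one row per rule giving the count
#'   removed and the count remaining.
#' @export
apply_cohort_filters <- function(discharges, facilities, hospitals) {
  if (!all(discharges$hospital_id %in% hospitals$hospital_id)) {
    stop("discharges reference hospital ids absent from the hospital table")
  }
  ok_fac <- is.na(discharges$chosen_facility_id) |
    discharges$chosen_facility_id %in% facilities$facility_id
  if (!all(ok_fac)) {
    stop("discharges reference facility ids absent from the facility table")
  }
  fac_state <- stats::setNames(facilities$state_id, facilities$facility_id)
  hosp_state <- stats::setNames(hospitals$state_id, hospitals$hospital_id)
  fac_geo_ok <- stats::setNames(
    is.finite(facilities$latitude) & is.finite(facilities$longitude),
    facilities$facility_id)

  d <- discharges
  log <- list()
  step <- function(d, keep, rule) {
    keep[is.na(keep)] <- FALSE
    log[[length(log) + 1L]] <<- data.frame(
      rule = rule, removed = sum(!keep), remaining = sum(keep),
      stringsAsFactors = FALSE)
    d[keep, , drop = FALSE]
  }
  d <- step(d, d$age >= 18, "age >= 18")
  d <- step(d, d$snf_admission_lag_days <= 1,
            "SNF admission within 1 day of discharge")
  d <- step(d, !d$had_prior_year_snf, "no SNF stay in prior year")
  d <- step(d, fac_state[d$chosen_facility_id] ==
              hosp_state[d$hospital_id],
            "chosen SNF in same state as hospital")
  d <- step(d, is.finite(d$home_latitude) & is.finite(d$home_longitude) &
              fac_geo_ok[d$chosen_facility_id],
            "complete geocoding")
  list(kept = d, exclusion_log = do.call(rbind, log))
}

#' Classify a hospital's preferred SNFs from prior-year volumes
#'
#' Rank-sorts facilities by descending shared discharge volume (ties broken
#' by ascending facility id) and walks the ranking accumulating volume
#' shares; the preferred set contains facilities up to and including the
#' first whose addition reaches the cumulative threshold. With zero total
#' volume the preferred set is empty and a warning is issued.
#'
#' @param volumes Named integer vector: prior-year discharge counts per
#'   facility id.
#' @param threshold Cumulative volume-share threshold in (0, 1); default
#'   0.50, with 0.10-0.80 supported for sensitivity grids.
#' @return A list of class `"preferred_network"` with `ranked_facilities`,
#'   `volumes` (in rank order), `preferred_set`,
#'   `cumulative_share_achieved`, and `threshold`.
#' @export
classify_preferred <- function(volumes, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  volumes <- volumes[volumes > 0]
  total <- sum(volumes)
  if (length(volumes) == 0L || total == 0) {
    warning("hospital had no prior-year SNF discharges; ",
            "preferred set is empty")
    return(structure(list(ranked_facilities = character(0),
                          volumes = integer(0),
                          preferred_set = character(0),
                          cumulative_share_achieved = 0,
                          threshold = threshold),
                     class = "preferred_network"))
  }
  ord <- order(-volumes, names(volumes))
  v <- volumes[ord]
  cum <- cumsum(v) / total
  n_pref <- which(cum >= threshold)[1L]
  structure(list(
    ranked_facilities = names(v),
    volumes = unname(as.integer(v)),
    preferred_set = names(v)[seq_len(n_pref)],
    cumulative_share_achieved = unname(cum[n_pref]),
    threshold = threshold
  ), class = "preferred_network")
}

#' Prior-year shared discharge volumes for one hospital
#'
#' Counts, per facility, the discharges from `hospital_id` in calendar year
#' `year - 1` that went to a SNF. Volumes are computed on the full discharge
#' flow, before cohort exclusions: referral relationships reflect total
#' patient flow.
#'
#' @param discharges Full discharge table.
#' @param hospital_id Hospital identifier.
#' @param year Index year; volumes come from `year - 1`.
#' @return Named integer vector of counts (possibly empty).
#' @export
prior_year_volumes <- function(discharges, hospital_id, year) {
  yr <- as.integer(format(discharges$discharge_date, "%Y"))
  sel <- discharges$hospital_id == hospital_id & yr == year - 1L &
    !is.na(discharges$chosen_facility_id)
  tab <- table(discharges$chosen_facility_id[sel])
  stats::setNames(as.integer(tab), names(tab))
}

#' Construct one hospital-year choice set
#'
#' The choice set is the union, restricted to the hospital's state, of
#' (a) all SNFs that received at least one discharge from the hospital that
#' year, (b) all SNFs within `radius_km` of the hospital, and (c) the
#' `k_nearest` SNFs closest to the hospital. Ordering is deterministic:
#' descending shared discharge volume that year, then ascending hospital
#' distance, then facility id.
#'
#' @param hospital One-row data frame with `hospital_id`, `state_id`,
#'   `latitude`, `longitude`.
#' @param year Calendar year of the set.
#' @param facilities Facility table (any states; filtered internally).
#' @param year_discharges Discharges from this hospital in this year (used
#'   for category (a) and for volume ordering).
#' @param radius_km Radius rule, km (default 22).
#' @param k_nearest Nearest-k rule (default 15).
#' @return Data frame with `facility_id` and `dist_hospital_km`, in
#'   canonical order.
#' @export
build_choice_set <- function(hospital, year, facilities, year_discharges,
                             radius_km = 22, k_nearest = 15L) {
  f <- facilities[facilities$state_id == hospital$state_id, , drop = FALSE]
  if (nrow(f) == 0L) {
    stop("no SNFs in state ", hospital$state_id,
         ": choice set undefined for hospital ", hospital$hospital_id)
  }
  d <- distance_km(hospital$latitude, hospital$longitude,
                   f$latitude, f$longitude)
  vol_tab <- table(year_discharges$chosen_facility_id)
  vol <- as.integer(vol_tab[f$facility_id])
  vol[is.na(vol)] <- 0L
  keep <- vol > 0L | d <= radius_km |
    rank(d, ties.method = "first") <= k_nearest
  ord <- order(-vol[keep], d[keep], f$facility_id[keep])
  data.frame(
    facility_id = f$facility_id[keep][ord],
    dist_hospital_km = d[keep][ord],
    stringsAsFactors = FALSE
  )
}

#' Build choice sets and preferred networks for all hospital-years
#'
#' For every hospital-year present in `kept_discharges`, constructs the
#' choice set via [build_choice_set()] and the preferred network via
#' [classify_preferred()] on prior-year volumes drawn from
#' `volume_discharges` (by default the kept table itself; pass the
#' pre-exclusion discharge flow to count total referral volume).
#'
#' @param kept_discharges Filtered discharges defining which hospital-years
#'   are needed.
#' @param facilities,hospitals Linked tables.
#' @param volume_discharges Discharge table used both for category (a) of
#'   the choice set and for prior-year volumes; defaults to
#'   `kept_discharges`.
#' @param radius_km,k_nearest,threshold Choice-set and preferred parameters.
#' @return A data frame with one row per (hospital, year, alternative):
#'   `hospital_id`, `year`, `facility_id`, `dist_hospital_km`, `alt_order`,
#'   `preferred`.
#' @export
build_hospital_year_sets <- function(kept_discharges, facilities, hospitals,
                                     volume_discharges = kept_discharges,
                                     radius_km = 22, k_nearest = 15L,
                                     threshold = 0.5) {
  yr <- as.integer(format(kept_discharges$discharge_date, "%Y"))
  vyr <- as.integer(format(volume_discharges$discharge_date, "%Y"))
  keys <- unique(data.frame(hospital_id = kept_discharges$hospital_id,
                            year = yr, stringsAsFactors = FALSE))
  keys <- keys[order(keys$hospital_id, keys$year), ]
  rownames(hospitals) <- hospitals$hospital_id
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    h <- hospitals[keys$hospital_id[i], ]
    y <- keys$year[i]
    ydis <- volume_discharges[volume_discharges$hospital_id ==
                                h$hospital_id & vyr == y, , drop = FALSE]
    cs <- build_choice_set(h, y, facilities, ydis, radius_km, k_nearest)
    vol <- prior_year_volumes(volume_discharges, h$hospital_id, y)
    net <- suppressWarnings(classify_preferred(vol, threshold))
    out[[i]] <- data.frame(
      hospital_id = h$hospital_id, year = y,
      facility_id = cs$facility_id,
      dist_hospital_km = cs$dist_hospital_km,
      alt_order = seq_len(nrow(cs)),
      preferred = cs$facility_id %in% net$preferred_set,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Assemble the long-format choice table
#'
#' One row per (discharge, alternative) with the alternative's attribute
#' vector, the choice indicator, the patient's OUD flag, the hospital state
#' (clustering variable), a unit weight placeholder, and a closest-SNF flag
#' (minimum home distance, facility-id tie-break). Missing star ratings are
#' imputed at 3 for the choice model and the imputation count is recorded in
#' the `"n_stars_imputed"` attribute; [make_outcomes()] handles missingness
#' for the quality outcomes separately.
#'
#' A discharge whose chosen SNF is absent from its hospital-year set
#' indicates an upstream bug and raises an error naming the discharge.
#'
#' @param kept_discharges Filtered discharges.
#' @param hy_sets Hospital-year sets from [build_hospital_year_sets()].
#' @param facilities,hospitals Linked tables.
#' @return Long-format data frame sorted by discharge id and alternative
#'   order, with columns `discharge_id`, `hospital_id`, `year`,
#'   `facility_id`, `state_id`, `choice`, `oud`, `weight`, `is_closest`,
#'   and the [SNF_ATTRIBUTES].
#' @export
assemble_choice_data <- function(kept_discharges, hy_sets, facilities,
                                 hospitals) {
  d <- kept_discharges
  yr <- as.integer(format(d$discharge_date, "%Y"))
  rownames(facilities) <- facilities$facility_id
  hosp_state <- stats::setNames(hospitals$state_id, hospitals$hospital_id)

  key <- paste(hy_sets$hospital_id, hy_sets$year)
  set_idx <- split(seq_len(nrow(hy_sets)), key)
  dkey <- paste(d$hospital_id, yr)
  missing_sets <- setdiff(unique(dkey), names(set_idx))
  if (length(missing_sets)) {
    stop("no choice set built for hospital-year(s): ",
         paste(missing_sets, collapse = ", "))
  }

  blocks <- vector("list", nrow(d))
  n_imputed <- 0L
  for (i in seq_len(nrow(d))) {
    rows <- hy_sets[set_idx[[dkey[i]]], ]
    m <- nrow(rows)
    if (!d$chosen_facility_id[i] %in% rows$facility_id) {
      stop("chosen SNF ", d$chosen_facility_id[i],
           " absent from the choice set of discharge ", d$discharge_id[i],
           " (upstream bug)")
    }
    f <- facilities[rows$facility_id, ]
    stars <- f$star_rating
    n_imputed <- n_imputed + sum(is.na(stars))
    stars[is.na(stars)] <- 3
    dist_home <- distance_km(d$home_latitude[i], d$home_longitude[i],
                             f$latitude, f$longitude)
    closest <- order(dist_home, f$facility_id)[1L]
    blocks[[i]] <- data.frame(
      discharge_id = d$discharge_id[i],
      hospital_id = d$hospital_id[i],
      year = yr[i],
      facility_id = rows$facility_id,
      state_id = unname(hosp_state[d$hospital_id[i]]),
      choice = as.integer(rows$facility_id == d$chosen_facility_id[i]),
      oud = d$oud[i],
      weight = 1,
      is_closest = seq_len(m) == closest,
      preferred = as.numeric(rows$preferred),
      stars = stars,
      dist_home_km = dist_home,
      dist_hospital_km = rows$dist_hospital_km,
      for_profit = as.numeric(f$for_profit),
      chain = as.numeric(f$chain),
      hospital_affiliated = as.numeric(f$hospital_affiliated),
      beds = f$beds,
      occupancy_pct = f$occupancy_pct,
      pct_medicaid = f$pct_medicaid,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, blocks)
  # stable sort: within-discharge rows keep the canonical set order
  out <- out[order(out$discharge_id), ]
  rownames(out) <- NULL
  attr(out, "n_stars_imputed") <- n_imputed
  out
}
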