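# Synthetic hospitals, SNFs, and discharge cohorts with a known ground-truth
# choice process, so every downstream stage can be tested without restricted
# claims data.

#' Canonical SNF attribute names, in model order
#'
#' The attribute vector entering the choice model: preferred status, overall
#' star rating, distance from patient home to the SNF (km), distance from the
#' discharging hospital to the SNF (km), for-profit ownership, multifacility
#' chain membership, hospital affiliation, bed count, occupancy rate (%), and
#' percent of residents funded by Medicaid.
#' @export
SNF_ATTRIBUTES <- c(
  "preferred", "stars", "dist_home_km", "dist_hospital_km",
  "for_profit", "chain", "hospital_affiliated",
  "beds", "occupancy_pct", "pct_medicaid"
)

#' Configuration for the synthetic-population generator
#'
#' Builds and validates the parameter set controlling [generate_population()].
#' The seed fully determines all outputs. States are rectangular tiles;
#' hospitals are scattered uniformly within their state tile and SNFs cluster
#' around hospitals with exponential radial decay, so that both the 22 km
#' radius rule and the 15-nearest rule bind in some markets.
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_states,n_hospitals,n_snfs,n_discharges Counts (all >= 1);
#'   `n_snfs` must be at least `n_states` so every state has a SNF market.
#' @param oud_prevalence Target marginal prevalence of opioid use disorder,
#'   strictly in (0, 1). Default 0.012, matching the roughly 1.2% observed in
#'   national Medicare SNF-bound discharges.
#' @param true_beta Named numeric vector of main-effect choice coefficients
#'   over [SNF_ATTRIBUTES].
#' @param true_delta Named numeric vector of OUD-by-attribute interaction
#'   coefficients, same names. Defaults carry negative OUD-by-preferred and
#'   OUD-by-star effects, the differential-access signal of interest.
#' @param propensity_coefs Named coefficients mapping patient covariates to
#'   the log-odds of OUD: `age1`/`age2` are per-year slopes on a two-piece
#'   linear age spline with knot `knot_age`, plus `female`, `dual`, `ma`
#'   (Medicare Advantage), `esrd`, and `elix` (per Elixhauser point). The
#'   intercept is calibrated internally so the realized marginal prevalence
#'   targets `oud_prevalence`. Defaults make OUD patients younger and more
#'   often dual-eligible.
#' @param knot_age Age-spline knot, years (default 65).
#' @param spatial_extent_km Side length of each state's square tile.
#' @param snf_decay_km Mean of the exponential radial offset of SNFs from
#'   their anchor hospital.
#' @param years Calendar years of the discharge window. The first year serves
#'   as a burn-in establishing prior-year referral volumes; its discharges
#'   are generated with an empty preferred network.
#' @param radius_km,k_nearest,preferred_threshold Choice-set radius, nearest-k
#'   rule, and cumulative volume-share threshold used by the ground-truth
#'   choice process (defaults 22 km, 15, 0.50).
#' @param star_missing_rate Probability a facility's star rating is missing.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             n_states = 4L,
                             n_hospitals = 12L,
                             n_snfs = 90L,
                             n_discharges = 5000L,
                             oud_prevalence = 0.012,
                             true_beta = default_true_beta(),
                             true_delta = default_true_delta(),
                             propensity_coefs = default_propensity_coefs(),
                             knot_age = 65,
                             spatial_extent_km = 90,
                             snf_decay_km = 8,
                             years = 2016:2018,
                             radius_km = 22,
                             k_nearest = 15L,
                             preferred_threshold = 0.5,
                             star_missing_rate = 0.03) {
  cfg <- list(
    seed = as.integer(seed), n_states = as.integer(n_states),
    n_hospitals = as.integer(n_hospitals), n_snfs = as.integer(n_snfs),
    n_discharges = as.integer(n_discharges),
    oud_prevalence = oud_prevalence,
    true_beta = complete_coef(true_beta), true_delta = complete_coef(true_delta),
    propensity_coefs = propensity_coefs, knot_age = knot_age,
    spatial_extent_km = spatial_extent_km, snf_decay_km = snf_decay_km,
    years = as.integer(years), radius_km = radius_km,
    k_nearest = as.integer(k_nearest),
    preferred_threshold = preferred_threshold,
    star_missing_rate = star_missing_rate
  )
  with(cfg, {
    stopifnot(n_states >= 1, n_hospitals >= 1, n_snfs >= 1, n_discharges >= 1)
    if (oud_prevalence <= 0 || oud_prevalence >= 1) {
      stop("oud_prevalence must lie strictly in (0, 1)", call. = FALSE)
    }
    if (n_snfs < n_states) {
      stop("need at least one SNF per state: n_snfs < n_states leaves a ",
           "state with an undefined choice set", call. = FALSE)
    }
    if (n_hospitals < n_states) {
      stop("need at least one hospital per state", call. = FALSE)
    }
  })
  structure(cfg, class = "generator_config")
}

default_true_beta <- function() {
  c(preferred = 1.4, stars = 0.25, dist_home_km = -0.12,
    dist_hospital_km = -0.04, for_profit = 0.05, chain = 0.02,
    hospital_affiliated = 0.15, beds = 0.002, occupancy_pct = 0.004,
    pct_medicaid = -0.004)
}

default_true_delta <- function() {
  c(preferred = -0.25, stars = -0.20, dist_home_km = 0,
    dist_hospital_km = 0, for_profit = 0, chain = 0,
    hospital_affiliated = 0, beds = 0, occupancy_pct = 0, pct_medicaid = 0)
}

default_propensity_coefs <- function() {
  c(age1 = -0.015, age2 = -0.09, female = -0.2, dual = 0.8,
    ma = 0, esrd = 0.3, elix = 0.05)
}

# fill unspecified attributes with zero, in canonical order
complete_coef <- function(x) {
  out <- stats::setNames(numeric(length(SNF_ATTRIBUTES)), SNF_ATTRIBUTES)
  if (is.null(names(x)) && length(x) == length(SNF_ATTRIBUTES)) {
    names(x) <- SNF_ATTRIBUTES
  }
  bad <- setdiff(names(x), SNF_ATTRIBUTES)
  if (length(bad)) stop("unknown attribute(s): ", paste(bad, collapse = ", "))
  out[names(x)] <- x
  out
}

# km -> degrees on the working sphere
KM_PER_DEG_LAT <- pi * EARTH_RADIUS_KM / 180

#' Generate a synthetic population of hospitals, SNFs, and discharges
#'
#' Draws facilities and hospitals on rectangular state tiles, patient
#' covariates, OUD status from a logistic propensity model, and each chosen
#' SNF from the conditional-logit probabilities implied by `true_beta` and
#' `true_delta` over that discharge's hospital-year choice set (union of the
#' radius and nearest-k rules). Preferred status within the ground-truth
#' utility is computed from the previous year's realized referral volumes, so
#' the first configured year acts as a burn-in with an empty preferred
#' network.
#'
#' @param config A [generator_config()].
#' @return A list with elements `facilities`, `hospitals`, `discharges`
#'   (data frames) and `ground_truth`, a list holding the true coefficients,
#'   the calibrated propensity intercept, the per-hospital-year alternative
#'   sets (`choice_sets`), and the preferred networks actually used by the
#'   generating process (`networks`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  geo <- draw_geography(config)
  facilities <- geo$facilities
  hospitals <- geo$hospitals
  if (!all(hospitals$state_id %in% facilities$state_id)) {
    stop("a state has hospitals but zero SNFs; choice sets undefined")
  }

  discharges <- draw_patients(config, hospitals)

  # ground-truth alternative sets per hospital-year: radius + nearest-k,
  # same state (category (a) of the analysis-side rule emerges from the
  # realized choices themselves)
  alt_sets <- generator_choice_sets(facilities, hospitals,
                                    radius_km = config$radius_km,
                                    k_nearest = config$k_nearest)

  drawn <- draw_choices(config, discharges, facilities, hospitals, alt_sets)
  discharges$chosen_facility_id <- drawn$chosen

  ground_truth <- list(
    config = config,
    true_beta = config$true_beta,
    true_delta = config$true_delta,
    propensity_coefs = config$propensity_coefs,
    propensity_intercept = attr(discharges, "propensity_intercept"),
    choice_sets = alt_sets,
    networks = drawn$networks
  )
  attr(discharges, "propensity_intercept") <- NULL
  list(facilities = facilities, hospitals = hospitals,
       discharges = discharges, ground_truth = ground_truth)
}

draw_geography <- function(config) {
  ns <- config$n_states
  ext <- config$spatial_extent_km
  base_lat <- 40
  deg_lat <- ext / KM_PER_DEG_LAT
  deg_lon <- ext / (KM_PER_DEG_LAT * cos(base_lat * pi / 180))
  state_ids <- sprintf("S%d", seq_len(ns))
  # tiles side by side along longitude, 1-tile gap between states
  tile_lon0 <- -100 + (seq_len(ns) - 1) * 2 * deg_lon

  h_state <- rep_len(seq_len(ns), config$n_hospitals)
  hospitals <- data.frame(
    hospital_id = sprintf("H%02d", seq_len(config$n_hospitals)),
    state_id = state_ids[h_state],
    latitude = base_lat + stats::runif(config$n_hospitals) * deg_lat,
    longitude = tile_lon0[h_state] +
      stats::runif(config$n_hospitals) * deg_lon,
    stringsAsFactors = FALSE
  )

  f_state <- rep_len(seq_len(ns), config$n_snfs)
  # anchor each SNF to a random hospital of its state, exponential radial
  # offset so markets are dense near hospitals and sparse far out
  lat <- lon <- numeric(config$n_snfs)
  for (i in seq_len(config$n_snfs)) {
    hh <- which(h_state == f_state[i])
    a <- hospitals[sample(hh, 1L), ]
    r <- stats::rexp(1, rate = 1 / config$snf_decay_km)
    th <- stats::runif(1, 0, 2 * pi)
    lat[i] <- a$latitude + (r * sin(th)) / KM_PER_DEG_LAT
    lon[i] <- a$longitude + (r * cos(th)) /
      (KM_PER_DEG_LAT * cos(base_lat * pi / 180))
    # keep inside the state tile so same-state distance logic stays clean
    lat[i] <- min(max(lat[i], base_lat), base_lat + deg_lat)
    lon[i] <- min(max(lon[i], tile_lon0[f_state[i]]),
                  tile_lon0[f_state[i]] + deg_lon)
  }
  n <- config$n_snfs
  stars <- sample(1:5, n, replace = TRUE,
                  prob = c(0.10, 0.16, 0.24, 0.28, 0.22))
  stars[stats::runif(n) < config$star_missing_rate] <- NA_integer_
  facilities <- data.frame(
    facility_id = sprintf("F%04d", seq_len(n)),
    state_id = state_ids[f_state],
    latitude = lat, longitude = lon,
    star_rating = stars,
    for_profit = stats::runif(n) < 0.71,
    chain = stats::runif(n) < 0.58,
    hospital_affiliated = stats::runif(n) < 0.05,
    beds = pmax(20L, stats::rpois(n, 110)),
    occupancy_pct = pmin(100, pmax(20, stats::rnorm(n, 80, 10))),
    pct_medicaid = pmin(100, pmax(0, stats::rnorm(n, 50, 15))),
    stringsAsFactors = FALSE
  )
  list(facilities = facilities, hospitals = hospitals)
}

draw_patients <- function(config, hospitals) {
  n <- config$n_discharges
  hosp_idx <- sample(nrow(hospitals), n, replace = TRUE)
  yr <- sample(config$years, n, replace = TRUE)
  origin <- as.Date(sprintf("%d-01-01", yr))
  date <- origin + sample.int(365, n, replace = TRUE) - 1L

  age <- round(pmin(100, pmax(18, stats::rnorm(n, 79, 10))))
  sex <- ifelse(stats::runif(n) < 0.60, "female", "male")
  race <- sample(c("white", "black", "hispanic", "other"), n, replace = TRUE,
                 prob = c(0.82, 0.09, 0.05, 0.04))
  dual <- stats::runif(n) < 0.26
  ma <- stats::runif(n) < 0.15
  esrd <- stats::runif(n) < 0.012
  ruca <- sample(RUCA_LEVELS, n, replace = TRUE,
                 prob = c(0.75, 0.12, 0.07, 0.06))
  elix <- pmin(15L, stats::rpois(n, 3))

  pc <- config$propensity_coefs
  lp <- pc["age1"] * pmin(age, config$knot_age) +
    pc["age2"] * pmax(age - config$knot_age, 0) +
    pc["female"] * (sex == "female") + pc["dual"] * dual +
    pc["ma"] * ma + pc["esrd"] * esrd + pc["elix"] * elix
  # calibrate intercept so the marginal prevalence hits the target
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + lp)) - config$oud_prevalence,
    interval = c(-40, 40), tol = 1e-10
  )$root
  oud <- stats::runif(n) < stats::plogis(intercept + lp)

  # homes near the discharging hospital
  home_r <- stats::rexp(n, rate = 1 / 10)
  home_th <- stats::runif(n, 0, 2 * pi)
  hlat <- hospitals$latitude[hosp_idx]
  hlon <- hospitals$longitude[hosp_idx]
  out <- data.frame(
    discharge_id = sprintf("D%06d", seq_len(n)),
    patient_id = sprintf("P%06d", seq_len(n)),
    hospital_id = hospitals$hospital_id[hosp_idx],
    discharge_date = date,
    chosen_facility_id = NA_character_,
    snf_admission_lag_days = ifelse(stats::runif(n) < 0.30, 1L, 0L),
    had_prior_year_snf = stats::runif(n) < 0.02,
    oud = oud,
    age = age, sex = sex, race_ethnicity = race,
    dual_eligible = dual, medicare_advantage = ma, esrd_eligibility = esrd,
    ruca = ruca, elixhauser = as.integer(elix),
    home_latitude = hlat + (home_r * sin(home_th)) / KM_PER_DEG_LAT,
    home_longitude = hlon + (home_r * cos(home_th)) /
      (KM_PER_DEG_LAT * cos(40 * pi / 180)),
    stringsAsFactors = FALSE
  )
  attr(out, "propensity_intercept") <- intercept
  out
}

#' RUCA urbanicity categories
#' @export
RUCA_LEVELS <- c("metropolitan", "micropolitan", "small town", "rural")

# hospital-year-invariant alternative sets: same-state SNFs within radius_km
# of the hospital, union the k nearest
generator_choice_sets <- function(facilities, hospitals, radius_km,
                                  k_nearest) {
  out <- vector("list", nrow(hospitals))
  for (i in seq_len(nrow(hospitals))) {
    h <- hospitals[i, ]
    f <- facilities[facilities$state_id == h$state_id, ]
    d <- distance_km(h$latitude, h$longitude, f$latitude, f$longitude)
    keep <- d <= radius_km | rank(d, ties.method = "first") <= k_nearest
    out[[i]] <- data.frame(
      hospital_id = h$hospital_id,
      facility_id = f$facility_id[keep],
      dist_hospital_km = d[keep],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# facility attribute matrix in canonical order, dist_home left at 0;
# missing stars imputed at 3 for the generating utility
facility_attr_matrix <- function(f, dist_hospital) {
  stars <- ifelse(is.na(f$star_rating), 3, f$star_rating)
  cbind(preferred = 0, stars = stars, dist_home_km = 0,
        dist_hospital_km = dist_hospital,
        for_profit = as.numeric(f$for_profit), chain = as.numeric(f$chain),
        hospital_affiliated = as.numeric(f$hospital_affiliated),
        beds = f$beds, occupancy_pct = f$occupancy_pct,
        pct_medicaid = f$pct_medicaid)
}

draw_choices <- function(config, discharges, facilities, hospitals,
                         alt_sets) {
  beta <- config$true_beta
  delta <- config$true_delta
  yr <- as.integer(format(discharges$discharge_date, "%Y"))
  chosen <- character(nrow(discharges))
  networks <- list()
  rownames(facilities) <- facilities$facility_id
  # realized volumes from the previous generated year, per hospital
  prev_vol <- list()

  for (y in sort(unique(yr))) {
    this_vol <- list()
    for (h in hospitals$hospital_id) {
      rows <- which(yr == y & discharges$hospital_id == h)
      aset <- alt_sets[alt_sets$hospital_id == h, ]
      f <- facilities[aset$facility_id, ]
      m <- nrow(f)
      X <- facility_attr_matrix(f, aset$dist_hospital_km)
      pv <- prev_vol[[h]]
      if (!is.null(pv) && sum(pv) > 0) {
        net <- classify_preferred(pv, config$preferred_threshold)
        X[, "preferred"] <- as.numeric(f$facility_id %in% net$preferred_set)
      }
      networks[[length(networks) + 1L]] <- data.frame(
        hospital_id = h, year = y, facility_id = f$facility_id,
        preferred = X[, "preferred"] == 1, stringsAsFactors = FALSE
      )
      if (!length(rows)) next
      dd <- discharges[rows, ]
      Dh <- distance_matrix_km(f$latitude, f$longitude,
                               dd$home_latitude, dd$home_longitude)
      fix_b <- drop(X[, -3, drop = FALSE] %*% beta[-3])
      fix_d <- drop(X[, -3, drop = FALSE] %*% delta[-3])
      V <- fix_b + beta["dist_home_km"] * Dh
      oudr <- rep(as.numeric(dd$oud), each = m)
      V <- V + oudr * (fix_d + delta["dist_home_km"] * Dh)
      V <- sweep(V, 2, apply(V, 2, max))
      P <- exp(V)
      P <- sweep(P, 2, colSums(P), "/")
      CP <- apply(P, 2, cumsum)
      if (m == 1L) CP <- matrix(CP, nrow = 1L)
      u <- stats::runif(length(rows))
      pick <- colSums(CP < rep(u, each = m)) + 1L
      pick <- pmin(pick, m)
      chosen[rows] <- f$facility_id[pick]
      this_vol[[h]] <- table(factor(f$facility_id[pick],
                                    levels = f$facility_id))
    }
    prev_vol <- lapply(this_vol, function(t) {
      v <- as.integer(t); names(v) <- names(t); v
    })
  }
  list(chosen = chosen, networks = do.call(rbind, networks))
}

#' Simulate long-format choice data directly from known coefficients
#'
#' A lightweight companion to [generate_population()] for replication-heavy
#' simulation studies (parameter recovery, test calibration, IIA checks):
#' draws independent choice sets with iid alternative attributes and samples
#' each choice from the implied conditional-logit probabilities. Attribute
#' distributions mimic realistic SNF markets (star ratings 1-5, exponential
#' distances, Bernoulli structure flags).
#'
#' @param n_sets Number of choice sets (discharges).
#' @param n_alts Alternatives per set.
#' @param beta,delta Named coefficient vectors over [SNF_ATTRIBUTES];
#'   unspecified attributes default to zero.
#' @param oud_share Probability a discharge carries the OUD flag.
#' @param n_states Number of state clusters, assigned uniformly to sets.
#' @param seed Integer seed.
#' @return A long-format data frame, one row per (set, alternative), with
#'   `discharge_id`, `facility_id`, `state_id`, `choice`, `oud`, `weight`,
#'   `is_closest`, and the attribute columns.
#' @export
simulate_choice_data <- function(n_sets, n_alts, beta, delta = numeric(0),
                                 oud_share = 0.5, n_states = 10L, seed = 1L) {
  set.seed(seed)
  beta <- complete_coef(beta)
  delta <- complete_coef(delta)
  n <- n_sets * n_alts
  X <- cbind(
    preferred = as.numeric(stats::runif(n) < 0.3),
    stars = sample(1:5, n, replace = TRUE),
    dist_home_km = stats::rexp(n, 1 / 8),
    dist_hospital_km = stats::rexp(n, 1 / 6),
    for_profit = as.numeric(stats::runif(n) < 0.7),
    chain = as.numeric(stats::runif(n) < 0.6),
    hospital_affiliated = as.numeric(stats::runif(n) < 0.08),
    beds = pmax(20, stats::rpois(n, 110)),
    occupancy_pct = pmin(100, pmax(20, stats::rnorm(n, 80, 10))),
    pct_medicaid = pmin(100, pmax(0, stats::rnorm(n, 50, 15)))
  )
  g <- rep(seq_len(n_sets), each = n_alts)
  oud <- stats::runif(n_sets) < oud_share
  v <- drop(X %*% beta) + as.numeric(oud[g]) * drop(X %*% delta)
  vmax <- tapply(v, g, max)[g]
  p <- exp(v - vmax)
  p <- p / tapply(p, g, sum)[g]
  cp <- unlist(tapply(p, g, cumsum), use.names = FALSE)
  u <- rep(stats::runif(n_sets), each = n_alts)
  pick <- tapply(cp < u, g, sum) + 1L
  choice <- integer(n)
  choice[(seq_len(n_sets) - 1L) * n_alts + pmin(pick, n_alts)] <- 1L
  dh <- X[, "dist_home_km"]
  closest <- unlist(tapply(dh, g, function(z) {
    out <- numeric(length(z)); out[which.min(z)] <- 1; out
  }), use.names = FALSE)
  data.frame(
    discharge_id = sprintf("D%06d", g),
    facility_id = sprintf("F%06d", seq_len(n)),
    state_id = sprintf("S%02d", sample.int(n_states, n_sets,
                                           replace = TRUE))[g],
    choice = choice,
    oud = oud[g],
    weight = 1,
    is_closest = closest == 1,
    X,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-discharge binary outcomes with a hospital fixed effect
#'
#' Generates data for testing the within-hospital linear probability model:
#' outcome probability = hospital base rate + `oud_gap` for OUD discharges +
#' small covariate effects, truncated to (0.02, 0.98).
#'
#' @param n Number of discharges.
#' @param n_hospitals Number of hospitals (base rates uniform on 0.3-0.7).
#' @param oud_gap Within-hospital probability gap attached to the OUD flag
#'   (e.g. -0.03).
#' @param oud_share Share of OUD discharges.
#' @param seed Integer seed.
#' @return Data frame with `hospital_id`, `oud`, covariates, and outcome `y`.
#' @export
simulate_lpm_data <- function(n, n_hospitals = 20L, oud_gap = -0.03,
                              oud_share = 0.5, seed = 1L) {
  set.seed(seed)
  hosp <- sample.int(n_hospitals, n, replace = TRUE)
  base <- stats::runif(n_hospitals, 0.3, 0.7)
  oud <- stats::runif(n) < oud_share
  age <- round(pmin(100, pmax(18, stats::rnorm(n, 75, 10))))
  female <- stats::runif(n) < 0.6
  dual <- stats::runif(n) < 0.3
  elix <- pmin(15L, stats::rpois(n, 3))
  p <- base[hosp] + oud_gap * oud + 0.002 * (age - 75) +
    0.01 * female - 0.02 * dual - 0.005 * elix
  p <- pmin(0.98, pmax(0.02, p))
  data.frame(
    hospital_id = sprintf("H%03d", hosp),
    oud = oud, age = age, female = female, dual_eligible = dual,
    elixhauser = as.integer(elix),
    y = as.integer(stats::runif(n) < p),
    stringsAsFactors = FALSE
  )
}

#' Inject records that violate the cohort inclusion rules
#'
#' Deterministically appends constructed discharge records that each violate
#' exactly one cohort filter, for testing the exclusion machinery. The
#' `spec` list may request counts under the names `lag2` (SNF admission two
#' days after discharge), `prior_snf` (a SNF stay in the prior year),
#' `out_of_state` (chosen SNF in a different state than the hospital),
#' `missing_coords` (missing home geocode), and `underage` (age below 18).
#' An empty spec returns the tables unchanged.
#'
#' @param population A list as returned by [generate_population()].
#' @param spec Named list of non-negative counts.
#' @return The population with modified `discharges`.
#' @export
inject_edge_cases <- function(population, spec = list()) {
  if (!length(spec)) return(population)
  bad <- setdiff(names(spec), c("lag2", "prior_snf", "out_of_state",
                                "missing_coords", "underage"))
  if (length(bad)) stop("unknown edge-case kind(s): ",
                        paste(bad, collapse = ", "))
  d <- population$discharges
  f <- population$facilities
  h <- population$hospitals
  proto <- d[1L, ]
  rows <- list()
  k <- 0L
  add <- function(rec, kind, i) {
    k <<- k + 1L
    rec$discharge_id <- sprintf("EDGE_%s_%03d", kind, i)
    rec$patient_id <- sprintf("EDGEP_%s_%03d", kind, i)
    rows[[k]] <<- rec
  }
  for (i in seq_len(spec$lag2 %||% 0L)) {
    r <- proto; r$snf_admission_lag_days <- 2L
    add(r, "LAG2", i)
  }
  for (i in seq_len(spec$prior_snf %||% 0L)) {
    r <- proto; r$had_prior_year_snf <- TRUE
    add(r, "PRIOR", i)
  }
  for (i in seq_len(spec$out_of_state %||% 0L)) {
    hs <- h$state_id[h$hospital_id == proto$hospital_id]
    other <- f$facility_id[f$state_id != hs]
    if (!length(other)) stop("cannot construct out-of-state case: ",
                             "only one state present")
    r <- proto; r$chosen_facility_id <- other[1L]
    add(r, "XSTATE", i)
  }
  for (i in seq_len(spec$missing_coords %||% 0L)) {
    r <- proto; r$home_latitude <- NA_real_; r$home_longitude <- NA_real_
    add(r, "NOGEO", i)
  }
  for (i in seq_len(spec$underage %||% 0L)) {
    r <- proto; r$age <- 17
    add(r, "MINOR", i)
  }
  population$discharges <- rbind(d, do.call(rbind, rows))
  population
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated population to delimited tables plus a sidecar
#'
#' Writes `facilities.csv`, `hospitals.csv`, `discharges.csv` (UTF-8,
#' ISO-8601 dates, empty fields for missing values) and
#' `ground_truth.json` holding the seed and true coefficients.
#'
#' @param population A list from [generate_population()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(population$facilities, file.path(dir, "facilities.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(population$hospitals, file.path(dir, "hospitals.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(population$discharges, file.path(dir, "discharges.csv"),
                   row.names = FALSE, na = "")
  gt <- population$ground_truth
  jsonlite::write_json(
    list(seed = gt$config$seed,
         true_beta = as.list(gt$true_beta),
         true_delta = as.list(gt$true_delta),
         propensity_coefs = as.list(gt$propensity_coefs),
         propensity_intercept = gt$propensity_intercept),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a population written by [write_population()]
#' @param dir Directory holding the CSV tables.
#' @return List with `facilities`, `hospitals`, `discharges`.
#' @export
read_population <- function(dir) {
  d <- utils::read.csv(file.path(dir, "discharges.csv"),
                       stringsAsFactors = FALSE)
  d$discharge_date <- as.Date(d$discharge_date)
  for (col in c("had_prior_year_snf", "oud", "dual_eligible",
                "medicare_advantage", "esrd_eligibility")) {
    d[[col]] <- as.logical(d[[col]])
  }
  f <- utils::read.csv(file.path(dir, "facilities.csv"),
                       stringsAsFactors = FALSE)
  for (col in c("for_profit", "chain", "hospital_affiliated")) {
    f[[col]] <- as.logical(f[[col]])
  }
  list(
    facilities = f,
    hospitals = utils::read.csv(file.path(dir, "hospitals.csv"),
                                stringsAsFactors = FALSE),
    discharges = d
  )
}
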