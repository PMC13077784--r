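# End-to-end pipeline orchestration: simulate -> filter -> build -> match ->
# weight -> fit-lpm -> fit-clogit -> margins -> iia, with per-stage outputs,
# a structured count log, and resumable stages.

#' Pipeline configuration
#'
#' Collects every analysis parameter with the study defaults: a 22 km
#' choice-set radius, 15-nearest rule, 0.50 preferred volume-share threshold
#' (with a 0.10-0.80 sensitivity grid), 1:1 matching within +/- 2 days,
#' age-spline knot at 65, score trimming at \[0.01, 0.99\], and the 4-5 star
#' high-quality rule. The resolved configuration is written next to every
#' run's outputs.
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param generator A [generator_config()] for the synthetic stage (its own
#'   seed is overridden by `seed`).
#' @param preferred_threshold,sensitivity_grid Volume-share threshold and
#'   sensitivity grid.
#' @param radius_km,k_nearest Choice-set rules.
#' @param match_ratio,match_window_days Matching parameters.
#' @param knot_age,trim_bounds Propensity spline knot and trimming bounds.
#' @param high_quality_stars Ratings counted as high-quality.
#' @param iia_drop_fractions Thinning fractions for the IIA check.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = generator_config(),
                            preferred_threshold = 0.5,
                            sensitivity_grid = seq(0.1, 0.8, 0.1),
                            radius_km = 22,
                            k_nearest = 15L,
                            match_ratio = 1L,
                            match_window_days = 2L,
                            knot_age = 65,
                            trim_bounds = c(0.01, 0.99),
                            high_quality_stars = c(4L, 5L),
                            iia_drop_fractions = c(0.05, 0.10, 0.20)) {
  generator$seed <- as.integer(seed)
  structure(list(
    seed = as.integer(seed), generator = generator,
    preferred_threshold = preferred_threshold,
    sensitivity_grid = sensitivity_grid,
    radius_km = radius_km, k_nearest = as.integer(k_nearest),
    match_ratio = as.integer(match_ratio),
    match_window_days = as.integer(match_window_days),
    knot_age = knot_age, trim_bounds = trim_bounds,
    high_quality_stars = as.integer(high_quality_stars),
    iia_drop_fractions = iia_drop_fractions
  ), class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 0L, match = 101L, iia = 202L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing each stage's tables under
#' `out_dir`. A stage whose output files already exist is skipped, so
#' deleting an intermediate re-executes only that stage and everything
#' downstream. All randomness flows from the config seed through named
#' per-stage substreams, making two runs with the same config byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the run directory and the in-memory stage
#'   results (`population`, `kept`, `exclusion_log`, `hy_sets`,
#'   `choice_table`, `cohort`, `propensity`, `ipw`, `lpm`, `clogit`,
#'   `clogit_ipw`, `margins`, `iia`, `log`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- unclass(config)
  cfg_json$generator <- unclass(cfg_json$generator)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list()
  note <- function(stage, ...) {
    counts <- c(...)
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, key = names(counts), count = as.numeric(counts),
      stringsAsFactors = FALSE)
  }
  path <- function(f) file.path(out_dir, f)
  done <- function(...) all(file.exists(vapply(list(...), path, "")))

  # -- simulate ------------------------------------------------------------
  if (!done("discharges.csv")) {
    gcfg <- config$generator
    gcfg$seed <- stage_seed(config, "simulate")
    pop <- generate_population(gcfg)
    write_population(pop, out_dir)
  }
  pop <- read_population(out_dir)
  note("simulate", n_facilities = nrow(pop$facilities),
       n_hospitals = nrow(pop$hospitals),
       n_discharges = nrow(pop$discharges),
       n_oud = sum(pop$discharges$oud))

  # -- filter --------------------------------------------------------------
  flt <- apply_cohort_filters(pop$discharges, pop$facilities, pop$hospitals)
  analysis_years <- setdiff(
    unique(as.integer(format(pop$discharges$discharge_date, "%Y"))),
    min(as.integer(format(pop$discharges$discharge_date, "%Y"))))
  kept <- flt$kept[as.integer(format(flt$kept$discharge_date, "%Y")) %in%
                     analysis_years, , drop = FALSE]
  utils::write.csv(flt$exclusion_log, path("exclusion_log.csv"),
                   row.names = FALSE)
  note("filter", n_input = nrow(pop$discharges),
       n_after_rules = nrow(flt$kept), n_analysis_years = nrow(kept))

  # -- build ---------------------------------------------------------------
  hy_sets <- build_hospital_year_sets(
    kept, pop$facilities, pop$hospitals,
    volume_discharges = pop$discharges,
    radius_km = config$radius_km, k_nearest = config$k_nearest,
    threshold = config$preferred_threshold)
  choice_table <- assemble_choice_data(kept, hy_sets, pop$facilities,
                                       pop$hospitals)
  if (!done("choice_long.csv")) {
    utils::write.csv(choice_table, path("choice_long.csv"),
                     row.names = FALSE)
    utils::write.csv(hy_sets, path("networks.csv"), row.names = FALSE)
  }
  note("build", n_choice_sets = length(unique(choice_table$discharge_id)),
       n_alternatives = nrow(choice_table),
       n_stars_imputed = attr(choice_table, "n_stars_imputed") %||% 0)

  # -- match ---------------------------------------------------------------
  cohort <- match_discharges(kept, ratio = config$match_ratio,
                             window_days = config$match_window_days,
                             seed = stage_seed(config, "match"))
  if (!done("matched.csv")) {
    utils::write.csv(cohort$pairs, path("matched.csv"), row.names = FALSE)
  }
  note("match", n_cases_matched = cohort$n_cases_matched,
       n_unmatched_oud = cohort$unmatched_oud,
       n_pairs = nrow(cohort$pairs))

  # -- weight --------------------------------------------------------------
  mids <- matched_ids(cohort)
  md <- kept[kept$discharge_id %in% mids, , drop = FALSE]
  prop <- fit_propensity(md, knot_age = config$knot_age)
  ipw <- compute_ipw(prop, trim_bounds = config$trim_bounds)
  ipw$quintile <- assign_quintiles(ipw$score)
  if (!done("weights.csv")) {
    utils::write.csv(ipw, path("weights.csv"), row.names = FALSE)
  }
  note("weight", n_matched_sample = nrow(md),
       n_trimmed = attr(ipw, "n_trimmed"))

  # -- fit-lpm (full filtered sample) --------------------------------------
  outcomes <- make_outcomes(kept, hy_sets, pop$facilities)
  lpm_data <- cbind(kept, outcomes[match(kept$discharge_id,
                                         outcomes$discharge_id), -1])
  covs <- c("oud", "age", "sex", "race_ethnicity", "dual_eligible",
            "ruca", "elixhauser")
  lpm <- list(
    preferred = fit_lpm_fe(lpm_data, "preferred_entry", covs),
    quality = fit_lpm_fe(lpm_data, "high_quality_entry", covs),
    quality_given_preferred = fit_lpm_fe(
      lpm_data, "high_quality_given_preferred", covs)
  )
  if (!done("lpm_results.csv")) {
    lt <- do.call(rbind, lapply(names(lpm), function(nm)
      cbind(outcome = nm, lpm[[nm]]$table)))
    utils::write.csv(lt, path("lpm_results.csv"), row.names = FALSE)
  }
  note("fit-lpm", n_preferred_model = lpm$preferred$n_used,
       n_quality_model = lpm$quality$n_used)

  # -- fit-clogit (matched subsample) --------------------------------------
  mct <- choice_table[choice_table$discharge_id %in% mids, , drop = FALSE]
  fit <- fit_clogit(mct)
  wtab <- stats::setNames(ipw$weight, ipw$discharge_id)
  wct <- mct[mct$discharge_id %in% ipw$discharge_id, , drop = FALSE]
  wct$weight <- unname(wtab[wct$discharge_id])
  fit_ipw <- fit_clogit(wct)
  if (!done("clogit_results.csv")) {
    ctab <- rbind(cbind(model = "matched", coef_table(fit)),
                  cbind(model = "ipw", coef_table(fit_ipw)))
    utils::write.csv(ctab, path("clogit_results.csv"), row.names = FALSE)
  }
  note("fit-clogit", n_sets = fit$n_choice_sets,
       n_alternatives = fit$n_alternatives,
       converged = as.numeric(fit$converged))

  # -- margins -------------------------------------------------------------
  # quintile subclassification is the alternative to weighting, so the
  # within-quintile fits are unweighted (on the trimmed matched sample)
  qtab <- ipw[, c("discharge_id", "quintile")]
  tct <- mct[mct$discharge_id %in% ipw$discharge_id, , drop = FALSE]
  qfits <- suppressWarnings(fit_by_quintile(tct, qtab))
  mrows <- list()
  for (manip in c("preferred", "stars")) {
    mrows[[length(mrows) + 1L]] <-
      closest_snf_margin(fit, mct, manip, label = "overall")
    mrows[[length(mrows) + 1L]] <-
      closest_snf_margin(fit_ipw, wct, manip, label = "ipw")
    for (q in names(qfits)) {
      sub <- tct[tct$discharge_id %in%
                   qtab$discharge_id[qtab$quintile == as.integer(q)], ]
      mrows[[length(mrows) + 1L]] <- closest_snf_margin(
        qfits[[q]], sub, manip, label = paste0("quintile_", q))
    }
  }
  margins <- do.call(rbind, mrows)
  if (!done("margins.csv")) {
    utils::write.csv(margins, path("margins.csv"), row.names = FALSE)
  }
  note("margins", n_rows = nrow(margins))

  # -- iia -----------------------------------------------------------------
  iia <- lapply(config$iia_drop_fractions, function(fr)
    iia_thinning_check(mct, fr, seed = stage_seed(config, "iia"),
                       full_fit = fit))
  names(iia) <- paste0("drop_", config$iia_drop_fractions)
  if (!done("iia_results.csv")) {
    it <- do.call(rbind, lapply(iia, function(x)
      cbind(drop_fraction = x$drop_fraction, x$comparison)))
    utils::write.csv(it, path("iia_results.csv"), row.names = FALSE)
  }
  note("iia", max_shift_in_se = max(vapply(
    iia, function(x) max(abs(x$comparison$shift_in_se)), numeric(1))))

  log_df <- do.call(rbind, log)
  utils::write.csv(log_df, path("pipeline_log.csv"), row.names = FALSE)
  invisible(list(
    out_dir = out_dir, population = pop, kept = kept,
    exclusion_log = flt$exclusion_log, hy_sets = hy_sets,
    choice_table = choice_table, cohort = cohort, propensity = prop,
    ipw = ipw, lpm = lpm, clogit = fit, clogit_ipw = fit_ipw,
    quintile_fits = qfits, margins = margins, iia = iia, log = log_df
  ))
}

#' Covariate balance across full, matched, and weighted samples
#'
#' A descriptive balance report: per-covariate means (or percentages) by OUD
#' group with standardized mean differences, in three panels — the full
#' filtered sample, the matched sample, and the matched sample under IPW.
#'
#' @param discharges Full filtered discharge table.
#' @param cohort A [match_discharges()] result (optional).
#' @param ipw An IPW table from [compute_ipw()] (optional).
#' @return Data frame: `panel`, `covariate`, `mean_nonoud`, `mean_oud`,
#'   `smd`.
#' @export
summarize_balance <- function(discharges, cohort = NULL, ipw = NULL) {
  covs <- list(
    age = function(d) d$age,
    female = function(d) as.numeric(d$sex == "female"),
    dual_eligible = function(d) as.numeric(d$dual_eligible),
    medicare_advantage = function(d) as.numeric(d$medicare_advantage),
    esrd_eligibility = function(d) as.numeric(d$esrd_eligibility),
    elixhauser = function(d) d$elixhauser
  )
  panel <- function(d, name, w = NULL) {
    if (!any(d$oud) || !any(!d$oud)) {
      warning("panel '", name, "' has an empty exposure group")
      return(data.frame(panel = name, covariate = names(covs),
                        mean_nonoud = NA_real_, mean_oud = NA_real_,
                        smd = NA_real_, stringsAsFactors = FALSE))
    }
    if (is.null(w)) w <- rep(1, nrow(d))
    do.call(rbind, lapply(names(covs), function(nm) {
      x <- covs[[nm]](d)
      data.frame(
        panel = name, covariate = nm,
        mean_nonoud = stats::weighted.mean(x[!d$oud], w[!d$oud]),
        mean_oud = stats::weighted.mean(x[d$oud], w[d$oud]),
        smd = smd(x, d$oud, w), stringsAsFactors = FALSE)
    }))
  }
  out <- panel(discharges, "full")
  if (!is.null(cohort)) {
    md <- discharges[discharges$discharge_id %in% matched_ids(cohort), ]
    out <- rbind(out, panel(md, "matched"))
    if (!is.null(ipw)) {
      wd <- md[match(ipw$discharge_id, md$discharge_id), ]
      wd <- wd[!is.na(wd$discharge_id), ]
      ww <- ipw$weight[match(wd$discharge_id, ipw$discharge_id)]
      out <- rbind(out, panel(wd, "matched_ipw", ww))
    }
  }
  rownames(out) <- NULL
  out
}
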