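# Matching on hospital and discharge date, propensity-score estimation,
# inverse-probability weights, and quintile subclassification.

#' Match OUD discharges to non-OUD discharges on hospital and date
#'
#' Greedy 1:k matching without replacement. OUD cases are processed in a
#' seeded random order; eligible controls share the discharging hospital and
#' lie within `window_days` of the case's discharge date, and are ranked by
#' absolute date difference with seeded random tie-breaks. Cases with no
#' eligible control are dropped and counted.
#'
#' @param discharges Discharge table with `discharge_id`, `hospital_id`,
#'   `discharge_date`, and logical `oud`.
#' @param ratio Maximum controls per case: 1, 2, or 3.
#' @param window_days Calendar-day window (default 2, i.e. +/- 2 days).
#' @param seed Integer seed for the processing order and tie-breaks.
#' @return An object of class `"matched_cohort"`: a list with `pairs`
#'   (data frame `oud_discharge_id`, `control_discharge_id`, `control_rank`),
#'   `ratio`, `window_days`, `unmatched_oud`, and `n_cases_matched`.
#' @export
match_discharges <- function(discharges, ratio = 1L, window_days = 2L,
                             seed = 1L) {
  if (!ratio %in% 1:3) stop("ratio must be 1, 2, or 3")
  set.seed(seed)
  d <- discharges
  day <- as.integer(d$discharge_date)
  cases <- which(d$oud)
  controls <- which(!d$oud)
  tiebreak <- stats::runif(nrow(d))
  case_order <- cases[sample.int(length(cases))]

  ctl_by_hosp <- split(controls, d$hospital_id[controls])
  used <- logical(nrow(d))
  pairs <- vector("list", length(cases))
  unmatched <- 0L
  k <- 0L
  for (i in case_order) {
    cand <- ctl_by_hosp[[d$hospital_id[i]]]
    if (!is.null(cand)) {
      cand <- cand[!used[cand]]
      diff <- abs(day[cand] - day[i])
      cand <- cand[diff <= window_days]
    }
    if (is.null(cand) || !length(cand)) {
      unmatched <- unmatched + 1L
      next
    }
    diff <- abs(day[cand] - day[i])
    take <- cand[order(diff, tiebreak[cand])][seq_len(min(ratio,
                                                          length(cand)))]
    used[take] <- TRUE
    k <- k + 1L
    pairs[[k]] <- data.frame(
      oud_discharge_id = d$discharge_id[i],
      control_discharge_id = d$discharge_id[take],
      control_rank = seq_along(take),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    pairs = if (k) do.call(rbind, pairs[seq_len(k)]) else
      data.frame(oud_discharge_id = character(0),
                 control_discharge_id = character(0),
                 control_rank = integer(0)),
    ratio = as.integer(ratio),
    window_days = as.integer(window_days),
    unmatched_oud = unmatched,
    n_cases_matched = k
  ), class = "matched_cohort")
}

#' Discharge ids in the matched sample
#' @param cohort A [match_discharges()] result.
#' @return Character vector of case and control discharge ids.
#' @export
matched_ids <- function(cohort) {
  unique(c(cohort$pairs$oud_discharge_id,
           cohort$pairs$control_discharge_id))
}

# design matrix for the propensity model: two-piece linear age spline,
# sex, race/ethnicity dummies, dual eligibility, Medicare Advantage, ESRD
# eligibility, RUCA dummies, Elixhauser index
propensity_design <- function(d, knot_age = 65) {
  X <- cbind(
    age1 = pmin(d$age, knot_age),
    age2 = pmax(d$age - knot_age, 0),
    female = as.numeric(d$sex == "female"),
    dual = as.numeric(d$dual_eligible),
    ma = as.numeric(d$medicare_advantage),
    esrd = as.numeric(d$esrd_eligibility),
    elix = d$elixhauser
  )
  for (lev in setdiff(unique(d$race_ethnicity), "white")) {
    X <- cbind(X, as.numeric(d$race_ethnicity == lev))
    colnames(X)[ncol(X)] <- paste0("race_", gsub(" ", "_", lev))
  }
  for (lev in setdiff(unique(d$ruca), "metropolitan")) {
    X <- cbind(X, as.numeric(d$ruca == lev))
    colnames(X)[ncol(X)] <- paste0("ruca_", gsub(" ", "_", lev))
  }
  X
}

#' Fit the OUD propensity model
#'
#' Maximum-likelihood logistic regression of the OUD flag on age (two-piece
#' linear spline with knot `knot_age`), sex, race/ethnicity, dual
#' eligibility, Medicare Advantage enrollment, ESRD eligibility, RUCA
#' category, and the Elixhauser index. Constant covariate columns are
#' dropped with a warning; complete or quasi-complete separation fails with
#' a diagnostic naming the offending covariate.
#'
#' @param d Discharge table restricted to the matched sample.
#' @param knot_age Age-spline knot in years (default 65, the Medicare
#'   eligibility boundary).
#' @return Object of class `"propensity_fit"`: list with `coefficients`,
#'   `scores` (data frame `discharge_id`, `oud`, `score`), `knot_age`,
#'   `dropped` (names of dropped constant columns), and the `glm` fit.
#' @export
fit_propensity <- function(d, knot_age = 65) {
  X <- propensity_design(d, knot_age)
  const <- apply(X, 2, function(x) max(x) == min(x))
  if (any(const)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  df <- data.frame(oud = as.numeric(d$oud), X)
  fit <- suppressWarnings(
    stats::glm(oud ~ ., data = df, family = stats::binomial())
  )
  cf <- stats::coef(fit)[-1L]
  if (!fit$converged || any(abs(cf) > 15)) {
    worst <- names(cf)[which.max(abs(cf))]
    stop("propensity model shows separation; offending covariate: ", worst)
  }
  e <- stats::fitted(fit)
  structure(list(
    coefficients = stats::coef(fit),
    scores = data.frame(discharge_id = d$discharge_id, oud = d$oud,
                        score = as.numeric(e), stringsAsFactors = FALSE),
    knot_age = knot_age,
    dropped = colnames(propensity_design(d, knot_age))[const],
    glm = fit
  ), class = "propensity_fit")
}

#' Inverse-probability-of-treatment weights from a propensity fit
#'
#' ATE-style weights: `1/e` for OUD discharges and `1/(1-e)` for controls,
#' computed after dropping records whose score falls outside the trimming
#' bounds, then normalized to mean 1 within each exposure group.
#'
#' @param fit A [fit_propensity()] result.
#' @param trim_bounds Length-2 numeric: scores outside this interval are
#'   trimmed (default `c(0.01, 0.99)`).
#' @return Data frame `discharge_id`, `oud`, `score`, `weight` on the
#'   trimmed sample, with attribute `"n_trimmed"`.
#' @export
compute_ipw <- function(fit, trim_bounds = c(0.01, 0.99)) {
  s <- fit$scores
  keep <- s$score >= trim_bounds[1] & s$score <= trim_bounds[2]
  if (!any(keep)) stop("all records trimmed; check the propensity model")
  s <- s[keep, , drop = FALSE]
  w <- ifelse(s$oud, 1 / s$score, 1 / (1 - s$score))
  for (g in c(TRUE, FALSE)) {
    idx <- s$oud == g
    if (any(idx)) w[idx] <- w[idx] / mean(w[idx])
  }
  out <- data.frame(s, weight = w, stringsAsFactors = FALSE)
  attr(out, "n_trimmed") <- sum(!keep)
  out
}

#' Assign pooled propensity-score quintiles
#'
#' Quintile cut points come from the pooled (both-group) score distribution
#' of the trimmed sample; counts per quintile are near-equal up to ties.
#'
#' @param scores Numeric vector of (trimmed) propensity scores.
#' @return Integer vector of labels 1-5, monotone in score.
#' @export
assign_quintiles <- function(scores) {
  if (length(unique(scores)) < 5L) {
    stop("fewer than 5 distinct propensity scores; ",
         "quintile subclassification undefined")
  }
  br <- stats::quantile(scores, probs = seq(0, 1, 0.2), names = FALSE)
  if (anyDuplicated(br)) {
    stop("tied propensity-score quantiles; quintile cut points are not ",
         "distinct (scores too coarse)")
  }
  as.integer(cut(scores, breaks = br, include.lowest = TRUE, labels = FALSE))
}

#' Standardized mean difference between exposure groups
#'
#' Difference in (optionally weighted) group means divided by the pooled
#' unweighted standard deviation, so that weighting moves means but not the
#' denominator.
#'
#' @param x Numeric covariate.
#' @param group Logical exposure indicator.
#' @param w Optional weights.
#' @return The standardized mean difference (treated minus control).
#' @export
smd <- function(x, group, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  m1 <- stats::weighted.mean(x[group], w[group])
  m0 <- stats::weighted.mean(x[!group], w[!group])
  sp <- sqrt((stats::var(x[group]) + stats::var(x[!group])) / 2)
  if (sp == 0) return(0)
  (m1 - m0) / sp
}
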