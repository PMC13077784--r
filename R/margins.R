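# Counterfactual closest-SNF marginal effects by OUD group, interaction-based
# difference tests, and the choice-set thinning check of the IIA assumption.

# closest row index per set: minimum home distance, facility-id tie-break
closest_rows <- function(ct) {
  if (!is.null(ct$is_closest)) return(which(ct$is_closest))
  g <- factor(ct$discharge_id, levels = unique(ct$discharge_id))
  idx <- split(seq_len(nrow(ct)), g)
  vapply(idx, function(i) {
    i[order(ct$dist_home_km[i], ct$facility_id[i])[1L]]
  }, integer(1))
}

#' Counterfactual closest-SNF marginal effects
#'
#' For every discharge, re-evaluates the fitted choice probabilities after
#' manipulating its closest SNF's attribute — preferred status set to 1
#' versus 0, or star rating raised by one (capped at 5) — holding all other
#' characteristics of every alternative fixed, and records the change in the
#' closest SNF's predicted probability. Changes are averaged within OUD
#' groups, in percentage points; when the fit is weighted the group averages
#' use the same weights. Fully deterministic given the fit.
#'
#' Under the star manipulation, discharges whose closest SNF already has 5
#' stars admit no manipulation under the linear star entry; they are
#' excluded from the quality margin and counted, as are closest SNFs with a
#' missing rating.
#'
#' @param fit A [fit_clogit()] object.
#' @param choice_table Long-format choice table the margins are evaluated
#'   on (typically the estimation table).
#' @param manipulation `"preferred"` (flip 0 to 1) or `"stars"` (+1 star).
#' @param label Stratum label recorded in the output (e.g. `"overall"`).
#' @return Object of class `"margin_table"`: a one-row data frame with
#'   `attribute`, `margin_nonoud_pp`, `margin_oud_pp`, `difference_pp`
#'   (OUD minus non-OUD), `p_interaction`, `n_nonoud`, `n_oud`,
#'   `n_excluded`, `stratum`.
#' @export
closest_snf_margin <- function(fit, choice_table,
                               manipulation = c("preferred", "stars"),
                               label = "overall") {
  manipulation <- match.arg(manipulation)
  ct <- choice_table
  cr <- closest_rows(ct)
  n_sets <- length(cr)

  lo <- ct
  hi <- ct
  keep <- rep(TRUE, n_sets)
  if (manipulation == "preferred") {
    lo$preferred[cr] <- 0
    hi$preferred[cr] <- 1
  } else {
    s <- ct$stars[cr]
    keep <- !is.na(s) & s < 5
    hi$stars[cr] <- ifelse(keep, s + 1, s)
  }
  p_lo <- predict_clogit_prob(fit, lo)[cr]
  p_hi <- predict_clogit_prob(fit, hi)[cr]
  dp <- 100 * (p_hi - p_lo)

  oud <- ct$oud[cr]
  w <- if (fit$weighted) fit$set_weights else rep(1, n_sets)
  if (length(w) != n_sets) w <- rep(1, n_sets)
  gmean <- function(grp) {
    sel <- keep & oud == grp
    if (!any(sel)) return(NA_real_)
    stats::weighted.mean(dp[sel], w[sel])
  }
  m0 <- gmean(FALSE)
  m1 <- gmean(TRUE)
  attr_name <- if (manipulation == "preferred") "preferred" else "stars"
  out <- data.frame(
    attribute = attr_name,
    margin_nonoud_pp = m0,
    margin_oud_pp = m1,
    difference_pp = m1 - m0,
    p_interaction = margin_difference_test(fit, attr_name),
    n_nonoud = sum(keep & !oud),
    n_oud = sum(keep & oud),
    n_excluded = sum(!keep),
    stratum = label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("margin_table", "data.frame")
  out
}

#' Wald test of the OUD-by-attribute interaction
#'
#' Two-sided test of the interaction coefficient for an attribute, using the
#' fit's cluster-robust variance. This is the significance test attached to
#' the difference column of the marginal-effect table: group differences in
#' closest-SNF margins are tested through the interaction term, not through
#' the simulated margins themselves.
#'
#' @param fit A [fit_clogit()] object.
#' @param attribute Attribute name (e.g. `"preferred"`, `"stars"`).
#' @return Two-sided p-value.
#' @export
margin_difference_test <- function(fit, attribute) {
  term <- paste0("oud_x_", attribute)
  if (!term %in% names(fit$coefficients)) {
    stop("no interaction term for attribute '", attribute, "' in the fit")
  }
  se <- sqrt(fit$vcov[term, term])
  z <- fit$coefficients[term] / se
  unname(2 * stats::pnorm(-abs(z)))
}

#' Choice-set thinning check of the IIA assumption
#'
#' Randomly removes a fraction of non-chosen alternatives from each choice
#' set (the chosen alternative is never removable and at least one
#' non-chosen alternative is always retained), refits the model, and
#' reports per-coefficient shifts and their ratio to the full-model
#' cluster-robust standard errors. Under a correctly specified conditional
#' logit the relative odds between remaining alternatives are unaffected by
#' removal, so coefficient drift should stay within sampling error.
#'
#' @param choice_table Long-format choice table.
#' @param drop_fraction Probability each non-chosen alternative is removed,
#'   in \[0, 0.20\].
#' @param seed Integer seed for the removal draws.
#' @param full_fit Optional pre-computed full-sample [fit_clogit()] (refit
#'   if omitted).
#' @param ... Passed to [fit_clogit()] for both fits.
#' @return Object of class `"iia_check"`: list with `drop_fraction`,
#'   `comparison` (data frame: term, full, thinned, shift, se_full,
#'   shift_in_se), `n_rows_removed`, and the two fits.
#' @export
iia_thinning_check <- function(choice_table, drop_fraction, seed = 1L,
                               full_fit = NULL, ...) {
  if (drop_fraction < 0 || drop_fraction > 0.20) {
    stop("drop_fraction must lie in [0, 0.20]")
  }
  if (is.null(full_fit)) full_fit <- fit_clogit(choice_table, ...)
  set.seed(seed)
  ct <- choice_table
  u <- stats::runif(nrow(ct))
  drop <- ct$choice == 0L & u < drop_fraction
  # retain at least one non-chosen alternative per set (skip removal in
  # sets that would fall below 2 alternatives)
  g <- factor(ct$discharge_id, levels = unique(ct$discharge_id))
  for (i in split(seq_len(nrow(ct)), g)) {
    nonch <- i[ct$choice[i] == 0L]
    if (length(nonch) && all(drop[nonch])) {
      drop[nonch[which.max(u[nonch])]] <- FALSE
    }
  }
  thinned <- ct[!drop, , drop = FALSE]
  thin_fit <- fit_clogit(thinned, ...)
  se <- sqrt(diag(full_fit$vcov))
  cmp <- data.frame(
    term = names(full_fit$coefficients),
    full = unname(full_fit$coefficients),
    thinned = unname(thin_fit$coefficients),
    shift = unname(thin_fit$coefficients - full_fit$coefficients),
    se_full = unname(se),
    shift_in_se = unname((thin_fit$coefficients - full_fit$coefficients) /
                           se),
    stringsAsFactors = FALSE
  )
  structure(list(drop_fraction = drop_fraction, comparison = cmp,
                 n_rows_removed = sum(drop), full_fit = full_fit,
                 thinned_fit = thin_fit),
            class = "iia_check")
}

#' @export
print.iia_check <- function(x, ...) {
  cat(sprintf("IIA thinning check: %.0f%% of non-chosen alternatives removed (%d rows)\n",
              100 * x$drop_fraction, x$n_rows_removed))
  cat(sprintf("max |shift| / full-model SE = %.3f\n",
              max(abs(x$comparison$shift_in_se))))
  print(x$comparison, digits = 4)
  invisible(x)
}
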