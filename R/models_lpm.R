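# Linear probability models with hospital fixed effects, estimated by the
# within transformation, with heteroskedasticity-robust standard errors.

#' Per-discharge binary outcomes
#'
#' Derives the three outcomes of the fixed-effect models: entry into a
#' preferred SNF, entry into a high-quality (4-5 star) SNF, and — among
#' preferred-SNF discharges — entry into a high-quality preferred SNF.
#' Discharges whose chosen SNF has a missing star rating get `NA` for the
#' quality outcomes (they are excluded listwise from quality models but kept
#' for the preferred outcome); the count is recorded in the
#' `"n_missing_rating"` attribute.
#'
#' @param kept_discharges Filtered discharge table.
#' @param hy_sets Hospital-year sets from [build_hospital_year_sets()]
#'   (supplies the preferred flag of the chosen SNF).
#' @param facilities Facility table (supplies raw star ratings).
#' @return Data frame `discharge_id`, `preferred_entry`,
#'   `high_quality_entry`, `high_quality_given_preferred`.
#' @export
make_outcomes <- function(kept_discharges, hy_sets, facilities) {
  d <- kept_discharges
  yr <- as.integer(format(d$discharge_date, "%Y"))
  key <- paste(hy_sets$hospital_id, hy_sets$year, hy_sets$facility_id)
  pref <- stats::setNames(hy_sets$preferred, key)
  p <- unname(pref[paste(d$hospital_id, yr, d$chosen_facility_id)])
  stars <- stats::setNames(facilities$star_rating, facilities$facility_id)
  s <- unname(stars[d$chosen_facility_id])
  hq <- ifelse(is.na(s), NA, s %in% c(4L, 5L))
  out <- data.frame(
    discharge_id = d$discharge_id,
    preferred_entry = p,
    high_quality_entry = hq,
    high_quality_given_preferred = ifelse(p, hq, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_missing_rating") <- sum(is.na(s))
  out
}

#' Linear probability model with hospital fixed effects
#'
#' Estimates a binary-outcome OLS with hospital intercepts absorbed by the
#' within (group-demeaning) transformation. Rows with a missing outcome are
#' dropped listwise; hospitals contributing a single (remaining) row are
#' singletons that cannot identify their own fixed effect and are dropped
#' and counted. Standard errors are heteroskedasticity-robust (HC1) with
#' degrees of freedom corrected for the absorbed fixed effects.
#'
#' @param data Per-discharge data frame.
#' @param outcome Name of the binary outcome column.
#' @param covariates Character vector of covariate columns; factors and
#'   character columns expand to treatment-coded dummies.
#' @param fe Name of the fixed-effect grouping column (default
#'   `"hospital_id"`).
#' @return Object of class `"lpm_fit"`: list with `outcome`, `table`
#'   (term, estimate, se, ci_low, ci_high, p), `n_used`,
#'   `n_singletons_dropped`, `n_missing_outcome`, `n_groups`, `df_residual`.
#' @export
fit_lpm_fe <- function(data, outcome, covariates, fe = "hospital_id") {
  y <- data[[outcome]]
  keep <- !is.na(y)
  n_missing <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  y <- as.numeric(y[keep])

  g <- d[[fe]]
  sing <- names(which(table(g) == 1L))
  n_sing <- sum(g %in% sing)
  if (n_sing) {
    keep2 <- !g %in% sing
    d <- d[keep2, , drop = FALSE]
    y <- y[keep2]
    g <- g[keep2]
  }
  if (!nrow(d)) stop("no observations left after dropping singletons")

  mf <- d[, covariates, drop = FALSE]
  for (j in seq_along(mf)) {
    if (is.logical(mf[[j]])) mf[[j]] <- as.numeric(mf[[j]])
    if (is.character(mf[[j]])) mf[[j]] <- factor(mf[[j]])
  }
  X <- stats::model.matrix(~ ., mf)[, -1, drop = FALSE]

  demean <- function(v) v - ave(v, g)
  yd <- demean(y)
  Xd <- apply(X, 2, demean)
  if (!is.matrix(Xd)) Xd <- matrix(Xd, ncol = ncol(X),
                                   dimnames = list(NULL, colnames(X)))

  G <- length(unique(g))
  if (all(abs(yd) < 1e-12)) {
    warning("outcome constant within every ", fe,
            "; all slope coefficients are 0")
    tab <- data.frame(term = colnames(X), estimate = 0, se = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(outcome = outcome, table = tab,
                          n_used = length(yd),
                          n_singletons_dropped = n_sing,
                          n_missing_outcome = n_missing, n_groups = G,
                          df_residual = NA_real_),
                     class = "lpm_fit"))
  }

  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    drop_cols <- colnames(Xd)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping collinear column(s) after demeaning: ",
            paste(drop_cols, collapse = ", "))
    Xd <- Xd[, setdiff(colnames(Xd), drop_cols), drop = FALSE]
    qrX <- qr(Xd)
  }
  b <- qr.coef(qrX, yd)
  e <- yd - Xd %*% b
  n <- length(yd)
  k <- ncol(Xd)
  dfres <- n - k - G
  XtXinv <- chol2inv(qr.R(qrX))
  meat <- crossprod(Xd * as.vector(e))
  V <- XtXinv %*% meat %*% XtXinv * n / dfres
  se <- sqrt(diag(V))
  tcrit <- stats::qt(0.975, dfres)
  p <- 2 * stats::pt(-abs(b / se), dfres)
  tab <- data.frame(term = colnames(Xd), estimate = unname(b), se = se,
                    ci_low = unname(b - tcrit * se),
                    ci_high = unname(b + tcrit * se), p = p,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(outcome = outcome, table = tab, n_used = n,
                 n_singletons_dropped = n_sing,
                 n_missing_outcome = n_missing, n_groups = G,
                 df_residual = dfres),
            class = "lpm_fit")
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat("Hospital fixed-effect linear probability model:", x$outcome, "\n")
  cat(sprintf("n = %d (%d singleton rows dropped, %d missing outcome), %d groups\n",
              x$n_used, x$n_singletons_dropped, x$n_missing_outcome,
              x$n_groups))
  print(x$table, digits = 4)
  invisible(x)
}
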