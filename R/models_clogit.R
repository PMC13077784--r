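# McFadden conditional logit with OUD-by-attribute interactions, estimated
# from the likelihood up: analytic gradient and Hessian, Newton with line
# search (BFGS fallback), optional observation weights, and cluster-robust
# sandwich covariance.
#
# The linear index of alternative j for discharge i is
#   v_ij = x_j' beta + d_i * (x_j' delta)
# where d_i is the OUD flag. The patient-level OUD main effect is constant
# within a choice set and therefore unidentified; it enters only through the
# interactions, as the model class requires.

# internal: validate and index a long choice table
clogit_index <- function(choice_table, attributes, weights = NULL) {
  ct <- choice_table
  gfac <- factor(ct$discharge_id, levels = unique(ct$discharge_id))
  g <- as.integer(gfac)
  n_sets <- nlevels(gfac)
  nch <- rowsum(ct$choice, g)
  bad <- which(nch != 1L)
  if (length(bad)) {
    stop("choice set(s) with 0 or >= 2 chosen rows: ",
         paste(utils::head(levels(gfac)[bad], 5L), collapse = ", "))
  }
  X <- as.matrix(ct[, attributes, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite attribute values in choice table")
  oud <- as.numeric(ct$oud)
  Z <- cbind(X, X * oud)
  colnames(Z) <- c(attributes, paste0("oud_x_", attributes))
  if (is.null(weights)) {
    w <- if (!is.null(ct$weight)) ct$weight[!duplicated(g)] else
      rep(1, n_sets)
  } else {
    w <- weights
    if (length(w) == nrow(ct)) w <- w[!duplicated(g)]
    stopifnot(length(w) == n_sets)
  }
  if (any(!is.finite(w)) || any(w < 0)) stop("invalid weights")
  # chosen rows ordered by set index, robust to interleaved input rows
  ch <- which(ct$choice == 1L)
  ch <- ch[order(g[ch])]
  list(Z = Z, g = g, n_sets = n_sets, chosen = ch,
       w = as.numeric(w), levels = levels(gfac))
}

# internal: weighted log-likelihood, gradient, and (optionally) the observed
# information A - B, all on the scale of Z
clogit_core <- function(theta, idx, hessian = FALSE) {
  Z <- idx$Z
  g <- idx$g
  v <- drop(Z %*% theta)
  vmax <- as.vector(tapply(v, g, max))
  p <- exp(v - vmax[g])
  S <- drop(rowsum(p, g))
  ll <- sum(idx$w * (v[idx$chosen] - (vmax + log(S))))
  pr <- p / S[g]
  M <- rowsum(Z * pr, g)
  grad <- drop(crossprod(Z[idx$chosen, , drop = FALSE] - M, idx$w))
  out <- list(value = ll, gradient = grad, prob = pr)
  if (hessian) {
    sw <- sqrt(idx$w[g] * pr)
    A <- crossprod(Z * sw)
    B <- crossprod(M * sqrt(idx$w))
    out$info <- A - B  # negative Hessian of the log-likelihood
  }
  out
}

#' Conditional-logit log-likelihood and analytic gradient
#'
#' Evaluates the weighted conditional-logit log-likelihood and its gradient
#' at given main-effect and interaction coefficients, on the original
#' attribute scale. The per-set log-sum-exp is max-stabilized, so no
#' overflow occurs for linear indices up to about 700 in magnitude.
#'
#' @param beta Named main-effect coefficients over the attribute columns.
#' @param delta Named OUD-interaction coefficients (same attributes).
#' @param choice_table Long-format table as from [assemble_choice_data()] or
#'   [simulate_choice_data()]: must carry `discharge_id`, `choice`, `oud`,
#'   and the attribute columns.
#' @param weights Optional per-set (or per-row, constant within set)
#'   weights; defaults to the table's `weight` column or 1.
#' @param attributes Attribute column names (default [SNF_ATTRIBUTES]).
#' @return List with `value` (log-likelihood) and `gradient` (named, main
#'   effects then `oud_x_*` interactions).
#' @export
loglik_and_gradient <- function(beta, delta, choice_table, weights = NULL,
                                attributes = SNF_ATTRIBUTES) {
  idx <- clogit_index(choice_table, attributes, weights)
  theta <- c(complete_coef(beta)[attributes],
             complete_coef(delta)[attributes])
  res <- clogit_core(theta, idx)
  names(res$gradient) <- colnames(idx$Z)
  res[c("value", "gradient")]
}

#' Fit the conditional logit with OUD interactions
#'
#' Maximizes the (optionally weighted) conditional-logit likelihood by
#' Newton's method with step-halving line search, falling back to BFGS if
#' the observed information is not positive definite. Continuous attributes
#' are standardized internally for optimizer conditioning and estimates are
#' reported on the original scale. The covariance is a cluster-robust
#' sandwich: per-set score contributions are summed within clusters (states
#' by default), with a G/(G-1) small-sample factor.
#'
#' Attributes that are constant within every choice set are unidentified in
#' a conditional logit (they cancel from every within-set contrast) and
#' raise an error.
#'
#' @inheritParams loglik_and_gradient
#' @param cluster Name of the cluster column (default `"state_id"`), or a
#'   vector of cluster labels per row or per set.
#' @param tol Convergence tolerance on the max-norm of the score (default
#'   1e-8, on the standardized scale).
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `"clogit_fit"`: list with `coefficients` (named,
#'   original scale: main effects then `oud_x_*`), `beta`, `delta`, `vcov`
#'   (cluster-robust, original scale), `loglik`, `score_norm`,
#'   `n_choice_sets`, `n_alternatives`, `n_clusters`, `iterations`,
#'   `converged`, `weighted`, and `attributes`.
#' @export
fit_clogit <- function(choice_table, weights = NULL, cluster = "state_id",
                       attributes = SNF_ATTRIBUTES, tol = 1e-8,
                       max_iter = 50L) {
  idx <- clogit_index(choice_table, attributes, weights)
  Z <- idx$Z
  g <- idx$g

  # identification: every column must vary within at least one choice set
  within_dev <- abs(Z - rowsum(Z, g)[g, , drop = FALSE] /
                      tabulate(g)[g])
  const_within <- colSums(within_dev > 1e-12) == 0
  if (any(const_within)) {
    stop("attribute(s) constant within every choice set and therefore ",
         "unidentified in a conditional logit: ",
         paste(colnames(Z)[const_within], collapse = ", "),
         ". Patient-level covariates must enter via interactions.")
  }
  # collinearity of the within-set-demeaned design
  Zd <- Z - (rowsum(Z, g) / tabulate(g))[g, , drop = FALSE]
  if (qr(Zd)$rank < ncol(Z)) {
    stop("choice-model design is collinear within choice sets; ",
         "remove redundant attributes or interactions")
  }

  # standardize for conditioning; back-transform at the end
  scl <- apply(Z, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  idx$Z <- sweep(Z, 2, scl, "/")

  theta <- numeric(ncol(Z))
  cur <- clogit_core(theta, idx, hessian = TRUE)
  converged <- FALSE
  iter <- 0L
  used_bfgs <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$gradient), error = function(e) NULL)
    if (is.null(step)) {
      # non-PD information: fall back to BFGS from the current point
      used_bfgs <- TRUE
      opt <- stats::optim(
        theta, fn = function(t) -clogit_core(t, idx)$value,
        gr = function(t) -clogit_core(t, idx)$gradient,
        method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
      theta <- opt$par
      cur <- clogit_core(theta, idx, hessian = TRUE)
      break
    }
    lam <- 1
    repeat {
      cand <- theta + lam * step
      res <- clogit_core(cand, idx)
      if (res$value >= cur$value || lam < 1e-10) break
      lam <- lam / 2
    }
    theta <- theta + lam * step
    cur <- clogit_core(theta, idx, hessian = TRUE)
    if (max(abs(cur$gradient)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(cur$gradient)) < tol) converged <- TRUE
  if (!converged && !used_bfgs) {
    warning("conditional logit did not reach score tolerance ", tol,
            " in ", max_iter, " iterations (score max-norm ",
            format(max(abs(cur$gradient))), ")")
  }

  # cluster-robust sandwich on the standardized scale, then back-transform
  cl <- cluster_labels(choice_table, cluster, idx)
  Zs <- idx$Z
  si <- (Zs[idx$chosen, , drop = FALSE] -
           rowsum(Zs * cur$prob, g)) * idx$w       # per-set scores
  Sc <- rowsum(si, cl)
  G <- nrow(Sc)
  meat <- crossprod(Sc) * G / max(G - 1, 1)
  bread <- solve(cur$info)
  Vs <- bread %*% meat %*% bread
  coefs <- theta / scl
  V <- Vs / tcrossprod(scl)
  names(coefs) <- colnames(Z)
  dimnames(V) <- list(colnames(Z), colnames(Z))

  p <- length(attributes)
  structure(list(
    coefficients = coefs,
    beta = coefs[seq_len(p)],
    delta = stats::setNames(coefs[p + seq_len(p)], attributes),
    vcov = V,
    loglik = cur$value,
    score_norm = max(abs(cur$gradient)),
    n_choice_sets = idx$n_sets,
    n_alternatives = nrow(Z),
    n_clusters = G,
    iterations = iter,
    converged = converged || max(abs(cur$gradient)) < 1e-6,
    weighted = !is.null(weights) ||
      (!is.null(choice_table$weight) && any(choice_table$weight != 1)),
    attributes = attributes,
    set_weights = idx$w,
    cluster = cluster
  ), class = "clogit_fit")
}

# one cluster label per choice set
cluster_labels <- function(choice_table, cluster, idx) {
  if (length(cluster) == 1L && is.character(cluster) &&
      cluster %in% names(choice_table)) {
    lab <- choice_table[[cluster]]
  } else {
    lab <- cluster
  }
  if (length(lab) == nrow(choice_table)) lab <- lab[!duplicated(idx$g)]
  stopifnot(length(lab) == idx$n_sets)
  lab
}

#' Coefficient table of a conditional-logit fit
#' @param fit A [fit_clogit()] object.
#' @return Data frame: term, estimate, cluster-robust se, z, p.
#' @export
coef_table <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("Conditional logit:", x$n_choice_sets, "choice sets,",
      x$n_alternatives, "alternatives,", x$n_clusters, "clusters\n")
  cat(sprintf("log-likelihood %.4f; score max-norm %.2e; %d iteration(s)%s\n",
              x$loglik, x$score_norm, x$iterations,
              if (x$weighted) "; weighted" else ""))
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Predicted choice probabilities
#'
#' Evaluates the fitted softmax probability for every row of a long-format
#' choice table. Within every choice set the probabilities sum to 1.
#'
#' @param fit A [fit_clogit()] object.
#' @param choice_table Long-format table with the fit's attribute columns.
#' @return Numeric vector of probabilities, one per row.
#' @export
predict_clogit_prob <- function(fit, choice_table) {
  X <- as.matrix(choice_table[, fit$attributes, drop = FALSE])
  v <- drop(X %*% fit$beta) +
    as.numeric(choice_table$oud) * drop(X %*% fit$delta)
  gfac <- factor(choice_table$discharge_id,
                 levels = unique(choice_table$discharge_id))
  g <- as.integer(gfac)
  vmax <- as.vector(tapply(v, g, max))
  p <- exp(v - vmax[g])
  p / drop(rowsum(p, g))[g]
}

#' Re-estimate the choice model within propensity-score quintiles
#'
#' Splits the choice table by each discharge's quintile label and fits the
#' conditional logit independently in each stratum. Strata with fewer than
#' `min_sets` choice sets are skipped with a warning.
#'
#' @param choice_table Long-format choice table.
#' @param quintiles Data frame `discharge_id`, `quintile` (1-5), or a named
#'   vector of labels keyed by discharge id.
#' @param min_sets Minimum choice sets per stratum (default 50).
#' @param ... Passed to [fit_clogit()].
#' @return Named list of `clogit_fit` objects (possibly with gaps).
#' @export
fit_by_quintile <- function(choice_table, quintiles, min_sets = 50L, ...) {
  if (is.data.frame(quintiles)) {
    q <- stats::setNames(quintiles$quintile, quintiles$discharge_id)
  } else {
    q <- quintiles
  }
  lab <- q[choice_table$discharge_id]
  keep <- !is.na(lab)
  if (length(unique(lab[keep])) < 2L) {
    stop("quintile labels are all identical; no strata to fit")
  }
  out <- list()
  for (v in sort(unique(lab[keep]))) {
    sub <- choice_table[keep & lab == v, , drop = FALSE]
    nsets <- length(unique(sub$discharge_id))
    if (nsets < min_sets) {
      warning("quintile ", v, " has only ", nsets,
              " choice sets; fit skipped")
      next
    }
    out[[as.character(v)]] <- fit_clogit(sub, ...)
  }
  out
}
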