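test_that("degenerate choice sets hit the documented trivial values", {
  # single-alternative set contributes exactly zero
  ct1 <- hand_fixture()[1, ]
  ct1$choice <- 1L
  res <- loglik_and_gradient(numeric(0), numeric(0), ct1)
  expect_identical(res$value, 0)
  # uniform softmax: beta = delta = 0, J = 4
  ct4 <- hand_fixture()[1:4, ]
  ct4$discharge_id <- "D1"
  ct4$choice <- c(1L, 0L, 0L, 0L)
  res <- loglik_and_gradient(numeric(0), numeric(0), ct4)
  expect_equal(res$value, log(1 / 4), tolerance = 1e-12)
})

test_that("log-likelihood matches brute force and the gradient matches finite differences", {
  ct <- hand_fixture()
  set.seed(81)
  for (rep in 1:5) {
    beta <- setNames(rnorm(10, 0, 0.3), SNF_ATTRIBUTES)
    beta[c("beds", "occupancy_pct", "pct_medicaid")] <-
      beta[c("beds", "occupancy_pct", "pct_medicaid")] / 50
    delta <- setNames(rnorm(10, 0, 0.2), SNF_ATTRIBUTES)
    delta[c("beds", "occupancy_pct", "pct_medicaid")] <-
      delta[c("beds", "occupancy_pct", "pct_medicaid")] / 50
    res <- loglik_and_gradient(beta, delta, ct)
    expect_equal(res$value, brute_force_loglik(beta, delta, ct),
                 tolerance = 1e-10)
    expect_equal(unname(res$gradient), numeric_gradient(beta, delta, ct),
                 tolerance = 1e-6)
  }
})

test_that("malformed choice sets fail naming the discharge", {
  ct <- hand_fixture()
  ct$choice[1:3] <- 0L
  expect_error(loglik_and_gradient(numeric(0), numeric(0), ct), "D01")
  ct$choice[1:2] <- 1L
  expect_error(loglik_and_gradient(numeric(0), numeric(0), ct), "D01")
})

test_that("the log-sum-exp is stable for large linear indices", {
  ct <- hand_fixture()
  beta <- setNames(numeric(10), SNF_ATTRIBUTES)
  beta["dist_home_km"] <- -80  # |v| up to ~700
  res <- loglik_and_gradient(beta, numeric(0), ct)
  expect_true(is.finite(res$value))
  expect_true(all(is.finite(res$gradient)))
})

test_that("softmax location invariance: a constant added within sets leaves the likelihood unchanged", {
  ct <- hand_fixture()
  beta <- setNames(rep(0.1, 10), SNF_ATTRIBUTES)
  base <- loglik_and_gradient(beta, numeric(0), ct)$value
  # shift every alternative's index by a per-set constant and recompute by
  # direct enumeration: the chosen probabilities must be unchanged
  shift <- c(D01 = 1, D02 = -2, D03 = 0.5)[ct$discharge_id]
  X <- as.matrix(ct[, SNF_ATTRIBUTES])
  v <- drop(X %*% beta) + shift
  g <- ct$discharge_id
  ll <- sum(log(tapply(exp(v) * ct$choice, g, sum) /
                  tapply(exp(v), g, sum)))
  expect_equal(ll, base, tolerance = 1e-12)
})

test_that("simulated coefficients are recovered within 3 cluster-robust SEs", {
  beta <- c(preferred = 1.2, stars = 0.25, dist_home_km = -0.12,
            dist_hospital_km = -0.04, for_profit = 0.1, chain = 0.05,
            hospital_affiliated = 0.2, beds = 0.002,
            occupancy_pct = 0.004, pct_medicaid = -0.004)
  delta <- c(preferred = -0.4, stars = -0.25)
  ct <- simulate_choice_data(5000, 10, beta, delta, seed = 82L)
  fit <- fit_clogit(ct)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-8)
  se <- sqrt(diag(fit$vcov))
  truth <- c(full_coef(beta), setNames(full_coef(delta),
                                       paste0("oud_x_", SNF_ATTRIBUTES)))
  zdev <- abs(fit$coefficients - truth[names(fit$coefficients)]) / se
  expect_true(all(zdev < 3))
})

test_that("within-set predicted probabilities sum to one", {
  ct <- simulate_choice_data(200, 6, c(preferred = 1), c(stars = -0.2),
                             seed = 83L)
  fit <- fit_clogit(ct)
  p <- predict_clogit_prob(fit, ct)
  sums <- tapply(p, ct$discharge_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("patient-level attributes that never vary within sets are unidentified", {
  ct <- hand_fixture()
  ct$stars <- ave(ct$stars, ct$discharge_id)  # constant within every set
  expect_error(fit_clogit(ct, attributes = c("preferred", "stars")),
               "unidentified")
})

test_that("with one cluster per choice set the sandwich equals a brute-force heteroskedasticity-robust form", {
  attrs <- c("preferred", "stars", "dist_home_km")
  ct <- simulate_choice_data(50, 4, c(preferred = 0.8, stars = 0.2),
                             c(preferred = -0.3), seed = 84L)
  fit <- fit_clogit(ct, cluster = ct$discharge_id, attributes = attrs)
  theta <- fit$coefficients

  # brute-force per-set scores and information by direct enumeration
  ids <- unique(ct$discharge_id)
  P <- length(theta)
  S <- matrix(0, length(ids), P)
  H <- matrix(0, P, P)
  for (k in seq_along(ids)) {
    rows <- ct[ct$discharge_id == ids[k], ]
    Z <- cbind(as.matrix(rows[, attrs]),
               as.matrix(rows[, attrs]) * as.numeric(rows$oud))
    v <- drop(Z %*% theta)
    p <- exp(v - max(v)); p <- p / sum(p)
    m <- drop(t(Z) %*% p)
    S[k, ] <- Z[rows$choice == 1, ] - m
    H <- H + t(Z) %*% diag(p) %*% Z - m %*% t(m)
  }
  G <- length(ids)
  bread <- solve(H)
  V <- bread %*% (crossprod(S) * G / (G - 1)) %*% bread
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-7)
})

test_that("estimates are invariant to row order and to duplication with halved weights", {
  ct <- simulate_choice_data(300, 5, c(preferred = 1, stars = 0.2),
                             c(preferred = -0.3), seed = 85L)
  fit <- fit_clogit(ct)
  set.seed(86)
  perm <- sample(nrow(ct))
  fit_perm <- fit_clogit(ct[perm, ])
  expect_equal(sort(names(fit$coefficients)),
               sort(names(fit_perm$coefficients)))
  expect_equal(fit$coefficients, fit_perm$coefficients, tolerance = 1e-8)
  expect_equal(fit$loglik, fit_perm$loglik, tolerance = 1e-8)

  dup <- rbind(ct, transform(ct, discharge_id = paste0(discharge_id, "_b")))
  dup$weight <- 0.5
  fit_dup <- fit_clogit(dup)
  expect_equal(fit_dup$coefficients, fit$coefficients, tolerance = 1e-6)
  expect_equal(fit_dup$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("the unweighted fit agrees with an independent conditional-logit implementation", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  ct <- simulate_choice_data(500, 5, c(preferred = 1, stars = 0.2,
                                       dist_home_km = -0.1),
                             seed = 87L)
  fit <- fit_clogit(ct, attributes = c("preferred", "stars",
                                       "dist_home_km"))
  dd <- ct
  dd$ox_pref <- as.numeric(dd$oud) * dd$preferred
  dd$ox_stars <- as.numeric(dd$oud) * dd$stars
  dd$ox_dist <- as.numeric(dd$oud) * dd$dist_home_km
  ref <- survival::clogit(
    choice ~ preferred + stars + dist_home_km + ox_pref + ox_stars +
      ox_dist + survival::strata(discharge_id), data = dd)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("quintile-stratified fits behave under homogeneous and degenerate labels", {
  ct <- simulate_choice_data(600, 5, c(preferred = 1), c(preferred = -0.3),
                             seed = 88L)
  ids <- unique(ct$discharge_id)
  q <- data.frame(discharge_id = ids,
                  quintile = rep(1:5, length.out = length(ids)))
  fits <- fit_by_quintile(ct, q, attributes = c("preferred", "stars"))
  expect_identical(length(fits), 5L)
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  # all-identical labels: no strata
  q1 <- transform(q, quintile = 1L)
  expect_error(fit_by_quintile(ct, q1), "identical")
  # an undersized stratum is skipped with a warning
  q2 <- q
  q2$quintile[q2$quintile == 5] <- 4L
  q2$quintile[seq_len(10)] <- 5L
  expect_warning(f2 <- fit_by_quintile(ct, q2,
                                       attributes = c("preferred", "stars")),
                 "skipped")
  expect_false("5" %in% names(f2))
})

test_that("covariance is symmetric positive semi-definite and the score vanishes at the optimum", {
  ct <- simulate_choice_data(400, 6, c(preferred = 1, stars = 0.2),
                             c(preferred = -0.2), seed = 89L)
  fit <- fit_clogit(ct)
  expect_lt(fit$score_norm, 1e-8)
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})
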