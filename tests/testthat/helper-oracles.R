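# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized implementations: explicit loops and exponentials only.

# pad a partial named coefficient vector to the full attribute order
full_coef <- function(x) {
  out <- setNames(numeric(length(SNF_ATTRIBUTES)), SNF_ATTRIBUTES)
  out[names(x)] <- x
  out
}

# brute-force conditional-logit log-likelihood on a long table
brute_force_loglik <- function(beta, delta, ct) {
  ll <- 0
  for (id in unique(ct$discharge_id)) {
    rows <- ct[ct$discharge_id == id, ]
    X <- as.matrix(rows[, SNF_ATTRIBUTES])
    v <- numeric(nrow(rows))
    for (j in seq_len(nrow(rows))) {
      v[j] <- sum(X[j, ] * beta) + rows$oud[j] * sum(X[j, ] * delta)
    }
    pj <- exp(v) / sum(exp(v))
    w <- if (is.null(rows$weight)) 1 else rows$weight[1]
    ll <- ll + w * log(pj[rows$choice == 1])
  }
  ll
}

# central finite-difference gradient of the packaged log-likelihood
numeric_gradient <- function(beta, delta, ct, h = 1e-6) {
  theta <- c(beta, delta)
  p <- length(beta)
  g <- numeric(length(theta))
  for (k in seq_along(theta)) {
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    fu <- loglik_and_gradient(up[1:p], up[(p + 1):(2 * p)], ct)$value
    fd <- loglik_and_gradient(dn[1:p], dn[(p + 1):(2 * p)], ct)$value
    g[k] <- (fu - fd) / (2 * h)
  }
  g
}

# all-prefixes oracle for the preferred-network rule: the smallest prefix of
# the descending-volume ranking whose share reaches the threshold
prefix_preferred_oracle <- function(volumes, threshold) {
  volumes <- volumes[volumes > 0]
  if (!length(volumes)) return(character(0))
  ord <- order(-volumes, names(volumes))
  v <- volumes[ord]
  total <- sum(v)
  for (k in seq_along(v)) {
    if (sum(v[seq_len(k)]) / total >= threshold) {
      return(names(v)[seq_len(k)])
    }
  }
  names(v)
}

# a tiny hand-written 3-set x 3-alternative fixture with known attributes
hand_fixture <- function() {
  ct <- expand.grid(alt = 1:3, set = 1:3)
  n <- nrow(ct)
  data.frame(
    discharge_id = sprintf("D%02d", ct$set),
    facility_id = sprintf("F%02d", seq_len(n)),
    state_id = c("S1", "S1", "S2")[ct$set],
    choice = as.integer(ct$alt == c(1, 2, 3)[ct$set]),
    oud = c(FALSE, TRUE, TRUE)[ct$set],
    weight = 1,
    preferred = as.numeric(ct$alt == 1),
    stars = c(1, 3, 5, 2, 4, 4, 5, 1, 3)[seq_len(n)],
    dist_home_km = c(2.0, 5.5, 9.1, 1.2, 7.7, 3.3, 8.8, 0.4, 6.6),
    dist_hospital_km = c(1.1, 4.2, 8.3, 2.2, 6.1, 3.9, 7.5, 1.3, 5.0),
    for_profit = c(1, 0, 1, 1, 1, 0, 0, 1, 0),
    chain = c(0, 1, 1, 0, 0, 1, 1, 1, 0),
    hospital_affiliated = c(0, 0, 1, 0, 1, 0, 0, 0, 1),
    beds = c(80, 120, 200, 60, 150, 95, 110, 75, 130),
    occupancy_pct = c(70, 85, 90, 65, 88, 75, 92, 60, 80),
    pct_medicaid = c(40, 55, 62, 35, 48, 50, 70, 30, 45),
    stringsAsFactors = FALSE
  )
}

# small generated population shared by several files (built once per run)
tiny_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 42L, n_states = 3, n_hospitals = 9,
                              n_snfs = 60, n_discharges = 3000,
                              oud_prevalence = 0.25)
      cache <<- generate_population(cfg)
    }
    cache
  }
})
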