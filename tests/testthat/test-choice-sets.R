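test_that("cohort filters exclude exactly the constructed violations, in order", {
  pop <- tiny_population()
  out <- inject_edge_cases(pop, list(lag2 = 2, prior_snf = 1,
                                     out_of_state = 3, missing_coords = 1,
                                     underage = 2))
  flt <- apply_cohort_filters(out$discharges, out$facilities, out$hospitals)
  log <- flt$exclusion_log
  # clean generator rows can also violate lag/prior rules, so compare
  # against direct counts instead of just the injected totals
  d <- out$discharges
  expect_identical(log$removed[log$rule == "age >= 18"], 2L)
  expect_identical(
    log$removed[log$rule == "SNF admission within 1 day of discharge"],
    sum(d$snf_admission_lag_days > 1 & d$age >= 18))
  expect_false(any(flt$kept$snf_admission_lag_days > 1))
  expect_false(any(flt$kept$had_prior_year_snf))
  fs <- setNames(out$facilities$state_id, out$facilities$facility_id)
  hs <- setNames(out$hospitals$state_id, out$hospitals$hospital_id)
  expect_true(all(fs[flt$kept$chosen_facility_id] ==
                    hs[flt$kept$hospital_id]))
  # conservation: removals sum to input minus output
  expect_identical(sum(log$removed), nrow(d) - nrow(flt$kept))
})

test_that("a fully clean table passes the filters unchanged with an all-zero log", {
  pop <- tiny_population()
  d <- pop$discharges
  d <- d[d$snf_admission_lag_days <= 1 & !d$had_prior_year_snf, ]
  flt <- apply_cohort_filters(d, pop$facilities, pop$hospitals)
  expect_identical(flt$kept, d)
  expect_true(all(flt$exclusion_log$removed == 0L))
})

test_that("unlinkable ids are reported as corrupt input", {
  pop <- tiny_population()
  d <- pop$discharges[1:5, ]
  d$hospital_id[1] <- "H_NOPE"
  expect_error(apply_cohort_filters(d, pop$facilities, pop$hospitals),
               "hospital ids")
  d <- pop$discharges[1:5, ]
  d$chosen_facility_id[2] <- "F_NOPE"
  expect_error(apply_cohort_filters(d, pop$facilities, pop$hospitals),
               "facility ids")
})

test_that("preferred classification matches the worked examples", {
  net <- classify_preferred(c(A = 50L, B = 30L, C = 20L), 0.5)
  expect_identical(net$preferred_set, "A")
  expect_equal(net$cumulative_share_achieved, 0.5)
  net <- classify_preferred(c(A = 40L, B = 35L, C = 25L), 0.5)
  expect_identical(net$preferred_set, c("A", "B"))
  expect_equal(net$cumulative_share_achieved, 0.75)
  expect_warning(empty <- classify_preferred(c(A = 0L), 0.5), "no prior-year")
  expect_identical(empty$preferred_set, character(0))
})

test_that("preferred sets match the all-prefixes oracle and are minimal on 1,000 random volume vectors", {
  set.seed(51)
  for (i in 1:1000) {
    k <- sample(1:12, 1)
    vol <- setNames(rpois(k, 8), sprintf("F%02d", sample(99, k)))
    thr <- runif(1, 0.05, 0.95)
    if (sum(vol) == 0) vol[1] <- 1L
    net <- classify_preferred(vol, thr)
    expect_identical(net$preferred_set, prefix_preferred_oracle(vol, thr))
    expect_gte(net$cumulative_share_achieved, thr)
    # minimality: dropping the lowest-volume member falls below threshold
    if (length(net$preferred_set) > 1) {
      share_without <- sum(net$volumes[seq_len(
        length(net$preferred_set) - 1)]) / sum(vol[vol > 0])
      expect_lt(share_without, thr)
    }
  }
})

test_that("preferred set size is non-decreasing in the 10%-80% threshold grid", {
  set.seed(52)
  grid <- seq(0.1, 0.8, 0.1)
  for (i in 1:50) {
    vol <- setNames(rpois(10, 10) + 1L, sprintf("F%02d", 1:10))
    sizes <- vapply(grid, function(t)
      length(classify_preferred(vol, t)$preferred_set), numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("choice sets are the union of the discharge, radius, and nearest-k rules", {
  pop <- tiny_population()
  h <- pop$hospitals[1, ]
  f <- pop$facilities
  d <- pop$discharges
  yr <- as.integer(format(d$discharge_date, "%Y"))
  y <- max(yr)
  ydis <- d[d$hospital_id == h$hospital_id & yr == y, ]
  got <- build_choice_set(h, y, f, ydis, radius_km = 22, k_nearest = 15L)

  # brute-force union oracle over all same-state facilities
  fs <- f[f$state_id == h$state_id, ]
  dist <- distance_km(h$latitude, h$longitude, fs$latitude, fs$longitude)
  cat_a <- unique(ydis$chosen_facility_id)
  cat_b <- fs$facility_id[dist <= 22]
  cat_c <- fs$facility_id[order(dist)][seq_len(min(15, nrow(fs)))]
  oracle <- union(union(cat_a, cat_b), cat_c)
  expect_setequal(got$facility_id, oracle)
  # every chosen SNF of the hospital-year is a member
  expect_true(all(ydis$chosen_facility_id %in% got$facility_id))
  expect_false(anyDuplicated(got$facility_id) > 0)
})

test_that("a tiny market returns all its SNFs under the truncated nearest-k rule", {
  h <- data.frame(hospital_id = "H1", state_id = "SX",
                  latitude = 40, longitude = -100)
  f <- data.frame(facility_id = c("FA", "FB", "FC"), state_id = "SX",
                  latitude = 40 + c(0.5, 0.6, 0.7), longitude = -100,
                  stringsAsFactors = FALSE)
  empty <- data.frame(chosen_facility_id = character(0))
  got <- build_choice_set(h, 2018, f, empty)
  expect_setequal(got$facility_id, c("FA", "FB", "FC"))
  # all farther than 22 km, no discharges: forced by rule (c) alone
  expect_true(all(got$dist_hospital_km > 22))
  expect_error(build_choice_set(h, 2018, f[0, ], empty), "no SNFs in state")
})

test_that("the long choice table has one row per alternative and one chosen row per set", {
  pop <- tiny_population()
  flt <- apply_cohort_filters(pop$discharges, pop$facilities, pop$hospitals)
  yr <- as.integer(format(flt$kept$discharge_date, "%Y"))
  kept <- flt$kept[yr > min(yr), ][1:50, ]
  hy <- build_hospital_year_sets(kept, pop$facilities, pop$hospitals,
                                 volume_discharges = pop$discharges)
  ct <- assemble_choice_data(kept, hy, pop$facilities, pop$hospitals)

  sizes <- table(ct$discharge_id)
  key <- paste(hy$hospital_id, hy$year)
  expected_sizes <- table(key)[paste(kept$hospital_id,
                                     format(kept$discharge_date, "%Y"))]
  expect_identical(as.integer(sizes[kept$discharge_id]),
                   as.integer(expected_sizes))
  expect_identical(nrow(ct), sum(as.integer(expected_sizes)))
  expect_true(all(tapply(ct$choice, ct$discharge_id, sum) == 1L))
  # closest flag attains the minimum home distance within every set
  mins <- tapply(ct$dist_home_km, ct$discharge_id, min)
  expect_equal(as.vector(ct$dist_home_km[ct$is_closest]),
               as.vector(mins[unique(ct$discharge_id)]),
               tolerance = 1e-12)
})

test_that("permuting input discharge order leaves the canonical choice table unchanged", {
  pop <- tiny_population()
  flt <- apply_cohort_filters(pop$discharges, pop$facilities, pop$hospitals)
  yr <- as.integer(format(flt$kept$discharge_date, "%Y"))
  kept <- flt$kept[yr > min(yr), ][1:30, ]
  hy <- build_hospital_year_sets(kept, pop$facilities, pop$hospitals,
                                 volume_discharges = pop$discharges)
  a <- assemble_choice_data(kept, hy, pop$facilities, pop$hospitals)
  set.seed(53)
  b <- assemble_choice_data(kept[sample(nrow(kept)), ], hy,
                            pop$facilities, pop$hospitals)
  attributes(a) <- attributes(a)[c("names", "class")]
  attributes(b) <- attributes(b)[c("names", "class")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("a chosen SNF missing from its set is a hard failure", {
  pop <- tiny_population()
  flt <- apply_cohort_filters(pop$discharges, pop$facilities, pop$hospitals)
  yr <- as.integer(format(flt$kept$discharge_date, "%Y"))
  kept <- flt$kept[yr > min(yr), ][1:10, ]
  hy <- build_hospital_year_sets(kept, pop$facilities, pop$hospitals,
                                 volume_discharges = pop$discharges)
  hy_broken <- hy[hy$facility_id != kept$chosen_facility_id[1] |
                    hy$hospital_id != kept$hospital_id[1], ]
  expect_error(
    assemble_choice_data(kept, hy_broken, pop$facilities, pop$hospitals),
    "absent from the choice set")
})
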