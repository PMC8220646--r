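test_that("absence draws are binomial over half-person slots", {
  expect_true(all(draw_absences(10, 0, 500) == 0))
  expect_true(all(draw_absences(10, 1, 500) == 10))
  set.seed(31)
  x <- draw_absences(10, 0.03, 1e5)
  se <- sqrt(20 * 0.03 * 0.97) / 2 / sqrt(1e5)
  expect_lt(abs(mean(x) - 0.3), 2 * se + 1e-6)
  # half-person granularity
  expect_true(all(round(2 * x) == 2 * x))
  expect_error(draw_absences(10, 1.2), class = "wardflex_config_error")
})

test_that("status classification applies the strict 15% trigger", {
  expect_equal(classify_status(100, 84)$status, "understaffed")
  expect_true(classify_status(100, 84)$triggered)
  expect_equal(classify_status(100, 86)$status, "adequate")
  expect_equal(classify_status(100, 85)$status, "adequate") # exactly 15%
  expect_equal(classify_status(50, 50)$status, "adequate")
  expect_equal(classify_status(50, 50)$shortfall_hours, 0)
  expect_equal(classify_status(10, 12)$status, "overstaffed")
  # zero requirement is never understaffed
  expect_equal(classify_status(0, 0)$status, "adequate")
  expect_equal(classify_status(0, 4)$status, "overstaffed")
})

test_that("floating matches the worked two-unit example and the donor floor", {
  # A requires 10 blocks-worth (40 h), has 48 h; B requires 40 h, has 32 h
  # (triggered): 2 blocks float A -> B; both end at their requirement
  fl <- float_staff(required = c(40, 40), available = c(48, 32),
                    block_hours = 4, unit_ids = c("A", "B"))
  expect_equal(fl$floated_out, c(8, 0))
  expect_equal(fl$floated_in, c(0, 8))
  expect_equal(c(48, 32) - fl$floated_out + fl$floated_in, c(40, 40))
  # no overstaffed units: nothing moves
  fl0 <- float_staff(c(40, 40), c(40, 30), block_hours = 4)
  expect_equal(nrow(fl0$transfers), 0L)
  # donor would drop below its requirement: transfer truncated at surplus
  fl1 <- float_staff(c(40, 40), c(45, 20), block_hours = 4,
                     unit_ids = c("A", "B"))
  expect_equal(fl1$floated_out, c(4, 0)) # only one whole block of surplus
  expect_gte(45 - fl1$floated_out[1], 40)
})

test_that("temporary hires request covering blocks, bank first then agency", {
  # availability none: no hires however large the shortfall
  h0 <- hire_temporary(c(40, 12), p_bank = 0, p_agency = 0)
  expect_equal(h0$bank_hours + h0$agency_hours, c(0, 0))
  expect_equal(h0$requested_blocks, c(10L, 3L))
  # agency certainty fills every residual block
  set.seed(1)
  h1 <- hire_temporary(c(40, 12, 7), p_bank = 0.5, p_agency = 1)
  expect_equal(h1$bank_hours + h1$agency_hours, c(40, 12, 8))
  # single-block requests at bank p = 0.5, agency p = 0: fill rate 1/2
  set.seed(2)
  h2 <- hire_temporary(rep(2, 10000), p_bank = 0.5, p_agency = 0,
                       block_hours = 4)
  fills <- mean(h2$bank_hours > 0)
  expect_lt(abs(fills - 0.5), 2 * 0.5 / sqrt(10000))
})

test_that("fill resolution equals the straight-line oracle on 1000 toy instances", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:3, 1)
    block <- 4
    # up to 6 staff of 8 h: required/available on a half-shift lattice
    required <- round(runif(n, 0, 48) / 2) * 2
    available <- sample(0:12, n, replace = TRUE) * block
    group <- if (n == 3 && runif(1) < 0.3) c("g1", "g1", "g2") else
      rep("g1", n)
    pb <- sample(c(0, 0.3, 0.5, 1), 1)
    pa <- sample(c(0, 0.5, 1), 1)
    allow <- runif(1) < 0.8
    B <- 16L
    ub <- matrix(runif(n * B), n, B)
    ua <- matrix(runif(n * B), n, B)
    ids <- sprintf("u%02d", seq_len(n))
    eng <- resolve_shift(required, available, group, tolerance = 0.15,
                         block_hours = block, allow_float = allow,
                         p_bank = pb, p_agency = pa, u_bank = ub,
                         u_agency = ua, unit_ids = ids)
    ora <- oracle_fill(required, available, group, tolerance = 0.15,
                       block_hours = block, allow_float = allow,
                       p_bank = pb, p_agency = pa, u_bank = ub,
                       u_agency = ua, unit_ids = ids)
    expect_identical(eng$floated_in, ora$floated_in)
    expect_identical(eng$floated_out, ora$floated_out)
    expect_identical(eng$bank_hours, ora$bank_hours)
    expect_identical(eng$agency_hours, ora$agency_hours)
    expect_identical(eng$achieved, ora$achieved)
  }
})

test_that("run_shift reduces to the roster in the identity limit", {
  hs <- generate_hospital(small_gen_config(6L), seed = 3)$hospitals[[1]]
  est <- build_establishment(hs, "standard", seed = 3)
  cfg <- simulator_config(absence_rates = c(RN = 0, `NA` = 0),
                          availability = availability_preset("none"),
                          allow_floating = FALSE, master_seed = 3)
  led <- run_shift(hs, day = 2, shift = "late", est, cfg)
  expect_equal(led$achieved_hours, led$rostered_hours)
  expect_true(all(led$absent_hours == 0))
  expect_true(all(led$bank_hours == 0 & led$agency_hours == 0))
  expect_true(all(led$floated_in_hours == 0 & led$floated_out_hours == 0))
})

test_that("no fill actions target units inside the tolerance", {
  hs <- generate_hospital(small_gen_config(6L), seed = 4)$hospitals[[1]]
  cfg <- simulator_config(days = 40, master_seed = 4,
                          availability = availability_preset("higher"))
  r <- run_scenario(hs, "standard", cfg)
  got_fill <- r$floated_in_hours > 0 | r$bank_hours > 0 | r$agency_hours > 0
  expect_true(all(r$status_before[got_fill] == "understaffed"))
  # and every fill/transfer is a half-shift multiple
  cols <- cbind(r$floated_in_hours, r$floated_out_hours, r$bank_hours,
                r$agency_hours)
  expect_true(all(abs(cols / 4 - round(cols / 4)) < 1e-9))
})

test_that("scenario runs are deterministic, conservative, and stream-aligned", {
  hs <- generate_hospital(small_gen_config(6L), seed = 5)$hospitals[[1]]
  cfg <- simulator_config(days = 30, master_seed = 5)
  r1 <- run_scenario(hs, "standard", cfg)
  r2 <- run_scenario(hs, "standard", cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 6 * 2 * 3 * 30)

  # ledger identity per row
  expect_equal(r1$achieved_hours,
               r1$rostered_hours - r1$absent_hours - r1$floated_out_hours +
                 r1$floated_in_hours + r1$bank_hours + r1$agency_hours,
               tolerance = 1e-9)
  # conservation per shift per role: floats cancel
  agg <- aggregate(cbind(achieved_hours, rostered_hours, absent_hours,
                         bank_hours, agency_hours, floated_in_hours,
                         floated_out_hours) ~ day + shift + role,
                   data = r1, sum)
  expect_equal(agg$achieved_hours,
               agg$rostered_hours - agg$absent_hours + agg$bank_hours +
                 agg$agency_hours, tolerance = 1e-9)
  expect_equal(agg$floated_in_hours, agg$floated_out_hours,
               tolerance = 1e-9)

  # run_shift reproduces the full run's rows for the same (day, shift)
  est <- build_establishment(hs, "standard", seed = 5)
  one <- run_shift(hs, day = 17, shift = "night", est, cfg)
  sub <- as.data.frame(r1[r1$day == 17 & r1$shift == "night", ])
  rownames(sub) <- NULL
  expect_equal(one[order(one$role, one$unit_id), ],
               sub[order(sub$role, sub$unit_id), ],
               ignore_attr = TRUE)

  # demand and absence streams are shared across plans (common random
  # numbers): required hours identical, absences identical where rosters
  # coincide
  r_flex <- run_scenario(hs, "flexible", cfg)
  expect_equal(r_flex$required_hours, r1$required_hours)
  expect_equal(r_flex$census, r1$census)
  same_roster <- r_flex$rostered_hours == r1$rostered_hours
  expect_equal(r_flex$absent_hours[same_roster],
               r1$absent_hours[same_roster])
})

test_that("a degenerate one-group hospital floats between its two units", {
  u1 <- make_unit("A", "G", census_mean = 10, census_sd = 3, beds = 20)
  u2 <- make_unit("B", "G", census_mean = 10, census_sd = 3, beds = 20)
  h <- make_hospital(list(u1, u2))
  cfg <- simulator_config(days = 60, master_seed = 11,
                          availability = availability_preset("none"))
  r <- run_scenario(h, "flexible", cfg)
  expect_gt(sum(r$floated_in_hours), 0)
  expect_true(all(r$specialty_group == "G"))
})
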