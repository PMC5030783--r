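mask_of <- function(idx, d = c(2, 3, 2)) {
  m <- array(FALSE, d)
  m[idx] <- TRUE
  m
}

test_that("double-labeled voxels are reassigned to dead", {
  live <- mask_of(c(1, 2, 3))
  dead <- mask_of(c(3, 4))
  r <- reassign_double_labeled(live, dead)
  expect_identical(r$live, mask_of(c(1, 2)))
  expect_identical(r$dead, dead)
  expect_identical(r$double, mask_of(3))
  # disjoint masks unchanged
  r2 <- reassign_double_labeled(mask_of(1:2), mask_of(3:4))
  expect_identical(r2$live, mask_of(1:2))
  # live == dead annihilates the live mask
  r3 <- reassign_double_labeled(mask_of(1:3), mask_of(1:3))
  expect_false(any(r3$live))
})

test_that("reassignment is a partition of the input union", {
  set.seed(11)
  for (i in 1:20) {
    live <- array(runif(60) < 0.4, c(3, 5, 4))
    dead <- array(runif(60) < 0.4, c(3, 5, 4))
    r <- reassign_double_labeled(live, dead)
    expect_false(any(r$live & r$dead))
    expect_identical(r$live | r$dead, live | dead)
    f <- live_fraction(sum(r$live), sum(r$dead))
    if (!is.na(f)) {
      expect_equal(f + 100 * sum(r$dead) / (sum(r$live) + sum(r$dead)), 100)
    }
  }
})

test_that("coverage is a voxel count, additive over disjoint masks", {
  expect_equal(coverage_area(array(FALSE, c(2, 2, 2))), 0)
  expect_equal(coverage_area(array(TRUE, c(10, 10, 10))), 1000)
  a <- mask_of(1:4); b <- mask_of(7:9)
  expect_equal(coverage_area(a | b), coverage_area(a) + coverage_area(b))
})

test_that("live fraction follows the 100% = live + dead convention", {
  expect_equal(live_fraction(75, 25), 75)
  expect_equal(live_fraction(10, 0), 100)
  expect_true(is.na(live_fraction(0, 0)))
  expect_error(live_fraction(-1, 5), "non-negative")
})

test_that("survival series aggregates fields with sample SD", {
  m <- data.frame(subject = "S1", timepoint = "T0",
                  fraction_live = c(50, 60, 70, 80, 90))
  s <- build_survival_series(m)
  t0 <- s[s$timepoint == "T0", ]
  expect_equal(t0$mean_fraction, 70)
  expect_equal(t0$sd_fraction, sqrt(250))
  expect_equal(t0$n_fields, 5)
  # missing time points are gaps, not zeros
  expect_true(is.na(s$mean_fraction[s$timepoint == "T2"]))
  # single field: SD undefined
  s1 <- build_survival_series(data.frame(subject = "S1", timepoint = "T1",
                                         fraction_live = 42))
  expect_equal(s1$mean_fraction[s1$timepoint == "T1"], 42)
  expect_true(is.na(s1$sd_fraction[s1$timepoint == "T1"]))
})

test_that("series excludes undefined fractions with a warning, never as 0", {
  m <- data.frame(subject = "S1", timepoint = "T0",
                  fraction_live = c(80, NA, 90))
  expect_warning(s <- build_survival_series(m), "undefined")
  expect_equal(s$mean_fraction[s$timepoint == "T0"], 85)
  expect_equal(s$n_fields[s$timepoint == "T0"], 2)
})

test_that("series is invariant to measurement order", {
  set.seed(3)
  m <- data.frame(subject = rep(c("S1", "S2"), each = 8),
                  timepoint = rep(rep(c("T0", "T3"), each = 4), 2),
                  fraction_live = runif(16, 40, 90))
  s1 <- build_survival_series(m)
  s2 <- build_survival_series(m[sample(nrow(m)), ])
  expect_equal(s1, s2)
})

test_that("quantification recovers quiet scenes exactly", {
  sim <- generate_stack_pair(quiet_stack_params(n_live = 80L, n_dead = 20L,
                                                seed = 21))
  m <- quantify_stack_pair(sim$pair)
  expect_equal(m$fraction_live, 80)
  expect_equal(m$fraction_live, sim$truth$true_fraction)

  # all signal in the dead channel only
  sim_d <- generate_stack_pair(quiet_stack_params(n_live = 0L, n_dead = 30L,
                                                  seed = 22))
  expect_equal(quantify_stack_pair(sim_d$pair)$fraction_live, 0)

  # double-labeled cells only: all counted dead
  sim_o <- generate_stack_pair(quiet_stack_params(n_live = 0L, n_dead = 0L,
                                                  n_double = 10L, seed = 23))
  expect_equal(quantify_stack_pair(sim_o$pair)$fraction_live, 0)

  # empty foreground: undefined, not zero
  sim_e <- generate_stack_pair(quiet_stack_params(n_live = 0L, n_dead = 0L))
  expect_true(quantify_stack_pair(sim_e$pair)$undefined)
})

test_that("audit masks expose the partitioned foreground", {
  sim <- generate_stack_pair(stack_sim_params(seed = 8))
  m <- quantify_stack_pair(sim$pair, keep_masks = TRUE)
  expect_false(any(m$masks$live & m$masks$dead))
  expect_equal(sum(m$masks$live), m$live_voxels)
  expect_equal(sum(m$masks$dead), m$dead_voxels)
  expect_type(m$provenance$live_background_max, "double")
})
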