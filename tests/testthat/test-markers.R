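test_that("WMH burden is the base-10 log of volume in ml", {
  expect_equal(log_wmh_burden(1.0), 0.0)
  expect_equal(log_wmh_burden(10.0), 1.0)
  expect_equal(log_wmh_burden(0.986), log10(0.986))
  # a ~1 ml lesion load sits near 0, matching a low-burden reference group
  expect_lt(abs(log_wmh_burden(0.986)), 0.01)
  expect_error(log_wmh_burden(0), "floor")
  expect_equal(log_wmh_burden(0, floor = 0.01), -2)
  expect_equal(log_wmh_burden(exp(1), base = exp(1)), 1)
})

test_that("choroid normalization is the mm3/ml ratio and unit-consistent", {
  expect_equal(normalize_choroid(1600, 1480), 1600 / 1480, tolerance = 1e-12)
  expect_equal(round(normalize_choroid(1600, 1480), 3), 1.081)
  expect_equal(normalize_choroid(0, 1500), 0)
  # doubling both volumes in consistent units leaves the ratio unchanged
  expect_equal(normalize_choroid(2 * 1600, 2 * 1480),
               normalize_choroid(1600, 1480))
  expect_error(normalize_choroid(1600, 0), "tiv")
})

test_that("basal ganglia PVS rater matches the printed rules on all boundaries", {
  # exhaustive truth table over the boundary-relevant counts
  counts <- c(0, 1, 4, 5, 7, 10, 11, 25, 100)
  expected <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  expect_equal(rate_pvs_bg(counts), expected)
  expect_equal(rate_pvs_bg(0, countable = FALSE), 4L)
  expect_equal(rate_pvs_bg(c(3, 12), countable = c(TRUE, FALSE)), c(1L, 4L))
  expect_error(rate_pvs_bg(-1), "non-negative")
})

test_that("white matter PVS rater matches the printed rules on all boundaries", {
  # (total, max per section) -> grade
  cases <- rbind(
    c(0, 0, 1), c(8, 5, 1), c(9, 9, 1),
    c(10, 5, 2), c(15, 9, 2), c(30, 10, 2),
    c(15, 11, 3), c(25, 20, 3),
    c(40, 25, 4), c(21, 21, 4))
  expect_equal(rate_pvs_wm(cases[, 1], cases[, 2]), as.integer(cases[, 3]))
  expect_error(rate_pvs_wm(5, 8), "exceed")
  expect_error(rate_pvs_wm(-1, -1), "non-negative")
})

test_that("PVS raters are monotone and produce exactly one grade per input", {
  g_bg <- rate_pvs_bg(0:60)
  expect_true(all(diff(g_bg) >= 0))
  expect_true(all(g_bg %in% 1:3))
  for (total in c(12, 25, 60)) {
    g_wm <- rate_pvs_wm(rep(total, total + 1), 0:total)
    expect_true(all(diff(g_wm) >= 0))
    expect_true(all(g_wm %in% 1:4))
  }
})

test_that("amyloid positivity is strict at SUVR 1.11", {
  expect_true(amyloid_positive(1.12))
  expect_false(amyloid_positive(1.11))
  expect_false(amyloid_positive(1.024))
  expect_error(amyloid_positive(0), "positive")
})

test_that("group assignment follows diagnosis, amyloid status and Fazekas rule", {
  expect_equal(as.character(assign_group("CN", FALSE, 1)), "CN-")
  expect_equal(as.character(assign_group("CN", FALSE, 2)), "excluded")
  expect_equal(as.character(assign_group("CN", TRUE, 3)), "CN+")
  expect_equal(as.character(assign_group("MCI", TRUE, 0)), "MCI+")
  expect_equal(as.character(assign_group("dementia", TRUE, 3)), "AD+")
  expect_equal(as.character(assign_group("dementia", FALSE, 0)), "excluded")
  expect_error(assign_group("SCD", TRUE, 0), "unknown diagnosis")
  # the assignment partitions every record into exactly one bin
  grid <- expand.grid(dx = c("CN", "MCI", "dementia"),
                      amy = c(TRUE, FALSE), fz = 0:3,
                      stringsAsFactors = FALSE)
  g <- assign_group(grid$dx, grid$amy, grid$fz)
  expect_true(all(g %in% c("CN-", "CN+", "MCI+", "AD+", "excluded")))
  expect_true(all(!is.na(attr(g, "reason")[g == "excluded"])))
})

test_that("QC exclusions drop on GDS, chin-up and PET-DTI interval with reasons", {
  rec <- data.frame(id = c("a", "b", "c", "d", "e"),
                    gds = c(5, 0, 0, 0, 4),
                    acpc_angle_deg = c(5, 30, 5, 5, 20),
                    pet_dti_interval_months = c(6, 6, 12, 6, 11.9))
  res <- apply_exclusions(rec)
  expect_equal(res$keep, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_match(res$reasons[1], "GDS")
  expect_match(res$reasons[2], "chin-up")
  expect_match(res$reasons[3], "interval")
  # reasons accumulate
  rec2 <- data.frame(gds = 7, acpc_angle_deg = 25,
                     pet_dti_interval_months = 14)
  expect_equal(length(strsplit(apply_exclusions(rec2)$reasons, "; ")[[1]]), 3)
  # missing QC fields error unless lenient
  expect_error(apply_exclusions(data.frame(gds = 1)), "missing QC field")
  expect_true(apply_exclusions(data.frame(gds = 1), lenient = TRUE)$keep)
})

test_that("vascular risk score counts the five recorded flags", {
  rec <- data.frame(hypertension = c(1, 0), diabetes = c(1, 0),
                    hyperlipidemia = c(1, 0), smoking = c(1, 0),
                    heart_disease = c(1, 1))
  expect_equal(vascular_risk_score(rec), c(5L, 1L))
  expect_error(vascular_risk_score(data.frame(hypertension = 1)), "missing")
})
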