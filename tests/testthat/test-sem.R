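test_that("default generator parameters encode the study conditions", {
  p <- default_sem_params()
  expect_equal(p$n, 93L)
  expect_equal(p$n_reference, 40L)
  expect_equal(p$r_wmh_alps, -0.458)
  expect_equal(p$r_wmh_choroid, 0.294)
  expect_equal(unname(p$r_alps_cog["memory"]), 0.470)
  expect_equal(p$n_boot, 5000L)
  expect_equal(unname(p$group_weights), c(48, 26, 19))
})

test_that("generated cohort has the full schema, group counts and amyloid status", {
  coh <- generate_cohort(default_sem_params(seed = 3))
  expect_equal(nrow(coh), 133)
  expect_equal(unname(table(coh$group)[c("CN-", "CN+", "MCI+", "AD+")]),
               c(40L, 48L, 26L, 19L), ignore_attr = TRUE)
  expect_true(all(c("id", "suvr", "wmh_burden", "choroid_norm", "alps",
                    "bg_pvs_grade", "memory", "fazekas", "gds") %in%
                    names(coh)))
  # amyloid status is consistent with group membership
  expect_true(all(amyloid_positive(coh$suvr[coh$group != "CN-"])))
  expect_true(all(!amyloid_positive(coh$suvr[coh$group == "CN-"])))
  # derived columns are internally consistent
  expect_equal(coh$wmh_burden, log10(coh$wmh_volume))
  expect_equal(coh$choroid_norm, coh$choroid_mm3 / coh$tiv)
  expect_true(all(coh$bg_pvs_grade %in% 1:4 & coh$wm_pvs_grade %in% 1:4))
  # CN- records satisfy the Fazekas < 2 rule of their group definition
  expect_true(all(coh$fazekas[coh$group == "CN-"] < 2))
})

test_that("cohort generation is deterministic given the seed", {
  c1 <- generate_cohort(default_sem_params(seed = 17))
  c2 <- generate_cohort(default_sem_params(seed = 17))
  c3 <- generate_cohort(default_sem_params(seed = 18))
  expect_identical(c1, c2)
  expect_false(identical(c1$alps, c3$alps))
})

test_that("n = 0 yields an empty table with the full schema", {
  coh <- generate_cohort(default_sem_params(n = 0, n_reference = 0))
  expect_equal(nrow(coh), 0)
  expect_true(all(c("id", "alps", "memory", "heart_disease") %in% names(coh)))
})

test_that("null generator (equal group means, zero paths) gives near-zero partials", {
  coh <- generate_cohort(null_sem_params(n = 40000, seed = 4))
  # adjust for the full covariate set so no covariate-induced (rather than
  # path-induced) association remains
  covs <- c("age", "sex", "tiv", "education", "apoe4_carrier")
  vars <- c("wmh_burden", "suvr", "alps", "choroid_norm", "memory",
            "language")
  for (i in seq_along(vars)[-length(vars)])
    for (j in (i + 1):length(vars)) {
      r <- partial_corr(coh, vars[i], vars[j], covs)$r
      expect_lt(abs(r), 0.03)
    }
})

test_that("an injected WMH-ALPS partial correlation is recovered at large n", {
  coh <- generate_cohort(default_sem_params(n = 10000, n_reference = 0,
                                            seed = 8))
  r <- partial_corr(coh, "wmh_burden", "alps",
                    c("age", "sex", "tiv", "apoe4_carrier"))$r
  expect_lt(abs(r - (-0.458)), 0.03)
})

test_that("sample moments at large n match the implied latent structure", {
  p <- default_sem_params(n = 50000, n_reference = 0, seed = 12)
  str <- sem_structure(p)
  coh <- generate_cohort(p)
  covs <- c("age", "sex", "tiv", "apoe4_carrier")
  # implied correlations of (alps, choroid, wmh) are reproduced within
  # 3 Monte-Carlo standard errors (~0.013 at n = 50000 for these r)
  pairs <- list(c("alps", "choroid_norm", str$Sigma4["alps", "choroid"]),
                c("wmh_burden", "alps", str$Sigma4["wmh", "alps"]),
                c("wmh_burden", "choroid_norm", str$Sigma4["wmh", "choroid"]))
  for (pr in pairs) {
    r <- partial_corr(coh, pr[1], pr[2], covs)$r
    expect_lt(abs(r - as.numeric(pr[3])), 3 / sqrt(nrow(coh)) * 1.1)
  }
  # marker locations land on the requested scale
  expect_lt(abs(mean(coh$alps) - p$alps_mean), 0.01)
  expect_lt(abs(sd(coh$alps) - p$alps_sd), 0.01)
})

test_that("infeasible effect sizes are rejected as non-invertible covariance", {
  expect_error(sem_params(r_wmh_alps = 0.9, r_abeta_alps = 0.9),
               "non-invertible")
  expect_error(sem_params(cut_bg = c(1, 1, 2)), "increasing")
  expect_error(sem_params(n = -1), ">= 0")
})

test_that("generator parameters round-trip through YAML", {
  p <- default_sem_params(n = 50, seed = 9, r_wmh_alps = -0.3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sem_params(p, f)
  p2 <- read_sem_params(f)
  expect_equal(unclass(p), unclass(p2), tolerance = 1e-12)
  expect_identical(generate_cohort(p), generate_cohort(p2))
})
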