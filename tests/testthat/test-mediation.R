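sim_mediation_data <- function(n = 300, a = 0.5, b = 0.4, cp = 0.2,
                               noise = 1, seed = 1) {
  set.seed(seed)
  d <- data.frame(age = rnorm(n, 75, 8), sex = rbinom(n, 1, 0.4),
                  apoe4_carrier = rbinom(n, 1, 0.5))
  d$x <- rnorm(n)
  d$m <- a * d$x + rnorm(n, 0, noise)
  d$y <- cp * d$x + b * d$m + rnorm(n, 0, noise)
  d
}

test_that("total = direct + indirect holds exactly on arbitrary data", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(30:150, 1)
    d <- data.frame(x = rnorm(n), m = rnorm(n), y = rnorm(n),
                    age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    apoe4_carrier = rbinom(n, 1, 0.5))
    res <- mediate(d, "x", "m", "y", n_boot = 100, seed = rep)
    expect_lt(abs(res$total - res$direct - res$indirect), 1e-10)
    # point estimates agree with the closed-form normal-equations oracle
    zs <- function(v) (v - mean(v)) / sd(v)
    o <- oracle_mediation(zs(d$x), zs(d$m), zs(d$y),
                          as.matrix(d[c("age", "sex", "apoe4_carrier")]))
    expect_lt(abs(res$indirect - o$indirect), 1e-10)
    expect_lt(abs(res$total - o$total), 1e-10)
  }
})

test_that("noiseless linear data give the exact path decomposition", {
  n <- 50
  set.seed(21)
  d <- data.frame(x = rnorm(n), age = rnorm(n), sex = rbinom(n, 1, 0.5),
                  apoe4_carrier = rbinom(n, 1, 0.5))
  # mediator variation orthogonal (in sample) to x and the covariates keeps
  # the design identifiable while leaving every path coefficient exact
  e <- lm.fit(cbind(1, d$x, d$age, d$sex, d$apoe4_carrier),
              rnorm(n))$residuals
  d$m <- 2 * d$x + e
  d$y <- 1 * d$x + 0.5 * d$m
  res <- mediate(d, "x", "m", "y", n_boot = 100, seed = 1,
                 standardize = FALSE)
  expect_equal(res$a, 2, tolerance = 1e-10)
  expect_equal(res$b, 0.5, tolerance = 1e-10)
  expect_equal(res$indirect, 1.0, tolerance = 1e-10)
  expect_equal(res$total, 2.0, tolerance = 1e-10)
})

test_that("bootstrap is deterministic given the seed and preserves caller RNG", {
  d <- sim_mediation_data(150, seed = 3)
  set.seed(42); marker <- rnorm(1)
  r1 <- mediate(d, "x", "m", "y", n_boot = 200, seed = 7)
  r2 <- mediate(d, "x", "m", "y", n_boot = 200, seed = 7)
  r3 <- mediate(d, "x", "m", "y", n_boot = 200, seed = 8)
  expect_identical(r1$ci, r2$ci)
  expect_false(identical(r1$ci, r3$ci))
  set.seed(42)
  expect_identical(rnorm(1), marker)
})

test_that("null mediator effect gives CIs that cover zero at roughly nominal rate", {
  covered <- vapply(1:60, function(s) {
    d <- sim_mediation_data(400, a = 0.5, b = 0, cp = 0.3, seed = 100 + s)
    res <- mediate(d, "x", "m", "y", n_boot = 200, seed = s)
    res$ci["indirect", 1] <= 0 && res$ci["indirect", 2] >= 0
  }, logical(1))
  expect_gt(mean(covered), 0.85)
})

test_that("mediate validates its inputs", {
  d <- sim_mediation_data(50)
  expect_error(mediate(d, "x", "m", "y", n_boot = 50), ">= 100")
  expect_error(mediate(d, "x", "m", "nope", n_boot = 100), "lacks column")
  d$x2 <- d$x
  expect_error(mediate(d, "x", "m", "y", covariates = c("x2", "age"),
                       n_boot = 100), "rank-deficient")
  expect_error(mediate(d[1:5, ], "x", "m", "y", n_boot = 100), "at least")
})

test_that("battery has the 2 x 4 grid per mediator and per-mediator FDR", {
  coh <- generate_cohort(default_sem_params(seed = 30, n_reference = 0))
  bat <- mediation_battery(coh, n_boot = 120, seed = 5)
  expect_equal(nrow(bat), 16)
  expect_equal(unname(table(bat$mediator)), c(8L, 8L), ignore_attr = TRUE)
  for (med in unique(bat$mediator)) {
    sel <- bat$mediator == med
    expect_equal(bat$fdr_p[sel], fdr_adjust(bat$p[sel]))
  }
  expect_true(all(bat$ci_lower <= bat$indirect + 1e-12 |
                    bat$ci_upper >= bat$indirect - 1e-12))
  expect_lt(max(abs(bat$total - bat$direct - bat$indirect)), 1e-10)
})

test_that("a single non-null path is the battery's strongest signal", {
  hits <- vapply(1:20, function(s) {
    d <- sim_mediation_data(800, a = -0.45, b = 0.45, cp = -0.1,
                            seed = 200 + s)
    names(d)[names(d) == "x"] <- "wmh_burden"
    names(d)[names(d) == "m"] <- "alps"
    names(d)[names(d) == "y"] <- "memory"
    set.seed(1000 + s)
    d$suvr <- rnorm(nrow(d))
    d$choroid_norm <- rnorm(nrow(d))
    d$executive <- rnorm(nrow(d)); d$visuospatial <- rnorm(nrow(d))
    d$language <- rnorm(nrow(d))
    bat <- mediation_battery(d, n_boot = 150, seed = s)
    target <- bat$exposure == "wmh_burden" & bat$mediator == "alps" &
      bat$outcome == "memory"
    rank(abs(bat$indirect))[target] == nrow(bat) && bat$fdr_p[target] <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
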