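test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(30:200, 1)
    k <- sample(0:4, 1)
    Z <- if (k) matrix(rnorm(n * k), n) else NULL
    x <- rnorm(n) + if (k) Z %*% rnorm(k) else 0
    y <- rnorm(n) + 0.4 * x + if (k) Z %*% rnorm(k) else 0
    d <- data.frame(x = as.numeric(x), y = as.numeric(y))
    covs <- character(0)
    if (k) {
      covs <- paste0("z", seq_len(k))
      d[covs] <- as.data.frame(Z)
    }
    pc <- partial_corr(d, "x", "y", covs)
    expect_lt(abs(pc$r - oracle_partial_corr(d$x, d$y, Z)), 1e-12)
  }
})

test_that("partial correlation handles identity, null and rank cases", {
  d <- data.frame(x = rnorm(50))
  d$y <- d$x
  expect_equal(partial_corr(d, "x", "y")$r, 1)
  # x and y conditionally independent given z
  set.seed(11)
  z <- rnorm(10000)
  d2 <- data.frame(x = z + rnorm(10000), y = z + rnorm(10000), z = z)
  pc <- partial_corr(d2, "x", "y", "z")
  expect_lt(abs(pc$r), 0.03)
  # spearman variant is invariant to monotone transforms of x and y
  d3 <- data.frame(x = rexp(200), z = rnorm(200))
  d3$y <- d3$x^2 + rnorm(200, 0, 0.1)
  r1 <- partial_corr(d3, "x", "y", "z", method = "spearman")$r
  d3$x <- log(d3$x); d3$y <- sqrt(d3$y - min(d3$y) + 1)
  r2 <- partial_corr(d3, "x", "y", "z", method = "spearman")$r
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_error(partial_corr(data.frame(x = 1:2, y = 1:2), "x", "y",
                            character(0)), "complete cases")
  d4 <- data.frame(x = rep(1, 30), y = rnorm(30))
  expect_error(partial_corr(d4, "x", "y"), "zero-variance")
})

test_that("BH adjustment equals the definitional brute force on all orderings", {
  base_sets <- list(
    c(0.01, 0.02, 0.03, 0.04),
    c(0.001, 0.008, 0.039, 0.041, 0.27, 0.9),
    runif(5),
    c(0.5, 0.5, 0.5),
    c(1, 1, 1, 1))
  for (p in base_sets) {
    # every permutation must agree with the oracle and preserve input order
    perms <- permutations(length(p))
    for (i in seq_len(nrow(perms))) {
      pp <- p[perms[i, ]]
      expect_equal(fdr_adjust(pp), oracle_bh(pp), tolerance = 1e-12)
    }
  }
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("ordinal fit recovers a known latent slope and flags degeneracy", {
  set.seed(12)
  n <- 5000
  d <- data.frame(wmh_burden = rnorm(n), suvr = rnorm(n), age = rnorm(n),
                  sex = rbinom(n, 1, 0.5), tiv = rnorm(n))
  latent <- 1.0 * d$wmh_burden + rlogis(n)
  d$grade <- findInterval(latent, c(-1, 0, 1)) + 1L
  fit <- ordinal_fit(d, "grade", model = 1)
  beta <- fit$coefficients
  expect_lt(abs(beta$beta[beta$term == "wmh_burden"] - 1.0), 0.15)
  expect_lt(abs(beta$beta[beta$term == "suvr"]), 0.1)
  expect_true(fit$converged)
  expect_true(all(diff(fit$cutpoints) > 0))
  d$grade <- 2L
  expect_error(ordinal_fit(d, "grade"), "single observed grade")
})

test_that("null ordinal model gives small slopes", {
  set.seed(13)
  n <- 5000
  d <- data.frame(wmh_burden = rnorm(n), suvr = rnorm(n), age = rnorm(n),
                  sex = rbinom(n, 1, 0.5), tiv = rnorm(n),
                  grade = findInterval(rlogis(n), c(-1, 0, 1)) + 1L)
  fit <- ordinal_fit(d, "grade", model = 1)
  expect_true(all(abs(fit$coefficients$beta[1:2]) < 0.1))
})

test_that("group comparison detects a shifted group and respects a true null", {
  set.seed(14)
  d <- data.frame(group = rep(c("A", "B"), each = 200),
                  age = rnorm(400, 75, 5), sex = rbinom(400, 1, 0.4))
  d$age[d$group == "B"] <- d$age[d$group == "B"] + 15  # 3 SD shift
  tab <- group_compare(d, continuous = "age", categorical = "sex")
  expect_lt(as.numeric(tab$p[tab$variable == "age"]), 0.001)
  # identical categorical distributions give a zero chi-square statistic
  d2 <- data.frame(group = rep(c("A", "B"), each = 100),
                   sex = rep(c(0, 1), 200))
  tab2 <- group_compare(d2, continuous = character(0), categorical = "sex")
  expect_match(tab2$statistic, "0.00")
  expect_error(group_compare(d[d$group == "A", ]), "2 groups")
})

test_that("continuum curve is flat for constant scores and monotone for monotone means", {
  stage <- rep(c("CN-", "CN+", "MCI+", "AD+"), each = 30)
  flat <- continuum_curve(rep(2, 120) + rnorm(120, 0, 1e-8), stage,
                          n_boot = 20)
  expect_lt(diff(range(flat$grid$fit)), 1e-6)
  set.seed(15)
  w <- as.integer(factor(stage, levels = c("CN-", "CN+", "MCI+", "AD+"))) +
    rnorm(120, 0, 0.2)
  cc <- continuum_curve(w, stage, seed = 2)
  expect_true(all(diff(cc$fitted_at_stage) > 0))
  expect_true(all(cc$grid$lower <= cc$grid$upper))
  # deterministic given the seed
  cc2 <- continuum_curve(w, stage, seed = 2)
  expect_identical(cc$grid, cc2$grid)
  expect_error(continuum_curve(w[1:90], stage[1:90]), "must be present")
})
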