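#' Parameters of the synthetic cohort generator
#'
#' The generator is a linear structural-equation model over standardized
#' latent variables: two exposures (WMH burden, global amyloid SUVR) whose
#' locations shift across the AD-continuum groups, two glymphatic mediators
#' (ALPS, normalized choroid plexus volume) and four cognitive composites
#' driven by the exposures and mediators, plus covariates (age, sex, TIV,
#' education, APOE e4) and latent-threshold ordinal PVS grades. Effect sizes
#' are injected as covariate-adjusted partial correlations: path coefficients
#' are back-solved analytically so that, in the population, the partial
#' correlation between any marker pair given the adjustment covariates equals
#' the requested value (see [sem_structure()]).
#'
#' Defaults reproduce the study conditions of an amyloid-positive
#' AD-continuum cohort: n = 93 split 48/26/19 across CN+/MCI+/AD+, a CN-
#' reference group of 40, group means and SDs for SUVR and WMH burden, and
#' the reported model-2 partial correlations (WMH-ALPS -0.458, amyloid-ALPS
#' -0.249, WMH-choroid 0.294, amyloid-choroid 0.223) and marker-cognition
#' correlations (ALPS: 0.470/0.358/0.223/0.419; choroid:
#' -0.315/-0.321/-0.233/-0.261 for memory/executive/visuospatial/language).
#'
#' Note: even with all path coefficients at 0 the two exposures retain a
#' small (~0.04) correlation induced by their shared group-mean structure; a
#' strict null requires equal group means.
#'
#' @param n number of amyloid-positive participants (>= 0).
#' @param n_reference number of CN- reference participants (>= 0).
#' @param group_weights allocation weights of the positive groups.
#' @param suvr_mean,suvr_sd,wmh_mean,wmh_sd named per-group location/scale of
#'   the exposures (groups `CN-`, `CN+`, `MCI+`, `AD+`).
#' @param r_wmh_alps,r_abeta_alps,r_wmh_choroid,r_abeta_choroid target
#'   covariate-adjusted partial correlations, exposure -> mediator.
#' @param r_alps_cog,r_choroid_cog named (memory, executive, visuospatial,
#'   language) target partial correlations, mediator -> cognition.
#' @param c_wmh_cog,c_abeta_cog direct standardized effects of the exposures
#'   on each cognitive domain (held fixed while mediator paths are solved).
#' @param alps_mean,alps_sd,choroid_mean,choroid_sd marker location/scale.
#' @param age_mean,age_sd,tiv_mean,tiv_sd,edu_mean,edu_sd,sex_p,apoe_p
#'   covariate distributions (sex is Bernoulli(`sex_p`) male, APOE carriage
#'   Bernoulli(`apoe_p`)).
#' @param gamma named list of covariate effects (on the standardized scale)
#'   for each endogenous variable; each element is a named vector over
#'   `age`, `sex`, `tiv`, `education`, `apoe`.
#' @param theta_bg,theta_wm latent slopes (per standardized exposure, order
#'   `wmh`, `abeta`) of the basal-ganglia and white-matter PVS grades.
#' @param cut_bg,cut_wm strictly increasing length-3 latent cutpoints.
#' @param n_boot default bootstrap replicate count consumed by downstream
#'   mediation (5000).
#' @param seed integer seed.
#' @return An object of class `sem_params`.
#' @seealso [default_sem_params()], [generate_cohort()]
#' @export
sem_params <- function(
    n = 93L, n_reference = 40L,
    group_weights = c("CN+" = 48, "MCI+" = 26, "AD+" = 19),
    suvr_mean = c("CN-" = 1.024, "CN+" = 1.298, "MCI+" = 1.458, "AD+" = 1.417),
    suvr_sd = c("CN-" = 0.047, "CN+" = 0.178, "MCI+" = 0.201, "AD+" = 0.161),
    wmh_mean = c("CN-" = -0.006, "CN+" = 0.391, "MCI+" = 0.418, "AD+" = 0.868),
    wmh_sd = c("CN-" = 0.505, "CN+" = 0.723, "MCI+" = 0.646, "AD+" = 0.532),
    r_wmh_alps = -0.458, r_abeta_alps = -0.249,
    r_wmh_choroid = 0.294, r_abeta_choroid = 0.223,
    r_alps_cog = c(memory = 0.470, executive = 0.358,
                   visuospatial = 0.223, language = 0.419),
    r_choroid_cog = c(memory = -0.315, executive = -0.321,
                      visuospatial = -0.233, language = -0.261),
    c_wmh_cog = c(memory = -0.1, executive = -0.1,
                  visuospatial = -0.1, language = -0.1),
    c_abeta_cog = c(memory = -0.1, executive = -0.1,
                    visuospatial = -0.1, language = -0.1),
    alps_mean = 1.28, alps_sd = 0.16,
    choroid_mean = 1.06, choroid_sd = 0.26,
    age_mean = 75.2, age_sd = 8.4, tiv_mean = 1470, tiv_sd = 160,
    edu_mean = 16.1, edu_sd = 2.4, sex_p = 0.38, apoe_p = 0.5,
    gamma = NULL,
    theta_bg = c(wmh = 0.34, abeta = -0.24),
    theta_wm = c(wmh = -0.04, abeta = -0.15),
    cut_bg = c(-1.5, 0.5, 2.5), cut_wm = c(-1.5, 0.5, 2.5),
    n_boot = 5000L, seed = 1L) {

  if (n < 0 || n_reference < 0) stop("n and n_reference must be >= 0")
  if (any(c(suvr_sd, wmh_sd, alps_sd, choroid_sd, age_sd, tiv_sd, edu_sd) <= 0))
    stop("all residual/marker SDs must be > 0")
  if (any(diff(cut_bg) <= 0) || any(diff(cut_wm) <= 0))
    stop("ordinal cutpoints must be strictly increasing")
  if (sex_p <= 0 || sex_p >= 1 || apoe_p <= 0 || apoe_p >= 1)
    stop("sex_p and apoe_p must be in (0, 1)")
  if (is.null(gamma)) gamma <- default_gamma()
  gamma <- lapply(gamma, function(g) {
    full <- setNames(numeric(5), c("age", "sex", "tiv", "education", "apoe"))
    full[names(g)] <- g
    full
  })
  p <- list(
    n = as.integer(n), n_reference = as.integer(n_reference),
    group_weights = group_weights,
    suvr_mean = suvr_mean, suvr_sd = suvr_sd,
    wmh_mean = wmh_mean, wmh_sd = wmh_sd,
    r_wmh_alps = r_wmh_alps, r_abeta_alps = r_abeta_alps,
    r_wmh_choroid = r_wmh_choroid, r_abeta_choroid = r_abeta_choroid,
    r_alps_cog = r_alps_cog, r_choroid_cog = r_choroid_cog,
    c_wmh_cog = c_wmh_cog, c_abeta_cog = c_abeta_cog,
    alps_mean = alps_mean, alps_sd = alps_sd,
    choroid_mean = choroid_mean, choroid_sd = choroid_sd,
    age_mean = age_mean, age_sd = age_sd, tiv_mean = tiv_mean,
    tiv_sd = tiv_sd, edu_mean = edu_mean, edu_sd = edu_sd,
    sex_p = sex_p, apoe_p = apoe_p, gamma = gamma,
    theta_bg = theta_bg, theta_wm = theta_wm,
    cut_bg = cut_bg, cut_wm = cut_wm,
    n_boot = as.integer(n_boot), seed = as.integer(seed)
  )
  class(p) <- "sem_params"
  sem_structure(p)  # validates feasibility; error if implied cov degenerate
  p
}

# Default covariate effects on the standardized scale. TIV has no effect on
# any endogenous variable (ALPS is a ratio, choroid is already
# TIV-normalized) and education only affects cognition, so that the injected
# partial correlations hold exactly under both adjustment sets in use
# (age/sex/TIV/APOE for marker-marker, age/sex/education/APOE for
# marker-cognition).
default_gamma <- function() {
  cog <- c(age = -0.15, education = 0.25, apoe = -0.10)
  list(
    wmh = c(age = 0.30),
    abeta = c(age = 0.15, apoe = 0.25),
    alps = c(age = -0.30, sex = 0.10),
    choroid = c(age = 0.20, sex = 0.15),
    memory = cog, executive = cog, visuospatial = cog, language = cog
  )
}

#' Study-condition default generator parameters
#'
#' Returns the fully populated default [sem_params()]: 93 amyloid-positive
#' participants (48 CN+, 26 MCI+, 19 AD+) plus 40 CN- reference records,
#' exposure locations per group, the reported covariate-adjusted partial
#' correlations as generative effect sizes, and a default downstream
#' bootstrap replicate count of 5000.
#'
#' @param ... overrides passed to [sem_params()].
#' @return An `sem_params` object.
#' @export
default_sem_params <- function(...) sem_params(...)

#' Implied latent structure of the cohort generator
#'
#' Back-solves the path coefficients from the requested partial correlations
#' and returns the implied correlation matrix of the standardized latent
#' variables, the residual SDs and the covariate loading scales. Errors when
#' the requested correlations are infeasible (non-positive implied residual
#' variance, i.e. a non-invertible implied covariance).
#'
#' @param params an [sem_params()].
#' @return A list: `rho_wa` (exposure correlation induced by the group
#'   mixture), `Sigma4` (implied correlation of alps, choroid, wmh, abeta),
#'   `beta_alps`, `beta_choroid`, `tau_alps`, `tau_choroid`, per-domain
#'   `beta_cog` and `tau_cog`, mixture moments and `lambda` scales.
#' @export
sem_structure <- function(params) {
  stopifnot(inherits(params, "sem_params"))
  pos <- names(params$group_weights)
  pi_g <- params$group_weights / sum(params$group_weights)

  mix <- function(mean, sd) {
    m <- sum(pi_g * mean[pos])
    v <- sum(pi_g * (sd[pos]^2 + mean[pos]^2)) - m^2
    list(mean = m, sd = sqrt(v))
  }
  mm_suvr <- mix(params$suvr_mean, params$suvr_sd)
  mm_wmh <- mix(params$wmh_mean, params$wmh_sd)

  # exposure correlation induced by shared group means (within-group noises
  # are independent)
  z_w <- (params$wmh_mean[pos] - mm_wmh$mean) / mm_wmh$sd
  z_a <- (params$suvr_mean[pos] - mm_suvr$mean) / mm_suvr$sd
  rho_wa <- sum(pi_g * z_w * z_a)

  Sigma2 <- matrix(c(1, rho_wa, rho_wa, 1), 2)
  solve_path <- function(r_targets, label) {
    beta <- solve(Sigma2, r_targets)
    tau2 <- 1 - drop(t(beta) %*% Sigma2 %*% beta)
    if (tau2 <= 0)
      stop("requested partial correlations for ", label,
           " imply a non-invertible covariance (residual variance <= 0)")
    list(beta = beta, tau = sqrt(tau2))
  }
  al <- solve_path(c(params$r_wmh_alps, params$r_abeta_alps), "alps")
  ch <- solve_path(c(params$r_wmh_choroid, params$r_abeta_choroid), "choroid")

  rho_ac <- drop(t(al$beta) %*% Sigma2 %*% ch$beta)
  Sigma4 <- rbind(
    c(1, rho_ac, params$r_wmh_alps, params$r_abeta_alps),
    c(rho_ac, 1, params$r_wmh_choroid, params$r_abeta_choroid),
    c(params$r_wmh_alps, params$r_wmh_choroid, 1, rho_wa),
    c(params$r_abeta_alps, params$r_abeta_choroid, rho_wa, 1))
  dimnames(Sigma4) <- rep(list(c("alps", "choroid", "wmh", "abeta")), 2)

  domains <- names(params$r_alps_cog)
  beta_cog <- list(); tau_cog <- numeric(0)
  for (d in domains) {
    cc <- c(params$c_wmh_cog[d], params$c_abeta_cog[d])
    rhs <- c(params$r_alps_cog[d], params$r_choroid_cog[d]) -
      drop(Sigma4[1:2, 3:4] %*% cc)
    b <- solve(Sigma4[1:2, 1:2], rhs)
    beta4 <- c(b, cc)
    tau2 <- 1 - drop(t(beta4) %*% Sigma4 %*% beta4)
    if (tau2 <= 0)
      stop("requested correlations for cognitive domain '", d,
           "' imply a non-invertible covariance")
    beta_cog[[d]] <- setNames(beta4, c("alps", "choroid", "wmh", "abeta"))
    tau_cog[d] <- sqrt(tau2)
  }

  lambda <- vapply(params$gamma, function(g) {
    s2 <- 1 - sum(g^2)
    if (s2 <= 0) stop("covariate effects too large: sum of squared gamma ",
                      "must be < 1")
    sqrt(s2)
  }, numeric(1))

  list(rho_wa = rho_wa, Sigma4 = Sigma4,
       beta_alps = al$beta, tau_alps = al$tau,
       beta_choroid = ch$beta, tau_choroid = ch$tau,
       beta_cog = beta_cog, tau_cog = tau_cog,
       mm_suvr = mm_suvr, mm_wmh = mm_wmh, lambda = lambda)
}

cohort_columns <- function() {
  c("id", "group", "diagnosis", "age", "sex", "education", "apoe4_carrier",
    "tiv", "suvr", "wmh_volume", "wmh_burden", "choroid_mm3", "choroid_norm",
    "bg_pvs_grade", "wm_pvs_grade", "alps",
    "memory", "executive", "visuospatial", "language",
    "fazekas", "gds", "acpc_angle_deg", "pet_dti_interval_months",
    "hypertension", "diabetes", "hyperlipidemia", "smoking", "heart_disease")
}

#' Generate a synthetic AD-continuum cohort
#'
#' Draws a cohort from the structural-equation model described in
#' [sem_params()]: `n_reference` CN- records plus `n` amyloid-positive
#' records allocated across CN+/MCI+/AD+ by the group weights. Observed SUVR
#' is clamped to respect each group's amyloid status (positive groups
#' strictly above the 1.11 cutoff, CN- at or below it); the latent amyloid
#' variable driving the path structure is the unclamped draw, so injected
#' WMH-related and mediator-cognition partial correlations are unaffected.
#' The caller's RNG state is preserved.
#'
#' @param params an [sem_params()]; `params$seed` drives all randomness.
#' @return A data frame, one row per participant, with the full marker /
#'   covariate / QC schema (see package vignette). `n = n_reference = 0`
#'   yields an empty table with the full schema.
#' @export
generate_cohort <- function(params = default_sem_params()) {
  stopifnot(inherits(params, "sem_params"))
  str <- sem_structure(params)
  n_pos <- params$n; n_ref <- params$n_reference
  n <- n_pos + n_ref
  if (n == 0L) return(empty_cohort())

  with_preserved_seed(params$seed, {
    group <- c(rep("CN-", n_ref),
               allocate_groups(n_pos, params$group_weights))

    # covariates (raw and analytically standardized)
    age <- round(rnorm(n, params$age_mean, params$age_sd), 1)
    sex <- rbinom(n, 1, params$sex_p)
    tiv <- round(rnorm(n, params$tiv_mean, params$tiv_sd), 1)
    education <- round(rnorm(n, params$edu_mean, params$edu_sd), 1)
    apoe <- rbinom(n, 1, params$apoe_p)
    Cs <- cbind(
      age = (age - params$age_mean) / params$age_sd,
      sex = (sex - params$sex_p) / sqrt(params$sex_p * (1 - params$sex_p)),
      tiv = (tiv - params$tiv_mean) / params$tiv_sd,
      education = (education - params$edu_mean) / params$edu_sd,
      apoe = (apoe - params$apoe_p) / sqrt(params$apoe_p * (1 - params$apoe_p)))

    # exposures: group-mixture draws standardized by the amyloid-positive
    # mixture moments
    suvr_latent <- rnorm(n, params$suvr_mean[group], params$suvr_sd[group])
    wmh_latent <- rnorm(n, params$wmh_mean[group], params$wmh_sd[group])
    s_abeta <- (suvr_latent - str$mm_suvr$mean) / str$mm_suvr$sd
    s_wmh <- (wmh_latent - str$mm_wmh$mean) / str$mm_wmh$sd

    # mediators and cognition on the standardized latent scale
    s_alps <- str$beta_alps[1] * s_wmh + str$beta_alps[2] * s_abeta +
      str$tau_alps * rnorm(n)
    s_choroid <- str$beta_choroid[1] * s_wmh + str$beta_choroid[2] * s_abeta +
      str$tau_choroid * rnorm(n)
    S4 <- cbind(alps = s_alps, choroid = s_choroid, wmh = s_wmh,
                abeta = s_abeta)
    domains <- names(str$beta_cog)
    s_cog <- matrix(0, n, length(domains), dimnames = list(NULL, domains))
    for (d in domains)
      s_cog[, d] <- drop(S4 %*% str$beta_cog[[d]]) + str$tau_cog[d] * rnorm(n)

    # observed scale: covariate part + scaled structural part
    observed <- function(v, s) {
      drop(Cs %*% params$gamma[[v]]) + str$lambda[v] * s
    }
    z_wmh <- observed("wmh", s_wmh)
    z_abeta <- observed("abeta", s_abeta)
    z_alps <- observed("alps", s_alps)
    z_choroid <- observed("choroid", s_choroid)

    wmh_burden <- str$mm_wmh$mean + str$mm_wmh$sd * z_wmh
    suvr <- str$mm_suvr$mean + str$mm_suvr$sd * z_abeta
    # respect each group's amyloid status at the 1.11 cutoff
    suvr <- ifelse(group == "CN-", pmin(suvr, 1.109), pmax(suvr, 1.111))
    alps <- params$alps_mean + params$alps_sd * z_alps
    choroid_norm <- pmax(params$choroid_mean + params$choroid_sd * z_choroid,
                         0.05)
    cog <- matrix(0, n, length(domains), dimnames = list(NULL, domains))
    for (d in domains) cog[, d] <- observed(d, s_cog[, d])

    # ordinal PVS grades from a latent cumulative-logit model
    lat_bg <- params$theta_bg["wmh"] * s_wmh +
      params$theta_bg["abeta"] * s_abeta + rlogis(n)
    lat_wm <- params$theta_wm["wmh"] * s_wmh +
      params$theta_wm["abeta"] * s_abeta + rlogis(n)
    bg_pvs <- findInterval(lat_bg, params$cut_bg) + 1L
    wm_pvs <- findInterval(lat_wm, params$cut_wm) + 1L

    fazekas <- ifelse(group == "CN-",
                      sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4)),
                      findInterval(s_wmh, c(-0.3, 0.8, 1.8)))

    df <- data.frame(
      id = sprintf("S%04d", seq_len(n)),
      group = group,
      diagnosis = c("CN-" = "CN", "CN+" = "CN", "MCI+" = "MCI",
                    "AD+" = "dementia")[group],
      age = age, sex = sex, education = education,
      apoe4_carrier = apoe, tiv = tiv,
      suvr = suvr, wmh_volume = 10^wmh_burden, wmh_burden = wmh_burden,
      choroid_mm3 = choroid_norm * tiv, choroid_norm = choroid_norm,
      bg_pvs_grade = bg_pvs, wm_pvs_grade = wm_pvs, alps = alps,
      memory = cog[, "memory"], executive = cog[, "executive"],
      visuospatial = cog[, "visuospatial"], language = cog[, "language"],
      fazekas = as.integer(fazekas),
      gds = sample(0:4, n, replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.07, 0.03)),
      acpc_angle_deg = round(pmin(abs(rnorm(n, 5, 4)), 19.5), 1),
      pet_dti_interval_months = round(runif(n, 0, 11.5), 1),
      hypertension = rbinom(n, 1, 0.44),
      diabetes = rbinom(n, 1, 0.07),
      hyperlipidemia = rbinom(n, 1, 0.47),
      smoking = rbinom(n, 1, 0.17),
      heart_disease = rbinom(n, 1, 0.13),
      row.names = NULL, stringsAsFactors = FALSE
    )
    rownames(df) <- NULL
    df
  })
}

# zero-row cohort carrying the full, correctly typed schema
empty_cohort <- function() {
  data.frame(
    id = character(0), group = character(0), diagnosis = character(0),
    age = numeric(0), sex = integer(0), education = numeric(0),
    apoe4_carrier = integer(0), tiv = numeric(0), suvr = numeric(0),
    wmh_volume = numeric(0), wmh_burden = numeric(0),
    choroid_mm3 = numeric(0), choroid_norm = numeric(0),
    bg_pvs_grade = integer(0), wm_pvs_grade = integer(0), alps = numeric(0),
    memory = numeric(0), executive = numeric(0), visuospatial = numeric(0),
    language = numeric(0), fazekas = integer(0), gds = integer(0),
    acpc_angle_deg = numeric(0), pet_dti_interval_months = numeric(0),
    hypertension = integer(0), diabetes = integer(0),
    hyperlipidemia = integer(0), smoking = integer(0),
    heart_disease = integer(0), stringsAsFactors = FALSE)
}

# largest-remainder allocation of n participants to weighted groups
allocate_groups <- function(n, weights) {
  if (n == 0L) return(character(0))
  target <- n * weights / sum(weights)
  counts <- floor(target)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(weights), counts)
}

#' Serialize / deserialize generator parameters as YAML
#'
#' @param params an [sem_params()].
#' @param path YAML file path.
#' @return `write_sem_params()` returns `path` invisibly;
#'   `read_sem_params()` returns the reconstructed `sem_params`.
#' @export
write_sem_params <- function(params, path) {
  stopifnot(inherits(params, "sem_params"))
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(unclass(params)), path)
  invisible(path)
}

#' @rdname write_sem_params
#' @export
read_sem_params <- function(path) {
  y <- yaml::read_yaml(path)
  num <- function(x) if (is.list(x)) unlist(x) else x
  do.call(sem_params, list(
    n = y$n, n_reference = y$n_reference,
    group_weights = num(y$group_weights),
    suvr_mean = num(y$suvr_mean), suvr_sd = num(y$suvr_sd),
    wmh_mean = num(y$wmh_mean), wmh_sd = num(y$wmh_sd),
    r_wmh_alps = y$r_wmh_alps, r_abeta_alps = y$r_abeta_alps,
    r_wmh_choroid = y$r_wmh_choroid, r_abeta_choroid = y$r_abeta_choroid,
    r_alps_cog = num(y$r_alps_cog), r_choroid_cog = num(y$r_choroid_cog),
    c_wmh_cog = num(y$c_wmh_cog), c_abeta_cog = num(y$c_abeta_cog),
    alps_mean = y$alps_mean, alps_sd = y$alps_sd,
    choroid_mean = y$choroid_mean, choroid_sd = y$choroid_sd,
    age_mean = y$age_mean, age_sd = y$age_sd, tiv_mean = y$tiv_mean,
    tiv_sd = y$tiv_sd, edu_mean = y$edu_mean, edu_sd = y$edu_sd,
    sex_p = y$sex_p, apoe_p = y$apoe_p,
    gamma = lapply(y$gamma, num),
    theta_bg = num(y$theta_bg), theta_wm = num(y$theta_wm),
    cut_bg = num(y$cut_bg), cut_wm = num(y$cut_wm),
    n_boot = y$n_boot, seed = y$seed))
}
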