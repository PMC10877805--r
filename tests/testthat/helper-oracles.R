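# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take different numerical routes than the package code.

# partial correlation via explicit projection matrices (normal equations,
# not QR): residualize x and y on [1, Z] and correlate.
oracle_partial_corr <- function(x, y, Z = NULL) {
  n <- length(x)
  X <- cbind(rep(1, n), Z)
  P <- X %*% solve(t(X) %*% X) %*% t(X)
  rx <- x - P %*% x
  ry <- y - P %*% y
  drop((t(rx) %*% ry) / sqrt((t(rx) %*% rx) * (t(ry) %*% ry)))
}

# definitional Benjamini-Hochberg: adjusted p_(k) = min_{j >= k} n p_(j) / j,
# written as an explicit double loop over sorted indices.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (k in seq_len(n)) {
    best <- Inf
    for (j in k:n) best <- min(best, n * ps[j] / j)
    adj[k] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# closed-form OLS mediation effects via solve() on the normal equations
oracle_mediation <- function(x, m, y, Z = NULL) {
  n <- length(x)
  ols <- function(X, v) solve(t(X) %*% X, t(X) %*% v)
  X1 <- cbind(1, x, Z)
  a <- ols(X1, m)[2]
  X2 <- cbind(1, x, m, Z)
  f2 <- ols(X2, y)
  total <- ols(X1, y)[2]
  list(a = a, b = f2[3], direct = f2[2], indirect = a * f2[3],
       total = total)
}

# brute-force spherical mask: triple loop over all voxels
oracle_sphere_count <- function(vol, center, radius) {
  dims <- dim(vol$dxx)
  count <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      mm <- vol$affine %*% c(i - 1, j - 1, k - 1, 1)
      if (sum((mm[1:3] - center)^2) <= radius^2 + 1e-9)
        count <- count + 1L
    }
  count
}

# all permutations of 1..n (n <= 6) as rows of a matrix
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# a small off-template grid that still contains the default ROI set
small_phantom_spec <- function(...) {
  phantom_spec(dims = c(48L, 56L, 48L), ...)
}

# quick null cohort: equal group means, all paths zero
null_sem_params <- function(n = 2000, seed = 1) {
  eq <- c("CN-" = 1.3, "CN+" = 1.3, "MCI+" = 1.3, "AD+" = 1.3)
  sdq <- c("CN-" = 0.15, "CN+" = 0.15, "MCI+" = 0.15, "AD+" = 0.15)
  wq <- c("CN-" = 0.3, "CN+" = 0.3, "MCI+" = 0.3, "AD+" = 0.3)
  wsd <- c("CN-" = 0.6, "CN+" = 0.6, "MCI+" = 0.6, "AD+" = 0.6)
  sem_params(n = n, n_reference = 0,
             suvr_mean = eq, suvr_sd = sdq, wmh_mean = wq, wmh_sd = wsd,
             r_wmh_alps = 0, r_abeta_alps = 0,
             r_wmh_choroid = 0, r_abeta_choroid = 0,
             r_alps_cog = c(memory = 0, executive = 0, visuospatial = 0,
                            language = 0),
             r_choroid_cog = c(memory = 0, executive = 0, visuospatial = 0,
                               language = 0),
             c_wmh_cog = c(memory = 0, executive = 0, visuospatial = 0,
                           language = 0),
             c_abeta_cog = c(memory = 0, executive = 0, visuospatial = 0,
                             language = 0),
             theta_bg = c(wmh = 0, abeta = 0),
             theta_wm = c(wmh = 0, abeta = 0),
             seed = seed)
}
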