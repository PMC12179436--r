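# Shared fixture builders. All synthetic, generated in code.

# minimal valid tract table with overridable columns
make_tracts <- function(n, ...) {
  df <- data.frame(
    tract_id = sprintf("m%03d", seq_len(n)),
    county = "c1",
    centroid_lat = 42 + seq_len(n) * 0.01,
    centroid_lon = -85 - seq_len(n) * 0.01,
    population = rep(1000L, n), workers = rep(500L, n),
    density = rep(100, n),
    pct_minority = seq(0, 100, length.out = n),
    pct_low_income = rep(30, n), pct_no_hs = rep(6, n),
    pct_under5 = rep(6, n), pct_over64 = rep(16, n),
    occ_contaminants = rep(50L, n), occ_equipment = rep(30L, n),
    occ_conditions = rep(20L, n), occ_disease = rep(20L, n),
    occ_proximity = rep(88L, n),
    occ_noise_workers = rep(60L, n),
    env_pm25 = rep(8, n), env_diesel = rep(0.3, n), env_ozone = rep(43, n),
    env_airtox_cancer = rep(24, n), env_resp_hazard = rep(0.3, n),
    env_traffic = rep(300, n), env_transport_noise_pct = rep(1, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  validate_tract_table(df)
}

# a well-separated three-blob exposure-profile config for recovery tests
blob_config <- function(seed, n_rows = 12, n_cols = 12) {
  cen <- rbind(c(30, 15, 10, 10, 60, 5, 6.0, 0.10, 38, 15, 0.10, 50, 0.5),
               c(90, 45, 30, 30, 110, 15, 7.5, 0.40, 43, 25, 0.30, 800, 5),
               c(160, 80, 50, 50, 170, 30, 9.5, 0.80, 48, 45, 0.50, 5000, 20))
  colnames(cen) <- c(occ_indicators(), env_indicators())
  sim_config(n_rows = n_rows, n_cols = n_cols, seed = seed,
             spatial_rho = 0, spatial_sd = 0, demog_effect = 0,
             cluster_spec = list(centroids = cen, weights = c(1, 1, 1) / 3,
                                 enrichment = c(0, 0, 0), cv = 0.05))
}

# best-permutation label accuracy for small k
perm_accuracy <- function(est, truth) {
  k <- max(est, truth)
  perms <- if (k == 1) list(1) else
    apply(gtools_permutations(k), 1, identity, simplify = FALSE)
  max(vapply(perms, function(p) mean(p[est] == truth), numeric(1)))
}

# all permutations of 1..k (tiny k) without extra dependencies
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- gtools_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(setdiff(seq_len(k), i)[sub], nrow = nrow(sub))) }))
}

# brute-force O(n^2) average silhouette oracle
silhouette_oracle <- function(z, labels) {
  n <- nrow(z)
  D <- as.matrix(stats::dist(z))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(D[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}
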