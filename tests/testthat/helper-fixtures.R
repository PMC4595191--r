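# Shared fixture builders. Everything is constructed in code; the only
# files read are the plain-text CSVs under inst/extdata.

make_obs <- function(animal, species, sex, region = "inguinal",
                     cluster = "c1", partner = NA_character_,
                     site = "S1", mode = "laid_down") {
  n <- max(length(animal), length(species), length(sex), length(region),
           length(cluster), length(partner))
  data.frame(site_id = rep_len(site, n),
             animal_id = rep_len(as.character(animal), n),
             inspection_mode = rep_len(mode, n),
             species = rep_len(species, n), sex = rep_len(sex, n),
             body_region = rep_len(region, n),
             cluster_id = rep_len(cluster, n),
             partner_species = rep_len(partner, n),
             stringsAsFactors = FALSE)
}

site55_table <- function() {
  read_mating_table(system.file("extdata", "site55_mating_table.csv",
                                package = "tickRI"))
}

site55_observations <- function() {
  read_survey(system.file("extdata", "site55_observations.csv",
                          package = "tickRI"))$observations
}

coinfestation_observations <- function() {
  read_survey(system.file("extdata", "coinfestation_observations.csv",
                          package = "tickRI"))$observations
}

# Brute-force checkerboard-unit oracle: counts ordered unit pairs (u, v)
# with group i present only in u and group j present only in v.
cscore_oracle <- function(m, g_i, g_j) {
  x <- m[, g_i] > 0
  y <- m[, g_j] > 0
  cb <- 0L
  for (u in seq_len(nrow(m))) {
    for (v in seq_len(nrow(m))) {
      if (u != v && x[u] && !y[u] && !x[v] && y[v]) cb <- cb + 1L
    }
  }
  cb / (sum(x) * sum(y))
}

# Independent beta-binomial log-pmf via log-gamma sums.
bb_logpmf_oracle <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
    lgamma(k + a) + lgamma(n - k + b) - lgamma(n + a + b) +
    lgamma(a + b) - lgamma(a) - lgamma(b)
}
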