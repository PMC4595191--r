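## Seeded synthetic-survey generators. The mechanistic generator emulates
## the hierarchical structure the analysis assumes: negative-binomial host
## burdens, pheromone-driven aggregation of males into clusters, female
## attraction to male clusters, species/sex-dependent mate choice and
## within-host correlation of mating outcomes. The direct-draw generator
## produces regression datasets from exact beta-binomial ground truth.

#' Simulation configuration
#'
#' Parameters of the synthetic survey world. Defaults describe a sympatric
#' contact-zone site: low, overdispersed adult burdens (a few ticks per
#' host), strong concentration of attachment on the perineum/inguinal/
#' axillary regions, con-specific-biased aggregation and mate choice, and
#' a within-host mating correlation of 0.37.
#'
#' @param n_sites number of sites.
#' @param animals_per_site animals examined per site.
#' @param mean_abundance named per-host mean adult burden per species.
#' @param nb_size negative-binomial dispersion (size) per species;
#'   small values give the aggregated counts typical of tick burdens.
#' @param male_fraction probability a tick is male.
#' @param attachment_pref 2 x 8 matrix of attachment-region preferences
#'   (rows `Av`, `Ah`, columns [BODY_REGIONS], rows sum to 1).
#' @param w_con,w_het,w_new male cluster-joining weights: an arriving male
#'   joins an existing cluster with weight `w_con` per con-specific male
#'   plus `w_het` per hetero-specific male, or founds a new cluster with
#'   weight `w_new`. `w_het = 0` strictly forbids joining clusters that
#'   contain hetero-specific males.
#' @param a_con,a_het,a_new female attraction weights over male clusters
#'   (per con-/hetero-specific male), and the weight of settling away from
#'   any male cluster.
#' @param m_con,m_het mate-choice odds per con-/hetero-specific male in
#'   the female's cluster.
#' @param single_prob probability an attached female remains single even
#'   when males are available in her cluster.
#' @param corridor_fraction fraction of animals examined in the corridor
#'   (no body-region or cluster detail recorded).
#' @param rho_sim,beta_sim ground truth for [generate_mating_counts()]:
#'   intraclass correlation and regression coefficients (intercept,
#'   species effect, x_male, x_female, interaction).
#' @param trials_mean mean extra trials per unit in
#'   [generate_mating_counts()] (trials ~ 1 + Poisson(trials_mean)).
#' @param n_units units for [generate_mating_counts()].
#' @param seed default seed used by the generators.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 1,
                              animals_per_site = 60,
                              mean_abundance = c(Av = 6, Ah = 3),
                              nb_size = c(Av = 1, Ah = 1),
                              male_fraction = 0.6,
                              attachment_pref = default_attachment_pref(),
                              w_con = 2, w_het = 1, w_new = 1,
                              a_con = 2, a_het = 1, a_new = 0.5,
                              m_con = 6, m_het = 1,
                              single_prob = 0.15,
                              corridor_fraction = 0,
                              rho_sim = 0.37,
                              beta_sim = c(intercept = 0.9, species = 0,
                                           x_male = 3, x_female = 0.5,
                                           interaction = -6),
                              trials_mean = 2,
                              n_units = 200,
                              seed = 1L) {
  cfg <- list(n_sites = n_sites, animals_per_site = animals_per_site,
              mean_abundance = mean_abundance, nb_size = nb_size,
              male_fraction = male_fraction,
              attachment_pref = attachment_pref,
              w_con = w_con, w_het = w_het, w_new = w_new,
              a_con = a_con, a_het = a_het, a_new = a_new,
              m_con = m_con, m_het = m_het, single_prob = single_prob,
              corridor_fraction = corridor_fraction,
              rho_sim = rho_sim, beta_sim = beta_sim,
              trials_mean = trials_mean, n_units = n_units, seed = seed)
  stopifnot(all(unlist(cfg[c("w_con", "w_het", "w_new", "a_con", "a_het",
                             "a_new", "m_con", "m_het")]) >= 0),
            single_prob >= 0, single_prob <= 1,
            male_fraction > 0, male_fraction < 1,
            corridor_fraction >= 0, corridor_fraction <= 1,
            rho_sim >= 0, rho_sim < 1,
            all(mean_abundance >= 0), all(nb_size > 0),
            identical(dim(attachment_pref), c(2L, 8L)),
            all(abs(rowSums(attachment_pref) - 1) < 1e-9),
            length(beta_sim) == 5)
  structure(cfg, class = "simulation_config")
}

#' Default species attachment-region preferences
#'
#' Over 90% of the mass on the perineum/inguinal/axillary regions for both
#' species, with mild between-species differences.
#'
#' @return 2 x 8 preference matrix (rows `Av`, `Ah`).
#' @export
default_attachment_pref <- function() {
  m <- rbind(Av = c(0.34, 0.34, 0.24, 0.02, 0.01, 0.01, 0.02, 0.02),
             Ah = c(0.40, 0.32, 0.20, 0.02, 0.01, 0.01, 0.02, 0.02))
  colnames(m) <- BODY_REGIONS
  m
}

# Cluster weight seen by an arriving male of the focal species.
male_cluster_weight_ <- function(n_con, n_het, w_con, w_het) {
  w <- w_con * n_con + w_het * n_het
  if (w_het == 0 && n_het > 0) w <- 0
  w
}

#' Generate a synthetic survey
#'
#' Hierarchical draw: per-host adult counts per species (negative
#' binomial), sexes (binomial), male body regions (species preference
#' multinomial), male cluster membership (weighted preferential
#' attachment within the chosen region), female placement (attraction to
#' male clusters across the host), and partner assignment (mate-choice
#' odds among the males in the female's cluster, otherwise single).
#' Corridor-examined animals contribute counts without body-region,
#' cluster or pairing detail.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (default `config$seed`); identical seeds give
#'   byte-identical surveys.
#' @return list with `observations`, `animals` (schema of [tick_survey]),
#'   and `truth` (the generating parameters plus realised totals).
#' @export
generate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_(seed, {
    obs_list <- list()
    animal_rows <- list()
    for (s in seq_len(config$n_sites)) {
      site <- sprintf("S%02d", s)
      for (a in seq_len(config$animals_per_site)) {
        animal <- sprintf("A%03d", a)
        mode <- if (stats::runif(1) < config$corridor_fraction) "corridor"
                else "laid_down"
        animal_rows[[length(animal_rows) + 1]] <- data.frame(
          site_id = site, animal_id = animal, inspection_mode = mode,
          days_since_amitraz = NA_integer_,
          days_since_pyrethroid = NA_integer_, stringsAsFactors = FALSE)
        counts <- vapply(TICK_SPECIES, function(sp)
          stats::rnbinom(1, mu = config$mean_abundance[[sp]],
                         size = config$nb_size[[sp]]), 0)
        if (sum(counts) == 0) next
        species <- rep(TICK_SPECIES, counts)
        sex <- ifelse(stats::rbinom(length(species), 1,
                                    config$male_fraction) == 1, "M", "F")
        if (mode == "corridor") {
          obs_list[[length(obs_list) + 1]] <- data.frame(
            site_id = site, animal_id = animal, inspection_mode = mode,
            species = species, sex = sex, body_region = NA_character_,
            cluster_id = NA_character_, partner_species = NA_character_,
            stringsAsFactors = FALSE)
          next
        }
        obs_list[[length(obs_list) + 1]] <-
          place_on_animal_(site, animal, species, sex, config)
      }
    }
    observations <- if (length(obs_list)) do.call(rbind, obs_list)
      else data.frame(site_id = character(), animal_id = character(),
                      inspection_mode = character(), species = character(),
                      sex = character(), body_region = character(),
                      cluster_id = character(), partner_species = character(),
                      stringsAsFactors = FALSE)
    animals <- do.call(rbind, animal_rows)
    rownames(observations) <- NULL
    truth <- c(unclass(config),
               list(realised_ticks = nrow(observations), seed_used = seed))
    list(observations = observations, animals = animals, truth = truth)
  })
}

# Place laid-down ticks on one animal: males first (region preference +
# cluster preferential attachment), then females (attraction to male
# clusters), then mate choice within the female's cluster.
place_on_animal_ <- function(site, animal, species, sex, config) {
  pref <- config$attachment_pref
  # clusters: list of list(region, id, n_males per species)
  clusters <- list()
  next_cluster_id <- integer(length(BODY_REGIONS))
  names(next_cluster_id) <- BODY_REGIONS
  n <- length(species)
  region <- character(n)
  cluster <- character(n)
  partner <- rep(NA_character_, n)
  ord <- c(sample(which(sex == "M")), sample(which(sex == "F")))
  for (i in ord) {
    sp <- species[i]
    if (sex[i] == "M") {
      rg <- sample(BODY_REGIONS, 1, prob = pref[sp, ])
      local <- which(vapply(clusters, function(cl) cl$region == rg, TRUE))
      w <- vapply(local, function(k) {
        cl <- clusters[[k]]
        male_cluster_weight_(cl$males[[sp]],
                             cl$males[[setdiff(TICK_SPECIES, sp)]],
                             config$w_con, config$w_het)
      }, 0)
      choice <- sample.int(length(local) + 1L, 1,
                           prob = c(w, config$w_new))
      if (choice <= length(local)) {
        k <- local[choice]
      } else {
        next_cluster_id[rg] <- next_cluster_id[rg] + 1L
        clusters[[length(clusters) + 1]] <-
          list(region = rg, id = sprintf("%s_c%d", rg, next_cluster_id[rg]),
               males = list(Av = 0L, Ah = 0L))
        k <- length(clusters)
      }
      clusters[[k]]$males[[sp]] <- clusters[[k]]$males[[sp]] + 1L
      region[i] <- clusters[[k]]$region
      cluster[i] <- clusters[[k]]$id
    } else {
      w <- vapply(clusters, function(cl) {
        config$a_con * cl$males[[sp]] +
          config$a_het * cl$males[[setdiff(TICK_SPECIES, sp)]]
      }, 0)
      choice <- sample.int(length(clusters) + 1L, 1,
                           prob = c(w, config$a_new))
      if (choice <= length(clusters)) {
        k <- choice
      } else {
        rg <- sample(BODY_REGIONS, 1, prob = pref[sp, ])
        next_cluster_id[rg] <- next_cluster_id[rg] + 1L
        clusters[[length(clusters) + 1]] <-
          list(region = rg, id = sprintf("%s_c%d", rg, next_cluster_id[rg]),
               males = list(Av = 0L, Ah = 0L))
        k <- length(clusters)
      }
      region[i] <- clusters[[k]]$region
      cluster[i] <- clusters[[k]]$id
      n_con <- clusters[[k]]$males[[sp]]
      n_het <- clusters[[k]]$males[[setdiff(TICK_SPECIES, sp)]]
      if (n_con + n_het == 0 || stats::runif(1) < config$single_prob) {
        partner[i] <- "single"
      } else {
        odds <- c(config$m_con * n_con, config$m_het * n_het)
        if (sum(odds) == 0) {
          partner[i] <- "single"
        } else {
          pick <- sample.int(2, 1, prob = odds)
          partner[i] <- if (pick == 1) sp else setdiff(TICK_SPECIES, sp)
        }
      }
    }
  }
  data.frame(site_id = site, animal_id = animal,
             inspection_mode = "laid_down", species = species, sex = sex,
             body_region = region, cluster_id = cluster,
             partner_species = partner, stringsAsFactors = FALSE)
}

#' Generate a regression dataset from exact beta-binomial ground truth
#'
#' Bypasses the mechanistic layer: covariates are drawn directly, the unit
#' mean follows the logistic model of `config$beta_sim`, and successes are
#' beta-binomial with correlation `config$rho_sim`. Used for parameter
#' recovery and test calibration where the generating distribution must be
#' known exactly.
#'
#' @param config a [simulation_config()].
#' @param n_units number of units (default `config$n_units`).
#' @param seed integer seed (default `config$seed`).
#' @param trials optional fixed trials vector (overrides the Poisson
#'   draw).
#' @return a `bb_dataset` with attributes `beta_true` and `rho_true`.
#' @export
generate_mating_counts <- function(config, n_units = config$n_units,
                                   seed = config$seed, trials = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_(seed, {
    b <- config$beta_sim
    rho <- config$rho_sim
    fs <- sample(rep_len(TICK_SPECIES, n_units))
    x_m <- stats::rbeta(n_units, 2, 2) - 0.5
    x_f <- stats::rbeta(n_units, 2, 2) - 0.5
    if (is.null(trials)) trials <- 1L + stats::rpois(n_units,
                                                     config$trials_mean)
    trials <- rep_len(as.integer(trials), n_units)
    eta <- b[1] + b[2] * (fs == "Ah") + b[3] * x_m + b[4] * x_f +
      b[5] * x_m * x_f
    mu <- stats::plogis(eta)
    p_unit <- if (rho < 1e-12) mu
      else stats::rbeta(n_units, mu * (1 - rho) / rho,
                        (1 - mu) * (1 - rho) / rho)
    succ <- stats::rbinom(n_units, trials, p_unit)
    out <- bb_dataset(trials, succ, fs, x_m, x_f)
    attr(out, "beta_true") <- b
    attr(out, "rho_true") <- rho
    out
  })
}
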