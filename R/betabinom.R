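## Beta-binomial logistic regression of the proportion of con-specific
## mating pairs, with a within-host intraclass correlation rho, LRTs and
## a prediction surface over con-specific male/female proportions.

#' Beta-binomial probability mass function (mean / correlation form)
#'
#' Parameterized by mean `mu` and intraclass correlation `rho`, with shape
#' parameters `a = mu (1 - rho) / rho`, `b = (1 - mu)(1 - rho) / rho`.
#' `rho -> 0` recovers the binomial.
#'
#' @param x number of successes (vectorized).
#' @param size number of trials.
#' @param mu mean success probability in `(0, 1)`.
#' @param rho intraclass correlation in `[0, 1)`.
#' @param log return log density.
#' @return density values.
#' @export
dbetabinom <- function(x, size, mu, rho, log = FALSE) {
  stopifnot(all(rho >= 0), all(rho < 1))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  n <- max(length(x), length(size), length(mu), length(rho))
  x <- rep_len(x, n); size <- rep_len(size, n)
  mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  tiny <- rho < 1e-8
  if (any(tiny))
    out[tiny] <- stats::dbinom(x[tiny], size[tiny], mu[tiny], log = TRUE)
  if (any(!tiny)) {
    i <- !tiny
    a <- mu[i] * (1 - rho[i]) / rho[i]
    b <- (1 - mu[i]) * (1 - rho[i]) / rho[i]
    out[i] <- lchoose(size[i], x[i]) + lbeta(x[i] + a, size[i] - x[i] + b) -
      lbeta(a, b)
  }
  if (log) out else exp(out)
}

#' Build the mating regression dataset from survey observations
#'
#' One observation unit per (site, animal, mated-female species):
#' `trials` = mated females of that species on the animal, `successes` =
#' those mating con-specifically. Covariates are computed from the
#' animal's full adult tick composition relative to the unit's female
#' species and centred on 0.5: `x_male` = proportion of con-specific males
#' minus 0.5, `x_female` = proportion of con-specific females minus 0.5.
#' Units on animals with no males are dropped with a warning (`x_male`
#' undefined).
#'
#' @param observations observations data.frame.
#' @return data.frame of class `bb_dataset` with columns `site_id`,
#'   `animal_id`, `female_species`, `trials`, `successes`, `x_male`,
#'   `x_female`.
#' @export
build_bb_dataset <- function(observations) {
  obs <- observations
  key <- paste(obs$site_id, obs$animal_id, sep = ":")
  mated <- obs$sex == "F" & !is.na(obs$partner_species) &
    obs$partner_species %in% TICK_SPECIES
  if (!any(mated)) stop("no mated females in observations", call. = FALSE)
  units <- unique(data.frame(key = key[mated],
                             site_id = obs$site_id[mated],
                             animal_id = obs$animal_id[mated],
                             female_species = obs$species[mated],
                             stringsAsFactors = FALSE))
  males_av <- tapply(obs$species == "Av" & obs$sex == "M", key, sum)
  males_ah <- tapply(obs$species == "Ah" & obs$sex == "M", key, sum)
  fem_av <- tapply(obs$species == "Av" & obs$sex == "F", key, sum)
  fem_ah <- tapply(obs$species == "Ah" & obs$sex == "F", key, sum)
  rows <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    nm <- c(Av = males_av[[u$key]], Ah = males_ah[[u$key]])
    nf <- c(Av = fem_av[[u$key]], Ah = fem_ah[[u$key]])
    if (sum(nm) == 0) return(NULL)
    sel <- mated & key == u$key & obs$species == u$female_species
    data.frame(site_id = u$site_id, animal_id = u$animal_id,
               female_species = u$female_species,
               trials = sum(sel),
               successes = sum(obs$partner_species[sel] == u$female_species),
               x_male = nm[[u$female_species]] / sum(nm) - 0.5,
               x_female = nf[[u$female_species]] / sum(nf) - 0.5,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    warning(sprintf("%d unit(s) dropped: animal has no males", dropped))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all units dropped", call. = FALSE)
  class(out) <- c("bb_dataset", class(out))
  out
}

#' Construct a regression dataset directly
#'
#' @param trials,successes integer vectors.
#' @param female_species `"Av"`/`"Ah"` vector.
#' @param x_male,x_female centred con-specific proportions in
#'   `[-0.5, 0.5]`.
#' @param animal_id optional unit identifiers.
#' @return a `bb_dataset` data.frame.
#' @export
bb_dataset <- function(trials, successes, female_species, x_male, x_female,
                       animal_id = seq_along(trials)) {
  stopifnot(all(successes >= 0), all(successes <= trials),
            all(abs(x_male) <= 0.5 + 1e-9), all(abs(x_female) <= 0.5 + 1e-9),
            all(female_species %in% TICK_SPECIES))
  out <- data.frame(site_id = "s1", animal_id = as.character(animal_id),
                    female_species = female_species,
                    trials = as.integer(trials),
                    successes = as.integer(successes),
                    x_male = x_male, x_female = x_female,
                    stringsAsFactors = FALSE)
  class(out) <- c("bb_dataset", class(out))
  out
}

BB_TERMS <- c("female_species", "x_male", "x_female", "interaction")

bb_design_ <- function(data, terms) {
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if ("female_species" %in% terms)
    X <- cbind(X, speciesAh = as.numeric(data$female_species == "Ah"))
  if ("x_male" %in% terms) X <- cbind(X, x_male = data$x_male)
  if ("x_female" %in% terms) X <- cbind(X, x_female = data$x_female)
  if ("interaction" %in% terms)
    X <- cbind(X, `x_male:x_female` = data$x_male * data$x_female)
  X
}

#' Beta-binomial log-likelihood
#'
#' Sum over units of the beta-binomial log pmf with
#' `logit(mu) = X beta` for the design implied by `terms`.
#'
#' @param beta coefficient vector matching the design.
#' @param rho intraclass correlation in `[0, 1)`.
#' @param data a `bb_dataset`.
#' @param terms model terms (subset of `female_species`, `x_male`,
#'   `x_female`, `interaction`).
#' @return log-likelihood value.
#' @export
bb_loglik <- function(beta, rho, data, terms = BB_TERMS) {
  X <- bb_design_(data, terms)
  stopifnot(length(beta) == ncol(X))
  mu <- stats::plogis(drop(X %*% beta))
  sum(dbetabinom(data$successes, data$trials, mu, rho, log = TRUE))
}

#' Fit the beta-binomial mating regression by maximum likelihood
#'
#' Optimizes coefficients on the logit-mean scale and `logit(rho)` so all
#' constraints stay interior (Nelder-Mead then BFGS polish); covariance
#' from the observed information at the optimum. The Wald test for `rho`
#' is computed on the logit scale (the natural scale has a boundary at 0).
#'
#' @param data a `bb_dataset` with at least 6 units.
#' @param terms model terms, see [bb_loglik()].
#' @param start optional start values `c(beta, logit_rho)`.
#' @param fix_rho fix `rho` at this value instead of estimating (e.g. 0
#'   for the pure binomial model).
#' @return object of class `bb_fit`: `coefficients`, `rho`, `loglik`,
#'   `vcov` (on the optimization scale, `logit_rho` last when estimated),
#'   `rho_p_wald`, `convergence`, `boundary_rho`, `rho_identifiable`,
#'   `terms`, `npar`, `data`.
#' @export
bb_fit <- function(data, terms = BB_TERMS, start = NULL, fix_rho = NULL) {
  stopifnot(inherits(data, "bb_dataset"))
  if (length(terms)) terms <- match.arg(terms, BB_TERMS, several.ok = TRUE)
  else terms <- character(0)   # intercept-only model
  if (nrow(data) < 6) stop("need at least 6 units to fit", call. = FALSE)
  X <- bb_design_(data, terms)
  p <- ncol(X)
  rho_identifiable <- any(data$trials > 1)
  if (!rho_identifiable && is.null(fix_rho)) {
    warning("all units have a single trial: rho is unidentifiable, fixed at 0")
    fix_rho <- 0
  }
  est_rho <- is.null(fix_rho)
  negll <- function(th) {
    beta <- th[seq_len(p)]
    rho <- if (est_rho) stats::plogis(th[p + 1]) else fix_rho
    ll <- bb_loglik(beta, rho, data, terms)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  if (is.null(start)) {
    g <- suppressWarnings(stats::glm(
      cbind(data$successes, data$trials - data$successes) ~ X - 1,
      family = stats::binomial()))
    start <- unname(stats::coef(g))
    start[!is.finite(start)] <- 0
    if (est_rho) start <- c(start, stats::qlogis(0.1))
  }
  opt <- if (length(start) == 1)
    stats::optim(start, negll, method = "Brent", lower = -30, upper = 30)
  else stats::optim(start, negll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  opt2 <- tryCatch(stats::optim(opt$par, negll, method = "BFGS",
                                control = list(maxit = 500)),
                   error = function(e) opt)
  if (opt2$value <= opt$value) opt <- opt2
  theta <- unname(opt$par)
  H <- tryCatch(stats::optimHess(theta, negll), error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  rho <- if (est_rho) stats::plogis(theta[p + 1]) else fix_rho
  rho_p <- NA_real_
  if (est_rho && !is.null(V) && V[p + 1, p + 1] > 0) {
    z <- theta[p + 1] / sqrt(V[p + 1, p + 1])
    rho_p <- 2 * stats::pnorm(-abs(z))
  }
  coefficients <- setNames(theta[seq_len(p)], colnames(X))
  structure(list(coefficients = coefficients, rho = rho,
                 loglik = -opt$value, vcov = V,
                 rho_p_wald = rho_p,
                 convergence = opt$convergence,
                 boundary_rho = est_rho && rho < 1e-3,
                 rho_identifiable = rho_identifiable,
                 rho_estimated = est_rho,
                 terms = terms, npar = p + as.integer(est_rho),
                 data = data),
            class = "bb_fit")
}

#' @export
print.bb_fit <- function(x, ...) {
  cat("Beta-binomial logistic regression (", nrow(x$data), " units)\n",
      sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("  rho = %.3f%s%s, loglik = %.3f\n", x$rho,
              if (x$rho_estimated && is.finite(x$rho_p_wald))
                sprintf(" (Wald p = %.3g)", x$rho_p_wald) else "",
              if (x$boundary_rho) " [boundary]" else "", x$loglik))
  if (!x$rho_identifiable) cat("  note: rho unidentifiable (all trials = 1)\n")
  invisible(x)
}

#' Likelihood-ratio test between nested beta-binomial fits
#'
#' @param fit_full,fit_reduced [bb_fit()] objects, reduced nested in full.
#' @return list with `chi2`, `df`, `p`.
#' @export
bb_lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "bb_fit"), inherits(fit_reduced, "bb_fit"))
  df <- fit_full$npar - fit_reduced$npar
  if (df <= 0) stop("reduced model must have fewer parameters", call. = FALSE)
  chi2 <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (chi2 < -1e-6)
    stop("full-model log-likelihood below reduced model: optimization failure",
         call. = FALSE)
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Draws from N(mean, V) via the Cholesky factor (V symmetric PSD).
mvn_draws_ <- function(n, mean, V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  z <- matrix(stats::rnorm(n * length(mean)), n)
  sweep(z %*% L, 2, mean, "+")
}

#' Prediction surface over con-specific male and female proportions
#'
#' Predicted mean proportion of con-specific mating pairs on a grid of
#' (con-specific male proportion, con-specific female proportion), plus a
#' coefficient of variation computed from parametric draws of the
#' coefficients from their asymptotic normal distribution.
#'
#' @param fit a converged [bb_fit()].
#' @param n_grid grid points per axis over `[0, 1]` (default 101).
#' @param n_draws coefficient draws for the CV surface (default 1000).
#' @param seed optional seed for the draws.
#' @param female_species species whose females the surface describes.
#' @return object of class `bb_surface`: list with `p_male`, `p_female`
#'   (axes), `mean` and `cv` matrices (`p_male` indexing rows), and the
#'   contour-ready axes. `cv` is `NULL` with a warning when the
#'   coefficient covariance is unavailable.
#' @export
bb_predict_surface <- function(fit, n_grid = 101, n_draws = 1000,
                               seed = NULL, female_species = "Av") {
  stopifnot(inherits(fit, "bb_fit"))
  if (fit$convergence != 0) stop("fit did not converge", call. = FALSE)
  p_male <- seq(0, 1, length.out = n_grid)
  p_female <- seq(0, 1, length.out = n_grid)
  grid <- expand.grid(x_male = p_male - 0.5, x_female = p_female - 0.5)
  grid$female_species <- female_species
  X <- bb_design_(grid, fit$terms)
  eta <- drop(X %*% fit$coefficients)
  mean_surface <- matrix(stats::plogis(eta), n_grid, n_grid)
  cv <- NULL
  p <- length(fit$coefficients)
  Vb <- if (!is.null(fit$vcov)) fit$vcov[seq_len(p), seq_len(p), drop = FALSE]
        else NULL
  if (!is.null(Vb)) {
    draws <- with_seed_(seed, mvn_draws_(n_draws, fit$coefficients, Vb))
    if (!is.null(draws)) {
      mu_draws <- stats::plogis(X %*% t(draws))   # cells x draws
      m <- rowMeans(mu_draws)
      s <- sqrt(rowMeans(mu_draws^2) - m^2)
      cv <- matrix(s / m, n_grid, n_grid)
    }
  }
  if (is.null(cv))
    warning("singular or missing covariance: CV surface unavailable")
  structure(list(p_male = p_male, p_female = p_female,
                 mean = mean_surface, cv = cv,
                 female_species = female_species),
            class = "bb_surface")
}

#' Fraction of the surface predicting mostly con-specific mating
#'
#' @param surface a [bb_predict_surface()] result.
#' @param level threshold on the predicted mean (default 0.5).
#' @return fraction of grid cells with predicted mean above `level`.
#' @export
surface_fraction_above <- function(surface, level = 0.5) {
  stopifnot(inherits(surface, "bb_surface"))
  mean(surface$mean > level)
}
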