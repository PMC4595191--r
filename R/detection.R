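## Herd-level probability of detecting tick presence, given sample sizes
## per inspection mode, a design prevalence and mode-specific detection
## sensitivities (freedom-from-infection style calculation).

#' Probability of detecting ticks in a herd
#'
#' With infinite-herd (binomial) sampling, the probability that at least
#' one sampled animal is infested *and* detected:
#' `P = 1 - (1 - prevalence * se_laid)^n_laid *
#' (1 - prevalence * se_corridor)^n_corridor`.
#' When `herd_size` is supplied, a finite-population (hypergeometric)
#' variant is used instead: the number of infested animals is
#' `max(1, round(prevalence * herd_size))` and the two samples are drawn
#' without replacement.
#'
#' @param n_laid_down number of animals examined laid down (sensitivity
#'   `se_laid`).
#' @param n_corridor number examined in the corridor (sensitivity
#'   `se_corridor`).
#' @param prevalence assumed within-herd prevalence (default 0.20).
#' @param se_laid detection sensitivity for laid-down inspection
#'   (default 1).
#' @param se_corridor detection sensitivity for corridor inspection
#'   (default 0.6).
#' @param herd_size optional herd size for the finite-population variant;
#'   must be at least `n_laid_down + n_corridor`.
#' @return detection probability in `[0, 1]`.
#' @export
detect_prob <- function(n_laid_down, n_corridor = 0, prevalence = 0.2,
                        se_laid = 1, se_corridor = 0.6, herd_size = NULL) {
  stopifnot(n_laid_down >= 0, n_corridor >= 0,
            prevalence >= 0, prevalence <= 1,
            se_laid >= 0, se_laid <= 1, se_corridor >= 0, se_corridor <= 1)
  if (is.null(herd_size)) {
    return(1 - (1 - prevalence * se_laid)^n_laid_down *
             (1 - prevalence * se_corridor)^n_corridor)
  }
  N <- herd_size
  n <- n_laid_down + n_corridor
  stopifnot(N >= n)
  if (prevalence == 0 || n == 0) return(0)
  D <- max(1L, round(prevalence * N))
  # P(miss) = E[(1-se_laid)^K1 (1-se_corridor)^K2], (K1, K2) the infested
  # counts in the two samples (multivariate hypergeometric).
  p_miss <- 0
  for (k1 in 0:min(n_laid_down, D)) {
    p1 <- stats::dhyper(k1, D, N - D, n_laid_down)
    if (p1 == 0) next
    k2max <- min(n_corridor, D - k1)
    k2 <- 0:k2max
    p2 <- stats::dhyper(k2, D - k1, (N - D) - (n_laid_down - k1), n_corridor)
    p_miss <- p_miss + p1 * sum(p2 * (1 - se_laid)^k1 * (1 - se_corridor)^k2)
  }
  1 - p_miss
}

#' Classify a detection probability as high or low
#'
#' `"high"` when the probability strictly exceeds the threshold
#' (default 0.7), `"low"` otherwise.
#'
#' @param p detection probability (vectorized).
#' @param threshold classification threshold (default 0.7).
#' @return character vector of `"high"`/`"low"`.
#' @export
classify_detection <- function(p, threshold = 0.7) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p > threshold, "high", "low")
}

#' Detection probability table for multiple sites
#'
#' @param sites data.frame with columns `site_id`, `n_laid_down`,
#'   `n_corridor` and optionally `herd_size`.
#' @inheritParams detect_prob
#' @param threshold classification threshold passed to
#'   [classify_detection()].
#' @return input data.frame with `detect_prob` and `class` columns added.
#' @export
detection_table <- function(sites, prevalence = 0.2, se_laid = 1,
                            se_corridor = 0.6, threshold = 0.7) {
  stopifnot(all(c("site_id", "n_laid_down", "n_corridor") %in% names(sites)))
  hs <- if ("herd_size" %in% names(sites)) sites$herd_size
        else rep(NA_real_, nrow(sites))
  p <- mapply(function(nl, nc, h)
    detect_prob(nl, nc, prevalence, se_laid, se_corridor,
                if (is.na(h)) NULL else h),
    sites$n_laid_down, sites$n_corridor, hs)
  sites$detect_prob <- p
  sites$class <- classify_detection(p, threshold)
  sites
}
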