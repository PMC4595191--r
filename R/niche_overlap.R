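## Schoener's D niche-overlap indices on attachment-site distributions:
## between species on co-infested animals (D_H) and within species across
## co-infestation status (D_C).

#' Schoener's D overlap between two attachment distributions
#'
#' `D = 1 - 1/2 * sum_i |p_i - q_i|`, in `[0, 1]`: 1 for identical
#' distributions, 0 for disjoint supports. Both inputs must be proportions
#' over the same named regions.
#'
#' @param p,q [attachment_distribution()] results (or named proportion
#'   vectors over the same regions, each summing to 1).
#' @return numeric scalar in `[0, 1]`.
#' @export
schoener_d <- function(p, q) {
  p <- unclass(p); q <- unclass(q)
  if (is.null(names(p)) || is.null(names(q)) ||
      !setequal(names(p), names(q)) || length(p) != length(q))
    stop("p and q must be proportions over the same named regions",
         call. = FALSE)
  q <- q[names(p)]
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1", call. = FALSE)
  1 - 0.5 * sum(abs(p - q))
}

# Animals (site:animal keys) hosting at least one tick of each species,
# among laid-down observations.
coinfested_animals_ <- function(obs) {
  laid <- obs[obs$inspection_mode == "laid_down", , drop = FALSE]
  key <- paste(laid$site_id, laid$animal_id, sep = ":")
  av <- unique(key[laid$species == "Av"])
  ah <- unique(key[laid$species == "Ah"])
  list(both = intersect(av, ah), av_only = setdiff(av, ah),
       ah_only = setdiff(ah, av), key = key, laid = laid)
}

# Total adult Amblyomma burden (both species, both sexes) per laid-down
# animal, used for the three infestation strata.
animal_burden_ <- function(obs) {
  laid <- obs[obs$inspection_mode == "laid_down", , drop = FALSE]
  key <- paste(laid$site_id, laid$animal_id, sep = ":")
  table(key)
}

stratum_animals_ <- function(burden, stratum, breaks = c(30, 70)) {
  n <- as.numeric(burden)
  keys <- names(burden)
  switch(stratum,
         all = keys,
         lt_30 = keys[n < breaks[1]],
         `30_to_69` = keys[n >= breaks[1] & n < breaks[2]],
         ge_70 = keys[n >= breaks[2]],
         stop("unknown stratum: ", stratum))
}

STRATA <- c("all", "lt_30", "30_to_69", "ge_70")

overlap_row_ <- function(index, sex, stratum, species_a, species_b,
                         obs, animal_keys, min_ticks,
                         filter_a = NULL, filter_b = NULL) {
  da <- tryCatch(attachment_distribution(obs, species = species_a, sex = sex,
                                         animal_ids = filter_a %||%
                                           animal_keys),
                 error = function(e) NULL)
  db <- tryCatch(attachment_distribution(obs, species = species_b, sex = sex,
                                         animal_ids = filter_b %||%
                                           animal_keys),
                 error = function(e) NULL)
  n_a <- if (is.null(da)) 0L else attr(da, "n")
  n_b <- if (is.null(db)) 0L else attr(db, "n")
  ok <- n_a >= min_ticks && n_b >= min_ticks
  data.frame(index = index, sex = sex, stratum = stratum,
             n_a = n_a, n_b = n_b,
             value = if (ok) schoener_d(da, db) else NA_real_,
             available = ok, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Between-species attachment overlap on co-infested animals (D_H)
#'
#' Schoener's D between the attachment distributions of the two species
#' (given sex) on co-infested, laid-down animals, overall and per cattle
#' infestation stratum (total adult burden `< 30`, `[30, 70)`, `>= 70`).
#' Strata without enough ticks of either species are flagged unavailable
#' rather than silently reported as 0.
#'
#' @param observations observations data.frame.
#' @param sex `"M"` or `"F"`.
#' @param min_ticks_stratum minimum ticks of each species required per
#'   stratum (default 1).
#' @param strata_breaks burden cut points (default `c(30, 70)`).
#' @return data.frame with columns `index`, `sex`, `stratum`, `n_a`
#'   (*A. variegatum* ticks), `n_b` (*A. hebraeum* ticks), `value`,
#'   `available`.
#' @export
overlap_heterospecific <- function(observations, sex = c("M", "F"),
                                   min_ticks_stratum = 1,
                                   strata_breaks = c(30, 70)) {
  sex <- match.arg(sex)
  co <- coinfested_animals_(observations)
  burden <- animal_burden_(observations)
  do.call(rbind, lapply(STRATA, function(st) {
    keys <- intersect(co$both, stratum_animals_(burden, st, strata_breaks))
    overlap_row_("D_H", sex, st, "Av", "Ah", observations, keys,
                 min_ticks_stratum)
  }))
}

#' Within-species overlap across co-infestation status (D_C)
#'
#' Schoener's D between the attachment distribution of one species (given
#' sex) on animals infested by that species alone (O) versus animals
#' co-infested by both species (T).
#'
#' @inheritParams overlap_heterospecific
#' @param species focal species (`"Av"` or `"Ah"`).
#' @return data.frame as in [overlap_heterospecific()]; `n_a` counts ticks
#'   on single-species animals, `n_b` on co-infested animals.
#' @export
overlap_coinfestation <- function(observations, species = c("Av", "Ah"),
                                  sex = c("M", "F"), min_ticks_stratum = 1,
                                  strata_breaks = c(30, 70)) {
  species <- match.arg(species)
  sex <- match.arg(sex)
  co <- coinfested_animals_(observations)
  only <- if (species == "Av") co$av_only else co$ah_only
  burden <- animal_burden_(observations)
  do.call(rbind, lapply(STRATA, function(st) {
    in_st <- stratum_animals_(burden, st, strata_breaks)
    overlap_row_("D_C", sex, st, species, species, observations, NULL,
                 min_ticks_stratum,
                 filter_a = intersect(only, in_st),
                 filter_b = intersect(co$both, in_st))
  }))
}
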