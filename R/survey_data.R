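## Survey data model: CSV I/O, validation, eligibility filtering, abundance
## summaries, and construction of presence matrices, attachment
## distributions and mating tables.

OBS_COLUMNS <- c("site_id", "animal_id", "inspection_mode", "species", "sex",
                 "body_region", "cluster_id", "partner_species")
ANIMAL_COLUMNS <- c("site_id", "animal_id", "inspection_mode",
                    "days_since_amitraz", "days_since_pyrethroid")
SURVEY_SCHEMA_VERSIONS <- "1.0"

#' Construct a tick survey object
#'
#' Bundles the observation table (one row per adult tick found on an
#' animal) with the per-animal record table and validates both against the
#' survey schema.
#'
#' @param observations data.frame with columns `site_id`, `animal_id`,
#'   `inspection_mode` (`laid_down`/`corridor`), `species` (`Av`/`Ah`),
#'   `sex` (`M`/`F`), `body_region` (one of [BODY_REGIONS], `NA` for
#'   corridor rows), `cluster_id` (identifier within animal and body
#'   region, may be `NA`), `partner_species` (`Av`/`Ah`/`single`, females
#'   only, may be `NA`).
#' @param animals data.frame with columns `site_id`, `animal_id`,
#'   `inspection_mode`, `days_since_amitraz`, `days_since_pyrethroid`
#'   (non-negative integers, `NA` = never treated), or `NULL`.
#' @param validate run schema validation (default `TRUE`).
#' @return object of class `tick_survey`: list with `$observations` and
#'   `$animals`.
#' @export
tick_survey <- function(observations, animals = NULL, validate = TRUE) {
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (!is.null(animals)) {
    animals <- as.data.frame(animals, stringsAsFactors = FALSE)
  }
  if (validate) {
    problems <- c(validate_observations(observations),
                  if (!is.null(animals)) validate_animals(animals))
    if (length(problems)) {
      stop("invalid survey data:\n  ",
           paste(utils::head(problems, 10), collapse = "\n  "),
           if (length(problems) > 10) sprintf("\n  ... and %d more",
                                              length(problems) - 10),
           call. = FALSE)
    }
  }
  structure(list(observations = observations, animals = animals),
            class = "tick_survey")
}

#' @export
print.tick_survey <- function(x, ...) {
  cat(sprintf("tick_survey: %d observations at %d site(s)",
              nrow(x$observations), length(unique(x$observations$site_id))))
  if (!is.null(x$animals)) cat(sprintf(", %d animal records", nrow(x$animals)))
  cat("\n")
  invisible(x)
}

# Line-numbered validation; row i of the data is line i + 1 of the CSV
# (header on line 1). Returns a character vector of problems (possibly empty).
validate_observations <- function(obs) {
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols)) {
    return(sprintf("observations: missing column(s) %s",
                   paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(obs)
  if (n == 0) return(character())
  line <- seq_len(n) + 1L
  problems <- character()
  bad <- function(idx, field, why) {
    sprintf("line %d: field '%s' %s", line[idx], field, why)
  }
  chk_enum <- function(field, levels, allow_na = FALSE) {
    v <- obs[[field]]
    idx <- which(!(v %in% levels) & !(allow_na & is.na(v)))
    if (length(idx))

      problems <<- c(problems, bad(idx, field, sprintf(
        "must be one of {%s}%s (got '%s')", paste(levels, collapse = ", "),
        if (allow_na) " or empty" else "", v[idx])))
  }
  chk_enum("inspection_mode", INSPECTION_MODES)
  chk_enum("species", TICK_SPECIES)
  chk_enum("sex", TICK_SEXES)
  chk_enum("body_region", BODY_REGIONS, allow_na = TRUE)
  chk_enum("partner_species", PARTNER_LEVELS, allow_na = TRUE)

  idx <- which(obs$sex == "M" & !is.na(obs$partner_species))
  if (length(idx))
    problems <- c(problems,
                  bad(idx, "partner_species", "must be empty for males"))
  corridor <- obs$inspection_mode == "corridor"
  idx <- which(corridor & (!is.na(obs$body_region) | !is.na(obs$cluster_id)))
  if (length(idx))
    problems <- c(problems, bad(idx, "body_region/cluster_id",
                                "must be empty for corridor inspections"))
  idx <- which(!corridor & obs$inspection_mode == "laid_down" &
                 is.na(obs$body_region))
  if (length(idx))
    problems <- c(problems,
                  bad(idx, "body_region", "required for laid-down rows"))
  idx <- which(!is.na(obs$cluster_id) & is.na(obs$body_region))
  if (length(idx))
    problems <- c(problems,
                  bad(idx, "cluster_id", "set while body_region is empty"))
  problems
}

validate_animals <- function(animals) {
  missing_cols <- setdiff(ANIMAL_COLUMNS, names(animals))
  if (length(missing_cols)) {
    return(sprintf("animals: missing column(s) %s",
                   paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  key <- paste(animals$site_id, animals$animal_id)
  if (anyDuplicated(key))
    problems <- c(problems, sprintf(
      "animals: duplicated (site_id, animal_id): %s",
      paste(unique(key[duplicated(key)]), collapse = ", ")))
  for (field in c("days_since_amitraz", "days_since_pyrethroid")) {
    v <- animals[[field]]
    idx <- which(!is.na(v) & (!is.finite(suppressWarnings(as.numeric(v))) |
                                suppressWarnings(as.numeric(v)) < 0))
    if (length(idx))
      problems <- c(problems, sprintf(
        "animals line %d: field '%s' must be a non-negative integer or empty",
        idx + 1L, field))
  }
  problems
}

#' Read a survey from CSV files
#'
#' Reads the one-tick-per-row observation CSV (and optionally the
#' per-animal record CSV), validates every row against the schema, and
#' returns a [tick_survey]. Malformed rows are reported with their line
#' number and offending field.
#'
#' @param observations_path path to the observations CSV.
#' @param animals_path optional path to the animals CSV.
#' @param schema_version schema version string; only `"1.0"` is defined.
#' @return a [tick_survey].
#' @export
read_survey <- function(observations_path, animals_path = NULL,
                        schema_version = "1.0") {
  if (!schema_version %in% SURVEY_SCHEMA_VERSIONS)
    stop("unknown schema_version: ", schema_version, call. = FALSE)
  if (!file.exists(observations_path))
    stop("file not found: ", observations_path, call. = FALSE)
  obs <- read.csv(observations_path, colClasses = "character",
                  na.strings = c("", "NA"), stringsAsFactors = FALSE)
  extra <- setdiff(names(obs), OBS_COLUMNS)
  if (length(extra))
    stop("observations: unknown column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  animals <- NULL
  if (!is.null(animals_path)) {
    if (!file.exists(animals_path))
      stop("file not found: ", animals_path, call. = FALSE)
    animals <- read.csv(animals_path, colClasses = "character",
                        na.strings = c("", "NA"), stringsAsFactors = FALSE)
    for (field in c("days_since_amitraz", "days_since_pyrethroid")) {
      animals[[field]] <- suppressWarnings(as.integer(animals[[field]]))
    }
  }
  tick_survey(obs, animals, validate = TRUE)
}

#' Write a survey to CSV files
#'
#' Inverse of [read_survey()]; `read_survey(write_survey(x))` is the
#' identity on valid surveys. Output is deterministic (no timestamps).
#'
#' @param survey a [tick_survey].
#' @param observations_path output path for the observations CSV.
#' @param animals_path optional output path for the animals CSV.
#' @return invisibly, the paths written.
#' @export
write_survey <- function(survey, observations_path, animals_path = NULL) {
  stopifnot(inherits(survey, "tick_survey"))
  write.csv(survey$observations[OBS_COLUMNS], observations_path,
            row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(animals_path)) {
    if (is.null(survey$animals))
      stop("survey carries no animal records", call. = FALSE)
    write.csv(survey$animals[ANIMAL_COLUMNS], animals_path,
              row.names = FALSE, na = "", quote = FALSE)
  }
  invisible(c(observations_path, animals_path))
}

#' Filter animals by acaricide-treatment eligibility
#'
#' Retains animals whose last amitraz treatment was at least
#' `amitraz_min_days` days before the visit and whose last pyrethroid
#' treatment was at least `pyrethroid_min_days` days before (residual
#' acaricide effect windows). Animals never treated (`NA` days) are
#' retained.
#'
#' @param animals animals data.frame (see [tick_survey]).
#' @param amitraz_min_days minimum days since amitraz (default 8).
#' @param pyrethroid_min_days minimum days since pyrethroids (default 15).
#' @return the eligible subset of `animals`.
#' @export
eligibility_filter <- function(animals, amitraz_min_days = 8,
                               pyrethroid_min_days = 15) {
  stopifnot(amitraz_min_days > 0, pyrethroid_min_days > 0)
  am <- animals$days_since_amitraz
  py <- animals$days_since_pyrethroid
  keep <- (is.na(am) | am >= amitraz_min_days) &
    (is.na(py) | py >= pyrethroid_min_days)
  animals[keep, , drop = FALSE]
}

# Four half-open mean-abundance bins, left-closed as printed; "absent" only
# for a zero count.
infestation_category <- function(count, n_animals) {
  stopifnot(n_animals > 0)
  if (count == 0) return("absent")
  m <- count / n_animals
  if (m < 0.1) "lt_0.1" else if (m < 1) "0.1_to_1"
  else if (m < 10) "1_to_10" else "ge_10"
}

#' Summarise tick abundance at one site
#'
#' Mean abundance (adult ticks per animal examined) and the four-level
#' infestation category per species.
#'
#' @param observations observations data.frame.
#' @param animals animals data.frame (after any eligibility filtering);
#'   defines the number of animals examined.
#' @param site_id site to summarise.
#' @return one-row data.frame: `site_id`, `n_animals_examined`, `n_av`,
#'   `n_ah`, `mean_abundance_av`, `mean_abundance_ah`, `category_av`,
#'   `category_ah`.
#' @export
summarize_site <- function(observations, animals, site_id) {
  a <- animals[animals$site_id == site_id, , drop = FALSE]
  if (nrow(a) == 0)
    stop("no examined animals at site ", site_id, call. = FALSE)
  keep <- observations$site_id == site_id &
    paste(observations$site_id, observations$animal_id) %in%
      paste(a$site_id, a$animal_id)
  o <- observations[keep, , drop = FALSE]
  n_av <- sum(o$species == "Av")
  n_ah <- sum(o$species == "Ah")
  data.frame(site_id = site_id, n_animals_examined = nrow(a),
             n_av = n_av, n_ah = n_ah,
             mean_abundance_av = n_av / nrow(a),
             mean_abundance_ah = n_ah / nrow(a),
             category_av = infestation_category(n_av, nrow(a)),
             category_ah = infestation_category(n_ah, nrow(a)),
             stringsAsFactors = FALSE)
}

#' Summarise all sites in a survey
#'
#' @param survey a [tick_survey] with animal records.
#' @param apply_eligibility apply [eligibility_filter()] first.
#' @return data.frame with one [summarize_site()] row per site.
#' @export
summarize_sites <- function(survey, apply_eligibility = TRUE) {
  stopifnot(inherits(survey, "tick_survey"), !is.null(survey$animals))
  animals <- if (apply_eligibility) eligibility_filter(survey$animals)
             else survey$animals
  sites <- unique(animals$site_id)
  do.call(rbind, lapply(sites, function(s)
    summarize_site(survey$observations, animals, s)))
}

unit_ids_ <- function(obs, level) {
  switch(level,
         animal = paste(obs$site_id, obs$animal_id, sep = ":"),
         attachment_site = paste(obs$site_id, obs$animal_id,
                                 obs$body_region, sep = ":"),
         cluster = paste(obs$site_id, obs$animal_id, obs$body_region,
                         obs$cluster_id, sep = ":"))
}

group_of_ <- function(obs) paste0(obs$species, obs$sex)

#' Build a binary presence matrix at a chosen spatial level
#'
#' Rows are spatial units (host animal, attachment site, or 5-cm cluster),
#' columns are species-by-sex groups (`AvM`, `AvF`, `AhM`, `AhF`); a cell
#' is 1 when at least one tick of the group was found in the unit.
#' Sub-animal levels require laid-down inspections only; cluster level
#' additionally drops rows with unrecorded cluster ids (with a warning).
#'
#' @param observations observations data.frame.
#' @param level `"animal"`, `"attachment_site"` or `"cluster"`.
#' @param groups group labels to keep as columns (default: the four
#'   species-sex groups, restricted to those present).
#' @param drop_empty drop units with no tick of any kept group (default
#'   `TRUE`; unrecorded empty units are unobservable in the field
#'   protocol).
#' @return integer matrix of class `presence_matrix` with a `level`
#'   attribute.
#' @export
build_presence_matrix <- function(observations,
                                  level = c("animal", "attachment_site",
                                            "cluster"),
                                  groups = NULL, drop_empty = TRUE) {
  level <- match.arg(level)
  obs <- observations
  if (level != "animal" && any(obs$inspection_mode == "corridor"))
    stop("corridor observations cannot be placed at level '", level,
         "'; filter to laid-down inspections first", call. = FALSE)
  if (level == "cluster" && anyNA(obs$cluster_id)) {
    n_drop <- sum(is.na(obs$cluster_id))
    warning(sprintf("dropping %d observation(s) without cluster_id", n_drop))
    obs <- obs[!is.na(obs$cluster_id), , drop = FALSE]
  }
  grp <- group_of_(obs)
  if (is.null(groups)) groups <- intersect(GROUP_LABELS, unique(grp))
  keep <- grp %in% groups
  tab <- table(unit = unit_ids_(obs, level)[keep],
               group = factor(grp[keep], levels = groups))
  m <- matrix(as.integer(tab > 0), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  if (drop_empty && nrow(m)) m <- m[rowSums(m) > 0, , drop = FALSE]
  structure(m, class = c("presence_matrix", class(m)), level = level)
}

#' Write a presence matrix as dense CSV
#' @param matrix a [build_presence_matrix()] result.
#' @param path output path.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(unit = rownames(matrix),
                   as.data.frame(unclass(matrix)[, , drop = FALSE]),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attachment-site distribution of a tick selection
#'
#' Proportions of the selected ticks over the eight body regions
#' (laid-down inspections only). The result sums to 1.
#'
#' @param observations observations data.frame.
#' @param species optional species filter (`"Av"`/`"Ah"`).
#' @param sex optional sex filter (`"M"`/`"F"`).
#' @param animal_ids optional `site:animal` keys (as produced by
#'   `paste(site_id, animal_id, sep = ":")`) to restrict hosts.
#' @param where optional predicate taking the observation data.frame and
#'   returning a logical row selector.
#' @return named numeric 8-vector of class `attachment_distribution` with
#'   attribute `n` (number of ticks).
#' @export
attachment_distribution <- function(observations, species = NULL, sex = NULL,
                                    animal_ids = NULL, where = NULL) {
  obs <- observations[observations$inspection_mode == "laid_down", ,
                      drop = FALSE]
  if (!is.null(species)) obs <- obs[obs$species %in% species, , drop = FALSE]
  if (!is.null(sex)) obs <- obs[obs$sex %in% sex, , drop = FALSE]
  if (!is.null(animal_ids))
    obs <- obs[paste(obs$site_id, obs$animal_id, sep = ":") %in% animal_ids, ,
               drop = FALSE]
  if (!is.null(where)) obs <- obs[which(where(obs)), , drop = FALSE]
  if (nrow(obs) == 0)
    stop("empty selection: no laid-down ticks match", call. = FALSE)
  counts <- table(factor(obs$body_region, levels = BODY_REGIONS))
  p <- as.numeric(counts) / sum(counts)
  structure(setNames(p, BODY_REGIONS), class = "attachment_distribution",
            n = sum(counts))
}

#' Construct a 2x2 mating table
#'
#' @param pairs 2x2 matrix of mating-pair counts; rows = male species,
#'   columns = female species, in order `Av`, `Ah`.
#' @param single_females named counts of single (unmated attached) females
#'   per species.
#' @param population optional 2x2 matrix of all sampled individuals,
#'   rows = species (`Av`, `Ah`), columns = sex (`M`, `F`); enables PTI.
#' @return object of class `mating_table`.
#' @export
mating_table <- function(pairs, single_females = c(Av = 0, Ah = 0),
                         population = NULL) {
  pairs <- as.matrix(pairs)
  stopifnot(identical(dim(pairs), c(2L, 2L)), all(pairs >= 0),
            all(pairs == round(pairs)))
  dimnames(pairs) <- list(male = TICK_SPECIES, female = TICK_SPECIES)
  single_females <- setNames(as.numeric(single_females[TICK_SPECIES]),
                             TICK_SPECIES)
  single_females[is.na(single_females)] <- 0
  stopifnot(all(single_females >= 0))
  if (!is.null(population)) {
    population <- as.matrix(population)
    stopifnot(identical(dim(population), c(2L, 2L)), all(population >= 0))
    dimnames(population) <- list(species = TICK_SPECIES, sex = TICK_SEXES)
  }
  structure(list(pairs = pairs, single_females = single_females,
                 population = population),
            class = "mating_table")
}

#' @export
print.mating_table <- function(x, ...) {
  cat("mating_table (", sum(x$pairs), " pairs)\n", sep = "")
  print(x$pairs)
  cat("single females:", paste(names(x$single_females), x$single_females,
                               sep = "=", collapse = ", "), "\n")
  if (!is.null(x$population)) {
    cat("population totals:\n"); print(x$population)
  }
  invisible(x)
}

#' Build the mating table observed at a site
#'
#' Counts attached mating pairs by male and female species from female
#' observations carrying `partner_species`, tallies single females, and
#' fills population totals (all sampled individuals by species and sex)
#' from every observation at the site.
#'
#' @param observations observations data.frame.
#' @param site_id optional site filter (default: all observations).
#' @return a [mating_table].
#' @export
build_mating_table <- function(observations, site_id = NULL) {
  obs <- observations
  if (!is.null(site_id)) obs <- obs[obs$site_id %in% site_id, , drop = FALSE]
  fem <- obs[obs$sex == "F", , drop = FALSE]
  mated <- fem[!is.na(fem$partner_species) &
                 fem$partner_species %in% TICK_SPECIES, , drop = FALSE]
  pairs <- table(male = factor(mated$partner_species, TICK_SPECIES),
                 female = factor(mated$species, TICK_SPECIES))
  singles <- table(factor(fem$species[!is.na(fem$partner_species) &
                                        fem$partner_species == "single"],
                          TICK_SPECIES))
  population <- table(species = factor(obs$species, TICK_SPECIES),
                      sex = factor(obs$sex, TICK_SEXES))
  mating_table(unclass(pairs), setNames(as.numeric(singles), TICK_SPECIES),
               unclass(population))
}

#' Read / write a mating table CSV
#'
#' One-row CSV with columns `pairs_AvM_AvF`, `pairs_AvM_AhF`,
#' `pairs_AhM_AvF`, `pairs_AhM_AhF`, `single_Av`, `single_Ah` and optional
#' population totals `pop_AvM`, `pop_AvF`, `pop_AhM`, `pop_AhF`.
#'
#' @param path CSV path.
#' @return a [mating_table].
#' @export
read_mating_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, na.strings = c("", "NA"))
  need <- c("pairs_AvM_AvF", "pairs_AvM_AhF", "pairs_AhM_AvF",
            "pairs_AhM_AhF", "single_Av", "single_Ah")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("mating table CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pairs <- matrix(c(df$pairs_AvM_AvF, df$pairs_AhM_AvF,
                    df$pairs_AvM_AhF, df$pairs_AhM_AhF), 2, 2)
  pop <- NULL
  pop_cols <- c("pop_AvM", "pop_AvF", "pop_AhM", "pop_AhF")
  if (all(pop_cols %in% names(df)) && !anyNA(df[pop_cols])) {
    pop <- matrix(c(df$pop_AvM, df$pop_AhM, df$pop_AvF, df$pop_AhF), 2, 2)
  }
  mating_table(pairs, c(Av = df$single_Av, Ah = df$single_Ah), pop)
}

#' @rdname read_mating_table
#' @param table a [mating_table] to write.
#' @export
write_mating_table <- function(table, path) {
  stopifnot(inherits(table, "mating_table"))
  O <- table$pairs
  df <- data.frame(pairs_AvM_AvF = O[1, 1], pairs_AvM_AhF = O[1, 2],
                   pairs_AhM_AvF = O[2, 1], pairs_AhM_AhF = O[2, 2],
                   single_Av = table$single_females["Av"],
                   single_Ah = table$single_females["Ah"])
  if (!is.null(table$population)) {
    P <- table$population
    df <- cbind(df, pop_AvM = P[1, 1], pop_AvF = P[1, 2],
                pop_AhM = P[2, 1], pop_AhF = P[2, 2])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_group_ <- function(g) {
  sp <- substr(g, 1, 2)
  sx <- substr(g, 3, 3)
  if (!sp %in% TICK_SPECIES || !(sx == "" || sx %in% TICK_SEXES))
    stop("bad group label: ", g, " (expected e.g. 'AvM', 'AhF', 'Av')",
         call. = FALSE)
  list(species = sp, sex = if (sx == "") TICK_SEXES else sx)
}

#' Percentage of a group attached in presence of another group
#'
#' Percentage of focal-group ticks whose spatial unit (animal, attachment
#' site, or cluster) also holds at least one reference-group tick.
#'
#' @param observations observations data.frame.
#' @param focal,reference group labels such as `"AvM"`, `"AhF"` (or a
#'   species alone, e.g. `"Av"`).
#' @param level spatial level, as in [build_presence_matrix()].
#' @return percentage in `[0, 100]`.
#' @export
pct_attached_in_presence <- function(observations, focal, reference,
                                     level = c("animal", "attachment_site",
                                               "cluster")) {
  level <- match.arg(level)
  obs <- observations
  if (level != "animal") {
    if (any(obs$inspection_mode == "corridor"))
      stop("corridor observations cannot be placed at level '", level, "'",
           call. = FALSE)
    if (level == "cluster") obs <- obs[!is.na(obs$cluster_id), , drop = FALSE]
  }
  fg <- parse_group_(focal)
  rg <- parse_group_(reference)
  unit <- unit_ids_(obs, level)
  is_focal <- obs$species == fg$species & obs$sex %in% fg$sex
  is_ref <- obs$species == rg$species & obs$sex %in% rg$sex
  if (!any(is_focal)) stop("no focal ticks selected", call. = FALSE)
  100 * mean(unit[is_focal] %in% unique(unit[is_ref]))
}
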