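test_that("read/write round-trips are the identity on valid files", {
  obs <- rbind(
    make_obs("A1", "Av", "M"),
    make_obs("A1", "Ah", "F", region = "axillary", cluster = "c2",
             partner = "Av"),
    make_obs("A2", "Av", "F", partner = "single"),
    make_obs("A3", "Ah", "M", region = NA, cluster = NA, mode = "corridor"))
  animals <- data.frame(site_id = "S1", animal_id = c("A1", "A2", "A3"),
                        inspection_mode = c("laid_down", "laid_down",
                                            "corridor"),
                        days_since_amitraz = c(10L, NA, 8L),
                        days_since_pyrethroid = c(NA, 20L, 15L),
                        stringsAsFactors = FALSE)
  sv <- tick_survey(obs, animals)
  op <- tempfile(fileext = ".csv"); ap <- tempfile(fileext = ".csv")
  write_survey(sv, op, ap)
  sv2 <- read_survey(op, ap)
  expect_equal(sv2$observations, sv$observations, ignore_attr = TRUE)
  expect_equal(sv2$animals, sv$animals, ignore_attr = TRUE)
  # a second write is byte-identical
  op2 <- tempfile(fileext = ".csv")
  write_survey(sv2, op2)
  expect_identical(readLines(op), readLines(op2))
})

test_that("malformed rows are rejected with line and field diagnostics", {
  ok <- make_obs("A1", "Av", "M")
  male_partner <- make_obs("A1", "Av", "M", partner = "Av")
  expect_error(tick_survey(rbind(ok, male_partner)),
               "line 3.*partner_species.*males")
  bad_species <- make_obs("A1", "Aq", "M")
  expect_error(tick_survey(rbind(ok, bad_species)), "line 3.*species")
  bad_region <- make_obs("A1", "Av", "M", region = "neck")
  expect_error(tick_survey(bad_region), "line 2.*body_region")
  corridor_region <- make_obs("A1", "Av", "M", mode = "corridor")
  expect_error(tick_survey(corridor_region), "corridor")
  p <- tempfile(fileext = ".csv")
  write.csv(cbind(ok, extra = 1), p, row.names = FALSE)
  expect_error(read_survey(p), "unknown column")
})

test_that("eligibility filter honours treatment windows and nulls", {
  animals <- data.frame(
    site_id = "S1", animal_id = as.character(1:5),
    inspection_mode = "laid_down",
    days_since_amitraz = c(8L, 7L, NA, 30L, NA),
    days_since_pyrethroid = c(NA, NA, 14L, 15L, NA),
    stringsAsFactors = FALSE)
  kept <- eligibility_filter(animals)
  # amitraz = 8 retained ("eight days or more"); pyrethroid = 14 excluded;
  # untreated (both NA) retained
  expect_identical(kept$animal_id, c("1", "4", "5"))
  expect_error(eligibility_filter(animals, amitraz_min_days = 0))
})

test_that("site summaries compute mean abundance and category bins", {
  animals <- data.frame(site_id = "S1",
                        animal_id = sprintf("A%02d", 1:50),
                        inspection_mode = "laid_down",
                        days_since_amitraz = NA_integer_,
                        days_since_pyrethroid = NA_integer_,
                        stringsAsFactors = FALSE)
  obs <- make_obs(sprintf("A%02d", 1:5), "Av", "M")
  s <- summarize_site(obs, animals, "S1")
  expect_equal(s$mean_abundance_av, 0.1)
  expect_equal(s$category_av, "0.1_to_1")   # left-closed bin edge
  expect_equal(s$category_ah, "absent")

  animals61 <- data.frame(site_id = "S1",
                          animal_id = sprintf("A%03d", 1:61),
                          inspection_mode = "laid_down",
                          days_since_amitraz = NA_integer_,
                          days_since_pyrethroid = NA_integer_,
                          stringsAsFactors = FALSE)
  obs610 <- make_obs(sprintf("A%03d", rep(1:61, 10)), "Ah", "F",
                     partner = "single")
  s2 <- summarize_site(obs610, animals61, "S1")
  expect_equal(s2$mean_abundance_ah, 10)
  expect_equal(s2$category_ah, "ge_10")
  expect_error(summarize_site(obs, animals, "nope"), "no examined animals")
})

test_that("presence matrices are binary, level-aware and idempotent", {
  obs <- rbind(
    make_obs("A1", c("Av", "Av"), "M"),          # 2 AvM, same cluster
    make_obs("A2", "Ah", "M"),
    make_obs("A3", c("Av", "Ah"), "M", region = c("inguinal", "axillary")))
  m <- build_presence_matrix(obs, "animal", groups = c("AvM", "AhM"))
  expect_identical(sort(rownames(m)), c("S1:A1", "S1:A2", "S1:A3"))
  expect_equal(unname(m[order(rownames(m)), ]),
               rbind(c(1, 0), c(0, 1), c(1, 1)))
  # duplication of ticks within a unit changes nothing
  m2 <- build_presence_matrix(rbind(obs, obs), "animal",
                              groups = c("AvM", "AhM"))
  expect_equal(unclass(m2), unclass(m))
  # cluster level: one cell for the two co-clustered AvM
  mc <- build_presence_matrix(obs[1:2, ], "cluster", groups = "AvM")
  expect_equal(dim(mc), c(1L, 1L))
  expect_equal(unname(mc[1, 1]), 1L)
  # corridor rows cannot be placed below animal level
  corr <- make_obs("A9", "Av", "M", region = NA, cluster = NA,
                   mode = "corridor")
  expect_error(build_presence_matrix(rbind(obs, corr), "cluster"),
               "corridor")
  empty <- obs[0, ]
  expect_equal(nrow(build_presence_matrix(empty, "animal")), 0L)
})

test_that("attachment distributions are proportions over the 8 regions", {
  obs <- make_obs("A1", "Av", "M", region = rep("inguinal", 4))
  d <- attachment_distribution(obs)
  expect_equal(unname(d[BODY_REGIONS == "inguinal"]), 1)
  expect_equal(sum(d), 1)

  obs2 <- make_obs("A1", "Av", "M",
                   region = c("inguinal", "inguinal", "axillary", "head"))
  d2 <- attachment_distribution(obs2)
  expect_equal(unname(d2[c("inguinal", "axillary", "head")]),
               c(0.5, 0.25, 0.25))
  expect_error(attachment_distribution(obs2, species = "Ah"),
               "empty selection")
  # normalization property on generated surveys
  sim <- generate_survey(simulation_config(animals_per_site = 15), seed = 2)
  for (sp in c("Av", "Ah")) {
    dd <- attachment_distribution(sim$observations, species = sp)
    expect_equal(sum(dd), 1, tolerance = 1e-12)
  }
})

test_that("mating tables count pairs, singles and population", {
  obs <- site55_observations()
  tab <- build_mating_table(obs, site_id = "55")
  expect_equal(sum(tab$pairs), 73)
  expect_equal(unname(tab$pairs["Av", "Av"]), 40)
  expect_equal(unname(tab$pairs["Ah", "Av"]), 9)
  expect_equal(unname(tab$pairs["Av", "Ah"]), 4)
  expect_equal(unname(tab$pairs["Ah", "Ah"]), 20)
  expect_equal(unname(tab$single_females), c(9, 8))
  # Av-female cross-mating rate 9/58
  av_f <- tab$pairs["Ah", "Av"] /
    (sum(tab$pairs[, "Av"]) + tab$single_females["Av"])
  expect_equal(unname(100 * av_f), 15.5, tolerance = 0.005)
  expect_equal(unname(tab$population["Av", "F"]), 58)
  # all-single females give an all-zero pair table
  singles <- make_obs("A1", "Av", "F", partner = "single")
  expect_equal(sum(build_mating_table(singles)$pairs), 0)
})

test_that("pct_attached_in_presence matches brute force and is monotone in level", {
  together <- rbind(make_obs("A1", "Av", "M"), make_obs("A1", "Ah", "M"))
  expect_equal(pct_attached_in_presence(together, "AvM", "AhM", "animal"),
               100)
  apart <- rbind(make_obs("A1", "Av", "M"), make_obs("A2", "Ah", "M"))
  expect_equal(pct_attached_in_presence(apart, "AvM", "AhM", "cluster"), 0)
  expect_error(pct_attached_in_presence(apart, "AhF", "AvM", "animal"),
               "no focal ticks")

  # hand-built 5-animal fixture: brute-force expectation
  obs <- rbind(
    make_obs("A1", c("Av", "Av", "Ah"), "M"),
    make_obs("A2", "Av", "M"),
    make_obs("A3", c("Av", "Ah"), "M", region = c("inguinal", "axillary")),
    make_obs("A4", "Ah", "M"),
    make_obs("A5", "Av", "M"))
  # animals with AhM: A1, A3, A4; AvM ticks: 2 on A1, 1 each A2/A3/A5
  expect_equal(pct_attached_in_presence(obs, "AvM", "AhM", "animal"),
               100 * 3 / 5)
  # same attachment site only on A1 (A3 ticks are in different regions)
  expect_equal(pct_attached_in_presence(obs, "AvM", "AhM",
                                        "attachment_site"),
               100 * 2 / 5)

  # coarser levels can only add co-occurrence
  for (seed in 1:3) {
    sim <- generate_survey(simulation_config(animals_per_site = 20),
                           seed = seed)
    laid <- sim$observations
    p_an <- pct_attached_in_presence(laid, "AvM", "AhM", "animal")
    p_as <- pct_attached_in_presence(laid, "AvM", "AhM", "attachment_site")
    p_cl <- pct_attached_in_presence(laid, "AvM", "AhM", "cluster")
    expect_gte(p_an, p_as)
    expect_gte(p_as, p_cl)
  }
})
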