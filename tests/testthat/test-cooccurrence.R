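pm <- function(m, groups = paste0("g", seq_len(ncol(m)))) {
  dimnames(m) <- list(paste0("u", seq_len(nrow(m))), groups)
  m
}

test_that("c_score matches hand values and the brute-force oracle", {
  ident <- pm(cbind(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(c_score(ident, "g1", "g2"), 0)
  disj <- pm(cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(c_score(disj, "g1", "g2"), 1)
  expect_error(c_score(pm(cbind(c(1, 0), c(0, 0))), "g1", "g2"),
               "zero occupied")
  expect_error(c_score(ident, "g1", "nope"), "not found")
  set.seed(5)
  n_checked <- 0
  while (n_checked < 50) {
    m <- pm(matrix(rbinom(12, 1, 0.5), 6, 2))
    if (any(colSums(m) == 0)) next
    n_checked <- n_checked + 1
    expect_equal(c_score(m, "g1", "g2"), cscore_oracle(m, "g1", "g2"))
  }
})

test_that("c_score is invariant to unit order and group swap", {
  set.seed(9)
  m <- pm(matrix(rbinom(30, 1, 0.5), 10, 3))
  m[1, ] <- 1   # guard against empty groups
  perm <- sample(nrow(m))
  expect_equal(c_score(m[perm, ], "g1", "g2"), c_score(m, "g1", "g2"))
  expect_equal(c_score(m, "g2", "g1"), c_score(m, "g1", "g2"))
})

test_that("permutation nulls preserve their stated margins and reproduce", {
  set.seed(13)
  m <- pm(matrix(rbinom(40, 1, 0.4), 10, 4))
  m[1, ] <- 1
  for (method in c("fixed_fixed", "fixed_rows", "equiprobable_rows")) {
    perms <- permutation_null(m, method, n = 30, seed = 101)
    expect_length(perms, 30)
    if (method == "fixed_fixed") {
      for (p in perms) {
        expect_equal(colSums(p), colSums(m))
        expect_equal(rowSums(p), rowSums(m))
      }
    } else if (method == "fixed_rows") {
      for (p in perms) expect_equal(colSums(p), colSums(m))
    } else {
      for (p in perms) expect_equal(sum(p), sum(m))
    }
    again <- permutation_null(m, method, n = 30, seed = 101)
    expect_identical(perms, again)
  }
})

test_that("fixed_fixed explores the whole state space of a checkerboard", {
  cb <- pm(rbind(c(1, 0), c(0, 1)))
  perms <- permutation_null(cb, "fixed_fixed", n = 1000, seed = 4)
  states <- vapply(perms, function(p) p[1, 1], 0)
  expect_setequal(unique(states), c(0, 1))
  # roughly uniform across the two states
  expect_gt(mean(states), 0.4)
  expect_lt(mean(states), 0.6)
})

test_that("degenerate fixed_fixed nulls warn and report p = 1", {
  solid <- pm(cbind(c(1, 1, 1), c(1, 1, 1)))
  expect_warning(
    expect_warning(res <- c_score_test(solid, "g1", "g2", "fixed_fixed",
                                       n = 50, seed = 1),
                   "swappable"),
    "degenerate")
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")
})

test_that("c_score_test flags structured fixtures and reproduces by seed", {
  seg <- pm(cbind(c(rep(1, 8), rep(0, 8)), c(rep(0, 8), rep(1, 8))))
  t_seg <- c_score_test(seg, "g1", "g2", "fixed_rows", n = 500, seed = 2)
  expect_equal(t_seg$direction, "segregated")
  expect_lt(t_seg$p_value, 0.05)
  agg <- pm(cbind(c(rep(1, 6), rep(0, 10)), c(rep(1, 6), rep(0, 9), 1)))
  t_agg <- c_score_test(agg, "g1", "g2", "fixed_rows", n = 500, seed = 2)
  expect_equal(t_agg$direction, "aggregated")
  expect_lt(t_agg$p_value, 0.05)
  rerun <- c_score_test(seg, "g1", "g2", "fixed_rows", n = 500, seed = 2)
  expect_identical(rerun$null_scores, t_seg$null_scores)
  expect_identical(rerun$p_value, t_seg$p_value)
})

test_that("fixed_fixed is inherently degenerate for two-group matrices", {
  # with only two groups, preserved row sums pin each unit's richness, so
  # the shared-unit count S (hence C) is invariant; tests at fixed_fixed
  # must be run on the full multi-group matrix
  m <- pm(rbind(c(1, 1), c(1, 0), c(0, 1), c(1, 0)))
  expect_warning(res <- c_score_test(m, "g1", "g2", "fixed_fixed",
                                     n = 200, seed = 3),
                 "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo p matches the hypergeometric exhaustive oracle", {
  # under fixed_rows with two groups, the shared-unit count S is
  # hypergeometric(r1, U - r1, r2) and C is a deterministic function of S
  set.seed(33)
  U <- 6
  m <- pm(cbind(c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0)))
  r1 <- sum(m[, 1]); r2 <- sum(m[, 2])
  s_obs <- sum(m[, 1] & m[, 2])
  c_of_s <- function(s) (r1 - s) * (r2 - s) / (r1 * r2)
  support <- max(0, r1 + r2 - U):min(r1, r2)
  probs <- dhyper(support, r1, U - r1, r2)
  cs <- c_of_s(support)
  c_obs <- c_of_s(s_obs)
  p_exact <- min(1, 2 * min(sum(probs[cs >= c_obs]),
                            sum(probs[cs <= c_obs])))
  t_mc <- c_score_test(m, "g1", "g2", "fixed_rows", n = 5000, seed = 12)
  expect_equal(t_mc$c_score, c_obs)
  expect_lt(abs(t_mc$p_value - p_exact), 0.02)
})

test_that("Monte-Carlo p matches exhaustive fixed_fixed enumeration", {
  # 4 units x 3 groups: enumerate all binary matrices with the observed
  # margins and compare the uniform-null p for the (g1, g2) pair with the
  # quasiswap MC p (a third group is needed for a non-degenerate null)
  m <- pm(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 0, 0)))
  rs <- rowSums(m); cs_ <- colSums(m)
  all_c <- c()
  for (bits in 0:(2^12 - 1)) {
    cand <- matrix(as.integer(intToBits(bits))[1:12], 4, 3)
    if (all(rowSums(cand) == rs) && all(colSums(cand) == cs_)) {
      all_c <- c(all_c, c_score(pm(cand), "g1", "g2"))
    }
  }
  expect_gt(length(unique(all_c)), 1)
  c_obs <- c_score(m, "g1", "g2")
  p_exact <- min(1, 2 * min(mean(all_c >= c_obs), mean(all_c <= c_obs)))
  t_mc <- c_score_test(m, "g1", "g2", "fixed_fixed", n = 5000, seed = 21)
  expect_lt(abs(t_mc$p_value - p_exact), 0.02)
})

test_that("c_score_tests runs all pairs with order-independent child seeds", {
  set.seed(17)
  m <- pm(matrix(rbinom(60, 1, 0.5), 15, 4),
          groups = c("AvM", "AvF", "AhM", "AhF"))
  m[1, ] <- 1
  res <- c_score_tests(m, "all", method = "fixed_rows", n = 99, seed = 7)
  expect_equal(nrow(res), 6)
  one <- c_score_test(m, "AvM", "AhM", "fixed_rows", n = 99,
                      seed = child_seed(7, "cscore AvM AhM"))
  expect_equal(res$p_value[res$group_i == "AvM" & res$group_j == "AhM"],
               one$p_value)
})
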