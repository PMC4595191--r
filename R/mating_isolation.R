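## Sexual-isolation statistics on 2x2 mating tables: PSI, PTI, IPSI,
## IAPSI, bootstrap standard errors and two-tail deviation probabilities.

#' Expected mating pairs under random mating among mated individuals
#'
#' `E_ij = (row_i of O) * (column_j of O) / T` with `T` the total number of
#' observed pairs.
#'
#' @param table a [mating_table].
#' @return 2x2 numeric matrix of expected pair counts.
#' @export
expected_pairs_mated <- function(table) {
  stopifnot(inherits(table, "mating_table"))
  O <- table$pairs
  T_ <- sum(O)
  if (T_ == 0) stop("no mating pairs observed (T = 0)", call. = FALSE)
  outer(rowSums(O), colSums(O)) / T_
}

#' Pair sexual isolation index (PSI)
#'
#' `PSI_ij = O_ij / E_ij`, the ratio of observed to expected pairs under
#' random mating among the individuals that actually mated. Cells with a
#' zero expectation are returned as `NA` with a warning.
#'
#' @param table a [mating_table].
#' @return 2x2 matrix (rows = male species, columns = female species).
#' @export
psi <- function(table) {
  E <- expected_pairs_mated(table)
  out <- table$pairs / E
  if (any(E == 0)) {
    warning("zero expected cell(s): corresponding PSI unavailable")
    out[E == 0] <- NA_real_
  }
  out
}

#' Pair total index (PTI)
#'
#' `PTI_ij = O_ij / Ehat_ij` with expectations from random mating of *all*
#' sampled individuals: `Ehat_ij = T * (N_males_i / N_males) *
#' (N_females_j / N_females)` using population totals (mated + single).
#'
#' @param table a [mating_table] with population counts.
#' @return 2x2 matrix, or `NULL` when population totals are absent.
#' @export
pti <- function(table) {
  stopifnot(inherits(table, "mating_table"))
  if (is.null(table$population)) {
    message("population counts absent: PTI unavailable")
    return(NULL)
  }
  O <- table$pairs
  T_ <- sum(O)
  if (T_ == 0) stop("no mating pairs observed (T = 0)", call. = FALSE)
  N_m <- table$population[, "M"]
  N_f <- table$population[, "F"]
  if (sum(N_m) == 0 || sum(N_f) == 0)
    stop("population totals contain no males or no females", call. = FALSE)
  E_hat <- T_ * outer(N_m / sum(N_m), N_f / sum(N_f))
  out <- O / E_hat
  if (any(E_hat == 0)) {
    warning("zero expected cell(s): corresponding PTI unavailable")
    out[E_hat == 0] <- NA_real_
  }
  dimnames(out) <- dimnames(O)
  out
}

ipsi_from_psi_ <- function(P) {
  s <- sum(P)
  if (!is.finite(s) || s == 0) stop("all PSI values are zero", call. = FALSE)
  (P[1, 1] + P[2, 2] - P[1, 2] - P[2, 1]) / s
}

#' Joint isolation index (IPSI)
#'
#' `IPSI = (PSI_11 + PSI_22 - PSI_12 - PSI_21) / sum(PSI)`, in `[-1, 1]`:
#' 1 under complete isolation (only con-specific pairs), -1 under fully
#' hetero-specific mating.
#'
#' @param table a [mating_table].
#' @return numeric scalar in `[-1, 1]`.
#' @export
ipsi <- function(table) {
  ipsi_from_psi_(psi(table))
}

#' Asymmetry index of hetero-specific mating (IAPSI)
#'
#' Ratio of the larger to the smaller of the two hetero-specific PSI
#' values (`>= 1` by construction); 1 means symmetric hetero-specific
#' mating. A zero hetero-specific PSI yields `Inf` with a warning
#' (infinite asymmetry).
#'
#' @param table a [mating_table].
#' @return numeric scalar `>= 1` (possibly `Inf`).
#' @export
iapsi <- function(table) {
  P <- psi(table)
  hp <- c(P[1, 2], P[2, 1])
  if (anyNA(hp)) stop("hetero-specific PSI unavailable", call. = FALSE)
  if (any(hp == 0)) {
    warning("zero hetero-specific PSI: infinite asymmetry")
    return(Inf)
  }
  max(hp) / min(hp)
}

# One batch of multinomial pair-bootstrap replicates; returns the 4 x k
# count matrix (rows in column-major cell order of O).
boot_draw_ <- function(k, T_, prob) {
  stats::rmultinom(k, T_, prob)
}

#' Bootstrap inference for sexual-isolation indices
#'
#' Resamples the observed pair distribution (multinomial over the four
#' male-by-female cells, `T` pairs per replicate; this is the pair-level
#' reading of "bootstrap replicates of the original data"). Replicates
#' with an empty row or column marginal — for which PSI is undefined — are
#' redrawn so the replicate count is exact; the number redrawn is
#' reported. When population totals are present, male and female
#' populations are independently resampled per replicate for PTI.
#'
#' Two-tail probabilities use the percentile-crossing rule with add-one
#' correction, ties counted toward the null: the null value is 0 for IPSI
#' and 1 for PSI, PTI and IAPSI. Replicates with an infinite IAPSI are
#' excluded from its moments and counted separately.
#'
#' Note the `boot_mean` component: the reference JMating implementation
#' reports bootstrap means (not plug-in values) as its point estimates,
#' which matters for ratio indices such as IAPSI whose bootstrap
#' distribution is right-skewed.
#'
#' @param table a [mating_table] with `T >= 2` pairs.
#' @param n number of bootstrap replicates (default 10000).
#' @param seed optional integer seed.
#' @return object of class `isolation_result`: list with `psi`, `pti`,
#'   `ipsi`, `iapsi` (plug-in estimates), `boot_mean`, `se`, `p_two_tail`
#'   (each a list over indices), `n_bootstrap`, `n_redrawn`,
#'   `n_infinite_iapsi`, `seed`.
#' @export
bootstrap_isolation <- function(table, n = 10000, seed = NULL) {
  stopifnot(inherits(table, "mating_table"))
  O <- table$pairs
  T_ <- sum(O)
  if (T_ < 2) stop("need at least 2 observed pairs to bootstrap",
                   call. = FALSE)
  prob <- as.vector(O) / T_   # cells: (AvM,AvF), (AhM,AvF), (AvM,AhF), (AhM,AhF)
  have_pop <- !is.null(table$population)

  # Margins that are positive in the observed table must stay positive in a
  # replicate (else PSI is undefined there and the replicate is redrawn).
  # Margins that are zero in the data stay zero in every replicate; the
  # corresponding PSI cells are NA throughout and excluded from moments.
  rpos <- rowSums(O) > 0
  cpos <- colSums(O) > 0

  with_seed_(seed, {
    v <- boot_draw_(n, T_, prob)
    n_redrawn <- 0L
    repeat {
      row1 <- v[1, ] + v[3, ]; row2 <- v[2, ] + v[4, ]
      col1 <- v[1, ] + v[2, ]; col2 <- v[3, ] + v[4, ]
      bad <- which((rpos[1] & row1 == 0) | (rpos[2] & row2 == 0) |
                     (cpos[1] & col1 == 0) | (cpos[2] & col2 == 0))
      if (!length(bad)) break
      n_redrawn <- n_redrawn + length(bad)
      v[, bad] <- boot_draw_(length(bad), T_, prob)
    }
    # PSI per replicate, vectorized over the 4 cells; 0/0 -> NaN for cells
    # whose observed margin is empty.
    E11 <- row1 * col1 / T_; E21 <- row2 * col1 / T_
    E12 <- row1 * col2 / T_; E22 <- row2 * col2 / T_
    P11 <- v[1, ] / E11; P21 <- v[2, ] / E21
    P12 <- v[3, ] / E12; P22 <- v[4, ] / E22
    ipsi_rep <- (P11 + P22 - P12 - P21) / (P11 + P22 + P12 + P21)
    ia_rep <- pmax(P12, P21) / pmin(P12, P21)
    ia_finite <- is.finite(ia_rep)

    pti_rep <- NULL
    if (have_pop) {
      N_m <- table$population[, "M"]; N_f <- table$population[, "F"]
      mm <- stats::rmultinom(n, sum(N_m), N_m / sum(N_m))
      ff <- stats::rmultinom(n, sum(N_f), N_f / sum(N_f))
      pm1 <- mm[1, ] / sum(N_m); pm2 <- mm[2, ] / sum(N_m)
      pf1 <- ff[1, ] / sum(N_f); pf2 <- ff[2, ] / sum(N_f)
      pti_rep <- list(`AvM_AvF` = v[1, ] / (T_ * pm1 * pf1),
                      `AhM_AvF` = v[2, ] / (T_ * pm2 * pf1),
                      `AvM_AhF` = v[3, ] / (T_ * pm1 * pf2),
                      `AhM_AhF` = v[4, ] / (T_ * pm2 * pf2))
    }

    p_tail <- function(x, null) {
      x <- x[is.finite(x)]
      k <- length(x)
      if (k == 0) return(NA_real_)
      min(1, 2 * min(sum(x <= null) + 1, sum(x >= null) + 1) / (k + 1))
    }
    psi_reps <- list(`AvM_AvF` = P11, `AhM_AvF` = P21,
                     `AvM_AhF` = P12, `AhM_AhF` = P22)
    plug_psi <- suppressWarnings(psi(table))

    mean_ <- function(x) if (all(!is.finite(x))) NA_real_
                         else mean(x[is.finite(x)])
    sd_ <- function(x) if (all(!is.finite(x))) NA_real_
                       else stats::sd(x[is.finite(x)])
    res <- list(
      psi = plug_psi,
      pti = if (have_pop) pti(table) else NULL,
      ipsi = tryCatch(ipsi_from_psi_(plug_psi), error = function(e) NA_real_),
      iapsi = tryCatch(suppressWarnings(iapsi(table)),
                       error = function(e) NA_real_),
      boot_mean = list(
        psi = matrix(vapply(psi_reps, mean_, 0), 2, 2,
                     dimnames = dimnames(plug_psi)),
        ipsi = mean_(ipsi_rep),
        iapsi = mean_(ia_rep),
        pti = if (have_pop) matrix(vapply(pti_rep, mean_, 0), 2, 2,
                                   dimnames = dimnames(plug_psi)) else NULL),
      se = list(
        psi = matrix(vapply(psi_reps, sd_, 0), 2, 2,
                     dimnames = dimnames(plug_psi)),
        ipsi = sd_(ipsi_rep),
        iapsi = sd_(ia_rep),
        pti = if (have_pop) matrix(vapply(pti_rep, sd_, 0), 2, 2,
                                   dimnames = dimnames(plug_psi)) else NULL),
      p_two_tail = list(
        psi = matrix(vapply(psi_reps, p_tail, 0, null = 1), 2, 2,
                     dimnames = dimnames(plug_psi)),
        ipsi = p_tail(ipsi_rep, 0),
        iapsi = p_tail(ia_rep, 1),
        pti = if (have_pop) matrix(vapply(pti_rep, p_tail, 0, null = 1),
                                   2, 2, dimnames = dimnames(plug_psi))
              else NULL),
      n_bootstrap = n, n_redrawn = n_redrawn,
      n_infinite_iapsi = sum(!ia_finite), seed = seed)
    structure(res, class = "isolation_result")
  })
}

#' Exact expectation of the pair bootstrap
#'
#' The multinomial pair bootstrap of [bootstrap_isolation()] estimates, by
#' Monte Carlo, the expectation of each index over resampled tables. For
#' the table sizes seen in mating studies that expectation can be computed
#' exactly by enumerating every composition of `T` pairs over the four
#' cells, weighting by multinomial probability, and conditioning on the
#' same validity rule the bootstrap uses (margins that are positive in the
#' data stay positive). This removes all Monte-Carlo error from the
#' bootstrap-mean point estimates that the reference JMating software
#' reports.
#'
#' @param table a [mating_table]; enumeration is over
#'   `choose(T + 3, 3)` compositions, feasible for `T` up to a few
#'   hundred.
#' @return list with `psi` (2x2 exact bootstrap-mean PSI), `ipsi`,
#'   `iapsi` (expectation over replicates with finite asymmetry),
#'   `p_valid` (probability mass of valid replicates) and
#'   `p_finite_iapsi`.
#' @export
bootstrap_expectation <- function(table) {
  stopifnot(inherits(table, "mating_table"))
  O <- table$pairs
  T_ <- sum(O)
  if (T_ < 2) stop("need at least 2 observed pairs", call. = FALSE)
  if (T_ > 400) stop("enumeration impractical for T > 400", call. = FALSE)
  prob <- as.vector(O) / T_
  # all compositions (v1, v2, v3, v4) of T_ over the four cells
  grid <- expand.grid(v1 = 0:T_, v2 = 0:T_, v3 = 0:T_)
  grid <- grid[grid$v1 + grid$v2 + grid$v3 <= T_, , drop = FALSE]
  v1 <- grid$v1; v2 <- grid$v2; v3 <- grid$v3
  v4 <- T_ - v1 - v2 - v3
  logw <- lgamma(T_ + 1) - lgamma(v1 + 1) - lgamma(v2 + 1) -
    lgamma(v3 + 1) - lgamma(v4 + 1)
  for (i in 1:4) {
    v <- list(v1, v2, v3, v4)[[i]]
    if (prob[i] > 0) logw <- logw + v * log(prob[i])
    else logw[v > 0] <- -Inf
  }
  row1 <- v1 + v3; row2 <- v2 + v4; col1 <- v1 + v2; col2 <- v3 + v4
  rpos <- rowSums(O) > 0; cpos <- colSums(O) > 0
  valid <- is.finite(logw) &
    (!rpos[1] | row1 > 0) & (!rpos[2] | row2 > 0) &
    (!cpos[1] | col1 > 0) & (!cpos[2] | col2 > 0)
  w <- exp(logw[valid])
  p_valid <- sum(w)
  w <- w / p_valid
  v1 <- v1[valid]; v2 <- v2[valid]; v3 <- v3[valid]; v4 <- v4[valid]
  row1 <- row1[valid]; row2 <- row2[valid]
  col1 <- col1[valid]; col2 <- col2[valid]
  P11 <- v1 * T_ / (row1 * col1); P21 <- v2 * T_ / (row2 * col1)
  P12 <- v3 * T_ / (row1 * col2); P22 <- v4 * T_ / (row2 * col2)
  ew <- function(x) {
    ok <- is.finite(x)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  ipsi_v <- (P11 + P22 - P12 - P21) / (P11 + P22 + P12 + P21)
  ia_v <- pmax(P12, P21) / pmin(P12, P21)
  list(psi = matrix(c(ew(P11), ew(P21), ew(P12), ew(P22)), 2, 2,
                    dimnames = dimnames(O)),
       ipsi = ew(ipsi_v), iapsi = ew(ia_v), p_valid = p_valid,
       p_finite_iapsi = sum(w[is.finite(ia_v)]))
}

#' @export
print.isolation_result <- function(x, digits = 2, ...) {
  f <- function(v) sprintf("%.*f", digits, round_half_up_(v, digits))
  cat("Sexual isolation (", x$n_bootstrap, " bootstrap replicates)\n",
      sep = "")
  cat(sprintf("  IPSI = %s (boot mean %s, se %s, p = %.3g)\n",
              f(x$ipsi), f(x$boot_mean$ipsi), f(x$se$ipsi),
              x$p_two_tail$ipsi))
  cat(sprintf("  IAPSI = %s (boot mean %s, se %s, p = %.3g)\n",
              f(x$iapsi), f(x$boot_mean$iapsi), f(x$se$iapsi),
              x$p_two_tail$iapsi))
  cat("  PSI (plug-in / boot mean):\n")
  for (i in 1:2) for (j in 1:2) {
    cat(sprintf("    %s male x %s female: %s / %s (se %s, p = %.3g)\n",
                TICK_SPECIES[i], TICK_SPECIES[j], f(x$psi[i, j]),
                f(x$boot_mean$psi[i, j]), f(x$se$psi[i, j]),
                x$p_two_tail$psi[i, j]))
  }
  if (!is.null(x$pti)) {
    cat("  PTI (plug-in):\n")
    for (i in 1:2) for (j in 1:2)
      cat(sprintf("    %s male x %s female: %s (se %s, p = %.3g)\n",
                  TICK_SPECIES[i], TICK_SPECIES[j], f(x$pti[i, j]),
                  f(x$se$pti[i, j]), x$p_two_tail$pti[i, j]))
  }
  if (x$n_redrawn > 0)
    cat("  degenerate replicates redrawn:", x$n_redrawn, "\n")
  if (x$n_infinite_iapsi > 0)
    cat("  replicates with infinite IAPSI (excluded from its moments):",
        x$n_infinite_iapsi, "\n")
  invisible(x)
}
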