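## Checkerboard C-score co-occurrence statistics and permutation null-model
## tests on binary presence matrices (units x groups).

#' Normalized checkerboard C-score for a pair of groups
#'
#' For groups occupying `r_i` and `r_j` units with `S` units shared, the
#' Stone–Roberts checkerboard score normalized to `[0, 1]`:
#' `(r_i - S)(r_j - S) / (r_i * r_j)`. 0 means complete co-occurrence
#' (aggregation), 1 complete segregation.
#'
#' @param matrix binary units-by-groups matrix ([build_presence_matrix()]).
#' @param g_i,g_j column names of the two groups.
#' @return numeric scalar in `[0, 1]`.
#' @export
c_score <- function(matrix, g_i, g_j) {
  m <- unclass(matrix)
  if (!all(c(g_i, g_j) %in% colnames(m)))
    stop("groups not found in matrix: ",
         paste(setdiff(c(g_i, g_j), colnames(m)), collapse = ", "),
         call. = FALSE)
  x <- m[, g_i] > 0
  y <- m[, g_j] > 0
  r_i <- sum(x); r_j <- sum(y); s <- sum(x & y)
  if (r_i == 0 || r_j == 0)
    stop("C-score undefined: group with zero occupied units", call. = FALSE)
  (r_i - s) * (r_j - s) / (r_i * r_j)
}

# TRUE when the matrix contains a swappable 2x2 checkerboard submatrix,
# i.e. some column pair has both a (1,0) unit and a (0,1) unit.
has_checkerboard_ <- function(m) {
  m <- unclass(m) > 0
  if (ncol(m) < 2 || nrow(m) < 2) return(FALSE)
  for (a in seq_len(ncol(m) - 1)) {
    for (b in seq((a + 1), ncol(m))) {
      if (any(m[, a] & !m[, b]) && any(!m[, a] & m[, b])) return(TRUE)
    }
  }
  FALSE
}

#' Generate null presence matrices by permutation
#'
#' Three null models for binary units-by-groups matrices:
#' \describe{
#'   \item{`fixed_fixed`}{both unit richness (row sums) and group occupancy
#'     (column sums) preserved; quasiswap algorithm via
#'     [vegan::nullmodel()]. The conservative default for incidence data.}
#'   \item{`fixed_rows`}{each group keeps its occupancy count, occupied
#'     units redrawn uniformly and independently per group.}
#'   \item{`equiprobable_rows`}{total fill preserved, presences placed
#'     uniformly over all cells.}
#' }
#'
#' @param matrix binary units-by-groups matrix.
#' @param method null model, see above.
#' @param n number of null matrices.
#' @param seed optional integer; the caller's RNG stream is left intact and
#'   the sequence is reproducible from the seed.
#' @return list of `n` binary matrices with the dimnames of `matrix`.
#' @export
permutation_null <- function(matrix,
                             method = c("fixed_fixed", "fixed_rows",
                                        "equiprobable_rows"),
                             n = 5000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  m <- unclass(matrix)
  m <- matrix(as.numeric(m > 0), nrow = nrow(m), dimnames = dimnames(m))
  if (method == "fixed_fixed" && !has_checkerboard_(m))
    warning("no swappable 2x2 submatrix: fixed_fixed null is degenerate")
  with_seed_(seed, {
    switch(method,
      fixed_fixed = {
        sims <- stats::simulate(vegan::nullmodel(m, "quasiswap"), nsim = n)
        lapply(seq_len(n), function(i) {
          out <- sims[, , i]
          dimnames(out) <- dimnames(m)
          out
        })
      },
      fixed_rows = {
        r <- colSums(m)
        U <- nrow(m)
        lapply(seq_len(n), function(i) {
          out <- m * 0
          for (j in seq_len(ncol(m))) out[sample.int(U, r[j]), j] <- 1
          out
        })
      },
      equiprobable_rows = {
        total <- sum(m)
        lapply(seq_len(n), function(i) {
          out <- m * 0
          out[sample.int(length(m), total)] <- 1
          out
        })
      })
  })
}

#' Permutation test of the pairwise C-score
#'
#' Compares the observed C-score of a group pair with its permutation null
#' distribution. Two-sided p-value with add-one correction:
#' `p = min(1, 2 * min((#\{C* >= C\} + 1), (#\{C* <= C\} + 1)) / (n + 1))`;
#' ties count toward the extreme tail (conservative). Direction is
#' `segregated` when the observed score exceeds the null mean, `aggregated`
#' when below it.
#'
#' @inheritParams permutation_null
#' @param g_i,g_j group column names.
#' @return object of class `c_score_test`: list with `level`, `group_pair`,
#'   `c_score`, `method`, `n_permutations`, `null_scores`, `p_value`,
#'   `direction`, `seed`.
#' @export
c_score_test <- function(matrix, g_i, g_j,
                         method = c("fixed_fixed", "fixed_rows",
                                    "equiprobable_rows"),
                         n = 5000, seed = NULL) {
  method <- match.arg(method)
  observed <- c_score(matrix, g_i, g_j)
  perms <- permutation_null(matrix, method, n, seed)
  null_scores <- vapply(perms, function(mm)
    tryCatch(c_score(mm, g_i, g_j), error = function(e) NA_real_),
    numeric(1))
  ok <- !is.na(null_scores)
  n_eff <- sum(ok)
  ns <- null_scores[ok]
  if (n_eff == 0 || all(ns == observed)) {
    warning("degenerate null distribution; p reported as 1")
    p <- 1
    direction <- "none"
  } else {
    p <- min(1, 2 * min(sum(ns >= observed) + 1, sum(ns <= observed) + 1) /
               (n_eff + 1))
    delta <- observed - mean(ns)
    direction <- if (delta > 0) "segregated" else if (delta < 0) "aggregated"
                 else "none"
  }
  structure(list(level = attr(matrix, "level"),
                 group_pair = c(g_i, g_j), c_score = observed,
                 method = method, n_permutations = n_eff,
                 null_scores = null_scores, p_value = p,
                 direction = direction, seed = seed),
            class = "c_score_test")
}

#' @export
print.c_score_test <- function(x, ...) {
  cat(sprintf("C-score test (%s null%s): %s vs %s\n", x$method,
              if (!is.null(x$level)) paste0(", level ", x$level) else "",
              x$group_pair[1], x$group_pair[2]))
  cat(sprintf("  C = %.4g, p = %.4g (%d permutations), direction: %s\n",
              x$c_score, x$p_value, x$n_permutations, x$direction))
  invisible(x)
}

#' C-score tests for all group pairs of a presence matrix
#'
#' @inheritParams c_score_test
#' @param pairs `"all"` or a list of 2-vectors of group names.
#' @param seed master seed; each pair gets an independent child seed via
#'   [child_seed()], so adding or reordering pairs never perturbs another
#'   pair's null stream.
#' @return data.frame with one row per pair: `level`, `group_i`, `group_j`,
#'   `c_score`, `p_value`, `direction`, `n_permutations`, `method`.
#' @export
c_score_tests <- function(matrix, pairs = "all",
                          method = c("fixed_fixed", "fixed_rows",
                                     "equiprobable_rows"),
                          n = 5000, seed = NULL) {
  method <- match.arg(method)
  if (identical(pairs, "all")) {
    cn <- colnames(matrix)
    pairs <- combn(cn, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    s <- if (is.null(seed)) NULL
         else child_seed(seed, paste("cscore", pr[1], pr[2]))
    t <- c_score_test(matrix, pr[1], pr[2], method, n, s)
    data.frame(level = attr(matrix, "level") %||% NA_character_,
               group_i = pr[1], group_j = pr[2], c_score = t$c_score,
               p_value = t$p_value, direction = t$direction,
               n_permutations = t$n_permutations, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
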