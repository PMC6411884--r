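#' Steel-type many-to-one rank test by max-T permutation
#'
#' Compares each treatment group against a single control with the Wilcoxon
#' rank-sum statistic (mid-ranks for ties), standardized under the
#' permutation null with tie correction. Family-wise adjusted p-values come
#' from the permutation distribution of the maximum standardized statistic
#' under joint relabelling of all observations, so exactness does not rely
#' on the classical multivariate-normal tables — important for the small
#' per-group sample sizes typical of embryo-injection experiments.
#'
#' With a single treatment and few observations the full set of
#' control/treatment partitions is enumerated exactly (whenever
#' `choose(n, n_control) <= n_permutations`), and the test coincides with
#' the exact rank-sum permutation test; otherwise `n_permutations` random
#' relabellings are drawn.
#'
#' @param control numeric vector of control observations (n >= 2).
#' @param treatments named list of numeric vectors (each n >= 2), or a
#'   single numeric vector.
#' @param alternative `"two.sided"` (default; the direction of the effect is
#'   not assumed) or `"greater"` (treatment stochastically larger).
#' @param n_permutations number of random relabellings (>= 100; fewer gives
#'   an unstable null).
#' @param seed integer seed; required whenever random relabelling is used.
#' @return A tibble of class `steel_test`: one row per treatment with `n`,
#'   rank-sum `W`, standardized `z` and family-wise adjusted `p_adj`.
#'   Attributes record `method` ("exact" or "permutation"), `alternative`,
#'   `n_permutations` and `seed`.
#' @export
steel_test <- function(control, treatments,
                       alternative = c("two.sided", "greater"),
                       n_permutations = 10000L, seed = NULL) {
  alternative <- match.arg(alternative)
  if (is.numeric(treatments)) treatments <- list(treatment = treatments)
  assert_that(length(treatments) >= 1 && !is.null(names(treatments)) &&
                all(nzchar(names(treatments))),
              "treatments must be a named list of numeric vectors")
  assert_that(length(control) >= 2, "control needs >= 2 observations")
  for (tr in treatments) {
    assert_that(length(tr) >= 2, "every treatment needs >= 2 observations")
  }
  assert_that(n_permutations >= 100,
              "n_permutations < 100 gives an unstable permutation null")

  k <- length(treatments)
  n1 <- length(control)
  sizes <- vapply(treatments, length, integer(1))
  pooled <- c(control, unlist(treatments, use.names = FALSE))
  N <- length(pooled)
  ctrl_pos <- seq_len(n1)
  slice <- vector("list", k)
  at <- n1
  for (j in seq_len(k)) {
    slice[[j]] <- at + seq_len(sizes[j])
    at <- at + sizes[j]
  }
  ties_possible <- anyDuplicated(pooled) > 0L

  # signed standardized rank-sum of trt vs ctrl (mid-ranks, tie-corrected);
  # all-tie pairs get z = 0
  pair_stat <- function(ctrl, trt) {
    m1 <- length(ctrl); m2 <- length(trt); m <- m1 + m2
    if (ties_possible) {
      r <- rank(c(ctrl, trt))
      W <- sum(r[m1 + seq_len(m2)])
      grp_sizes <- tabulate(match(r, unique(r)))
      tiecor <- sum(grp_sizes^3 - grp_sizes)
    } else {
      W <- m2 * (m2 + 1) / 2 + sum(findInterval(trt, sort(ctrl)))
      tiecor <- 0
    }
    v <- m1 * m2 / 12 * ((m + 1) - tiecor / (m * (m - 1)))
    if (v <= 0) return(c(W = W, z = 0))
    c(W = W, z = (W - m2 * (m + 1) / 2) / sqrt(v))
  }
  direct <- if (alternative == "two.sided") abs else identity

  obs <- vapply(seq_len(k), function(j) {
    pair_stat(control, treatments[[j]])
  }, numeric(2))
  obs_W <- obs["W", ]
  obs_z <- obs["z", ]
  obs_s <- direct(obs_z)

  exact_feasible <- k == 1L && choose(N, n1) <= n_permutations
  if (exact_feasible) {
    combs <- utils::combn(N, n1)
    stats <- apply(combs, 2, function(ci) {
      direct(pair_stat(pooled[ci], pooled[-ci])[["z"]])
    })
    p_adj <- mean(stats >= obs_s[1] - 1e-12)
    method <- "exact"
    B <- ncol(combs)
  } else {
    assert_that(!is.null(seed),
                "seed is required for Monte-Carlo permutation")
    B <- as.integer(n_permutations)
    withr::with_seed(as.integer(seed), {
      if (!ties_possible) {
        # vectorized path: with no ties the pair statistic is a linear
        # function of the count of (control < treatment) pairs
        perm <- vapply(seq_len(B), function(b) sample.int(N), integer(N))
        pv <- matrix(pooled[perm], N, B)
        ctrlM <- pv[ctrl_pos, , drop = FALSE]
        maxstat <- rep(-Inf, B)
        for (j in seq_len(k)) {
          trtM <- pv[slice[[j]], , drop = FALSE]
          m2 <- sizes[j]
          U <- numeric(B)
          if (n1 <= m2) {
            for (i in seq_len(n1)) {
              U <- U + colSums(trtM > matrix(ctrlM[i, ], m2, B, byrow = TRUE))
            }
          } else {
            for (i in seq_len(m2)) {
              U <- U + colSums(matrix(trtM[i, ], n1, B, byrow = TRUE) > ctrlM)
            }
          }
          m <- n1 + m2
          W <- U + m2 * (m2 + 1) / 2
          z <- (W - m2 * (m + 1) / 2) / sqrt(n1 * m2 * (m + 1) / 12)
          maxstat <- pmax(maxstat, direct(z))
        }
      } else {
        maxstat <- numeric(B)
        for (b in seq_len(B)) {
          p <- sample.int(N)
          ctrl <- pooled[p[ctrl_pos]]
          s <- -Inf
          for (j in seq_len(k)) {
            zj <- direct(pair_stat(ctrl, pooled[p[slice[[j]]]])[["z"]])
            if (zj > s) s <- zj
          }
          maxstat[b] <- s
        }
      }
    })
    p_adj <- vapply(obs_s, function(s0) {
      (1 + sum(maxstat >= s0 - 1e-12)) / (B + 1)
    }, numeric(1))
    method <- "permutation"
  }

  out <- tibble::tibble(
    treatment = names(treatments), n = sizes,
    n_control = n1, W = obs_W, z = obs_z, p_adj = p_adj
  )
  attr(out, "method") <- method
  attr(out, "alternative") <- alternative
  attr(out, "n_permutations") <- B
  attr(out, "seed") <- seed
  class(out) <- c("steel_test", class(out))
  out
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, 3 <= n <= 5000, not constant.
#' @return List with `statistic` (W) and `p`.
#' @export
check_normality <- function(values) {
  values <- values[!is.na(values)]
  assert_that(length(values) >= 3 && length(values) <= 5000,
              "Shapiro-Wilk requires 3 <= n <= 5000")
  assert_that(diff(range(values)) > 0, "sample is constant")
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Bartlett homoscedasticity check
#'
#' Bartlett's statistic against chi-squared with k - 1 degrees of freedom.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2,
#'   none constant).
#' @return List with `statistic`, `df` and `p`.
#' @export
check_homoscedasticity <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need >= 2 groups")
  for (g in groups) {
    assert_that(length(g) >= 2, "every group needs n >= 2")
    assert_that(diff(range(g)) > 0, "a constant group has undefined variance ratio")
  }
  bt <- bartlett.test(groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p = bt$p.value)
}

#' Fisher exact test on a 2x2 development-outcome table
#'
#' Two-sided exact hypergeometric test (sum over tables with probability at
#' most that of the observed table, margins fixed), as used to compare
#' success/failure counts at a developmental stage between two groups.
#' A table with an all-zero row or column carries no evidence; it returns
#' p = 1 with a warning rather than an error.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = success/failure).
#' @param alternative only `"two.sided"` is offered.
#' @return List with `p` and the conditional MLE `odds_ratio`.
#' @export
fisher_exact_outcome <- function(table, alternative = "two.sided") {
  alternative <- match.arg(alternative, "two.sided")
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2, 2)), "table must be 2x2")
  assert_that(all(table >= 0) && all(table == round(table)),
              "counts must be non-negative integers")
  assert_that(sum(table) > 0, "all-zero table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("a margin of the table is zero; the test is degenerate (p = 1)")
    return(list(p = 1, odds_ratio = NA_real_))
  }
  ft <- fisher.test(table, alternative = alternative)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}
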