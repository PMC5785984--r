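# Dilution-design calculations: separating homologous pairs into tubes.
#
# With k tubes and independent uniform assignment, the two copies of a pair
# land in distinct tubes with probability (k-1)/k; all n pairs separate with
# probability ((k-1)/k)^n; the expected number of separated pairs is
# n(k-1)/k by linearity.

#' Probability one homologous pair is separated by k tubes
#'
#' @param k Number of tubes (>= 1).
#' @return `(k - 1) / k`, exactly.
#' @examples
#' pair_separation_probability(8)  # 0.875
#' @export
pair_separation_probability <- function(k) {
  if (any(k < 1)) stop("k must be >= 1")
  (k - 1) / k
}

#' Expected number of separated homologous pairs
#'
#' @param n Number of homologous pairs (23 for a diploid human cell).
#' @param k Number of tubes.
#' @return `n * (k - 1) / k`. For 23 pairs in 8 tubes this is 20.125, i.e.
#'   on average 20 pairs end up physically separated.
#' @export
expected_separated_pairs <- function(n, k) {
  stopifnot(all(n >= 0))
  n * pair_separation_probability(k)
}

#' Probability that every homologous pair is separated
#'
#' @inheritParams expected_separated_pairs
#' @return `((k - 1) / k)^n`.
#' @export
perfect_separation_probability <- function(n, k) {
  stopifnot(all(n >= 0))
  pair_separation_probability(k)^n
}

#' Monte-Carlo simulation of pair separation
#'
#' Each replicate drops two copies of each of `n` pairs independently and
#' uniformly into `k` tubes (each copy first being lost with probability
#' `loss_prob`) and counts pairs whose two copies survive in distinct tubes.
#'
#' @inheritParams expected_separated_pairs
#' @param reps Number of replicates.
#' @param seed RNG seed.
#' @param loss_prob Per-copy loss probability (a lost copy leaves its pair
#'   unseparated and is not recovered).
#' @return List with `mean`, `sd` and `perfect_fraction` of the separated-pair
#'   count, `mean_recovered` copies, and `reps`.
#' @examples
#' mc_separation(23, 8, reps = 1000, seed = 1)$mean  # near 20.125
#' @export
mc_separation <- function(n, k, reps, seed = 1L, loss_prob = 0) {
  stopifnot(n >= 0, k >= 1, reps >= 1, loss_prob >= 0, loss_prob < 1)
  set.seed(seed)
  t1 <- matrix(sample.int(k, n * reps, replace = TRUE), nrow = n)
  t2 <- matrix(sample.int(k, n * reps, replace = TRUE), nrow = n)
  if (loss_prob > 0) {
    t1[matrix(stats::runif(n * reps) < loss_prob, nrow = n)] <- NA_integer_
    t2[matrix(stats::runif(n * reps) < loss_prob, nrow = n)] <- NA_integer_
  }
  sep <- colSums(!is.na(t1) & !is.na(t2) & t1 != t2)
  recovered <- colSums(!is.na(t1)) + colSums(!is.na(t2))
  list(mean = mean(sep), sd = stats::sd(sep),
       perfect_fraction = mean(sep == n),
       mean_recovered = mean(recovered), reps = reps)
}

#' Dilution design table over candidate tube counts
#'
#' One row per tube count: analytic separation probabilities and seeded
#' Monte-Carlo estimates. There is no single "right" number of tubes; rows
#' where the expected separated fraction reaches `annotate_fraction` are
#' flagged `recommended` as an annotation only.
#'
#' @inheritParams mc_separation
#' @param k_list Tube counts to evaluate.
#' @param annotate_fraction Expected-separated fraction above which a tube
#'   count is flagged.
#' @return data.frame with columns `n_pairs`, `k_tubes`, `p_pair_separated`,
#'   `p_perfect`, `expected_separated`, `mc_mean`, `mc_sd`,
#'   `mc_perfect_fraction`, `mc_mean_recovered`, `reps`, `recommended`.
#' @export
design_table <- function(n = 23, k_list = c(4, 8, 16, 24, 32), loss_prob = 0,
                         reps = 10000, seed = 1L, annotate_fraction = 0.85) {
  stopifnot(length(k_list) >= 1)
  rows <- lapply(seq_along(k_list), function(i) {
    k <- k_list[[i]]
    mc <- mc_separation(n, k, reps, seed = seed + i - 1L, loss_prob = loss_prob)
    data.frame(n_pairs = n, k_tubes = k,
               p_pair_separated = pair_separation_probability(k),
               p_perfect = perfect_separation_probability(n, k),
               expected_separated = expected_separated_pairs(n, k),
               mc_mean = mc$mean, mc_sd = mc$sd,
               mc_perfect_fraction = mc$perfect_fraction,
               mc_mean_recovered = mc$mean_recovered, reps = reps,
               recommended = expected_separated_pairs(n, k) >= annotate_fraction * n)
  })
  do.call(rbind, rows)
}
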