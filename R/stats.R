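# Exact and resampling statistics for CA analyses: Fisher 2x2, two-sided
# exact binomial (point-probability method), per-chromosome enrichment with
# multiple-testing control, and the loss/gain bias permutation test.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration (the
#' point-probability method: sum over all tables with the observed margins
#' whose probability does not exceed that of the observed table).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `(a, b, c, d)` filling the table by row.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(dim(tab) != 2L)) sk_parameter_error("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    sk_validation_error("table cells must be non-negative integers")
  if (sum(tab) == 0) sk_stop("sk_undefined_test_error", "all-zero table")
  fisher.test(tab)$p.value
}

#' Two-sided exact binomial test
#'
#' Exact two-sided p-value: the sum of probabilities of all outcomes whose
#' point probability does not exceed that of the observed count. For
#' `k = n` successes at `p0 = 0.5` this is exactly `2 * 0.5^n`.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability in `(0, 1)`.
#' @return Two-sided p-value.
#' @examples
#' binom_exact_two_sided(18, 18, 0.5)
#' @export
binom_exact_two_sided <- function(k, n, p0 = 0.5) {
  if (n < 0 || k < 0 || k > n || n != round(n) || k != round(k))
    sk_parameter_error("need integer 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) sk_parameter_error("p0 must be in (0, 1)")
  binom.test(k, n, p0)$p.value
}

#' Per-chromosome CA enrichment
#'
#' Under the null that each homologue acquires CAs with equal probability,
#' each chromosome's expected share of calls is its homologue count over
#' the population total (optionally taken from the consensus, so a trisomy
#' contributes three homologues). Each chromosome's call count is tested
#' against the total with a one-sided exact binomial test; p-values are
#' adjusted (Benjamini-Hochberg by default) and enrichment is flagged at
#' adjusted p < 0.05.
#'
#' @param calls an `sk_calls` table (>= 1 call).
#' @param genome the [genome_model()].
#' @param method `"bh"` or `"bonferroni"`.
#' @param homologues optional named per-chromosome homologue counts
#'   overriding the genome model (e.g. consensus-derived).
#' @param alpha flagging threshold on the adjusted p-value.
#' @return A `data.table`: chrom, n, expected_prop, p, p_adj, enriched.
#' @export
chromosome_enrichment <- function(calls, genome, method = c("bh", "bonferroni"),
                                  homologues = NULL, alpha = 0.05) {
  method <- match.arg(method)
  if (!nrow(calls)) sk_parameter_error("need at least one call")
  hom <- if (is.null(homologues))
    setNames(genome$homologues, genome$chrom) else homologues
  tot_h <- sum(hom)
  cnt <- data.table::as.data.table(calls)[, .(n = .N), by = chrom]
  cnt <- cnt[data.table::data.table(chrom = genome$chrom), on = "chrom"]
  cnt[is.na(n), n := 0L]
  n_tot <- sum(cnt$n)
  cnt[, expected_prop := hom[chrom] / tot_h]
  cnt[, p := mapply(function(x, p0)
    binom.test(x, n_tot, p0, alternative = "greater")$p.value,
    n, expected_prop)]
  cnt[, p_adj := p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")]
  cnt[, enriched := p_adj < alpha]
  cnt[]
}

#' Loss/gain direction bias permutation test
#'
#' Permutation null: each event's direction is flipped independently with
#' probability 0.5 (optionally within strata); the p-value is the fraction
#' of permutations whose absolute loss-gain imbalance (summed over strata)
#' reaches the observed imbalance. The unstratified construction converges
#' to the exact two-sided binomial tail at p = 0.5.
#'
#' @param losses,gains observed counts (their sum must be >= 1).
#' @param n_perm number of permutations (a warning is issued below 100).
#' @param strata optional data.frame with per-stratum `losses`/`gains`
#'   columns; when given, `losses`/`gains` arguments are ignored.
#' @param seed RNG seed; fixed seed gives a reproducible p-value.
#' @return list with `p`, `mc_se` (Monte-Carlo standard error), `observed`
#'   imbalance and `n_perm`.
#' @export
loss_gain_bias_test <- function(losses, gains, n_perm = 10000L, strata = NULL,
                                seed = 1L) {
  if (is.null(strata)) {
    strata <- data.frame(losses = losses, gains = gains)
  }
  if (sum(strata$losses) + sum(strata$gains) < 1)
    sk_parameter_error("need at least one event")
  if (n_perm < 100L) warning("n_perm < 100: the permutation p-value is unstable")
  with_rng_seed(seed, {
    obs <- sum(abs(strata$losses - strata$gains))
    stat <- numeric(n_perm)
    ns <- strata$losses + strata$gains
    for (s in seq_len(nrow(strata))) {
      flips <- rbinom(n_perm, ns[s], 0.5)   # events landing on "loss"
      stat <- stat + abs(2 * flips - ns[s])
    }
    exceed <- sum(stat >= obs)
    p <- (exceed + 1) / (n_perm + 1)
    list(p = p, mc_se = sqrt(p * (1 - p) / n_perm), observed = obs,
         n_perm = n_perm)
  })
}

#' Rank correlation of CA count with chromosome length
#'
#' Experimental helper for chromosome-size bias screening: Spearman
#' correlation between per-chromosome call counts and chromosome lengths.
#'
#' @param calls an `sk_calls` table.
#' @param genome the [genome_model()].
#' @return list with `rho` and `p` from `stats::cor.test`.
#' @export
size_bias_correlation <- function(calls, genome) {
  cnt <- data.table::as.data.table(calls)[, .(n = .N), by = chrom]
  cnt <- cnt[data.table::data.table(chrom = genome$chrom), on = "chrom"]
  cnt[is.na(n), n := 0L]
  ct <- stats::cor.test(cnt$n, genome$length, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}
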