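## Annotation-set statistics: hypergeometric overlap with representation
## factor, rank-based subset shift tests, and pre-ranked running-sum
## enrichment with gene-permutation normalization.

#' Hypergeometric overlap test with representation factor
#'
#' Upper-tail hypergeometric probability of observing at least `overlap_k`
#' common members between a set of size `set_k` and a draw of size `draw_n`
#' from a population of `population_n`, computed in log space so extreme
#' tails (far below the smallest representable double) are still reported
#' exactly as log10 values. The representation factor is the observed
#' overlap divided by the overlap expected under independence:
#' \eqn{RF = k N / (K n)}.
#'
#' @param population_n Population size.
#' @param set_k Size of the annotation set within the population.
#' @param draw_n Size of the drawn (e.g. regulated) set.
#' @param overlap_k Observed overlap.
#' @return An object of class `"overlap_test"`: list with the four counts,
#'   `p_upper` (possibly subnormal or 0 for extreme tails), `log10_p`, and
#'   `representation_factor`.
#' @examples
#' overlap_test(8112, 530, 548, 352)
#' @export
overlap_test <- function(population_n, set_k, draw_n, overlap_k) {
  counts <- c(population_n, set_k, draw_n, overlap_k)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (set_k > population_n || draw_n > population_n ||
      overlap_k > min(set_k, draw_n))
    stop("inconsistent counts: need overlap_k <= min(set_k, draw_n) <= population_n",
         call. = FALSE)
  log_p <- if (overlap_k == 0) 0 else
    stats::phyper(overlap_k - 1, set_k, population_n - set_k, draw_n,
                  lower.tail = FALSE, log.p = TRUE)
  rf <- if (set_k == 0 || draw_n == 0) NA_real_ else
    overlap_k * population_n / (set_k * draw_n)
  structure(list(
    population_n = population_n, set_k = set_k, draw_n = draw_n,
    overlap_k = overlap_k,
    p_upper = exp(log_p),
    log10_p = log_p / log(10),
    representation_factor = rf
  ), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: %d / min(%d, %d) in population %d\n",
              x$overlap_k, x$set_k, x$draw_n, x$population_n))
  cat(sprintf("  P(X >= k) = %.3g (log10 p = %.2f), RF = %.3f\n",
              x$p_upper, x$log10_p, x$representation_factor))
  invisible(x)
}

#' Rank-based shift test of a subset against a background
#'
#' Distribution-shift tests used to ask whether an annotated subset of
#' proteins moved relative to a background or between paired channels.
#' `mann_whitney_vs_background` runs the two-sample rank-sum test of the
#' subset values against the background values (exact when both groups are
#' small without ties, else normal approximation with tie correction and
#' continuity correction). `wilcoxon_paired_columns` runs the signed-rank
#' test on paired equal-length vectors (zero differences dropped).
#'
#' @param subset_values Numeric vector of the subset (or first paired
#'   column).
#' @param background_values Numeric vector of the background (or second
#'   paired column; equal length required for the paired mode).
#' @param mode `"mann_whitney_vs_background"` (default) or
#'   `"wilcoxon_paired_columns"`.
#' @return List with `statistic`, `p_value`, `median_shift` (median of the
#'   subset minus median of the background; median of the differences in
#'   the paired mode) and `mode`.
#' @export
rank_shift_test <- function(subset_values, background_values,
                            mode = c("mann_whitney_vs_background",
                                     "wilcoxon_paired_columns")) {
  mode <- match.arg(mode)
  x <- subset_values; y <- background_values
  if (length(x) == 0L || length(y) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  if (mode == "wilcoxon_paired_columns") {
    if (length(x) != length(y))
      stop("paired mode requires equal-length vectors", call. = FALSE)
    wt <- stats::wilcox.test(x, y, paired = TRUE, correct = TRUE)
    shift <- stats::median(x - y)
  } else {
    exact <- length(x) <= 12L && length(y) <= 12L &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    shift <- stats::median(x) - stats::median(y)
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_shift = shift, mode = mode)
}

#' Read annotation sets in GMT format
#'
#' @param path Path to a GMT file (set name, description, tab-separated
#'   members per line).
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

## weighted running-sum enrichment score for one set; scores sorted
## decreasing, hit = logical vector aligned with the sorted scores
.running_sum_es <- function(sorted_scores, hit, weight_exponent) {
  n <- length(sorted_scores)
  n_hit <- sum(hit)
  w <- abs(sorted_scores)^weight_exponent
  w_hit <- w * hit
  tot <- sum(w_hit)
  inc <- if (tot > 0) w_hit / tot else hit / max(n_hit, 1L)
  dec <- (!hit) / (n - n_hit)
  rs <- cumsum(inc - dec)
  rs[which.max(abs(rs))]
}

#' Pre-ranked running-sum enrichment with permutation normalization
#'
#' Weighted Kolmogorov-Smirnov-style enrichment of annotation sets in a
#' ranked score vector. Proteins are sorted by decreasing score (ties
#' broken lexicographically by id for determinism); walking down the
#' ranking, set members increment the running sum proportionally to
#' |score|^`weight_exponent` (normalized to 1 in total) and non-members
#' decrement it by 1/(N - set size); the enrichment score `es` is the
#' signed extremum. Significance comes from `n_perm` random same-size
#' member sets: `nes` is `es` divided by the mean |es| of the same-sign
#' permutation scores and `p_perm` is the add-one-corrected fraction of
#' same-sign permutation scores at least as extreme as `es`. Sets
#' intersecting the universe in fewer than `min_size` members are skipped
#' with a warning.
#'
#' @param ranked_scores Named numeric vector (names = protein ids), finite.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param weight_exponent Weighting exponent (0 recovers the classic
#'   equal-increment running sum).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param min_size Minimum overlap of a set with the universe (default 5).
#' @return Data frame with columns `set`, `size`, `es`, `nes`, `p_perm`,
#'   `n_perm`, `seed`.
#' @export
preranked_enrichment <- function(ranked_scores, sets, weight_exponent = 1,
                                 n_perm = 1000L, seed = 0L, min_size = 5L) {
  if (length(ranked_scores) == 0L)
    stop("empty ranked universe", call. = FALSE)
  if (any(!is.finite(ranked_scores)))
    stop("scores must be finite", call. = FALSE)
  ids <- names(ranked_scores)
  if (is.null(ids)) stop("'ranked_scores' must be named", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate protein ids", call. = FALSE)
  if (!is.list(sets)) sets <- list(set1 = sets)

  ord <- order(-ranked_scores, ids)
  sorted <- ranked_scores[ord]
  sorted_ids <- ids[ord]
  n <- length(sorted)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], ids)
    k <- length(members)
    if (k < min_size) {
      warning(sprintf("set '%s' has %d members in the universe (< %d); skipped",
                      nm, k, min_size), call. = FALSE)
      return(NULL)
    }
    hit <- sorted_ids %in% members
    es <- .running_sum_es(sorted, hit, weight_exponent)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      ph <- logical(n)
      ph[sample.int(n, k)] <- TRUE
      .running_sum_es(sorted, ph, weight_exponent)
    }, numeric(1L))
    same_sign <- perm_es[sign(perm_es) == sign(es)]
    nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    ## one-tailed permutation p against the same-sign portion of the null,
    ## add-one corrected so p >= 1/(n_same + 1) and is null-uniform
    p <- (1 + sum(abs(same_sign) >= abs(es))) / (length(same_sign) + 1)
    data.frame(set = nm, size = k, es = es, nes = nes, p_perm = p,
               n_perm = as.integer(n_perm), seed = as.integer(seed),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L)
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_perm = numeric(), n_perm = integer(),
                      seed = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
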