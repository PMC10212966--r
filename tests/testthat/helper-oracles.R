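# Independent brute-force oracles used across test files.

# direct numeric evaluation of the logistic, written independently of the
# package's melt_fraction
oracle_logistic <- function(tm, slope, plateau, t) {
  plateau + (1 - plateau) * (1 / (1 + exp(slope * (t - tm))))
}

# exhaustive hypergeometric upper tail: enumerate every draw of size n from
# a population of N in which elements 1..K form the annotation set
oracle_overlap_p <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# full-enumeration two-sided Mann-Whitney p-value for distinct values:
# enumerate every assignment of the pooled ranks to group 1
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  u_all <- apply(combos, 2, function(ix) sum(all_ranks[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# independent regex-based scanner for the RG-motif taxonomy: find maximal
# RG/RGG unit spans with gregexpr, then chain and count
oracle_motif <- function(sequence, position, max_spacer = 4L,
                         min_repeats = 2L, window = 10L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (position == n || chars[position + 1] != "G") return("non_rg")
  m <- gregexpr("RGG|RG", sequence)[[1]]
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  site_i <- which(starts == position)
  linked <- rep(FALSE, length(starts))
  linked[site_i] <- TRUE
  repeat {
    changed <- FALSE
    for (i in seq_along(starts)) {
      if (linked[i]) next
      for (j in which(linked)) {
        gap <- if (starts[i] > starts[j]) starts[i] - ends[j] - 1L
               else starts[j] - ends[i] - 1L
        if (abs(i - j) == 1L && gap <= max_spacer) {
          linked[i] <- TRUE; changed <- TRUE; break
        }
      }
    }
    if (!changed) break
  }
  extra <- linked & seq_along(starts) != site_i &
    abs(starts - position) <= window
  if (sum(extra) >= min_repeats - 1L) "canonical_rg" else "noncanonical_rg"
}

# random amino-acid sequence biased toward R and G so motifs are common
random_rg_sequence <- function(len) {
  paste(sample(c("R", "G", "A", "S", "P", "K", "L"), len, replace = TRUE,
               prob = c(0.25, 0.3, 0.15, 0.08, 0.07, 0.08, 0.07)),
        collapse = "")
}
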