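## Sequence-context classification of arginine methyl sites and fractional
## occupancy from counterpart-peptide depletion.

## all RG-unit start positions in a sequence vector of single residues;
## a unit is R followed by G (optionally a second G, giving length 3)
.rg_units <- function(chars) {
  n <- length(chars)
  starts <- which(chars == "R")
  starts <- starts[starts < n & chars[starts + 1L] == "G"]
  if (length(starts) == 0L)
    return(data.frame(start = integer(), end = integer()))
  ends <- ifelse(starts + 2L <= n & chars[starts + 2L] == "G",
                 starts + 2L, starts + 1L)
  data.frame(start = starts, end = ends)
}

#' Classify the RG-motif context of an arginine methyl site
#'
#' Classifies an arginine site by its glycine context: `non_rg` when the
#' residue after the site is not glycine (or the site is C-terminal);
#' otherwise the site anchors an RG/RGG unit and is `canonical_rg` when at
#' least `min_repeats - 1` additional RG or RGG units lie within `window`
#' residues of the site, chained to the site unit with inter-unit spacers
#' of at most `max_spacer` residues; an isolated RG is `noncanonical_rg`.
#' Only R-followed-by-G contexts count as RG; glycine-preceding (GR)
#' contexts are not counted (documented choice).
#'
#' @param sequence Amino-acid string (single-letter codes).
#' @param position 1-based index of the site; the residue there must be R.
#' @param max_spacer Maximum number of residues between consecutive units
#'   in a chain (default 4).
#' @param min_repeats Minimum number of units (including the site's) for a
#'   canonical call (default 2).
#' @param window Maximum distance (residues) from the site at which an
#'   additional unit may start (default 10).
#' @return One of `"canonical_rg"`, `"noncanonical_rg"`, `"non_rg"`.
#' @examples
#' classify_arg_motif("AARGGRGGAA", 3)   # canonical_rg
#' classify_arg_motif("AAARGAAAAAAAAAAA", 4)  # noncanonical_rg
#' classify_arg_motif("AAARAAAA", 4)     # non_rg
#' @export
classify_arg_motif <- function(sequence, position, max_spacer = 4L,
                               min_repeats = 2L, window = 10L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (position < 1L || position > n)
    stop("'position' out of range", call. = FALSE)
  if (chars[position] != "R")
    stop(sprintf("residue at position %d is '%s', not R", position,
                 chars[position]), call. = FALSE)
  if (position == n || chars[position + 1L] != "G") return("non_rg")

  units <- .rg_units(chars)
  site_row <- which(units$start == position)
  ## chain outward from the site unit: neighbours linked while the gap
  ## between consecutive units is <= max_spacer
  in_chain <- logical(nrow(units))
  in_chain[site_row] <- TRUE
  if (site_row > 1L) {
    for (i in seq(site_row - 1L, 1L)) {
      gap <- units$start[i + 1L] - units$end[i] - 1L
      if (in_chain[i + 1L] && gap <= max_spacer) in_chain[i] <- TRUE else break
    }
  }
  if (site_row < nrow(units)) {
    for (i in seq(site_row + 1L, nrow(units))) {
      gap <- units$start[i] - units$end[i - 1L] - 1L
      if (in_chain[i - 1L] && gap <= max_spacer) in_chain[i] <- TRUE else break
    }
  }
  extra <- in_chain & seq_len(nrow(units)) != site_row &
    abs(units$start - position) <= window
  if (sum(extra) >= min_repeats - 1L) "canonical_rg" else "noncanonical_rg"
}

#' Annotate a table of methyl sites with motif class and flank
#'
#' @param sites Data frame with columns `protein_id`, `position` (1-based)
#'   and `residue` (`"R"` or `"K"`).
#' @param sequences Named character vector of protein sequences, or a path
#'   to a FASTA file (read with Biostrings).
#' @param flank Number of residues either side of the site to report
#'   (truncated at sequence ends, no padding).
#' @param ... Passed to [classify_arg_motif()].
#' @return The input with `flank` and `motif_class` columns added; lysine
#'   sites get `motif_class = "not_applicable"`.
#' @export
annotate_methyl_sites <- function(sites, sequences, flank = 5L, ...) {
  stopifnot(is.data.frame(sites),
            all(c("protein_id", "position", "residue") %in% names(sites)))
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    aa <- Biostrings::readAAStringSet(sequences)
    sequences <- stats::setNames(as.character(aa),
                                 sub("\\s.*$", "", names(aa)))
  }
  out <- sites
  out$flank <- rep(NA_character_, nrow(out))
  out$motif_class <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(out))) {
    seq_i <- if (out$protein_id[i] %in% names(sequences))
      sequences[[out$protein_id[i]]] else NULL
    if (is.null(seq_i) || is.na(seq_i))
      stop(sprintf("no sequence for protein '%s'", out$protein_id[i]),
           call. = FALSE)
    pos <- out$position[i]
    nchar_i <- nchar(seq_i)
    if (pos < 1L || pos > nchar_i)
      stop(sprintf("position %d out of range for '%s'", pos,
                   out$protein_id[i]), call. = FALSE)
    res <- substr(seq_i, pos, pos)
    if (res != out$residue[i])
      stop(sprintf("residue mismatch at %s:%d (sequence has '%s')",
                   out$protein_id[i], pos, res), call. = FALSE)
    out$flank[i] <- substr(seq_i, max(1L, pos - flank),
                           min(nchar_i, pos + flank))
    out$motif_class[i] <- if (res == "K") "not_applicable"
                          else classify_arg_motif(seq_i, pos, ...)
  }
  out
}

#' Fractional occupancy from counterpart-peptide depletion
#'
#' Estimates the fraction of molecules modified at a site from the decrease
#' of the unmodified counterpart peptide between a reference and a test
#' condition:
#' \deqn{\theta = 1 - \frac{U_{test}/L_{test}}{U_{ref}/L_{ref}}}
#' clamped to \[0, 1\]. The estimator only needs the unmodified peptide
#' (response factors of the modified forms cancel out of the question);
#' loading factors correct for unequal amounts of material.
#'
#' @param unmod_reference,unmod_test Positive unmodified-peptide
#'   quantities in the reference (unmodified) and test conditions.
#' @param loading_reference,loading_test Positive loading factors.
#' @return An object of class `"occupancy_estimate"`: list with `theta`,
#'   `method` and `inputs`.
#' @examples
#' estimate_occupancy(10, 2)$theta  # 0.8
#' @export
estimate_occupancy <- function(unmod_reference, unmod_test,
                               loading_reference = 1, loading_test = 1) {
  vals <- c(unmod_reference, unmod_test, loading_reference, loading_test)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("quantities and loadings must be positive", call. = FALSE)
  theta <- 1 - (unmod_test / loading_test) / (unmod_reference / loading_reference)
  theta <- min(max(theta, 0), 1)
  structure(list(
    theta = theta,
    method = "counterpart_decrease",
    inputs = list(unmod_reference = unmod_reference, unmod_test = unmod_test,
                  loading_reference = loading_reference,
                  loading_test = loading_test)
  ), class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("Fractional occupancy (counterpart decrease): theta = %.3f\n",
              x$theta))
  invisible(x)
}
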