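## End-to-end orchestration and the tab-separated file dialects.
## All tables are UTF-8 TSV with a header row, '.' decimal separator.

#' Write a quantity matrix as TSV
#'
#' First column `protein_id`, remaining columns the
#' `<condition>_<channel>_rep<k>` sample names.
#'
#' @param matrix Log2 quantity matrix with rownames and sample colnames.
#' @param path Output path.
#' @export
write_quant_table <- function(matrix, path) {
  df <- data.frame(protein_id = rownames(matrix), matrix,
                   check.names = FALSE, row.names = NULL,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a quantity matrix from TSV
#'
#' Accepts either the native dialect (first column `protein_id`) or a
#' protein-group-style export (`Protein IDs` id column plus per-sample
#' reporter columns) via `column_map`. Duplicate protein ids and
#' non-numeric cells are rejected with descriptive errors.
#'
#' @param path Input path.
#' @param column_map Optional list with `id` (name of the id column) and
#'   `samples` (named character vector mapping native sample names to file
#'   column names) for non-native headers.
#' @param log2_transform Set TRUE when the file stores linear-scale
#'   intensities that should be log2-transformed on read.
#' @return Numeric matrix, rownames = protein ids.
#' @export
read_quant_table <- function(path, column_map = NULL, log2_transform = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  id_col <- if (is.null(column_map)) "protein_id" else column_map$id
  if (!id_col %in% names(df))
    stop(sprintf("missing id column '%s' in %s", id_col, path), call. = FALSE)
  ids <- as.character(df[[id_col]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("duplicate protein id(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  if (is.null(column_map)) {
    sample_cols <- setdiff(names(df), id_col)
  } else {
    missing <- setdiff(unname(column_map$samples), names(df))
    if (length(missing) > 0)
      stop(sprintf("mapped column(s) not found in %s: %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    df <- df[c(id_col, unname(column_map$samples))]
    names(df) <- c(id_col, names(column_map$samples))
    sample_cols <- names(column_map$samples)
  }
  for (cc in sample_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1L]
      stop(sprintf("non-numeric cell in column '%s' of %s (data line %d)",
                   cc, path, bad), call. = FALSE)
    }
  }
  m <- as.matrix(df[sample_cols])
  rownames(m) <- ids
  if (log2_transform) m <- log2(m)
  m
}

#' Write / read a gradient table
#'
#' Columns `protein_id`, `condition`, `temperature_c`, `replicate`,
#' `quantity`.
#'
#' @param table Data frame as produced by [simulate_gradient_dataset()].
#' @param path File path.
#' @export
write_gradient_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gradient_table
#' @export
read_gradient_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("protein_id", "condition", "temperature_c", "replicate",
            "quantity")
  if (!all(need %in% names(df)))
    stop(sprintf("gradient table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  df
}

#' Carrier-based normalization of a gradient table
#'
#' Divides every quantity by a per-temperature/replicate scaling factor,
#' the median ratio of the carrier proteins to their across-replicate mean
#' at that temperature, removing per-sample loading differences. Without a
#' carrier, normalize each protein within [fit_melting_curve()] via
#' `normalize_to_lowest` instead.
#'
#' @param table Gradient data frame.
#' @param carrier_ids Protein ids of the carrier proteome.
#' @return The table with normalized `quantity`.
#' @export
carrier_normalize <- function(table, carrier_ids) {
  car <- table[table$protein_id %in% carrier_ids, , drop = FALSE]
  if (nrow(car) == 0L) stop("no carrier proteins in table", call. = FALSE)
  ## mean over replicates per carrier protein x condition x temperature
  key_mean <- stats::aggregate(
    quantity ~ protein_id + condition + temperature_c, data = car, FUN = mean)
  names(key_mean)[names(key_mean) == "quantity"] <- "ref"
  car <- merge(car, key_mean)
  car$ratio <- car$quantity / car$ref
  fac <- stats::aggregate(
    ratio ~ condition + temperature_c + replicate, data = car,
    FUN = stats::median)
  out <- merge(table, fac, by = c("condition", "temperature_c", "replicate"),
               all.x = TRUE)
  out$quantity <- out$quantity / out$ratio
  out$ratio <- NULL
  out[order(out$protein_id, out$condition, out$replicate,
            out$temperature_c), ]
}

#' Run the full pooled-temperature differential workflow
#'
#' Orchestrates the analysis of one experiment with one or more treatments:
#' per treatment and channel, normalization, moderated testing, BH
#' adjustment and the regulation call; then the consensus across
#' treatments (set intersection of per-treatment calls, matching the
#' "in common" presentation), joint stability/abundance classification
#' per treatment, and an optional pre-ranked enrichment of the stability
#' ranking. Deterministic given inputs and `seed`.
#'
#' @param treatments Named list; each element a list with `stability` and
#'   `abundance` log2 matrices (columns `control_*` / `treated_*`).
#' @param fc_threshold,p_threshold Regulation thresholds (assay-standard
#'   defaults 0.1 and 0.01).
#' @param concordance_margin Margin for the joint classification.
#' @param normalize Normalize matrices before testing.
#' @param gmt Optional named list of annotation sets for enrichment of the
#'   first treatment's stability log2 ratios.
#' @param n_perm,seed Enrichment permutation settings.
#' @param out_dir Optional directory; when given, per-treatment result
#'   tables, the consensus sets and a machine-readable run report are
#'   written there as TSV/JSON-like text.
#' @return Object of class `"pisa_workflow"`: list with `results` (one
#'   data frame per treatment with both channels, fdr, regulation and
#'   joint class), `consensus_up`, `consensus_down`, `enrichment`,
#'   `report`.
#' @export
run_pisa_workflow <- function(treatments, fc_threshold = 0.1,
                              p_threshold = 0.01, concordance_margin = 0.1,
                              normalize = TRUE, gmt = NULL, n_perm = 1000L,
                              seed = 0L, out_dir = NULL) {
  stopifnot(is.list(treatments), length(treatments) >= 1L)
  if (is.null(names(treatments)))
    names(treatments) <- sprintf("treatment%d", seq_along(treatments))

  universe <- rownames(treatments[[1L]]$stability)
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    if (!all(c("stability", "abundance") %in% names(tr)))
      stop(sprintf("treatment '%s' needs 'stability' and 'abundance' matrices",
                   nm), call. = FALSE)
    if (!identical(rownames(tr$stability), universe) ||
        !identical(rownames(tr$abundance), universe))
      stop("all matrices must share one protein universe (same rownames)",
           call. = FALSE)
  }

  results <- list()
  up_sets <- list()
  down_sets <- list()
  counts <- list()
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    sta <- diff_channel(tr$stability, normalize = normalize,
                        fc_threshold = fc_threshold,
                        p_threshold = p_threshold)
    abu <- diff_channel(tr$abundance, normalize = normalize,
                        fc_threshold = fc_threshold,
                        p_threshold = p_threshold)
    res <- data.frame(
      protein_id = sta$protein_id,
      log2fc_stability = sta$log2fc, p_stability = sta$p,
      fdr_stability = sta$fdr, regulated_stability = sta$regulated,
      log2fc_abundance = abu$log2fc, p_abundance = abu$p,
      fdr_abundance = abu$fdr, regulated_abundance = abu$regulated,
      stringsAsFactors = FALSE)
    res$joint_class <- joint_stability_abundance_classify(
      res$regulated_stability, res$regulated_abundance,
      res$log2fc_stability, res$log2fc_abundance,
      concordance_margin = concordance_margin)
    results[[nm]] <- res
    up_sets[[nm]] <- res$protein_id[res$regulated_stability == "up"]
    down_sets[[nm]] <- res$protein_id[res$regulated_stability == "down"]
    counts[[nm]] <- c(read = length(universe),
                      up = length(up_sets[[nm]]),
                      down = length(down_sets[[nm]]))
  }

  consensus_up <- Reduce(intersect, up_sets)
  consensus_down <- Reduce(intersect, down_sets)
  if (length(treatments) > 1L && length(consensus_up) == 0L &&
      length(consensus_down) == 0L)
    warning("empty consensus across treatments", call. = FALSE)

  enrichment <- NULL
  if (!is.null(gmt)) {
    scores <- stats::setNames(results[[1L]]$log2fc_stability,
                              results[[1L]]$protein_id)
    enrichment <- preranked_enrichment(scores, gmt, n_perm = n_perm,
                                       seed = seed)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("meltshift")),
    seed = as.integer(seed),
    thresholds = list(fc = fc_threshold, p = p_threshold,
                      concordance_margin = concordance_margin),
    n_proteins = length(universe),
    per_treatment = counts,
    consensus = c(up = length(consensus_up), down = length(consensus_down))
  )

  out <- structure(list(results = results, consensus_up = consensus_up,
                        consensus_down = consensus_down,
                        enrichment = enrichment, report = report),
                   class = "pisa_workflow")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results)) {
      utils::write.table(results[[nm]],
                         file.path(out_dir, paste0("diff_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(consensus_up, file.path(out_dir, "consensus_up.txt"))
    writeLines(consensus_down, file.path(out_dir, "consensus_down.txt"))
    rep_lines <- c(
      sprintf("package_version\t%s", report$package_version),
      sprintf("seed\t%d", report$seed),
      sprintf("n_proteins\t%d", report$n_proteins),
      vapply(names(counts), function(nm) {
        sprintf("%s\tread=%d\tup=%d\tdown=%d", nm, counts[[nm]]["read"],
                counts[[nm]]["up"], counts[[nm]]["down"])
      }, character(1L)),
      sprintf("consensus\tup=%d\tdown=%d", length(consensus_up),
              length(consensus_down)))
    writeLines(rep_lines, file.path(out_dir, "run_report.tsv"))
  }
  out
}

#' @export
print.pisa_workflow <- function(x, ...) {
  r <- x$report
  cat(sprintf("PISA differential workflow: %d proteins, %d treatment(s)\n",
              r$n_proteins, length(x$results)))
  for (nm in names(x$results)) {
    cc <- r$per_treatment[[nm]]
    cat(sprintf("  %s: %d up, %d down (stability)\n", nm, cc["up"],
                cc["down"]))
  }
  cat(sprintf("  consensus: %d up, %d down\n", length(x$consensus_up),
              length(x$consensus_down)))
  invisible(x)
}

#' @export
summary.pisa_workflow <- function(object, ...) {
  print(object)
  for (nm in names(object$results)) {
    cat(sprintf("\nJoint classes (%s):\n", nm))
    print(table(object$results[[nm]]$joint_class))
  }
  invisible(object)
}
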