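## Synthetic thermal-proteome experiments with recoverable ground truth.
## All noise is multiplicative log-normal parameterized by a coefficient of
## variation; lognormal meanlog is offset so the noise factor has mean 1.

.lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

## truncated-normal draw by inverse-CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Sample a synthetic proteome with melting parameters
#'
#' Draws a proteome of `n_proteins` with per-protein logistic melting
#' parameters and linear-scale base abundances. Melting points come from a
#' normal distribution truncated to \[40, 70\] degC centred by default in the
#' middle of the 51-56 degC pooling window; slopes are log-normal around
#' 1/degC; plateaus are uniform on \[0, `plateau_max`\]; base abundances are
#' log-normal spanning several orders of magnitude (log10 abundance is
#' normal with sd 1), as reporter-intensity distributions are.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @param tm_mean,tm_sd Mean and sd (degC) of the untruncated Tm
#'   distribution; `tm_sd` must be positive.
#' @param plateau_max Upper bound of the uniform plateau distribution,
#'   in \[0, 1).
#' @return A list of class `"proteome_model"` with `protein_ids`,
#'   `tm`, `slope`, `plateau` (numeric vectors) and `base_abundance`.
#' @export
sample_proteome_model <- function(n_proteins, seed = 0L, tm_mean = 52.5,
                                  tm_sd = 2, plateau_max = 0.2) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1)
    stop("'n_proteins' must be a positive count", call. = FALSE)
  if (!is.numeric(tm_sd) || tm_sd <= 0)
    stop("'tm_sd' must be positive", call. = FALSE)
  if (plateau_max < 0 || plateau_max >= 1)
    stop("'plateau_max' must lie in [0, 1)", call. = FALSE)
  n <- as.integer(n_proteins)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  structure(list(
    protein_ids = sprintf("P%05d", seq_len(n)),
    tm = .rtruncnorm(n, tm_mean, tm_sd, 40, 70),
    slope = exp(stats::rnorm(n, 0, 0.25)),
    plateau = stats::runif(n, 0, plateau_max),
    base_abundance = 10^stats::rnorm(n, 6, 1),
    seed = as.integer(seed)
  ), class = "proteome_model")
}

## save/restore the global RNG state so generators are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.proteome_model <- function(x, ...) {
  cat(sprintf("Synthetic proteome: %d proteins (seed %d)\n",
              length(x$protein_ids), x$seed))
  cat(sprintf("  Tm: %.1f-%.1f degC (median %.1f)\n",
              min(x$tm), max(x$tm), stats::median(x$tm)))
  invisible(x)
}

#' Assign treatment effects and ground-truth labels
#'
#' Selects a minority fraction of proteins as thermally shifted substrates
#' and an (by default disjoint) fraction with abundance changes, emulating a
#' treatment in which a small substrate subset gains stability while an
#' independent subset changes expression. Effect magnitudes are drawn from
#' normal distributions around the stated means with their sign forced to
#' the sign of the mean, so the per-class counts are exactly
#' `round(frac * n)`.
#'
#' @param model A [sample_proteome_model()] object.
#' @param frac_stabilized Fraction of proteins given a thermal shift
#'   (label `substrate_stabilized` for positive `mean_delta_tm`, else
#'   `substrate_destabilized`).
#' @param mean_delta_tm,sd_delta_tm Mean and sd of the Tm shift in degC.
#' @param frac_abundance Fraction given an abundance change (label
#'   `abundance_changed`), disjoint from the substrate set.
#' @param mean_log2_abund,sd_log2_abund Mean and sd of the log2 abundance
#'   effect.
#' @param seed Integer seed.
#' @return A list of class `"treatment_effect"` with per-protein
#'   `delta_tm`, `log2_abundance_effect` and `labels`, plus a
#'   `ground_truth` data frame (one row per protein).
#' @export
apply_treatment_effect <- function(model, frac_stabilized = 0.05,
                                   mean_delta_tm = 1.5, sd_delta_tm = 0.5,
                                   frac_abundance = 0.05,
                                   mean_log2_abund = -0.5,
                                   sd_log2_abund = 0.25, seed = 0L) {
  stopifnot(inherits(model, "proteome_model"))
  if (frac_stabilized < 0 || frac_stabilized > 1 ||
      frac_abundance < 0 || frac_abundance > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (frac_stabilized + frac_abundance > 1)
    stop("disjoint effect sets require frac_stabilized + frac_abundance <= 1",
         call. = FALSE)
  n <- length(model$protein_ids)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  delta_tm <- numeric(n)
  log2_ab <- numeric(n)
  labels <- rep("null", n)

  ## a zero mean effect is no effect: keep labels consistent with effects
  n_stab <- if (mean_delta_tm == 0) 0L else round(frac_stabilized * n)
  n_ab <- if (mean_log2_abund == 0) 0L else round(frac_abundance * n)
  pick <- sample.int(n, n_stab + n_ab)
  idx_stab <- pick[seq_len(n_stab)]
  idx_ab <- pick[n_stab + seq_len(n_ab)]

  if (n_stab > 0) {
    draw <- stats::rnorm(n_stab, mean_delta_tm, sd_delta_tm)
    delta_tm[idx_stab] <- sign(mean_delta_tm) * abs(draw)
    labels[idx_stab] <- if (mean_delta_tm >= 0) "substrate_stabilized"
                        else "substrate_destabilized"
  }
  if (n_ab > 0) {
    draw <- stats::rnorm(n_ab, mean_log2_abund, sd_log2_abund)
    log2_ab[idx_ab] <- sign(mean_log2_abund) * abs(draw)
    labels[idx_ab] <- "abundance_changed"
  }

  structure(list(
    protein_ids = model$protein_ids,
    delta_tm = delta_tm,
    log2_abundance_effect = log2_ab,
    labels = labels,
    ground_truth = data.frame(
      protein_id = model$protein_ids,
      label = labels,
      delta_tm = delta_tm,
      log2_abundance_effect = log2_ab,
      stringsAsFactors = FALSE
    ),
    seed = as.integer(seed)
  ), class = "treatment_effect")
}

#' Experiment design for a pooled-temperature simulation
#'
#' @param temperatures Ordered window temperatures in degC (>= 2); default
#'   the 51-56 degC window.
#' @param n_reps_control,n_reps_treated Replicates per arm (>= 2 each); the
#'   default is the 3-vs-3 design, and 3-vs-2 is supported.
#' @param noise_cv Multiplicative coefficient of variation of the
#'   measurement noise (>= 0).
#' @param seed Integer seed.
#' @return A list of class `"experiment_design"`.
#' @export
experiment_design <- function(temperatures = 51:56, n_reps_control = 3L,
                              n_reps_treated = 3L, noise_cv = 0.08,
                              seed = 0L) {
  if (length(temperatures) < 2L)
    stop("need >= 2 window temperatures", call. = FALSE)
  if (n_reps_control < 2L || n_reps_treated < 2L)
    stop("need >= 2 replicates per arm", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  structure(list(temperatures = as.numeric(temperatures),
                 n_reps_control = as.integer(n_reps_control),
                 n_reps_treated = as.integer(n_reps_treated),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate a paired stability/abundance PISA experiment
#'
#' For every replicate, the stability-channel quantity of a protein is its
#' base abundance, times the abundance effect when treated, times the mean
#' soluble fraction over the window temperatures (with the Tm shift applied
#' when treated), times an independent log-normal noise factor. The
#' abundance-channel quantity omits the melting term. Both channels are
#' returned as log2 matrices with `<condition>_<channel>_rep<k>` columns, so
#' a pure abundance effect propagates equally into both channels (the basis
#' of the stability/abundance decoupling step downstream).
#'
#' @param model A [sample_proteome_model()] object.
#' @param effect A matching [apply_treatment_effect()] object.
#' @param design An [experiment_design()].
#' @return List with `stability` and `abundance` (log2 matrices, proteins x
#'   samples, rownames = protein ids) and `ground_truth` (data frame).
#' @export
simulate_pisa_dataset <- function(model, effect, design = experiment_design()) {
  stopifnot(inherits(model, "proteome_model"),
            inherits(effect, "treatment_effect"),
            inherits(design, "experiment_design"))
  if (!identical(model$protein_ids, effect$protein_ids))
    stop("'model' and 'effect' must cover the same proteins", call. = FALSE)
  if (length(design$temperatures) == 0L)
    stop("empty temperature window", call. = FALSE)
  n <- length(model$protein_ids)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)

  ## window-mean melting fractions, control and shifted
  pisa_ctrl <- vapply(seq_len(n), function(i) {
    mean(.melt_frac(model$tm[i], model$slope[i], model$plateau[i],
                    design$temperatures))
  }, numeric(1L))
  pisa_trt <- vapply(seq_len(n), function(i) {
    mean(.melt_frac(model$tm[i] + effect$delta_tm[i], model$slope[i],
                    model$plateau[i], design$temperatures))
  }, numeric(1L))
  ab_fac <- 2^effect$log2_abundance_effect

  mk <- function(base, n_reps, cv) {
    m <- vapply(seq_len(n_reps),
                function(k) base * .lognorm_noise(n, cv), numeric(n))
    matrix(m, nrow = n)
  }
  cv <- design$noise_cv
  sta <- cbind(mk(model$base_abundance * pisa_ctrl, design$n_reps_control, cv),
               mk(model$base_abundance * ab_fac * pisa_trt,
                  design$n_reps_treated, cv))
  abu <- cbind(mk(model$base_abundance, design$n_reps_control, cv),
               mk(model$base_abundance * ab_fac, design$n_reps_treated, cv))

  cn <- function(channel) c(
    sprintf("control_%s_rep%d", channel, seq_len(design$n_reps_control)),
    sprintf("treated_%s_rep%d", channel, seq_len(design$n_reps_treated)))
  dimnames(sta) <- list(model$protein_ids, cn("stability"))
  dimnames(abu) <- list(model$protein_ids, cn("abundance"))

  list(stability = log2(sta), abundance = log2(abu),
       ground_truth = effect$ground_truth)
}

#' Simulate a spike-in temperature-gradient experiment
#'
#' Emulates a spike-in assay in which target proteins are measured under two
#' conditions (e.g. methylated vs unmethylated) across a temperature
#' gradient over a carrier proteome. Soluble quantities follow each
#' condition's logistic curve times log-normal noise; carrier proteins share
#' one curve across conditions and denature with temperature.
#'
#' @param targets Named list; each element is a list with components
#'   `control` and `treated`, both [melt_params()].
#' @param carrier Optional [sample_proteome_model()] whose proteins are
#'   added under both conditions (carrier curves from their own melting
#'   parameters).
#' @param temperatures Gradient temperatures in degC (>= 3); the default
#'   five-point gradient spans the transition.
#' @param n_reps Replicates per condition (>= 2).
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @return Data frame with columns `protein_id`, `condition`,
#'   `temperature_c`, `replicate`, `quantity`.
#' @export
simulate_gradient_dataset <- function(targets, carrier = NULL,
                                      temperatures = c(49, 51, 53, 55, 57),
                                      n_reps = 2L, noise_cv = 0.05,
                                      seed = 0L) {
  if (length(temperatures) < 3L)
    stop("need >= 3 temperatures (curve comparison underdetermined)",
         call. = FALSE)
  if (n_reps < 2L) stop("need >= 2 replicates", call. = FALSE)
  stopifnot(is.list(targets), length(targets) >= 1L)
  if (is.null(names(targets)))
    names(targets) <- sprintf("target%d", seq_along(targets))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  rows <- list()
  add <- function(id, cond, params) {
    f <- melt_fraction(params, temperatures)
    for (k in seq_len(n_reps)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        protein_id = id, condition = cond, temperature_c = temperatures,
        replicate = k,
        quantity = f * .lognorm_noise(length(temperatures), noise_cv),
        stringsAsFactors = FALSE)
    }
  }
  for (nm in names(targets)) {
    add(nm, "control", as_melt_params(targets[[nm]]$control))
    add(nm, "treated", as_melt_params(targets[[nm]]$treated))
  }
  if (!is.null(carrier)) {
    stopifnot(inherits(carrier, "proteome_model"))
    for (i in seq_along(carrier$protein_ids)) {
      p <- melt_params(carrier$tm[i], carrier$slope[i], carrier$plateau[i])
      add(carrier$protein_ids[i], "control", p)
      add(carrier$protein_ids[i], "treated", p)
    }
  }
  do.call(rbind, rows)
}

#' Simulate modified/unmodified counterpart peptide quantities
#'
#' Generates a peptide-level quantification table for methyl-occupancy
#' estimation. For each site and condition, the unmodified counterpart
#' intensity is proportional to `loading * (1 - occupancy)` and the modified
#' intensity to `loading * occupancy`, split across methyl states by
#' `state_weights`; noise is multiplicative log-normal.
#'
#' @param true_occupancy Named numeric matrix or data frame: rows = sites,
#'   columns = conditions, entries in \[0, 1\]. A single named vector is
#'   treated as one site.
#' @param loading Positive per-condition loading factors (named as the
#'   conditions).
#' @param state_weights Positive weights splitting the modified signal
#'   across methyl states (default a single `me2` state).
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @return Data frame with columns `site`, `condition`, `form`
#'   (`unmodified` or a methyl state) and `quantity`.
#' @export
simulate_methyl_peptide_table <- function(true_occupancy, loading = NULL,
                                          state_weights = c(me2 = 1),
                                          noise_cv = 0.05, seed = 0L) {
  occ <- true_occupancy
  if (is.vector(occ)) occ <- matrix(occ, nrow = 1L,
                                    dimnames = list("site1", names(true_occupancy)))
  occ <- as.matrix(occ)
  if (any(occ < 0 | occ > 1))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  conds <- colnames(occ)
  if (is.null(conds)) conds <- sprintf("condition%d", seq_len(ncol(occ)))
  if (is.null(loading)) loading <- stats::setNames(rep(1, length(conds)), conds)
  if (any(loading <= 0)) stop("loadings must be positive", call. = FALSE)
  w <- state_weights / sum(state_weights)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  rows <- list()
  sites <- rownames(occ)
  if (is.null(sites)) sites <- sprintf("site%d", seq_len(nrow(occ)))
  for (i in seq_along(sites)) {
    for (j in seq_along(conds)) {
      th <- occ[i, j]; L <- loading[[conds[j]]]
      q <- c(unmodified = L * (1 - th), L * th * w)
      names(q) <- c("unmodified", names(w))
      q <- q * .lognorm_noise(length(q), noise_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        site = sites[i], condition = conds[j], form = names(q),
        quantity = unname(q), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
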