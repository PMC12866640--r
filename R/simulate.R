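#' Configure a ground-truth fractionation scenario
#'
#' Describes one simulated sample: a heavy-tailed transcript abundance
#' profile at a target sequencing depth, a partition of every transcript's
#' molecules into observable fractions plus an unobserved lost fraction, and
#' per-library recovery rates used to thin the true counts into observed
#' libraries.
#'
#' @param G Number of transcripts (default 5000).
#' @param total_reads Target whole-sample read depth (default 1.8e6, the
#'   scale of the long-read count profile the default abundance model is
#'   calibrated to; scalable).
#' @param n_fractions Number of observable fractions (default 2).
#' @param global_weights Expected share of whole-sample RNA per observable
#'   fraction plus the lost fraction (last element); must sum to 1.  Default
#'   `c(Frac1 = 0.4, Frac2 = 0.4, Lost = 0.2)`.
#' @param allocation_concentration Total concentration of the Dirichlet
#'   distribution of per-transcript allocations around `global_weights`
#'   (parameter vector = concentration * global_weights).  Small values give
#'   compartment-specific transcripts (most molecules of a transcript in one
#'   fraction), large values homogeneous allocation, `Inf` a point mass.
#'   Default 0.2, matching the strongly compartmentalized allocation seen in
#'   real fractionation data.  A vector of length `n_fractions + 1` is
#'   multiplied elementwise with `global_weights`.
#' @param recovery Named per-library observation probabilities in (0, 1]
#'   for `"Total"` and each fraction (default all 1).
#' @param n_replicates Independent library replicates to draw (default 1).
#' @param condition Condition label used in the emitted annotation.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param base_counts Optional empirical abundance vector replacing the
#'   log-normal base model (resampled to length `G` if needed).
#' @param meanlog,sdlog Parameters of the log-normal base abundance model
#'   (defaults 2 and 1.6, a heavy-tailed profile typical of transcriptome
#'   counts).
#' @return A validated list of class `fracprop_scenario`.
#' @seealso [simulate_truth()], [simulate_fractionation()]
#' @export
scenario_config <- function(G = 5000, total_reads = 1.8e6, n_fractions = 2,
                            global_weights = NULL,
                            allocation_concentration = 0.2,
                            recovery = NULL, n_replicates = 1,
                            condition = "cond1", seed = NULL,
                            base_counts = NULL, meanlog = 2, sdlog = 1.6) {
  if (G < 1 || total_reads < 1 || n_fractions < 1)
    ff_stop("fracprop_invalid_config", "G, total_reads and n_fractions must be positive")
  frac_names <- paste0("Frac", seq_len(n_fractions))
  if (is.null(global_weights)) {
    global_weights <- c(rep(0.8 / n_fractions, n_fractions), 0.2)
  }
  if (length(global_weights) != n_fractions + 1L)
    ff_stop("fracprop_invalid_config",
            "global_weights must have one entry per fraction plus the lost fraction")
  if (any(global_weights < 0) || abs(sum(global_weights) - 1) > 1e-8)
    ff_stop("fracprop_invalid_config", "global_weights must be non-negative and sum to 1")
  names(global_weights) <- c(frac_names, "Lost")
  if (is.null(recovery)) recovery <- stats::setNames(rep(1, n_fractions + 1L),
                                                     c("Total", frac_names))
  if (is.null(names(recovery)))
    names(recovery) <- c("Total", frac_names)
  if (!setequal(names(recovery), c("Total", frac_names)))
    ff_stop("fracprop_invalid_config",
            "recovery must be named for Total and each fraction")
  recovery <- recovery[c("Total", frac_names)]
  if (any(recovery <= 0) || any(recovery > 1))
    ff_stop("fracprop_invalid_config", "recovery rates must lie in (0, 1]")
  if (!length(allocation_concentration) %in% c(1L, n_fractions + 1L) ||
      any(allocation_concentration <= 0))
    ff_stop("fracprop_invalid_config",
            "allocation_concentration must be a positive scalar or length n_fractions + 1")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) ff_stop("fracprop_invalid_config", "seed must be an integer")
  }
  if (!is.null(base_counts) && (!is.numeric(base_counts) || any(base_counts < 0) ||
                                all(base_counts == 0)))
    ff_stop("fracprop_invalid_config", "base_counts must be non-negative with positive mass")
  structure(list(G = as.integer(G), total_reads = total_reads,
                 n_fractions = as.integer(n_fractions),
                 frac_names = frac_names, global_weights = global_weights,
                 allocation_concentration = allocation_concentration,
                 recovery = recovery, n_replicates = as.integer(n_replicates),
                 condition = condition, seed = seed, base_counts = base_counts,
                 meanlog = meanlog, sdlog = sdlog),
            class = "fracprop_scenario")
}

#' Simulate the unobserved ground truth of a fractionated sample
#'
#' Draws transcript abundances from the heavy-tailed base model (or an
#' empirical vector), realizes integer whole-sample counts at the target
#' depth by a multinomial draw, assigns each transcript a Dirichlet
#' allocation over observable fractions plus the lost fraction, and splits
#' every transcript's molecules multinomially.  Conservation holds exactly:
#' fraction counts (including lost) sum to the whole count per transcript.
#'
#' @param config A [scenario_config()].
#' @return An object of class `fracprop_truth`: `transcript_ids`,
#'   `whole_counts`, `fraction_counts` (G x (F+1), last column `Lost`),
#'   `allocations` (realized per-transcript proportions, `NA` where the
#'   whole count is 0), `allocation_probs` (the drawn Dirichlet
#'   probabilities), `global_weights` (realized), and the `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "fracprop_scenario"))
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- config$G
  lam <- config$base_counts
  if (is.null(lam)) {
    lam <- stats::rlnorm(g, config$meanlog, config$sdlog)
  } else if (length(lam) != g) {
    lam <- sample(lam, g, replace = TRUE)
  }
  whole <- as.vector(stats::rmultinom(1L, size = config$total_reads, prob = lam))
  k <- config$n_fractions + 1L
  conc <- config$allocation_concentration
  probs <- if (all(!is.finite(conc))) {
    # degenerate limit: every transcript carries the global mix exactly
    matrix(config$global_weights, nrow = g, ncol = k, byrow = TRUE)
  } else {
    rdirichlet(g, conc * config$global_weights)
  }
  colnames(probs) <- names(config$global_weights)
  frac <- matrix(0, nrow = g, ncol = k,
                 dimnames = list(NULL, names(config$global_weights)))
  pos <- which(whole > 0)
  frac[pos, ] <- t(vapply(pos, function(i)
    as.vector(stats::rmultinom(1L, whole[i], probs[i, ])), numeric(k)))
  alloc <- frac / ifelse(whole > 0, whole, NA_real_)
  ids <- sprintf("tx%05d", seq_len(g))
  rownames(frac) <- ids
  rownames(alloc) <- ids
  structure(list(transcript_ids = ids, whole_counts = whole,
                 fraction_counts = frac, allocations = alloc,
                 allocation_probs = probs,
                 global_weights = colSums(frac) / sum(whole),
                 recovery = config$recovery, config = config),
            class = "fracprop_truth")
}

#' Thin true counts into observed sequencing libraries
#'
#' Every observed library is an independent per-transcript binomial
#' subsample of the corresponding true counts: the Total library thins the
#' whole-sample counts at `recovery["Total"]`, each fraction library thins
#' that fraction's true counts at its recovery rate.  The lost fraction is
#' never emitted.  Replicates are independent thinnings of the same truth.
#'
#' @param truth A [simulate_truth()] result.
#' @param n_replicates,recovery,condition Optional overrides of the values
#'   in `truth$config`.
#' @param seed Seed for the thinning draws; defaults to an offset of the
#'   scenario seed so that simulate/subsample pairs are reproducible while
#'   truth and libraries use distinct streams.
#' @return List with `counts` (matrix, samples named
#'   `condition_repN_type`) and `design` (annotation `data.frame` matching
#'   [read_design()]).
#' @export
subsample_libraries <- function(truth, n_replicates = NULL, recovery = NULL,
                                condition = NULL, seed = NULL) {
  stopifnot(inherits(truth, "fracprop_truth"))
  cfg <- truth$config
  if (is.null(n_replicates)) n_replicates <- cfg$n_replicates
  if (is.null(recovery)) recovery <- cfg$recovery
  if (is.null(condition)) condition <- cfg$condition
  if (!setequal(names(recovery), c("Total", cfg$frac_names)))
    ff_stop("fracprop_invalid_config", "recovery must be named for Total and each fraction")
  recovery <- recovery[c("Total", cfg$frac_names)]
  if (is.null(seed) && !is.null(cfg$seed))
    seed <- as.integer((as.double(cfg$seed) + 500009) %% 2147483647)
  if (!is.null(seed)) set.seed(seed)

  g <- cfg$G
  cols <- list()
  design <- list()
  for (r in seq_len(n_replicates)) {
    rep_name <- paste0("rep", r)
    sm <- paste(condition, rep_name, "Total", sep = "_")
    cols[[sm]] <- stats::rbinom(g, truth$whole_counts, recovery[["Total"]])
    design[[sm]] <- data.frame(Sample = sm, Condition = condition,
                               Replicate = rep_name, Type = "Total",
                               stringsAsFactors = FALSE)
    for (f in cfg$frac_names) {
      sm <- paste(condition, rep_name, f, sep = "_")
      cols[[sm]] <- stats::rbinom(g, truth$fraction_counts[, f], recovery[[f]])
      design[[sm]] <- data.frame(Sample = sm, Condition = condition,
                                 Replicate = rep_name, Type = f,
                                 stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- truth$transcript_ids
  list(counts = counts, design = do.call(rbind, c(design, make.row.names = FALSE)))
}

#' Simulate a full fractionation experiment
#'
#' Convenience wrapper: [simulate_truth()] followed by
#' [subsample_libraries()].
#'
#' @param config A [scenario_config()].
#' @return List with `truth`, `counts`, `design`.
#' @export
simulate_fractionation <- function(config) {
  truth <- simulate_truth(config)
  obs <- subsample_libraries(truth)
  list(truth = truth, counts = obs$counts, design = obs$design)
}

#' Score a fit against its simulation ground truth
#'
#' Compares estimated global fraction weights (including the lost fraction)
#' to the realized true weights, and estimated per-transcript proportions
#' to the realized true allocations, restricted to transcripts whose true
#' whole-sample count is at least `min_true_count` (proportions of
#' near-zero-count transcripts are undefined noise).
#'
#' @param truth A `fracprop_truth`.
#' @param fit A `fracprop` fit computed from libraries generated from this
#'   truth.
#' @param min_true_count Transcript filter on the true whole count
#'   (default 10).
#' @return An object of class `fracprop_recovery`: `weights` (long table of
#'   true/estimated weights per replicate group), `max_weight_error`,
#'   `weight_cor` (Pearson over pooled weight pairs, `NA` with fewer than 3
#'   pairs), and `transcript` (list with `pearson`, `rmse`, `dispersion` =
#'   SD of residuals, `n`).
#' @export
evaluate_recovery <- function(truth, fit, min_true_count = 10) {
  stopifnot(inherits(truth, "fracprop_truth"), inherits(fit, "fracprop"))
  if (!identical(truth$transcript_ids, rownames(fit$counts)))
    ff_stop("fracprop_mismatched_transcripts",
            "transcript sets of truth and fit do not match")
  wnames <- names(truth$global_weights)
  wtab <- do.call(rbind, lapply(names(fit$fits), function(id) {
    est <- fit$fits[[id]]$weights
    if (!setequal(names(est), wnames))
      ff_stop("fracprop_mismatched_transcripts",
              "fraction names of truth and fit do not match")
    data.frame(group = id, fraction = wnames,
               true = unname(truth$global_weights[wnames]),
               estimated = unname(est[wnames]),
               stringsAsFactors = FALSE)
  }))
  keep <- truth$whole_counts >= min_true_count
  res_true <- c(); res_est <- c()
  for (id in names(fit$proportions)) {
    p_hat <- fit$proportions[[id]][keep, wnames, drop = FALSE]
    p_true <- truth$allocations[keep, wnames, drop = FALSE]
    ok <- is.finite(p_hat) & is.finite(p_true)
    res_true <- c(res_true, p_true[ok])
    res_est <- c(res_est, p_hat[ok])
  }
  res <- res_est - res_true
  structure(list(
    weights = wtab,
    max_weight_error = max(abs(wtab$estimated - wtab$true)),
    weight_cor = if (nrow(wtab) >= 3L) stats::cor(wtab$true, wtab$estimated) else NA_real_,
    transcript = list(pearson = stats::cor(res_true, res_est),
                      rmse = sqrt(mean(res^2)),
                      dispersion = stats::sd(res),
                      n = sum(keep)),
    min_true_count = min_true_count), class = "fracprop_recovery")
}

#' @export
print.fracprop_recovery <- function(x, ...) {
  cat("Recovery of simulation ground truth\n")
  cat(sprintf("  weights: max abs error %.4f, Pearson %.4f\n",
              x$max_weight_error, x$weight_cor))
  cat(sprintf("  transcripts (true count >= %d, n = %d): Pearson %.4f, RMSE %.4f, dispersion %.4f\n",
              x$min_true_count, x$transcript$n, x$transcript$pearson,
              x$transcript$rmse, x$transcript$dispersion))
  invisible(x)
}

#' Benchmark weight and proportion recovery over a scenario grid
#'
#' Runs the full simulate-fit-evaluate pipeline over a grid of global
#' weight layouts and recovery layouts at several seeds, and pools the
#' results.  The default grid spans balanced and imbalanced fraction
#' weights, substantial lost fractions, and uneven recovery of the Total or
#' the fraction libraries.
#'
#' @param seed Base integer seed; per-scenario seeds are derived from it.
#' @param G,total_reads Problem size per scenario.
#' @param n_seeds Seeds per grid cell (default 3).
#' @param weight_layouts List of weight vectors (fractions + lost).
#' @param recovery_layouts List of recovery vectors
#'   (Total, fraction 1, fraction 2, ...).
#' @param concentration Dirichlet allocation concentration.
#' @param min_true_count Transcript filter for proportion metrics.
#' @return List with `weight_pearson` (Pearson between true and estimated
#'   weights pooled over all scenario fits and fractions incl. lost),
#'   `scenarios` (per-scenario data.frame with `rmse`, `dispersion`,
#'   `max_weight_error`), and `pairs` (pooled weight pairs).
#' @export
benchmark_recovery <- function(seed = 1, G = 5000, total_reads = 1.8e6,
                               n_seeds = 3,
                               weight_layouts = list(c(0.4, 0.4, 0.2),
                                                     c(0.25, 0.15, 0.6),
                                                     c(0.6, 0.1, 0.3)),
                               recovery_layouts = list(c(1, 1, 1),
                                                       c(0.3, 1, 1),
                                                       c(1, 0.2, 0.2)),
                               concentration = 0.2, min_true_count = 10) {
  pairs <- list(); scen <- list()
  base <- as.double(seed) * 100000
  for (wi in seq_along(weight_layouts)) {
    for (ri in seq_along(recovery_layouts)) {
      for (s in seq_len(n_seeds)) {
        sc_seed <- as.integer((base + wi * 1000 + ri * 100 + s) %% 2147483647)
        nf <- length(weight_layouts[[wi]]) - 1L
        cfg <- scenario_config(
          G = G, total_reads = total_reads, n_fractions = nf,
          global_weights = weight_layouts[[wi]],
          allocation_concentration = concentration,
          recovery = stats::setNames(recovery_layouts[[ri]],
                                     c("Total", paste0("Frac", seq_len(nf)))),
          seed = sc_seed)
        sim <- simulate_fractionation(cfg)
        fit <- fracprop(sim$counts, sim$design)
        ev <- evaluate_recovery(sim$truth, fit, min_true_count = min_true_count)
        pairs[[length(pairs) + 1L]] <- ev$weights
        scen[[length(scen) + 1L]] <- data.frame(
          weight_layout = wi, recovery_layout = ri, seed = sc_seed,
          rmse = ev$transcript$rmse, dispersion = ev$transcript$dispersion,
          max_weight_error = ev$max_weight_error,
          transcript_pearson = ev$transcript$pearson)
      }
    }
  }
  pairs <- do.call(rbind, pairs)
  list(weight_pearson = stats::cor(pairs$true, pairs$estimated),
       scenarios = do.call(rbind, scen), pairs = pairs)
}
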