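# Writers for fits, test results and simulation truths, plus the JSON run
# manifest shared by the command-line entry points.

write_manifest <- function(dir, command, params = list(), inputs = character(),
                           seed = NULL, warnings_count = 0L) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command,
                   version = as.character(utils::packageVersion("fracprop")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, params = params, inputs = digests,
                   warnings_count = warnings_count)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    ff_stop("fracprop_missing_file", sprintf("no manifest.json in %s", dir))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a fitted model to a directory
#'
#' Writes `weights.tsv` (condition, replicate, fraction, weight),
#' `alpha.tsv` (normalization coefficients and regression diagnostics) and
#' `proportions.tsv` (corrected per-transcript proportions, one column per
#' condition.replicate.fraction including Lost).
#'
#' @param object A `fracprop` fit.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fracprop <- function(object, dir) {
  stopifnot(inherits(object, "fracprop"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtab <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(condition = f$condition, replicate = f$replicate,
               fraction = names(f$weights), weight = unname(f$weights),
               stringsAsFactors = FALSE)))
  atab <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(condition = f$condition, replicate = f$replicate,
               fraction = names(f$alpha), alpha = unname(f$alpha),
               r_squared = f$r_squared, n_selected = f$n_selected,
               stringsAsFactors = FALSE)))
  paths <- file.path(dir, c("weights.tsv", "alpha.tsv", "proportions.tsv"))
  utils::write.table(wtab, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(atab, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(transcript_proportions(object), paths[3L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write differential test results to a directory
#'
#' Writes `results.tsv` (one row per transcript) and `volcano.tsv`
#' (delta and -log10 adjusted p for tested transcripts, for external
#' plotting).
#'
#' @param results A `fracprop_diff` table.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_diff_results <- function(results, dir) {
  stopifnot(inherits(results, "fracprop_diff"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("results.tsv", "volcano.tsv"))
  utils::write.table(as.data.frame(results), paths[1L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ok <- results$tested & !is.na(results$p_adjusted)
  volcano <- data.frame(transcript_id = results$transcript_id[ok],
                        delta = results$delta[ok],
                        neg_log10_p_adjusted = -log10(results$p_adjusted[ok]))
  utils::write.table(volcano, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a simulation truth as JSON
#'
#' @param truth A `fracprop_truth`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "fracprop_truth"))
  cfg <- truth$config
  payload <- list(
    transcript_ids = truth$transcript_ids,
    whole_counts = truth$whole_counts,
    fraction_counts = apply(truth$fraction_counts, 2L, identity, simplify = FALSE),
    global_weights = as.list(truth$global_weights),
    recovery = as.list(truth$recovery),
    config = list(G = cfg$G, total_reads = cfg$total_reads,
                  n_fractions = cfg$n_fractions,
                  global_weights = as.list(cfg$global_weights),
                  allocation_concentration = cfg$allocation_concentration,
                  recovery = as.list(cfg$recovery),
                  n_replicates = cfg$n_replicates,
                  condition = cfg$condition, seed = cfg$seed))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation truth written by [write_truth()]
#'
#' @param path Path to a truth JSON file.
#' @return A `fracprop_truth` object.
#' @export
read_truth <- function(path) {
  if (!file.exists(path))
    ff_stop("fracprop_missing_file", sprintf("truth file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- x$config
  cfg <- scenario_config(G = cfgl$G, total_reads = cfgl$total_reads,
                         n_fractions = cfgl$n_fractions,
                         global_weights = unlist(cfgl$global_weights),
                         allocation_concentration = cfgl$allocation_concentration,
                         recovery = unlist(cfgl$recovery),
                         n_replicates = cfgl$n_replicates,
                         condition = cfgl$condition, seed = cfgl$seed)
  frac <- do.call(cbind, x$fraction_counts)
  rownames(frac) <- x$transcript_ids
  whole <- as.numeric(x$whole_counts)
  alloc <- frac / ifelse(whole > 0, whole, NA_real_)
  structure(list(transcript_ids = x$transcript_ids, whole_counts = whole,
                 fraction_counts = frac, allocations = alloc,
                 allocation_probs = NULL,
                 global_weights = unlist(x$global_weights),
                 recovery = unlist(x$recovery), config = cfg),
            class = "fracprop_truth")
}
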