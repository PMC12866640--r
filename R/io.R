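#' Read a transcript-by-sample count matrix
#'
#' Reads a tab-separated table whose first column holds transcript (or gene)
#' identifiers and whose remaining columns hold raw, non-negative integer
#' counts, one column per sequenced library.  The header row names the
#' samples.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix of counts with transcript row names and sample
#'   column names.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\tS1\tS2\tS3", "tx1\t5\t3\t2", "tx2\t0\t1\t4"), tsv)
#' m <- read_count_matrix(tsv)
#' colSums(m)
#' @seealso [read_design()], [fracprop()]
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path))
    ff_stop("fracprop_missing_file", sprintf("count file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    ff_stop("fracprop_invalid_count", "count file needs an id column and >= 2 sample columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    ff_stop("fracprop_duplicate_id", "duplicate transcript id in count file")
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    ff_stop("fracprop_duplicate_id", "duplicate sample id in count file header")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m))
    ff_stop("fracprop_invalid_count", "non-numeric count in count file")
  rownames(m) <- ids
  validate_counts(m)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]: writes a tab-separated table with a
#' leading `transcript_id` column.
#'
#' @param counts Matrix with transcript row names and sample column names.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Reads a CSV with header `Sample,Condition,Replicate,Type` describing each
#' sequenced library.  `Type` is the fraction type; the reserved value
#' `"Total"` (case-sensitive) marks the un-fractionated whole library, of
#' which each (condition, replicate) must have exactly one.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with character columns Sample, Condition,
#'   Replicate, Type.
#' @seealso [validate_design()]
#' @export
read_design <- function(path) {
  if (!file.exists(path))
    ff_stop("fracprop_missing_file", sprintf("annotation file not found: %s", path))
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("Sample", "Condition", "Replicate", "Type")
  miss <- setdiff(needed, colnames(tab))
  if (length(miss))
    ff_stop("fracprop_missing_column",
            sprintf("annotation is missing column(s): %s", paste(miss, collapse = ", ")))
  design <- tab[, needed]
  check_design_frame(design)
  design
}

# Structural checks shared by read_design() and validate_design().
check_design_frame <- function(design) {
  for (col in c("Sample", "Condition", "Replicate", "Type")) {
    v <- design[[col]]
    if (anyNA(v) || any(!nzchar(v)))
      ff_stop("fracprop_invalid_design", sprintf("empty value in annotation column %s", col))
  }
  if (anyDuplicated(design$Sample))
    ff_stop("fracprop_duplicate_id", "duplicate sample id in annotation")
  if (any(design$Type == "Lost"))
    ff_stop("fracprop_invalid_design",
            "fraction type \"Lost\" is reserved for the estimated lost fraction")
  key <- paste(design$Condition, design$Replicate, sep = "\r")
  for (g in unique(key)) {
    rows <- design[key == g, ]
    n_tot <- sum(rows$Type == "Total")
    lab <- sprintf("(%s, %s)", rows$Condition[1L], rows$Replicate[1L])
    if (n_tot == 0L)
      ff_stop("fracprop_no_total", sprintf("no Total sample for %s", lab))
    if (n_tot > 1L)
      ff_stop("fracprop_multiple_total", sprintf("multiple Total samples for %s", lab))
    if (nrow(rows) < 2L)
      ff_stop("fracprop_invalid_design", sprintf("no fraction sample for %s", lab))
  }
  invisible(design)
}

#' Pair Total and fraction libraries per (condition, replicate)
#'
#' Cross-checks a count matrix against an annotation table and assembles one
#' replicate group per (condition, replicate): the Total sample plus its
#' fraction samples, the latter ordered lexicographically by fraction type so
#' that downstream coefficient vectors are deterministic.  Samples present in
#' the count matrix but absent from the annotation are dropped with a
#' warning; samples annotated but missing from the counts are an error.  The
#' set of fraction types must be identical across replicates of a condition.
#'
#' @param counts Count matrix (see [read_count_matrix()]).
#' @param design Annotation `data.frame` (see [read_design()]).
#' @return An object of class `fracprop_design`: a list with elements
#'   `groups` (list of per-replicate groups), `samples` (annotated sample
#'   ids, in count-matrix order) and `conditions`.
#' @export
validate_design <- function(counts, design) {
  counts <- validate_counts(counts)
  check_design_frame(design)
  unknown <- setdiff(design$Sample, colnames(counts))
  if (length(unknown))
    ff_stop("fracprop_unknown_sample",
            sprintf("unknown sample in design (absent from counts): %s",
                    paste(unknown, collapse = ", ")))
  extra <- setdiff(colnames(counts), design$Sample)
  if (length(extra))
    ff_warn("fracprop_ignored_samples",
            sprintf("%d sample(s) in counts not annotated and excluded: %s",
                    length(extra), paste(extra, collapse = ", ")))

  key <- paste(design$Condition, design$Replicate, sep = "\r")
  groups <- lapply(unique(key), function(g) {
    rows <- design[key == g, ]
    fr <- rows[rows$Type != "Total", ]
    fr <- fr[order(fr$Type), ]
    fraction_samples <- stats::setNames(fr$Sample, fr$Type)
    list(condition = rows$Condition[1L],
         replicate = rows$Replicate[1L],
         total_sample = rows$Sample[rows$Type == "Total"],
         fraction_samples = fraction_samples)
  })
  names(groups) <- vapply(groups, function(g)
    paste(g$condition, g$replicate, sep = "."), character(1L))

  # fraction-type sets must agree across replicates within each condition
  conds <- unique(vapply(groups, `[[`, character(1L), "condition"))
  for (cn in conds) {
    sets <- lapply(groups[vapply(groups, `[[`, character(1L), "condition") == cn],
                   function(g) names(g$fraction_samples))
    if (length(unique(vapply(sets, paste, character(1L), collapse = "\r"))) > 1L)
      ff_stop("fracprop_inconsistent_fractions",
              sprintf("fraction sets differ across replicates of condition %s", cn))
  }

  structure(list(groups = groups,
                 samples = intersect(colnames(counts), design$Sample),
                 conditions = conds),
            class = "fracprop_design")
}

#' @export
print.fracprop_design <- function(x, ...) {
  cat(sprintf("Validated fractionation design: %d replicate group(s), %d sample(s)\n",
              length(x$groups), length(x$samples)))
  for (g in x$groups)
    cat(sprintf("  %s / %s: Total=%s, fractions: %s\n", g$condition, g$replicate,
                g$total_sample,
                paste(sprintf("%s=%s", names(g$fraction_samples), g$fraction_samples),
                      collapse = ", ")))
  invisible(x)
}
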