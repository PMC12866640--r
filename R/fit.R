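#' Select transcripts for the normalization regression
#'
#' The regression that estimates the per-fraction normalization coefficients
#' is restricted to transcripts that are informative and not dominating:
#' total-library count at least `min_total`, at least one read across the
#' fraction libraries, and (as a leverage guard) total count not above the
#' `max_total_quantile` quantile of the totals that survive the first two
#' rules.  Setting `max_total_quantile = 1` disables the guard.
#'
#' @param total Integer vector of total-library counts, length G.
#' @param fractions G x F matrix of fraction-library counts.
#' @param min_total Minimum total-library count (default 10).
#' @param max_total_quantile Upper quantile of selected totals above which
#'   transcripts are dropped (default 0.995).
#' @return Integer vector of selected row indices.
#' @export
select_regression_transcripts <- function(total, fractions, min_total = 10,
                                          max_total_quantile = 0.995) {
  fractions <- as.matrix(fractions)
  stopifnot(length(total) == nrow(fractions))
  nf <- ncol(fractions)
  keep <- which(total >= min_total & rowSums(fractions) >= 1)
  if (length(keep)) {
    thr <- stats::quantile(total[keep], max_total_quantile, names = FALSE)
    keep <- keep[total[keep] <= thr]
  }
  if (length(keep) < 10L * nf)
    ff_stop("fracprop_insufficient_transcripts",
            sprintf("insufficient transcripts for regression (%d selected, need >= %d)",
                    length(keep), 10L * nf))
  keep
}

#' Non-negative least squares fit of total counts on fraction counts
#'
#' Solves `min || total - fractions %*% alpha ||^2` subject to `alpha >= 0`
#' (Lawson-Hanson active set, no intercept).  The coefficient for fraction f
#' estimates the depth ratio s_total / s_f between the whole library and
#' that fraction library.
#'
#' @param total Response vector (total-library counts on the selected set).
#' @param fractions Predictor matrix (selected transcripts x fractions).
#' @return List with `alpha` (named non-negative coefficients), `r_squared`
#'   (1 - SSE/SST about the response mean, clipped to \[0, 1\]), `sse`, and
#'   `fitted`.
#' @export
fit_nnls <- function(total, fractions) {
  fractions <- as.matrix(fractions)
  stopifnot(length(total) == nrow(fractions), nrow(fractions) >= 1L)
  storage.mode(fractions) <- "double"
  total <- as.double(total)
  nf <- ncol(fractions)
  fnames <- colnames(fractions)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(nf))

  zero_col <- colSums(abs(fractions)) == 0
  alpha <- stats::setNames(numeric(nf), fnames)
  if (any(zero_col))
    ff_warn("fracprop_zero_fraction",
            sprintf("all-zero fraction column(s) %s: coefficient set to 0",
                    paste(fnames[zero_col], collapse = ", ")))
  if (!all(zero_col)) {
    sol <- pracma::lsqnonneg(fractions[, !zero_col, drop = FALSE], total)
    alpha[!zero_col] <- sol$x
  }
  fitted <- drop(fractions %*% alpha)
  sse <- sum((total - fitted)^2)
  sst <- sum((total - mean(total))^2)
  r2 <- if (sst > 0) 1 - sse / sst else as.numeric(sse == 0)
  list(alpha = alpha, r_squared = min(max(r2, 0), 1), sse = sse, fitted = fitted)
}

#' Global fraction weights, including the lost fraction
#'
#' Converts NNLS coefficients into the share of the whole sample's RNA that
#' each fraction represents: `weight_f = alpha_f * sum(Y^f) / sum(Y)`, with
#' library sums taken over all transcripts.  The lost fraction is the
#' complement `1 - sum(weight_f)`.  If the observable weights already exceed
#' 1 (NNLS does not enforce the compositional bound), the lost weight is
#' clamped to 0 and the observable weights renormalized, with a warning.
#'
#' @param alpha Named non-negative coefficient vector from [fit_nnls()].
#' @param total_sum Total-library count sum over all transcripts.
#' @param fraction_sums Named vector of per-fraction library count sums.
#' @return Named weight vector over the fractions plus `"Lost"`, summing
#'   to 1.
#' @export
estimate_global_weights <- function(alpha, total_sum, fraction_sums) {
  if (total_sum <= 0)
    ff_stop("fracprop_zero_total", "total library sum is zero")
  if (any(alpha < 0))
    ff_stop("fracprop_invalid_alpha", "alpha must be non-negative")
  w <- alpha * fraction_sums / total_sum
  names(w) <- names(alpha)
  lost <- 1 - sum(w)
  if (lost < -1e-9) {
    ff_warn("fracprop_lost_clamped",
            sprintf("observable fraction weights sum to %.4f > 1; lost fraction clamped to 0",
                    sum(w)))
    w <- w / sum(w)
  }
  c(w, Lost = max(lost, 0))
}

#' Depth-corrected per-transcript fraction proportions
#'
#' For each transcript i, the proportion of its molecules residing in
#' fraction f is estimated as
#' `p_i^f = alpha_f * Y_i^f / max(Y_i, sum_f alpha_f * Y_i^f)`;
#' the max in the denominator keeps all proportions in \[0, 1\] when the
#' rescaled fraction counts exceed the observed total.  The lost proportion
#' is the complement `1 - sum_f p_i^f`.  Transcripts with zero counts in the
#' total and in every fraction are undefined and returned as `NA`.
#'
#' @param alpha Named coefficient vector from [fit_nnls()].
#' @param total Total-library counts, length G (all transcripts).
#' @param fractions G x F matrix of fraction-library counts.
#' @return List with `proportions` (G x (F+1) matrix, last column `"Lost"`)
#'   and `corrected` (G x F matrix of corrected counts `alpha_f * Y_i^f`).
#' @export
correct_transcript_proportions <- function(alpha, total, fractions) {
  fractions <- as.matrix(fractions)
  stopifnot(length(total) == nrow(fractions), length(alpha) == ncol(fractions))
  corrected <- sweep(fractions, 2L, alpha, `*`)
  den <- pmax(total, rowSums(corrected))
  undefined <- total == 0 & rowSums(fractions) == 0
  p <- corrected / ifelse(den > 0, den, NA_real_)
  p[undefined, ] <- NA_real_
  # a transcript absent from the total but seen in fractions: the max picks
  # the corrected-count denominator, proportions sum to 1 and lost is 0
  lost <- 1 - rowSums(p)
  lost[lost < 0] <- 0  # guard against floating-point dust
  prop <- cbind(p, Lost = lost)
  colnames(prop) <- c(colnames(fractions), "Lost")
  rownames(prop) <- rownames(fractions)
  list(proportions = prop, corrected = corrected)
}

#' Fit the compositional fraction model
#'
#' The main entry point.  For every (condition, replicate) group the model
#' explains the un-fractionated Total library by its fraction libraries
#' through a non-negative least squares regression on a selected transcript
#' set, then derives global fraction weights (including the unobserved lost
#' fraction) and depth-corrected per-transcript proportions for all
#' transcripts.
#'
#' Each replicate group is fitted independently: depth factors are
#' library-specific, so coefficients cannot be shared across replicates.
#'
#' @param counts Count matrix (transcripts x samples) or path handled by
#'   [read_count_matrix()] upstream.
#' @param design Annotation `data.frame` (Sample, Condition, Replicate,
#'   Type) or a pre-validated `fracprop_design`.
#' @param min_total,max_total_quantile Transcript selection thresholds, see
#'   [select_regression_transcripts()].
#' @return An object of class `fracprop` with components `counts` (annotated
#'   samples only), `design`, `fits` (per-group list: `alpha`, `weights`,
#'   `r_squared`, `selected`, `n_selected`), `proportions` and `corrected`
#'   (per-group matrices), and `control`.
#' @examples
#' sim <- simulate_fractionation(scenario_config(G = 300, total_reads = 5e4, seed = 1))
#' fit <- fracprop(sim$counts, sim$design)
#' fit
#' weights(fit)
#' @seealso [diff_prop_test()], [simulate_fractionation()]
#' @export
fracprop <- function(counts, design, min_total = 10, max_total_quantile = 0.995) {
  counts <- validate_counts(counts)
  vd <- if (inherits(design, "fracprop_design")) design else validate_design(counts, design)
  counts <- counts[, vd$samples, drop = FALSE]

  fits <- list()
  proportions <- list()
  corrected <- list()
  for (id in names(vd$groups)) {
    g <- vd$groups[[id]]
    total <- counts[, g$total_sample]
    x <- counts[, g$fraction_samples, drop = FALSE]
    colnames(x) <- names(g$fraction_samples)
    res <- tryCatch({
      sel <- select_regression_transcripts(total, x, min_total, max_total_quantile)
      nn <- fit_nnls(total[sel], x[sel, , drop = FALSE])
      w <- estimate_global_weights(nn$alpha, sum(total), colSums(x))
      pr <- correct_transcript_proportions(nn$alpha, total, x)
      list(fit = list(condition = g$condition, replicate = g$replicate,
                      alpha = nn$alpha, weights = w, r_squared = nn$r_squared,
                      selected = sel, n_selected = length(sel)),
           prop = pr)
    }, fracprop_error = function(e) {
      ff_stop(class(e)[1L], sprintf("group %s: %s", id, conditionMessage(e)))
    })
    fits[[id]] <- res$fit
    proportions[[id]] <- res$prop$proportions
    corrected[[id]] <- res$prop$corrected
  }

  structure(list(counts = counts, design = vd, fits = fits,
                 proportions = proportions, corrected = corrected,
                 control = list(min_total = min_total,
                                max_total_quantile = max_total_quantile),
                 version = as.character(utils::packageVersion("fracprop")),
                 call = match.call()),
            class = "fracprop")
}

#' @export
print.fracprop <- function(x, ...) {
  cat(sprintf("Compositional fraction model: %d transcripts, %d samples, %d replicate group(s)\n",
              nrow(x$counts), ncol(x$counts), length(x$fits)))
  cat("Global fraction weights (share of whole-sample RNA):\n")
  print(round(weights(x), 4))
  invisible(x)
}

#' @export
summary.fracprop <- function(object, ...) {
  w <- weights(object)
  a <- coef(object)
  conds <- vapply(object$fits, `[[`, character(1L), "condition")
  mean_w <- do.call(rbind, lapply(unique(conds), function(cn)
    colMeans(w[conds == cn, , drop = FALSE])))
  rownames(mean_w) <- unique(conds)
  structure(list(weights = w, mean_weights = mean_w, alpha = a,
                 r_squared = vapply(object$fits, `[[`, numeric(1L), "r_squared"),
                 n_selected = vapply(object$fits, `[[`, numeric(1L), "n_selected"),
                 control = object$control),
            class = "summary.fracprop")
}

#' @export
print.summary.fracprop <- function(x, ...) {
  cat("Per-replicate global fraction weights:\n")
  print(round(x$weights, 4))
  cat("\nMean weights per condition:\n")
  print(round(x$mean_weights, 4))
  cat("\nNormalization coefficients (alpha = s_total / s_fraction):\n")
  print(round(x$alpha, 4))
  cat("\nRegression diagnostics:\n")
  print(data.frame(r_squared = round(x$r_squared, 4), n_selected = x$n_selected))
  invisible(x)
}

#' @export
coef.fracprop <- function(object, ...) {
  do.call(rbind, lapply(object$fits, `[[`, "alpha"))
}

#' @importFrom stats weights
#' @export
weights.fracprop <- function(object, ...) {
  do.call(rbind, lapply(object$fits, `[[`, "weights"))
}

#' @export
residuals.fracprop <- function(object, ...) {
  lapply(object$fits, function(f) {
    g <- object$design$groups[[paste(f$condition, f$replicate, sep = ".")]]
    sel <- f$selected
    total <- object$counts[sel, g$total_sample]
    x <- object$counts[sel, g$fraction_samples, drop = FALSE]
    total - drop(x %*% f$alpha)
  })
}

#' @export
plot.fracprop <- function(x, ...) {
  w <- t(weights(x))
  graphics::barplot(w, legend.text = rownames(w),
                    ylab = "global fraction weight", las = 2,
                    args.legend = list(x = "topright", bg = "white"), ...)
  invisible(x)
}

#' Corrected per-transcript proportions as a wide table
#'
#' @param object A `fracprop` fit.
#' @return A `data.frame` with a `transcript_id` column and one column per
#'   `condition.replicate.fraction` (including the `Lost` column per group).
#' @export
transcript_proportions <- function(object) {
  stopifnot(inherits(object, "fracprop"))
  cols <- do.call(cbind, lapply(names(object$proportions), function(id) {
    m <- object$proportions[[id]]
    colnames(m) <- paste(id, colnames(m), sep = ".")
    m
  }))
  data.frame(transcript_id = rownames(object$counts), cols,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Fraction-corrected counts as a wide table
#'
#' Corrected counts are `alpha_f * Y_i^f`: fraction counts rescaled to the
#' whole-library depth.
#'
#' @param object A `fracprop` fit.
#' @return A `data.frame` with a `transcript_id` column and one column per
#'   `condition.replicate.fraction`.
#' @export
corrected_counts <- function(object) {
  stopifnot(inherits(object, "fracprop"))
  cols <- do.call(cbind, lapply(names(object$corrected), function(id) {
    m <- object$corrected[[id]]
    colnames(m) <- paste(id, colnames(m), sep = ".")
    m
  }))
  data.frame(transcript_id = rownames(object$counts), cols,
             check.names = FALSE, stringsAsFactors = FALSE)
}
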