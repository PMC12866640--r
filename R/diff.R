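#' Assemble the per-replicate success/trial table for differential testing
#'
#' For each transcript and each replicate of the two conditions, the trials
#' are the Total-library count `n = Y_ij` and the successes are the
#' depth-corrected counts summed over the chosen fraction set,
#' `k = round(sum_{f in types} alpha_f * Y_ij^f)`, rounded half-up and
#' clamped to `[0, n]`.  Each replicate uses its own fitted `alpha`.
#'
#' @param object A `fracprop` fit.
#' @param conditions Character vector of two condition names.
#' @param types Fraction type(s) whose corrected counts are summed.
#' @return A `data.frame` with columns `transcript_id`, `condition`,
#'   `replicate`, `k`, `n`, one row per (transcript, replicate sample);
#'   attribute `n_clamped` counts successes clamped down to `n`.
#' @export
build_test_table <- function(object, conditions, types) {
  stopifnot(inherits(object, "fracprop"))
  if (length(conditions) != 2L)
    ff_stop("fracprop_unknown_condition", "exactly two conditions are required")
  known <- object$design$conditions
  if (!all(conditions %in% known))
    ff_stop("fracprop_unknown_condition",
            sprintf("unknown condition: %s",
                    paste(setdiff(conditions, known), collapse = ", ")))
  groups <- object$design$groups
  in_test <- vapply(groups, function(g) g$condition %in% conditions, logical(1L))
  for (g in groups[in_test]) {
    miss <- setdiff(types, names(g$fraction_samples))
    if (length(miss))
      ff_stop("fracprop_unknown_type",
              sprintf("fraction type(s) %s not sequenced in condition %s",
                      paste(miss, collapse = ", "), g$condition))
  }

  n_clamped <- 0L
  rows <- lapply(names(groups)[in_test], function(id) {
    g <- groups[[id]]
    alpha <- object$fits[[id]]$alpha[types]
    n <- object$counts[, g$total_sample]
    yf <- object$counts[, g$fraction_samples[types], drop = FALSE]
    k <- round_half_up(drop(yf %*% alpha))
    over <- k > n
    n_clamped <<- n_clamped + sum(over)
    k[over] <- n[over]
    data.frame(transcript_id = rownames(object$counts),
               condition = g$condition, replicate = g$replicate,
               k = k, n = as.numeric(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_clamped > 0L)
    ff_warn("fracprop_clamped_successes",
            sprintf("%d corrected success count(s) exceeded trials and were clamped", n_clamped))
  attr(out, "conditions") <- conditions
  attr(out, "types") <- types
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Binomial GLM likelihood-ratio test for one transcript
#'
#' Fits a logit-link binomial GLM of successes/trials on the condition
#' factor and compares it to the intercept-only model by likelihood-ratio
#' (chi-squared, 1 df).  When the fit is degenerate (all-zero or all-n
#' successes, non-convergence, or quasi-separation with runaway log-odds)
#' the empirical-logit test is used instead and flagged.
#'
#' @param k,n Successes and trials per replicate sample.
#' @param condition Condition label per replicate sample (two levels).
#' @return List with `statistic`, `p_value`, `fallback` (logical).
#' @export
glm_test <- function(k, n, condition) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; condition <- condition[keep]
  cond <- factor(condition, levels = unique(condition))
  if (nlevels(cond) != 2L)
    ff_stop("fracprop_unknown_condition", "need observations with n > 0 in both conditions")
  if (all(k == 0) || all(k == n))
    return(c(logit_test(k, n, condition), list(fallback = TRUE)))
  fit <- suppressWarnings(stats::glm(cbind(k, n - k) ~ cond,
                                     family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)[-1L]) > 15))
    return(c(logit_test(k, n, condition), list(fallback = TRUE)))
  stat <- max(fit$null.deviance - fit$deviance, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       fallback = FALSE)
}

#' Empirical-logit test for one transcript
#'
#' Computes the continuity-corrected empirical logit
#' `L = log((k + 0.5) / (n - k + 0.5))` with variance
#' `1/(k + 0.5) + 1/(n - k + 0.5)` per replicate, takes the
#' inverse-variance weighted mean per condition, and compares the two means
#' by a two-sided z test.  Finite at boundary counts thanks to the 0.5
#' correction.
#'
#' @inheritParams glm_test
#' @return List with `statistic` (z) and `p_value`.
#' @export
logit_test <- function(k, n, condition) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; condition <- condition[keep]
  cond <- factor(condition, levels = unique(condition))
  if (nlevels(cond) != 2L)
    ff_stop("fracprop_unknown_condition", "need observations with n > 0 in both conditions")
  l <- log((k + 0.5) / (n - k + 0.5))
  v <- 1 / (k + 0.5) + 1 / (n - k + 0.5)
  w <- 1 / v
  m <- vapply(levels(cond), function(cc) {
    i <- cond == cc
    sum(w[i] * l[i]) / sum(w[i])
  }, numeric(1L))
  vv <- vapply(levels(cond), function(cc) 1 / sum(w[cond == cc]), numeric(1L))
  z <- unname((m[1L] - m[2L]) / sqrt(vv[1L] + vv[2L]))
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# Negative log-likelihood of the beta-binomial with condition means p1, p2
# and shared overdispersion rho, on the (logit p1, logit p2, logit rho)
# scale.  rho -> 0 recovers the binomial.
betabin_nll <- function(theta, k, n, cond_idx) {
  p <- stats::plogis(theta[1:2])[cond_idx]
  rho <- stats::plogis(theta[3L])
  if (rho < 1e-8) {
    ll <- stats::dbinom(k, n, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE)
  } else {
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    ll <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  }
  -sum(ll)
}

#' Beta-binomial Wald test for one transcript
#'
#' Models replicate counts as beta-binomial with a per-condition mean
#' proportion and a shared overdispersion rho, estimated jointly by bounded
#' maximum likelihood.  The Wald statistic
#' `(p1 - p2) / sqrt(Var(p1) + Var(p2))` uses variances from the observed
#' information at the optimum; the p-value is two-sided normal.  With a
#' single replicate per condition the model degenerates to a binomial
#' (rho = 0) two-proportion Wald test on pooled counts.
#'
#' @inheritParams glm_test
#' @return List with `statistic`, `p_value`, `flagged` (TRUE when the
#'   optimizer or information matrix failed and a pooled binomial Wald was
#'   used, or no p-value could be produced).
#' @export
betabin_test <- function(k, n, condition) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; condition <- condition[keep]
  cond <- factor(condition, levels = unique(condition))
  if (nlevels(cond) != 2L)
    ff_stop("fracprop_unknown_condition", "need observations with n > 0 in both conditions")
  cond_idx <- as.integer(cond)

  pooled_wald <- function() {
    ks <- tapply(k, cond, sum); ns <- tapply(n, cond, sum)
    p <- ks / ns
    v <- p * (1 - p) / ns
    den <- sqrt(sum(v))
    z <- unname(if (den > 0) (p[1L] - p[2L]) / den else if (p[1L] == p[2L]) 0 else Inf)
    list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
  }

  if (max(table(cond)) < 2L)  # no replication: overdispersion not estimable
    return(c(pooled_wald(), list(flagged = FALSE)))

  p0 <- pmin(pmax(as.vector(tapply(k, cond, sum) + 0.5) /
                    as.vector(tapply(n, cond, sum) + 1), 1e-6), 1 - 1e-6)
  init <- c(stats::qlogis(p0), stats::qlogis(0.05))
  opt <- try(stats::optim(init, betabin_nll, k = k, n = n, cond_idx = cond_idx,
                          method = "L-BFGS-B",
                          lower = c(-12, -12, stats::qlogis(1e-6)),
                          upper = c(12, 12, stats::qlogis(0.9)),
                          hessian = TRUE), silent = TRUE)
  if (inherits(opt, "try-error"))
    return(c(pooled_wald(), list(flagged = TRUE)))
  p_hat <- stats::plogis(opt$par[1:2])
  vth <- tryCatch(diag(solve(opt$hessian))[1:2], error = function(e) rep(NA_real_, 2L))
  if (anyNA(vth) || any(vth < 0))
    vth <- tryCatch(diag(solve(opt$hessian[1:2, 1:2])),
                    error = function(e) rep(NA_real_, 2L))
  if (anyNA(vth) || any(vth < 0))
    return(c(pooled_wald(), list(flagged = TRUE)))
  v_p <- (p_hat * (1 - p_hat))^2 * vth  # delta method from the logit scale
  den <- sqrt(sum(v_p))
  z <- unname(if (den > 0) (p_hat[1L] - p_hat[2L]) / den
              else if (abs(p_hat[1L] - p_hat[2L]) < 1e-12) 0 else Inf)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)), flagged = FALSE)
}

#' Benjamini-Hochberg adjustment over non-missing p-values
#'
#' Step-up false discovery rate control applied to the non-missing entries
#' only (m = number of non-missing p-values); missing entries stay missing.
#'
#' @param p_values Numeric vector in \[0, 1\], `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    ff_stop("fracprop_invalid_pvalue", "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Differential proportion test between two conditions
#'
#' Tests, per transcript, whether the share of molecules residing in the
#' chosen fraction set differs between two conditions.  Successes/trials
#' per replicate come from [build_test_table()]; per-transcript tests are
#' independent of each other and of row order, so results do not depend on
#' execution order.  Transcripts are testable when the summed trials reach
#' `min_count` in both conditions; p-values of testable transcripts are BH
#' adjusted.
#'
#' @param object A `fracprop` fit.
#' @param conditions Character vector of two condition names; the reported
#'   `delta` is `prop2 - prop1` in this order.
#' @param types Fraction type(s) to test (corrected counts are summed over
#'   them).
#' @param method `"GLM"` (binomial likelihood-ratio), `"Logit"`
#'   (empirical-logit z) or `"BetaBin"` (beta-binomial Wald).  Matching is
#'   case-insensitive.
#' @param min_count Minimum summed trials per condition for a transcript to
#'   be testable (default 10).
#' @return A `data.frame` of class `fracprop_diff` with columns
#'   `transcript_id`, `prop1`, `prop2`, `delta`, `statistic`, `p_value`,
#'   `p_adjusted`, `method`, `tested`; attributes record conditions, types,
#'   and per-transcript failure/fallback counts.
#' @examples
#' cfg1 <- scenario_config(G = 200, total_reads = 4e4, n_replicates = 2,
#'                         condition = "A", seed = 11)
#' cfg2 <- scenario_config(G = 200, total_reads = 4e4, n_replicates = 2,
#'                         condition = "B", seed = 12)
#' s1 <- simulate_fractionation(cfg1); s2 <- simulate_fractionation(cfg2)
#' fit <- fracprop(cbind(s1$counts, s2$counts), rbind(s1$design, s2$design))
#' res <- diff_prop_test(fit, c("A", "B"), types = "Frac1", method = "GLM")
#' head(res)
#' @export
diff_prop_test <- function(object, conditions, types,
                           method = c("GLM", "Logit", "BetaBin"),
                           min_count = 10) {
  stopifnot(inherits(object, "fracprop"))
  if (identical(method, c("GLM", "Logit", "BetaBin"))) method <- "GLM"
  if (length(method) != 1L || !tolower(method) %in% c("glm", "logit", "betabin"))
    ff_stop("fracprop_unknown_method",
            sprintf("unknown method: %s (use GLM, Logit or BetaBin)",
                    paste(method, collapse = ", ")))
  method <- c(glm = "GLM", logit = "Logit", betabin = "BetaBin")[tolower(method)]

  tt <- build_test_table(object, conditions, types)
  g <- nrow(object$counts)
  ids <- rownames(object$counts)
  ns <- nrow(tt) / g  # replicate samples, table is stacked per group
  km <- matrix(tt$k, nrow = g)
  nm <- matrix(tt$n, nrow = g)
  cond_of_col <- tt$condition[seq(1L, nrow(tt), by = g)]

  i1 <- cond_of_col == conditions[1L]
  i2 <- cond_of_col == conditions[2L]
  n1 <- rowSums(nm[, i1, drop = FALSE]); k1 <- rowSums(km[, i1, drop = FALSE])
  n2 <- rowSums(nm[, i2, drop = FALSE]); k2 <- rowSums(km[, i2, drop = FALSE])
  prop1 <- ifelse(n1 > 0, k1 / n1, NA_real_)
  prop2 <- ifelse(n2 > 0, k2 / n2, NA_real_)
  testable <- n1 >= min_count & n2 >= min_count

  test_fun <- switch(method, GLM = glm_test, Logit = logit_test, BetaBin = betabin_test)
  statistic <- rep(NA_real_, g)
  p_value <- rep(NA_real_, g)
  n_fallback <- 0L
  n_failed <- 0L
  for (i in which(testable)) {
    res <- tryCatch(test_fun(km[i, ], nm[i, ], cond_of_col),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$p_value)) {
      n_failed <- n_failed + 1L
      next
    }
    statistic[i] <- res$statistic
    p_value[i] <- res$p_value
    if (isTRUE(res$fallback) || isTRUE(res$flagged)) n_fallback <- n_fallback + 1L
  }

  out <- data.frame(transcript_id = ids, prop1 = unname(prop1),
                    prop2 = unname(prop2), delta = unname(prop2 - prop1),
                    statistic = statistic, p_value = p_value,
                    p_adjusted = bh_adjust(p_value), method = method,
                    tested = unname(testable) & !is.na(p_value),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, conditions = conditions, types = types,
            n_tested = sum(out$tested), n_fallback = n_fallback,
            n_failed = n_failed, n_clamped = attr(tt, "n_clamped"),
            class = c("fracprop_diff", "data.frame"))
}

#' @export
print.fracprop_diff <- function(x, ...) {
  conds <- attr(x, "conditions")
  cat(sprintf("Differential proportion test (%s): %s vs %s on fraction(s) %s\n",
              x$method[1L], conds[1L], conds[2L],
              paste(attr(x, "types"), collapse = "+")))
  sig <- sum(x$p_adjusted < 0.05, na.rm = TRUE)
  cat(sprintf("  %d/%d transcripts tested, %d with adjusted p < 0.05 (%d fallback, %d failed)\n",
              attr(x, "n_tested"), nrow(x), sig, attr(x, "n_fallback"),
              attr(x, "n_failed")))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
plot.fracprop_diff <- function(x, alpha_level = 0.05, ...) {
  ok <- x$tested & !is.na(x$p_adjusted)
  graphics::plot(x$delta[ok], -log10(x$p_adjusted[ok]),
                 xlab = expression(Delta * " proportion"),
                 ylab = expression(-log[10] * " adjusted p"),
                 pch = 20, col = ifelse(x$p_adjusted[ok] < alpha_level, "red3", "grey50"),
                 ...)
  graphics::abline(h = -log10(alpha_level), lty = 2)
  invisible(x)
}
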