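# Internal helpers shared across the package.

# Classed error, so callers/tests can distinguish failure modes.
ff_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fracprop_error"), call = call))
}

ff_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "fracprop_warning")))
}

# Nearest integer, ties rounded half-up (base round() is half-even);
# binomial likelihoods need integer successes.
round_half_up <- function(x) floor(x + 0.5)

# Dirichlet sampler; `alpha` of length K, returns n x K.
# Infinite concentration degenerates to a point mass at alpha/sum(alpha).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  if (any(!is.finite(alpha))) {
    w <- ifelse(is.finite(alpha), 0, 1)
    w <- w / sum(w)
    return(matrix(w, nrow = n, ncol = k, byrow = TRUE))
  }
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  s <- rowSums(x)
  # all-zero draws can occur for very small shapes; fall back to the mean
  bad <- s == 0
  if (any(bad)) {
    x[bad, ] <- rep(alpha / sum(alpha), each = sum(bad))
    s[bad] <- 1
  }
  x / s
}

# Validate a count matrix (integral, non-negative, unique dimnames).
validate_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    ff_stop("fracprop_invalid_count", "counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ff_stop("fracprop_invalid_count", "counts must have transcript row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    ff_stop("fracprop_duplicate_id", "duplicate transcript id in count matrix")
  if (anyDuplicated(colnames(counts)))
    ff_stop("fracprop_duplicate_id", "duplicate sample id in count matrix")
  if (anyNA(counts) || any(!is.finite(counts)))
    ff_stop("fracprop_invalid_count", "non-numeric or missing count")
  if (any(counts < 0))
    ff_stop("fracprop_negative_count", "negative count in count matrix")
  if (any(counts != round(counts)))
    ff_stop("fracprop_invalid_count", "non-integer count in count matrix")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    ff_stop("fracprop_invalid_count", "count matrix needs >= 1 transcript and >= 2 samples")
  storage.mode(counts) <- "double"
  counts
}
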