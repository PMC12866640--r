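# Shared fixtures and independent oracles, all built in code.

# --- tiny deterministic dataset: total = LP + HP exactly, no lost mass ----
make_conserved_dataset <- function(G = 60, seed = 7, replicates = 1,
                                   condition = "A") {
  set.seed(seed)
  cols <- list()
  design <- list()
  for (r in seq_len(replicates)) {
    lp <- rpois(G, 30) + 1L
    hp <- rpois(G, 50) + 1L
    rep_name <- paste0("r", r)
    for (ty in c("Total", "HP", "LP")) {
      sm <- paste(condition, rep_name, ty, sep = "_")
      cols[[sm]] <- switch(ty, Total = lp + hp, HP = hp, LP = lp)
      design[[sm]] <- data.frame(Sample = sm, Condition = condition,
                                 Replicate = rep_name, Type = ty,
                                 stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("tx%03d", seq_len(G))
  list(counts = counts, design = do.call(rbind, c(design, make.row.names = FALSE)))
}

# --- minimal fitted object with hand-chosen alpha, for test-table checks ---
make_fake_fit <- function(counts, design, alphas) {
  vd <- validate_design(counts, design)
  fits <- lapply(names(vd$groups), function(id) {
    g <- vd$groups[[id]]
    alpha <- alphas[[id]]
    names(alpha) <- names(g$fraction_samples)
    list(condition = g$condition, replicate = g$replicate, alpha = alpha,
         weights = NULL, r_squared = NA_real_, selected = integer(),
         n_selected = 0L)
  })
  names(fits) <- names(vd$groups)
  structure(list(counts = counts[, vd$samples, drop = FALSE], design = vd,
                 fits = fits, proportions = list(), corrected = list(),
                 control = list()),
            class = "fracprop")
}

# --- independent NNLS oracle: enumerate predictor subsets, keep the -------
# --- SSE-minimal non-negative unconstrained LS solution --------------------
oracle_nnls <- function(x, y) {
  nf <- ncol(x)
  best <- list(sse = sum(y^2), alpha = numeric(nf))  # empty support
  subsets <- unlist(lapply(seq_len(nf), function(k)
    utils::combn(nf, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    xs <- x[, s, drop = FALSE]
    beta <- tryCatch(qr.solve(crossprod(xs), crossprod(xs, y)),
                     error = function(e) NULL)
    if (is.null(beta) || any(beta < 0)) next
    sse <- sum((y - xs %*% beta)^2)
    if (sse < best$sse - 1e-12) {
      alpha <- numeric(nf)
      alpha[s] <- beta
      best <- list(sse = sse, alpha = alpha)
    }
  }
  best
}

# --- independent Benjamini-Hochberg step-up oracle -------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))      # enforce step-up monotonicity
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- pooled two-proportion Wald test (closed-form rho -> 0 limit) ----------
pooled_wald <- function(k, n, condition) {
  ks <- tapply(k, condition, sum)
  ns <- tapply(n, condition, sum)
  p <- ks / ns
  z <- (p[[1L]] - p[[2L]]) / sqrt(sum(p * (1 - p) / ns))
  2 * stats::pnorm(-abs(z))
}

write_toy_counts <- function(path, header = "transcript_id\tS1\tS2\tS3",
                             rows = c("tx1\t5\t3\t2", "tx2\t0\t1\t4")) {
  writeLines(c(header, rows), path)
  path
}
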