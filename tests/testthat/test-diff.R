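# A two-condition layout with one fraction library per replicate and
# hand-chosen alpha, used to exercise the test table and the tests directly.
make_two_cond_fit <- function(total_a, frac_a, total_b, frac_b, alpha = 1,
                              frac_type = "LP") {
  n_rep <- ncol(frac_a)
  g <- nrow(frac_a)
  cols <- list(); design <- list(); alphas <- list()
  for (cn in c("A", "B")) {
    tot <- if (cn == "A") total_a else total_b
    fr <- if (cn == "A") frac_a else frac_b
    for (r in seq_len(n_rep)) {
      rep_name <- paste0("r", r)
      sm_t <- paste(cn, rep_name, "Total", sep = "_")
      sm_f <- paste(cn, rep_name, frac_type, sep = "_")
      cols[[sm_t]] <- tot[, r]
      cols[[sm_f]] <- fr[, r]
      design[[sm_t]] <- data.frame(Sample = sm_t, Condition = cn,
                                   Replicate = rep_name, Type = "Total")
      design[[sm_f]] <- data.frame(Sample = sm_f, Condition = cn,
                                   Replicate = rep_name, Type = frac_type)
      alphas[[paste(cn, rep_name, sep = ".")]] <- alpha
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("tx%04d", seq_len(g))
  make_fake_fit(counts, do.call(rbind, c(design, make.row.names = FALSE)), alphas)
}

test_that("the test table folds alpha into successes and clamps at the trials", {
  g <- 5
  tot <- matrix(10, g, 1); fr <- matrix(5, g, 1)
  fit <- make_two_cond_fit(tot, fr, tot, fr, alpha = 1)
  tt <- build_test_table(fit, c("A", "B"), "LP")
  expect_identical(unique(tt$k), 5)
  expect_identical(unique(tt$n), 10)

  # alpha = 2 on Y^f = 10, Y = 10: corrected successes clamp to the trials
  fit2 <- make_two_cond_fit(tot, matrix(10, g, 1), tot, fr, alpha = 2)
  expect_warning(tt2 <- build_test_table(fit2, c("A", "B"), "LP"),
                 class = "fracprop_clamped_successes")
  expect_true(all(tt2$k[tt2$condition == "A"] == 10))
  expect_identical(attr(tt2, "n_clamped"), 5L)

  expect_error(build_test_table(fit, c("A", "C"), "LP"),
               class = "fracprop_unknown_condition")
  expect_error(build_test_table(fit, c("A", "B"), "HP"),
               class = "fracprop_unknown_type")
})

test_that("summed fraction sets use each fraction's own alpha", {
  counts <- cbind(S1 = c(20, 20), S2 = c(3, 6), S3 = c(4, 2),
                  S4 = c(20, 20), S5 = c(3, 3), S6 = c(4, 4))
  rownames(counts) <- c("tx1", "tx2")
  design <- data.frame(Sample = paste0("S", 1:6),
                       Condition = rep(c("A", "B"), each = 3),
                       Replicate = "r1",
                       Type = rep(c("Total", "HP", "LP"), 2))
  fit <- make_fake_fit(counts, design,
                       list(A.r1 = c(2, 1), B.r1 = c(2, 1)))  # HP, LP order
  tt <- build_test_table(fit, c("A", "B"), c("LP", "HP"))
  # tx1 in A: k = round(1*4 + 2*3) = 10, n = 20
  row <- tt[tt$transcript_id == "tx1" & tt$condition == "A", ]
  expect_identical(row$k, 10)
  expect_identical(row$n, 20)
})

test_that("all three tests return the null on condition-identical inputs", {
  k <- c(30, 28, 31, 30, 28, 31); n <- rep(100, 6)
  cond <- rep(c("A", "B"), each = 3)
  k_sym <- rep(c(30, 28, 31), 2)
  g <- glm_test(k_sym, n, cond)
  expect_equal(g$statistic, 0, tolerance = 1e-8)
  expect_equal(g$p_value, 1, tolerance = 1e-6)
  l <- logit_test(k_sym, n, cond)
  expect_equal(l$statistic, 0, tolerance = 1e-12)
  expect_equal(l$p_value, 1, tolerance = 1e-12)
  b <- betabin_test(k_sym, n, cond)
  expect_equal(b$statistic, 0, tolerance = 1e-4)
  expect_equal(b$p_value, 1, tolerance = 1e-3)
})

test_that("a large planted effect is detected with overwhelming evidence", {
  set.seed(21)
  n <- rep(1000, 6); cond <- rep(c("A", "B"), each = 3)
  k <- c(rbinom(3, 1000, 0.2), rbinom(3, 1000, 0.8))
  expect_lt(glm_test(k, n, cond)$p_value, 1e-6)
  expect_lt(logit_test(k, n, cond)$p_value, 1e-6)
  expect_lt(betabin_test(k, n, cond)$p_value, 1e-6)
})

test_that("the empirical logit stays finite at boundary counts", {
  res <- logit_test(c(100, 0), c(100, 100), c("A", "B"))
  expect_true(is.finite(res$statistic))
  expect_lt(res$p_value, 1e-4)
})

test_that("degenerate GLM cases fall back to the logit test, flagged", {
  res <- glm_test(c(0, 0, 0, 0), rep(50, 4), rep(c("A", "B"), each = 2))
  expect_true(res$fallback)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  sep <- glm_test(c(50, 50, 0, 0), rep(50, 4), rep(c("A", "B"), each = 2))
  expect_true(sep$fallback)
  expect_true(is.finite(sep$p_value))
})

test_that("the logit test keeps most of the GLM's power", {
  set.seed(77)
  n_tr <- 150
  rej <- c(glm = 0, logit = 0)
  for (i in seq_len(n_tr)) {
    n <- rep(150, 6); cond <- rep(c("A", "B"), each = 3)
    k <- c(rbinom(3, 150, 0.4), rbinom(3, 150, 0.6))
    rej["glm"] <- rej["glm"] + (glm_test(k, n, cond)$p_value < 0.05)
    rej["logit"] <- rej["logit"] + (logit_test(k, n, cond)$p_value < 0.05)
  }
  expect_gte(rej[["logit"]] / n_tr, rej[["glm"]] / n_tr - 0.10)
})

test_that("the beta-binomial reduces to the pooled Wald test without overdispersion", {
  # replicate-identical counts leave no between-replicate variance, so the
  # shared overdispersion is driven to its lower bound
  cond <- rep(c("A", "B"), each = 3)
  cases <- list(list(k = c(160, 160, 160, 180, 180, 180), n = rep(400, 6)),
                list(k = c(50, 50, 50, 65, 65, 65), n = rep(200, 6)),
                list(k = c(300, 300, 300, 290, 290, 290), n = rep(1000, 6)))
  for (cs in cases) {
    bb <- betabin_test(cs$k, cs$n, cond)
    expect_lt(abs(bb$p_value - pooled_wald(cs$k, cs$n, cond)), 1e-3)
  }
})

test_that("the beta-binomial is calibrated under overdispersion where the GLM is not", {
  set.seed(55)
  n_tr <- 200
  rej <- c(glm = 0, bb = 0)
  for (i in seq_len(n_tr)) {
    n <- rep(300, 6); cond <- rep(c("A", "B"), each = 3)
    p_rep <- rbeta(6, 0.5 * 0.95 / 0.05, 0.5 * 0.95 / 0.05)  # rho = 0.05, null
    k <- rbinom(6, n, p_rep)
    rej["glm"] <- rej["glm"] + (glm_test(k, n, cond)$p_value < 0.05)
    rej["bb"] <- rej["bb"] + (betabin_test(k, n, cond)$p_value < 0.05)
  }
  expect_lte(rej[["bb"]], rej[["glm"]])
})

test_that("BH adjustment matches the textbook step-up procedure exactly", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p - 1e-12))
  }
  p_na <- c(0.01, NA, 0.04)
  adj <- bh_adjust(p_na)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracle_bh(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "fracprop_invalid_pvalue")
})

test_that("proportion estimates do not depend on the test method", {
  set.seed(31)
  g <- 40
  tot <- matrix(rpois(g * 2, 200), g, 2)
  fr <- matrix(rbinom(g * 2, 150, 0.4), g, 2)
  fit <- make_two_cond_fit(tot, fr, tot + 5L, fr + 2L, alpha = 1)
  r_glm <- suppressWarnings(diff_prop_test(fit, c("A", "B"), "LP", method = "GLM"))
  r_logit <- suppressWarnings(diff_prop_test(fit, c("A", "B"), "LP", method = "Logit"))
  expect_identical(r_glm$prop1, r_logit$prop1)
  expect_identical(r_glm$prop2, r_logit$prop2)
  expect_identical(r_glm$delta, r_logit$delta)
})

test_that("results are invariant to transcript order", {
  set.seed(32)
  g <- 30
  tot <- matrix(rpois(g * 2, 200), g, 2)
  fr <- matrix(rbinom(g * 2, 150, 0.4), g, 2)
  fit <- make_two_cond_fit(tot, fr, tot, fr + 3L, alpha = 1)
  res <- suppressWarnings(diff_prop_test(fit, c("A", "B"), "LP"))
  perm <- sample(g)
  fit_p <- make_two_cond_fit(tot[perm, , drop = FALSE], fr[perm, , drop = FALSE],
                             tot[perm, , drop = FALSE], (fr + 3L)[perm, , drop = FALSE],
                             alpha = 1)
  res_p <- suppressWarnings(diff_prop_test(fit_p, c("A", "B"), "LP"))
  expect_equal(res$p_value[perm], res_p$p_value, tolerance = 1e-12)
})

test_that("planted shifts are recovered and the null stays clean end to end", {
  set.seed(41)
  g <- 300; planted <- seq_len(30)
  n_rep <- 3
  p_base <- runif(g, 0.25, 0.55)
  p_a <- p_base; p_b <- p_base
  p_b[planted] <- p_b[planted] + 0.3
  tot <- matrix(500L, g, n_rep)
  fr_a <- matrix(rbinom(g * n_rep, 500, rep(p_a, n_rep)), g, n_rep)
  fr_b <- matrix(rbinom(g * n_rep, 500, rep(p_b, n_rep)), g, n_rep)
  fit <- make_two_cond_fit(tot, fr_a, tot, fr_b, alpha = 1)
  res <- suppressWarnings(diff_prop_test(fit, c("A", "B"), "LP", method = "GLM"))
  hits <- res$transcript_id[res$p_adjusted < 0.05 & res$tested]
  expect_gte(mean(sprintf("tx%04d", planted) %in% hits), 0.8)
  # untested transcripts carry missing statistics
  expect_true(all(is.na(res$statistic[!res$tested])))
  # a pure null comparison yields (almost) no discoveries
  fit0 <- make_two_cond_fit(tot, fr_a, tot,
                            matrix(rbinom(g * n_rep, 500, rep(p_a, n_rep)), g, n_rep),
                            alpha = 1)
  res0 <- suppressWarnings(diff_prop_test(fit0, c("A", "B"), "LP", method = "GLM"))
  expect_lte(sum(res0$p_adjusted < 0.05, na.rm = TRUE), 2)
})

test_that("unknown methods are rejected", {
  fit <- make_two_cond_fit(matrix(10, 2, 1), matrix(5, 2, 1),
                           matrix(10, 2, 1), matrix(5, 2, 1))
  expect_error(diff_prop_test(fit, c("A", "B"), "LP", method = "ANOVA"),
               "unknown method", class = "fracprop_unknown_method")
})
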