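test_that("cumulative score process is anchored and bridge-like", {
  set.seed(41)
  n <- 400; k <- 4
  sc <- matrix(rnorm(n * k), n)
  z <- rnorm(n)
  pr <- score_process(sc, z)
  expect_equal(unname(pr$process[1, ]), rep(0, k))
  # centering anchors the end point at zero exactly
  expect_lt(max(abs(pr$process[n + 1, ])), 1e-10)

  # zero scores give the identically-zero process
  sc0 <- matrix(0, n, k)
  expect_warning(pr0 <- score_process(sc0, z), "rank-deficient")
  expect_identical(pr0$k_eff, 0L)
  expect_true(all(pr0$process == 0))

  # component variance at t = 0.5 matches the Brownian bridge (~ t(1-t))
  vars <- replicate(600, {
    s1 <- matrix(rnorm(200), 200, 1)
    p1 <- score_process(s1, rnorm(200))
    p1$process[101, 1]
  })
  expect_lt(abs(var(vars) - 0.25), 0.04)
})

test_that("maxLM equals its exhaustive brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(60:160, 1)
    k <- sample(1:5, 1)
    sc <- matrix(rnorm(n * k), n)
    z <- rnorm(n)
    trim <- runif(1, 0.05, 0.3)
    res <- max_lm_numeric(sc, z, trim = trim)
    psi <- mgrtree:::decorrelate_scores(sc)
    ord <- order(z)
    cs <- apply(psi[ord, , drop = FALSE], 2, cumsum)
    vals <- vapply(seq_len(n - 1), function(j) {
      t <- j / n
      if (t < trim || t > 1 - trim) return(NA_real_)
      sum(cs[j, ]^2) / n / (t * (1 - t))
    }, numeric(1))
    expect_equal(res$statistic, max(vals, na.rm = TRUE), tolerance = 1e-10)
    expect_identical(res$cut_index, which.max(vals))
  }
})

test_that("maxLM localizes a planted score shift", {
  set.seed(43)
  hits <- 0L
  for (rep in 1:60) {
    n <- 500
    sc <- matrix(rnorm(n * 3), n)
    z <- rnorm(n)
    mid <- median(z)
    sc[z <= mid, 2] <- sc[z <= mid, 2] + 1.0
    res <- max_lm_numeric(sc, z, trim = 0.1)
    if (abs(res$cut_index - n / 2) <= 0.05 * n) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * 60)
})

test_that("LMuo is symmetric, relabel-invariant and chi-square calibrated", {
  set.seed(44)
  n <- 400; k <- 3
  sc <- matrix(rnorm(n * k), n)
  # mirrored categories: equal category contributions
  zc <- rep(c("a", "b"), each = n / 2)
  sc[zc == "b", ] <- -sc[zc == "a", ]
  psi <- mgrtree:::decorrelate_scores(sc)
  sums <- rowsum(psi, zc)
  expect_equal(unname(rowSums(sums^2))[1], unname(rowSums(sums^2))[2],
               tolerance = 1e-8)

  # category relabeling leaves the statistic unchanged
  sc2 <- matrix(rnorm(n * k), n)
  z3 <- factor(sample(c("x", "y", "w"), n, TRUE))
  s_orig <- lm_uo_categorical(sc2, z3)$statistic
  relab <- factor(c(x = "group2", y = "group3", w = "group1")[as.character(z3)])
  expect_equal(lm_uo_categorical(sc2, relab)$statistic, s_orig,
               tolerance = 1e-10)

  # null 95th percentile vs chi-square quantile (k = 3, C = 3, n = 800)
  stats <- replicate(2000, {
    s <- matrix(rnorm(800 * 3), 800)
    zz <- factor(sample(1:3, 800, TRUE))
    lm_uo_categorical(s, zz)$statistic
  })
  q95 <- unname(quantile(stats, 0.95))
  expect_lt(abs(q95 - qchisq(0.95, 6)) / qchisq(0.95, 6), 0.05)
})

test_that("maxLMo equals its exhaustive oracle and respects level order", {
  set.seed(45)
  for (rep in 1:100) {
    n <- sample(80:200, 1)
    k <- sample(1:4, 1)
    C <- sample(3:6, 1)
    sc <- matrix(rnorm(n * k), n)
    z <- factor(sample(seq_len(C), n, TRUE), levels = seq_len(C),
                ordered = TRUE)
    res <- max_lm_ordinal(sc, z)
    psi <- mgrtree:::decorrelate_scores(sc)
    lev <- levels(droplevels(z))
    vals <- vapply(seq_len(length(lev) - 1), function(cut) {
      inA <- as.character(z) %in% lev[seq_len(cut)]
      t <- mean(inA)
      sum(colSums(psi[inA, , drop = FALSE])^2) / n / (t * (1 - t))
    }, numeric(1))
    expect_equal(res$statistic, max(vals), tolerance = 1e-10)
  }

  # two-level ordinal covariate: single admissible cut
  sc <- matrix(rnorm(300), 100, 3)
  z2 <- factor(rep(1:2, 50), ordered = TRUE)
  r2 <- max_lm_ordinal(sc, z2)
  expect_identical(length(r2$profile), 1L)

  # monotone relabeling leaves the statistic unchanged
  z5 <- factor(sample(1:5, 100, TRUE), levels = 1:5, ordered = TRUE)
  r5 <- max_lm_ordinal(sc, z5)
  z5b <- factor(c(10, 20, 30, 40, 99)[as.integer(z5)],
                levels = c(10, 20, 30, 40, 99), ordered = TRUE)
  r5b <- max_lm_ordinal(sc, z5b)
  expect_equal(r5b$statistic, r5$statistic, tolerance = 1e-12)
})

test_that("p values behave at zero, match chi-square closed forms, and the
           maxLM closed form agrees with simulation in the tail", {
  p0 <- instability_p_value(0, "maxLM", 3, list(trim = 0.1), n_sim = 2000,
                            seed = 1)
  expect_gte(p0, 1 - 1e-3)
  # LMuo closed form is the chi-square tail: qchisq(.95, 2) -> p = .05
  p_lmuo <- instability_p_value(qchisq(0.95, 2), "LMuo", k = 2,
                                extra = list(n_categories = 2))
  expect_equal(p_lmuo, 0.05, tolerance = 1e-10)

  # closed form vs simulation for maxLM (k = 1, trim = 0.1), tail region
  ref <- mgrtree:::maxlm_null_sample(1, 0.1, 201, 50000, 5)
  for (x in seq(10, 19, by = 1)) {
    cf <- mgrtree:::p_maxlm_crossing(x, 1, 0.1)
    expect_lt(abs(cf - mean(ref >= x)), 0.01)
  }
  expect_error(instability_p_value(1, "unknown_kind", 2), "arg")
})

test_that("simulated maxLM p values reject at nominal rate under the null", {
  set.seed(46)
  ps <- replicate(400, {
    s <- matrix(rnorm(500 * 3), 500)
    zz <- rnorm(500)
    r <- max_lm_numeric(s, zz, trim = 0.1)
    instability_p_value(r$statistic, "maxLM", 3, list(trim = 0.1),
                        n_sim = 5000, seed = 99)
  })
  expect_gte(mean(ps < 0.05), 0.03)
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("covariate scan selects planted DIF and adjusts for multiplicity", {
  # R = 1: adjusted p equals raw p
  set.seed(47)
  sc <- matrix(rnorm(300 * 2), 300)
  Z1 <- data.frame(z = rnorm(300))
  tt <- test_all_covariates(NULL, sc, Z1, seed = 3)
  expect_equal(tt$results$p_adjusted, tt$results$p)

  # constant covariates are skipped with a note
  Zc <- data.frame(z = rnorm(300), const = rep(1, 300))
  tc <- test_all_covariates(NULL, sc, Zc, seed = 3)
  expect_identical(tc$results$kind[2], "skipped")

  # planted DIF among noise covariates is found
  fx <- cfa_fit_fixture()
  hits <- 0L
  for (r in 1:20) {
    par2 <- fx$params
    par2$latent_cov <- fx$params$latent_cov * 2
    d2 <- simulate_cfa(par2, 1000, seed = 600 + r)
    d1 <- simulate_cfa(fx$params, 1000, seed = 700 + r)
    dat <- rbind(d1, d2)
    zdif <- c(rnorm(1000, -1), rnorm(1000, 1))
    Z <- data.frame(zdif = zdif, r1 = rnorm(2000), r2 = rnorm(2000),
                    r3 = factor(sample(1:4, 2000, TRUE)),
                    r4 = factor(sample(1:5, 2000, TRUE), ordered = TRUE))
    f <- fit_ml(fx$spec, dat)
    scm <- score_matrix(f)
    sel <- test_all_covariates(f, scm, Z, seed = 5)$selected
    if (identical(sel, "zdif")) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("ordinal-response instability tests are not anticonservative
           relative to numeric responses", {
  # null rejection rates on discretized vs numeric data from the same
  # latent model, maxLM on a numeric covariate
  rej <- c(ordinal = 0, numeric = 0)
  n_rep <- 40L
  spec_o <- pieg_fixture()
  spec_n <- cfa_fixture()
  for (r in seq_len(n_rep)) {
    par_o <- sample_pieg_parameters(spec_o, seed = 800 + r)
    dat_o <- simulate_pieg(par_o, 800, seed = 900 + r)
    par_n <- sample_pieg_parameters(spec_n, seed = 800 + r)
    dat_n <- simulate_cfa(par_n, 800, seed = 900 + r)
    z <- rnorm(800)
    for (scale in c("ordinal", "numeric")) {
      dat <- if (scale == "ordinal") dat_o else dat_n
      f <- fit_ml(if (scale == "ordinal") spec_o else spec_n, dat)
      if (!f$converged) next
      scm <- score_matrix(f)
      res <- max_lm_numeric(scm, z, trim = 0.1)
      p <- instability_p_value(res$statistic, "maxLM", res$k_eff,
                               list(trim = 0.1), n_sim = 5000, seed = 17)
      if (p < 0.05) rej[scale] <- rej[scale] + 1
    }
  }
  expect_lte(rej["ordinal"] / n_rep, rej["numeric"] / n_rep + 0.1)
})
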