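test_that("thresholds are inverse-normal cumulative proportions", {
  y <- matrix(c(rep(0L, 50), rep(1L, 50)), ncol = 1,
              dimnames = list(NULL, "b"))
  thr <- estimate_thresholds(y, 2L)
  expect_equal(thr$b, 0, tolerance = 1e-12)

  y5 <- matrix(rep(1:5, each = 20), ncol = 1, dimnames = list(NULL, "y"))
  thr5 <- estimate_thresholds(y5, 5L)
  expect_equal(thr5$y, qnorm(c(.2, .4, .6, .8)), tolerance = 1e-12)

  # recovery of true thresholds at large n
  set.seed(31)
  tv <- c(-1, 0, 0.5, 1.5)
  z <- rnorm(1e5)
  yc <- matrix(findInterval(z, tv), ncol = 1, dimnames = list(NULL, "y"))
  thr_hat <- estimate_thresholds(yc, 5L)
  expect_lt(max(abs(thr_hat$y - tv)), 0.02)

  # single observed category errors, naming the item
  y1 <- matrix(rep(2L, 40), ncol = 1, dimnames = list(NULL, "stuck"))
  expect_error(estimate_thresholds(y1, 5L), "stuck")
})

test_that("polychoric correlations match independence, concordance and a
           grid-search oracle", {
  set.seed(32)
  # independent items
  yi <- cbind(a = sample(0:4, 1e4, TRUE), b = sample(0:4, 1e4, TRUE))
  pc <- polychoric(yi, 5L)
  expect_lt(abs(pc$kappa), 0.03)

  # perfectly concordant pair is clamped at the boundary
  v <- sample(1:5, 2000, TRUE)
  expect_warning(pcc <- polychoric(cbind(a = v, b = v), 5L), "clamped")
  expect_gte(pcc$kappa, 0.999)

  # 2x2 tables from rho = 0.5, thresholds (0, 0): grid-search oracle with
  # numerically integrated quadrant probabilities
  set.seed(33)
  n <- 1e5
  Yc <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, .5, .5, 1), 2))
  Yb <- (Yc > 0) + 0L
  colnames(Yb) <- c("a", "b")
  pc2 <- polychoric(Yb, 2L)
  expect_equal(unname(pc2$kappa), 0.5, tolerance = 0.01)

  tab <- table(Yb[, 1], Yb[, 2])
  quad_p11 <- function(r) {
    f <- function(x) dnorm(x) * pnorm((0 - r * x) / sqrt(1 - r^2))
    integrate(f, -Inf, 0)$value
  }
  grid <- seq(0.3, 0.7, by = 0.001)
  ll <- vapply(grid, function(r) {
    p11 <- quad_p11(r)
    p1 <- pnorm(0)
    P <- matrix(c(p11, p1 - p11, p1 - p11, 1 - 2 * p1 + p11), 2)
    sum(tab * log(P))
  }, numeric(1))
  oracle <- grid[which.max(ll)]
  expect_equal(unname(pc2$kappa), oracle, tolerance = 2e-3)
})

test_that("polychoric correlation is antisymmetric under category reversal", {
  spec <- pieg_fixture()
  dat <- simulate_pieg(sample_pieg_parameters(spec, seed = 2L), 800, seed = 9L)
  pc <- polychoric(dat[, 1:3], 5L)
  rev <- dat[, 1:3]
  rev[[2]] <- 6L - rev[[2]]
  pc_rev <- polychoric(rev, 5L)
  expect_equal(pc_rev$corr[1, 2], -pc$corr[1, 2], tolerance = 1e-6)
  expect_equal(pc_rev$corr[1, 3], pc$corr[1, 3], tolerance = 1e-6)
})

test_that("bivariate normal CDF kernel agrees with an independent
           implementation", {
  skip_if_not_installed("mvtnorm")
  set.seed(34)
  for (r in c(-0.999, -0.9, -0.4, 0, 0.55, 0.9, 0.999)) {
    x <- rnorm(12); y <- rnorm(12)
    ours <- mgrtree:::cpp_bvn_cdf(x, y, r)
    ref <- vapply(seq_along(x), function(i)
      mvtnorm::pmvnorm(upper = c(x[i], y[i]),
                       corr = matrix(c(1, r, r, 1), 2))[1], numeric(1))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("identity-weight WLS matches an independent least-squares solve", {
  spec <- pieg_fixture()
  par <- sample_pieg_parameters(spec, seed = 4L)
  dat <- simulate_pieg(par, 1500, seed = 5L)
  ps <- polychoric(dat, 5L)
  w_id <- fit_wls(spec, ps, weights = "identity")
  # independent minimisation of the unweighted residual sum of squares over
  # the latent covariance (optim from a different start, natural scale)
  Lam <- spec$loadings; Lam[is.na(Lam)] <- 1
  pair_ord <- mgrtree:::lower_pair_order(9)
  obj <- function(v) {
    Phi <- matrix(0, 5, 5)
    Phi[upper.tri(Phi, diag = TRUE)] <- v
    Phi <- Phi + t(Phi) - diag(diag(Phi))
    ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) return(1e6)
    Sig <- Lam %*% Phi %*% t(Lam) + diag(9)
    kap <- cov2cor(Sig)[lower.tri(Sig)][pair_ord]
    sum((ps$kappa - kap)^2)
  }
  v0 <- diag(5) * 0.6
  v0 <- v0[upper.tri(v0, diag = TRUE)]
  ora <- optim(v0, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(w_id$fwls, ora$value, tolerance = 1e-5)
})

test_that("full-weight WLS recovers self-simulated latent covariances and is
           calibrated", {
  spec <- pieg_fixture()
  par <- sample_pieg_parameters(spec, seed = 6L)
  tru <- flatten_parameters(par)[37:51]
  ests <- matrix(NA_real_, 10, 15)
  chi2s <- numeric(10)
  for (r in 1:10) {
    dat <- simulate_pieg(par, 2000, seed = 200 + r)
    w <- fit_wls(spec, polychoric(dat, 5L))
    ests[r, ] <- flatten_parameters(w$theta)[37:51]
    chi2s[r] <- w$chi2
  }
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  bias <- abs(colMeans(ests) - tru)
  expect_true(all(bias <= pmax(3 * mc_se, 0.02)))
  # chi2 ~ chi2_21 under the true model: mean within sampling slack
  expect_lt(abs(mean(chi2s) - 21), 10)
})

test_that("saturated correlation structure yields zero discrepancy", {
  # model with as many structural parameters as correlations is not
  # testable; df <= 0 must error
  L <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "f"))
  s <- mgr_spec(L, "ordinal", n_categories = 3L)
  set.seed(36)
  dat <- simulate_pieg(mgr_parameters(
    s, thresholds = list(a = c(-0.5, 0.5), b = c(-0.5, 0.5)),
    latent_cov = matrix(0.7, 1, 1)), 500, seed = 1L)
  expect_error(fit_wls(s, polychoric(dat, 3L)), "not testable")
})

test_that("RMSEA and its confidence interval follow the noncentral
           chi-square inversion", {
  expect_equal(mgrtree:::rmsea_point(24, 24, 501), 0)
  expect_equal(mgrtree:::rmsea_point(48, 24, 501), sqrt(24 / (24 * 500)))
  expect_equal(mgrtree:::rmsea_point(10, 24, 501), 0)

  # CI endpoints vs brute-force bisection on the noncentral CDF
  set.seed(37)
  for (case in 1:10) {
    df <- sample(5:40, 1)
    chi2 <- df * runif(1, 0.5, 3)
    n <- sample(200:3000, 1)
    ci <- rmsea_confint(chi2, df, n, 0.95)
    bisect <- function(target) {
      lo <- 0; hi <- max(chi2 * 4, 50)
      if (pchisq(chi2, df, ncp = 0) <= target) return(0)
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (pchisq(chi2, df, ncp = mid) > target) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    lam_lo <- bisect(0.975)
    lam_hi <- bisect(0.025)
    expect_equal(ci[1], sqrt(lam_lo / (df * (n - 1))), tolerance = 1e-4)
    expect_equal(ci[2], sqrt(lam_hi / (df * (n - 1))), tolerance = 1e-4)
    expect_true(ci[1] <= mgrtree:::rmsea_point(chi2, df, n) + 1e-12)
    expect_true(ci[2] >= mgrtree:::rmsea_point(chi2, df, n) - 1e-12)
  }
})

test_that("well-specified subsamples fit well; F_WLS is non-negative", {
  spec <- pieg_fixture()
  ok <- 0L
  for (r in 1:25) {
    par <- sample_pieg_parameters(spec, seed = 400 + r)
    dat <- simulate_pieg(par, 500, seed = 500 + r)
    w <- fit_wls(spec, polychoric(dat, 5L))
    expect_gte(w$fwls, 0)
    if (w$rmsea <= 0.05) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.9 * 25))
})
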