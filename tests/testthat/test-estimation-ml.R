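test_that("F_ML evaluates Eq-style discrepancy in closed form", {
  # fixed single-variance model vs S: F = ln|Sigma| + tr(S/Sigma) - ln|S| - 1
  # saturation: free variance reaches S exactly
  L <- matrix(1, 1, 1, dimnames = list("y1", "f"))
  s_sat <- mgr_spec(L, "numeric", latent_cov = matrix(NA_real_, 1, 1),
                    intercepts = 0, residuals = 1)
  set.seed(1)
  y <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "y1"))
  y <- y / sd(y) * sqrt(2)  # sample variance ~2
  f <- fit_ml(s_sat, y)
  expect_true(f$converged)
  expect_lt(f$fml, 1e-8)
  expect_equal(unname(f$theta$latent_cov[1, 1] + 1), unname(f$S[1, 1]),
               tolerance = 1e-4)

  # two-item model with only the latent variance free: compare with a
  # one-dimensional brute-force minimisation of the discrepancy
  s2 <- two_item_spec(residuals = c(1, 1))
  set.seed(2)
  d2 <- simulate_cfa(mgr_parameters(s2, intercepts = c(0, 0),
                                    latent_cov = matrix(0.8, 1, 1),
                                    residual_var = c(1, 1)), 1500, seed = 3)
  f2 <- fit_ml(s2, d2)
  S <- f2$S
  fml_v <- function(v) {
    Sig <- matrix(c(v + 1, v, v, v + 1), 2)
    log(det(Sig)) + sum(diag(S %*% solve(Sig))) - log(det(S)) - 2
  }
  vopt <- optimize(fml_v, c(0.01, 5), tol = 1e-9)
  expect_equal(unname(f2$theta$latent_cov[1, 1]), vopt$minimum,
               tolerance = 1e-4)
  expect_equal(f2$fml, vopt$objective, tolerance = 1e-6)
})

test_that("parameters of a self-simulated CFA twin are recovered", {
  fx <- cfa_fit_fixture()
  expect_true(fx$fit$converged)
  d <- abs(flatten_parameters(fx$fit$theta) - flatten_parameters(fx$params))
  # n = 2000; asymptotic sampling error per parameter is well under 0.15
  expect_lt(max(d), 0.15)
  expect_lt(mean(d), 0.05)
})

test_that("F_ML is invariant under joint item permutation", {
  fx <- cfa_fit_fixture()
  perm <- c(9, 1, 4, 2, 8, 3, 7, 5, 6)
  spec2 <- mgr_spec(fx$spec$loadings[perm, , drop = FALSE], "numeric",
                    latent_cov = fx$spec$latent_cov)
  f2 <- fit_ml(spec2, fx$data[, fx$spec$items[perm]])
  expect_equal(f2$fml, fx$fit$fml, tolerance = 1e-6)
})

test_that("casewise log-likelihoods follow the MVN kernel", {
  # Sigma = [1], pi = 0, y = 0 -> lnL = 0 under the kernel convention
  L <- matrix(1, 1, 1, dimnames = list("y1", "f"))
  s <- mgr_spec(L, "numeric", latent_cov = matrix(NA_real_, 1, 1),
                intercepts = 0, residuals = 0.5)
  set.seed(4)
  y <- matrix(rnorm(500, sd = 1), ncol = 1, dimnames = list(NULL, "y1"))
  f <- fit_ml(s, y)
  ll <- casewise_loglik(f)
  mom <- implied_moments(f$spec, f$theta)
  expect_equal(ll, -0.5 * (log(mom$cov[1, 1]) + y[, 1]^2 / mom$cov[1, 1]),
               ignore_attr = TRUE, tolerance = 1e-10)

  # identical cases get identical values
  fx <- cfa_fit_fixture()
  ll9 <- casewise_loglik(fx$fit)
  dup <- rbind(fx$data[1, ], fx$data[1, ])
  lld <- casewise_loglik(fx$fit, dup)
  expect_equal(lld[1], lld[2])

  # local optimum: total loglik at theta-hat >= at perturbed theta
  th <- flatten_parameters(fx$fit$theta)
  total <- sum(ll9)
  set.seed(5)
  for (r in 1:50) {
    delta <- rnorm(length(th), sd = 0.01)
    thp <- unflatten_parameters(fx$fit$spec, th + delta, validate = FALSE)
    okpd <- min(eigen(thp$latent_cov, only.values = TRUE)$values) > 0 &&
      all(thp$residual_var > 0)
    if (!okpd) next
    mom <- implied_moments(fx$fit$spec, thp)
    Rc <- sweep(as.matrix(fx$data), 2, mom$mean)
    llp <- sum(-0.5 * (determinant(mom$cov)$modulus[1] +
                         rowSums((Rc %*% solve(mom$cov)) * Rc)))
    expect_lte(llp, total + 1e-6)
  }
})

test_that("score matrix satisfies the estimating equations and matches
           finite differences", {
  fx <- cfa_fit_fixture()
  psi <- score_matrix(fx$fit)
  n <- fx$fit$n
  expect_identical(ncol(psi), count_free_parameters(fx$fit$spec))
  expect_lt(max(abs(colSums(psi))) / n, 1e-4)

  th <- flatten_parameters(fx$fit$theta)
  f_case <- function(v, j) {
    thx <- unflatten_parameters(fx$fit$spec, v, validate = FALSE)
    mom <- implied_moments(fx$fit$spec, thx)
    r <- as.numeric(fx$fit$data[j, ]) - mom$mean
    -0.5 * (determinant(mom$cov)$modulus[1] +
              t(r) %*% solve(mom$cov) %*% r)
  }
  set.seed(6)
  for (probe in 1:50) {
    j <- sample(n, 1)
    pidx <- sample(length(th), 1)
    h <- 1e-5 * (1 + abs(th[pidx]))
    vp <- th; vp[pidx] <- vp[pidx] + h
    vm <- th; vm[pidx] <- vm[pidx] - h
    num <- (f_case(vp, j) - f_case(vm, j)) / (2 * h)
    expect_equal(unname(psi[j, pidx]), as.numeric(num), tolerance = 1e-4)
  }

  # duplicated dataset duplicates score rows
  dd <- rbind(fx$data, fx$data)
  f2 <- fit_ml(fx$spec, dd, start = fx$fit$theta)
  psi2 <- score_matrix(f2)
  expect_equal(psi2[seq_len(n), ], psi2[n + seq_len(n), ], tolerance = 1e-10)

  # refuses a non-converged fit
  bad <- fx$fit
  bad$converged <- FALSE
  expect_error(score_matrix(bad), "converge")
})

test_that("likelihood-ratio test behaves at the null and matches casewise
           sums", {
  fx <- cfa_fit_fixture()
  n <- nrow(fx$data)
  # split into two copies of the same empirical distribution
  half <- seq_len(n / 2)
  dat2 <- rbind(fx$data[half, ], fx$data[half, ])
  tpl <- fit_ml(fx$spec, dat2)
  fl <- fit_ml(fx$spec, dat2[seq_along(half), ], start = tpl$theta)
  fr <- fit_ml(fx$spec, dat2[length(half) + seq_along(half), ],
               start = tpl$theta)
  lr <- lr_test(tpl, fl, fr)
  expect_lt(lr$statistic, 1e-4)
  expect_gt(lr$p_value, 0.999)
  # definitional identity
  expect_equal(lr$statistic,
               max(0, 2 * (sum(casewise_loglik(fl)) + sum(casewise_loglik(fr)) -
                             sum(casewise_loglik(tpl)))),
               tolerance = 1e-8)
  expect_identical(lr$df, count_free_parameters(tpl$spec))
})

test_that("LR test detects a planted loading shift", {
  # power check: loading differs by 0.8 between halves, n = 1000
  L <- matrix(c(NA, 1), 2, 1, dimnames = list(c("y1", "y2"), "f"))
  s <- mgr_spec(L, "numeric", latent_cov = matrix(1, 1, 1))
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    mk <- function(lam, seed) simulate_cfa(
      mgr_parameters(s, intercepts = c(0, 0),
                     loadings = matrix(c(lam, 1), 2, 1),
                     latent_cov = matrix(1, 1, 1),
                     residual_var = c(1, 1)), 500, seed = seed)
    d <- rbind(mk(0.6, 2 * r), mk(1.4, 2 * r + 1))
    tpl <- fit_ml(s, d)
    fl <- fit_ml(s, d[1:500, ], start = tpl$theta)
    fr <- fit_ml(s, d[501:1000, ], start = tpl$theta)
    if (lr_test(tpl, fl, fr)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("repeated self-simulation shows negligible estimation bias", {
  spec <- cfa_fixture()
  par <- sample_pieg_parameters(spec, seed = 3L)
  tru <- flatten_parameters(par)
  ests <- matrix(NA_real_, 20, length(tru))
  for (r in 1:20) {
    d <- simulate_cfa(par, 2000, seed = 100 + r)
    ests[r, ] <- flatten_parameters(fit_ml(spec, d)$theta)
  }
  bias <- abs(colMeans(ests) - tru)
  expect_lt(max(bias), 0.05)
})

test_that("singular sample covariance and missing data are rejected", {
  fx <- cfa_fit_fixture()
  dd <- fx$data
  dd[[2]] <- dd[[1]]  # collinear items
  names(dd) <- fx$spec$items
  expect_error(fit_ml(fx$spec, dd), "singular")
  dm <- fx$data
  dm[1, 1] <- NA
  expect_error(fit_ml(fx$spec, dm), "missing")
})
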