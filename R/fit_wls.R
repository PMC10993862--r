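#' Univariate threshold estimates for ordinal items
#'
#' Thresholds on the latent-response scale from cumulative category
#' proportions: alpha_ik = Phi^-1(P(Y_i < k)). Categories may be coded 0-based
#' or 1-based; coding is normalized internally.
#'
#' @param data ordinal response table (matrix or data frame of integer codes).
#' @param n_categories category count per item (length 1 or m). Defaults to
#'   the maximum observed code range.
#' @return list of per-item strictly increasing threshold vectors (equal
#'   thresholds can occur when a middle category is unobserved).
#' @export
estimate_thresholds <- function(data, n_categories = NULL) {
  Y <- ordinal_matrix(data, n_categories)
  K <- attr(Y, "n_categories")
  m <- ncol(Y)
  out <- vector("list", m)
  names(out) <- colnames(Y)
  n <- nrow(Y)
  for (i in seq_len(m)) {
    counts <- tabulate(Y[, i] + 1L, nbins = K[i])
    if (sum(counts > 0L) < 2L)
      stop("item ", colnames(Y)[i],
           " has a single observed category (node too homogeneous)")
    cum <- cumsum(counts)[seq_len(K[i] - 1L)] / n
    out[[i]] <- stats::qnorm(pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n)))
  }
  out
}

# normalize ordinal codes to 0..K-1 integers
ordinal_matrix <- function(data, n_categories = NULL) {
  Y <- as.matrix(as.data.frame(data))
  if (!is.numeric(Y)) stop("ordinal data must be integer-coded")
  if (anyNA(Y)) stop("missing values are not supported")
  if (any(Y != round(Y))) stop("ordinal data must be integer-coded")
  Y <- round(Y)
  m <- ncol(Y)
  if (is.null(n_categories)) n_categories <- max(Y) - min(1L, min(Y)) + 1L
  K <- as.integer(rep(n_categories, length.out = m))
  # coding convention: 1..K (shifted) or 0..K-1 (as-is)
  if (min(Y) >= 1L && max(Y) <= max(K)) Y <- Y - 1L
  else if (!(min(Y) >= 0L && max(Y) <= max(K) - 1L))
    stop("ordinal categories must be coded 0..K-1 or 1..K")
  for (i in seq_len(m))
    if (any(Y[, i] < 0L | Y[, i] >= K[i]))
      stop("item ", colnames(Y)[i], ": category code outside 0..", K[i] - 1L)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(m))
  storage.mode(Y) <- "integer"
  attr(Y, "n_categories") <- K
  Y
}

#' Polychoric correlations with empirical asymptotic covariance
#'
#' Two-step pairwise estimation: univariate thresholds first, then each
#' pairwise correlation maximizes the bivariate-normal likelihood of the
#' observed contingency table given the fixed marginal thresholds. The
#' asymptotic covariance of the stacked correlation estimates is assembled
#' empirically from casewise pairwise-likelihood influence contributions.
#'
#' @param data ordinal response table.
#' @param n_categories category counts (see [estimate_thresholds()]).
#' @return an object of class `mgr_polychoric`: `thresholds`, `corr` (the
#'   m x m correlation matrix K), `kappa` (lower-triangle vector, column-major
#'   over pairs (i,s), i < s), `acov` (Gamma, the asymptotic covariance of
#'   sqrt(n) kappa-hat), `n`, `n_categories`.
#' @export
polychoric <- function(data, n_categories = NULL) {
  Y <- ordinal_matrix(data, n_categories)
  m <- ncol(Y)
  if (m < 2L) stop("polychoric correlations need at least 2 items")
  n <- nrow(Y)
  thr <- estimate_thresholds(Y, attr(Y, "n_categories"))
  P <- m * (m - 1L) / 2L
  rho <- numeric(P)
  infl <- matrix(0, n, P)  # casewise influence on each rho-hat
  Kmat <- diag(1, m)
  pair <- 0L
  pair_names <- character(P)
  clamped <- FALSE
  for (s in 2:m) for (i in seq_len(s - 1L)) {
    pair <- pair + 1L
    pair_names[pair] <- paste0(colnames(Y)[i], ":", colnames(Y)[s])
    tab <- table(factor(Y[, i], levels = 0:(length(thr[[i]]))),
                 factor(Y[, s], levels = 0:(length(thr[[s]]))))
    counts <- unclass(tab)
    opt <- stats::optimize(function(r)
      cpp_poly_table_loglik(counts, thr[[i]], thr[[s]], r),
      interval = c(-0.999, 0.999), maximum = TRUE, tol = 1e-8)
    r <- opt$maximum
    if (abs(r) > 0.9985) { r <- sign(r) * 0.999; clamped <- TRUE }
    rho[pair] <- r
    Kmat[i, s] <- Kmat[s, i] <- r
    # casewise score of the pairwise log-likelihood at rho-hat
    Pc <- cpp_poly_cell_probs(thr[[i]], thr[[s]], r)
    dPc <- cpp_poly_cell_dprobs(thr[[i]], thr[[s]], r)
    sc_cell <- dPc / Pc
    sc <- sc_cell[cbind(Y[, i] + 1L, Y[, s] + 1L)]
    info <- mean(sc^2)
    if (info < 1e-12) info <- 1e-12
    infl[, pair] <- sc / info
  }
  if (clamped)
    warning("boundary polychoric correlation clamped to +/-0.999")
  Gamma <- crossprod(infl) / n   # acov of sqrt(n) (kappa-hat - kappa)
  names(rho) <- pair_names
  dimnames(Gamma) <- list(pair_names, pair_names)
  dimnames(Kmat) <- list(colnames(Y), colnames(Y))
  structure(
    list(thresholds = thr, corr = Kmat, kappa = rho, acov = Gamma, n = n,
         n_categories = attr(Y, "n_categories"), items = colnames(Y)),
    class = "mgr_polychoric")
}

#' @export
print.mgr_polychoric <- function(x, digits = 3L, ...) {
  cat(sprintf("Polychoric summary: %d items, n = %d\n", length(x$items), x$n))
  print(round(x$corr, digits))
  invisible(x)
}

#' Weighted least squares fit to polychoric correlations
#'
#' Minimizes F_WLS(theta) = (kappa-hat - kappa(theta))' W (kappa-hat -
#' kappa(theta)), where kappa(theta) is the model-implied correlation vector
#' of the latent responses (unit-diagonal scaling; thresholds are estimated
#' in the first step and do not enter the minimand) and W is the inverse of
#' the empirical asymptotic covariance of kappa-hat (full WLS). A
#' diagonal-weights (DWLS) and an identity-weights variant are available;
#' both deviate from the full-weight definition and are labelled as such.
#'
#' @param spec an ordinal [mgr_spec()].
#' @param summary an [polychoric()] summary (or an ordinal response table,
#'   which is summarized first).
#' @param weights `"full"` (default), `"diagonal"`, or `"identity"`.
#' @param conf_level confidence level for the RMSEA interval.
#' @return an object of class `mgr_wls`: `theta` (thresholds + latent
#'   covariances at the optimum), `fwls`, `chi2` (= n * F_WLS), `df`,
#'   `p_value`, `rmsea`, `rmsea_ci`, `n`, `converged`, `weights`.
#' @export
fit_wls <- function(spec, summary, weights = c("full", "diagonal", "identity"),
                    conf_level = 0.95) {
  stopifnot(inherits(spec, "mgr_spec"))
  if (spec$response != "ordinal")
    stop("fit_wls applies to ordinal specifications")
  weights <- match.arg(weights)
  if (!inherits(summary, "mgr_polychoric"))
    summary <- polychoric(summary, spec$n_categories)
  m <- length(spec$items)
  if (length(summary$items) != m) stop("summary does not match spec")
  P <- m * (m - 1L) / 2L
  k_struct <- n_structural_parameters(spec)
  df <- P - k_struct
  if (df <= 0) stop("model not testable (df <= 0)")

  W <- switch(weights,
    full = {
      G <- summary$acov
      Wf <- tryCatch(solve(G), error = function(e) NULL)
      tries <- 0L
      while (is.null(Wf) && tries < 6L) {
        tries <- tries + 1L
        G <- G + diag(1e-8 * 10^tries * mean(diag(G)), P)
        Wf <- tryCatch(solve(G), error = function(e) NULL)
      }
      if (is.null(Wf)) stop("weight matrix could not be inverted")
      Wf
    },
    diagonal = diag(1 / pmax(diag(summary$acov), 1e-12), P),
    identity = diag(1, P))

  sspec <- structural_spec(spec)
  map <- ml_param_map(sspec)
  kap_hat <- summary$kappa
  objective <- function(x) {
    pc <- ml_unpack(x, sspec, map)
    kap <- implied_kappa(pc$Lambda, pc$Phi)
    d <- kap_hat - kap
    sum(d * (W %*% d))
  }
  # analytic gradient for the common case: all loadings fixed, fully free
  # latent covariance (log-Cholesky block); otherwise numeric differences
  gradient <- NULL
  if (map$chol_mode && map$n_load == 0L) {
    Lam <- spec$loadings
    Lam[is.na(Lam)] <- 1
    p <- length(spec$latents)
    pair_ord <- lower_pair_order(m)
    Dlist <- list()  # dSigma/dPhi_gh as constant matrices, full-matrix view
    for (g in seq_len(p)) for (h in seq_len(g)) {
      E <- matrix(0, p, p)
      E[g, h] <- E[h, g] <- 1
      Dlist[[paste(g, h)]] <- Lam %*% E %*% t(Lam)
    }
    gradient <- function(x) {
      pc <- ml_unpack(x, sspec, map)
      Sig <- Lam %*% pc$Phi %*% t(Lam) + diag(m)
      dvec <- sqrt(diag(Sig))
      Kc <- Sig / (dvec %o% dvec)
      kap <- Kc[lower.tri(Kc)][pair_ord]
      res <- kap_hat - kap
      Wres <- as.numeric(W %*% res)
      flat <- matrix(0, p, p)
      for (g in seq_len(p)) for (h in seq_len(g)) {
        D <- Dlist[[paste(g, h)]]
        dd <- diag(D) / (2 * dvec)  # d d_i / dPhi_gh
        dK <- D / (dvec %o% dvec) -
          Sig * (outer(dd, dvec) + outer(dvec, dd)) / (dvec %o% dvec)^2
        dkap <- dK[lower.tri(dK)][pair_ord]
        flat[g, h] <- flat[h, g] <- -2 * sum(Wres * dkap)
      }
      Gphi <- flat
      Gphi[row(Gphi) != col(Gphi)] <- Gphi[row(Gphi) != col(Gphi)] / 2
      GL <- 2 * Gphi %*% pc$Lchol
      grad <- numeric(map$n_lc)
      idx <- 0L
      for (g in seq_len(p)) for (h in seq_len(g)) {
        idx <- idx + 1L
        grad[idx] <- if (g == h) GL[g, g] * pc$Lchol[g, g] else GL[g, h]
      }
      grad
    }
  }
  x0 <- wls_start_values(sspec, map, summary, spec)
  opt <- stats::optim(x0, objective, gradient, method = "BFGS",
                      control = list(maxit = 150L, reltol = 1e-12))
  if (opt$convergence != 0)
    opt <- stats::optim(opt$par, objective, gradient, method = "BFGS",
                        control = list(maxit = 150L, reltol = 1e-12))
  pc <- ml_unpack(opt$par, sspec, map)
  theta <- mgr_parameters(spec, thresholds = summary$thresholds,
                          loadings = pc$Lambda, latent_cov = pc$Phi,
                          validate = FALSE)
  fwls <- max(opt$value, 0)
  chi2 <- summary$n * fwls
  rms <- rmsea_point(chi2, df, summary$n)
  ci <- rmsea_confint(chi2, df, summary$n, conf_level)
  structure(
    list(theta = theta, fwls = fwls, chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         rmsea = rms, rmsea_ci = ci, n = summary$n,
         converged = TRUE, weights = weights, conf_level = conf_level),
    class = "mgr_wls")
}

# structural parameters entering kappa(theta): free loadings and free latent
# (co)variances; thresholds are first-step estimates
n_structural_parameters <- function(spec) {
  sum(is.na(spec$loadings)) +
    sum(is.na(spec$latent_cov[upper.tri(spec$latent_cov, diag = TRUE)]))
}

# numeric-view spec used only to reuse the optimizer parameter map for the
# structural block (no intercepts/residuals)
structural_spec <- function(spec) {
  s <- spec
  s$response <- "numeric"
  s$intercepts <- rep(0, length(spec$items))
  s$residuals <- rep(1, length(spec$items))
  names(s$intercepts) <- names(s$residuals) <- s$items
  s$n_categories <- NULL
  s
}

implied_kappa <- function(Lambda, Phi) {
  Sigma <- Lambda %*% Phi %*% t(Lambda) + diag(nrow(Lambda))
  Kc <- stats::cov2cor(Sigma)
  Kc[lower.tri(Kc)][lower_pair_order(nrow(Kc))]
}

# lower.tri() extracts column-major (columns i, rows s > i); our pair order is
# (i, s) for s = 2..m, i < s, i.e. pairs sorted by s then i. Map indices once.
lower_pair_order <- function(m) {
  lt <- which(lower.tri(matrix(0, m, m)), arr.ind = TRUE)  # (row=s, col=i)
  order_ours <- order(lt[, 1L], lt[, 2L])  # sort by s then i
  order_ours
}

wls_start_values <- function(sspec, map, summary, spec) {
  x <- ml_start_values(sspec, map, diag(length(sspec$items)))
  if (!map$chol_mode || map$n_load > 0L) return(x)
  # moment-matching start: the implied covariance is linear in Phi, so an
  # iterated unweighted least-squares solve (re-estimating the latent-response
  # scaling each pass) lands near the optimum
  Lam <- spec$loadings
  Lam[is.na(Lam)] <- 1
  m <- nrow(Lam); p <- ncol(Lam)
  pair_ord <- lower_pair_order(m)
  pairs <- which(lower.tri(matrix(0, m, m)), arr.ind = TRUE)[pair_ord, ,
                                                             drop = FALSE]
  P <- p * (p + 1L) / 2L
  A <- matrix(0, nrow(pairs), P)
  col <- 0L
  cols_gh <- matrix(0L, P, 2L)
  for (g in seq_len(p)) for (h in seq_len(g)) {
    col <- col + 1L
    cols_gh[col, ] <- c(g, h)
    s <- pairs[, 1L]; i <- pairs[, 2L]
    A[, col] <- if (g == h) Lam[i, g] * Lam[s, g]
                else Lam[i, g] * Lam[s, h] + Lam[i, h] * Lam[s, g]
  }
  d <- rep(1, m)
  phi <- NULL
  for (pass in 1:3) {
    target <- summary$kappa * d[pairs[, 2L]] * d[pairs[, 1L]]
    phi <- tryCatch(qr.solve(A, target), error = function(e) NULL)
    if (is.null(phi)) return(x)
    Phi0 <- matrix(0, p, p)
    for (c2 in seq_len(P)) {
      g <- cols_gh[c2, 1L]; h <- cols_gh[c2, 2L]
      Phi0[g, h] <- Phi0[h, g] <- phi[c2]
    }
    d <- sqrt(pmax(1 + diag(Lam %*% Phi0 %*% t(Lam)), 0.2))
  }
  # project to positive definite and convert to the log-Cholesky block
  ee <- eigen(Phi0, symmetric = TRUE)
  Phi0 <- ee$vectors %*% diag(pmax(ee$values, 1e-3), p) %*% t(ee$vectors)
  L <- tryCatch(t(chol(Phi0)), error = function(e) NULL)
  if (is.null(L)) return(x)
  lx <- numeric(0)
  for (g in seq_len(p)) for (h in seq_len(g))
    lx <- c(lx, if (g == h) log(max(L[g, h], 1e-4)) else L[g, h])
  x[map$n_load + seq_along(lx)] <- lx
  x
}

rmsea_point <- function(chi2, df, n) {
  if (df <= 0) return(NA_real_)
  sqrt(max(chi2 - df, 0) / (df * (n - 1)))
}

#' RMSEA confidence interval
#'
#' Interval from inverting the noncentral chi-square distribution of the test
#' statistic: the bounds are sqrt(lambda / (df (n - 1))) at the noncentrality
#' values where the observed statistic sits at the upper/lower tail
#' probability of the two-sided interval.
#'
#' @param chi2 test statistic. @param df degrees of freedom. @param n sample
#' size. @param conf_level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
rmsea_confint <- function(chi2, df, n, conf_level = 0.95) {
  if (df <= 0 || n <= 1) return(c(NA_real_, NA_real_))
  alpha <- (1 - conf_level) / 2
  ncp_for <- function(target) {
    # lambda with P(chisq_df(lambda) <= chi2) == target
    f <- function(l) stats::pchisq(chi2, df, ncp = l) - target
    if (f(0) < 0) return(0)
    hi <- max(chi2, df) + 10
    while (f(hi) > 0 && hi < 1e7) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  lo_ncp <- ncp_for(1 - alpha)
  hi_ncp <- ncp_for(alpha)
  c(sqrt(lo_ncp / (df * (n - 1))), sqrt(hi_ncp / (df * (n - 1))))
}

#' Fit indices of a WLS fit
#'
#' @param fit an [fit_wls()] object.
#' @return list with `chi2`, `df`, `p_value`, `rmsea`, `rmsea_ci`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "mgr_wls"))
  list(chi2 = fit$chi2, df = fit$df, p_value = fit$p_value,
       rmsea = fit$rmsea, rmsea_ci = fit$rmsea_ci)
}

#' @export
print.mgr_wls <- function(x, digits = 3L, ...) {
  cat(sprintf("WLS fit (%s weights): n = %d\n", x$weights, x$n))
  cat(sprintf("  chi2 = %.2f, df = %d, p = %.4f\n", x$chi2, x$df, x$p_value))
  cat(sprintf("  RMSEA = %.3f, %d%% CI [%.3f, %.3f]\n", x$rmsea,
              round(100 * x$conf_level), x$rmsea_ci[1], x$rmsea_ci[2]))
  invisible(x)
}

#' @export
coef.mgr_wls <- function(object, ...) flatten_parameters(object$theta)
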