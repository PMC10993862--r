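#' Limited-information maximum likelihood fit
#'
#' Fits a covariance-structure model by minimizing the ML discrepancy
#' F_ML(theta) = ln|Sigma(theta)| + tr(S Sigma(theta)^-1) - ln|S| - m,
#' where S is the sample covariance matrix. This is the tree-growing engine:
#' ordinal responses are accepted and treated as numeric scores (the spec is
#' converted to its numeric CFA twin via [as_numeric_spec()]), a deliberate
#' compromise that buys the casewise scores needed for instability testing.
#'
#' Free intercepts are profiled out at the sample means (they do not affect
#' F_ML). Variances are log-transformed during optimization and a fully free
#' latent covariance matrix is optimized through its Cholesky factor, so the
#' ordering/positivity invariants hold by construction.
#'
#' @param spec an [mgr_spec()]; ordinal specs are converted to the numeric
#'   twin for fitting.
#' @param data numeric matrix or data frame, n cases x m items. Columns are
#'   matched to `spec$items` by name when named.
#' @param start optional [mgr_parameters()] warm start.
#' @param control list: `maxit` (default 500), `reltol` (1e-12),
#'   `grad_tol` multiplier c in the convergence rule
#'   max|sum_j psi_j| <= c * n (default 1e-5), `restarts` (default 4).
#' @return an object of class `mgr_ml` with elements `theta`
#'   ([mgr_parameters()]), `fml`, `S`, `mean`, `n`, `converged`,
#'   `gradient_norm` (infinity norm of the casewise score column sums),
#'   `spec` (growth spec actually fitted), `input_spec`, and `data` (the
#'   response matrix used).
#' @export
fit_ml <- function(spec, data, start = NULL, control = list()) {
  stopifnot(inherits(spec, "mgr_spec"))
  input_spec <- spec
  spec <- as_numeric_spec(spec)
  ctl <- modifyList(list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-5,
                         restarts = 4L), control)
  Y <- as_response_matrix(data, spec$items)
  n <- nrow(Y); m <- ncol(Y)
  k <- count_free_parameters(spec)
  if (n <= k)
    stop("need more cases (n = ", n, ") than free parameters (k = ", k, ")")
  if (anyNA(Y)) stop("missing values in the response data are not supported")

  free_int <- is.na(spec$intercepts)
  if (any(free_int) && !all(free_int))
    stop("intercepts must be all free or all fixed")
  if (all(free_int)) {
    mu <- colMeans(Y)
  } else {
    mu <- spec$intercepts
  }
  R <- sweep(Y, 2L, mu)
  S <- crossprod(R) / n
  sch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(sch))
    stop("sample covariance matrix is singular; ",
         "more data or fewer items are needed")
  logdetS <- 2 * sum(log(diag(sch)))

  map <- ml_param_map(spec)
  x0 <- ml_start_values(spec, map, S, start)
  obj <- function(x) ml_objective(x, spec, map, S, logdetS)$value
  grd <- function(x) ml_objective(x, spec, map, S, logdetS)$grad

  opt <- stats::optim(x0, obj, grd, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  # BFGS restarts reset the Hessian approximation and polish the gradient
  # (transformed scale: at a boundary optimum — e.g. a singular latent
  # covariance — the natural-scale gradient cannot vanish, but the
  # log-Cholesky gradient does)
  for (r in seq_len(ctl$restarts)) {
    g <- grd(opt$par)
    if (max(abs(g)) <= 2 * ctl$grad_tol) break
    opt <- stats::optim(opt$par, obj, grd, method = "BFGS",
                        control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  }
  pieces <- ml_unpack(opt$par, spec, map)
  theta <- mgr_parameters(spec, intercepts = mu, loadings = pieces$Lambda,
                          latent_cov = pieces$Phi,
                          residual_var = pieces$theta_diag,
                          validate = FALSE)
  natural_grad <- ml_natural_gradient(theta, spec, S)
  # sum_j psi_j = -(n/2) dF/dtheta for covariance parameters; mean scores sum
  # to zero exactly at the profiled means
  score_sum_norm <- max(abs(natural_grad)) * n / 2
  interior_ok <- score_sum_norm <= ctl$grad_tol * n
  trans_ok <- is.finite(opt$value) && max(abs(grd(opt$par))) <= 2 * ctl$grad_tol
  # a vanishing log-Cholesky gradient with non-vanishing natural score sums
  # is a boundary optimum (near-singular latent covariance)
  converged <- interior_ok || trans_ok
  boundary <- trans_ok && !interior_ok
  structure(
    list(theta = theta, fml = opt$value, S = S, mean = mu, n = n,
         converged = converged, boundary = boundary,
         gradient_norm = score_sum_norm,
         spec = spec, input_spec = input_spec, data = Y),
    class = "mgr_ml")
}

#' @export
print.mgr_ml <- function(x, digits = 4L, ...) {
  cat(sprintf("Limited-information ML fit: n = %d, %d free parameters\n",
              x$n, count_free_parameters(x$spec)))
  cat(sprintf("  F_ML = %.*f  (converged: %s, max |score sum| = %.2e)\n",
              digits, x$fml, x$converged, x$gradient_norm))
  invisible(x)
}

#' @export
coef.mgr_ml <- function(object, ...) flatten_parameters(object$theta)

#' @export
logLik.mgr_ml <- function(object, ...) {
  ll <- sum(casewise_loglik(object))
  structure(ll, df = count_free_parameters(object$spec), nobs = object$n,
            class = "logLik")
}

# ---- internals -------------------------------------------------------------

as_response_matrix <- function(data, items) {
  Y <- as.matrix(as.data.frame(data))
  if (!is.numeric(Y)) stop("response data must be numeric")
  if (!is.null(colnames(Y)) && all(items %in% colnames(Y)))
    Y <- Y[, items, drop = FALSE]
  if (ncol(Y) != length(items))
    stop("expected ", length(items), " response columns")
  colnames(Y) <- items
  Y
}

# Optimizer parameter map. Modes:
#  - latent covariance fully free -> log-Cholesky block
#  - otherwise element-wise (log variances, raw covariances) with a PD barrier
ml_param_map <- function(spec) {
  p <- length(spec$latents)
  free_load <- which(is.na(spec$loadings), arr.ind = TRUE)
  if (nrow(free_load))
    free_load <- free_load[order(free_load[, 1L], free_load[, 2L]), , drop = FALSE]
  chol_mode <- all(is.na(spec$latent_cov))
  n_lc <- if (chol_mode) p * (p + 1L) / 2L else sum(is.na(spec$latent_cov[upper.tri(spec$latent_cov, diag = TRUE)]))
  free_res <- which(is.na(spec$residuals))
  list(p = p, free_load = free_load, chol_mode = chol_mode,
       n_load = nrow(free_load), n_lc = n_lc, free_res = free_res,
       n_res = length(free_res),
       n_par = nrow(free_load) + n_lc + length(free_res))
}

ml_unpack <- function(x, spec, map) {
  p <- map$p
  Lambda <- spec$loadings
  Lambda[is.na(Lambda)] <- 1
  pos <- 0L
  if (map$n_load) {
    Lambda[map$free_load] <- x[seq_len(map$n_load)]
    pos <- map$n_load
  }
  if (map$chol_mode) {
    L <- matrix(0, p, p)
    lx <- x[pos + seq_len(map$n_lc)]
    pos <- pos + map$n_lc
    idx <- 0L
    for (g in seq_len(p)) for (h in seq_len(g)) {
      idx <- idx + 1L
      L[g, h] <- if (g == h) exp(lx[idx]) else lx[idx]
    }
    Phi <- L %*% t(L)
    Lchol <- L
  } else {
    Phi <- spec$latent_cov
    for (g in seq_len(p)) if (is.na(Phi[g, g])) {
      pos <- pos + 1L; Phi[g, g] <- exp(x[pos])
    }
    if (p > 1L) for (h in 2:p) for (g in seq_len(h - 1L))
      if (is.na(Phi[g, h])) {
        pos <- pos + 1L; Phi[g, h] <- Phi[h, g] <- x[pos]
      }
    Lchol <- NULL
  }
  theta_diag <- if (spec$response == "numeric") {
    td <- spec$residuals
    free <- map$free_res
    if (length(free)) td[free] <- exp(x[pos + seq_along(free)])
    td
  } else rep(1, nrow(Lambda))
  list(Lambda = Lambda, Phi = Phi, theta_diag = theta_diag, Lchol = Lchol)
}

ml_start_values <- function(spec, map, S, start = NULL) {
  p <- map$p
  if (!is.null(start)) {
    stopifnot(inherits(start, "mgr_parameters"))
    x <- numeric(0)
    if (map$n_load) x <- c(x, start$loadings[map$free_load])
    if (map$chol_mode) {
      L <- t(chol(start$latent_cov))
      lx <- numeric(0)
      for (g in seq_len(p)) for (h in seq_len(g))
        lx <- c(lx, if (g == h) log(max(L[g, h], 1e-6)) else L[g, h])
      x <- c(x, lx)
    } else {
      Phi <- start$latent_cov
      for (g in seq_len(p)) if (is.na(spec$latent_cov[g, g]))
        x <- c(x, log(max(Phi[g, g], 1e-6)))
      if (p > 1L) for (h in 2:p) for (g in seq_len(h - 1L))
        if (is.na(spec$latent_cov[g, h])) x <- c(x, Phi[g, h])
    }
    if (map$n_res) x <- c(x, log(pmax(start$residual_var[map$free_res], 1e-6)))
    return(x)
  }
  x <- numeric(0)
  if (map$n_load) x <- c(x, rep(1, map$n_load))
  avg_var <- mean(diag(S))
  if (map$chol_mode) {
    lx <- numeric(0)
    for (g in seq_len(p)) for (h in seq_len(g))
      lx <- c(lx, if (g == h) log(sqrt(0.25 * avg_var)) else 0)
    x <- c(x, lx)
  } else {
    for (g in seq_len(p)) if (is.na(spec$latent_cov[g, g]))
      x <- c(x, log(0.25 * avg_var))
    if (p > 1L) for (h in 2:p) for (g in seq_len(h - 1L))
      if (is.na(spec$latent_cov[g, h])) x <- c(x, 0)
  }
  if (map$n_res) x <- c(x, log(pmax(diag(S)[map$free_res] / 2, 1e-6)))
  x
}

ml_objective <- function(x, spec, map, S, logdetS) {
  pc <- ml_unpack(x, spec, map)
  Sigma <- pc$Lambda %*% pc$Phi %*% t(pc$Lambda) + diag(pc$theta_diag, nrow(pc$Lambda))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch))
    return(list(value = 1e10 + sum(x^2), grad = 2 * x))
  Sinv <- chol2inv(ch)
  val <- 2 * sum(log(diag(ch))) + sum(Sinv * S) - logdetS - nrow(S)
  G <- Sinv - Sinv %*% S %*% Sinv  # dF/dSigma
  grad <- numeric(map$n_par)
  pos <- 0L
  if (map$n_load) {
    GLP <- 2 * G %*% pc$Lambda %*% pc$Phi
    grad[seq_len(map$n_load)] <- GLP[map$free_load]
    pos <- map$n_load
  }
  Gphi <- t(pc$Lambda) %*% G %*% pc$Lambda  # full-matrix dF/dPhi
  p <- map$p
  if (map$chol_mode) {
    GL <- 2 * Gphi %*% pc$Lchol
    idx <- 0L
    for (g in seq_len(p)) for (h in seq_len(g)) {
      idx <- idx + 1L
      grad[pos + idx] <- if (g == h) GL[g, g] * pc$Lchol[g, g] else GL[g, h]
    }
    pos <- pos + map$n_lc
  } else {
    for (g in seq_len(p)) if (is.na(spec$latent_cov[g, g])) {
      pos <- pos + 1L
      grad[pos] <- Gphi[g, g] * pc$Phi[g, g]  # chain rule for log
    }
    if (p > 1L) for (h in 2:p) for (g in seq_len(h - 1L))
      if (is.na(spec$latent_cov[g, h])) {
        pos <- pos + 1L
        grad[pos] <- 2 * Gphi[g, h]
      }
  }
  if (map$n_res) {
    grad[pos + seq_len(map$n_res)] <-
      diag(G)[map$free_res] * pc$theta_diag[map$free_res]
  }
  list(value = val, grad = grad)
}

# dF_ML/dtheta on the natural (flat, free) parameter scale, means excluded
# (profiled at sample means, where their gradient vanishes exactly).
ml_natural_gradient <- function(theta, spec, S) {
  Lambda <- theta$loadings; Phi <- theta$latent_cov
  Theta <- diag(theta$residual_var, nrow(Lambda))
  Sigma <- Lambda %*% Phi %*% t(Lambda) + Theta
  Sinv <- solve(Sigma)
  G <- Sinv - Sinv %*% S %*% Sinv
  out <- numeric(0)
  free_load <- which(is.na(spec$loadings), arr.ind = TRUE)
  if (nrow(free_load)) {
    free_load <- free_load[order(free_load[, 1L], free_load[, 2L]), , drop = FALSE]
    GLP <- 2 * G %*% Lambda %*% Phi
    out <- c(out, GLP[free_load])
  }
  Gphi <- t(Lambda) %*% G %*% Lambda
  p <- length(spec$latents)
  for (g in seq_len(p)) if (is.na(spec$latent_cov[g, g]))
    out <- c(out, Gphi[g, g])
  if (p > 1L) for (h in 2:p) for (g in seq_len(h - 1L))
    if (is.na(spec$latent_cov[g, h])) out <- c(out, 2 * Gphi[g, h])
  free_res <- which(is.na(spec$residuals))
  if (length(free_res)) out <- c(out, diag(G)[free_res])
  out
}

#' Casewise log-likelihood contributions
#'
#' Per-case multivariate-normal kernel log-likelihoods at the fitted
#' parameters: lnL_j = -(1/2) (ln|Sigma| + (y_j - pi)' Sigma^-1 (y_j - pi)).
#' The additive constant -(m/2) ln(2 pi) is omitted; it cancels in all
#' differences, scores and likelihood-ratio statistics.
#'
#' @param fit a converged [fit_ml()] object.
#' @param data optional response data (defaults to the data stored in `fit`).
#' @return numeric vector of length n.
#' @export
casewise_loglik <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mgr_ml"))
  if (!fit$converged) stop("fit did not converge")
  Y <- if (is.null(data)) fit$data else as_response_matrix(data, fit$spec$items)
  if (anyNA(Y)) stop("missing values are not supported")
  mom <- implied_moments(fit$spec, fit$theta)
  Sinv <- solve(mom$cov)
  logdet <- determinant(mom$cov, logarithm = TRUE)$modulus[1]
  Rc <- sweep(Y, 2L, mom$mean)
  -0.5 * (logdet + rowSums((Rc %*% Sinv) * Rc))
}

#' Casewise score matrix
#'
#' The n x k matrix of derivatives of the casewise log-likelihood (see
#' [casewise_loglik()]) with respect to the free model parameters at the
#' fitted values. Columns follow [free_parameter_names()] of the growth spec.
#' At a converged fit the column sums vanish (the M-estimation equations).
#'
#' @param fit a converged [fit_ml()] object.
#' @param data optional response data (defaults to the data stored in `fit`).
#' @param vartheta if `TRUE`, drop the residual-variance and intercept
#'   columns, retaining only the item-parameter block (loadings and latent
#'   (co)variances) — the scores with respect to the item parameter vector.
#' @return matrix with attribute `param_names`.
#' @export
score_matrix <- function(fit, data = NULL, vartheta = FALSE) {
  stopifnot(inherits(fit, "mgr_ml"))
  if (!fit$converged)
    stop("score test undefined off the optimum: fit did not converge")
  spec <- fit$spec
  Y <- if (is.null(data)) fit$data else as_response_matrix(data, spec$items)
  theta <- fit$theta
  Lambda <- theta$loadings; Phi <- theta$latent_cov
  Sigma <- Lambda %*% Phi %*% t(Lambda) + diag(theta$residual_var, nrow(Lambda))
  Sinv <- solve(Sigma)
  Rc <- sweep(Y, 2L, theta$intercepts)
  Q <- Rc %*% Sinv                      # q_j' rows
  U <- Q %*% Lambda                     # (Lambda' q_j)' rows
  C0 <- t(Lambda) %*% Sinv %*% Lambda
  K0 <- Sinv %*% Lambda %*% Phi
  V <- Q %*% Lambda %*% Phi
  p <- length(spec$latents)
  nm <- free_parameter_names(spec)
  cols <- vector("list", length(nm))
  pos <- 0L
  free_int <- which(is.na(spec$intercepts))
  for (i in free_int) { pos <- pos + 1L; cols[[pos]] <- Q[, i] }
  free_load <- which(is.na(spec$loadings), arr.ind = TRUE)
  if (nrow(free_load)) {
    free_load <- free_load[order(free_load[, 1L], free_load[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(free_load))) {
      i <- free_load[r, 1L]; g <- free_load[r, 2L]
      pos <- pos + 1L
      cols[[pos]] <- -K0[i, g] + Q[, i] * V[, g]
    }
  }
  for (g in seq_len(p)) if (is.na(spec$latent_cov[g, g])) {
    pos <- pos + 1L
    cols[[pos]] <- -0.5 * (C0[g, g] - U[, g]^2)
  }
  if (p > 1L) for (h in 2:p) for (g in seq_len(h - 1L))
    if (is.na(spec$latent_cov[g, h])) {
      pos <- pos + 1L
      cols[[pos]] <- -(C0[g, h] - U[, g] * U[, h])
    }
  free_res <- which(is.na(spec$residuals))
  for (i in free_res) {
    pos <- pos + 1L
    cols[[pos]] <- -0.5 * (Sinv[i, i] - Q[, i]^2)
  }
  psi <- do.call(cbind, cols)
  colnames(psi) <- nm
  if (vartheta) {
    keep <- !grepl("^(pi|psi)\\.", nm)
    psi <- psi[, keep, drop = FALSE]
  }
  attr(psi, "param_names") <- colnames(psi)
  psi
}

#' Likelihood-ratio test of a template against a two-group augmented model
#'
#' Tests whether letting all free parameters differ between two disjoint
#' subsamples (the augmented model) outperforms the pooled template fit.
#'
#' @param template [fit_ml()] on the pooled data.
#' @param augmented_left,augmented_right [fit_ml()] objects of the same spec
#'   on the two parts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(template, augmented_left, augmented_right) {
  stopifnot(inherits(template, "mgr_ml"))
  same <- function(a, b)
    identical(a$spec$items, b$spec$items) &&
      identical(dim(a$spec$loadings), dim(b$spec$loadings))
  if (!same(template, augmented_left) || !same(template, augmented_right))
    stop("all three fits must share the same specification")
  if (augmented_left$n + augmented_right$n != template$n)
    stop("the two augmented fits must partition the template sample")
  ll <- function(f) sum(casewise_loglik(f))
  stat <- 2 * (ll(augmented_left) + ll(augmented_right) - ll(template))
  stat <- max(stat, 0)
  df <- count_free_parameters(template$spec)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fit indices for an ML covariance-structure fit
#'
#' chi2 = n * F_ML against the saturated covariance model;
#' df = m(m+1)/2 minus the number of free covariance-structure parameters
#' (loadings, latent (co)variances, residual variances; intercepts are
#' saturated and contribute nothing). Used to evaluate terminal nodes of
#' numeric-response trees, where no WLS refit applies.
#'
#' @param fit an [fit_ml()] object.
#' @param conf_level confidence level for the RMSEA interval.
#' @return list with `chi2`, `df`, `p_value`, `rmsea`, `rmsea_ci`.
#' @export
ml_fit_indices <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "mgr_ml"))
  spec <- fit$spec
  m <- length(spec$items)
  k_cov <- sum(is.na(spec$loadings)) +
    sum(is.na(spec$latent_cov[upper.tri(spec$latent_cov, diag = TRUE)])) +
    sum(is.na(spec$residuals))
  df <- m * (m + 1) / 2 - k_cov
  if (df <= 0) stop("model not testable (df <= 0)")
  chi2 <- fit$n * fit$fml
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       rmsea = rmsea_point(chi2, df, fit$n),
       rmsea_ci = rmsea_confint(chi2, df, fit$n, conf_level))
}
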