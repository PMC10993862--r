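#' Structured model parameters
#'
#' Container for a full parameter set of a measurement model: thresholds
#' (ordinal) or intercepts (numeric), loadings, the latent covariance matrix,
#' and residual variances (numeric). Fixed entries of the specification must
#' be present at their fixed values; free entries carry the current values.
#'
#' @param spec an [mgr_spec()].
#' @param thresholds list (length m) of strictly increasing numeric vectors,
#'   one per item (ordinal specs).
#' @param intercepts numeric vector of length m (numeric specs).
#' @param loadings m x p matrix of loading values (defaults to the fixed
#'   pattern with free entries at 1).
#' @param latent_cov p x p positive-definite latent covariance matrix.
#' @param residual_var positive numeric vector of length m (numeric specs).
#' @param validate check invariants (ordering, positive definiteness)?
#' @return an object of class `mgr_parameters`.
#' @export
mgr_parameters <- function(spec, thresholds = NULL, intercepts = NULL,
                           loadings = NULL, latent_cov = NULL,
                           residual_var = NULL, validate = TRUE) {
  stopifnot(inherits(spec, "mgr_spec"))
  m <- length(spec$items); p <- length(spec$latents)
  if (is.null(loadings)) {
    loadings <- spec$loadings
    loadings[is.na(loadings)] <- 1
  }
  loadings <- as.matrix(loadings)
  dimnames(loadings) <- dimnames(spec$loadings)
  if (is.null(latent_cov)) {
    latent_cov <- spec$latent_cov
    latent_cov[is.na(latent_cov)] <- 0
    diag(latent_cov)[diag(is.na(spec$latent_cov))] <- 1
  }
  latent_cov <- as.matrix(latent_cov)
  dimnames(latent_cov) <- dimnames(spec$latent_cov)
  if (spec$response == "ordinal") {
    if (is.null(thresholds))
      thresholds <- lapply(spec$n_categories, function(K)
        stats::qnorm(seq_len(K - 1L) / K))
    names(thresholds) <- spec$items
    intercepts <- NULL; residual_var <- NULL
  } else {
    thresholds <- NULL
    if (is.null(intercepts)) {
      intercepts <- spec$intercepts
      intercepts[is.na(intercepts)] <- 0
    }
    if (is.null(residual_var)) {
      residual_var <- spec$residuals
      residual_var[is.na(residual_var)] <- 1
    }
    names(intercepts) <- names(residual_var) <- spec$items
  }
  out <- structure(
    list(thresholds = thresholds, intercepts = intercepts,
         loadings = loadings, latent_cov = latent_cov,
         residual_var = residual_var, spec = spec),
    class = "mgr_parameters")
  if (validate) validate_parameters(out)
  out
}

validate_parameters <- function(theta) {
  spec <- theta$spec
  if (spec$response == "ordinal") {
    for (i in seq_along(spec$items)) {
      a <- theta$thresholds[[i]]
      if (length(a) != spec$n_categories[i] - 1L)
        stop("item ", spec$items[i], ": expected ",
             spec$n_categories[i] - 1L, " thresholds")
      if (any(diff(a) <= 0))
        stop("item ", spec$items[i], ": thresholds must be strictly increasing")
    }
  } else {
    if (any(theta$residual_var <= 0)) stop("residual variances must be positive")
  }
  fixed <- !is.na(spec$loadings)
  if (any(abs(theta$loadings[fixed] - spec$loadings[fixed]) > 1e-10))
    stop("fixed loadings altered")
  ev <- eigen(theta$latent_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent covariance matrix must be positive definite")
  invisible(theta)
}

#' Flatten free parameters to a named vector
#'
#' Extracts the free entries of a structured parameter set in the
#' deterministic flat order of [free_parameter_names()]. The round trip with
#' [unflatten_parameters()] is the identity.
#'
#' @param theta an [mgr_parameters()] object.
#' @return named numeric vector of length [count_free_parameters()].
#' @export
flatten_parameters <- function(theta) {
  stopifnot(inherits(theta, "mgr_parameters"))
  spec <- theta$spec
  p <- length(spec$latents)
  x <- numeric(0)
  if (spec$response == "ordinal") {
    x <- c(x, unlist(theta$thresholds, use.names = FALSE))
  } else {
    x <- c(x, theta$intercepts[is.na(spec$intercepts)])
  }
  idx <- which(is.na(spec$loadings), arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    x <- c(x, theta$loadings[idx])
  }
  for (g in seq_len(p))
    if (is.na(spec$latent_cov[g, g])) x <- c(x, theta$latent_cov[g, g])
  if (p > 1L)
    for (h in 2:p) for (g in seq_len(h - 1L))
      if (is.na(spec$latent_cov[g, h])) x <- c(x, theta$latent_cov[g, h])
  if (spec$response == "numeric")
    x <- c(x, theta$residual_var[is.na(spec$residuals)])
  stats::setNames(as.numeric(x), free_parameter_names(spec))
}

#' Rebuild structured parameters from a flat vector
#'
#' @param spec an [mgr_spec()].
#' @param x numeric vector in the order of [free_parameter_names()].
#' @param validate check invariants?
#' @return an [mgr_parameters()] object.
#' @export
unflatten_parameters <- function(spec, x, validate = TRUE) {
  stopifnot(inherits(spec, "mgr_spec"))
  nm <- free_parameter_names(spec)
  if (length(x) != length(nm))
    stop("expected ", length(nm), " free parameters, got ", length(x))
  m <- length(spec$items); p <- length(spec$latents)
  pos <- 0L
  take <- function(k) {
    v <- x[pos + seq_len(k)]; pos <<- pos + k; v
  }
  thresholds <- NULL; intercepts <- NULL; residual_var <- NULL
  if (spec$response == "ordinal") {
    thresholds <- lapply(seq_len(m), function(i) take(spec$n_categories[i] - 1L))
    names(thresholds) <- spec$items
  } else {
    intercepts <- spec$intercepts
    free <- is.na(intercepts)
    intercepts[free] <- take(sum(free))
  }
  loadings <- spec$loadings
  idx <- which(is.na(spec$loadings), arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    loadings[idx] <- take(nrow(idx))
  }
  latent_cov <- spec$latent_cov
  for (g in seq_len(p))
    if (is.na(latent_cov[g, g])) latent_cov[g, g] <- take(1L)
  if (p > 1L)
    for (h in 2:p) for (g in seq_len(h - 1L))
      if (is.na(latent_cov[g, h]))
        latent_cov[g, h] <- latent_cov[h, g] <- take(1L)
  latent_cov[is.na(latent_cov)] <- t(latent_cov)[is.na(latent_cov)]
  if (spec$response == "numeric") {
    residual_var <- spec$residuals
    free <- is.na(residual_var)
    residual_var[free] <- take(sum(free))
  }
  mgr_parameters(spec, thresholds = thresholds, intercepts = intercepts,
                 loadings = loadings, latent_cov = latent_cov,
                 residual_var = residual_var, validate = validate)
}

#' @export
print.mgr_parameters <- function(x, digits = 3L, ...) {
  v <- flatten_parameters(x)
  cat(sprintf("MGR parameters (%d free):\n", length(v)))
  print(round(v, digits))
  invisible(x)
}
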