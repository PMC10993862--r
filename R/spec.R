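#' Measurement-model specification
#'
#' Defines a multidimensional graded response (MGR) or confirmatory factor
#' analysis (CFA) measurement model: which items load on which latent
#' variables, which loadings/variances are free or fixed, and whether the
#' response scale is ordinal (probit thresholds) or numeric (intercepts and
#' residual variances).
#'
#' @param loadings an m x p numeric matrix; `NA` entries mark free loadings,
#'   numeric entries are fixed values (typically 1). Row names are item names,
#'   column names latent-variable names.
#' @param response `"ordinal"` or `"numeric"`.
#' @param n_categories integer vector (length 1 or m) of category counts per
#'   item; required for ordinal specs. Categories are coded 0..K-1 internally;
#'   readers accept 1-based data and shift.
#' @param latent_cov a p x p matrix with `NA` for free entries and numbers for
#'   fixed values, or the string `"free"` (all variances and covariances free).
#' @param intercepts (numeric response) `"free"` or a numeric vector of fixed
#'   values.
#' @param residuals (numeric response) `"free"` or a numeric vector of fixed
#'   residual variances.
#'
#' @details
#' Identification follows the usual anchoring rule: for each latent variable,
#' its variance must be fixed (at 1) exactly when the first item loading on it
#' is free, and must be free when all its loadings are fixed. Ordinal specs
#' carry one free threshold fewer than the number of categories for every item;
#' the latent responses have unit-variance uniqueness by convention (probit
#' link), so ordinal specs have no residual-variance parameters.
#'
#' @return an object of class `mgr_spec`.
#' @seealso [pieg_spec()], [as_numeric_spec()], [count_free_parameters()]
#' @export
mgr_spec <- function(loadings, response = c("ordinal", "numeric"),
                     n_categories = NULL, latent_cov = "free",
                     intercepts = "free", residuals = "free") {
  response <- match.arg(response)
  loadings <- as.matrix(loadings)
  m <- nrow(loadings)
  p <- ncol(loadings)
  if (m < 1L || p < 1L) stop("need at least one item and one latent variable")
  if (is.null(rownames(loadings))) rownames(loadings) <- paste0("y", seq_len(m))
  if (is.null(colnames(loadings))) colnames(loadings) <- paste0("xi", seq_len(p))
  nonzero <- is.na(loadings) | loadings != 0
  if (any(rowSums(nonzero) == 0))
    stop("every item must have at least one nonzero loading")

  if (identical(latent_cov, "free")) {
    latent_cov <- matrix(NA_real_, p, p)
  }
  latent_cov <- as.matrix(latent_cov)
  if (!all(dim(latent_cov) == c(p, p))) stop("latent_cov must be p x p")
  if (!isTRUE(all.equal(latent_cov, t(latent_cov))) &&
      !all(is.na(latent_cov) == t(is.na(latent_cov)) &
           (is.na(latent_cov) | latent_cov == t(latent_cov))))
    stop("latent_cov structure must be symmetric")
  dimnames(latent_cov) <- list(colnames(loadings), colnames(loadings))

  # identification: Var(xi_g) fixed at 1 iff the first loading on g is free
  for (g in seq_len(p)) {
    rows <- which(nonzero[, g])
    first_free <- is.na(loadings[rows[1L], g])
    var_free <- is.na(latent_cov[g, g])
    if (first_free && var_free)
      stop("latent variable ", colnames(loadings)[g],
           ": both its variance and its anchoring loading are free ",
           "(model not identified)")
    if (!first_free && !var_free)
      stop("latent variable ", colnames(loadings)[g],
           ": both its variance and its anchoring loading are fixed ",
           "(fix one, free the other)")
    if (first_free && !var_free && latent_cov[g, g] != 1)
      stop("an anchoring latent variance must be fixed at 1")
  }

  if (response == "ordinal") {
    if (is.null(n_categories)) stop("ordinal specs need n_categories")
    n_categories <- as.integer(rep(n_categories, length.out = m))
    if (any(n_categories < 2L)) stop("every item needs at least 2 categories")
    intercepts <- NULL
    residuals <- NULL
  } else {
    n_categories <- NULL
    if (identical(intercepts, "free")) {
      intercepts <- rep(NA_real_, m)
    } else {
      intercepts <- rep(as.numeric(intercepts), length.out = m)
    }
    if (identical(residuals, "free")) {
      residuals <- rep(NA_real_, m)
    } else {
      residuals <- rep(as.numeric(residuals), length.out = m)
      if (any(residuals <= 0, na.rm = TRUE))
        stop("fixed residual variances must be positive")
    }
    names(intercepts) <- names(residuals) <- rownames(loadings)
  }

  structure(
    list(loadings = loadings, response = response,
         n_categories = n_categories, latent_cov = latent_cov,
         intercepts = intercepts, residuals = residuals,
         items = rownames(loadings), latents = colnames(loadings)),
    class = "mgr_spec")
}

#' @export
print.mgr_spec <- function(x, ...) {
  m <- length(x$items); p <- length(x$latents)
  cat(sprintf("MGR model spec: %d %s items, %d latent variable%s\n",
              m, x$response, p, if (p > 1) "s" else ""))
  if (x$response == "ordinal")
    cat("  categories per item:", paste(x$n_categories, collapse = " "), "\n")
  cat("  free parameters:", count_free_parameters(x), "\n")
  cat("  flat order:\n")
  nm <- free_parameter_names(x)
  cat(strwrap(paste(nm, collapse = ", "), width = 76, indent = 4,
              exdent = 4), sep = "\n")
  invisible(x)
}

#' Count the free parameters of a specification
#'
#' Counts entries marked free across thresholds (ordinal) or intercepts
#' (numeric), loadings, latent variances/covariances, and residual variances
#' (numeric). This equals the length of the flat free-parameter vector and the
#' column count of the casewise score matrix.
#'
#' @param spec an [mgr_spec()].
#' @return integer count.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "mgr_spec"))
  length(free_parameter_names(spec))
}

#' Names of the free parameters, in flat order
#'
#' The deterministic flat order is: thresholds (ordinal, item-major) or free
#' intercepts (numeric), free loadings (item-major), latent variances, latent
#' covariances (lower triangle, column-major), free residual variances
#' (numeric).
#'
#' @param spec an [mgr_spec()].
#' @return character vector of parameter names.
#' @export
free_parameter_names <- function(spec) {
  stopifnot(inherits(spec, "mgr_spec"))
  m <- length(spec$items); p <- length(spec$latents)
  nm <- character(0)
  if (spec$response == "ordinal") {
    for (i in seq_len(m))
      nm <- c(nm, paste0("alpha.", spec$items[i], ".", seq_len(spec$n_categories[i] - 1L)))
  } else {
    free <- which(is.na(spec$intercepts))
    nm <- c(nm, if (length(free)) paste0("pi.", spec$items[free]))
  }
  idx <- which(is.na(spec$loadings), arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    nm <- c(nm, paste0("beta.", spec$items[idx[, 1L]], ".", spec$latents[idx[, 2L]]))
  }
  for (g in seq_len(p))
    if (is.na(spec$latent_cov[g, g]))
      nm <- c(nm, paste0("var.", spec$latents[g]))
  if (p > 1L)
    for (h in 2:p) for (g in seq_len(h - 1L))
      if (is.na(spec$latent_cov[g, h]))
        nm <- c(nm, paste0("cov.", spec$latents[g], ".", spec$latents[h]))
  if (spec$response == "numeric") {
    free <- which(is.na(spec$residuals))
    nm <- c(nm, if (length(free)) paste0("psi.", spec$items[free]))
  }
  nm
}

#' PIEG measurement model
#'
#' Builds the probit multistate IRT model with latent item-effect variables
#' (PIEG) used as the data-generating and analysis model: one reference latent
#' state variable per time point, one item-effect latent per non-reference
#' item (shared across time points), all discrimination parameters fixed at 1,
#' all thresholds free, and a fully free latent covariance matrix.
#'
#' Items are laid out time-point major: `y<t>.<i>` is item i at time t; item 1
#' is the reference item of each time point and loads only on the state latent
#' `eta<t>`; item i > 1 additionally loads on its item-effect latent `b<i>`.
#'
#' @param n_timepoints number of time points (state latents).
#' @param n_items_per_timepoint items per time point (>= 1).
#' @param n_categories ordered categories per item (>= 2).
#' @return an ordinal [mgr_spec()].
#' @export
pieg_spec <- function(n_timepoints = 3L, n_items_per_timepoint = 3L,
                      n_categories = 5L) {
  Tn <- as.integer(n_timepoints); In <- as.integer(n_items_per_timepoint)
  if (Tn < 1L || In < 1L) stop("counts must be >= 1")
  if (n_categories < 2L) stop("need at least 2 categories")
  m <- Tn * In
  p <- Tn + max(In - 1L, 0L)
  latents <- c(paste0("eta", seq_len(Tn)),
               if (In > 1L) paste0("b", 2:In))
  items <- as.vector(outer(seq_len(In), seq_len(Tn),
                           function(i, t) paste0("y", t, ".", i)))
  L <- matrix(0, m, p, dimnames = list(items, latents))
  for (t in seq_len(Tn)) for (i in seq_len(In)) {
    row <- (t - 1L) * In + i
    L[row, t] <- 1
    if (i > 1L) L[row, Tn + i - 1L] <- 1
  }
  mgr_spec(L, response = "ordinal", n_categories = n_categories)
}

#' Numeric CFA twin of an ordinal specification
#'
#' Converts an ordinal spec into the confirmatory factor model with the same
#' loading pattern and latent covariance structure, numeric responses, free
#' intercepts, and free residual variances. This is the model used during ML
#' tree growth, where ordinal responses are deliberately treated as numeric.
#'
#' @param spec an [mgr_spec()].
#' @return a numeric-response [mgr_spec()].
#' @export
as_numeric_spec <- function(spec) {
  stopifnot(inherits(spec, "mgr_spec"))
  if (spec$response == "numeric") return(spec)
  mgr_spec(spec$loadings, response = "numeric",
           latent_cov = spec$latent_cov)
}

#' Model-implied moments
#'
#' Mean vector and covariance matrix implied by a specification and a
#' parameter set: Sigma = Lambda Phi Lambda' + Theta. For ordinal specs the
#' moments are those of the latent responses Y*, with unit uniqueness
#' (Theta = I) and zero mean by the probit-link convention; for numeric specs
#' Theta is the diagonal of residual variances and the mean is the intercept
#' vector.
#'
#' @param spec an [mgr_spec()].
#' @param theta an [mgr_parameters()] object conformable with `spec`.
#' @return list with components `mean` and `cov`.
#' @export
implied_moments <- function(spec, theta) {
  stopifnot(inherits(spec, "mgr_spec"), inherits(theta, "mgr_parameters"))
  L <- theta$loadings
  Phi <- theta$latent_cov
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("latent covariance matrix is not positive semidefinite")
  Theta <- if (spec$response == "ordinal") diag(nrow(L)) else diag(theta$residual_var, nrow(L))
  Sigma <- L %*% Phi %*% t(L) + Theta
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(spec$items, spec$items)
  mu <- if (spec$response == "ordinal") rep(0, nrow(L)) else theta$intercepts
  names(mu) <- spec$items
  list(mean = mu, cov = Sigma)
}
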