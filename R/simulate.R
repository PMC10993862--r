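#' Sample a PIEG parameter set
#'
#' Draws a random parameter set for the PIEG measurement model (or its
#' numeric CFA twin): thresholds iid N(0,1) sorted within item, latent
#' variances Uniform(0.5, 1.5), latent correlations Uniform(0.1, 0.5)
#' projected to the nearest positive-definite correlation matrix, intercepts
#' N(0,1) and residual variances Uniform(0.5, 1.5) for the numeric twin.
#'
#' @param spec an [mgr_spec()] (PIEG-structured; see [pieg_spec()]).
#' @param seed integer seed.
#' @return an [mgr_parameters()] object.
#' @export
sample_pieg_parameters <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mgr_spec"))
  with_seed(seed, {
    p <- length(spec$latents)
    m <- length(spec$items)
    v <- stats::runif(p, 0.5, 1.5)
    Rho <- diag(1, p)
    Rho[upper.tri(Rho)] <- stats::runif(p * (p - 1) / 2, 0.1, 0.5)
    Rho[lower.tri(Rho)] <- t(Rho)[lower.tri(Rho)]
    Rho <- nearest_pd_correlation(Rho)
    Phi <- diag(sqrt(v)) %*% Rho %*% diag(sqrt(v))
    Phi <- (Phi + t(Phi)) / 2
    if (spec$response == "ordinal") {
      thr <- lapply(spec$n_categories, function(K)
        sort(stats::rnorm(K - 1L)))
      mgr_parameters(spec, thresholds = thr, latent_cov = Phi)
    } else {
      mgr_parameters(spec, intercepts = stats::rnorm(m),
                     latent_cov = Phi,
                     residual_var = stats::runif(m, 0.5, 1.5))
    }
  })
}

nearest_pd_correlation <- function(R, eps = 1e-3) {
  ee <- eigen(R, symmetric = TRUE)
  if (min(ee$values) > eps) return(R)
  vals <- pmax(ee$values, eps)
  A <- ee$vectors %*% diag(vals) %*% t(ee$vectors)
  d <- sqrt(diag(A))
  A <- A / (d %o% d)
  (A + t(A)) / 2
}

#' Simulate ordinal PIEG responses
#'
#' Draws latent vectors from N(0, Phi), forms the latent responses
#' y* = eta_t + beta_i + e with a standard-normal unique part (the probit
#' convention), and discretizes by the item thresholds. Emitted categories
#' are coded 1..K.
#'
#' @param params an ordinal [mgr_parameters()].
#' @param n number of cases.
#' @param seed integer seed.
#' @return data frame of integer responses (1-based categories).
#' @export
simulate_pieg <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "mgr_parameters"))
  spec <- params$spec
  if (spec$response != "ordinal") stop("params must be for an ordinal spec")
  with_seed(seed, {
    ystar <- latent_responses(params, n)
    m <- ncol(ystar)
    out <- matrix(0L, n, m, dimnames = list(NULL, spec$items))
    for (i in seq_len(m))
      out[, i] <- findInterval(ystar[, i], params$thresholds[[i]]) + 1L
    as.data.frame(out)
  })
}

latent_responses <- function(params, n) {
  Phi <- params$latent_cov
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent covariance matrix is not positive definite")
  L <- params$loadings
  Xi <- matrix(stats::rnorm(n * ncol(Phi)), n) %*% chol(Phi)
  Xi %*% t(L) + matrix(stats::rnorm(n * nrow(L)), n)
}

#' Simulate numeric CFA responses
#'
#' Y_it = pi_it + eta_t + beta_i + e_i with independent normal residuals.
#'
#' @param params a numeric [mgr_parameters()].
#' @param n number of cases.
#' @param seed integer seed.
#' @return data frame of numeric responses.
#' @export
simulate_cfa <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "mgr_parameters"))
  spec <- params$spec
  if (spec$response != "numeric") stop("params must be for a numeric spec")
  if (any(params$residual_var <= 0)) stop("residual variances must be positive")
  with_seed(seed, {
    Phi <- params$latent_cov
    L <- params$loadings
    m <- nrow(L)
    Xi <- matrix(stats::rnorm(n * ncol(Phi)), n) %*% chol(Phi)
    E <- matrix(stats::rnorm(n * m, sd = rep(sqrt(params$residual_var),
                                             each = n)), n)
    Y <- sweep(Xi %*% t(L) + E, 2L, params$intercepts, `+`)
    colnames(Y) <- spec$items
    as.data.frame(Y)
  })
}

# ---- scenario builders -----------------------------------------------------

#' Simulation scenario 1: four covariate-defined DIF subgroups
#'
#' Builds a sample of 2000 cases in four subgroups of 500, each generated
#' from its own randomly drawn PIEG (ordinal) or CFA-twin (numeric)
#' parameter set, so the measurement model holds within every subgroup but
#' DIF is present overall. The subgroups are exclusive regions of the
#' relevant covariates:
#' R1 = num1 < 100 & cat1 in \{1,5\}; R2 = num1 < 100 & cat1 in \{2,3,4\};
#' R3 = num1 >= 100 & cat2 <= 2; R4 = num1 >= 100 & cat2 >= 3.
#' cat1 is unordered categorical (its planted rule is a non-contiguous
#' subset), cat2 ordinal, num1 integer 1..200; rand1, rand2 are numeric and
#' rand3..rand5 ordinal 5-point noise covariates independent of membership.
#' Per-subgroup parameter sets are resampled until the subgroup's own-model
#' fit (WLS for ordinal, ML for numeric responses) has RMSEA <= `rmsea_max`.
#'
#' @param response `"ordinal"` or `"numeric"`.
#' @param seed integer master seed.
#' @param n_per_group cases per subgroup (default 500).
#' @param rmsea_max acceptance bound for each subgroup's own-model fit.
#' @param max_tries resampling budget per subgroup.
#' @return list: `data` (responses), `Z` (covariates), `manifest` (labels,
#'   rules, per-group parameters, seeds).
#' @export
make_scenario1 <- function(response = c("ordinal", "numeric"), seed = 1L,
                           n_per_group = 500L, rmsea_max = 0.05,
                           max_tries = 40L) {
  response <- match.arg(response)
  spec <- pieg_spec(3L, 3L, 5L)
  gspec <- if (response == "ordinal") spec else as_numeric_spec(spec)
  rules <- list(
    R1 = list(list(covariate = "num1", op = "<=", value = 99),
              list(covariate = "cat1", op = "in", value = c(1, 5))),
    R2 = list(list(covariate = "num1", op = "<=", value = 99),
              list(covariate = "cat1", op = "in", value = c(2, 3, 4))),
    R3 = list(list(covariate = "num1", op = ">", value = 99),
              list(covariate = "cat2", op = "<=", value = 2)),
    R4 = list(list(covariate = "num1", op = ">", value = 99),
              list(covariate = "cat2", op = ">", value = 2)))
  groups <- names(rules)
  H <- length(groups)
  n <- H * n_per_group
  params <- vector("list", H); names(params) <- groups
  data_parts <- vector("list", H)
  seeds_used <- integer(H)
  for (h in seq_len(H)) {
    res <- sample_fitting_group(gspec, n_per_group, rmsea_max, max_tries,
                                seed_base = seed * 1000L + h * 101L)
    params[[h]] <- res$params
    data_parts[[h]] <- res$data
    seeds_used[h] <- res$seed
  }
  Z <- with_seed(seed * 1000L + 7L, {
    Z <- data.frame(num1 = integer(n), cat1 = integer(n), cat2 = integer(n))
    for (h in seq_len(H)) {
      idx <- (h - 1L) * n_per_group + seq_len(n_per_group)
      if (h <= 2L) Z$num1[idx] <- sample(1:99, n_per_group, replace = TRUE)
      else Z$num1[idx] <- sample(100:200, n_per_group, replace = TRUE)
      Z$cat1[idx] <- switch(h,
        sample(c(1L, 5L), n_per_group, replace = TRUE),
        sample(2:4, n_per_group, replace = TRUE),
        sample(1:5, n_per_group, replace = TRUE),
        sample(1:5, n_per_group, replace = TRUE))
      Z$cat2[idx] <- switch(h,
        sample(1:5, n_per_group, replace = TRUE),
        sample(1:5, n_per_group, replace = TRUE),
        sample(1:2, n_per_group, replace = TRUE),
        sample(3:5, n_per_group, replace = TRUE))
    }
    Z$cat1 <- factor(Z$cat1, levels = 1:5)
    Z$cat2 <- factor(Z$cat2, levels = 1:5, ordered = TRUE)
    Z$rand1 <- stats::rnorm(n)
    Z$rand2 <- stats::rnorm(n)
    Z$rand3 <- factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                      ordered = TRUE)
    Z$rand4 <- factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                      ordered = TRUE)
    Z$rand5 <- factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                      ordered = TRUE)
    Z
  })
  data <- do.call(rbind, data_parts)
  labels <- rep(groups, each = n_per_group)
  perm <- with_seed(seed * 1000L + 13L, sample.int(n))
  data <- data[perm, , drop = FALSE]
  Z <- Z[perm, , drop = FALSE]
  labels <- labels[perm]
  rownames(data) <- rownames(Z) <- NULL
  manifest <- list(scenario = 1L, response = response, labels = labels,
                   rules = rules, relevant = c("num1", "cat1", "cat2"),
                   group_parameters = params, seed = seed,
                   group_seeds = seeds_used, spec = gspec)
  stopifnot(all(evaluate_rules(rules, Z) == labels))
  list(data = data, Z = Z, manifest = manifest)
}

sample_fitting_group <- function(gspec, n, rmsea_max, max_tries, seed_base) {
  ordinal <- gspec$response == "ordinal"
  for (try in seq_len(max_tries)) {
    s <- seed_base + try * 7919L
    par <- sample_pieg_parameters(gspec, seed = s)
    dat <- if (ordinal) simulate_pieg(par, n, seed = s + 1L)
           else simulate_cfa(par, n, seed = s + 1L)
    rms <- tryCatch({
      if (ordinal) fit_wls(gspec, polychoric(dat, gspec$n_categories))$rmsea
      else ml_fit_indices(fit_ml(gspec, dat))$rmsea
    }, error = function(e) NA_real_)
    if (!is.na(rms) && rms <= rmsea_max)
      return(list(params = par, data = dat, seed = s, rmsea = rms))
  }
  stop("resampling budget exceeded: no parameter draw produced a subgroup ",
       "with RMSEA <= ", rmsea_max, " in ", max_tries, " tries")
}

evaluate_rule <- function(rule, Z) {
  keep <- rep(TRUE, nrow(Z))
  for (cond in rule) {
    z <- Z[[cond$covariate]]
    zv <- if (is.factor(z)) as.numeric(as.character(z)) else as.numeric(z)
    keep <- keep & switch(cond$op,
      "<=" = zv <= cond$value,
      ">"  = zv > cond$value,
      "in" = zv %in% cond$value,
      "not_in" = !(zv %in% cond$value),
      "==" = zv == cond$value,
      stop("unknown rule operator ", cond$op))
  }
  keep
}

evaluate_rules <- function(rules, Z) {
  lab <- rep("random", nrow(Z))
  for (g in names(rules)) {
    hit <- evaluate_rule(rules[[g]], Z)
    lab[hit] <- g
  }
  lab
}

#' Simulation scenario 2: two planted subgroups plus random responses
#'
#' Builds a sample of 2000 cases: two exclusive model-generated subgroups of
#' 500 (distinct PIEG/CFA parameter sets) and 1000 cases with random
#' responses (ordinal: uniform categories 1..5; numeric: Uniform(-3, 3)).
#' The subgroup regions are R1 = cat2 in \{3,4\} & num1 <= 50 and
#' R2 = dicho1 = 0 & cat1 in \{1,4,5\}; the remaining cases take covariate
#' values satisfying neither rule. cat1 and cat2 are unordered categorical,
#' num1 numeric (integer 1..200), dicho1 dichotomous; rand1..rand5 as in
#' scenario 1. This subgroup structure is not representable by one binary
#' tree, which motivates the forest.
#'
#' @inheritParams make_scenario1
#' @return list: `data`, `Z`, `manifest`.
#' @export
make_scenario2 <- function(response = c("ordinal", "numeric"), seed = 1L,
                           n_per_group = 500L, rmsea_max = 0.05,
                           max_tries = 40L) {
  response <- match.arg(response)
  spec <- pieg_spec(3L, 3L, 5L)
  gspec <- if (response == "ordinal") spec else as_numeric_spec(spec)
  rules <- list(
    R1 = list(list(covariate = "cat2", op = "in", value = c(3, 4)),
              list(covariate = "num1", op = "<=", value = 50)),
    R2 = list(list(covariate = "dicho1", op = "==", value = 0),
              list(covariate = "cat1", op = "in", value = c(1, 4, 5))))
  n_random <- 2L * n_per_group
  n <- 2L * n_per_group + n_random
  params <- list(); data_parts <- list(); seeds_used <- integer(2L)
  for (h in 1:2) {
    res <- sample_fitting_group(gspec, n_per_group, rmsea_max, max_tries,
                                seed_base = seed * 1000L + h * 211L)
    params[[h]] <- res$params
    data_parts[[h]] <- res$data
    seeds_used[h] <- res$seed
  }
  names(params) <- c("R1", "R2")
  rand_data <- with_seed(seed * 1000L + 19L, {
    if (response == "ordinal") {
      as.data.frame(matrix(sample(1:5, n_random * 9L, replace = TRUE),
                           n_random, 9L, dimnames = list(NULL, spec$items)))
    } else {
      as.data.frame(matrix(stats::runif(n_random * 9L, -3, 3),
                           n_random, 9L, dimnames = list(NULL, spec$items)))
    }
  })
  Z <- with_seed(seed * 1000L + 23L, {
    draw_covs <- function(k) {
      data.frame(num1 = sample(1:200, k, replace = TRUE),
                 cat1 = sample(1:5, k, replace = TRUE),
                 cat2 = sample(1:5, k, replace = TRUE),
                 dicho1 = sample(0:1, k, replace = TRUE))
    }
    in_r1 <- function(d) d$cat2 %in% c(3, 4) & d$num1 <= 50
    in_r2 <- function(d) d$dicho1 == 0 & d$cat1 %in% c(1, 4, 5)
    draw_until <- function(k, cond) {
      out <- NULL
      while (is.null(out) || nrow(out) < k) {
        cand <- draw_covs(2L * k + 50L)
        cand <- cand[cond(cand), , drop = FALSE]
        out <- rbind(out, cand)
      }
      out[seq_len(k), , drop = FALSE]
    }
    z1 <- draw_until(n_per_group, function(d) in_r1(d) & !in_r2(d))
    z2 <- draw_until(n_per_group, function(d) in_r2(d) & !in_r1(d))
    z0 <- draw_until(n_random, function(d) !in_r1(d) & !in_r2(d))
    Z <- rbind(z1, z2, z0)
    Z$cat1 <- factor(Z$cat1, levels = 1:5)
    Z$cat2 <- factor(Z$cat2, levels = 1:5)
    Z$dicho1 <- factor(Z$dicho1, levels = 0:1)
    k <- nrow(Z)
    Z$rand1 <- stats::rnorm(k)
    Z$rand2 <- stats::rnorm(k)
    Z$rand3 <- factor(sample(1:5, k, replace = TRUE), levels = 1:5,
                      ordered = TRUE)
    Z$rand4 <- factor(sample(1:5, k, replace = TRUE), levels = 1:5,
                      ordered = TRUE)
    Z$rand5 <- factor(sample(1:5, k, replace = TRUE), levels = 1:5,
                      ordered = TRUE)
    Z
  })
  data <- rbind(data_parts[[1L]], data_parts[[2L]], rand_data)
  labels <- c(rep("R1", n_per_group), rep("R2", n_per_group),
              rep("random", n_random))
  perm <- with_seed(seed * 1000L + 29L, sample.int(n))
  data <- data[perm, , drop = FALSE]
  Z <- Z[perm, , drop = FALSE]
  labels <- labels[perm]
  rownames(data) <- rownames(Z) <- NULL
  manifest <- list(scenario = 2L, response = response, labels = labels,
                   rules = rules,
                   relevant = c("num1", "cat1", "cat2", "dicho1"),
                   group_parameters = params, seed = seed,
                   group_seeds = seeds_used, spec = gspec)
  stopifnot(all(evaluate_rules(rules, Z) == labels))
  list(data = data, Z = Z, manifest = manifest)
}

#' Null sample: one homogeneous population, scenario-1 covariates
#'
#' Generates responses from a single randomly drawn parameter set for all
#' cases (no DIF anywhere) together with the eight scenario-1-style
#' partitioning covariates, drawn independently of the responses. This is
#' the harness for checking the family-wise error of the stopping rule: with
#' no DIF, the root node should select no covariate in about 1 - alpha of
#' samples.
#'
#' @param response `"ordinal"` or `"numeric"`.
#' @param seed integer seed.
#' @param n sample size (default 2000).
#' @return list: `data`, `Z`, `params`.
#' @export
make_null_scenario <- function(response = c("ordinal", "numeric"), seed = 1L,
                               n = 2000L) {
  response <- match.arg(response)
  spec <- pieg_spec(3L, 3L, 5L)
  gspec <- if (response == "ordinal") spec else as_numeric_spec(spec)
  par <- sample_pieg_parameters(gspec, seed = seed * 3L + 1L)
  data <- if (response == "ordinal") simulate_pieg(par, n, seed = seed * 3L + 2L)
          else simulate_cfa(par, n, seed = seed * 3L + 2L)
  Z <- with_seed(seed * 3L + 3L, {
    data.frame(
      num1 = sample(1:200, n, replace = TRUE),
      cat1 = factor(sample(1:5, n, replace = TRUE), levels = 1:5),
      cat2 = factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                    ordered = TRUE),
      rand1 = stats::rnorm(n),
      rand2 = stats::rnorm(n),
      rand3 = factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                     ordered = TRUE),
      rand4 = factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                     ordered = TRUE),
      rand5 = factor(sample(1:5, n, replace = TRUE), levels = 1:5,
                     ordered = TRUE))
  })
  list(data = data, Z = Z, params = par, spec = gspec)
}
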