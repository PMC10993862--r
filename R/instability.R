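#' Cumulative score process along a covariate
#'
#' Orders the cases by the covariate, decorrelates the casewise scores with
#' the root inverse of their empirical covariance, and accumulates the scaled
#' partial sums B(j/n) = n^{-1/2} I-hat^{-1/2} sum_{u<=j} psi_u. Score columns
#' are centered first, so the process starts and ends at zero exactly (the
#' M-estimation equations hold up to optimizer tolerance).
#'
#' Ties in the covariate are kept adjacent; within a tie the order is
#' randomized under the supplied seed, and candidate cuts are only taken
#' between distinct covariate values.
#'
#' @param scores an n x k score matrix (see [score_matrix()]).
#' @param z covariate vector of length n (numeric or ordered).
#' @param seed integer seed for the within-tie shuffle.
#' @return list: `process` ((n+1) x k matrix, row 1 is B(0) = 0), `ordering`,
#'   `t` (cumulative fractions), `cuts` (indices after which a cut between
#'   distinct values is admissible), `k_eff` (rank of the score covariance).
#' @export
score_process <- function(scores, z, seed = 1L) {
  n <- nrow(scores)
  stopifnot(length(z) == n)
  ord <- order(z, sample_shuffle(n, seed))
  psi <- decorrelate_scores(scores)
  B <- rbind(0, apply(psi[ord, , drop = FALSE], 2L, cumsum)) / sqrt(n)
  zs <- z[ord]
  cuts <- which(zs[-n] != zs[-1L])
  list(process = B, ordering = ord, t = seq_len(n) / n, cuts = cuts,
       k_eff = attr(psi, "k_eff"))
}

sample_shuffle <- function(n, seed) {
  with_seed(seed, sample.int(n))
}

# center columns and scale by the root inverse of the empirical score
# covariance; rank-deficient covariances fall back to a pseudo-inverse
decorrelate_scores <- function(scores) {
  psi <- sweep(as.matrix(scores), 2L, colMeans(scores))
  n <- nrow(psi)
  I_hat <- crossprod(psi) / n
  ee <- eigen(I_hat, symmetric = TRUE)
  tol <- max(ee$values) * 1e-10
  pos <- ee$values > tol
  if (!any(pos)) {
    # degenerate scores (e.g. all zero): keep the zero process
    warning("rank-deficient score covariance; scores are degenerate")
    attr(psi, "k_eff") <- 0L
    return(psi)
  }
  if (!all(pos))
    warning("rank-deficient score covariance; using pseudo-inverse (",
            sum(pos), " of ", length(pos), " directions kept)")
  root_inv <- ee$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(ee$values[pos]), sum(pos))
  out <- psi %*% root_inv
  attr(out, "k_eff") <- sum(pos)
  out
}

#' maxLM statistic for a numeric covariate
#'
#' The supremum over admissible cut points of the LM form
#' ||B(t)||^2 / (t (1 - t)), taken from the cumulative score process. Cuts
#' are admissible when they fall between distinct covariate values, inside
#' the trimming window, and leave both prospective children at least
#' `min_child` cases.
#'
#' @param process a [score_process()] result, or a score matrix (then `z`
#'   must be given).
#' @param z covariate (if `process` is a score matrix).
#' @param trim trimming fraction on the cumulative proportion (default 0.1).
#' @param min_child minimum prospective child size (default 0).
#' @param seed tie-shuffle seed when the process is built here.
#' @return list: `statistic`, `cut_index` (cases in the left child at the
#'   argmax), `boundary` (largest covariate value in the left child, `NA`
#'   when built from a prepared process), `profile` (statistic at every
#'   admissible cut), `cuts`, `k_eff`. `statistic` is `NA` with a note when
#'   no cut is admissible.
#' @export
max_lm_numeric <- function(process, z = NULL, trim = 0.1, min_child = 0L,
                           seed = 1L) {
  stopifnot(trim > 0, trim < 0.5)
  zvals <- NULL
  if (!is.list(process)) {
    zvals <- z
    process <- score_process(process, z, seed = seed)
  }
  n <- nrow(process$process) - 1L
  tt <- process$t
  ok <- process$cuts
  ok <- ok[tt[ok] >= trim & tt[ok] <= 1 - trim]
  ok <- ok[ok >= min_child & (n - ok) >= min_child]
  if (length(ok) < 1L)
    return(list(statistic = NA_real_, cut_index = NA_integer_,
                boundary = NA_real_, profile = numeric(0), cuts = integer(0),
                k_eff = process$k_eff, note = "not testable"))
  B2 <- rowSums(process$process[ok + 1L, , drop = FALSE]^2)
  lm <- B2 / (tt[ok] * (1 - tt[ok]))
  best <- which.max(lm)
  cut_index <- ok[best]
  boundary <- if (!is.null(zvals)) sort(zvals)[cut_index] else NA_real_
  list(statistic = lm[best], cut_index = cut_index, boundary = boundary,
       profile = lm, cuts = ok, k_eff = process$k_eff)
}

#' LMuo statistic for an unordered categorical covariate
#'
#' Sum over categories of the squared scaled within-category score sums:
#' sum_c ||I-hat^{-1/2} sum_{j in c} psi_j||^2 / (n p-hat_c). Asymptotically
#' chi-square with k (C - 1) degrees of freedom under stability.
#'
#' @param scores n x k score matrix.
#' @param z factor (or vector coerced to factor).
#' @return list: `statistic`, `df`, `k_eff`, `n_categories`.
#' @export
lm_uo_categorical <- function(scores, z) {
  z <- factor(z)
  z <- droplevels(z)
  C <- nlevels(z)
  if (C < 2L)
    return(list(statistic = NA_real_, df = NA_integer_, k_eff = NA_integer_,
                n_categories = C, note = "not testable"))
  psi <- decorrelate_scores(scores)
  n <- nrow(psi)
  sums <- rowsum(psi, z)                  # C x k
  p_hat <- as.numeric(table(z)) / n
  stat <- sum(rowSums(sums^2) / (n * p_hat))
  k_eff <- attr(psi, "k_eff")
  list(statistic = stat, df = k_eff * (C - 1L), k_eff = k_eff,
       n_categories = C)
}

#' maxLMo statistic for an ordered covariate
#'
#' The maximum over the C - 1 level cuts of the LM form evaluated at the
#' cumulative score sum through the cut, with t the cumulative proportion.
#'
#' @param scores n x k score matrix.
#' @param z ordered factor (or integer vector interpreted as ordered levels).
#' @param min_child minimum prospective child size.
#' @return list: `statistic`, `best_cut` (largest level in the left group),
#'   `profile`, `t`, `k_eff`.
#' @export
max_lm_ordinal <- function(scores, z, min_child = 0L) {
  z <- if (is.ordered(z)) droplevels(z) else
    factor(z, levels = sort(unique(z)), ordered = TRUE)
  C <- nlevels(z)
  if (C < 2L)
    return(list(statistic = NA_real_, best_cut = NA, profile = numeric(0),
                k_eff = NA_integer_, note = "not testable"))
  psi <- decorrelate_scores(scores)
  n <- nrow(psi)
  sums <- rowsum(psi, z)                  # level sums in level order
  counts <- as.numeric(table(z))
  cs <- apply(sums, 2L, cumsum)[-C, , drop = FALSE]
  tt <- cumsum(counts)[-C] / n
  lm <- rowSums(cs^2) / n / (tt * (1 - tt))
  nl <- cumsum(counts)[-C]
  ok <- which(nl >= min_child & (n - nl) >= min_child)
  if (length(ok) < 1L)
    return(list(statistic = NA_real_, best_cut = NA, profile = lm, t = tt,
                k_eff = attr(psi, "k_eff"), note = "not testable"))
  best <- ok[which.max(lm[ok])]
  list(statistic = max(lm[ok]), best_cut = levels(z)[best], profile = lm,
       t = tt, k_eff = attr(psi, "k_eff"), cut_level_index = best)
}

#' p value for an instability statistic
#'
#' Closed forms: LMuo uses the chi-square upper tail with k (C - 1) degrees
#' of freedom; maxLM has a boundary-crossing approximation for the supremum
#' of the squared standardized Brownian bridge. The default for maxLM and
#' maxLMo is simulation from the limiting process (seeded, with a
#' add-one continuity correction): Brownian-bridge replicates on an
#' equally spaced grid (maxLM) or at the observed cumulative proportions
#' (maxLMo). Reference samples are cached per (k, trim, grid, n_sim, seed).
#'
#' @param statistic observed statistic (>= 0).
#' @param statistic_kind `"maxLM"`, `"LMuo"`, or `"maxLMo"`.
#' @param k number of (effective) parameters.
#' @param extra list: `trim` (maxLM), `n_categories` (LMuo), `t` (maxLMo:
#'   cumulative proportions at the cuts).
#' @param method `"simulate"` (default for maxLM/maxLMo) or `"closed_form"`
#'   (default and exact-asymptotic for LMuo; an approximation for maxLM).
#' @param n_sim simulation replicates (default 5000).
#' @param seed seed for the simulated reference distribution.
#' @return p value in (0, 1].
#' @export
instability_p_value <- function(statistic, statistic_kind, k, extra = list(),
                                method = NULL, n_sim = 5000L, seed = 1L) {
  if (is.na(statistic)) return(NA_real_)
  stopifnot(statistic >= 0)
  kind <- match.arg(statistic_kind, c("maxLM", "LMuo", "maxLMo"))
  if (is.null(method))
    method <- if (kind == "LMuo") "closed_form" else "simulate"
  method <- match.arg(method, c("closed_form", "simulate"))
  if (kind == "LMuo") {
    C <- extra$n_categories
    stopifnot(!is.null(C))
    if (method == "closed_form")
      return(max(stats::pchisq(statistic, df = k * (C - 1L),
                               lower.tail = FALSE), 1e-100))
    ref <- simulate_lmuo_null(k, extra$p_hat %||% rep(1 / C, C), n_sim, seed)
    return((1 + sum(ref >= statistic)) / (n_sim + 1))
  }
  if (kind == "maxLM") {
    trim <- extra$trim %||% 0.1
    if (method == "closed_form") return(p_maxlm_crossing(statistic, k, trim))
    ref <- maxlm_null_sample(k, trim, grid = extra$grid %||% 201L,
                             n_sim = n_sim, seed = seed)
    exceed <- sum(ref >= statistic)
    if (exceed == 0L) {
      # beyond the simulated reference: continue with the closed-form tail
      # so that covariate ranking stays resolved below the simulation floor;
      # 1e-100 bounds every reported p away from zero
      return(min(max(p_maxlm_crossing(statistic, k, trim), 1e-100),
                 1 / (n_sim + 1)))
    }
    return((1 + exceed) / (n_sim + 1))
  }
  # maxLMo
  tt <- extra$t
  stopifnot(!is.null(tt))
  if (method == "closed_form")
    stop("no closed form for maxLMo; use method = 'simulate'")
  ref <- simulate_maxlmo_null(k, tt, n_sim, seed)
  exceed <- sum(ref >= statistic)
  if (exceed == 0L) {
    # Bonferroni tail over the marginal chi-square cuts, continuous deep in
    # the tail; floored at 1e-100
    tail_p <- min(1, length(tt) *
                    stats::pchisq(statistic, k, lower.tail = FALSE))
    return(min(max(tail_p, 1e-100), 1 / (n_sim + 1)))
  }
  (1 + exceed) / (n_sim + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DeLong-type boundary-crossing approximation for
# P( sup_{t in [a, 1-a]} ||B(t)||^2 / (t(1-t)) >= x ), B a k-dim Brownian
# bridge; accurate in the tail, capped into [0, 1].
p_maxlm_crossing <- function(x, k, trim) {
  if (x <= 0) return(1)
  logL <- log(((1 - trim) / trim)^2)
  dens <- exp((k / 2) * log(x / 2) - x / 2 - lgamma(k / 2))
  p <- dens * (logL * (1 - k / x) + 4 / x)
  min(max(p, stats::pchisq(x, k, lower.tail = FALSE)), 1)
}

# cached Brownian-bridge reference sample for maxLM on an equally spaced grid
.mgr_cache <- new.env(parent = emptyenv())

maxlm_null_sample <- function(k, trim, grid = 201L, n_sim = 5000L, seed = 1L) {
  key <- paste("maxLM", k, round(trim, 6), grid, n_sim, seed, sep = "|")
  hit <- .mgr_cache[[key]]
  if (!is.null(hit)) return(hit)
  tt <- seq(trim, 1 - trim, length.out = grid)
  ref <- with_seed(seed, bridge_sup_sample(k, tt, n_sim))
  .mgr_cache[[key]] <- ref
  ref
}

simulate_maxlmo_null <- function(k, tt, n_sim = 5000L, seed = 1L) {
  # bridge evaluated at the cumulative proportions tt (length C-1)
  seed2 <- (seed + 1000003 * as.numeric(stable_hash(tt))) %% 2147483647
  key <- paste("maxLMo", k, paste(round(tt, 8), collapse = ","), n_sim,
               seed2, sep = "|")
  hit <- .mgr_cache[[key]]
  if (!is.null(hit)) return(hit)
  ref <- with_seed(seed2, bridge_sup_sample(k, tt, n_sim))
  if (length(ls(.mgr_cache)) < 512L) .mgr_cache[[key]] <- ref
  ref
}

# n_sim replicates of max_t ||B(t)||^2 / (t(1-t)) for a k-dimensional
# Brownian bridge evaluated at the grid tt
bridge_sup_sample <- function(k, tt, n_sim) {
  G <- length(tt)
  sdv <- sqrt(diff(c(0, tt, 1)))
  SS <- matrix(0, G, n_sim)
  for (comp in seq_len(k)) {
    v <- stats::rnorm((G + 1L) * n_sim) * sdv
    cv <- cumsum(v)
    M <- matrix(cv, G + 1L, n_sim)
    ends <- M[G + 1L, ]
    # remove the running offset so each column is a within-replicate cumsum
    offs <- c(0, ends[-n_sim])
    W <- sweep(M, 2L, offs)
    tot <- ends - offs
    B <- W[seq_len(G), , drop = FALSE] - outer(tt, tot)
    SS <- SS + B * B
  }
  SS <- SS / (tt * (1 - tt))
  # columnwise max without apply()
  out <- SS[1L, ]
  if (G > 1L) for (g in 2:G) out <- pmax(out, SS[g, ])
  out
}

simulate_lmuo_null <- function(k, p_hat, n_sim = 5000L, seed = 1L) {
  C <- length(p_hat)
  seed2 <- (seed + 2000003 * as.numeric(stable_hash(p_hat))) %% 2147483647
  with_seed(seed2, {
    out <- numeric(n_sim)
    for (r in seq_len(n_sim)) {
      # category sums of iid N(0, I_k) scores, centered across categories
      Sc <- matrix(stats::rnorm(C * k, sd = rep(sqrt(p_hat), k)), C, k)
      Sc <- Sc - outer(p_hat, colSums(Sc))
      out[r] <- sum(rowSums(Sc^2) / p_hat)
    }
    out
  })
}

stable_hash <- function(x) {
  v <- as.integer(round(1e6 * (as.numeric(x) %% 1))) + as.integer(round(as.numeric(x)))
  h <- 0
  for (u in v) h <- (h * 31 + (u %% 97)) %% 1000003L
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Test all covariates for parameter instability
#'
#' Runs the kind-appropriate instability test for every covariate (maxLM for
#' numeric, LMuo for unordered factors, maxLMo for ordered factors), applies
#' a Bonferroni adjustment over the number of covariates tested, and selects
#' the covariate with the smallest adjusted p value when it falls below
#' `alpha`.
#'
#' @param fit a converged [fit_ml()] object (used for its convergence state).
#' @param scores casewise score matrix from [score_matrix()].
#' @param Z data frame of covariates; column classes determine the test kind.
#' @param alpha significance level (default 0.05).
#' @param bonferroni apply the multiple-testing adjustment (default TRUE)?
#' @param trim trimming fraction for maxLM.
#' @param min_child minimum prospective child size for cut admissibility.
#' @param n_sim simulation replicates for simulated null distributions.
#' @param seed seed governing simulated p values and tie shuffles.
#' @param p_method optional override of the p-value method.
#' @return list: `results` (data frame: covariate, kind, statistic, p,
#'   p_adjusted, breakpoint), `selected` (covariate name or `NA`), `alpha`.
#' @export
test_all_covariates <- function(fit, scores, Z, alpha = 0.05,
                                bonferroni = TRUE, trim = 0.1,
                                min_child = 0L, n_sim = 5000L, seed = 1L,
                                p_method = NULL) {
  if (!is.null(fit) && !fit$converged)
    stop("score test undefined off the optimum: fit did not converge")
  Z <- as.data.frame(Z)
  R <- ncol(Z)
  stopifnot(R >= 1L)
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    z <- Z[[r]]
    nm <- names(Z)[r]
    if (length(unique(z)) < 2L) {
      rows[[r]] <- data.frame(covariate = nm, kind = "skipped",
                              statistic = NA_real_, p = NA_real_,
                              breakpoint = NA_character_,
                              note = "constant covariate",
                              stringsAsFactors = FALSE)
      next
    }
    kind <- covariate_kind(z)
    if (kind == "numeric") {
      res <- max_lm_numeric(scores, z, trim = trim, min_child = min_child,
                            seed = seed + r)
      p <- instability_p_value(res$statistic, "maxLM", res$k_eff,
                               extra = list(trim = trim), method = p_method,
                               n_sim = n_sim, seed = seed)
      bp <- as.character(res$boundary)
    } else if (kind == "categorical") {
      res <- lm_uo_categorical(scores, z)
      p <- instability_p_value(res$statistic, "LMuo", res$k_eff,
                               extra = list(n_categories = res$n_categories),
                               method = p_method, n_sim = n_sim, seed = seed)
      bp <- NA_character_
    } else {
      res <- max_lm_ordinal(scores, z, min_child = min_child)
      p <- instability_p_value(res$statistic, "maxLMo", res$k_eff,
                               extra = list(t = res$t),
                               method = if (is.null(p_method)) NULL else
                                 "simulate",
                               n_sim = n_sim, seed = seed)
      bp <- as.character(res$best_cut)
    }
    rows[[r]] <- data.frame(covariate = nm, kind = kind,
                            statistic = res$statistic, p = p,
                            breakpoint = bp, note = res$note %||% "",
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  tested <- !is.na(results$p)
  R_eff <- sum(tested)
  results$p_adjusted <- ifelse(tested,
                               if (bonferroni) pmin(1, R_eff * results$p)
                               else results$p, NA_real_)
  selected <- NA_character_
  if (R_eff > 0L) {
    best <- which.min(replace(results$p_adjusted, !tested, Inf))
    if (results$p_adjusted[best] < alpha) selected <- results$covariate[best]
  }
  list(results = results, selected = selected, alpha = alpha)
}

covariate_kind <- function(z) {
  if (is.ordered(z)) "ordinal"
  else if (is.factor(z) || is.character(z) || is.logical(z)) "categorical"
  else "numeric"
}
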