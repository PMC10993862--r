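#' Tree-growing controls
#'
#' @param alpha significance level for the stopping rule (default 0.05).
#' @param bonferroni Bonferroni-adjust over the covariates tested at each
#'   node (default TRUE)?
#' @param min_size minimum terminal-node size. `NULL` (default) enforces only
#'   the fitting floor of k + 10 cases per child, with k the number of free
#'   growth-model parameters. A warning is given when an explicit `min_size`
#'   falls below the free-parameter count.
#' @param method split-point search: `"score"` (score-guided: argmax of the
#'   score-based statistic, one fit per node), `"objective"` (one fit per
#'   candidate segmentation, minimized summed children deviance), or
#'   `"naive"` (exhaustive likelihood-ratio search per covariate).
#' @param trim trimming fraction for maxLM on numeric covariates.
#' @param seed master seed for simulated p values and tie shuffles.
#' @param max_depth optional depth cap (root has depth 0).
#' @param n_sim replicates for simulated null distributions.
#' @param mtry covariates randomly sampled as split candidates at each node
#'   (`NULL`: all covariates — single-tree behaviour).
#' @param score_params `"theta"` (all free growth-model parameters, default)
#'   or `"vartheta"` (drop intercept and residual-variance score columns).
#' @return a list of class `mgr_tree_control`.
#' @export
mgr_tree_control <- function(alpha = 0.05, bonferroni = TRUE, min_size = NULL,
                             method = c("score", "objective", "naive"),
                             trim = 0.1, seed = 1L, max_depth = Inf,
                             n_sim = 5000L, mtry = NULL,
                             score_params = c("theta", "vartheta")) {
  stopifnot(alpha > 0, alpha < 1, trim > 0, trim < 0.5)
  structure(list(alpha = alpha, bonferroni = bonferroni, min_size = min_size,
                 method = match.arg(method), trim = trim,
                 seed = as.integer(seed), max_depth = max_depth,
                 n_sim = as.integer(n_sim), mtry = mtry,
                 score_params = match.arg(score_params)),
            class = "mgr_tree_control")
}

#' Grow a DIF-detection tree
#'
#' Recursively partitions the sample over the covariates: at each node the
#' measurement model is fitted by limited-information ML (ordinal responses
#' treated as numeric scores), every candidate covariate is tested for
#' parameter instability with its kind-appropriate score-based statistic, and
#' the node is split on the covariate with the smallest (Bonferroni-adjusted)
#' p value below `alpha`; otherwise it becomes a leaf. Terminal nodes of
#' ordinal-response trees are then re-estimated with the distribution-free
#' WLS estimator (see [refit_terminal_nodes()], called automatically unless
#' `refit = FALSE`).
#'
#' @param data response table (ordinal integer codes or numeric), n x m.
#' @param Z covariate data frame (numeric, factor, ordered columns), n rows.
#' @param spec an [mgr_spec()] describing the measurement model.
#' @param control an [mgr_tree_control()].
#' @param refit WLS-refit the terminal nodes (ordinal specs)?
#' @return an object of class `mgr_tree`: `nodes` (list of node records),
#'   `spec`, `growth_spec`, `control`, `data`, `Z`, `n_skipped`.
#' @export
mgr_tree <- function(data, Z, spec, control = mgr_tree_control(),
                     refit = TRUE) {
  stopifnot(inherits(spec, "mgr_spec"), inherits(control, "mgr_tree_control"))
  Z <- as.data.frame(Z)
  data <- as.data.frame(data)
  if (nrow(data) != nrow(Z)) stop("data and Z must be row-aligned")
  growth_spec <- as_numeric_spec(spec)
  k <- count_free_parameters(growth_spec)
  floor_n <- k + 10L
  min_size <- control$min_size
  if (is.null(min_size)) min_size <- 0L
  if (min_size > 0L && min_size < k)
    warning("min_size (", min_size, ") is below the free-parameter count (",
            k, "); growth-stage fits may be unstable")
  min_child <- max(min_size, floor_n)

  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$next_id <- 1L

  grow_node <- function(cases, depth, parent, start, rule_path) {
    id <- env$next_id
    env$next_id <- id + 1L
    node <- list(id = id, depth = depth, parent = parent, cases = cases,
                 rule_path = rule_path, split = NULL, children = NULL,
                 fit = NULL, tests = NULL, terminal_reason = NULL)
    fit <- tryCatch(
      fit_ml(spec, data[cases, , drop = FALSE], start = start),
      error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      if (depth == 0L)
        stop("root model fit failed: ",
             if (inherits(fit, "error")) conditionMessage(fit)
             else "no convergence")
      warning("node ", id, ": growth-stage fit failed; made terminal")
      node$terminal_reason <- "fit_failure"
      if (!inherits(fit, "error")) node$fit <- fit
      env$nodes[[id]] <- node
      return(id)
    }
    node$fit <- fit
    n_node <- length(cases)
    node_seed <- (control$seed + 97L * id) %% .Machine$integer.max

    if (depth >= control$max_depth || n_node < 2L * min_child) {
      node$terminal_reason <- if (depth >= control$max_depth) "max_depth"
                              else "size"
      env$nodes[[id]] <- node
      return(id)
    }

    cand <- names(Z)
    if (!is.null(control$mtry) && control$mtry < length(cand))
      cand <- with_seed(node_seed, sample(cand, control$mtry))
    Znode <- Z[cases, cand, drop = FALSE]
    Znode[] <- lapply(Znode, function(z) if (is.factor(z)) droplevels(z) else z)

    if (control$method == "naive") {
      ns <- find_split_naive(fit, data, Znode, cases, min_child, control)
      if (is.null(ns)) {
        node$terminal_reason <- "no_significant_instability"
        env$nodes[[id]] <- node
        return(id)
      }
      node$tests <- ns$tests
      split <- ns$split
    } else {
      scores <- score_matrix(fit, vartheta = control$score_params == "vartheta")
      tests <- test_all_covariates(fit, scores, Znode, alpha = control$alpha,
                                   bonferroni = control$bonferroni,
                                   trim = control$trim, min_child = min_child,
                                   n_sim = control$n_sim,
                                   seed = control$ref_seed %||% control$seed)
      node$tests <- tests$results
      if (is.na(tests$selected)) {
        node$terminal_reason <- "no_significant_instability"
        env$nodes[[id]] <- node
        return(id)
      }
      zsel <- Znode[[tests$selected]]
      split <- if (control$method == "score")
        find_split_score_guided(scores, zsel, tests$selected, min_child,
                                control, node_seed)
      else
        find_split_objective(spec, data, cases, zsel, tests$selected,
                             min_child, fit)
    }
    if (is.null(split)) {
      node$terminal_reason <- "no_admissible_boundary"
      env$nodes[[id]] <- node
      return(id)
    }
    left <- cases[split_goes_left(split, Z[cases, split$covariate])]
    right <- setdiff(cases, left)
    if (length(left) < min_child || length(right) < min_child) {
      node$terminal_reason <- "no_admissible_boundary"
      env$nodes[[id]] <- node
      return(id)
    }
    node$split <- split
    env$nodes[[id]] <- node  # reserve slot before recursion
    lid <- grow_node(left, depth + 1L, id, fit$theta,
                     c(rule_path, split_label(split, TRUE)))
    rid <- grow_node(right, depth + 1L, id, fit$theta,
                     c(rule_path, split_label(split, FALSE)))
    node$children <- c(lid, rid)
    env$nodes[[id]] <- node
    id
  }

  grow_node(seq_len(nrow(data)), 0L, NA_integer_, NULL, character(0))
  tree <- structure(
    list(nodes = env$nodes, spec = spec, growth_spec = growth_spec,
         control = control, data = data, Z = Z),
    class = "mgr_tree")
  if (refit) tree <- refit_terminal_nodes(tree)
  tree
}

# ---- split representation --------------------------------------------------

new_split <- function(covariate, kind, boundary, tie = FALSE) {
  list(covariate = covariate, kind = kind, boundary = boundary, tie = tie)
}

split_goes_left <- function(split, z) {
  switch(split$kind,
    numeric_threshold = as.numeric(z) <= split$boundary,
    ordinal_threshold = {
      lv <- if (is.ordered(z)) match(as.character(z), levels(z))
            else as.numeric(z)
      bnd <- split$boundary
      if (is.ordered(z)) lv <= match(as.character(bnd), levels(z))
      else lv <= as.numeric(bnd)
    },
    category_subset = as.character(z) %in% as.character(split$boundary),
    stop("unknown split kind"))
}

split_label <- function(split, left) {
  switch(split$kind,
    numeric_threshold = sprintf("%s %s %s", split$covariate,
                                if (left) "<=" else ">",
                                format(split$boundary)),
    ordinal_threshold = sprintf("%s %s %s", split$covariate,
                                if (left) "<=" else ">",
                                format(split$boundary)),
    category_subset = sprintf("%s %sin {%s}", split$covariate,
                              if (left) "" else "not ",
                              paste(split$boundary, collapse = ",")))
}

# ---- split search ----------------------------------------------------------

#' Score-guided split-point search
#'
#' Given the covariate selected by the instability tests, locates the
#' boundary at the argmax of the corresponding score-based statistic — the
#' model is fitted only once per node. For unordered categorical covariates
#' all binary partitions of the (up to 10) observed categories are scored by
#' the two-sample LM form; ties break to the smallest boundary or
#' lexicographically smallest subset.
#'
#' @param scores casewise score matrix of the node fit.
#' @param z the selected covariate (node cases only).
#' @param covariate its name.
#' @param min_child minimum prospective child size.
#' @param control an [mgr_tree_control()].
#' @param seed tie-shuffle seed.
#' @return a split object or `NULL` when no admissible boundary exists.
#' @export
find_split_score_guided <- function(scores, z, covariate, min_child,
                                    control = mgr_tree_control(), seed = 1L) {
  kind <- covariate_kind(z)
  if (kind == "numeric") {
    res <- max_lm_numeric(scores, z, trim = control$trim,
                          min_child = min_child, seed = seed)
    if (is.na(res$statistic)) return(NULL)
    prof <- res$profile
    best_stat <- max(prof)
    ties <- res$cuts[prof >= best_stat - 1e-12]
    zs <- sort(as.numeric(z))
    boundary <- min(zs[ties])
    new_split(covariate, "numeric_threshold", boundary,
              tie = length(ties) > 1L)
  } else if (kind == "ordinal") {
    res <- max_lm_ordinal(scores, z, min_child = min_child)
    if (is.na(res$statistic)) return(NULL)
    new_split(covariate, "ordinal_threshold", res$best_cut)
  } else {
    best_subset_split(scores, z, covariate, min_child)
  }
}

# exhaustive binary-partition search for categorical covariates, scored by
# the two-sample LM form on the decorrelated score sums
best_subset_split <- function(scores, z, covariate, min_child) {
  z <- factor(z)
  lev <- levels(droplevels(z))
  C <- length(lev)
  if (C < 2L) return(NULL)
  if (C > 10L)
    stop("categorical covariate with more than 10 levels: subset search ",
         "is exhaustive; recode the covariate")
  psi <- decorrelate_scores(scores)
  n <- nrow(psi)
  sums <- rowsum(psi, factor(z, levels = lev))
  counts <- as.numeric(table(factor(z, levels = lev)))
  best <- NULL; best_stat <- -Inf; tie <- FALSE
  for (code in seq_len(2^(C - 1L) - 1L)) {
    A <- lev[bitwAnd(code, 2^(seq_len(C) - 1L)) > 0]
    nA <- sum(counts[lev %in% A])
    if (nA < min_child || (n - nA) < min_child) next
    t_frac <- nA / n
    SA <- colSums(sums[lev %in% A, , drop = FALSE])
    stat <- sum(SA^2) / (n * t_frac * (1 - t_frac))
    if (stat > best_stat + 1e-12) {
      best_stat <- stat; best <- A; tie <- FALSE
    } else if (stat > best_stat - 1e-12 && !is.null(best)) {
      tie <- TRUE  # keep earlier (lexicographically smaller code) subset
    }
  }
  if (is.null(best)) return(NULL)
  new_split(covariate, "category_subset", best, tie = tie)
}

#' Objective-comparison split-point search
#'
#' Fits the measurement model separately on the two children of every
#' admissible segmentation of the selected covariate and picks the boundary
#' minimizing the summed minimized negative log-likelihoods (the segmented
#' objective function comparison).
#'
#' @param spec measurement-model spec.
#' @param data full response table.
#' @param cases node case indices.
#' @param z selected covariate (node cases only).
#' @param covariate its name.
#' @param min_child minimum prospective child size.
#' @param node_fit the node's [fit_ml()] (used as warm start).
#' @return a split object or `NULL`.
#' @export
find_split_objective <- function(spec, data, cases, z, covariate, min_child,
                                 node_fit = NULL) {
  cand <- candidate_splits(z, covariate, min_child)
  if (!length(cand)) return(NULL)
  start <- if (!is.null(node_fit)) node_fit$theta else NULL
  obj <- rep(NA_real_, length(cand))
  for (ci in seq_along(cand)) {
    left <- split_goes_left(cand[[ci]], z)
    val <- tryCatch({
      fl <- fit_ml(spec, data[cases[left], , drop = FALSE], start = start)
      fr <- fit_ml(spec, data[cases[!left], , drop = FALSE], start = start)
      if (!fl$converged || !fr$converged) NA_real_
      else -(sum(casewise_loglik(fl)) + sum(casewise_loglik(fr)))
    }, error = function(e) NA_real_)
    obj[ci] <- val
  }
  if (all(is.na(obj))) return(NULL)
  best <- which.min(obj)
  ties <- which(!is.na(obj) & obj <= obj[best] + 1e-9)
  sp <- cand[[min(ties)]]
  sp$tie <- length(ties) > 1L
  sp
}

candidate_splits <- function(z, covariate, min_child) {
  kind <- covariate_kind(z)
  n <- length(z)
  if (kind == "numeric") {
    zs <- sort(unique(as.numeric(z)))
    if (length(zs) < 2L) return(list())
    cuts <- zs[-length(zs)]
    keep <- vapply(cuts, function(cv) {
      nl <- sum(as.numeric(z) <= cv)
      nl >= min_child && (n - nl) >= min_child
    }, logical(1))
    lapply(cuts[keep], function(cv)
      new_split(covariate, "numeric_threshold", cv))
  } else if (kind == "ordinal") {
    zf <- if (is.ordered(z)) droplevels(z) else
      factor(z, levels = sort(unique(z)), ordered = TRUE)
    lev <- levels(zf)
    if (length(lev) < 2L) return(list())
    cuts <- lev[-length(lev)]
    keep <- vapply(cuts, function(cv) {
      nl <- sum(match(as.character(zf), lev) <= match(cv, lev))
      nl >= min_child && (n - nl) >= min_child
    }, logical(1))
    lapply(cuts[keep], function(cv)
      new_split(covariate, "ordinal_threshold", cv))
  } else {
    zf <- droplevels(factor(z))
    lev <- levels(zf)
    C <- length(lev)
    if (C < 2L) return(list())
    if (C > 10L) stop("categorical covariate with more than 10 levels")
    out <- list()
    for (code in seq_len(2^(C - 1L) - 1L)) {
      A <- lev[bitwAnd(code, 2^(seq_len(C) - 1L)) > 0]
      nA <- sum(as.character(zf) %in% A)
      if (nA >= min_child && (n - nA) >= min_child)
        out[[length(out) + 1L]] <- new_split(covariate, "category_subset", A)
    }
    out
  }
}

#' Naive likelihood-ratio split search
#'
#' For every covariate, the boundary maximizing the likelihood ratio against
#' the node's template fit is located by exhaustive child refits; the
#' covariate with the smallest (Bonferroni-adjusted) LR p value is selected
#' when it falls below `alpha`.
#'
#' @param fit node template [fit_ml()].
#' @param data full response table.
#' @param Znode covariates restricted to the node cases.
#' @param cases node case indices.
#' @param min_child minimum prospective child size.
#' @param control an [mgr_tree_control()].
#' @return list(`split`, `tests`) or `NULL` when no covariate is significant.
#' @export
find_split_naive <- function(fit, data, Znode, cases, min_child, control) {
  spec <- fit$input_spec
  R <- ncol(Znode)
  rows <- list(); best <- NULL; best_p <- Inf
  for (r in seq_len(R)) {
    z <- Znode[[r]]
    cand <- candidate_splits(z, names(Znode)[r], min_child)
    if (!length(cand)) next
    stats_r <- rep(NA_real_, length(cand))
    for (ci in seq_along(cand)) {
      left <- split_goes_left(cand[[ci]], z)
      stats_r[ci] <- tryCatch({
        fl <- fit_ml(spec, data[cases[left], , drop = FALSE],
                     start = fit$theta)
        fr <- fit_ml(spec, data[cases[!left], , drop = FALSE],
                     start = fit$theta)
        if (!fl$converged || !fr$converged) NA_real_
        else lr_test(fit, fl, fr)$statistic
      }, error = function(e) NA_real_)
    }
    if (all(is.na(stats_r))) next
    bi <- which.max(stats_r)
    df <- count_free_parameters(fit$spec)
    p <- stats::pchisq(stats_r[bi], df, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(covariate = names(Znode)[r], kind = covariate_kind(z),
                 statistic = stats_r[bi], p = p,
                 breakpoint = format(cand[[bi]]$boundary[1]),
                 stringsAsFactors = FALSE)
    if (p < best_p) {
      best_p <- p
      best <- cand[[bi]]
    }
  }
  if (!length(rows)) return(NULL)
  tests <- do.call(rbind, rows)
  R_eff <- nrow(tests)
  tests$p_adjusted <- if (control$bonferroni) pmin(1, R_eff * tests$p)
                      else tests$p
  if (min(tests$p_adjusted) >= control$alpha) return(NULL)
  sel <- tests$covariate[which.min(tests$p_adjusted)]
  if (best$covariate != sel) {
    # recompute the best split for the selected covariate
    idx <- which(tests$covariate == sel)
    z <- Znode[[sel]]
    cand <- candidate_splits(z, sel, min_child)
    stats_r <- vapply(cand, function(sp) {
      left <- split_goes_left(sp, z)
      tryCatch({
        fl <- fit_ml(spec, data[cases[left], , drop = FALSE],
                     start = fit$theta)
        fr <- fit_ml(spec, data[cases[!left], , drop = FALSE],
                     start = fit$theta)
        if (!fl$converged || !fr$converged) NA_real_
        else lr_test(fit, fl, fr)$statistic
      }, error = function(e) NA_real_)
    }, numeric(1))
    best <- cand[[which.max(stats_r)]]
  }
  list(split = best, tests = tests)
}

# ---- terminal-node evaluation ---------------------------------------------

#' WLS refit of the terminal nodes
#'
#' Ordinal-response trees: every leaf gains threshold estimates, polychoric
#' correlations, a distribution-free WLS fit and its fit indices; the
#' growth-stage ML fits are retained for audit. Numeric-response trees skip
#' the refit (not applicable) and store ML-based fit indices instead. Leaves
#' too homogeneous for polychoric estimation are flagged unevaluable.
#'
#' @param tree an [mgr_tree()].
#' @param data optional response table (defaults to the data stored in the
#'   tree).
#' @return the tree with `wls` (or `ml_indices`) entries on its leaves.
#' @export
refit_terminal_nodes <- function(tree, data = NULL) {
  stopifnot(inherits(tree, "mgr_tree"))
  if (is.null(data)) data <- tree$data
  for (id in seq_along(tree$nodes)) {
    node <- tree$nodes[[id]]
    if (!is.null(node$split)) next
    if (tree$spec$response == "ordinal") {
      node$wls <- tryCatch(
        fit_wls(tree$spec,
                polychoric(data[node$cases, , drop = FALSE],
                           tree$spec$n_categories)),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "mgr_unevaluable"))
    } else {
      fit <- node$fit
      node$ml_indices <- if (!is.null(fit) && fit$converged)
        tryCatch(ml_fit_indices(fit), error = function(e) NULL)
      else NULL
    }
    tree$nodes[[id]] <- node
  }
  tree
}

#' @export
print.mgr_tree <- function(x, digits = 3L, ...) {
  cat(sprintf("MGR model tree (%s method): n = %d, %d terminal node%s\n",
              x$control$method, nrow(x$data), n_leaves(x),
              if (n_leaves(x) > 1) "s" else ""))
  render_node <- function(id, indent) {
    node <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (is.null(node$split)) {
      fitstr <- leaf_fit_string(node, digits)
      cat(sprintf("%s* leaf %d: n = %d%s\n", pad, node$id,
                  length(node$cases), fitstr))
    } else {
      cat(sprintf("%s+ node %d: n = %d, split on %s\n", pad, node$id,
                  length(node$cases), node$split$covariate))
      for (side in 1:2) {
        child <- x$nodes[[node$children[side]]]
        cat(sprintf("%s  [%s]\n", pad,
                    split_label(node$split, side == 1L)))
        render_node(child$id, indent + 2L)
      }
    }
  }
  render_node(1L, 0L)
  invisible(x)
}

leaf_fit_string <- function(node, digits = 3L) {
  if (!is.null(node$wls)) {
    if (inherits(node$wls, "mgr_unevaluable"))
      return(" (unevaluable)")
    return(sprintf(", WLS chi2 = %.2f (df %d), RMSEA = %.3f",
                   node$wls$chi2, node$wls$df, node$wls$rmsea))
  }
  if (!is.null(node$ml_indices))
    return(sprintf(", ML chi2 = %.2f (df %d), RMSEA = %.3f",
                   node$ml_indices$chi2, node$ml_indices$df,
                   node$ml_indices$rmsea))
  ""
}

n_leaves <- function(tree) sum(vapply(tree$nodes,
                                      function(nd) is.null(nd$split),
                                      logical(1)))

#' Terminal nodes of a tree
#'
#' @param tree an [mgr_tree()].
#' @return list of leaf node records (id, cases, rule_path, fits).
#' @export
tree_leaves <- function(tree) {
  Filter(function(nd) is.null(nd$split), tree$nodes)
}

#' @export
summary.mgr_tree <- function(object, ...) {
  leaves <- tree_leaves(object)
  df <- do.call(rbind, lapply(leaves, function(nd) {
    fi <- if (!is.null(nd$wls) && !inherits(nd$wls, "mgr_unevaluable"))
      fit_indices(nd$wls)
    else if (!is.null(nd$ml_indices)) nd$ml_indices
    else list(chi2 = NA_real_, df = NA_real_, p_value = NA_real_,
              rmsea = NA_real_, rmsea_ci = c(NA_real_, NA_real_))
    data.frame(node = nd$id, n = length(nd$cases),
               rule = if (length(nd$rule_path))
                 paste(nd$rule_path, collapse = " & ") else "<root>",
               chi2 = fi$chi2, df = fi$df, p = fi$p_value, rmsea = fi$rmsea,
               rmsea_lo = fi$rmsea_ci[1], rmsea_hi = fi$rmsea_ci[2],
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Classify a grown tree against the generating truth
#'
#' Three stability levels: `"stable"` when the leaf partition equals the
#' planted subgroup partition exactly; `"inaccurate_split_point"` when the
#' structure is correct (all split covariates relevant, non-numeric
#' boundaries exact) but a numeric boundary is misplaced — snapping every
#' numeric boundary to the nearest true boundary reproduces the planted
#' partition; `"incorrect_split"` otherwise (at least one faulty split).
#'
#' @param tree an [mgr_tree()].
#' @param manifest a scenario manifest (see [make_scenario1()]).
#' @return one of `"stable"`, `"inaccurate_split_point"`, `"incorrect_split"`.
#' @export
classify_tree_stability <- function(tree, manifest) {
  stopifnot(inherits(tree, "mgr_tree"))
  if (length(manifest$labels) != nrow(tree$data))
    stop("manifest does not match the tree's sample")
  truth <- split(seq_along(manifest$labels), manifest$labels)
  truth_sets <- lapply(truth, sort)
  # derive leaf membership from the split rules themselves (robust to any
  # inconsistency between stored case sets and rules)
  resplit_with <- function(tr, id, cases) {
    nd <- tr$nodes[[id]]
    if (is.null(nd$split)) return(list(sort(cases)))
    left <- cases[split_goes_left(nd$split, tree$Z[cases, nd$split$covariate])]
    right <- setdiff(cases, left)
    c(resplit_with(tr, nd$children[1L], left),
      resplit_with(tr, nd$children[2L], right))
  }
  leaf_sets <- resplit_with(tree, 1L, seq_len(nrow(tree$data)))
  split_covs <- unlist(lapply(tree$nodes, function(nd)
    if (is.null(nd$split)) NULL else nd$split$covariate))
  same_partition <- function(a, b) {
    if (length(a) != length(b)) return(FALSE)
    ka <- sort(unname(vapply(a, function(s) paste(s, collapse = ","),
                             character(1))))
    kb <- sort(unname(vapply(b, function(s) paste(s, collapse = ","),
                             character(1))))
    all(ka == kb)
  }
  if (same_partition(leaf_sets, truth_sets) &&
      all(split_covs %in% manifest$relevant)) return("stable")

  # structural check with numeric boundaries snapped to the truth
  true_numeric <- list()
  for (g in names(manifest$rules)) for (cond in manifest$rules[[g]]) {
    if (cond$op %in% c("<=", ">"))
      true_numeric[[cond$covariate]] <-
        unique(c(true_numeric[[cond$covariate]], cond$value))
  }
  relevant <- manifest$relevant
  ok_structure <- TRUE
  snapped <- tree
  for (id in seq_along(snapped$nodes)) {
    sp <- snapped$nodes[[id]]$split
    if (is.null(sp)) next
    if (!(sp$covariate %in% relevant)) { ok_structure <- FALSE; break }
    if (sp$kind == "numeric_threshold") {
      tb <- true_numeric[[sp$covariate]]
      if (is.null(tb)) { ok_structure <- FALSE; break }
      snapped$nodes[[id]]$split$boundary <- tb[which.min(abs(tb - sp$boundary))]
    }
  }
  if (ok_structure) {
    resplit <- function(id, cases) {
      nd <- snapped$nodes[[id]]
      if (is.null(nd$split)) return(list(sort(cases)))
      left <- cases[split_goes_left(nd$split, tree$Z[cases, nd$split$covariate])]
      right <- setdiff(cases, left)
      c(resplit(nd$children[1L], left), resplit(nd$children[2L], right))
    }
    snapped_sets <- resplit(1L, seq_len(nrow(tree$data)))
    if (same_partition(snapped_sets, truth_sets))
      return("inaccurate_split_point")
  }
  "incorrect_split"
}
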