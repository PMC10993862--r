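#' Grow a forest of decorrelated DIF-detection trees
#'
#' Grows `n_trees` trees on the full sample (no bagging, by design: terminal
#' node parameter estimates stay directly replicable on the original data).
#' Decorrelation comes from random split selection: at every node of every
#' tree an independent seeded draw of `mtry` covariates is considered.
#' After growth, terminal nodes are evaluated (WLS refit for ordinal
#' responses, ML fit indices for numeric) and leaves passing the fit cutoff
#' are pooled into subgroup reports (see [filter_subgroups()]).
#'
#' Per-tree seeds are derived deterministically from the master seed; the
#' simulated null references for the instability tests are shared across
#' trees, so identical inputs yield identical forests.
#'
#' @param data response table. @param Z covariate data frame.
#' @param spec an [mgr_spec()].
#' @param n_trees ensemble size (default 50).
#' @param mtry covariates sampled at each node (default 3).
#' @param cutoff_kind `"rmsea"` (leaf passes if RMSEA <= cutoff_value) or
#'   `"chi2_p"` (leaf passes if the chi-square p value >= cutoff_value).
#' @param cutoff_value cutoff (default 0.05).
#' @param control an [mgr_tree_control()]; its `min_size` defaults to 100
#'   here if unset.
#' @param seed master seed.
#' @param bootstrap non-canonical bootstrap resampling flag (default FALSE;
#'   the canonical forest refits the full sample in every tree).
#' @return an object of class `mgr_forest`: `trees` (lightweight per-tree
#'   leaf records), `reports` ([filter_subgroups()] output), controls and
#'   bookkeeping (`n_skipped` trees whose root fit failed).
#' @export
mgr_forest <- function(data, Z, spec, n_trees = 50L, mtry = 3L,
                       cutoff_kind = c("rmsea", "chi2_p"),
                       cutoff_value = 0.05,
                       control = mgr_tree_control(min_size = 100L),
                       seed = 1L, bootstrap = FALSE) {
  cutoff_kind <- match.arg(cutoff_kind)
  Z <- as.data.frame(Z)
  data <- as.data.frame(data)
  stopifnot(n_trees >= 1L, mtry >= 1L, mtry <= ncol(Z))
  if (is.null(control$min_size)) control$min_size <- 100L
  control$mtry <- as.integer(mtry)
  n <- nrow(data)
  trees <- vector("list", n_trees)
  n_skipped <- 0L
  for (b in seq_len(n_trees)) {
    ctl_b <- control
    ctl_b$seed <- (as.integer(seed) + 104729L * b) %% .Machine$integer.max
    # shared null references across trees (and across forests when a caller
    # presets ref_seed)
    ctl_b$ref_seed <- control$ref_seed %||% as.integer(seed)
    rows <- seq_len(n)
    if (bootstrap)
      rows <- with_seed(ctl_b$seed + 1L, sample.int(n, n, replace = TRUE))
    tr <- tryCatch(
      suppressWarnings(mgr_tree(data[rows, , drop = FALSE],
                                Z[rows, , drop = FALSE], spec,
                                control = ctl_b)),
      error = function(e) e)
    if (inherits(tr, "error")) {
      n_skipped <- n_skipped + 1L
      trees[[b]] <- NULL
      next
    }
    trees[[b]] <- forest_tree_record(tr, rows)
  }
  forest <- structure(
    list(trees = trees, spec = spec, n_trees = n_trees, mtry = mtry,
         cutoff_kind = cutoff_kind, cutoff_value = cutoff_value,
         control = control, seed = as.integer(seed), bootstrap = bootstrap,
         n_skipped = n_skipped, n = n),
    class = "mgr_forest")
  forest$reports <- filter_subgroups(forest, data)
  forest
}

# strip a grown tree to the leaf records the forest needs
forest_tree_record <- function(tree, rows) {
  leaves <- tree_leaves(tree)
  list(leaves = lapply(leaves, function(nd) {
    fi <- if (!is.null(nd$wls) && !inherits(nd$wls, "mgr_unevaluable"))
      fit_indices(nd$wls)
    else if (!is.null(nd$ml_indices)) nd$ml_indices
    else NULL
    list(cases = sort(rows[nd$cases]),
         rule = if (length(nd$rule_path))
           paste(nd$rule_path, collapse = " & ") else "<root>",
         n = length(nd$cases), indices = fi)
  }))
}

#' Pool and filter well-fitting forest subgroups
#'
#' Leaves whose fit passes the forest's cutoff are pooled across trees;
#' leaves realizing the same case set (possibly via different but equivalent
#' rules) are merged, with `freq` counting the trees that identified the
#' subgroup. Strict-subset relations among the reported case sets are
#' annotated (`subset_of`), since forests typically surface random subsets
#' of true subgroups alongside the subgroups themselves. Reports are sorted
#' by fit (ascending RMSEA).
#'
#' @param forest an [mgr_forest()].
#' @param data response table (unused for filtering; retained so reports can
#'   be recomputed against the sample).
#' @return data frame of class `mgr_subgroups` with columns rule, n, chi2,
#'   df, p, rmsea, rmsea_lo, rmsea_hi, freq, subset_of, and attribute
#'   `case_sets` (list of the matching case-index vectors).
#' @export
filter_subgroups <- function(forest, data = NULL) {
  stopifnot(inherits(forest, "mgr_forest"))
  passes <- function(fi) {
    if (is.null(fi)) return(FALSE)
    if (forest$cutoff_kind == "rmsea") fi$rmsea <= forest$cutoff_value
    else fi$p_value >= forest$cutoff_value
  }
  pool <- new.env(parent = emptyenv())
  for (tr in forest$trees) {
    if (is.null(tr)) next
    for (lf in tr$leaves) {
      if (!passes(lf$indices)) next
      key <- paste(lf$cases, collapse = ",")
      hit <- pool[[key]]
      if (is.null(hit)) {
        pool[[key]] <- list(cases = lf$cases, rule = lf$rule, n = lf$n,
                            indices = lf$indices, freq = 1L)
      } else {
        hit$freq <- hit$freq + 1L
        pool[[key]] <- hit
      }
    }
  }
  keys <- ls(pool)
  if (!length(keys)) {
    out <- data.frame(rule = character(0), n = integer(0), chi2 = numeric(0),
                      df = numeric(0), p = numeric(0), rmsea = numeric(0),
                      rmsea_lo = numeric(0), rmsea_hi = numeric(0),
                      freq = integer(0), subset_of = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "case_sets") <- list()
    class(out) <- c("mgr_subgroups", class(out))
    return(out)
  }
  recs <- lapply(keys, function(k) pool[[k]])
  df <- do.call(rbind, lapply(recs, function(r) {
    ci <- r$indices$rmsea_ci
    data.frame(rule = r$rule, n = r$n, chi2 = r$indices$chi2,
               df = r$indices$df, p = r$indices$p_value,
               rmsea = r$indices$rmsea,
               rmsea_lo = ci[1], rmsea_hi = ci[2], freq = r$freq,
               stringsAsFactors = FALSE)
  }))
  sets <- lapply(recs, function(r) r$cases)
  ord <- order(df$rmsea, -df$freq, df$n)
  df <- df[ord, , drop = FALSE]
  sets <- sets[ord]
  subset_of <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    sup <- which(vapply(seq_len(nrow(df)), function(j) {
      j != i && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
    subset_of[i] <- if (length(sup)) paste(sup, collapse = ";") else ""
  }
  df$subset_of <- subset_of
  rownames(df) <- NULL
  attr(df, "case_sets") <- sets
  class(df) <- c("mgr_subgroups", class(df))
  df
}

#' @export
print.mgr_forest <- function(x, max_rows = 10L, ...) {
  grown <- sum(!vapply(x$trees, is.null, logical(1)))
  cat(sprintf(
    "MGR model forest: %d trees grown (%d skipped), mtry = %d, %s cutoff %g\n",
    grown, x$n_skipped, x$mtry, x$cutoff_kind, x$cutoff_value))
  rep <- x$reports
  cat(sprintf("Filtered subgroups: %d\n", nrow(rep)))
  if (nrow(rep)) {
    show <- utils::head(as.data.frame(rep)[, c("rule", "n", "chi2", "df",
                                               "rmsea", "freq", "subset_of")],
                        max_rows)
    show$chi2 <- round(show$chi2, 2)
    show$rmsea <- round(show$rmsea, 3)
    print(show)
    if (nrow(rep) > max_rows) cat("  ... and", nrow(rep) - max_rows, "more\n")
  }
  invisible(x)
}

#' Subgroup recovery experiment
#'
#' Repeats the scenario-2 pipeline: generate a dataset, grow a forest,
#' filter subgroups, and score whether the planted subgroups were recovered.
#' A subgroup counts as recovered when some filtered report's case set
#' equals the planted case set exactly (default), or at Jaccard similarity
#' of at least `jaccard` when `relaxed = TRUE` (reported separately).
#'
#' @param scenario `"sim2_ordinal"` or `"sim2_numeric"`.
#' @param n_datasets replicate datasets.
#' @param n_trees trees per forest.
#' @param mtry,cutoff_value,control forwarded to [mgr_forest()].
#' @param seed master seed.
#' @param relaxed also compute Jaccard-relaxed recovery?
#' @param jaccard threshold for the relaxed criterion.
#' @return list with `at_least_one`, `both` (fractions with binomial
#'   standard errors), the relaxed variants when requested, and the
#'   per-dataset detail table.
#' @export
recovery_experiment <- function(scenario = c("sim2_ordinal", "sim2_numeric"),
                                n_datasets = 20L, n_trees = 10L, mtry = 3L,
                                cutoff_value = 0.05,
                                control = mgr_tree_control(min_size = 100L),
                                seed = 1L, relaxed = FALSE, jaccard = 0.95) {
  scenario <- match.arg(scenario)
  response <- if (scenario == "sim2_ordinal") "ordinal" else "numeric"
  detail <- vector("list", n_datasets)
  control$ref_seed <- as.integer(seed)  # one null reference per experiment
  for (d in seq_len(n_datasets)) {
    ds_seed <- (as.integer(seed) + 7907L * d) %% .Machine$integer.max
    sc <- make_scenario2(response, seed = ds_seed)
    fo <- mgr_forest(sc$data, sc$Z, sc$manifest$spec, n_trees = n_trees,
                     mtry = mtry, cutoff_value = cutoff_value,
                     control = control, seed = ds_seed)
    sets <- attr(fo$reports, "case_sets")
    planted <- lapply(split(seq_along(sc$manifest$labels),
                            sc$manifest$labels)[c("R1", "R2")], sort)
    exact <- vapply(planted, function(ps)
      any(vapply(sets, function(s) length(s) == length(ps) &&
                   all(s == ps), logical(1))), logical(1))
    jac <- vapply(planted, function(ps)
      any(vapply(sets, function(s) {
        length(intersect(s, ps)) / length(union(s, ps)) >= jaccard
      }, logical(1))), logical(1))
    detail[[d]] <- data.frame(dataset = d, seed = ds_seed,
                              r1 = exact[1], r2 = exact[2],
                              r1_jaccard = jac[1], r2_jaccard = jac[2])
  }
  detail <- do.call(rbind, detail)
  frac <- function(x) {
    f <- mean(x)
    list(fraction = f, se = sqrt(f * (1 - f) / length(x)))
  }
  out <- list(scenario = scenario, n_datasets = n_datasets,
              n_trees = n_trees,
              at_least_one = frac(detail$r1 | detail$r2),
              both = frac(detail$r1 & detail$r2),
              detail = detail)
  if (relaxed) {
    out$at_least_one_jaccard <- frac(detail$r1_jaccard | detail$r2_jaccard)
    out$both_jaccard <- frac(detail$r1_jaccard & detail$r2_jaccard)
  }
  out
}
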