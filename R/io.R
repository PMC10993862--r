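#' Read a response/covariate dataset from delimited text
#'
#' Reads a delimited file with a header row and splits it into the response
#' table and the covariate table according to a schema. Ordinal response
#' columns are validated as integers within the declared category range;
#' covariates are coerced to their declared kinds. Row alignment is
#' preserved; missing cells are an error (missing data are unsupported).
#'
#' @param path file path (tab- or comma-delimited; inferred from the
#'   extension, `.csv` means comma).
#' @param schema list with `responses` (character vector of column names),
#'   `response_scale` (`"ordinal"`/`"numeric"`), `n_categories` (ordinal),
#'   and `covariates` (named character vector of kinds: `"numeric"`,
#'   `"ordinal"`, `"categorical"`).
#' @return list with `data` (responses) and `Z` (covariates).
#' @export
read_dataset <- function(path, schema) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c(schema$responses, names(schema$covariates)), names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(raw[c(schema$responses, names(schema$covariates))]))
    stop("missing cells are not supported")
  data <- raw[schema$responses]
  if (identical(schema$response_scale, "ordinal")) {
    K <- schema$n_categories
    for (j in seq_along(data)) {
      v <- data[[j]]
      if (!is.numeric(v) || any(v != round(v)))
        stop("response column ", schema$responses[j],
             " must be integer-coded")
      lo <- min(v)
      if (!(lo %in% c(0L, 1L)))
        stop("response column ", schema$responses[j],
             ": categories must start at 0 or 1")
      bad <- which(v - lo >= K | v < lo)
      if (length(bad))
        stop("response column ", schema$responses[j], ", row ", bad[1],
             ": category ", v[bad[1]], " outside the declared range")
    }
  }
  Z <- raw[names(schema$covariates)]
  for (j in seq_along(Z)) {
    kind <- schema$covariates[[j]]
    v <- Z[[j]]
    Z[[j]] <- switch(kind,
      numeric = {
        if (!is.numeric(v)) stop("covariate ", names(Z)[j], " must be numeric")
        v
      },
      ordinal = {
        if (!is.numeric(v) || any(v != round(v)))
          stop("covariate ", names(Z)[j],
               " is declared ordinal but has non-integer values")
        factor(v, levels = sort(unique(v)), ordered = TRUE)
      },
      categorical = factor(v),
      stop("unknown covariate kind ", kind))
  }
  list(data = data, Z = Z)
}

#' Write a dataset (responses + covariates) as tab-delimited text
#'
#' @param data response table. @param Z covariate table. @param path output
#' file.
#' @export
write_dataset <- function(data, Z, path) {
  out <- cbind(as.data.frame(data), as.data.frame(Z))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a measurement-model specification from a YAML config
#'
#' The config declares `response` (ordinal/numeric), `n_categories`,
#' `items`, `latents`, and `loadings` as a list of `[item, latent, value]`
#' entries where `value` is a number (fixed) or `"free"`. Optional keys:
#' `latent_cov` (`"free"` or explicit entries), `intercepts`, `residuals`.
#'
#' @param path YAML file path.
#' @return an [mgr_spec()].
#' @export
read_mgr_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read spec configs")
  cfg <- yaml::read_yaml(path)
  items <- as.character(cfg$items)
  latents <- as.character(cfg$latents)
  L <- matrix(0, length(items), length(latents),
              dimnames = list(items, latents))
  for (e in cfg$loadings) {
    it <- as.character(e[[1]]); lt <- as.character(e[[2]])
    if (!(it %in% items) || !(lt %in% latents))
      stop("loading entry refers to unknown item/latent: ", it, "/", lt)
    L[it, lt] <- if (identical(e[[3]], "free")) NA_real_ else as.numeric(e[[3]])
  }
  mgr_spec(L, response = cfg$response,
           n_categories = cfg$n_categories,
           latent_cov = cfg$latent_cov %||% "free",
           intercepts = cfg$intercepts %||% "free",
           residuals = cfg$residuals %||% "free")
}

#' Write a flat parameter table as tab-delimited text
#'
#' @param fit an [fit_ml()] or [fit_wls()] object.
#' @param path output file.
#' @return the path, invisibly. WLS fits append a one-line fit summary
#'   (chi2, df, p, rmsea, ci, n) as comment lines.
#' @export
write_fit_report <- function(fit, path) {
  est <- if (inherits(fit, "mgr_ml") || inherits(fit, "mgr_wls"))
    flatten_parameters(fit$theta)
  else stop("unsupported fit object")
  df <- data.frame(parameter = names(est), estimate = as.numeric(est))
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(fit, "mgr_wls"))
    writeLines(sprintf(
      "# chi2=%.6g df=%d p=%.6g rmsea=%.6g ci_low=%.6g ci_high=%.6g n=%d",
      fit$chi2, fit$df, fit$p_value, fit$rmsea, fit$rmsea_ci[1],
      fit$rmsea_ci[2], fit$n), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a forest subgroup report as tab-delimited text
#'
#' Mirrors the forest summary layout: rule, n, chi2, df, p, rmsea, CI
#' bounds, frequency, and subset links.
#'
#' @param reports a [filter_subgroups()] result.
#' @param path output file.
#' @export
write_subgroup_report <- function(reports, path) {
  utils::write.table(as.data.frame(reports), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a tree to a nested JSON-style structure
#'
#' @param tree an [mgr_tree()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required for JSON serialization")
  as_list <- function(id) {
    nd <- tree$nodes[[id]]
    out <- list(id = nd$id, n = length(nd$cases),
                rule_path = paste(nd$rule_path, collapse = " & "))
    fi <- if (!is.null(nd$wls) && !inherits(nd$wls, "mgr_unevaluable"))
      fit_indices(nd$wls)
    else if (!is.null(nd$ml_indices)) nd$ml_indices else NULL
    if (!is.null(fi))
      out$fit <- list(chi2 = fi$chi2, df = fi$df, p = fi$p_value,
                      rmsea = fi$rmsea)
    if (!is.null(nd$split)) {
      out$split <- list(covariate = nd$split$covariate,
                        kind = nd$split$kind,
                        boundary = nd$split$boundary)
      out$children <- lapply(nd$children, as_list)
    }
    out
  }
  js <- jsonlite::toJSON(as_list(1L), auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
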