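# The family-level workflow: dependent-variable transform, single-feature
# screens, correlation matrix, full and reduced structural models
# (VIF filtering then backward elimination), full and reduced categorical
# models (backward elimination only), and an optional combined model built
# from the union of the two reduced feature sets.

feature_columns <- c("ecd_distance", "ecd_contacts", "tmd_distance",
                     "tmd_contacts", "tmd_crossing_angle", "tmd_exit_angle")

#' Read a performance table CSV
#'
#' Expected columns: design_id, os_meptr, fi, ntev_ecd, ntev_tmd,
#' ctev_ecd, ctev_tmd, ligand.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_performance_table <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("design_id", "os_meptr", "fi")
  missing <- setdiff(needed, names(p))
  if (length(missing) > 0) {
    stop("performance table missing columns: ",
         paste(missing, collapse = ", "))
  }
  p
}

#' Run the structure-function analysis for one receptor family
#'
#' Steps, in order: (1) optional log10 transform of the dependent
#' variable; (2) single-feature regressions; (3) Pearson correlation
#' matrix of the structural features; (4) full structural model on
#' standardized features; (5) VIF reduction followed by backward
#' elimination, giving the reduced structural model; (6) full and reduced
#' (backward elimination only) categorical one-hot models, when the
#' performance table carries design columns; (7) optional combined model
#' on the union of the reduced structural and reduced categorical feature
#' sets. Every reduction is recorded in a trace.
#'
#' @param features data.frame with design_id + the six structural feature
#'   columns (a subset is allowed: features absent from the table, e.g. a
#'   contact count that is identically zero and was dropped, are simply
#'   not modeled).
#' @param performance data.frame with design_id, os_meptr, fi and
#'   (optionally) the categorical design columns.
#' @param dv Dependent variable: `"os"` or `"fi"`.
#' @param log_dv Apply log10 to the dependent variable first.
#' @param combined Also fit the combined model (default TRUE when both
#'   reduced models retain features).
#' @param alpha Backward-elimination significance level (default 0.05).
#' @param vif_threshold VIF removal threshold (default 10).
#' @param family Label stored in the report.
#' @param categorical_vif Also run the VIF phase on categorical models
#'   (default FALSE: categorical reductions use backward elimination only).
#' @return List of class `recep_report`; see details in the fields:
#'   `single_feature`, `correlation`, `full_structural`,
#'   `reduced_structural`, `vif_trace`, `elimination_trace`,
#'   `full_categorical`, `reduced_categorical`, `categorical_trace`,
#'   `combined`, `config`.
#' @export
run_family_analysis <- function(features, performance, dv = c("os", "fi"),
                                log_dv = FALSE, combined = TRUE,
                                alpha = 0.05, vif_threshold = 10,
                                family = "family",
                                categorical_vif = FALSE) {
  dv <- match.arg(dv)
  if (!"design_id" %in% names(features)) stop("features need design_id")
  if (!"design_id" %in% names(performance)) {
    stop("performance needs design_id")
  }
  unmatched <- setdiff(performance$design_id, features$design_id)
  if (length(unmatched) > 0) {
    stop("designs missing from feature table: ",
         paste(utils::head(unmatched, 5), collapse = ", "),
         if (length(unmatched) > 5) " ..." else "")
  }
  # deterministic row order regardless of input order
  performance <- performance[order(performance$design_id), , drop = FALSE]
  merged <- merge(performance, features, by = "design_id", sort = TRUE)

  yraw <- if (dv == "os") merged$os_meptr else merged$fi
  y <- if (log_dv) log_transform(yraw, merged$design_id) else yraw

  fcols <- intersect(feature_columns, names(features))
  Xraw <- as.matrix(merged[, fcols, drop = FALSE])
  Z <- standardize(Xraw)

  single <- simple_regressions(Z, y)
  corr <- pearson_correlation_matrix(Xraw)

  full_structural <- ols_fit(Z, y)
  red_vif <- reduce_by_vif(Z, threshold = vif_threshold)
  red_be <- backward_eliminate(red_vif$X, y, alpha = alpha)

  full_cat <- reduced_cat <- cat_trace <- NULL
  has_design <- all(c("ntev_ecd", "ntev_tmd", "ctev_ecd", "ctev_tmd",
                      "ligand") %in% names(merged))
  if (has_design) {
    H <- one_hot_encode(merged)
    full_cat <- ols_fit(H, y)
    Hsel <- H
    cat_vif_trace <- NULL
    if (categorical_vif) {
      rv <- reduce_by_vif(H, threshold = vif_threshold)
      Hsel <- rv$X
      cat_vif_trace <- rv$trace
    }
    cat_be <- backward_eliminate(Hsel, y, alpha = alpha)
    reduced_cat <- cat_be
    cat_trace <- rbind(cat_vif_trace, cat_be$trace)
  }

  comb <- NULL
  if (combined && has_design &&
      length(red_be$kept) > 0 && length(reduced_cat$kept) > 0) {
    Xc <- cbind(Z[, red_be$kept, drop = FALSE],
                H[, reduced_cat$kept, drop = FALSE])
    comb <- ols_fit(Xc, y)
  }

  out <- list(
    family = family,
    dv = dv, log_dv = log_dv, n = nrow(merged),
    design_ids = merged$design_id,
    single_feature = single,
    correlation = corr,
    full_structural = full_structural,
    reduced_structural = red_be$fit,
    reduced_structural_features = red_be$kept,
    structural_intercept_only = red_be$intercept_only,
    vif_trace = red_vif$trace,
    elimination_trace = red_be$trace,
    full_categorical = full_cat,
    reduced_categorical = if (is.null(reduced_cat)) NULL else reduced_cat$fit,
    reduced_categorical_features =
      if (is.null(reduced_cat)) NULL else reduced_cat$kept,
    categorical_trace = cat_trace,
    combined = comb,
    config = list(dv = dv, log_dv = log_dv, alpha = alpha,
                  vif_threshold = vif_threshold,
                  categorical_vif = categorical_vif,
                  features = fcols)
  )
  class(out) <- "recep_report"
  out
}

#' @export
print.recep_report <- function(x, ...) {
  cat("<recep_report> family:", x$family, " n =", x$n, " dv =",
      if (x$log_dv) paste0("log10(", x$dv, ")") else x$dv, "\n")
  cat("full structural adj R2:",
      round(x$full_structural$adj_r_squared, 3), "\n")
  cat("reduced structural [",
      paste(x$reduced_structural_features, collapse = ", "),
      "] adj R2:", round(x$reduced_structural$adj_r_squared, 3), "\n")
  if (!is.null(x$full_categorical)) {
    cat("full categorical adj R2:",
        round(x$full_categorical$adj_r_squared, 3), "\n")
    cat("reduced categorical [",
        paste(x$reduced_categorical_features, collapse = ", "),
        "] adj R2:", round(x$reduced_categorical$adj_r_squared, 3), "\n")
  }
  if (!is.null(x$combined)) {
    cat("combined adj R2:", round(x$combined$adj_r_squared, 3), "\n")
  }
  invisible(x)
}

fit_to_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(terms = names(fit$coefficients),
       coefficients = unname(fit$coefficients), se = unname(fit$se),
       t = unname(fit$t), p = unname(fit$p),
       ci_lower = unname(fit$ci_lower), ci_upper = unname(fit$ci_upper),
       r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
       n = fit$n, k = fit$k, df_residual = fit$df_residual,
       rank_deficient = fit$rank_deficient)
}

#' Serialize an analysis report to JSON
#'
#' @param report A `recep_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    family = report$family, dv = report$dv, log_dv = report$log_dv,
    n = report$n, config = report$config,
    single_feature = report$single_feature,
    correlation = list(features = colnames(report$correlation),
                       matrix = unclass(report$correlation)),
    full_structural = fit_to_list(report$full_structural),
    reduced_structural = fit_to_list(report$reduced_structural),
    reduced_structural_features = report$reduced_structural_features,
    vif_trace = report$vif_trace,
    elimination_trace = report$elimination_trace,
    full_categorical = fit_to_list(report$full_categorical),
    reduced_categorical = fit_to_list(report$reduced_categorical),
    reduced_categorical_features = report$reduced_categorical_features,
    categorical_trace = report$categorical_trace,
    combined = fit_to_list(report$combined)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Render an analysis report as Markdown
#'
#' @param report A `recep_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_markdown <- function(report, path) {
  fmt_fit <- function(fit, title) {
    if (is.null(fit)) return(character(0))
    tab <- coef_table(fit)
    c(paste0("## ", title),
      sprintf("n = %d, k = %d, R2 = %.4f, adj R2 = %.4f%s", fit$n, fit$k,
              fit$r_squared, fit$adj_r_squared,
              if (fit$rank_deficient) " (rank-deficient, minimum-norm)"
              else ""),
      "", "| term | estimate | se | p |", "|---|---|---|---|",
      sprintf("| %s | %.4f | %.4f | %.4g |", tab$term, tab$estimate,
              tab$se, tab$p), "")
  }
  fmt_trace <- function(trace, title) {
    if (is.null(trace) || nrow(trace) == 0) return(character(0))
    c(paste0("## ", title), "", "| step | removed | criterion | value |",
      "|---|---|---|---|",
      sprintf("| %d | %s | %s | %.4g |", trace$step, trace$removed,
              trace$criterion, trace$value), "")
  }
  lines <- c(
    paste0("# Structure-function analysis: ", report$family),
    sprintf("Dependent variable: %s%s, n = %d", report$dv,
            if (report$log_dv) " (log10)" else "", report$n), "",
    "## Single-feature regressions", "",
    "| feature | r | R2 | slope | p |", "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %.3f | %.4g |",
            report$single_feature$feature, report$single_feature$r,
            report$single_feature$r_squared, report$single_feature$slope,
            report$single_feature$p), "",
    fmt_fit(report$full_structural, "Full structural model"),
    fmt_trace(report$vif_trace, "VIF reduction trace"),
    fmt_trace(report$elimination_trace, "Backward elimination trace"),
    fmt_fit(report$reduced_structural, "Reduced structural model"),
    fmt_fit(report$full_categorical, "Full categorical model"),
    fmt_trace(report$categorical_trace, "Categorical reduction trace"),
    fmt_fit(report$reduced_categorical, "Reduced categorical model"),
    fmt_fit(report$combined, "Combined model")
  )
  writeLines(lines, path)
  invisible(path)
}
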