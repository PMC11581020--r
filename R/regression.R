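# Linear-model workflow: transformations, OLS with full inference,
# collinearity screening (VIF), backward elimination, and one-hot
# categorical encoding. Fitting is done explicitly through the
# (pseudo-)inverse of the normal equations rather than lm() so that
# rank-deficient design matrices -- which arise by construction when a
# full one-hot encoding is combined with an intercept -- are handled the
# way permissive OLS software handles them: minimum-norm coefficients,
# residual degrees of freedom n - rank, and a recorded rank warning.

#' Base-10 logarithm of a positive dependent variable
#'
#' @param values Numeric vector, all > 0.
#' @param ids Optional identifiers used in the error message.
#' @return `log10(values)`.
#' @export
log_transform <- function(values, ids = NULL) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0) {
    lab <- if (is.null(ids)) paste("index", bad[1]) else ids[bad[1]]
    stop("log transform requires positive values; offending entry: ", lab,
         " (", values[bad[1]], ")")
  }
  log10(values)
}

#' Standardize columns to mean 0, sample standard deviation 1
#'
#' Uses the sample standard deviation (denominator n - 1).
#'
#' @param x Numeric matrix or data.frame (observations x features).
#' @return Matrix of the same shape.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0) {
    nm <- colnames(x)[zero[1]]
    if (is.null(nm)) nm <- paste("column", zero[1])
    stop("cannot standardize zero-variance column: ", nm)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Pearson correlation matrix of features
#'
#' @param x Numeric matrix or data.frame with >= 3 rows and nonzero-variance
#'   columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 observations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  stats::cor(x)
}

#' Ordinary least squares with Student-t inference
#'
#' Fits `y ~ X` with an intercept (added internally). Rank-deficient
#' designs are fit by the Moore-Penrose pseudo-inverse (minimum-norm
#' solution) and flagged in `$rank_deficient`; residual degrees of freedom
#' are `n - rank`. Two-sided p-values and 95% confidence intervals use the
#' Student t distribution on the residual degrees of freedom.
#'
#' @param X Numeric matrix/data.frame (observations x features); may have
#'   zero columns for an intercept-only fit.
#' @param y Numeric response vector.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @param force Fit even when `n <= k + 1` leaves no residual degrees of
#'   freedom (inference columns become NA).
#' @return Object of class `recep_fit`: list with `features`,
#'   `coefficients` (named, intercept first), `se`, `t`, `p`,
#'   `ci_lower`, `ci_upper`, `r_squared`, `adj_r_squared`, `n`, `k`,
#'   `df_residual`, `rank_deficient`, `fitted`, `residuals`.
#' @export
ols_fit <- function(X, y, conf_level = 0.95, force = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) == 0 && length(y) > 0) X <- matrix(nrow = length(y), ncol = 0)
  n <- length(y)
  if (nrow(X) != n) stop("X and y have different numbers of observations")
  k <- ncol(X)
  feat <- colnames(X)
  if (is.null(feat) && k > 0) feat <- paste0("x", seq_len(k))
  Xi <- cbind(`(Intercept)` = 1, X)
  colnames(Xi) <- c("(Intercept)", feat)

  sv <- svd(Xi)
  tol <- max(dim(Xi)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  rank_deficient <- rank < ncol(Xi)
  df_res <- n - rank
  if (df_res < 1 && !force) {
    stop("insufficient residual degrees of freedom (n = ", n,
         ", rank = ", rank, "); pass force = TRUE to fit without inference")
  }
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  pinv <- sv$v %*% (dinv * t(sv$u))          # pseudo-inverse of Xi
  beta <- as.numeric(pinv %*% y)
  names(beta) <- colnames(Xi)
  fitted <- as.numeric(Xi %*% beta)
  resid <- y - fitted

  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  adj_r2 <- if (df_res > 0 && n > 1) {
    1 - (1 - r2) * (n - 1) / df_res
  } else {
    NA_real_
  }
  if (df_res > 0) {
    sigma2 <- ss_res / df_res
    covb <- sv$v %*% (dinv^2 * t(sv$v)) * sigma2   # pinv(Xi'Xi) * sigma2
    se <- sqrt(pmax(diag(covb), 0))
    tval <- ifelse(se > 0, beta / se, NA_real_)
    pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
    ci_lo <- beta - tcrit * se
    ci_hi <- beta + tcrit * se
  } else {
    se <- tval <- pval <- ci_lo <- ci_hi <- rep(NA_real_, length(beta))
  }
  names(se) <- names(tval) <- names(pval) <- names(beta)
  names(ci_lo) <- names(ci_hi) <- names(beta)
  structure(list(features = feat, coefficients = beta, se = se, t = tval,
                 p = pval, ci_lower = ci_lo, ci_upper = ci_hi,
                 r_squared = r2, adj_r_squared = adj_r2, n = n, k = k,
                 df_residual = df_res, rank_deficient = rank_deficient,
                 fitted = fitted, residuals = resid,
                 conf_level = conf_level),
            class = "recep_fit")
}

#' @export
print.recep_fit <- function(x, ...) {
  cat("<recep_fit> n =", x$n, " features =", x$k,
      if (x$rank_deficient) " [rank-deficient: minimum-norm fit]" else "",
      "\n")
  tab <- data.frame(coef = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  cat(sprintf("R-squared %.4f   adjusted %.4f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

# Coefficient table (data.frame) of a fit, intercept included.
coef_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(fit$se),
             t = unname(fit$t), p = unname(fit$p),
             ci_lower = unname(fit$ci_lower),
             ci_upper = unname(fit$ci_upper),
             stringsAsFactors = FALSE)
}

#' Single-feature regressions
#'
#' One simple regression of the response on each feature (with intercept),
#' reporting Pearson r, R-squared (= r^2), and the fitted slope.
#'
#' @param features data.frame or matrix of numeric features (a design_id
#'   column, if present, is dropped).
#' @param y Numeric response.
#' @return data.frame with feature, r, r_squared, slope, p.
#' @export
simple_regressions <- function(features, y) {
  if (is.data.frame(features) && "design_id" %in% names(features)) {
    features <- features[, setdiff(names(features), "design_id"),
                         drop = FALSE]
  }
  X <- as.matrix(features)
  out <- lapply(colnames(X), function(nm) {
    fit <- ols_fit(X[, nm, drop = FALSE], y)
    r <- suppressWarnings(stats::cor(X[, nm], y))
    data.frame(feature = nm, r = r, r_squared = fit$r_squared,
               slope = unname(fit$coefficients[nm]),
               p = unname(fit$p[nm]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` with `R^2_j` from regressing feature j on all
#' other features (with intercept). Perfect collinearity yields `Inf`.
#'
#' @param X Numeric matrix/data.frame with >= 2 columns.
#' @return Named numeric vector of VIFs (all >= 1, possibly `Inf`).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF requires at least 2 features")
  nm <- colnames(X)
  if (is.null(nm)) nm <- colnames(X) <- paste0("x", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- ols_fit(X[, -j, drop = FALSE], X[, j], force = TRUE)
    r2 <- min(fit$r_squared, 1)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, nm)
}

#' Iterative VIF-based feature removal
#'
#' While the largest VIF meets the threshold and at least two features
#' remain, the feature with the largest VIF is removed (ties: the later
#' column in declared order) and VIFs are recomputed.
#'
#' @param X Numeric matrix/data.frame of features.
#' @param threshold Removal threshold (default 10, i.e. remove when
#'   `VIF >= 10`).
#' @return List with `kept` (character vector), `X` (reduced matrix), and
#'   `trace` (data.frame: step, removed, criterion, value).
#' @export
reduce_by_vif <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  trace <- data.frame(step = integer(0), removed = character(0),
                      criterion = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  step <- 0
  while (ncol(X) >= 2) {
    v <- vif(X)
    mx <- max(v)
    if (mx < threshold) break
    # ties: remove the later column in declared order
    drop_j <- max(which(v == mx))
    step <- step + 1
    trace <- rbind(trace, data.frame(step = step,
                                     removed = colnames(X)[drop_j],
                                     criterion = "VIF", value = mx,
                                     stringsAsFactors = FALSE))
    X <- X[, -drop_j, drop = FALSE]
  }
  list(kept = colnames(X), X = X, trace = trace)
}

#' Backward elimination by coefficient p-value
#'
#' Iteratively refits and removes the feature with the largest p-value
#' while that p-value is `>= alpha` (ties: the later column). The
#' intercept is never removed. If every feature is eliminated, the
#' intercept-only fit is returned with `intercept_only = TRUE`.
#'
#' @param X Numeric matrix/data.frame of features.
#' @param y Numeric response.
#' @param alpha Significance level (default 0.05).
#' @return List with `fit` (a `recep_fit`), `kept`, `trace` (data.frame:
#'   step, removed, criterion, value), `intercept_only`.
#' @export
backward_eliminate <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  trace <- data.frame(step = integer(0), removed = character(0),
                      criterion = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  step <- 0
  repeat {
    fit <- ols_fit(X, y)
    if (ncol(X) == 0) break
    pv <- fit$p[fit$features]
    # rank-deficient fits can have NA p-values for aliased columns; treat
    # those as the least informative (largest) p-values
    pv[is.na(pv)] <- Inf
    mx <- max(pv)
    if (mx < alpha) break
    drop_j <- max(which(pv == mx))
    step <- step + 1
    trace <- rbind(trace, data.frame(step = step,
                                     removed = fit$features[drop_j],
                                     criterion = "p-value",
                                     value = unname(mx),
                                     stringsAsFactors = FALSE))
    X <- X[, -drop_j, drop = FALSE]
  }
  list(fit = fit, kept = colnames(X), trace = trace,
       intercept_only = ncol(X) == 0)
}

#' One-hot encode receptor design columns
#'
#' One binary column per (chain role x ECD level) and (chain role x TMD
#' level), plus one per ligand level when more than one ligand is present.
#' All levels are encoded -- no reference level is dropped -- so each
#' factor's level columns sum to 1 in every row, and the encoding is
#' rank-deficient by construction once an intercept is added. Column order
#' is deterministic: role (ntev, ctev), then factor (ecd, tmd), then level
#' (lexicographic); ligand columns last.
#'
#' @param design data.frame with columns ntev_ecd, ntev_tmd, ctev_ecd,
#'   ctev_tmd, ligand.
#' @return Numeric 0/1 matrix with one row per design.
#' @export
one_hot_encode <- function(design) {
  needed <- c("ntev_ecd", "ntev_tmd", "ctev_ecd", "ctev_tmd", "ligand")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    stop("design table missing columns: ", paste(missing, collapse = ", "))
  }
  encode_col <- function(values, prefix) {
    levels <- sort(unique(values))
    m <- vapply(levels, function(lv) as.numeric(values == lv),
                numeric(length(values)))
    m <- matrix(m, nrow = length(values))
    colnames(m) <- paste0(prefix, ":", levels)
    m
  }
  parts <- list(
    encode_col(design$ntev_ecd, "ntev_ecd"),
    encode_col(design$ntev_tmd, "ntev_tmd"),
    encode_col(design$ctev_ecd, "ctev_ecd"),
    encode_col(design$ctev_tmd, "ctev_tmd")
  )
  if (length(unique(design$ligand)) > 1) {
    parts <- c(parts, list(encode_col(design$ligand, "ligand")))
  }
  do.call(cbind, parts)
}
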