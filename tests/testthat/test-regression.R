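# Regression workflow: transforms, OLS inference, VIF, backward
# elimination, one-hot encoding.

test_that("log_transform is base 10 and rejects nonpositive values", {
  expect_equal(log_transform(c(1, 10, 100)), c(0, 1, 2))
  expect_error(log_transform(c(1, 0, 3), ids = c("a", "b", "c")), "b")
})

test_that("standardize gives mean 0, sample sd 1, and is idempotent", {
  expect_equal(as.numeric(standardize(matrix(1:3))), c(-1, 0, 1))
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5)
  Z <- standardize(X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-12)
  expect_lt(max(abs(standardize(Z) - Z)), 1e-12)
  Xc <- cbind(X, const = 5)
  expect_error(standardize(Xc), "const")
})

test_that("pearson_correlation_matrix basic properties", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  C <- pearson_correlation_matrix(X)
  expect_equal(diag(C), c(a = 1, b = 1, c = 1))
  expect_equal(C, t(C))
  expect_true(all(abs(C) <= 1 + 1e-12))
  X2 <- cbind(x = X[, 1], negx = -X[, 1])
  expect_equal(pearson_correlation_matrix(X2)["x", "negx"], -1)
  expect_error(pearson_correlation_matrix(X[1:2, ]), "at least 3")
})

test_that("ols_fit matches the normal-equations oracle and lm inference", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:60, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("f", seq_len(k))))
    y <- rnorm(n, 2 + X %*% rnorm(k), 0.7)
    fit <- ols_fit(X, y)
    Xi <- cbind(1, X)
    beta_oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)   # normal equations
    expect_lt(max(abs(fit$coefficients - beta_oracle)), 1e-8)
    sm <- summary(lm(y ~ X))
    expect_equal(unname(fit$se), unname(sm$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$p), unname(sm$coefficients[, 4]),
                 tolerance = 1e-10)
    expect_equal(fit$r_squared, sm$r.squared, tolerance = 1e-12)
    expect_equal(fit$adj_r_squared, sm$adj.r.squared, tolerance = 1e-12)
    # adjusted R2 formula check
    expect_equal(fit$adj_r_squared,
                 1 - (1 - fit$r_squared) * (n - 1) / (n - k - 1))
    expect_lte(fit$adj_r_squared, fit$r_squared)
    # CIs contain their coefficients
    expect_true(all(fit$ci_lower <= fit$coefficients &
                      fit$coefficients <= fit$ci_upper))
  }
})

test_that("exact linear data gives R2 = 1; the 4-point line is exact", {
  X <- matrix(0:3, ncol = 1, dimnames = list(NULL, "x"))
  y <- c(1, 3, 5, 7)
  fit <- ols_fit(X, y)
  expect_equal(unname(fit$coefficients), c(1, 2))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$adj_r_squared, 1)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("rank-deficient designs fit via minimum-norm with a flag", {
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  Xd <- cbind(X, dup = X[, 1])
  y <- rnorm(20, X %*% c(1, -1))
  fit <- ols_fit(Xd, y)
  expect_true(fit$rank_deficient)
  expect_equal(fit$df_residual, 20 - 3)   # rank 3, not 4
  # fitted values equal those of the full-rank fit
  fit2 <- ols_fit(X, y)
  expect_equal(fit$fitted, fit2$fitted, tolerance = 1e-8)
  # insufficient df errors unless forced
  expect_error(ols_fit(matrix(rnorm(12), 3, 4), rnorm(3)), "insufficient")
})

test_that("simple_regressions reports r, R2 = r^2, slope sign = sign(r)", {
  set.seed(13)
  X <- data.frame(up = 1:20 + rnorm(20, 0, 0.1),
                  down = -(1:20) + rnorm(20, 0, 0.1),
                  noise = rnorm(20))
  y <- as.numeric(1:20)
  tab <- simple_regressions(X, y)
  expect_equal(tab$r_squared, tab$r^2, tolerance = 1e-12)
  expect_equal(sign(tab$slope), sign(tab$r))
  expect_gt(tab$r[tab$feature == "up"], 0.99)
  expect_lt(tab$r[tab$feature == "down"], -0.99)
  # perfectly correlated pair
  tab2 <- simple_regressions(data.frame(x = y), y)
  expect_equal(tab2$r, 1)
  expect_equal(tab2$r_squared, 1)
})

test_that("vif matches the closed form and flags perfect collinearity", {
  set.seed(14)
  n <- 50
  x1 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = x1 + rnorm(n, 0, 0.1), x3 = rnorm(n))
  v <- vif(X)
  oracle <- vapply(1:3, function(j) {
    1 / (1 - summary(lm(X[, j] ~ X[, -j]))$r.squared)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-8)
  expect_true(all(v >= 1))
  # columns orthogonal to each other and the intercept: all VIF = 1
  Q <- unclass(poly(1:20, 3))
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-8)
  # duplicated column: infinite for both copies
  Xd <- cbind(a = x1, b = x1)
  expect_equal(unname(vif(Xd)), c(Inf, Inf))
})

test_that("reduce_by_vif removes iteratively until all VIF < threshold", {
  set.seed(15)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(a = x1, b = x2, c = x1 + rnorm(n, 0, 0.01))
  red <- reduce_by_vif(X, threshold = 10)
  expect_equal(nrow(red$trace), 1)
  expect_equal(red$trace$criterion, "VIF")
  expect_true(all(vif(red$X) < 10))
  # clean features: untouched, empty trace
  Xok <- cbind(a = x1, b = x2, c = rnorm(n))
  red2 <- reduce_by_vif(Xok)
  expect_equal(red2$kept, c("a", "b", "c"))
  expect_equal(nrow(red2$trace), 0)
  # exact duplicates: exactly one copy removed (the later column)
  Xd <- cbind(a = x1, b = x2, a2 = x1)
  red3 <- reduce_by_vif(Xd)
  expect_equal(red3$trace$removed, "a2")
  expect_true(all(vif(red3$X) < 10))
  # single feature terminates trivially
  red4 <- reduce_by_vif(X[, 1, drop = FALSE])
  expect_equal(red4$kept, "a")
})

test_that("backward elimination keeps significant features and traces", {
  set.seed(16)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * X[, 1] + rnorm(n, 0, 0.3)
  res <- backward_eliminate(X, y, alpha = 0.05)
  expect_true("a" %in% res$kept)
  expect_true(all(res$fit$p[res$fit$features] < 0.05))
  expect_equal(res$trace$criterion, rep("p-value", nrow(res$trace)))
  expect_false(res$intercept_only)
  # all features already significant: unchanged
  y2 <- 1 + X %*% c(2, -2, 2) + rnorm(n, 0, 0.1)
  res2 <- backward_eliminate(X, y2)
  expect_equal(res2$kept, c("a", "b", "c"))
  expect_equal(nrow(res2$trace), 0)
})

test_that("planted-support recovery: >= 95% of 200 seeded replicates", {
  # n = 32, 6 standardized features, beta = (1, 1, 0, 0, 0, 0), sd 0.5
  hits <- 0; intercept_only_null <- 0
  for (s in 1:200) {
    set.seed(s)
    X <- matrix(rnorm(32 * 6), 32, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    Z <- standardize(X)
    y <- Z %*% c(1, 1, 0, 0, 0, 0) + rnorm(32, 0, 0.5)
    res <- backward_eliminate(Z, y, alpha = 0.05)
    if (all(c("f1", "f2") %in% res$kept)) hits <- hits + 1
    # pure-noise response on the same X
    ynull <- rnorm(32, 0, 1)
    resn <- backward_eliminate(Z, ynull, alpha = 0.05)
    if (resn$intercept_only) intercept_only_null <- intercept_only_null + 1
  }
  expect_gte(hits, 190)                    # >= 95%
  expect_gt(intercept_only_null, 100)      # majority intercept-only on noise
})

test_that("one-hot encoding: column counts and partition property", {
  vegf <- enumerate_design_space("vegf")
  H <- one_hot_encode(vegf)
  expect_equal(ncol(H), 12)
  il10 <- enumerate_design_space("il10")
  expect_equal(ncol(one_hot_encode(il10)), 10)     # single ligand: no column
  tnf <- enumerate_design_space("tnf")
  expect_equal(ncol(one_hot_encode(tnf)), 13)
  # each factor's level-columns sum to 1 in every row
  for (prefix in c("ntev_ecd", "ntev_tmd", "ctev_ecd", "ctev_tmd",
                   "ligand")) {
    cols <- grep(paste0("^", prefix, ":"), colnames(H))
    expect_true(all(rowSums(H[, cols, drop = FALSE]) == 1))
  }
  expect_true(all(H %in% c(0, 1)))
  expect_error(one_hot_encode(vegf[, -2]), "missing columns")
})

test_that("R2, p-values and selection are invariant to the log base", {
  set.seed(18)
  X <- matrix(rnorm(32 * 3), 32, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- standardize(X)
  os <- 10^(2 + Z %*% c(1, -0.5, 0) + rnorm(32, 0, 0.3))
  f10 <- ols_fit(Z, log10(os))
  fln <- ols_fit(Z, log(os))
  expect_equal(f10$r_squared, fln$r_squared, tolerance = 1e-12)
  expect_equal(f10$adj_r_squared, fln$adj_r_squared, tolerance = 1e-12)
  expect_equal(unname(f10$p), unname(fln$p), tolerance = 1e-9)
  expect_equal(backward_eliminate(Z, log10(os))$kept,
               backward_eliminate(Z, log(os))$kept)
})
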