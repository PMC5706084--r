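# helper: positive data matrix with an exactly diagonal sample covariance
diag_design <- function(vars) {
  v <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1)) / sqrt(4 / 3)
  X <- v[, seq_along(vars), drop = FALSE] %*% diag(sqrt(vars), length(vars))
  X <- X + 10  # shift positive; centering removes it again
  colnames(X) <- paste0("chem", seq_along(vars))
  rownames(X) <- paste0("P", 1:4)
  X
}

test_that("covariance PCA reproduces known diagonal and rank-1 spectra", {
  # two perfectly correlated unit-variance variables: all variance on PC1
  x <- scale(cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4)))[, ] # unit var
  p <- covariance_pca(x)
  expect_equal(unname(p$explained_fraction), c(1, 0), tolerance = 1e-12)

  # uncorrelated variables with variances 4 and 1
  X <- diag_design(c(4, 1))
  p2 <- covariance_pca(X)
  expect_equal(unname(p2$eigenvalues), c(4, 1), tolerance = 1e-12)
  expect_equal(unname(p2$explained_fraction), c(0.8, 0.2), tolerance = 1e-12)
})

test_that("PCA agrees with an SVD oracle and keeps structural invariants", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:6, 1); m <- sample(2:6, 1)
    X <- matrix(stats::rnorm(n * m, sd = sample(1:3, 1)), n, m,
                dimnames = list(paste0("P", 1:n), paste0("V", 1:m)))
    p <- covariance_pca(X)
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(n - 1, m)
    expect_equal(unname(p$eigenvalues[1:k]), unname(pr$sdev[1:k]^2),
                 tolerance = 1e-10)
    # trace conservation and fraction normalisation
    expect_equal(sum(p$eigenvalues), sum(apply(X, 2, stats::var)),
                 tolerance = 1e-9)
    expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-9)
    # loadings orthonormal
    expect_equal(crossprod(p$loadings), diag(m), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # full reconstruction of the centred matrix
    Xc <- sweep(X, 2, colMeans(X))
    expect_equal(p$scores %*% t(p$loadings), Xc, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # sign convention: dominant loading element positive
    expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  }
})

test_that("the two orientations share their nonzero uncentred spectrum", {
  set.seed(7)
  X <- matrix(stats::rexp(5 * 4), 5, 4,
              dimnames = list(paste0("P", 1:5), paste0("V", 1:4)))
  m <- make_cmatrix(X, kind = "hq")
  a <- covariance_pca(m, "chemicals_as_variables", center = FALSE)
  b <- covariance_pca(m, "samples_as_variables", center = FALSE)
  ea <- a$eigenvalues * (a$n_obs - 1)
  eb <- b$eigenvalues * (b$n_obs - 1)
  k <- min(length(ea), length(eb))
  expect_equal(unname(ea[1:k]), unname(eb[1:k]), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected or warned about", {
  const <- make_cmatrix(matrix(1, 4, 3), kind = "hq")
  expect_error(covariance_pca(const), "zero")
  raw <- make_cmatrix(matrix(1:6, 3, 2), kind = "raw")
  expect_error(covariance_pca(raw), "normalised")
  X <- matrix(stats::runif(18), 6, 3)
  X[1:4, 1] <- NA
  expect_warning(covariance_pca(make_cmatrix(X, "hq")), "missing")
})

test_that("variance weights sum to 100 and detect degenerate layouts", {
  # one variable holds all the variance
  X <- diag_design(c(1, 1))
  X2 <- cbind(X[, 1, drop = FALSE] * 3, chem2 = rep(5, 4))
  w <- variable_variance_weights(covariance_pca(X2))
  expect_equal(unname(w), c(100, 0))
  # equal-variance independent variables: 25% each
  X4 <- matrix(stats::rnorm(40), 10, 4)
  X4 <- scale(X4)  # unit sample variance per column
  colnames(X4) <- paste0("c", 1:4)
  w4 <- variable_variance_weights(covariance_pca(X4))
  expect_equal(unname(w4), rep(25, 4), tolerance = 1e-9)
  expect_equal(sum(w4), 100, tolerance = 1e-9)
  # wrong orientation is an error
  p <- covariance_pca(make_cmatrix(diag_design(c(2, 1)), "hq"),
                      "samples_as_variables")
  expect_error(variable_variance_weights(p), "orientation")
})

test_that("dominant elimination removes the column and rescales fractions", {
  X <- diag_design(c(100, 10, 1))
  m <- make_cmatrix(X, kind = "hq")
  el <- eliminate_dominant_and_rerun(m)  # auto -> largest weight
  expect_identical(el$removed, "chem1")
  expect_equal(unname(el$pca$explained_fraction), c(10 / 11, 1 / 11),
               tolerance = 1e-10)
  expect_identical(colnames(el$matrix$values), c("chem2", "chem3"))
  expect_error(eliminate_dominant_and_rerun(m, "nope"), "not present")
  m2 <- make_cmatrix(X[, 1:2], kind = "hq")
  expect_error(eliminate_dominant_and_rerun(m2, "chem1"), "fewer than 2")
})

test_that("scree selection follows the configured deterministic rule", {
  expect_identical(scree_select(c(99, 0.5, 0.5)), 1L)
  expect_identical(scree_select(c(85, 13, 1, 1)), 2L)
  # uniform spectrum: k = ceil(0.95 m)
  expect_identical(scree_select(rep(2, 4)), 4L)
  expect_identical(scree_select(rep(1, 20)), 19L)
  expect_identical(scree_select(c(85, 13, 1, 1), rule = "drop"), 2L)
  expect_error(scree_select(numeric()), "empty")
})

test_that("score-space outlier ranking finds displaced positions", {
  set.seed(11)
  n_pos <- 12
  prof <- stats::runif(6, 1, 3)  # shared chemical profile
  X <- sapply(seq_len(n_pos), function(i) prof * exp(stats::rnorm(6, 0, 0.01)))
  dimnames(X) <- list(paste0("c", 1:6), sprintf("P%02d", 1:n_pos))
  X[, "P05"] <- prof * 3  # one position displaced far along the lead direction
  m <- make_cmatrix(t(X), kind = "hq")
  p <- covariance_pca(m, "samples_as_variables")
  rk <- rank_score_outliers(p, n_components = 2)
  expect_identical(rk$ranking$position[1], "P05")
  expect_true("P05" %in% rk$selected)
  rk2 <- rank_score_outliers(p, n_components = 2, method = "per_pc_extreme")
  expect_true("P05" %in% rk2$selected)
  expect_error(rank_score_outliers(p, n_components = 50), "spectrum")

  # all positions identical: nothing to select
  Xe <- matrix(rep(prof, 8), nrow = 8, byrow = TRUE,
               dimnames = list(paste0("P", 1:8), paste0("c", 1:6)))
  pe <- covariance_pca(make_cmatrix(Xe, "hq"), "samples_as_variables")
  expect_length(rank_score_outliers(pe, 2)$selected, 0)
})

test_that("class-restricted PCA matches the full run on the full subset", {
  set.seed(3)
  X <- matrix(stats::rexp(40, 0.2), 8, 5)
  dimnames(X) <- list(paste0("P", 1:8), paste0("chem", 1:5))
  reg <- make_registry(5, classes = c("heavy_metal", "heavy_metal", "pah",
                                      "pah", "hydrocarbon"))
  m <- make_cmatrix(X, "hq")
  full <- subset_pca(m, reg, c("heavy_metal", "pah", "hydrocarbon"))
  ref <- covariance_pca(m, "samples_as_variables")
  expect_equal(full$eigenvalues, ref$eigenvalues, tolerance = 1e-12)
  pah <- subset_pca(m, reg, "pah", orientation = "chemicals_as_variables")
  expect_identical(rownames(pah$loadings), c("chem3", "chem4"))
  # constant subset: zero covariance
  X2 <- X; X2[, 3:4] <- 1
  expect_error(subset_pca(make_cmatrix(X2, "hq"), reg, "pah",
                          orientation = "chemicals_as_variables"), "zero")
  expect_error(subset_pca(m, reg, "aggregate"), "no chemicals")
})
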