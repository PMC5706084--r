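#' Variance-covariance principal component analysis
#'
#' Eigendecomposition of the variance-covariance matrix of a contamination
#' matrix in either orientation.  With `chemicals_as_variables` the rows
#' (sampling positions) are the observations and each chemical is a
#' variable; with `samples_as_variables` the matrix is transposed, the
#' chemicals act as observations, and each sampling position is a variable
#' -- the orientation used to spot positions that do not represent the
#' overall contamination pattern.
#'
#' Columns are centered but *not* scaled to unit variance, so chemicals
#' (or positions) with large absolute variance dominate the leading
#' components; `use_correlation = TRUE` switches to the correlation matrix
#' for sensitivity analysis.  Missing cells are handled by
#' pairwise-complete covariance, an approximation that can make the
#' covariance estimate slightly non-positive-definite; small negative
#' eigenvalues are tolerated and clipped when computing explained
#' fractions.
#'
#' Eigenvector signs are fixed by orienting each loading vector so that its
#' largest-magnitude element is positive.
#'
#' @param x a [contam_matrix] whose `value_kind` is `"hq"` or
#'   `"risk_quotient"`, or a bare numeric matrix (positions x chemicals).
#' @param orientation `"chemicals_as_variables"` or
#'   `"samples_as_variables"` (prefixes allowed).
#' @param center center the variables before forming the covariance
#'   (default `TRUE`; disable only to compare the two orientations'
#'   spectra, which coincide for uncentered cross-products).
#' @param use_correlation use the correlation instead of the covariance
#'   matrix.
#' @return An object of class `cov_pca` with elements `eigenvalues`
#'   (descending), `explained_fraction`, `loadings` (variables x
#'   components), `scores` (observations x components),
#'   `variable_weights` (per-variable share of total variance), `center`,
#'   `cov`, `orientation`, `n_obs`.
#' @export
covariance_pca <- function(x, orientation = c("chemicals_as_variables",
                                              "samples_as_variables"),
                           center = TRUE, use_correlation = FALSE) {
  orientation <- match.arg(orientation)
  vals <- if (inherits(x, "contam_matrix")) {
    if (x$value_kind == "raw") {
      stop("PCA expects a normalised matrix (hazard or risk quotients); ",
           "call compute_hq() or risk_normalize() first")
    }
    x$values
  } else as.matrix(x)
  X <- if (orientation == "samples_as_variables") t(vals) else vals
  if (ncol(X) < 2L || nrow(X) < 2L) {
    stop("need at least 2 variables and 2 observations for PCA")
  }
  frac_missing <- colMeans(is.na(X))
  if (any(frac_missing > 0.5)) {
    warning("variable(s) with >50% missing values: ",
            paste(colnames(X)[frac_missing > 0.5], collapse = ", "))
  }
  mu <- if (center) colMeans(X, na.rm = TRUE) else rep(0, ncol(X))
  S <- if (any(is.na(X))) {
    stats::cov(X, use = "pairwise.complete.obs")
  } else {
    crossprod(sweep(X, 2L, mu, `-`)) / (nrow(X) - 1L)
  }
  if (use_correlation) S <- stats::cov2cor(S)
  if (anyNA(S)) {
    stop("covariance is undefined for some variable pairs (no joint coverage)")
  }
  tr <- sum(diag(S))
  if (tr <= .Machine$double.eps * ncol(S)) {
    stop("constant matrix: total variance is zero")
  }
  ed <- eigen(S, symmetric = TRUE)
  ev <- ed$values
  V <- ed$vectors
  # sign convention: dominant element of each loading vector positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  Xc <- sweep(X, 2L, mu, `-`)
  Xc[is.na(Xc)] <- 0  # mean-imputed for score projection only
  scores <- Xc %*% V
  evc <- pmax(ev, 0)
  structure(list(
    orientation = orientation,
    eigenvalues = stats::setNames(ev, colnames(V)),
    explained_fraction = stats::setNames(evc / sum(evc), colnames(V)),
    loadings = V,
    scores = scores,
    variable_weights = diag(S) / tr,
    center = mu,
    cov = S,
    n_obs = nrow(X),
    correlation = use_correlation
  ), class = "cov_pca")
}

#' @export
print.cov_pca <- function(x, k = 5L, ...) {
  cat(sprintf("covariance PCA (%s): %d variables, %d observations\n",
              x$orientation, ncol(x$loadings), x$n_obs))
  k <- min(k, length(x$eigenvalues))
  tab <- rbind(eigenvalue = x$eigenvalues[seq_len(k)],
               `fraction of variance` = x$explained_fraction[seq_len(k)],
               cumulative = cumsum(x$explained_fraction)[seq_len(k)])
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.cov_pca <- function(object, ...) {
  structure(list(pca = object, k95 = scree_select(object, threshold = 0.95)),
            class = "summary.cov_pca")
}

#' @export
print.summary.cov_pca <- function(x, ...) {
  print(x$pca, k = length(x$pca$eigenvalues))
  cat(sprintf("components retained at 95%% cumulative variance: %d\n", x$k95))
  invisible(x)
}

#' Scree and score plots for a covariance PCA
#'
#' @param x a `cov_pca` object.
#' @param type `"scree"` for the eigenvalue-versus-rank plot, `"scores"`
#'   for a scatter of observations, `"variables"` for the variables in the
#'   plane of two components.
#' @param components which two components to draw for scatter plots.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.cov_pca <- function(x, type = c("scree", "scores", "variables"),
                         components = c(1L, 2L), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
                   xlab = "component", ylab = "eigenvalue",
                   main = "scree plot", ...)
  } else {
    M <- if (type == "scores") x$scores else
      x$loadings %*% diag(sqrt(pmax(x$eigenvalues, 0)))
    lab <- sprintf("PC%d (%.1f%%)", components,
                   100 * x$explained_fraction[components])
    graphics::plot(M[, components[1L]], M[, components[2L]],
                   xlab = lab[1L], ylab = lab[2L], type = "n", ...)
    graphics::text(M[, components[1L]], M[, components[2L]],
                   labels = rownames(M), cex = 0.7)
    graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Per-variable share of the overall variance
#'
#' The diagonal of the covariance matrix over its trace, expressed as
#' percentages summing to 100.  With chemicals as variables this is the
#' "weight of each chemical on the overall variance" used to recognise a
#' dominant diffuse pollutant.
#'
#' @param result a `cov_pca` fitted with `chemicals_as_variables`.
#' @return Named numeric vector of percentages.
#' @export
variable_variance_weights <- function(result) {
  stopifnot(inherits(result, "cov_pca"))
  if (result$orientation != "chemicals_as_variables") {
    stop("variance weights are defined for the chemicals_as_variables orientation")
  }
  100 * result$variable_weights
}

#' Remove a dominant pollutant and re-run the PCA
#'
#' A single chemical carrying most of the overall variance (typically the
#' signature of diffuse, nonpoint pollution) masks the structure of the
#' remaining chemicals.  This drops that column and recomputes the
#' chemicals-oriented PCA on the reduced matrix.
#'
#' @param matrix a [contam_matrix] (`"hq"` or `"risk_quotient"`).
#' @param variable chemical to remove; `NULL` picks the chemical with the
#'   largest variance weight automatically.
#' @param ... passed on to [covariance_pca()].
#' @return List with `removed` (the chemical name), `pca` (the re-run
#'   `cov_pca`) and `matrix` (the reduced [contam_matrix]).
#' @export
eliminate_dominant_and_rerun <- function(matrix, variable = NULL, ...) {
  stopifnot(inherits(matrix, "contam_matrix"))
  chems <- chemicals(matrix)
  if (is.null(variable)) {
    w <- variable_variance_weights(
      covariance_pca(matrix, "chemicals_as_variables", ...))
    variable <- names(which.max(w))
  }
  if (!variable %in% chems) {
    stop("chemical not present in matrix: ", variable)
  }
  if (length(chems) - 1L < 2L) {
    stop("removing ", variable, " would leave fewer than 2 variables")
  }
  keep <- setdiff(chems, variable)
  red <- contam_matrix(matrix$values[, keep, drop = FALSE],
                       matrix$bdl[, keep, drop = FALSE],
                       value_kind = matrix$value_kind,
                       campaigns = matrix$campaigns[, keep, drop = FALSE])
  list(removed = variable,
       pca = covariance_pca(red, "chemicals_as_variables", ...),
       matrix = red)
}

#' Number of components retained from a scree
#'
#' The scree plot is traditionally read by eye; for reproducibility a
#' deterministic rule is applied: either the smallest number of components
#' whose cumulative explained fraction reaches a threshold (default 0.95),
#' or the position of the largest relative drop between consecutive
#' eigenvalues.
#'
#' @param eigenvalues descending numeric vector, or a `cov_pca` object.
#' @param rule `"cumulative"` or `"drop"`.
#' @param threshold cumulative-fraction threshold for the default rule.
#' @return Integer number of retained components.
#' @export
scree_select <- function(eigenvalues, rule = c("cumulative", "drop"),
                         threshold = 0.95) {
  rule <- match.arg(rule)
  if (inherits(eigenvalues, "cov_pca")) eigenvalues <- eigenvalues$eigenvalues
  ev <- pmax(as.numeric(eigenvalues), 0)
  if (!length(ev)) stop("empty eigenvalue spectrum")
  if (rule == "cumulative") {
    frac <- cumsum(ev) / sum(ev)
    as.integer(which(frac >= threshold - 1e-12)[1L])
  } else {
    if (length(ev) == 1L) return(1L)
    ratio <- ev[-length(ev)] / pmax(ev[-1L], .Machine$double.xmin)
    as.integer(which.max(ratio))
  }
}

#' Position coordinates in component space
#'
#' For a samples-as-variables PCA each sampling position is a variable;
#' its coordinate on component `j` is its loading scaled by the component's
#' standard deviation, the covariance-scaled representation in which
#' anomalous positions separate from the bulk.
#'
#' @param result a `cov_pca` with `orientation = "samples_as_variables"`.
#' @param n_components how many leading components to keep.
#' @return Numeric matrix, positions x components.
#' @export
position_coordinates <- function(result, n_components = 2L) {
  stopifnot(inherits(result, "cov_pca"))
  if (result$orientation != "samples_as_variables") {
    stop("position coordinates require the samples_as_variables orientation")
  }
  if (n_components > length(result$eigenvalues)) {
    stop("n_components exceeds the available spectrum")
  }
  k <- seq_len(n_components)
  L <- result$loadings[, k, drop = FALSE] %*%
    diag(sqrt(pmax(result$eigenvalues[k], 0)), n_components)
  colnames(L) <- colnames(result$loadings)[k]
  L
}

#' Rank sampling positions as score-space outliers
#'
#' Positions far from the robust centre of the retained component space are
#' candidate point sources.  With `method = "robust_distance"` every
#' position gets, per component, a robust outlier score (deviation from the
#' component median in units of the median absolute deviation, see
#' [on_score()]); scores are combined across components by the maximum and
#' positions with a combined score at or above `cutoff` are selected.
#' `method = "per_pc_extreme"` instead selects, for each retained
#' component, the position with the largest absolute deviation -- a
#' reading-off-the-scatterplot heuristic.
#'
#' @param result a `cov_pca` with `orientation = "samples_as_variables"`.
#' @param n_components number of retained components (e.g. from
#'   [scree_select()]).
#' @param method `"robust_distance"` (default) or `"per_pc_extreme"`.
#' @param cutoff selection threshold on the combined robust score
#'   (default 4).
#' @return An object of class `outlier_ranking`: data frame `ranking`
#'   (position, distance), character vector `selected`, the per-component
#'   score matrix, and the selection-rule descriptor.
#' @export
rank_score_outliers <- function(result, n_components = 2L,
                                method = c("robust_distance", "per_pc_extreme"),
                                cutoff = 4) {
  method <- match.arg(method)
  coords <- position_coordinates(result, n_components)
  # components carrying no real variance are numerical noise, not structure
  ev <- pmax(result$eigenvalues[seq_len(n_components)], 0)
  live <- ev > 1e-10 * max(result$eigenvalues, 0)
  per_pc <- vapply(seq_len(n_components), function(j) {
    if (!live[j]) return(numeric(nrow(coords)))
    v <- coords[, j]
    s <- on_score(v, v)
    # deviations at floating-point dust level are not outlyingness
    s[abs(v - stats::median(v)) <= 1e-8 * max(abs(v))] <- 0
    s
  }, numeric(nrow(coords)))
  dimnames(per_pc) <- dimnames(coords)
  if (method == "robust_distance") {
    dist <- apply(per_pc, 1L, max)
    selected <- names(dist)[dist >= cutoff]
    rule <- sprintf("max per-component On over %d components >= %g",
                    n_components, cutoff)
  } else {
    dev <- abs(sweep(coords, 2L, apply(coords, 2L, stats::median), `-`))
    dev[, !live] <- 0
    dev[sweep(dev, 2L, 1e-8 * apply(abs(coords), 2L, max), `<=`)] <- 0
    colmax <- apply(dev, 2L, max)
    rel <- sweep(dev, 2L, ifelse(colmax > 0, colmax, 1), `/`)
    dist <- apply(rel, 1L, max)
    spread <- colmax > 0
    selected <- unique(unlist(lapply(which(spread), function(j) {
      rownames(dev)[which.max(dev[, j])]
    })))
    rule <- sprintf("largest |deviation| on each of %d components", n_components)
  }
  ord <- order(-dist, rownames(coords))
  ranking <- data.frame(position = rownames(coords)[ord],
                        distance = dist[ord], row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, selected = sort(selected),
                 scores = per_pc, method = method, cutoff = cutoff,
                 n_components = n_components, rule = rule),
            class = "outlier_ranking")
}

#' @export
print.outlier_ranking <- function(x, n = 10L, ...) {
  cat("score-space outlier ranking (", x$rule, ")\n", sep = "")
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  print(utils::head(x$ranking, n))
  invisible(x)
}

#' PCA restricted to chemical classes
#'
#' Runs [covariance_pca()] on the chemicals belonging to the requested
#' classes only (e.g. a PAH/hydrocarbon run and a heavy-metal run), so that
#' sources of one contaminant family are not hidden by the variance of the
#' other.
#'
#' @param matrix a [contam_matrix].
#' @param registry a [chem_registry] giving each chemical's class.
#' @param classes subset of `c("heavy_metal", "pah", "hydrocarbon",
#'   "aggregate")`.
#' @param orientation,... passed to [covariance_pca()].
#' @export
subset_pca <- function(matrix, registry, classes,
                       orientation = "samples_as_variables", ...) {
  stopifnot(inherits(matrix, "contam_matrix"))
  cls <- registry$chem_class[match(chemicals(matrix), registry$name)]
  keep <- chemicals(matrix)[cls %in% classes]
  if (!length(keep)) stop("no chemicals in class(es): ",
                          paste(classes, collapse = ", "))
  sub <- contam_matrix(matrix$values[, keep, drop = FALSE],
                       matrix$bdl[, keep, drop = FALSE],
                       value_kind = matrix$value_kind)
  covariance_pca(sub, orientation = orientation, ...)
}
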