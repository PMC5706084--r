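#' Upper-triangular ratio matrix of one sample
#'
#' The fingerprint of a sample: every concentration divided by every other,
#' of which only the strictly upper triangle is informative (`m` chemicals
#' give `m(m-1)/2` ratios).  Ratios are unchanged by dilution of the whole
#' sample with inert material, which is what makes them usable as source
#' signatures.  Entries involving a missing, zero or below-detection-limit
#' concentration are masked (`NA`): a ratio built on a censored value is
#' not fingerprint evidence.
#'
#' @param concentrations named numeric vector of concentrations.
#' @param chemicals ordering of chemicals to use (default: the names of
#'   `concentrations`).
#' @param bdl optional logical vector marking below-detection-limit values.
#' @return An `m x m` matrix of class `ratio_matrix`; `[i, j]` holds
#'   `c_i / c_j` for `i < j`, everything else `NA`.
#' @export
ratio_matrix <- function(concentrations, chemicals = names(concentrations),
                         bdl = NULL) {
  if (is.null(chemicals)) stop("concentrations must be named")
  x <- as.numeric(concentrations[chemicals])
  valid <- !is.na(x) & is.finite(x) & x > 0
  if (!is.null(bdl)) {
    b <- if (!is.null(names(bdl))) bdl[chemicals] else rep_len(bdl, length(x))
    valid <- valid & !(b %in% TRUE)
  }
  if (sum(valid) < 2L) {
    stop("fewer than 2 valid (positive, detected) concentrations")
  }
  m <- length(chemicals)
  R <- matrix(NA_real_, m, m, dimnames = list(chemicals, chemicals))
  ut <- upper.tri(R)
  R[ut] <- outer(x, x, `/`)[ut]
  R[!outer(valid, valid, `&`)] <- NA_real_
  R[!ut] <- NA_real_
  structure(R, class = c("ratio_matrix", "matrix"))
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("ratio matrix: %d chemicals, %d/%d unmasked ratio(s)\n",
              ncol(x), sum(!is.na(x)), ncol(x) * (ncol(x) - 1L) / 2L))
  invisible(x)
}

#' Compare two ratio fingerprints
#'
#' Divides each ratio of sample `a` by the corresponding ratio of sample
#' `b` over the jointly unmasked pairs, and computes the fraction of
#' quotients that fall inside the acceptance band.  The printed band
#' 0.90--1.10 is not reciprocal-symmetric (1/0.9 > 1.1), so by default the
#' symmetrised test `min(r, 1/r) >= low` is applied, which makes the
#' comparison independent of the order of the two samples;
#' `mode = "literal"` applies the interval as printed.
#'
#' @param a,b [ratio_matrix] objects over the same chemical ordering.
#' @param band numeric `c(low, high)` acceptance band (default
#'   `c(0.90, 1.10)`).
#' @param mode `"symmetric"` (default) or `"literal"`.
#' @return An object of class `pair_similarity` with the quotient matrix,
#'   `in_band_fraction` and the number of compared pairs.
#' @export
compare_ratios <- function(a, b, band = c(0.90, 1.10),
                           mode = c("symmetric", "literal")) {
  mode <- match.arg(mode)
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stop("band must be c(low, high) with low < high")
  }
  if (!identical(colnames(a), colnames(b))) {
    stop("ratio matrices use different chemical orderings")
  }
  q <- unclass(a) / unclass(b)
  ok <- !is.na(q)
  if (!any(ok)) stop("no jointly unmasked ratio pairs to compare")
  inb <- if (mode == "symmetric") pmin(q[ok], 1 / q[ok]) >= band[1L]
         else q[ok] >= band[1L] & q[ok] <= band[2L]
  structure(list(quotients = q, in_band_fraction = mean(inb),
                 n_compared = sum(ok), band = band, mode = mode),
            class = "pair_similarity")
}

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("ratio-matching similarity: %d pair(s) compared, %.3f in band [%g, %g] (%s)\n",
              x$n_compared, x$in_band_fraction, x$band[1L], x$band[2L], x$mode))
  invisible(x)
}

#' Cluster positions by shared ratio fingerprints
#'
#' Computes the pairwise in-band fraction between the ratio fingerprints of
#' the requested positions (optionally restricted to a subset of
#' chemicals), links two positions when the fraction reaches
#' `link_threshold`, and returns the connected components of the link
#' graph.  Components of size one are the singletons: positions whose
#' fingerprint matches no other position, the pattern expected of an
#' isolated spill.  An average-linkage hierarchical alternative
#' (`method = "average"`, cutting `1 - in_band_fraction` at
#' `1 - link_threshold`) is available.
#'
#' Ratios of hazard or risk quotients differ from ratios of raw
#' concentrations only by a fixed per-pair constant, so the pairwise
#' quotients -- and hence the clustering -- are identical for any
#' `value_kind`.
#'
#' @param matrix a [contam_matrix]; rows are the candidate samples or
#'   positions.
#' @param positions which rows to cluster (default: all; at least 2).
#' @param band,mode see [compare_ratios()].
#' @param link_threshold minimum in-band fraction to link two positions
#'   (default 0.90).
#' @param chem_subset optional character vector of chemicals to restrict
#'   the fingerprints to.
#' @param method `"components"` (default) or `"average"`.
#' @return An object of class `cluster_set`: `clusters` (list of
#'   multi-member position sets), `singletons`, the pairwise `similarity`
#'   matrix, and the clustering parameters.
#' @export
ratio_cluster <- function(matrix, positions = NULL, band = c(0.90, 1.10),
                          link_threshold = 0.90, chem_subset = NULL,
                          mode = c("symmetric", "literal"),
                          method = c("components", "average")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(matrix, "contam_matrix"))
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stop("band must be c(low, high) with low < high")
  }
  if (is.null(positions)) positions <- rownames(matrix$values)
  if (length(positions) < 2L) stop("need at least 2 positions to cluster")
  miss <- setdiff(positions, rownames(matrix$values))
  if (length(miss)) stop("unknown position(s): ", paste(miss, collapse = ", "))
  chems <- chemicals(matrix)
  if (!is.null(chem_subset)) {
    bad <- setdiff(chem_subset, chems)
    if (length(bad)) stop("unknown chemical(s): ", paste(bad, collapse = ", "))
    chems <- chems[chems %in% chem_subset]
    if (length(chems) < 2L) stop("chemical subset has fewer than 2 members")
  }
  rmats <- lapply(positions, function(p) {
    tryCatch(ratio_matrix(matrix$values[p, chems], chems,
                          bdl = matrix$bdl[p, chems]),
             error = function(e) NULL)
  })
  names(rmats) <- positions
  n <- length(positions)
  sim <- diag(1, n)
  dimnames(sim) <- list(positions, positions)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      sim[i, j] <- sim[j, i] <- if (is.null(rmats[[i]]) || is.null(rmats[[j]])) {
        NA_real_
      } else {
        ps <- tryCatch(compare_ratios(rmats[[i]], rmats[[j]], band, mode),
                       error = function(e) NULL)
        if (is.null(ps)) NA_real_ else ps$in_band_fraction
      }
    }
  }
  if (method == "components") {
    adj <- !is.na(sim) & sim >= link_threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
  } else {
    d <- 1 - sim
    d[is.na(d)] <- 1
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    memb <- stats::cutree(hc, h = 1 - link_threshold)
    names(memb) <- positions
  }
  groups <- split(names(memb), memb)
  sizes <- lengths(groups)
  structure(list(
    clusters = unname(lapply(groups[sizes > 1L], sort)),
    singletons = sort(unlist(groups[sizes == 1L], use.names = FALSE)),
    band = band, link_threshold = link_threshold, mode = mode,
    method = method, similarity = sim, chemicals = chems,
    membership = memb
  ), class = "cluster_set")
}

#' Cluster flagged point sources by their own fingerprint chemicals
#'
#' Step-3 clustering driven by a Step-2 outlier report: two flagged
#' positions are compared over the *intersection* of their flagged
#' chemicals -- the chemicals hypothesised to carry each source's
#' signature -- and linked when the in-band fraction of their ratio
#' quotients reaches `link_threshold`.  Pairs sharing fewer than
#' `min_shared` flagged chemicals cannot form a link (one common chemical
#' yields no ratio).  Clusters are the connected components of the link
#' graph; flagged positions without any link come back as singletons, the
#' pattern expected of an isolated spill.
#'
#' @param matrix the [contam_matrix] holding the fingerprint values
#'   (any `value_kind`: ratio quotients are identical for raw
#'   concentrations and hazard or risk quotients).
#' @param report an [identify_point_sources()] `outlier_report` (or a
#'   named list mapping positions to their flagged chemicals).
#' @param band,mode,link_threshold see [compare_ratios()] and
#'   [ratio_cluster()].
#' @param min_shared minimum number of jointly flagged chemicals for a
#'   pair to be comparable (default 2).
#' @return A `cluster_set` over the flagged positions.
#' @export
cluster_sources <- function(matrix, report, band = c(0.90, 1.10),
                            link_threshold = 0.90,
                            mode = c("symmetric", "literal"),
                            min_shared = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "contam_matrix"))
  per_chem <- if (inherits(report, "outlier_report")) {
    report$per_source_chemicals
  } else as.list(report)
  pos <- names(per_chem)
  miss <- setdiff(pos, rownames(matrix$values))
  if (length(miss)) stop("unknown position(s): ", paste(miss, collapse = ", "))
  n <- length(pos)
  sim <- diag(1, n)
  dimnames(sim) <- list(pos, pos)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        shared <- intersect(per_chem[[i]], per_chem[[j]])
        sim[i, j] <- sim[j, i] <- if (length(shared) < min_shared) {
          NA_real_
        } else {
          ps <- tryCatch(compare_ratios(
            ratio_matrix(matrix$values[pos[i], shared], shared,
                         bdl = matrix$bdl[pos[i], shared]),
            ratio_matrix(matrix$values[pos[j], shared], shared,
                         bdl = matrix$bdl[pos[j], shared]),
            band, mode), error = function(e) NULL)
          if (is.null(ps)) NA_real_ else ps$in_band_fraction
        }
      }
    }
  }
  adj <- !is.na(sim) & sim >= link_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  groups <- split(names(memb), memb)
  sizes <- lengths(groups)
  structure(list(clusters = unname(lapply(groups[sizes > 1L], sort)),
                 singletons = sort(unlist(groups[sizes == 1L],
                                          use.names = FALSE)),
                 band = band, link_threshold = link_threshold, mode = mode,
                 method = "components", similarity = sim,
                 chemicals = sort(unique(unlist(per_chem))),
                 membership = memb),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("ratio-matching clusters (band [%g, %g], link >= %g, %d chemicals)\n",
              x$band[1L], x$band[2L], x$link_threshold, length(x$chemicals)))
  if (length(x$clusters)) {
    for (i in seq_along(x$clusters)) {
      cat(sprintf("  cluster %d: %s\n", i,
                  paste(x$clusters[[i]], collapse = ", ")))
    }
  } else cat("  (no multi-member clusters)\n")
  if (length(x$singletons)) {
    cat("  singletons:", paste(x$singletons, collapse = ", "), "\n")
  }
  invisible(x)
}
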