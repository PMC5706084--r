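#' Median absolute deviation about the median
#'
#' The raw MAD: `median(|x - median(x)|)`, with no consistency constant, so
#' the statistic reads directly as "typical absolute deviation from the
#' median".
#'
#' @param x numeric vector with at least one finite value.
#' @param na.rm drop `NA`s (default `TRUE`).
#' @return A single non-negative number.
#' @export
mad_raw <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (!length(x) || !all(is.finite(x))) {
    stop("mad_raw needs at least one finite value")
  }
  stats::mad(x, constant = 1)
}

#' Robust outlier score On
#'
#' `On(x) = |x - median(values)| / MAD(values)`: how many raw MADs the
#' point lies from the median of the reference distribution.  The scored
#' point is conventionally part of the reference set.  When the MAD is
#' zero the score is 0 at the median and `+Inf` elsewhere (a sentinel, not
#' an error, so that degenerate columns can still be reported).
#'
#' @param x numeric value(s) to score.
#' @param values reference distribution.
#' @param na.rm drop `NA`s from the reference.
#' @return Numeric vector of scores, same length as `x`.
#' @export
on_score <- function(x, values, na.rm = TRUE) {
  if (na.rm) values <- values[!is.na(values)]
  if (!length(values)) stop("empty reference distribution")
  med <- stats::median(values)
  m <- stats::mad(values, constant = 1)
  dev <- abs(x - med)
  if (m == 0) {
    out <- ifelse(dev == 0, 0, Inf)
    out[is.na(x)] <- NA_real_
    return(out)
  }
  dev / m
}

#' Identify possible point sources by per-chemical On scoring
#'
#' Each chemical column of a normalised contamination matrix defines a
#' reference distribution over positions; every (position, chemical) cell
#' is given an [on_score()] against its column.  Positions with at least
#' one score at or above `cutoff` are reported as possible point sources,
#' ranked by their maximum score over chemicals (ties broken by the number
#' of flagged chemicals, then by position id).  Columns with zero MAD are
#' listed as degenerate.
#'
#' @param matrix a [contam_matrix] with `value_kind` `"hq"` or
#'   `"risk_quotient"`.
#' @param cutoff positive outlier cutoff (default 4); raising it never adds
#'   a source.
#' @param min_positions minimum non-missing positions required per column
#'   (default 5); sparser columns are skipped.
#' @param flag_bdl treat below-detection-limit cells as flaggable (default
#'   `FALSE`): a censored measurement, substituted at half its detection
#'   limit, can sit several MADs *below* the column median, but a
#'   non-detect is never evidence of a contamination point source.  BDL
#'   cells always remain part of the reference distribution.
#' @return An object of class `outlier_report`: `scores` (positions x
#'   chemicals On matrix), `sources` (ranked data frame with `position`,
#'   `max_on`, `n_flagged`), `per_source_chemicals` (named list),
#'   `degenerate` (character), `cutoff`.
#' @export
identify_point_sources <- function(matrix, cutoff = 4, min_positions = 5L,
                                   flag_bdl = FALSE) {
  stopifnot(inherits(matrix, "contam_matrix"))
  if (!matrix$value_kind %in% c("hq", "risk_quotient")) {
    stop("expected a normalised matrix (hq or risk_quotient)")
  }
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  vals <- matrix$values
  scores <- vals * NA_real_
  degenerate <- character()
  for (j in seq_len(ncol(vals))) {
    col <- vals[, j]
    if (sum(!is.na(col)) < min_positions) next
    if (stats::mad(col, constant = 1, na.rm = TRUE) == 0) {
      degenerate <- c(degenerate, colnames(vals)[j])
    }
    scores[, j] <- on_score(col, col)
  }
  flagged <- !is.na(scores) & scores >= cutoff
  if (!flag_bdl) flagged <- flagged & !matrix$bdl
  src <- rownames(vals)[rowSums(flagged) > 0L]
  max_on <- apply(scores[src, , drop = FALSE], 1L, max, na.rm = TRUE)
  n_flag <- rowSums(flagged[src, , drop = FALSE])
  ord <- order(-max_on, -n_flag, src)
  sources <- data.frame(position = src[ord], max_on = max_on[ord],
                        n_flagged = n_flag[ord], row.names = NULL,
                        stringsAsFactors = FALSE)
  per_chem <- lapply(sources$position, function(p) {
    colnames(vals)[flagged[p, ]]
  })
  names(per_chem) <- sources$position
  structure(list(cutoff = cutoff, scores = scores, sources = sources,
                 per_source_chemicals = per_chem, degenerate = degenerate),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("MAD outlier report (cutoff On >= %g): %d possible point source(s)\n",
              x$cutoff, nrow(x$sources)))
  if (nrow(x$sources)) {
    for (i in seq_len(nrow(x$sources))) {
      p <- x$sources$position[i]
      cat(sprintf("  %s (max On = %.3g): %s\n", p, x$sources$max_on[i],
                  paste(x$per_source_chemicals[[p]], collapse = ", ")))
    }
  }
  if (length(x$degenerate)) {
    cat("degenerate (zero-MAD) column(s):",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.outlier_report <- function(x, ...) {
  grid <- expand.grid(position = rownames(x$scores),
                      chemical = colnames(x$scores),
                      stringsAsFactors = FALSE)
  grid$on <- as.vector(x$scores)
  grid$flagged <- !is.na(grid$on) & grid$on >= x$cutoff
  grid[!is.na(grid$on), , drop = FALSE]
}

#' @export
summary.outlier_report <- function(object, ...) {
  data.frame(position = object$sources$position,
             max_on = object$sources$max_on,
             chemicals = vapply(object$per_source_chemicals, paste,
                                "", collapse = ";"),
             row.names = NULL, stringsAsFactors = FALSE)
}
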