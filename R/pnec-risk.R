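#' Sediment PNEC from the water PNEC and partition coefficient
#'
#' `PNEC_sediment = Kp * PNEC_water`: the equilibrium-partitioning estimate
#' used when no measured sediment effect threshold is available.
#'
#' @param kp sediment--water partition coefficient, L/kg (> 0).
#' @param pnec_water predicted no-effect concentration in water, mg/L
#'   (> 0).
#' @return Sediment PNEC in mg/kg (vectorised).
#' @export
pnec_sediment <- function(kp, pnec_water) {
  if (any(is.na(kp)) || any(is.na(pnec_water)) ||
      any(kp <= 0) || any(pnec_water <= 0)) {
    stop("kp and pnec_water must be positive")
  }
  kp * pnec_water
}

#' PNEC by the assessment-factor approach
#'
#' When only acute toxicity endpoints are available, each endpoint
#' concentration is divided by its assessment factor and the minimum of
#' the resulting quotients is taken as the PNEC -- the standard
#' technical-guidance convention.
#'
#' @param endpoints a two-column `data.frame` (or matrix) with columns
#'   `conc` (mg/L) and `af` (assessment factor), one row per endpoint.
#' @return PNEC in mg/L.
#' @export
pnec_from_af <- function(endpoints) {
  ep <- as.data.frame(endpoints)
  if (!nrow(ep)) stop("at least one toxicity endpoint is required")
  if (is.null(ep$conc) || is.null(ep$af)) {
    names(ep)[1:2] <- c("conc", "af")
  }
  if (any(is.na(ep$af)) || any(ep$af <= 0)) stop("assessment factors must be > 0")
  if (any(is.na(ep$conc)) || any(ep$conc <= 0)) {
    stop("endpoint concentrations must be > 0")
  }
  min(ep$conc / ep$af)
}

#' Resolve a sediment PNEC for every chemical
#'
#' Resolution order per chemical: an explicit sediment PNEC in the
#' registry, then the partitioning product `Kp * PNEC_water`, then the
#' assessment-factor derivation (whose mg/L result is converted with `Kp`
#' when available, otherwise used only if a sediment value cannot be
#' formed -- such chemicals resolve to `NA`).
#'
#' @param registry a [chem_registry].
#' @return A data frame `name`, `pnec_sediment` (mg/kg, `NA` when
#'   unresolvable) and `method` -- the audit trail of which path supplied
#'   each value.
#' @export
resolve_pnec <- function(registry) {
  res <- data.frame(name = registry$name,
                    pnec_sediment = NA_real_,
                    method = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(registry))) {
    if (!is.na(registry$pnec_sediment[i])) {
      res$pnec_sediment[i] <- registry$pnec_sediment[i]
      res$method[i] <- "explicit_sediment"
    } else if (!is.na(registry$kp[i]) && !is.na(registry$pnec_water[i])) {
      res$pnec_sediment[i] <- pnec_sediment(registry$kp[i],
                                            registry$pnec_water[i])
      res$method[i] <- "kp_x_pnec_water"
    } else if (!is.null(registry$endpoints[[i]]) && !is.na(registry$kp[i])) {
      res$pnec_sediment[i] <- registry$kp[i] *
        pnec_from_af(registry$endpoints[[i]])
      res$method[i] <- "assessment_factor"
    }
  }
  res
}

#' Normalise concentrations by sediment PNECs
#'
#' Divides every cell of a raw concentration matrix by the chemical's
#' resolved sediment PNEC, yielding risk quotients (quotient > 1 means the
#' concentration exceeds the predicted no-effect level).  Chemicals whose
#' PNEC cannot be resolved (typically aggregate indicators such as a PAH
#' sum) are dropped with a warning by default.
#'
#' @param matrix a [contam_matrix] with `value_kind = "raw"`.
#' @param registry a [chem_registry].
#' @param on_unresolved `"drop"` (default) or `"error"`.
#' @return A [contam_matrix] with `value_kind = "risk_quotient"` and the
#'   PNEC resolution audit attached as attribute `"pnec_audit"`.
#' @export
risk_normalize <- function(matrix, registry,
                           on_unresolved = c("drop", "error")) {
  on_unresolved <- match.arg(on_unresolved)
  stopifnot(inherits(matrix, "contam_matrix"))
  if (matrix$value_kind != "raw") {
    stop("risk_normalize expects a raw concentration matrix")
  }
  audit <- resolve_pnec(registry)
  chems <- chemicals(matrix)
  pnec <- audit$pnec_sediment[match(chems, audit$name)]
  unresolved <- chems[is.na(pnec)]
  if (length(unresolved)) {
    if (on_unresolved == "error" || length(unresolved) == length(chems)) {
      stop("no resolvable sediment PNEC for chemical(s): ",
           paste(unresolved, collapse = ", "))
    }
    warning("dropping chemical(s) with no resolvable PNEC: ",
            paste(unresolved, collapse = ", "))
  }
  keep <- chems[!is.na(pnec)]
  vals <- sweep(matrix$values[, keep, drop = FALSE], 2L,
                pnec[match(keep, chems)], `/`)
  out <- contam_matrix(vals, matrix$bdl[, keep, drop = FALSE],
                       value_kind = "risk_quotient")
  attr(out, "pnec_audit") <- audit[audit$name %in% keep, , drop = FALSE]
  out
}

#' Rank positions by ecotoxicological risk
#'
#' Samples-as-variables covariance PCA on a risk-quotient matrix followed
#' by [rank_score_outliers()]: the positions far from the robust centre of
#' the retained component space are those whose PNEC-normalised profiles
#' depart most from the common contamination pattern -- the candidates at
#' highest environmental risk.
#'
#' @param matrix a [contam_matrix] with `value_kind = "risk_quotient"`.
#' @param cutoff On cutoff for the selection (default 4).
#' @param n_components retained components; `NULL` uses
#'   [scree_select()] with its default rule, floored at 2.
#' @return An object of class `risk_ranking` with the PCA, the
#'   [rank_score_outliers()] result and `highest_risk` (the selected
#'   positions).
#' @export
rank_by_risk <- function(matrix, cutoff = 4, n_components = NULL) {
  stopifnot(inherits(matrix, "contam_matrix"))
  if (matrix$value_kind != "risk_quotient") {
    stop("rank_by_risk expects a risk-quotient matrix; call risk_normalize()")
  }
  pca <- covariance_pca(matrix, "samples_as_variables")
  if (is.null(n_components)) {
    n_components <- max(2L, scree_select(pca))
    n_components <- min(n_components, length(pca$eigenvalues))
  }
  ranking <- rank_score_outliers(pca, n_components = n_components,
                                 cutoff = cutoff)
  structure(list(pca = pca, ranking = ranking,
                 highest_risk = ranking$selected, matrix = matrix),
            class = "risk_ranking")
}

#' @export
print.risk_ranking <- function(x, ...) {
  cat("PNEC-normalised risk ranking\n")
  cat("highest-risk positions:",
      if (length(x$highest_risk)) paste(x$highest_risk, collapse = ", ")
      else "(none)", "\n")
  print(utils::head(x$ranking$ranking, 10L))
  invisible(x)
}
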