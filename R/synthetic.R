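#' Default chemical panel for synthetic harbour scenarios
#'
#' Twenty-eight chemicals -- 11 heavy metals, 14 individual PAH plus the
#' aggregate PAH sum, and 2 hydrocarbon fractions -- with plausible
#' regulatory limits (mg/kg dry weight), water PNECs (mg/L), sediment-water
#' partition coefficients (L/kg) and, for two chemicals, acute toxicity
#' endpoints so the assessment-factor PNEC path is exercised.  The
#' aggregate PAH sum carries no PNEC information and is therefore dropped
#' by the risk stage, as an aggregate indicator should be.  Values are
#' typical magnitudes for Mediterranean harbour sediment guidelines, not a
#' transcription of any specific regulatory table.
#'
#' @return A [chem_registry] of 28 chemicals.
#' @export
default_chemicals <- function() {
  metals <- data.frame(
    name = c("Arsenic", "Cadmium", "Cobalt", "Chromium total", "Chromium VI",
             "Mercury", "Nickel", "Lead", "Copper", "Tin", "Zinc"),
    lcl = c(12, 0.3, 20, 50, 2, 0.3, 30, 30, 40, 3, 100),
    pnec_water = c(0.005, 0.0002, 0.003, 0.005, NA, 0.00005, 0.004,
                   0.0012, 0.0008, 0.0002, 0.0078),
    kp = c(500, 1300, 400, 2000, 1500, 10000, 800, 9000, 12000, 2500, 7000),
    stringsAsFactors = FALSE
  )
  pah <- data.frame(
    name = c("Benzo(a)anthracene", "Benzo(a)pyrene", "Benzo(b)fluoranthene",
             "Benzo(k)fluoranthene", "Benzo(g,h,i)perylene", "Chrysene",
             "Dibenzo(a,h)anthracene", "Indeno(1,2,3-c,d)pyrene", "Pyrene",
             "Fluoranthene", "Phenanthrene", "Anthracene", "Naphthalene",
             "Fluorene"),
    lcl = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.2, 0.1, 0.2, 0.5,
            0.5, 0.25, 0.1, 0.35, 0.2),
    pnec_water = c(0.0003, 0.00005, 0.00003, 0.00003, 0.00003, 0.00007,
                   0.00003, 0.00003, NA, 0.0001, 0.0013, 0.0001, 0.002,
                   0.0015),
    kp = c(30000, 50000, 60000, 60000, 70000, 40000, 80000, 70000, 8000,
           10000, 5000, 6000, 1500, 3000),
    stringsAsFactors = FALSE
  )
  hc <- data.frame(
    name = c("Hydrocarbons C<12", "Hydrocarbons C>12"),
    lcl = c(10, 50),
    pnec_water = c(0.05, 0.1),
    kp = c(200, 500),
    stringsAsFactors = FALSE
  )
  name <- c(metals$name, pah$name, "Sum-PAH", hc$name)
  cls <- c(rep("heavy_metal", nrow(metals)), rep("pah", nrow(pah)),
           "aggregate", rep("hydrocarbon", nrow(hc)))
  lcl <- c(metals$lcl, pah$lcl, 4, hc$lcl)
  pnec_w <- c(metals$pnec_water, pah$pnec_water, NA, hc$pnec_water)
  kp <- c(metals$kp, pah$kp, NA, hc$kp)
  eps <- vector("list", length(name))
  # endpoint-only chemicals: PNEC via the assessment-factor route
  eps[[match("Chromium VI", name)]] <- data.frame(conc = 0.01, af = 1000)
  eps[[match("Pyrene", name)]] <- data.frame(conc = c(0.012, 0.03),
                                             af = c(1000, 10000))
  chem_registry(name, cls, lcl_limit = lcl, pnec_water = pnec_w, kp = kp,
                endpoints = eps)
}

#' Default background contamination profile
#'
#' Median hazard quotients (concentration over regulatory limit) of the
#' diffuse background per chemical.  Zinc is far above its limit --
#' the dominant, nonpoint pollutant of the scenario -- followed by lead and
#' heavy hydrocarbons, echoing the variance ordering typical of an
#' industrial Mediterranean harbour.
#'
#' @return Named numeric vector of median hazard quotients.
#' @export
default_background_hq <- function() {
  c(Arsenic = 0.20, Cadmium = 0.30, Cobalt = 0.05, `Chromium total` = 0.20,
    `Chromium VI` = 0.02, Mercury = 0.25, Nickel = 0.15, Lead = 1.30,
    Copper = 0.50, Tin = 0.15, Zinc = 25,
    `Benzo(a)anthracene` = 0.15, `Benzo(a)pyrene` = 0.10,
    `Benzo(b)fluoranthene` = 0.10, `Benzo(k)fluoranthene` = 0.09,
    `Benzo(g,h,i)perylene` = 0.07, Chrysene = 0.15,
    `Dibenzo(a,h)anthracene` = 0.03, `Indeno(1,2,3-c,d)pyrene` = 0.08,
    Pyrene = 0.20, Fluoranthene = 0.15, Phenanthrene = 0.10,
    Anthracene = 0.08, Naphthalene = 0.05, Fluorene = 0.06,
    `Sum-PAH` = 0.45, `Hydrocarbons C<12` = 0.05, `Hydrocarbons C>12` = 0.70)
}

default_sources <- function() {
  list(
    pah_spill = list(
      positions = "S07",
      signature = c(Chrysene = 1.0, `Indeno(1,2,3-c,d)pyrene` = 0.6,
                    Pyrene = 1.4, Fluoranthene = 1.2,
                    `Benzo(a)anthracene` = 0.5),
      strength = 50),
    metal_source = list(
      positions = c("S21", "S55"),
      signature = c(Cadmium = 1.0, Lead = 0.8, Mercury = 0.5),
      strength = 50),
    hc_source = list(
      positions = c("S12", "S33", "S60"),
      signature = c(`Hydrocarbons C>12` = 1.0, `Hydrocarbons C<12` = 0.3,
                    `Sum-PAH` = 0.6),
      strength = 50)
  )
}

#' Define a synthetic harbour contamination scenario
#'
#' Generative model, per sample (replicate) at position `p` and chemical
#' `i`, in hazard-quotient units:
#' \deqn{HQ = (m_i G_p W_{p,i} H_s + S_k s_{ki} m_i f_s)\,\epsilon_{si}}
#' where `m_i` is the background median HQ and `G_p` a position enrichment
#' factor shared by all chemicals of the position: the diffuse background
#' co-varies across chemicals through fines content and organic carbon, and
#' because every position is a mixture of a clean-sand and a
#' contaminated-silt end-member the factor is *bounded* -- it is drawn
#' log-uniform with standard deviation `position_sigma` on the log scale.
#' `W_p` is an extra lognormal factor applied to the dominant pollutant
#' only (diffuse contamination with genuinely heavy spread, inflating its
#' variance to the requested share of the total), `H_s` a per-sample
#' lognormal factor (aliquot heterogeneity, shared across chemicals within
#' a sample), `S_k s_{ki} m_i f_s` the point-source term (signature
#' relative level times strength times a per-sample dilution factor, only
#' at source positions) and `\epsilon` a small per-cell lognormal
#' analytical error.  Ratio fingerprints of source-dominated chemicals are
#' exact up to `\epsilon` and the background leakage because `f_s` cancels
#' within a sample.
#'
#' The dominant pollutant's extra spread is solved numerically so that its
#' expected share of the total column variance equals `dominant_share`.
#'
#' @param seed integer seed; the same scenario always generates the same
#'   dataset.
#' @param n_positions number of sampling positions (default 68).
#' @param chemicals a [chem_registry] (default [default_chemicals()], 28
#'   chemicals).
#' @param background_hq named median hazard quotients per chemical.
#' @param dominant name of the dominant nonpoint pollutant (`NULL` for
#'   none).
#' @param dominant_share target share of total variance for the dominant
#'   pollutant (default 0.76; `NULL` disables the extra spread).
#' @param position_sigma sd (log scale) of the bounded, log-uniform
#'   position enrichment field shared by all chemicals (default 0.12).
#' @param sample_sigma lognormal sd of the per-sample factor (default
#'   0.03).
#' @param noise_cv lognormal sd of the per-cell analytical error (default
#'   0.01).
#' @param dilution_range `c(min, max)` of the uniform per-sample dilution
#'   factor applied to source contributions (default `c(0.5, 2)`).
#' @param sources named list; each source has `positions`, a named
#'   `signature` of relative levels (multiples of the chemical's background
#'   median, or absolute hazard-quotient units for chemicals with zero
#'   background) and a `strength` multiplier.
#' @param replicate_counts integer vector of samples per position
#'   (recycled); default: 2 replicates at every fifth position, 1
#'   elsewhere.
#' @param bdl_fraction expected fraction of background draws below the
#'   detection limit (default 0.05); detection limits are set at the
#'   corresponding background quantile.
#' @return An object of class `harbour_scenario`.
#' @export
harbour_scenario <- function(seed = 1L, n_positions = 68L,
                             chemicals = default_chemicals(),
                             background_hq = default_background_hq(),
                             dominant = "Zinc", dominant_share = 0.76,
                             position_sigma = 0.12, sample_sigma = 0.03,
                             noise_cv = 0.01, dilution_range = c(0.5, 2),
                             sources = default_sources(),
                             replicate_counts = NULL,
                             bdl_fraction = 0.05) {
  stopifnot(inherits(chemicals, "chem_registry"))
  miss <- setdiff(chemicals$name, names(background_hq))
  if (length(miss)) {
    stop("background_hq missing chemical(s): ", paste(miss, collapse = ", "))
  }
  if (any(background_hq < 0)) stop("background medians must be >= 0")
  if (length(dilution_range) != 2L || any(dilution_range <= 0) ||
      dilution_range[1L] > dilution_range[2L]) {
    stop("dilution_range must be positive c(min, max)")
  }
  if (position_sigma < 0 || sample_sigma < 0 || noise_cv < 0) {
    stop("dispersion parameters must be >= 0")
  }
  positions <- sprintf("S%02d", seq_len(n_positions))
  if (is.null(replicate_counts)) {
    replicate_counts <- rep(1L, n_positions)
    replicate_counts[seq_len(n_positions) %% 5L == 0L] <- 2L
  } else {
    replicate_counts <- rep_len(as.integer(replicate_counts), n_positions)
  }
  if (!is.null(sources) && length(sources)) {
    all_pos <- unlist(lapply(sources, `[[`, "positions"))
    if (anyDuplicated(all_pos)) {
      stop("source position assignments must be disjoint")
    }
    if (!all(all_pos %in% positions)) {
      stop("source positions outside the scenario grid")
    }
    for (s in sources) {
      if (any(s$signature <= 0)) stop("source signatures must be positive")
      bad <- setdiff(names(s$signature), chemicals$name)
      if (length(bad)) stop("signature names not in registry: ",
                            paste(bad, collapse = ", "))
    }
  } else sources <- list()
  scn <- structure(list(
    seed = as.integer(seed), n_positions = as.integer(n_positions),
    positions = positions, chemicals = chemicals,
    background_hq = background_hq[chemicals$name],
    dominant = dominant, dominant_share = dominant_share,
    dominant_sigma = 0,
    position_sigma = position_sigma, sample_sigma = sample_sigma,
    noise_cv = noise_cv, dilution_range = dilution_range,
    sources = sources, replicate_counts = replicate_counts,
    bdl_fraction = bdl_fraction
  ), class = "harbour_scenario")
  if (!is.null(dominant) && !is.null(dominant_share)) {
    if (!dominant %in% chemicals$name) stop("unknown dominant chemical")
    base <- dominant_variance_share(scn, 0)
    if (base >= dominant_share) {
      scn$dominant_sigma <- 0
    } else {
      scn$dominant_sigma <- stats::uniroot(
        function(s) dominant_variance_share(scn, s) - dominant_share,
        lower = 0, upper = 5, tol = 1e-10)$root
    }
  }
  scn
}

#' @export
print.harbour_scenario <- function(x, ...) {
  cat(sprintf("synthetic harbour scenario: %d positions, %d chemicals, %d source(s), seed %d\n",
              x$n_positions, nrow(x$chemicals), length(x$sources), x$seed))
  if (!is.null(x$dominant)) {
    cat(sprintf("  dominant pollutant %s (target variance share %.0f%%, extra sigma %.3f)\n",
                x$dominant, 100 * (x$dominant_share %||% 0), x$dominant_sigma))
  }
  for (nm in names(x$sources)) {
    s <- x$sources[[nm]]
    cat(sprintf("  source %s: %s <- %s\n", nm,
                paste(s$positions, collapse = ","),
                paste(names(s$signature), collapse = ",")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# moments of the log-uniform position factor: log G ~ U(-a, a), a = sqrt(3)*sigma
logunif_moment <- function(k, sigma) {
  a <- sqrt(3) * sigma
  if (a < 1e-12) return(1)
  sinh(k * a) / (k * a)
}

# Expected variance of each position-aggregated HQ column under the
# generative model (exact log-uniform/lognormal/uniform moments; mixture
# over positions).  Used both to solve the dominant pollutant's extra
# spread and as ground truth for variance-weight recovery tests.
expected_column_variances <- function(scn, dominant_sigma = scn$dominant_sigma) {
  m <- scn$background_hq
  chems <- names(m)
  a <- scn$dilution_range[1L]; b <- scn$dilution_range[2L]
  mu_f <- (a + b) / 2
  m2_f <- (a^2 + a * b + b^2) / 3
  a1 <- exp(scn$sample_sigma^2 / 2); h2 <- exp(2 * scn$sample_sigma^2)
  e1 <- exp(scn$noise_cv^2 / 2); e2 <- exp(2 * scn$noise_cv^2)
  src_of <- stats::setNames(rep(NA_integer_, scn$n_positions), scn$positions)
  for (k in seq_along(scn$sources)) {
    src_of[scn$sources[[k]]$positions] <- k
  }
  r <- scn$replicate_counts
  out <- stats::setNames(numeric(length(chems)), chems)
  for (i in seq_along(chems)) {
    is_dom <- !is.null(scn$dominant) && chems[i] == scn$dominant
    w1 <- if (is_dom) exp(dominant_sigma^2 / 2) else 1
    w2 <- if (is_dom) exp(2 * dominant_sigma^2) else 1
    g1 <- logunif_moment(1, scn$position_sigma) * w1
    g2 <- logunif_moment(2, scn$position_sigma) * w2
    cc <- vapply(seq_len(scn$n_positions), function(p) {
      k <- src_of[p]
      if (is.na(k)) return(0)
      sig <- scn$sources[[k]]$signature
      if (chems[i] %in% names(sig)) {
        scn$sources[[k]]$strength * sig[[chems[i]]] *
          (if (m[i] > 0) m[i] else 1)
      } else 0
    }, 0)
    mu_p <- (m[i] * g1 * a1 + cc * mu_f) * e1
    eX2_given <- m[i]^2 * g2 * a1^2 + 2 * m[i] * g1 * a1 * cc * mu_f +
      cc^2 * mu_f^2
    eY2 <- (m[i]^2 * g2 * h2 + 2 * m[i] * g1 * a1 * cc * mu_f +
              cc^2 * m2_f) * e2
    v_within <- (eY2 - eX2_given * e1^2) / r
    v_between <- eX2_given * e1^2 - mu_p^2
    v_p <- v_within + v_between
    n <- scn$n_positions
    out[i] <- sum(v_p) / n + sum((mu_p - mean(mu_p))^2) / (n - 1)
  }
  out
}

dominant_variance_share <- function(scn, dominant_sigma) {
  v <- expected_column_variances(scn, dominant_sigma)
  unname(v[scn$dominant] / sum(v))
}

#' Expected variance weights of a scenario
#'
#' Analytic per-chemical shares of the total column variance (in percent)
#' implied by the generative model -- the ground truth against which the
#' empirical [variable_variance_weights()] of a generated dataset can be
#' checked.
#'
#' @param scenario a [harbour_scenario].
#' @return Named numeric vector of percentages summing to 100.
#' @export
expected_weights <- function(scenario) {
  v <- expected_column_variances(scenario)
  100 * v / sum(v)
}

#' Generate a synthetic monitoring dataset
#'
#' Draws the dataset defined by a [harbour_scenario()]: replicate samples
#' at every position, below-detection-limit censoring, and the planted
#' point sources.  The same scenario (same seed) always yields an
#' identical dataset; the caller's random-number state is left untouched.
#'
#' @param scenario a [harbour_scenario].
#' @return A list with `samples` ([sample_records]), `chemicals`
#'   ([chem_registry]), `truth` (list: `labels` -- named vector mapping
#'   every position to `"background"` or its source name, `sources`,
#'   `dominant`, `expected_weights`) and the `scenario` itself.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "harbour_scenario"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(scenario$seed)
  reg <- scenario$chemicals
  chems <- reg$name
  lcl <- reg$lcl_limit
  m_hq <- scenario$background_hq
  n <- scenario$n_positions
  pos <- scenario$positions
  # detection limits placed near the lower background quantile: log-uniform
  # field quantile times the (normal) sample/analytical quantile -- an
  # approximate placement rule, the realised censoring rate is close to
  # but not exactly bdl_fraction
  q_bg <- sqrt(3) * scenario$position_sigma * (2 * scenario$bdl_fraction - 1) +
    stats::qnorm(scenario$bdl_fraction) *
      sqrt(scenario$sample_sigma^2 + scenario$noise_cv^2)
  dl <- vapply(seq_along(chems), function(i) {
    if (scenario$bdl_fraction <= 0 || m_hq[i] <= 0) return(0)
    m_hq[i] * lcl[i] * exp(q_bg)
  }, 0)
  src_of <- stats::setNames(rep(NA_character_, n), pos)
  for (nm in names(scenario$sources)) {
    src_of[scenario$sources[[nm]]$positions] <- nm
  }
  a_pos <- sqrt(3) * scenario$position_sigma
  G <- exp(stats::runif(n, -a_pos, a_pos))
  W <- exp(stats::rnorm(n, 0, scenario$dominant_sigma))
  idom <- if (is.null(scenario$dominant)) 0L else match(scenario$dominant, chems)
  rows <- vector("list", n)
  for (p in seq_len(n)) {
    r <- scenario$replicate_counts[p]
    k <- src_of[p]
    sig_hq <- numeric(length(chems))
    if (!is.na(k)) {
      s <- scenario$sources[[k]]
      j <- match(names(s$signature), chems)
      # signature levels are multiples of the background median where one
      # exists, absolute hazard-quotient units otherwise
      sig_hq[j] <- s$strength * s$signature * ifelse(m_hq[j] > 0, m_hq[j], 1)
    }
    rep_rows <- vector("list", r)
    for (s_i in seq_len(r)) {
      H <- exp(stats::rnorm(1, 0, scenario$sample_sigma))
      f <- stats::runif(1, scenario$dilution_range[1L],
                        scenario$dilution_range[2L])
      eps <- exp(stats::rnorm(length(chems), 0, scenario$noise_cv))
      w_i <- ifelse(seq_along(chems) == idom, W[p], 1)
      hq <- (m_hq * G[p] * w_i * H + sig_hq * f) * eps
      val <- hq * lcl
      bdl <- val < dl
      val[bdl] <- dl[bdl]
      rep_rows[[s_i]] <- data.frame(
        sample_id = sprintf("%s-%d", pos[p], s_i), point_id = pos[p],
        campaign_id = "C1", chemical = chems, value = val, bdl = bdl,
        stringsAsFactors = FALSE)
    }
    rows[[p]] <- do.call(rbind, rep_rows)
  }
  long <- do.call(rbind, rows)
  labels <- ifelse(is.na(src_of), "background", src_of)
  names(labels) <- pos
  list(
    samples = sample_records(long$sample_id, long$point_id, long$campaign_id,
                             long$chemical, long$value, long$bdl),
    chemicals = reg,
    truth = list(labels = labels, sources = scenario$sources,
                 dominant = scenario$dominant,
                 expected_weights = expected_weights(scenario)),
    scenario = scenario
  )
}

merge_cluster_sets <- function(cluster_sets, universe) {
  # union of per-subset clusterings: positions linked in any run share a
  # merged cluster (connected components across runs)
  edges <- character(0)
  for (cs in cluster_sets) {
    for (cl in cs$clusters) {
      if (length(cl) > 1L) {
        edges <- c(edges, as.vector(rbind(cl[-length(cl)], cl[-1L])))
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(universe)
  if (length(edges)) g <- g + igraph::edges(edges)
  igraph::components(g)$membership[universe]
}

#' Score recovery of planted ground truth
#'
#' Compares pipeline outputs against the planted sources of a synthetic
#' scenario: sensitivity and specificity of the flagged position set, and
#' the adjusted Rand agreement between the ratio-matching cluster
#' assignment and the planted source labels (computed over the positions
#' the clustering covered; singletons count as their own group).
#'
#' @param truth the `truth` element of [generate_scenario()] output.
#' @param report flagged positions: an `outlier_report`, an
#'   `outlier_ranking`, or a character vector.
#' @param clusters a `cluster_set`, or a list of them (merged by linking
#'   positions that share a cluster in any run).
#' @return List with `sensitivity`, `specificity`, `false_positives`,
#'   `agreement` (`NA` when no clustering is supplied), `planted`,
#'   `flagged`.
#' @export
score_recovery <- function(truth, report = NULL, clusters = NULL) {
  labels <- truth$labels
  planted <- names(labels)[labels != "background"]
  flagged <- if (is.null(report)) character() else
    if (inherits(report, "outlier_report")) report$sources$position else
    if (inherits(report, "outlier_ranking")) report$selected else
    as.character(report)
  unknown <- setdiff(flagged, names(labels))
  if (length(unknown)) {
    stop("flagged position(s) not in the scenario: ",
         paste(unknown, collapse = ", "))
  }
  tp <- length(intersect(flagged, planted))
  fp <- length(setdiff(flagged, planted))
  n_bg <- length(labels) - length(planted)
  agreement <- NA_real_
  if (!is.null(clusters)) {
    if (inherits(clusters, "cluster_set")) clusters <- list(clusters)
    covered <- sort(unique(unlist(lapply(clusters, function(cs) {
      c(unlist(cs$clusters), cs$singletons)
    }))))
    unknown <- setdiff(covered, names(labels))
    if (length(unknown)) {
      stop("clustered position(s) not in the scenario: ",
           paste(unknown, collapse = ", "))
    }
    if (length(covered) >= 2L) {
      memb <- merge_cluster_sets(clusters, covered)
      agreement <- mclust::adjustedRandIndex(labels[covered], memb)
    }
  }
  list(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       specificity = if (n_bg) 1 - fp / n_bg else NA_real_,
       false_positives = fp, agreement = agreement,
       planted = planted, flagged = sort(flagged))
}
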