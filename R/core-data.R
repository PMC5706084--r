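#' Chemical metadata registry
#'
#' Builds the per-chemical metadata table used throughout the screening:
#' chemical class, regulatory limit used as the hazard-quotient denominator,
#' and the ecotoxicological quantities needed to resolve a sediment PNEC
#' (either an explicit sediment PNEC, a water PNEC plus a sediment--water
#' partition coefficient, or acute toxicity endpoints with assessment
#' factors).
#'
#' @param name character vector of chemical names.
#' @param chem_class one of `"heavy_metal"`, `"pah"`, `"hydrocarbon"`,
#'   `"aggregate"` per chemical.
#' @param lcl_limit regulatory limit in mg/kg dry weight (> 0, or `NA`).
#' @param pnec_water predicted no-effect concentration in water, mg/L
#'   (optional, `NA` allowed).
#' @param kp sediment--water partition coefficient, L/kg (> 0 or `NA`).
#' @param endpoints list column: per chemical either `NULL` or a two-column
#'   `data.frame` with columns `conc` (mg/L) and `af` (assessment factor).
#' @param pnec_sediment explicit sediment PNEC in mg/kg (optional).
#'
#' @return A `data.frame` of class `chem_registry`.
#' @seealso [read_chemicals()] for the CSV reader.
#' @export
chem_registry <- function(name, chem_class, lcl_limit = NA_real_,
                          pnec_water = NA_real_, kp = NA_real_,
                          endpoints = NULL, pnec_sediment = NA_real_) {
  name <- as.character(name)
  n <- length(name)
  chem_class <- rep_len(as.character(chem_class), n)
  ok <- chem_class %in% c("heavy_metal", "pah", "hydrocarbon", "aggregate")
  if (!all(ok)) {
    stop("unknown chemical class: ", paste(unique(chem_class[!ok]), collapse = ", "))
  }
  lcl_limit <- rep_len(as.numeric(lcl_limit), n)
  pnec_water <- rep_len(as.numeric(pnec_water), n)
  kp <- rep_len(as.numeric(kp), n)
  pnec_sediment <- rep_len(as.numeric(pnec_sediment), n)
  if (any(!is.na(lcl_limit) & lcl_limit <= 0)) {
    stop("lcl_limit must be > 0 where present")
  }
  if (any(!is.na(kp) & kp <= 0)) stop("kp must be > 0 where present")
  if (anyDuplicated(name)) stop("duplicated chemical names in registry")
  if (is.null(endpoints)) endpoints <- vector("list", n)
  stopifnot(length(endpoints) == n)
  reg <- data.frame(
    name = name, chem_class = chem_class, lcl_limit = lcl_limit,
    pnec_water = pnec_water, kp = kp, pnec_sediment = pnec_sediment,
    stringsAsFactors = FALSE
  )
  reg$endpoints <- endpoints
  class(reg) <- c("chem_registry", "data.frame")
  reg
}

parse_endpoints <- function(x) {
  # "conc:af;conc:af" -> data.frame(conc, af)
  if (is.na(x) || !nzchar(trimws(x))) return(NULL)
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  pairs <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(pairs) != 2)) {
    stop("malformed endpoints field (expected 'conc:AF;conc:AF'): ", x)
  }
  conc <- as.numeric(vapply(pairs, `[`, "", 1L))
  af <- as.numeric(vapply(pairs, `[`, "", 2L))
  data.frame(conc = conc, af = af)
}

#' Read a chemicals metadata CSV
#'
#' Expected columns: `name`, `class`, `lcl_limit`, `pnec_water`, `kp`,
#' `endpoints` (semicolon-separated `conc:AF` pairs) and optionally
#' `pnec_sediment`.  Limits are mg/kg dry weight, water PNECs mg/L,
#' partition coefficients L/kg.
#'
#' @param path path to the CSV file.
#' @return A [chem_registry] data frame.
#' @export
read_chemicals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "class", "lcl_limit")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("chemicals file is missing column(s): ", paste(miss, collapse = ", "))
  }
  get_num <- function(col) if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  eps <- if ("endpoints" %in% names(df)) {
    lapply(as.character(df$endpoints), parse_endpoints)
  } else NULL
  chem_registry(
    name = df$name, chem_class = df$class,
    lcl_limit = get_num("lcl_limit"), pnec_water = get_num("pnec_water"),
    kp = get_num("kp"), endpoints = eps,
    pnec_sediment = get_num("pnec_sediment")
  )
}

#' Sampling-point alias table
#'
#' Maps raw sampling-point names to canonical position ids, e.g. when two
#' physically coincident points were logged under `"F2"` and `"F2bis"` in
#' different campaigns.  The mapping must be a function: each raw name has
#' exactly one canonical id.
#'
#' @param raw_name character vector of raw point names.
#' @param canonical_name canonical position id per raw name.
#' @return A named character vector of class `alias_table` (names = raw).
#' @export
alias_table <- function(raw_name = character(), canonical_name = character()) {
  raw_name <- as.character(raw_name)
  canonical_name <- as.character(canonical_name)
  stopifnot(length(raw_name) == length(canonical_name))
  if (anyDuplicated(raw_name)) {
    stop("alias table maps a raw name to more than one canonical id")
  }
  structure(stats::setNames(canonical_name, raw_name), class = "alias_table")
}

#' @rdname alias_table
#' @param path CSV with columns `raw_name`, `canonical_name`.
#' @export
read_aliases <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("raw_name", "canonical_name"), names(df))
  if (length(miss)) {
    stop("alias file is missing column(s): ", paste(miss, collapse = ", "))
  }
  alias_table(df$raw_name, df$canonical_name)
}

apply_aliases <- function(points, aliases = NULL) {
  points <- as.character(points)
  if (is.null(aliases) || !length(aliases)) return(points)
  hit <- points %in% names(aliases)
  points[hit] <- unname(aliases[points[hit]])
  points
}

#' Build a table of sample records
#'
#' Long-format container for raw monitoring measurements: one row per
#' (sample, chemical).  Concentrations are mg/kg dry weight; `bdl` marks
#' below-detection-limit entries, whose `value` is the detection limit
#' itself (half of it is substituted at the aggregation stage).
#'
#' @param sample_id,point_id,campaign_id,chemical character vectors.
#' @param value numeric concentrations, mg/kg dry weight (>= 0 or `NA`).
#' @param bdl logical, below-detection-limit flag.
#' @return A `data.frame` of class `sample_records`.
#' @export
sample_records <- function(sample_id, point_id, campaign_id, chemical,
                           value, bdl = FALSE) {
  df <- data.frame(
    sample_id = as.character(sample_id), point_id = as.character(point_id),
    campaign_id = as.character(campaign_id), chemical = as.character(chemical),
    value = as.numeric(value), bdl = rep_len(as.logical(bdl), length(value)),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(df$value) & df$value < 0
  if (any(bad)) {
    stop("negative concentration in sample(s): ",
         paste(unique(df$sample_id[bad]), collapse = ", "))
  }
  class(df) <- c("sample_records", "data.frame")
  df
}

#' Read a samples CSV
#'
#' The file is wide: columns `sample_id`, `point_id`, `campaign_id`, then
#' one column per chemical.  An optional units row (a data row whose
#' `sample_id` equals `"units"`) declares per-column units; `ug/kg` columns
#' are converted to the canonical mg/kg.  Below-detection-limit entries are
#' written as `"<DL"` (e.g. `"<0.05"`); empty cells mean not measured.
#'
#' @param path path to the samples CSV.
#' @param registry optional [chem_registry]; when supplied, chemical columns
#'   not present in the registry raise an error.
#' @return A [sample_records] data frame in long format.
#' @export
read_samples <- function(path, registry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  need <- c("sample_id", "point_id", "campaign_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("samples file is missing column(s): ", paste(miss, collapse = ", "))
  }
  chem_cols <- setdiff(names(df), need)
  if (!length(chem_cols)) stop("samples file has no chemical columns")
  if (!is.null(registry)) {
    unknown <- setdiff(chem_cols, registry$name)
    if (length(unknown)) {
      stop("unknown chemical(s) not in registry: ",
           paste(unknown, collapse = ", "))
    }
  }
  scale <- rep(1, length(chem_cols))
  names(scale) <- chem_cols
  urow <- which(tolower(df$sample_id) == "units")
  if (length(urow)) {
    units <- tolower(trimws(unlist(df[urow[1L], chem_cols])))
    units[units == ""] <- "mg/kg"
    bad <- !units %in% c("mg/kg", "ug/kg", "µg/kg")
    if (any(bad)) {
      stop("unsupported unit(s): ", paste(unique(units[bad]), collapse = ", "))
    }
    scale[units != "mg/kg"] <- 1e-3
    df <- df[-urow, , drop = FALSE]
  }
  long <- do.call(rbind, lapply(chem_cols, function(ch) {
    raw <- trimws(df[[ch]])
    bdl <- startsWith(raw, "<")
    num <- suppressWarnings(as.numeric(sub("^<", "", raw)))
    num[raw == ""] <- NA_real_
    parse_fail <- raw != "" & is.na(num)
    if (any(parse_fail)) {
      stop("non-numeric concentration for ", ch, " in sample(s): ",
           paste(df$sample_id[parse_fail], collapse = ", "))
    }
    data.frame(sample_id = df$sample_id, point_id = df$point_id,
               campaign_id = df$campaign_id, chemical = ch,
               value = num * scale[[ch]], bdl = bdl & !is.na(num),
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  rownames(long) <- NULL
  sample_records(long$sample_id, long$point_id, long$campaign_id,
                 long$chemical, long$value, long$bdl)
}

#' Read a complete monitoring dataset
#'
#' @param samples_path,chemicals_path,alias_path file paths; the alias table
#'   is optional and defaults to the identity mapping.
#' @return A list with elements `samples` ([sample_records]), `chemicals`
#'   ([chem_registry]) and `aliases` ([alias_table]).
#' @export
read_dataset <- function(samples_path, chemicals_path, alias_path = NULL) {
  chemicals <- read_chemicals(chemicals_path)
  samples <- read_samples(samples_path, registry = chemicals)
  aliases <- if (is.null(alias_path)) alias_table() else read_aliases(alias_path)
  list(samples = samples, chemicals = chemicals, aliases = aliases)
}

#' Canonical sampling positions
#'
#' Collapses raw sampling-point names to the sorted set of unique canonical
#' position ids: aliases are resolved and points re-sampled in later
#' campaigns count once.  Idempotent.
#'
#' @param x a [sample_records] data frame, or a character vector of raw
#'   point names.
#' @param aliases optional [alias_table].
#' @return Sorted character vector of canonical position ids.
#' @export
canonical_positions <- function(x, aliases = NULL) {
  points <- if (is.data.frame(x)) x$point_id else as.character(x)
  if (!length(points)) stop("no sampling points supplied")
  sort(unique(apply_aliases(points, aliases)))
}

#' Contamination matrix
#'
#' Positions-by-chemicals value grid with below-detection-limit flags and a
#' `value_kind` marker (`"raw"` mg/kg, `"hq"` hazard quotients, or
#' `"risk_quotient"` concentration/PNEC ratios).
#'
#' @param values numeric matrix, positions in rows (named), chemicals in
#'   columns (named); no negative entries.
#' @param bdl logical matrix of the same shape (default all `FALSE`).
#' @param value_kind one of `"raw"`, `"hq"`, `"risk_quotient"`.
#' @param campaigns optional character matrix of per-cell campaign
#'   provenance.
#' @return An object of class `contam_matrix`.
#' @export
contam_matrix <- function(values, bdl = NULL,
                          value_kind = c("raw", "hq", "risk_quotient"),
                          campaigns = NULL) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("contamination matrix needs position row names and chemical column names")
  }
  if (any(values < 0, na.rm = TRUE)) stop("negative values in contamination matrix")
  if (is.null(bdl)) {
    bdl <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  stopifnot(identical(dim(bdl), dim(values)))
  structure(list(values = values, bdl = bdl, value_kind = value_kind,
                 campaigns = campaigns),
            class = "contam_matrix")
}

#' @export
dim.contam_matrix <- function(x) dim(x$values)

#' @export
as.matrix.contam_matrix <- function(x, ...) x$values

#' @export
print.contam_matrix <- function(x, ...) {
  cat(sprintf("contamination matrix: %d positions x %d chemicals [%s]\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  cat(sprintf("  below detection limit: %d cells; not measured: %d cells\n",
              sum(x$bdl, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}

positions <- function(x) rownames(x$values)
chemicals <- function(x) colnames(x$values)

#' Aggregate sample records to a position-by-chemical matrix
#'
#' Replicate samples at one canonical position are combined by the chosen
#' aggregator.  Below-detection-limit measurements contribute half their
#' detection limit; a cell is flagged BDL only when every contributing
#' replicate was below the limit.  Chemicals never measured at a position
#' stay `NA` (they are masked downstream, never imputed).
#'
#' @param records a [sample_records] data frame.
#' @param aliases optional [alias_table] applied to point ids first.
#' @param aggregator `"mean"` (default) or `"median"`.
#' @param bdl_substitute fraction of the detection limit substituted for
#'   BDL replicates (default 0.5).
#' @return A [contam_matrix] with `value_kind = "raw"`.
#' @export
aggregate_to_matrix <- function(records, aliases = NULL,
                                aggregator = c("mean", "median"),
                                bdl_substitute = 0.5) {
  aggregator <- match.arg(aggregator)
  if (!nrow(records)) stop("no sample records to aggregate")
  agg_fun <- if (aggregator == "mean") mean else stats::median
  pos <- apply_aliases(records$point_id, aliases)
  pts <- sort(unique(pos))
  chems <- unique(records$chemical)
  vals <- matrix(NA_real_, length(pts), length(chems),
                 dimnames = list(pts, chems))
  bdl <- matrix(FALSE, length(pts), length(chems),
                dimnames = list(pts, chems))
  camp <- matrix(NA_character_, length(pts), length(chems),
                 dimnames = list(pts, chems))
  use_val <- ifelse(records$bdl, records$value * bdl_substitute, records$value)
  key <- split(seq_len(nrow(records)),
               interaction(factor(pos, pts), factor(records$chemical, chems),
                           sep = "\001", drop = TRUE))
  for (k in names(key)) {
    idx <- key[[k]]
    i <- match(pos[idx[1L]], pts)
    j <- match(records$chemical[idx[1L]], chems)
    vals[i, j] <- agg_fun(use_val[idx])
    bdl[i, j] <- all(records$bdl[idx])
    camp[i, j] <- paste(sort(unique(records$campaign_id[idx])), collapse = ",")
  }
  all_na <- colSums(!is.na(vals)) == 0L
  if (any(all_na)) {
    warning("chemical(s) with no measurements retained as all-NA column(s): ",
            paste(chems[all_na], collapse = ", "))
  }
  contam_matrix(vals, bdl, value_kind = "raw", campaigns = camp)
}

#' Express a raw matrix as hazard quotients
#'
#' Divides every cell by the chemical's regulatory limit (`lcl_limit` in
#' the registry), turning concentrations into dimensionless hazard
#' quotients; HQ > 1 signals exceedance of the guideline.
#'
#' @param matrix a [contam_matrix] with `value_kind = "raw"`.
#' @param registry a [chem_registry] supplying `lcl_limit` for every
#'   chemical in the matrix.
#' @return A [contam_matrix] with `value_kind = "hq"`.
#' @export
compute_hq <- function(matrix, registry) {
  if (matrix$value_kind != "raw") {
    stop("compute_hq expects a raw concentration matrix")
  }
  chems <- chemicals(matrix)
  lim <- registry$lcl_limit[match(chems, registry$name)]
  bad <- is.na(lim)
  if (any(bad)) {
    stop("no regulatory limit for chemical(s): ",
         paste(chems[bad], collapse = ", "))
  }
  vals <- sweep(matrix$values, 2L, lim, `/`)
  contam_matrix(vals, matrix$bdl, value_kind = "hq",
                campaigns = matrix$campaigns)
}

#' Read a campaign scheme table
#'
#' A small bookkeeping table with one row per monitoring campaign and
#' columns `campaign`, `collected_samples`, `sampling_points`,
#' `heavy_metals`, `pah`, `hc` (chemical counts per family; aggregate
#' indicators such as a PAH sum are included in the family count).
#'
#' @param path CSV path.
#' @return A validated `data.frame`.
#' @export
read_campaign_scheme <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("campaign", "collected_samples", "sampling_points",
            "heavy_metals", "pah", "hc")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("campaign scheme is missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in need[-1L]) df[[col]] <- as.integer(df[[col]])
  df
}
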