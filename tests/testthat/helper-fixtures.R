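# small in-code fixtures shared across test files

make_registry <- function(n = 3, classes = rep("heavy_metal", n),
                          lcl = rep(10, n)) {
  chem_registry(paste0("chem", seq_len(n)), classes, lcl_limit = lcl,
                pnec_water = rep(0.001, n), kp = rep(1000, n))
}

make_cmatrix <- function(values, kind = "hq", bdl = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("chem", seq_len(ncol(values)))
  }
  contam_matrix(values, bdl = bdl, value_kind = kind)
}

# a wide samples CSV on disk; concentrations is a named list of rows
write_samples_csv <- function(rows, chems, units = NULL) {
  path <- tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r$sample_id, point_id = r$point_id,
               campaign_id = r$campaign_id,
               as.list(stats::setNames(r$conc, chems)),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  if (!is.null(units)) {
    df <- rbind(data.frame(sample_id = "units", point_id = "", campaign_id = "",
                           as.list(stats::setNames(units, chems)),
                           check.names = FALSE, stringsAsFactors = FALSE), df)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_chemicals_csv <- function(reg = make_registry()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(name = reg$name, class = reg$chem_class,
                              lcl_limit = reg$lcl_limit,
                              pnec_water = reg$pnec_water, kp = reg$kp),
                   path, row.names = FALSE, quote = FALSE)
  path
}

# compact scenario for property tests: full chemistry, fewer positions
tiny_scenario <- function(seed = 1, ...) {
  harbour_scenario(seed = seed, n_positions = 24,
                   sources = list(
                     spill = list(positions = "S03",
                                  signature = c(Chrysene = 1, Pyrene = 1.3,
                                                Fluoranthene = 0.8),
                                  strength = 50),
                     metals = list(positions = c("S10", "S17"),
                                   signature = c(Cadmium = 1, Lead = 0.7,
                                                 Mercury = 0.4),
                                   strength = 50)),
                   ...)
}
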