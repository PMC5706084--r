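test_that("samples reader parses well-formed files, units and censoring", {
  chems <- c("chem1", "chem2")
  path <- write_samples_csv(list(
    list(sample_id = "s1", point_id = "P1", campaign_id = "C1", conc = c(1, 2)),
    list(sample_id = "s2", point_id = "P2", campaign_id = "C1", conc = c(3, 4)),
    list(sample_id = "s3", point_id = "P3", campaign_id = "C2", conc = c(5, 6))
  ), chems)
  rec <- read_samples(path)
  expect_s3_class(rec, "sample_records")
  expect_identical(sort(unique(rec$sample_id)), c("s1", "s2", "s3"))
  expect_equal(rec$value[rec$sample_id == "s2" & rec$chemical == "chem2"], 4)

  # ug/kg columns convert to mg/kg; "<x" is a censored value at x
  path2 <- write_samples_csv(list(
    list(sample_id = "s1", point_id = "P1", campaign_id = "C1",
         conc = c("1000", "<0.5"))
  ), chems, units = c("ug/kg", "mg/kg"))
  rec2 <- read_samples(path2)
  expect_equal(rec2$value[rec2$chemical == "chem1"], 1)
  expect_equal(rec2$value[rec2$chemical == "chem2"], 0.5)
  expect_true(rec2$bdl[rec2$chemical == "chem2"])

  # negative concentrations are rejected with the offending sample named
  path3 <- write_samples_csv(list(
    list(sample_id = "bad1", point_id = "P1", campaign_id = "C1",
         conc = c(-1, 2))
  ), chems)
  expect_error(read_samples(path3), "bad1")

  # schema and registry validation
  expect_error(read_samples(write_chemicals_csv()), "missing column")
  expect_error(read_samples(path, registry = make_registry(1)),
               "unknown chemical")
})

test_that("alias tables map raw names onto canonical positions", {
  chems <- "chem1"
  spath <- write_samples_csv(list(
    list(sample_id = "s1", point_id = "F2bis", campaign_id = "C1", conc = 1),
    list(sample_id = "s2", point_id = "F2", campaign_id = "C2", conc = 3)
  ), chems)
  apath <- tempfile(fileext = ".csv")
  writeLines(c("raw_name,canonical_name", "F2bis,F2"), apath)
  ds <- read_dataset(spath, write_chemicals_csv(make_registry(1)), apath)
  m <- aggregate_to_matrix(ds$samples, ds$aliases)
  expect_identical(rownames(m$values), "F2")
  expect_equal(m$values["F2", "chem1"], 2)  # mean of the two campaigns
  expect_error(alias_table(c("a", "a"), c("x", "y")), "more than one")
})

test_that("canonical_positions deduplicates, resolves aliases, idempotent", {
  al <- alias_table("F2bis", "F2")
  pts <- c("A1", "A1", "F2bis", "F2", "B1")
  got <- canonical_positions(pts, al)
  expect_identical(got, c("A1", "B1", "F2"))
  expect_identical(canonical_positions(got, al), got)
  expect_identical(canonical_positions(c("X", "Y")), c("X", "Y"))
  expect_error(canonical_positions(character()), "no sampling points")
})

test_that("replicate aggregation honours the aggregator and masks", {
  rec <- sample_records(
    sample_id = c("a", "b", "c", "d", "e"),
    point_id = c("P1", "P1", "P2", "P2", "P2"),
    campaign_id = "C1",
    chemical = "chem1",
    value = c(10, 20, 1, 2, 100))
  m_mean <- aggregate_to_matrix(rec)
  expect_equal(m_mean$values["P1", "chem1"], 15)
  m_med <- aggregate_to_matrix(rec, aggregator = "median")
  expect_equal(m_med$values["P2", "chem1"], 2)
  expect_identical(m_mean$value_kind, "raw")

  # single record per position is the identity
  one <- sample_records("s", "P1", "C1", c("chem1", "chem2"), c(3.5, 7.25))
  expect_equal(unname(aggregate_to_matrix(one)$values["P1", ]), c(3.5, 7.25))

  # censored replicates contribute half the detection limit; a cell is BDL
  # only when all replicates are
  cen <- sample_records(c("a", "b"), "P1", "C1", "chem1", c(1, 1),
                        bdl = c(TRUE, FALSE))
  m <- aggregate_to_matrix(cen)
  expect_equal(m$values["P1", "chem1"], 0.75)
  expect_false(m$bdl["P1", "chem1"])
  allc <- aggregate_to_matrix(sample_records("a", "P1", "C1", "chem1", 1,
                                             bdl = TRUE))
  expect_true(allc$bdl["P1", "chem1"])
  expect_equal(allc$values["P1", "chem1"], 0.5)
})

test_that("hazard-quotient normalisation divides by limits and inverts", {
  reg <- make_registry(2, lcl = c(100, 50))
  m <- make_cmatrix(matrix(c(50, 100, 0, 25), 2, 2), kind = "raw")
  hq <- compute_hq(m, reg)
  expect_identical(hq$value_kind, "hq")
  expect_equal(unname(hq$values[, "chem1"]), c(0.5, 1))
  expect_equal(unname(hq$values[, "chem2"]), c(0, 0.5))
  # zero matrix stays zero
  z <- compute_hq(make_cmatrix(matrix(0, 2, 2), kind = "raw"), make_registry(2))
  expect_true(all(z$values == 0))
  # round trip to raw within 1e-12 relative
  back <- sweep(hq$values, 2, reg$lcl_limit, `*`)
  expect_lt(max(abs(back - m$values)), 1e-12 * max(m$values))
  # a chemical with no limit is an error naming it
  reg2 <- make_registry(2)
  reg2$lcl_limit[2] <- NA
  expect_error(compute_hq(m, reg2), "chem2")
})

test_that("all-missing chemical columns warn but are retained", {
  rec <- sample_records(c("a", "a", "b"), c("P1", "P1", "P2"), "C1",
                        c("chem1", "chem2", "chem1"), c(1, NA, 2))
  rec <- rec[!is.na(rec$value), ]
  rec2 <- rbind(rec, data.frame(sample_id = "c", point_id = "P3",
                                campaign_id = "C1", chemical = "chem2",
                                value = NA_real_, bdl = FALSE))
  class(rec2) <- class(rec)
  expect_warning(m <- aggregate_to_matrix(rec2), "chem2")
  expect_true("chem2" %in% colnames(m$values))
  expect_true(all(is.na(m$values[, "chem2"])))
})

test_that("chemicals reader round-trips metadata and endpoints", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "name,class,lcl_limit,pnec_water,kp,endpoints",
    "Cadmium,heavy_metal,0.3,0.0002,1300,",
    "Pyrene,pah,0.5,,8000,0.012:1000;0.03:10000"
  ), path)
  reg <- read_chemicals(path)
  expect_s3_class(reg, "chem_registry")
  expect_equal(reg$kp[1], 1300)
  expect_null(reg$endpoints[[1]])
  expect_equal(reg$endpoints[[2]]$af, c(1000, 10000))
  expect_error(chem_registry("x", "metal"), "unknown chemical class")
  expect_error(chem_registry("x", "pah", lcl_limit = -1), "lcl_limit")
})
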