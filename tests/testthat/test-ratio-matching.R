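test_that("ratio matrices hold the strictly upper triangle of c_i / c_j", {
  rm <- ratio_matrix(c(a = 2, b = 4, c = 8))
  expect_equal(rm["a", "b"], 0.5)
  expect_equal(rm["a", "c"], 0.25)
  expect_equal(rm["b", "c"], 0.5)
  expect_true(all(is.na(rm[lower.tri(rm, diag = TRUE)])))

  eq <- ratio_matrix(stats::setNames(rep(3, 4), letters[1:4]))
  expect_true(all(eq[upper.tri(eq)] == 1))

  # m chemicals give m(m-1)/2 ratios; m = 28 -> 378
  m28 <- ratio_matrix(stats::setNames(stats::runif(28, 1, 2),
                                      default_chemicals()$name))
  expect_identical(sum(!is.na(m28)), 378L)

  # zeros and censored values are masked, never ratioed
  rm2 <- ratio_matrix(c(a = 1, b = 0, c = 2, d = 3), bdl = c(FALSE, FALSE,
                                                             TRUE, FALSE))
  expect_true(all(is.na(rm2[, "b"])) && all(is.na(rm2["b", ])))
  expect_true(all(is.na(rm2[, "c"])) && all(is.na(rm2["c", ])))
  expect_equal(rm2["a", "d"], 1 / 3)
  expect_error(ratio_matrix(c(a = 1, b = 0)), "fewer than 2")
})

test_that("fingerprint comparison is dilution-invariant and reciprocal", {
  conc <- c(a = 1.2, b = 3.4, c = 0.7, d = 9)
  A <- ratio_matrix(conc)
  B <- ratio_matrix(conc * 3)  # same sample diluted/concentrated
  cmp <- compare_ratios(A, B)
  expect_equal(unname(cmp$quotients[upper.tri(cmp$quotients)]), rep(1, 6))
  expect_equal(cmp$in_band_fraction, 1)
  self <- compare_ratios(A, A)
  expect_true(all(self$quotients[upper.tri(self$quotients)] == 1))

  # reciprocity of the symmetrised band
  set.seed(21)
  for (i in 1:10) {
    x <- ratio_matrix(stats::setNames(stats::rlnorm(5), letters[1:5]))
    y <- ratio_matrix(stats::setNames(stats::rlnorm(5), letters[1:5]))
    expect_equal(compare_ratios(x, y)$in_band_fraction,
                 compare_ratios(y, x)$in_band_fraction)
  }
})

test_that("one discordant ratio out of three gives in-band fraction 2/3", {
  A <- ratio_matrix(c(a = 2, b = 4, c = 8))
  B <- ratio_matrix(c(a = 2, b = 4, c = 8))
  B["a", "b"] <- B["a", "b"] / 1.5  # perturb a single stored ratio
  cmp <- compare_ratios(A, B, band = c(0.90, 1.10))
  expect_equal(cmp$n_compared, 3L)
  expect_equal(cmp$in_band_fraction, 2 / 3)
})

test_that("comparison rejects incompatible or disjoint fingerprints", {
  A <- ratio_matrix(c(a = 1, b = 2, c = 3))
  B <- ratio_matrix(c(x = 1, y = 2, z = 3))
  expect_error(compare_ratios(A, B), "orderings")
  # disjoint masks: nothing to compare
  C <- ratio_matrix(c(a = 1, b = 2, c = 3), bdl = c(FALSE, FALSE, TRUE))
  D <- ratio_matrix(c(a = 1, b = 2, c = 3), bdl = c(TRUE, FALSE, FALSE))
  expect_error(compare_ratios(C, D), "jointly")
  expect_error(compare_ratios(A, A, band = c(1.1, 0.9)), "band")
})

test_that("band clustering groups shared signatures and isolates unique ones", {
  sigA <- c(ch1 = 2, ch2 = 6, ch3 = 1, ch4 = 4)
  sigB <- c(ch1 = 5, ch2 = 1, ch3 = 3, ch4 = 0.5)
  X <- rbind(p1 = sigA * 1.0, p2 = sigA * 2.5,   # dilution factors differ
             p3 = sigB * 0.8, p4 = sigB * 3.1)
  m <- make_cmatrix(X, kind = "raw")
  cs <- ratio_cluster(m, link_threshold = 0.9)
  expect_length(cs$clusters, 2)
  expect_true(list(c("p1", "p2")) %in% cs$clusters &&
                list(c("p3", "p4")) %in% cs$clusters)

  # all positions identical: a single all-member cluster
  same <- make_cmatrix(rbind(q1 = sigA, q2 = sigA, q3 = sigA), kind = "raw")
  cs2 <- ratio_cluster(same)
  expect_length(cs2$clusters, 1)
  expect_identical(cs2$clusters[[1]], c("q1", "q2", "q3"))

  # a unique signature among copies of another comes back as a singleton
  uni <- make_cmatrix(rbind(p1 = sigA, p2 = sigA * 4, lone = sigB),
                      kind = "raw")
  cs3 <- ratio_cluster(uni)
  expect_identical(cs3$singletons, "lone")

  # average-linkage alternative agrees on this clean layout
  cs4 <- ratio_cluster(m, method = "average")
  expect_length(cs4$clusters, 2)
  expect_error(ratio_cluster(m, band = c(1.2, 1.1)), "band")
  expect_error(ratio_cluster(m, positions = "p1"), "at least 2")
})

test_that("clustering is invariant to dilution and chemical order", {
  set.seed(31)
  sig <- c(w = 1, x = 2, y = 4, z = 8)
  X <- rbind(p1 = sig, p2 = sig * 0.3, p3 = rev(sig)[c(2, 1, 4, 3)] * 2)
  colnames(X) <- names(sig)
  base <- ratio_cluster(make_cmatrix(X, "raw"))
  # multiply one sample's full vector by any c > 0
  X2 <- X; X2["p2", ] <- X2["p2", ] * 17.3
  expect_identical(ratio_cluster(make_cmatrix(X2, "raw"))$clusters,
                   base$clusters)
  # permute chemicals consistently
  perm <- c("y", "w", "z", "x")
  expect_identical(ratio_cluster(make_cmatrix(X[, perm], "raw"))$clusters,
                   base$clusters)
})

test_that("hazard-quotient and raw fingerprints cluster identically", {
  gen <- generate_scenario(tiny_scenario(seed = 4))
  raw <- aggregate_to_matrix(gen$samples)
  hq <- compute_hq(raw, gen$chemicals)
  pos <- c("S10", "S17", "S03", "S01")
  sub <- c("Cadmium", "Lead", "Mercury")
  a <- ratio_cluster(raw, pos, chem_subset = sub)
  b <- ratio_cluster(hq, pos, chem_subset = sub)
  expect_equal(a$similarity, b$similarity, tolerance = 1e-12)
})

test_that("source clustering compares pairs over shared flagged chemicals", {
  sig <- c(m1 = 10, m2 = 30, m3 = 5, p1 = 0.2, p2 = 0.1)
  X <- rbind(A = sig, B = sig * 2, C = sig)
  X["C", c("p1", "p2")] <- c(40, 90)   # C's anomaly lives elsewhere
  m <- make_cmatrix(X, kind = "raw")
  flags <- list(A = c("m1", "m2", "m3"), B = c("m1", "m2", "m3"),
                C = c("p1", "p2"))
  cs <- cluster_sources(m, flags)
  expect_identical(cs$clusters, list(c("A", "B")))
  expect_identical(cs$singletons, "C")
  # fewer than two shared chemicals: no comparison, hence no link
  expect_true(is.na(cs$similarity["A", "C"]))
})
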