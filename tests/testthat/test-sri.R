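# Every index name printed in the benchmark comparison table; the registry
# must resolve each one.
TABLE_SRI_NAMES <- c(
  "SR (550;670)", "NRI (1510;660)", "MTCI (800;750;670)", "CI (415;695)",
  "NDSI (403;830)", "SAVI (807;736)", "NDSI (543;548)", "RBI (695;445)",
  "NDSI (933;948)", "SR (690;655)", "SR (960;950)", "WI (950;900)",
  "PRI * CI (570;530;760;700)", "SR (440;685)", "NDWI (970;920)",
  "WI (900;970)", "WI (970;900)", "PRI (550;531)", "MCARI (700;670;550)",
  "TCARI (700;600;550;850;670)", "AI (740;887;691;698)", "PRI (512;531)",
  "NDSI (410;550)", "NDSI (1060;1118)", "RE (670;780)", "SAVI 2 (800;670)",
  "NDTI (1650;2215)", "WDVI (830;660)", "NDSI (940;1122)", "NDSI (442;438)",
  "NDWI (870;1260)", "BI (460;660)", "NDSI (503;483)", "TCARI (700;670;550)",
  "SIPI (800;440;680)", "NDWI (970;850)", "Datt (850;710;680)")

test_that("registry carries the named water and chlorophyll indices", {
  reg <- sri_registry()
  nwi3 <- sri_lookup(reg, "NWI-3")
  expect_setequal(nwi3$wavelengths[[1]], c(970, 920))
  expect_equal(nwi3$expression, "(R970 - R920) / (R970 + R920)")
  mtci <- sri_lookup(reg, "MTCI")
  expect_setequal(mtci$wavelengths[[1]], c(800, 750, 670))
  expect_setequal(sri_lookup(reg, "WI2")$wavelengths[[1]], c(970, 900))
  expect_false(anyDuplicated(reg$name) > 0)
  # base-name lookup must refuse genuinely ambiguous names
  expect_error(sri_lookup(reg, "WI"), class = "spectrait_lookup_error")
})

test_that("every index named in the comparison table resolves", {
  reg <- sri_registry()
  for (nm in TABLE_SRI_NAMES) {
    expect_no_error(sri_lookup(reg, nm))
  }
})

test_that("index formulas evaluate to their hand-computed values", {
  s <- toy_spectra(matrix(c(0.30, 0.30, 0.45, 0.30, 0.50, 0.40, 0.05),
                          nrow = 1),
                   wl = c(920, 970, 807, 736, 800, 750, 670))
  expect_equal(compute_index(s, "NWI-3"), 0)
  expect_equal(compute_index(s, "SAVI (807;736)"), 1.5 * 0.15 / 1.25) # 0.18
  expect_equal(compute_index(s, "MTCI"), 0.10 / 0.35)                 # 0.2857
})

test_that("zero denominators yield missing values, not errors", {
  s <- toy_spectra(matrix(c(0, 0), nrow = 1), wl = c(920, 970))
  expect_true(is.na(compute_index(s, "NWI-3")))
  s2 <- toy_spectra(matrix(c(0, 0.4), nrow = 1), wl = c(900, 970))
  expect_true(is.na(compute_index(s2, "WI2")))  # 0.4/0: undefined ratio
})

test_that("missing bands raise an error naming the wavelength", {
  s <- toy_spectra(matrix(c(0.3, 0.4), nrow = 1), wl = c(900, 920))
  err <- expect_error(compute_index(s, "NWI-3"),
                      class = "spectrait_band_error")
  expect_match(conditionMessage(err), "970")
})

test_that("NDSI antisymmetry and SR reciprocity hold numerically", {
  set.seed(21)
  for (i in 1:20) {
    a <- sample(400:2400, 1); b <- sample(setdiff(400:2400, a), 1)
    s <- toy_spectra(matrix(runif(10, 0.05, 0.9), nrow = 5),
                     wl = sort(c(a, b)))
    nd_ab <- compute_index(s, sri_ndsi(a, b))
    nd_ba <- compute_index(s, sri_ndsi(b, a))
    expect_equal(nd_ab, -nd_ba, tolerance = 1e-12)
    sr_ab <- compute_index(s, sri_sr(a, b))
    sr_ba <- compute_index(s, sri_sr(b, a))
    expect_equal(sr_ab * sr_ba, rep(1, 5), tolerance = 1e-12)
  }
})

test_that("normalized differences and ratios are scale-invariant; soil-adjusted forms are not", {
  set.seed(22)
  wl <- c(660, 670, 736, 800, 807, 830, 900, 920, 970)
  v <- runif(length(wl), 0.1, 0.6)
  s1 <- toy_spectra(matrix(v, nrow = 1), wl = wl)
  s2 <- toy_spectra(matrix(3 * v / 4, nrow = 1), wl = wl)  # c = 0.75
  expect_equal(compute_index(s1, "NWI-3"), compute_index(s2, "NWI-3"))
  expect_equal(compute_index(s1, "WI2"), compute_index(s2, "WI2"))
  expect_false(isTRUE(all.equal(compute_index(s1, "SAVI (807;736)"),
                                compute_index(s2, "SAVI (807;736)"))))
  expect_false(isTRUE(all.equal(compute_index(s1, "WDVI (830;660)"),
                                compute_index(s2, "WDVI (830;660)"))))
})

test_that("every registry entry evaluates on a full-range canopy spectrum", {
  fx <- scene16()
  one <- fx$spectra[1, ]
  reg <- sri_registry()
  vals <- compute_indices(one, reg)
  expect_equal(ncol(vals), nrow(reg) + 1L)
  expect_true(all(is.finite(unlist(vals[-1]))))
})

test_that("bulk evaluation matches the per-row, per-index loop", {
  fx <- scene16()
  sp <- fx$spectra[1:6, ]
  reg <- sri_registry()
  bulk <- compute_indices(sp, reg)
  for (j in sample(nrow(reg), 8)) {
    per_row <- vapply(seq_len(nrow(sp)), function(i)
      compute_index(sp[i, ], reg[j, ]), numeric(1))
    expect_equal(bulk[[reg$name[j]]], per_row)
  }
})

test_that("a flat spectrum zeroes every normalized difference", {
  s <- toy_spectra(matrix(0.4, 2, 2151), wl = 350:2500)
  reg <- sri_registry()
  vals <- compute_indices(s, reg)
  nd <- reg$name[reg$kind == "normalized_difference"]
  for (nm in nd) expect_equal(vals[[nm]], c(0, 0))
})

test_that("indices whose bands were trimmed yield all-missing columns with a warning", {
  fx <- scene16()
  sp <- trim_noise_bands(fx$spectra[1:3, ], list(c(940, 1000)))
  warnings_seen <- character()
  withCallingHandlers(
    vals <- compute_indices(sp),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("NWI-3", warnings_seen)))
  expect_true(all(is.na(vals[["NWI-3"]])))
  expect_true(all(is.finite(vals[["MTCI (800;750;670)"]])))
})

test_that("registries round-trip through the declarative text format", {
  reg <- dplyr::bind_rows(sri_registry(), sri_ndsi(1100, 1205))
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_equal(back$name, reg$name)
  expect_equal(back$expression, reg$expression)
  expect_equal(back$wavelengths, reg$wavelengths)
  s <- scene16()$spectra[1, ]
  expect_equal(compute_indices(s, back), compute_indices(s, reg))
})

test_that("constructors reject out-of-range wavelengths", {
  expect_error(sri_ndsi(300, 800), class = "spectrait_format_error")
  expect_error(sri_sr(900, 2600), class = "spectrait_format_error")
})
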