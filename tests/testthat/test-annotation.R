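pl_index <- function() {
  comps <- dplyr::bind_rows(lapply(c("PC", "PE", "PG", "PI"), function(cl) {
    enumerate_compositions(default_acyl_pool(), cl)
  }))
  build_index(comps)
}

test_that("a PC 32:0 peak in the precursor-184 scan annotates with ~0 error", {
  sp <- new_spectrum(scan_mode("PIS", "+", 184.07), "PL",
                     tibble::tibble(mz = 734.5694, intensity = 1e5))
  ann <- match_peaks(sp, pl_index())
  expect_equal(nrow(ann), 1)
  expect_equal(ann$composition, "PC 32:0")
  expect_lt(abs(ann$error_mDa), 0.1)
  expect_equal(ann$flags, "")
})

test_that("empty spectra give empty annotation tables", {
  sp <- new_spectrum(scan_mode("PIS", "+", 184.07), "PL",
                     tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  ann <- match_peaks(sp, pl_index())
  expect_equal(nrow(ann), 0)
  expect_true(all(c("class", "composition", "error_mDa", "flags") %in% names(ann)))
})

test_that("scan-mode class gating holds: PIS-184 annotates PC only", {
  idx <- pl_index()
  # a PG [M-H]- peak presented to a PIS-184 spectrum finds nothing
  pg_mz <- ion_mz(assemble_species_formula("PG", c("16:0", "16:1")), "[M-H]-")
  sp <- new_spectrum(scan_mode("PIS", "+", 184.07), "PL",
                     tibble::tibble(mz = pg_mz, intensity = 1))
  expect_equal(nrow(match_peaks(sp, idx)), 0)
  q1 <- new_spectrum(scan_mode("Q1", "-"), "PL",
                     tibble::tibble(mz = pg_mz, intensity = 1))
  ann <- match_peaks(q1, idx)
  expect_true(all(ann$class %in% c("PG", "PI", "PE")))
  expect_equal(ann$composition[ann$rank == 1], "PG 32:1")
  expect_error(match_peaks(q1, idx[idx$mode == "PIS184+", ]), "no entries")
})

test_that("a peak between two candidates returns both, flagged ambiguous", {
  idx <- tibble::tibble(
    class = "PC", composition = c("PC 90:0", "PC 90:1"), sn_resolved = FALSE,
    mode = "PIS184+", adduct = "[M+H]+", mz = c(1000.000, 1000.010)
  )
  sp <- new_spectrum(scan_mode("PIS", "+", 184.07), "PL",
                     tibble::tibble(mz = 1000.005, intensity = 1))
  ann <- match_peaks(sp, idx, tolerance = 0.01)
  expect_equal(nrow(ann), 2)
  expect_true(all(ann$flags == "ambiguous_multi_candidate"))
})

test_that("enlarging the tolerance never removes an annotation", {
  fx <- packaged_fixtures(n_decoys = 40, seed = 3)
  sp <- generate_scan(fx$fsolaris_pl, scan_mode("PIS", "+", 184.07))
  idx <- pl_index()
  tols <- c(0.002, 0.005, 0.01, 0.05, 0.2)
  prev <- NULL
  for (tol in tols) {
    ann <- match_peaks(sp, idx, tolerance = tol)
    if (!is.null(prev)) {
      prev_keys <- paste(prev$observed_mz, prev$composition, prev$adduct)
      keys <- paste(ann$observed_mz, ann$composition, ann$adduct)
      expect_true(all(prev_keys %in% keys))
    }
    prev <- ann
  }
})

test_that("match_peaks equals an exhaustive linear scan over candidates", {
  idx <- pl_index()
  set.seed(5)
  mzs <- sort(c(stats::runif(150, 600, 900), idx$mz[sample(nrow(idx), 50)] +
                  stats::runif(50, -0.02, 0.02)))
  sp <- new_spectrum(scan_mode("Q1", "-"), "PL",
                     tibble::tibble(mz = mzs, intensity = 1))
  ann <- match_peaks(sp, idx, tolerance = 0.01)
  sub <- idx[idx$mode == "Q1-", ]
  for (mz in mzs) {
    want <- linear_scan(sub, mz, 0.01)
    got <- ann[ann$observed_mz == mz, ]
    expect_equal(nrow(got), nrow(want))
    expect_setequal(got$composition, want$composition)
  }
})

test_that("isotopic M+2 overlap pairs are flagged by window arithmetic", {
  # PC 36:6 and PC 36:5 differ by 2.01565; the M+2 spacing is 2.00671
  comps <- enumerate_compositions(default_acyl_pool(), "PC")
  idx <- build_index(comps[comps$composition %in% c("PC 36:6", "PC 36:5"), ])
  wide <- flag_isotopic_overlap(idx, window = 0.02)
  expect_equal(nrow(wide), 1)
  expect_equal(wide$composition_a, "PC 36:6") # lighter species first
  expect_equal(wide$composition_b, "PC 36:5")
  expect_equal(abs(wide$offset_from_m2), 2.01565 - 2 * 1.003355,
               tolerance = 1e-4)
  narrow <- flag_isotopic_overlap(idx, window = 0.005)
  expect_equal(nrow(narrow), 0)
  one <- build_index(comps[comps$composition == "PC 36:6", ])
  expect_equal(nrow(flag_isotopic_overlap(one, 0.02)), 0)
})

test_that("profile resolution deduplicates species and runs the checks", {
  expect_s3_class(resolve_profile(tibble::tibble()), "lipid_profile")
  empty <- resolve_profile(tibble::tibble())
  expect_equal(empty$n_total, 0)
  expect_true(as.logical(empty$checks$value[empty$checks$check == "pe_absent"]))
  # same species seen twice (two scans) counts once
  ann <- tibble::tibble(
    fraction = "PL", scan_mode = c("PIS184+", "Q1-"),
    observed_mz = c(734.5694, 732.5549), intensity = 1,
    class = "PC", composition = "PC 32:0", adduct = c("[M+H]+", "[M-H]-"),
    theoretical_mz = c(734.5694, 732.5549), error_mDa = 0, error_ppm = 0,
    rank = 1L, flags = ""
  )
  prof <- resolve_profile(ann)
  expect_equal(prof$n_total, 1)
  expect_equal(prof$counts$n[prof$counts$class == "PC"], 1)
  g <- glance(prof)
  expect_equal(g$n_species, 1)
  expect_true(g$pe_absent)
  expect_s3_class(tidy(prof), "tbl_df")
  expect_s3_class(autoplot(prof), "ggplot")
})
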