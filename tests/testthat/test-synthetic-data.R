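test_that("packaged rosters reproduce the fraction profiles and constraints", {
  fx <- packaged_fixtures()
  pl <- fx$fsolaris_pl$roster
  gl <- fx$fsolaris_gl$roster
  expect_equal(nrow(pl), 14)
  expect_equal(sum(pl$class == "PC"), 11)
  expect_equal(sum(pl$class == "PG"), 2)
  expect_equal(sum(pl$class == "PI"), 1)
  expect_equal(nrow(gl), 16)
  expect_equal(sum(gl$class == "MGDG"), 8)
  expect_equal(sum(gl$class == "DGDG"), 5)
  expect_equal(sum(gl$class == "SQDG"), 3)
  all_species <- dplyr::bind_rows(pl, gl)
  # no PE anywhere
  expect_equal(sum(all_species$class == "PE"), 0)
  # chloroplast lipids and PG/PI carry a C16 acyl at sn-2
  chloro <- all_species[all_species$class %in%
                          c("MGDG", "DGDG", "SQDG", "PG", "PI"), ]
  expect_true(all(grepl("^16:", chloro$sn2)))
  # C18 chains occur only at the sn-2 position of PCs
  expect_false(any(grepl("^18:", c(all_species$sn1, chloro$sn2))))
  c18 <- grepl("^18:", all_species$sn2)
  expect_true(all(all_species$class[c18] == "PC"))
  # EPA-containing eukaryotic PCs have EPA at sn-1; PC 20:5/20:5 present
  euk_pc <- all_species$class == "PC" & !grepl("^16:|^14:", all_species$sn2)
  expect_true(all(all_species$sn1[euk_pc] == "20:5"))
  expect_true(any(all_species$sn1 == "20:5" & all_species$sn2 == "20:5"))
  # no 22:6 in the fixtures
  expect_false(any(c(all_species$sn1, all_species$sn2) == "22:6"))
})

test_that("fixture species are mutually non-isobaric within detection modes", {
  fx <- packaged_fixtures()
  for (fix in fx) {
    for (key in c("PIS184+", "NL162+", "Q1-")) {
      cls <- lipid_classes()
      vis <- vapply(fix$roster$class, function(cid) {
        key %in% cls$detection_modes[[match(cid, cls$class_id)]]
      }, logical(1))
      sub <- fix$roster[vis, ]
      if (nrow(sub) < 2) next
      adduct <- default_mode_adducts()[[key]][1]
      mzs <- vapply(seq_len(nrow(sub)), function(i) {
        ion_mz(assemble_species_formula(sub$class[i], c(sub$sn1[i], sub$sn2[i])),
               adduct)
      }, numeric(1))
      d <- abs(outer(mzs, mzs, "-"))
      expect_true(all(d[upper.tri(d)] > 0.02))
    }
  }
})

test_that("survey scans are gated by class and deterministic under the seed", {
  fx <- packaged_fixtures(seed = 42)
  pis <- generate_scan(fx$fsolaris_pl, scan_mode("PIS", "+", 184.07))
  expect_equal(nrow(pis$peaks), 11) # PCs only; PG/PI invisible here
  q1 <- generate_scan(fx$fsolaris_pl, scan_mode("Q1", "-"))
  expect_equal(nrow(q1$peaks), 3) # 2 PG + 1 PI
  nl <- generate_scan(fx$fsolaris_gl, scan_mode("NL", "+", 162))
  expect_equal(nrow(nl$peaks), 13) # 8 MGDG + 5 DGDG
  again <- generate_scan(fx$fsolaris_pl, scan_mode("PIS", "+", 184.07))
  expect_identical(pis, again)
})

test_that("decoy peaks are seeded, reproducible and kept off true peaks", {
  fx <- packaged_fixtures(n_decoys = 30, seed = 9)
  sp1 <- generate_scan(fx$fsolaris_pl, scan_mode("PIS", "+", 184.07))
  sp2 <- generate_scan(fx$fsolaris_pl, scan_mode("PIS", "+", 184.07))
  expect_identical(sp1, sp2)
  expect_equal(nrow(sp1$peaks), 11 + 30)
  clean <- generate_scan(packaged_fixtures(seed = 9)$fsolaris_pl,
                         scan_mode("PIS", "+", 184.07))
  decoys <- setdiff(sp1$peaks$mz, clean$peaks$mz)
  expect_length(decoys, 30)
  expect_true(all(vapply(decoys, function(d) {
    all(abs(d - clean$peaks$mz) > 0.05)
  }, logical(1))))
  other_seed <- generate_scan(packaged_fixtures(n_decoys = 30, seed = 10)$fsolaris_pl,
                              scan_mode("PIS", "+", 184.07))
  expect_false(identical(sp1$peaks, other_seed$peaks))
})

test_that("the isotope envelope follows the binomial 13C model", {
  fx <- packaged_fixtures(isotope = TRUE)
  pis <- generate_scan(fx$fsolaris_pl, scan_mode("PIS", "+", 184.07))
  # PC 16:0/16:0 has 40 carbons; [M+H]+ adds none
  m <- pis$peaks[abs(pis$peaks$mz - 734.5694) < 0.001, ]
  m1 <- pis$peaks[abs(pis$peaks$mz - (734.5694 + 1.003355)) < 0.001, ]
  m2 <- pis$peaks[abs(pis$peaks$mz - (734.5694 + 2 * 1.003355)) < 0.001, ]
  p <- 0.0107
  expect_equal(m1$intensity / m$intensity,
               stats::dbinom(1, 40, p) / stats::dbinom(0, 40, p),
               tolerance = 1e-6)
  expect_equal(m2$intensity / m$intensity,
               stats::dbinom(2, 40, p) / stats::dbinom(0, 40, p),
               tolerance = 1e-6)
  expect_equal(m1$intensity / m$intensity, 40 * p / (1 - p), tolerance = 1e-6)
})

test_that("product scans encode the sn-2 intensity convention", {
  sp <- generate_product_scan("PC", c("20:5", "16:1"), r = 2)
  i205 <- sp$peaks$intensity[abs(sp$peaks$mz - ORACLE$carbox_20_5) < 0.001]
  i161 <- sp$peaks$intensity[abs(sp$peaks$mz - ORACLE$carbox_16_1) < 0.001]
  expect_equal(i161 / i205, 2)
  eq <- generate_product_scan("PC", c("20:5", "16:1"), r = 1)
  e205 <- eq$peaks$intensity[abs(eq$peaks$mz - ORACLE$carbox_20_5) < 0.001]
  e161 <- eq$peaks$intensity[abs(eq$peaks$mz - ORACLE$carbox_16_1) < 0.001]
  expect_equal(e161, e205)
  tag <- generate_product_scan("TAG", c("16:0", "16:1", "20:5"), r = 2)
  ints <- vapply(c("16:0", "16:1", "20:5"), function(ch) {
    tag$peaks$intensity[abs(tag$peaks$mz -
                              diagnostic_mz("acyl_carboxylate", ch)) < 0.001]
  }, numeric(1))
  expect_equal(names(which.max(ints)), "16:1") # sn-2 most intense
  expect_error(generate_product_scan("PC", c("20:5", NA)), "resolved")
})

test_that("fixture validation rejects malformed rosters", {
  bad <- tibble::tibble(class = "PC", sn1 = "16:0", sn2 = "16:0", sn3 = NA,
                        abundance = 1.5)
  expect_error(fixture_spec(bad, "PL"), "abundances")
  bad2 <- tibble::tibble(class = "TAG", sn1 = "16:0", sn2 = "16:0", sn3 = NA,
                         abundance = 0.5)
  expect_error(fixture_spec(bad2, "PL"), "needs 3 chains")
  expect_error(fixture_spec(bad2[0, ], "PL"), "empty")
})
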