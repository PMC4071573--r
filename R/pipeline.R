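#' Simulate all scans for a fixture into a run directory
#'
#' Writes the fraction's survey scans (precursor-ion 184 positive and
#' negative Q1 for PL; neutral-loss 162 positive and negative Q1 for GL),
#' a negative-mode product-ion scan per roster species bundled as one MGF,
#' the ground-truth roster, the run configuration and a file manifest.
#' Deterministic under the fixture seed: re-runs are byte-identical.
#'
#' @param fixture A [fixture_spec()] or a packaged fixture name
#'   (`"fsolaris_pl"`, `"fsolaris_gl"`).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed override for a named packaged fixture.
#' @param r sn-2 : sn-1 carboxylate ratio for the product scans.
#' @param scale Survey precursor intensity scale.
#' @return Invisibly, a character vector of the files written.
#' @export
run_simulate <- function(fixture, out_dir, seed = 1L, r = 2, scale = 1e5) {
  if (is.character(fixture)) {
    fixtures <- packaged_fixtures(seed = seed)
    if (!fixture %in% names(fixtures)) {
      stop("unknown packaged fixture: ", fixture, " (have: ",
           paste(names(fixtures), collapse = ", "), ")", call. = FALSE)
    }
    fixture_name <- fixture
    fixture <- fixtures[[fixture]]
  } else {
    stopifnot(inherits(fixture, "fixture_spec"))
    fixture_name <- "custom"
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  modes <- if (fixture$fraction == "PL") {
    list(pis184_pos = scan_mode("PIS", "+", 184.07), q1_neg = scan_mode("Q1", "-"))
  } else {
    list(nl162_pos = scan_mode("NL", "+", 162), q1_neg = scan_mode("Q1", "-"))
  }
  files <- character(0)
  for (nm in names(modes)) {
    sp <- generate_scan(fixture, modes[[nm]], scale = scale)
    f <- file.path(out_dir, paste0("scan_", nm, ".tsv"))
    write_peaklist(sp, f)
    files <- c(files, f)
  }
  prods <- purrr::map(seq_len(nrow(fixture$roster)), function(i) {
    row <- fixture$roster[i, ]
    generate_product_scan(row$class, roster_chains(row), polarity = "-",
                          r = r, fraction = fixture$fraction)
  })
  f <- file.path(out_dir, "scan_products.mgf")
  write_mgf(prods, f)
  files <- c(files, f)
  truth <- fixture$roster
  truth$species <- vapply(seq_len(nrow(truth)), function(i) {
    species_label(truth$class[i], roster_chains(truth[i, ]))
  }, character(1))
  tf <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  config <- list(fixture = fixture_name, fraction = fixture$fraction,
                 n_species = nrow(fixture$roster),
                 n_decoys = fixture$n_decoys, isotope = fixture$isotope,
                 seed = fixture$seed, product_ratio_r = r, scale = scale)
  cf <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cf, auto_unbox = TRUE, pretty = TRUE)
  all_files <- c(files, tf, cf)
  manifest <- file.path(out_dir, "manifest.txt")
  writeLines(sort(basename(all_files)), manifest)
  invisible(c(all_files, manifest))
}

#' Annotate the scans of a run directory
#'
#' Reads every `scan_*.tsv` survey scan and the `scan_products.mgf`
#' product scans, builds a candidate index from the acyl pool, matches
#' peaks under scan-mode class gating, resolves the deduplicated species
#' profile, assigns sn positions from the product scans and classifies
#' each resolved species as prokaryotic or eukaryotic assembly. Writes
#' `annotations.tsv`, `species.tsv`, `profile.json` and `profile.txt`.
#'
#' @param run_dir Directory produced by [run_simulate()].
#' @param out_dir Output directory (defaults to `run_dir`).
#' @param tolerance Matching tolerance in Da.
#' @param tau Positional intensity-ratio threshold.
#' @param pool Acyl-chain pool for candidate enumeration.
#' @param classes Classes to enumerate candidates for.
#' @return The `lipid_profile`, invisibly.
#' @export
run_annotate <- function(run_dir, out_dir = run_dir, tolerance = 0.01,
                         tau = 1.5, pool = default_acyl_pool(),
                         classes = c("PC", "PE", "PG", "PI", "MGDG",
                                     "DGDG", "SQDG")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scan_files <- sort(list.files(run_dir, pattern = "^scan_.*\\.tsv$",
                                full.names = TRUE))
  comps <- dplyr::bind_rows(lapply(classes, function(cl) {
    enumerate_compositions(pool, cl)
  }))
  index <- build_index(comps)
  annotations <- purrr::map_dfr(scan_files, function(f) {
    match_peaks(read_peaklist(f), index, tolerance = tolerance)
  })
  profile <- resolve_profile(annotations)
  mgf <- file.path(run_dir, "scan_products.mgf")
  if (file.exists(mgf) && nrow(profile$species) > 0) {
    prods <- read_peaklist(mgf, format = "mgf")
    if (inherits(prods, "difi_spectrum")) prods <- list(prods)
    species <- positional_calls(prods, profile$species, tau = tau,
                                tolerance = tolerance)
    species <- classify_assembly(species)
    profile <- profile_from_species(species)
  }
  ann_out <- annotations
  if (nrow(ann_out) > 0 && "positional" %in% names(profile$species)) {
    pos <- profile$species[, c("class", "composition", "positional")]
    ann_out <- dplyr::left_join(ann_out, pos, by = c("class", "composition"))
  }
  write_annotation_table(ann_out, file.path(out_dir, "annotations.tsv"))
  utils::write.table(as.data.frame(profile$species),
                     file.path(out_dir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_profile_json(profile, file.path(out_dir, "profile.json"))
  txt <- utils::capture.output(print(profile))
  writeLines(txt, file.path(out_dir, "profile.txt"))
  invisible(profile)
}

#' Search the canonical EPA-incorporation routes
#'
#' Runs the reaction-network search for the three scheme queries:
#' the one-step PDAT conversion of PC 20:5/20:5 + DAG 16:0/16:1 into an
#' EPA-containing TAG; the three-step acyl-editing + head-group-exchange
#' synthesis of DAG 20:5/16:1 from an EPA-bearing eukaryotic PC; and the
#' desaturation/elongation reachability of an EPA-bearing PC from
#' PC 16:0/18:1. Writes `routes.json` when `out_dir` is given.
#'
#' @param out_dir Optional output directory for `routes.json`.
#' @param max_depth Search depth for the two targeted route searches.
#' @return A named list: `pdat_tag` (list of minimal routes),
#'   `acyl_editing_dag` (list of minimal routes), `epa_synthesis`
#'   (one route).
#' @export
run_routes <- function(out_dir = NULL, max_depth = 4) {
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  pdat <- find_routes(lipid_pool(c("PC 20:5/20:5", "DAG 16:0/16:1")),
                      "TAG 16:0/16:1/20:5", max_depth = max_depth)
  editing <- find_routes(lipid_pool(c("PC 20:5/18:2", "DAG 16:0/16:1"),
                                    coa = "16:1"),
                         "DAG 20:5/16:1", max_depth = max_depth)
  epa <- epa_synthesis_reachability("PC 16:0/18:1")
  out <- list(pdat_tag = pdat, acyl_editing_dag = editing,
              epa_synthesis = epa)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_routes_json(c(pdat, editing, list(epa)),
                      file.path(out_dir, "routes.json"))
  }
  out
}
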