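#' Define a synthetic-fixture specification
#'
#' A fixture is a roster of positionally resolved species with relative
#' abundances, a fraction label, and a noise/isotope model. Together with
#' a seed it fully determines every generated scan (same spec, same seed,
#' byte-identical output).
#'
#' @param roster Tibble with columns `class`, `sn1`, `sn2`, `sn3`
#'   (NA for diacyl classes), `abundance` in (0, 1].
#' @param fraction `"PL"` or `"GL"`.
#' @param n_decoys Number of uniform decoy (noise) peaks per scan.
#' @param decoy_intensity Upper bound of decoy peak intensity.
#' @param isotope Logical; append M+1/M+2 isotopologue peaks using a
#'   binomial 13C model.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(roster, fraction, n_decoys = 0,
                         decoy_intensity = 2000, isotope = FALSE, seed = 1L) {
  roster <- tibble::as_tibble(roster)
  need <- c("class", "sn1", "sn2", "sn3", "abundance")
  if (!all(need %in% names(roster))) {
    stop("roster needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(roster) == 0) stop("roster is empty", call. = FALSE)
  if (any(roster$abundance <= 0 | roster$abundance > 1)) {
    stop("abundances must lie in (0, 1]", call. = FALSE)
  }
  cls <- lipid_classes()
  for (i in seq_len(nrow(roster))) {
    chains <- roster_chains(roster[i, ])
    n_acyl <- cls$n_acyl[match(roster$class[i], cls$class_id)]
    if (is.na(n_acyl)) stop("unknown class in roster: ", roster$class[i], call. = FALSE)
    if (length(chains) != n_acyl) {
      stop("row ", i, ": ", roster$class[i], " needs ", n_acyl, " chains",
           call. = FALSE)
    }
    parse_acyl(chains)
  }
  structure(list(roster = roster, fraction = fraction,
                 n_decoys = as.integer(n_decoys),
                 decoy_intensity = decoy_intensity,
                 isotope = isotope, seed = as.integer(seed)),
            class = "fixture_spec")
}

roster_chains <- function(row) {
  ch <- c(row$sn1, row$sn2, row$sn3)
  ch[!is.na(ch) & ch != "NA"]
}

#' Packaged F. solaris-like fixtures
#'
#' Two rosters emulating the polar-lipid profile of an EPA-rich pennate
#' diatom: a phospholipid fraction of 11 PC + 2 PG + 1 PI species (no PE)
#' and a glycolipid fraction of 8 MGDG + 5 DGDG + 3 SQDG species. The
#' rosters honor the profile's positional constraints: every chloroplast
#' lipid (MGDG/DGDG/SQDG/PG/PI) carries a C16 acyl at sn-2; C18 acyls
#' occur only at the sn-2 position of PCs; EPA-containing eukaryotic PCs
#' carry EPA (20:5) at sn-1; PC 20:5/20:5 is present. Chain identities
#' are a synthetic stand-in chosen from the default pool under those
#' constraints (see `inst/extdata/fsolaris_roster.tsv`).
#'
#' @param n_decoys,decoy_intensity,isotope,seed Passed to [fixture_spec()];
#'   defaults give noiseless, isotope-free scans.
#' @return Named list with elements `fsolaris_pl` and `fsolaris_gl`.
#' @export
packaged_fixtures <- function(n_decoys = 0, decoy_intensity = 2000,
                              isotope = FALSE, seed = 1L) {
  path <- system.file("extdata", "fsolaris_roster.tsv", package = "lipidsn",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  tab$abundance <- as.numeric(tab$abundance)
  tab <- tibble::as_tibble(tab)
  mk <- function(fix, fraction) {
    fixture_spec(tab[tab$fixture == fix,
                     c("class", "sn1", "sn2", "sn3", "abundance")],
                 fraction, n_decoys = n_decoys,
                 decoy_intensity = decoy_intensity,
                 isotope = isotope, seed = seed)
  }
  list(fsolaris_pl = mk("fsolaris_pl", "PL"),
       fsolaris_gl = mk("fsolaris_gl", "GL"))
}

# Relative M+k/M intensity for a molecule with n_c carbons under a binomial
# 13C model with per-carbon abundance p: choose(n_c, k) * (p/(1-p))^k.
isotope_ratio <- function(n_carbons, k, p = 0.0107) {
  choose(n_carbons, k) * (p / (1 - p))^k
}

#' Generate a survey scan from a fixture
#'
#' Emits one precursor peak per roster species whose class is detectable
#' in the requested mode, at the m/z of the mode's default (or given)
#' adduct, with intensity `abundance * scale`. Optionally appends an
#' M+1/M+2 isotope envelope (binomial 13C model, p = 0.0107) and seeded
#' uniform decoy peaks over m/z 400-1000; decoys are never placed within
#' 0.05 Da of a true peak.
#'
#' @param fixture A [fixture_spec()].
#' @param mode A [scan_mode()] (`Q1`, `PIS` or `NL`).
#' @param scale Intensity of a species with abundance 1.
#' @param adduct Adduct name; default is the mode's first default adduct.
#' @return A `difi_spectrum`.
#' @export
generate_scan <- function(fixture, mode, scale = 1e5, adduct = NULL) {
  stopifnot(inherits(fixture, "fixture_spec"), inherits(mode, "scan_mode"))
  key <- mode_key(mode)
  if (is.na(key)) stop("use generate_product_scan() for PRODUCT mode", call. = FALSE)
  defaults <- default_mode_adducts()
  if (is.null(adduct)) {
    if (!key %in% names(defaults)) stop("no default adduct for mode ", key, call. = FALSE)
    adduct <- defaults[[key]][1]
  }
  cls <- lipid_classes()
  roster <- fixture$roster
  visible <- vapply(roster$class, function(cid) {
    key %in% cls$detection_modes[[match(cid, cls$class_id)]]
  }, logical(1))
  sub <- roster[visible, ]
  peaks <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    chains <- roster_chains(sub[i, ])
    f <- assemble_species_formula(sub$class[i], chains)
    mz0 <- ion_mz(f, adduct)
    out <- tibble::tibble(mz = mz0, intensity = sub$abundance[i] * scale)
    if (fixture$isotope) {
      nc <- if ("C" %in% names(f)) f[["C"]] else 0L
      # adduct may add carbons (e.g. formate)
      delta <- .adduct_row(adduct)$delta[[1]]
      if ("C" %in% names(delta)) nc <- nc + delta[["C"]]
      iso <- tibble::tibble(
        mz = mz0 + 1:2 * C13_C12_DELTA,
        intensity = sub$abundance[i] * scale * isotope_ratio(nc, 1:2)
      )
      out <- dplyr::bind_rows(out, iso)
    }
    out
  })
  if (fixture$n_decoys > 0) {
    true_mz <- peaks$mz
    decoy_seed <- (fixture$seed * 1009L +
                     sum(utf8ToInt(paste0(key, adduct)))) %% .Machine$integer.max
    decoys <- withr::with_seed(decoy_seed, {
      got <- numeric(0)
      tries <- 0L
      while (length(got) < fixture$n_decoys && tries < 100L * fixture$n_decoys) {
        x <- stats::runif(1, 400, 1000)
        if (all(abs(x - true_mz) > 0.05) && all(abs(x - got) > 0.05)) {
          got <- c(got, x)
        }
        tries <- tries + 1L
      }
      tibble::tibble(mz = got,
                     intensity = stats::runif(length(got), 0,
                                              fixture$decoy_intensity))
    })
    peaks <- dplyr::bind_rows(peaks, decoys)
  }
  peaks <- peaks[order(peaks$mz), ]
  new_spectrum(mode, fixture$fraction, peaks)
}

#' Generate a product-ion scan for one resolved species
#'
#' In negative mode, emits the `[RCOO]-` carboxylate of each acyl chain
#' with the sn-2 fragment `r` times as intense as sn-1 (and sn-3), the
#' positional convention shared with [assign_positions()]; coincident
#' fragments of identical chains are summed. A head-group marker peak is
#' added (deprotonated head group in negative mode; the 184.0733
#' phosphocholine cation for PC in positive mode). The precursor m/z of
#' the scan mode is the species' `[M-H]-` (negative) or `[M+H]+`
#' (positive) ion.
#'
#' @param class_id Lipid class.
#' @param chains Character vector of resolved chains in sn order
#'   (sn-1, sn-2\[, sn-3\]); no NA.
#' @param polarity `"-"` (default) or `"+"`.
#' @param r sn-2 : sn-1 carboxylate intensity ratio (default 2.0).
#' @param scale Base fragment intensity.
#' @param fraction Fraction label for the emitted spectrum.
#' @return A `difi_spectrum` in `PRODUCT` mode.
#' @examples
#' generate_product_scan("PC", c("20:5", "16:1"))
#' @export
generate_product_scan <- function(class_id, chains, polarity = "-", r = 2,
                                  scale = 1e4, fraction = "PL") {
  if (any(is.na(chains)) || length(chains) < 2) {
    stop("product scans need fully resolved sn positions", call. = FALSE)
  }
  row <- .class_row(class_id)
  if (length(chains) != row$n_acyl) {
    stop(class_id, " expects ", row$n_acyl, " chains", call. = FALSE)
  }
  f <- assemble_species_formula(class_id, chains)
  precursor <- ion_mz(f, if (polarity == "-") "[M-H]-" else "[M+H]+")
  weight <- rep(1, length(chains))
  weight[2] <- r # sn-2 is the middle position
  frag <- tibble::tibble(
    mz = vapply(chains, function(ch) diagnostic_mz("acyl_carboxylate", ch),
                numeric(1)),
    intensity = weight * scale
  )
  frag <- dplyr::summarise(dplyr::group_by(frag, .data$mz),
                           intensity = sum(.data$intensity), .groups = "drop")
  head_f <- row$head_formula[[1]]
  head_peak <- NULL
  if (polarity == "+" && class_id %in% c("PC", "LPC")) {
    head_peak <- tibble::tibble(mz = diagnostic_mz("phosphocholine_fragment"),
                                intensity = 0.5 * scale)
  } else if (polarity == "-" && length(head_f) > 0 &&
             any(c("P", "S") %in% names(head_f))) {
    head_peak <- tibble::tibble(mz = ion_mz(head_f, "[M-H]-"),
                                intensity = 0.5 * scale)
  }
  peaks <- dplyr::bind_rows(frag, head_peak)
  peaks <- peaks[order(peaks$mz), ]
  new_spectrum(scan_mode("PRODUCT", polarity, precursor), fraction, peaks)
}
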