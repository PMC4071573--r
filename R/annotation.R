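#' Match observed peaks against a candidate index
#'
#' Every index entry whose mode matches the spectrum's scan mode and whose
#' m/z lies within `tolerance` of an observed peak becomes an annotation.
#' Class gating is carried by the index: a positive precursor-ion-184 scan
#' only ever matches PC candidates, a positive neutral-loss-162 scan only
#' MGDG/DGDG, a negative Q1 survey only SQDG/PG/PI/PE (class resolved by
#' head-group mass). Candidates for one peak are ranked by absolute mass
#' error; when more than one candidate falls inside the tolerance all of
#' them are flagged `ambiguous_multi_candidate`.
#'
#' @param spectrum A `difi_spectrum` (survey mode: Q1/PIS/NL).
#' @param index Candidate index from [build_index()].
#' @param tolerance Matching tolerance in Da (default 0.01, unit-resolution
#'   triple-quadrupole practice).
#' @return A tibble with one row per (peak, candidate): `fraction`,
#'   `scan_mode`, `observed_mz`, `intensity`, `class`, `composition`,
#'   `adduct`, `theoretical_mz`, `error_mDa`, `error_ppm`, `rank`, `flags`.
#' @export
match_peaks <- function(spectrum, index, tolerance = 0.01) {
  stopifnot(inherits(spectrum, "difi_spectrum"), tolerance > 0)
  key <- mode_key(spectrum$mode)
  if (is.na(key)) {
    stop("match_peaks() annotates survey scans; use assign_positions() for product scans",
         call. = FALSE)
  }
  sub <- index[index$mode == key, ]
  if (nrow(sub) == 0) {
    stop("candidate index has no entries for scan mode ", key, call. = FALSE)
  }
  empty <- tibble::tibble(
    fraction = character(0), scan_mode = character(0),
    observed_mz = numeric(0), intensity = numeric(0), class = character(0),
    composition = character(0),
    adduct = character(0), theoretical_mz = numeric(0),
    error_mDa = numeric(0), error_ppm = numeric(0), rank = integer(0),
    flags = character(0)
  )
  if (nrow(spectrum$peaks) == 0) return(empty)
  rows <- purrr::map_dfr(seq_len(nrow(spectrum$peaks)), function(i) {
    mz <- spectrum$peaks$mz[i]
    hits <- index_lookup(sub, mz, tolerance)
    if (nrow(hits) == 0) return(NULL)
    hits <- hits[order(abs(hits$mz - mz)), ]
    tibble::tibble(
      fraction = spectrum$fraction, scan_mode = key,
      observed_mz = mz, intensity = spectrum$peaks$intensity[i],
      class = hits$class, composition = hits$composition,
      adduct = hits$adduct,
      theoretical_mz = hits$mz,
      error_mDa = (mz - hits$mz) * 1000,
      error_ppm = (mz - hits$mz) / hits$mz * 1e6,
      rank = seq_len(nrow(hits)),
      flags = if (nrow(hits) > 1) "ambiguous_multi_candidate" else ""
    )
  })
  if (is.null(rows) || nrow(rows) == 0) empty else rows
}

#' Flag candidate pairs at risk of M+2 isotopic overlap
#'
#' A species one double bond more saturated sits 2.01565 Da above its
#' homologue, only ~9 mDa away from the homologue's M+2 isotopologue
#' (2 x 1.003355 Da). Direct infusion cannot separate these, so every
#' candidate pair (A, B) in the same detection mode with
#' `|mz(B) - mz(A) - 2*1.003355| <= window` is reported symmetrically.
#' The flags are warnings for downstream interpretation; nothing is
#' deleted.
#'
#' @param index Candidate index from [build_index()].
#' @param window Width in Da around the M+2 spacing (default 0.02).
#' @return A tibble of pairs: `mode`, `composition_a`, `composition_b`,
#'   `mz_a`, `mz_b`, `delta`, `offset_from_m2`.
#' @export
flag_isotopic_overlap <- function(index, window = 0.02) {
  stopifnot(window > 0)
  m2 <- 2 * C13_C12_DELTA
  purrr::map_dfr(split(index, index$mode), function(sub) {
    if (nrow(sub) < 2) return(NULL)
    sub <- sub[order(sub$mz), ]
    out <- NULL
    for (i in seq_len(nrow(sub) - 1)) {
      j <- i + 1
      while (j <= nrow(sub) && sub$mz[j] - sub$mz[i] <= m2 + window) {
        d <- sub$mz[j] - sub$mz[i]
        if (abs(d - m2) <= window) {
          out <- dplyr::bind_rows(out, tibble::tibble(
            mode = sub$mode[i],
            composition_a = sub$composition[i], composition_b = sub$composition[j],
            adduct_a = sub$adduct[i], adduct_b = sub$adduct[j],
            mz_a = sub$mz[i], mz_b = sub$mz[j],
            delta = d, offset_from_m2 = d - m2
          ))
        }
        j <- j + 1
      }
    }
    out
  })
}

#' Resolve a per-fraction lipid profile from annotations
#'
#' Deduplicates annotations to distinct species keyed on
#' (class, composition): a species seen in several scans or adducts is one
#' species, and an ambiguous peak counts once toward its best-ranked
#' candidate (the ambiguity flag is retained). Evaluates the profile's
#' constraint checks: PE absent; C18 chains confined to PC; prevalence of
#' C16 at sn-2 among positionally resolved species.
#'
#' @param annotations Annotation tibble ([match_peaks()] output, possibly
#'   several scans bound together; a `positional` column, if present, is
#'   carried through).
#' @return An object of class `"lipid_profile"`: list with `species`
#'   (tibble), `counts` (tibble class/n), `n_total`, `checks` (tibble).
#' @export
resolve_profile <- function(annotations) {
  ann <- tibble::as_tibble(annotations)
  if (nrow(ann) > 0) {
    best <- ann[ann$rank == 1L, ]
    best <- best[order(best$class, best$composition,
                       abs(best$error_mDa)), ]
    species <- best[!duplicated(paste(best$class, best$composition)), ]
    keep <- intersect(c("fraction", "class", "composition", "chain_key",
                        "positional", "scan_mode", "adduct", "observed_mz",
                        "theoretical_mz", "error_mDa", "flags"),
                      names(species))
    species <- species[, keep]
  } else {
    species <- tibble::tibble(fraction = character(0), class = character(0),
                              composition = character(0),
                              scan_mode = character(0), adduct = character(0),
                              observed_mz = numeric(0),
                              theoretical_mz = numeric(0),
                              error_mDa = numeric(0), flags = character(0))
  }
  profile_from_species(species)
}

# chains of a species row, if resolvable: from chain_key ("20:5_16:1") or a
# resolved positional assignment ("20:5/16:1", "a_b/sn2"); NULL if unknown.
species_chains <- function(row) {
  ck <- if ("chain_key" %in% names(row)) row$chain_key else NA_character_
  if (!is.na(ck) && nzchar(ck)) {
    return(strsplit(ck, "_", fixed = TRUE)[[1]])
  }
  pos <- if ("positional" %in% names(row)) row$positional else NA_character_
  if (!is.na(pos) && grepl("/", pos, fixed = TRUE)) {
    return(unlist(strsplit(strsplit(pos, "/", fixed = TRUE)[[1]], "_",
                           fixed = TRUE)))
  }
  NULL
}

#' Build a profile report from a species table
#'
#' Lower-level constructor behind [resolve_profile()], useful when the
#' species table has been augmented (e.g. with a `positional` column from
#' [positional_calls()]) and the counts and constraint checks need
#' re-deriving.
#'
#' @param species Tibble of distinct species with at least `class`,
#'   `composition`, `chain_key` columns.
#' @return A `lipid_profile`.
#' @export
profile_from_species <- function(species) {
  species <- tibble::as_tibble(species)
  counts <- dplyr::count(species, .data$class, name = "n")
  c18_rows <- if (nrow(species) > 0) {
    vapply(seq_len(nrow(species)), function(i) {
      ch <- species_chains(species[i, ])
      !is.null(ch) && any(grepl("^18:", ch))
    }, logical(1))
  } else logical(0)
  pe_absent <- !"PE" %in% species$class
  c18_only_pc <- all(species$class[c18_rows] == "PC")
  sn2 <- if ("positional" %in% names(species)) {
    pos <- species$positional[!is.na(species$positional) &
                                grepl("/", species$positional, fixed = TRUE)]
    vapply(pos, function(p) {
      parts <- strsplit(p, "/", fixed = TRUE)[[1]]
      grepl("^16:", parts[2])
    }, logical(1))
  } else logical(0)
  checks <- tibble::tibble(
    check = c("pe_absent", "c18_only_on_pc", "sn2_c16_fraction"),
    value = c(pe_absent, c18_only_pc,
              if (length(sn2) > 0) mean(sn2) else NA_real_),
    detail = c(
      sprintf("%d PE species", sum(species$class == "PE")),
      sprintf("C18-bearing species outside PC: %s",
              paste(species$composition[c18_rows & species$class != "PC"],
                    collapse = ", ")),
      sprintf("%d of %d resolved species have C16 at sn-2",
              sum(sn2), length(sn2))
    )
  )
  structure(list(species = species, counts = counts,
                 n_total = nrow(species), checks = checks),
            class = "lipid_profile")
}

#' @export
print.lipid_profile <- function(x, ...) {
  cat("<lipid_profile>", x$n_total, "species\n")
  if (nrow(x$counts) > 0) {
    cat(paste(sprintf("  %s: %d", x$counts$class, x$counts$n),
              collapse = "\n"), "\n")
  }
  shown <- vapply(seq_len(nrow(x$checks)), function(i) {
    v <- x$checks$value[i]
    if (is.na(v)) "NA"
    else if (x$checks$check[i] == "sn2_c16_fraction") sprintf("%.2f", v)
    else if (as.logical(v)) "yes" else "NO"
  }, character(1))
  cat("  checks:",
      paste(sprintf("%s=%s", x$checks$check, shown), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a lipid profile
#'
#' `tidy()` returns the per-species table; `glance()` a one-row summary
#' with the total species count, per-class counts and constraint checks.
#'
#' @param x A `lipid_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lipid_profile
#' @export
tidy.lipid_profile <- function(x, ...) x$species

#' @rdname tidy.lipid_profile
#' @method glance lipid_profile
#' @export
glance.lipid_profile <- function(x, ...) {
  wide <- stats::setNames(as.list(x$counts$n), paste0("n_", x$counts$class))
  tibble::as_tibble(c(list(n_species = x$n_total), wide,
                      list(pe_absent = as.logical(x$checks$value[1]),
                           c18_only_on_pc = as.logical(x$checks$value[2]),
                           sn2_c16_fraction = as.numeric(x$checks$value[3]))))
}

#' Plot per-class species counts of a profile
#'
#' @param object A `lipid_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lipid_profile
#' @export
autoplot.lipid_profile <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = stats::reorder(.data$class, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "lipid class", y = "species",
                  title = sprintf("%d species", object$n_total)) +
    ggplot2::theme_minimal()
}

#' Write a profile report as JSON
#'
#' @param profile A `lipid_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  payload <- list(
    n_total = profile$n_total,
    counts = stats::setNames(as.list(profile$counts$n), profile$counts$class),
    checks = stats::setNames(
      lapply(seq_len(nrow(profile$checks)), function(i) {
        v <- profile$checks$value[i]
        if (profile$checks$check[i] == "sn2_c16_fraction") v else as.logical(v)
      }),
      profile$checks$check
    ),
    species = profile$species
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
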