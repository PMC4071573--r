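#' Assign sn positions from a product-ion scan
#'
#' Locates the `[RCOO]-` carboxylate fragment of every chain in the
#' composition and applies the positional convention shared with the
#' synthetic generator: the sn-2 acyl gives the most intense carboxylate.
#' Observed per-chain intensities are normalized by chain multiplicity
#' (a chain occupying two positions contributes two fragments at one m/z).
#' If the normalized max/min ratio reaches `tau` the most intense chain is
#' called sn-2; otherwise the call is `"ambiguous"`. A composition of
#' identical chains is resolved without ratios. For triacyl species only
#' the sn-2 chain is identified; sn-1 vs sn-3 stays unresolved (reported
#' as `"a_b/sn2"`).
#'
#' @param product_spectrum A `difi_spectrum` in `PRODUCT` mode.
#' @param chains Character vector of the composition's chains (any order).
#' @param tau Intensity-ratio threshold (default 1.5).
#' @param tolerance Fragment matching tolerance in Da.
#' @return A one-row tibble: `chain_key`, `n_acyl`, `assignment`,
#'   `sn1`, `sn2`, `sn3`, `ratio`, `confidence`, `note`.
#' @examples
#' sp <- generate_product_scan("PC", c("20:5", "16:1"), r = 2)
#' assign_positions(sp, c("16:1", "20:5"))
#' @export
assign_positions <- function(product_spectrum, chains, tau = 1.5,
                             tolerance = 0.01) {
  stopifnot(inherits(product_spectrum, "difi_spectrum"))
  if (product_spectrum$mode$kind != "PRODUCT") {
    stop("assign_positions() needs a PRODUCT scan", call. = FALSE)
  }
  chains <- canonical_chains(chains)
  key <- chain_key(chains)
  n <- length(chains)
  call_row <- function(assignment, sn1, sn2, sn3, ratio, confidence, note) {
    tibble::tibble(chain_key = key, n_acyl = n, assignment = assignment,
                   sn1 = sn1, sn2 = sn2, sn3 = sn3, ratio = ratio,
                   confidence = confidence, note = note)
  }
  uniq <- unique(chains)
  if (length(uniq) == 1) {
    sn3 <- if (n == 3) uniq else NA_character_
    return(call_row(paste(chains, collapse = "/"), uniq, uniq, sn3,
                    NA_real_, "assigned", "symmetric composition"))
  }
  peaks <- product_spectrum$peaks
  obs <- vapply(uniq, function(ch) {
    mz <- diagnostic_mz("acyl_carboxylate", ch)
    hit <- peaks$intensity[abs(peaks$mz - mz) <= tolerance]
    if (length(hit) == 0) NA_real_ else max(hit)
  }, numeric(1))
  if (anyNA(obs)) {
    return(call_row("ambiguous", NA_character_, NA_character_, NA_character_,
                    NA_real_,
                    "ambiguous",
                    paste("missing carboxylate fragment for:",
                          paste(uniq[is.na(obs)], collapse = ", "))))
  }
  mult <- vapply(uniq, function(ch) sum(chains == ch), numeric(1))
  norm <- obs / mult
  ratio <- max(norm) / min(norm)
  top <- uniq[norm == max(norm)]
  if (ratio < tau || length(top) > 1) {
    return(call_row("ambiguous", NA_character_, NA_character_, NA_character_,
                    ratio, "ambiguous", "intensity ratio below threshold"))
  }
  sn2 <- top
  rest <- chains[-match(sn2, chains)]
  if (n == 2) {
    call_row(paste0(rest, "/", sn2), rest, sn2, NA_character_, ratio,
             "assigned", "")
  } else {
    rest <- canonical_chains(rest)
    call_row(paste0(paste(rest, collapse = "_"), "/", sn2),
             NA_character_, sn2, NA_character_, ratio, "assigned",
             "sn-1 vs sn-3 unresolved")
  }
}

#' Positional calls for a set of annotated compositions
#'
#' Survey scans resolve only the composition (`"PC 36:6"`); the
#' product-ion scan resolves both the fatty acid composition and the
#' positions. For each annotated composition this pairs the product scan
#' whose precursor m/z matches the composition's ion within `tolerance`,
#' identifies the chain multiset as the unique pool isomer whose
#' carboxylate fragments are all present in the scan, and then calls
#' [assign_positions()]. No consistent isomer, or more than one, gives an
#' ambiguous call.
#'
#' @param product_spectra List of `difi_spectrum` objects in PRODUCT mode.
#' @param species Tibble with columns `class` and `composition` (e.g.
#'   the `species` table of a [resolve_profile()] result).
#' @param pool Acyl-chain pool used to enumerate candidate isomers.
#' @param tau,tolerance Passed to [assign_positions()].
#' @return `species` with added columns `chain_key`, `positional`,
#'   `pos_ratio`, `confidence` (NA where no product scan matched).
#' @export
positional_calls <- function(product_spectra, species,
                             pool = default_acyl_pool(), tau = 1.5,
                             tolerance = 0.01) {
  species <- tibble::as_tibble(species)
  if (!"chain_key" %in% names(species)) species$chain_key <- NA_character_
  species$positional <- NA_character_
  species$pos_ratio <- NA_real_
  species$confidence <- NA_character_
  if (length(product_spectra) == 0 || nrow(species) == 0) return(species)
  isomers_by_class <- lapply(
    stats::setNames(nm = unique(species$class)),
    function(cl) enumerate_compositions(pool, cl)
  )
  prec <- vapply(product_spectra, function(sp) sp$mode$parameter, numeric(1))
  pol <- vapply(product_spectra, function(sp) sp$mode$polarity, character(1))
  for (i in seq_len(nrow(species))) {
    iso <- isomers_by_class[[species$class[i]]]
    iso <- iso[iso$composition == species$composition[i], ]
    if (nrow(iso) == 0) next
    theo <- vapply(c("-" = "[M-H]-", "+" = "[M+H]+"), function(a) {
      ion_mz(assemble_species_formula(species$class[i], iso$chains[[1]]), a)
    }, numeric(1))
    j <- which(abs(prec - theo[pol]) <= tolerance)
    if (length(j) == 0) next
    sp <- product_spectra[[j[1]]]
    consistent <- vapply(iso$chains, function(chains) {
      all(vapply(unique(chains), function(ch) {
        mz <- diagnostic_mz("acyl_carboxylate", ch)
        any(abs(sp$peaks$mz - mz) <= tolerance)
      }, logical(1)))
    }, logical(1))
    if (sum(consistent) != 1) {
      species$positional[i] <- "ambiguous"
      species$confidence[i] <- "ambiguous"
      next
    }
    chains <- iso$chains[[which(consistent)]]
    call <- assign_positions(sp, chains, tau = tau, tolerance = tolerance)
    species$chain_key[i] <- call$chain_key
    species$positional[i] <- call$assignment
    species$pos_ratio[i] <- call$ratio
    species$confidence[i] <- call$confidence
  }
  species
}
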