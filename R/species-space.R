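#' Default acyl-chain pool
#'
#' The fatty acyl chains observed in diatom polar lipids: myristate,
#' C16 series, C18 desaturation series, the C20 elongation products and
#' EPA, plus DHA (22:6, reported in related diatoms; kept in the pool
#' but absent from the packaged fixtures).
#'
#' @return Character vector of chain strings.
#' @export
default_acyl_pool <- function() {
  c("14:0", "16:0", "16:1", "16:2", "16:3",
    "18:1", "18:2", "18:3", "18:4",
    "20:4", "20:5", "22:6")
}

# Canonical order inside an unresolved composition: descending carbons,
# then descending double bonds. "_" separates unresolved chains; "/" is
# reserved for resolved sn-1/sn-2(/sn-3).
canonical_chains <- function(chains) {
  p <- parse_acyl(chains)
  chains[order(-p$carbons, -p$double_bonds)]
}

#' Composition and species labels
#'
#' `composition_label("PC", c("20:5","16:1"))` gives `"PC 36:6"`;
#' `chain_key()` gives the canonical unresolved chain string
#' (`"20:5_16:1"`); `species_label()` gives the positionally resolved
#' form (`"PC 20:5/16:1"`).
#'
#' @param class_id Lipid class.
#' @param chains Character vector of chains.
#' @return A string.
#' @export
composition_label <- function(class_id, chains) {
  p <- parse_acyl(chains)
  paste0(class_id, " ", sum(p$carbons), ":", sum(p$double_bonds))
}

#' @rdname composition_label
#' @export
chain_key <- function(chains) paste(canonical_chains(chains), collapse = "_")

#' @rdname composition_label
#' @export
species_label <- function(class_id, chains) {
  paste0(class_id, " ", paste(chains, collapse = "/"))
}

#' Enumerate composition-level candidate species
#'
#' All unordered multisets of chains from the pool, sized by the class's
#' acyl count: n(n+1)/2 compositions for a diacyl class, choose(n+2, 3)
#' for a triacyl class. Order is deterministic: total carbons, then total
#' double bonds, then the canonical chain key.
#'
#' @param pool Character vector of acyl chains (non-empty, no duplicates).
#' @param class_id Lipid class.
#' @return A tibble with columns `class`, `composition`, `chains` (list
#'   column, canonical order), `chain_key`, `total_carbons`, `total_db`.
#' @examples
#' nrow(enumerate_compositions(default_acyl_pool(), "PC")) # 78
#' @export
enumerate_compositions <- function(pool, class_id) {
  if (length(pool) == 0) stop("acyl pool is empty", call. = FALSE)
  if (anyDuplicated(pool)) stop("acyl pool has duplicate chains", call. = FALSE)
  parse_acyl(pool) # validates
  n_acyl <- .class_row(class_id)$n_acyl
  idx <- utils::combn(length(pool) + n_acyl - 1, n_acyl)
  # multisets via stars-and-bars on sorted index combinations
  combos <- apply(idx, 2, function(j) pool[j - seq_len(n_acyl) + 1L],
                  simplify = FALSE)
  tib <- tibble::tibble(
    class = class_id,
    chains = lapply(combos, canonical_chains)
  )
  tib$chain_key <- vapply(tib$chains, function(ch) chain_key(ch), character(1))
  totals <- lapply(tib$chains, parse_acyl)
  tib$total_carbons <- vapply(totals, function(p) sum(p$carbons), integer(1))
  tib$total_db <- vapply(totals, function(p) sum(p$double_bonds), integer(1))
  tib$composition <- paste0(class_id, " ", tib$total_carbons, ":", tib$total_db)
  tib <- tib[order(tib$total_carbons, tib$total_db, tib$chain_key), ]
  tibble::as_tibble(tib[, c("class", "composition", "chains", "chain_key",
                            "total_carbons", "total_db")])
}

#' Default adducts generated/matched per scan mode
#'
#' Positive precursor-ion 184 scans are matched as `[M+H]+`; positive
#' neutral-loss 162 scans as `[M+H]+` and `[M+Na]+` (the adduct carrying
#' the galactolipid signal under acidified solvent is not fixed, so both
#' are indexed); negative Q1 as `[M-H]-`.
#'
#' @return Named list: mode key -> character vector of adduct names.
#' @export
default_mode_adducts <- function() {
  list("PIS184+" = "[M+H]+",
       "NL162+"  = c("[M+H]+", "[M+Na]+"),
       "Q1-"     = "[M-H]-")
}

#' Build an m/z-sorted candidate index
#'
#' One entry per (composition, detection mode, adduct) allowed by the
#' class's detection modes; sorted ascending by m/z; bit-identical under
#' re-build.
#'
#' @param compositions Tibble from [enumerate_compositions()] (rows of
#'   several classes may be bound together). Acyl-chain isomers share a
#'   composition (and an exact mass), so the index is collapsed to one
#'   entry per (class, composition, mode, adduct): survey scans resolve
#'   composition only; chains and positions come from product-ion scans.
#' @param mode_adducts Named list mapping mode keys to adduct names;
#'   defaults to [default_mode_adducts()].
#' @return A tibble with columns `class`, `composition`, `sn_resolved`,
#'   `mode`, `adduct`, `mz`, sorted by `mz`.
#' @export
build_index <- function(compositions, mode_adducts = default_mode_adducts()) {
  if (nrow(compositions) == 0) stop("no compositions to index", call. = FALSE)
  if (length(mode_adducts) == 0 || any(lengths(mode_adducts) == 0)) {
    stop("mode_adducts must give at least one adduct per mode", call. = FALSE)
  }
  compositions <- compositions[!duplicated(paste(compositions$class,
                                                 compositions$composition)), ]
  cls <- lipid_classes()
  rows <- purrr::pmap(compositions[, c("class", "composition", "chains")],
    function(class, composition, chains) {
      modes <- intersect(cls$detection_modes[[match(class, cls$class_id)]],
                         names(mode_adducts))
      if (length(modes) == 0) return(NULL)
      f <- assemble_species_formula(class, chains)
      purrr::map_dfr(modes, function(mode) {
        adducts <- mode_adducts[[mode]]
        tibble::tibble(
          class = class, composition = composition,
          sn_resolved = FALSE, mode = mode, adduct = adducts,
          mz = vapply(adducts, function(a) ion_mz(f, a), numeric(1),
                      USE.NAMES = FALSE)
        )
      })
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no indexed entries: no class is detectable in the given modes",
                           call. = FALSE)
  out <- out[order(out$mz, out$class, out$composition, out$adduct), ]
  tibble::as_tibble(out)
}

#' Query a candidate index by m/z
#'
#' Binary-search lookup of all entries within `tol` Da of `mz`;
#' equivalent to a linear scan over the index.
#'
#' @param index Tibble from [build_index()].
#' @param mz Query m/z (scalar).
#' @param tol Tolerance in Da.
#' @return The matching rows of `index`.
#' @export
index_lookup <- function(index, mz, tol) {
  stopifnot(tol > 0)
  lo <- findInterval(mz - tol, index$mz) + 1L
  hi <- findInterval(mz + tol, index$mz)
  if (hi < lo) return(index[0, ])
  hit <- index[lo:hi, ]
  hit[abs(hit$mz - mz) <= tol, ]
}

#' Export a candidate index as TSV
#'
#' Columns: class, composition, sn_resolved, adduct, mz (4 decimals).
#'
#' @param index Tibble from [build_index()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index_tsv <- function(index, path) {
  out <- data.frame(
    class = index$class, composition = index$composition,
    sn_resolved = index$sn_resolved, adduct = index$adduct,
    mz = sprintf("%.4f", index$mz)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
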