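# Monoisotopic atomic masses (CODATA/IUPAC standard values; C-12 scale).
# Kept as a named constant so every mass in the package traces to one table;
# the same table ships as inst/extdata/atomic_masses.tsv.
ATOMIC_MASSES <- c(
  C  = 12,
  H  = 1.0078250319,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  S  = 31.9720707,
  Na = 22.9897693
)

ELECTRON_MASS <- 0.00054858
PROTON_MASS <- ATOMIC_MASSES[["H"]] - ELECTRON_MASS
C13_C12_DELTA <- 1.003355

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of element counts over
#' C, H, N, O, P, S, Na. All counts must be non-negative; zero-count
#' elements are dropped so that equal formulas compare identical.
#'
#' @param ... Named integer counts, e.g. `elemental_formula(C = 6, H = 12, O = 6)`.
#' @return A named integer vector of class `"elemental_formula"`.
#' @examples
#' elemental_formula(C = 6, H = 12, O = 6)
#' @export
elemental_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    return(structure(integer(0), class = "elemental_formula"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all element counts must be named", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(ATOMIC_MASSES))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("element counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("element counts must be integers", call. = FALSE)
  counts <- counts[counts > 0]
  # canonical Hill-ish order: C, H, then the rest alphabetically
  ord <- c("C", "H", sort(setdiff(names(ATOMIC_MASSES), c("C", "H"))))
  counts <- counts[intersect(ord, names(counts))]
  structure(as.integer(round(counts)), names = names(counts),
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Format an elemental formula as a string
#'
#' @param formula An `elemental_formula`.
#' @return A string such as `"C40H80NO8P"`.
#' @export
format_formula <- function(formula) {
  if (length(formula) == 0) return("")
  paste0(names(formula), ifelse(formula == 1, "", formula), collapse = "")
}

#' Add or subtract elemental formulas
#'
#' Element-wise arithmetic on element counts. Subtraction that would take
#' any count below zero is an error (a fragment cannot remove atoms the
#' molecule does not have).
#'
#' @param a,b `elemental_formula` objects.
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(rep(0L, length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  do.call(elemental_formula, as.list(out))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(rep(0L, length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    stop("formula subtraction would give a negative count for: ",
         paste(els[out < 0], collapse = ", "), call. = FALSE)
  }
  do.call(elemental_formula, as.list(out))
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count times the standard monoisotopic mass of each element
#' (most abundant isotope, C-12 scale). Additive by construction:
#' `monoisotopic_mass(formula_add(a, b)) == monoisotopic_mass(a) + monoisotopic_mass(b)`.
#'
#' @param formula An `elemental_formula` (or named count vector).
#' @return Mass in Da (numeric scalar); `0` for the empty formula.
#' @examples
#' monoisotopic_mass(elemental_formula(H = 2, O = 1)) # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  if (length(formula) == 0) return(0)
  unknown <- setdiff(names(formula), names(ATOMIC_MASSES))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(ATOMIC_MASSES[names(formula)] * as.numeric(formula))
}

# ---- acyl chains -------------------------------------------------------------

#' Parse and validate acyl chain shorthand
#'
#' Acyl chains use the lipidomics shorthand `"carbons:double_bonds"`,
#' e.g. `"16:0"` (palmitate) or `"20:5"` (EPA). Double-bond positions and
#' the omega series are not modeled: `"20:5"` stands for EPA by convention.
#' A chain is valid when carbons >= 2 and 0 <= double_bonds <= floor(carbons/2).
#'
#' @param chain Character vector of chain strings.
#' @return A tibble with columns `chain`, `carbons`, `double_bonds`.
#' @examples
#' parse_acyl(c("16:0", "20:5"))
#' @export
parse_acyl <- function(chain) {
  stopifnot(is.character(chain))
  m <- regmatches(chain, regexec("^([0-9]+):([0-9]+)$", chain))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed acyl chain: ", paste(chain[bad], collapse = ", "),
         call. = FALSE)
  }
  carbons <- vapply(m, function(x) as.integer(x[2]), integer(1))
  db <- vapply(m, function(x) as.integer(x[3]), integer(1))
  invalid <- carbons < 2 | db < 0 | db > carbons %/% 2
  if (any(invalid)) {
    stop("invalid acyl chain (need carbons >= 2, 0 <= double bonds <= carbons/2): ",
         paste(chain[invalid], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(chain = chain, carbons = carbons, double_bonds = db)
}

#' Elemental formula of a free fatty acid
#'
#' For a chain with `c` carbons and `d` double bonds the free-acid
#' stoichiometry is C\eqn{_c}H\eqn{_{2c-2d}}O\eqn{_2}.
#'
#' @param chain A single chain string such as `"16:0"`.
#' @return An `elemental_formula`.
#' @examples
#' acyl_formula("20:5") # C20H30O2
#' @export
acyl_formula <- function(chain) {
  p <- parse_acyl(chain)
  if (nrow(p) != 1) stop("acyl_formula() takes a single chain", call. = FALSE)
  elemental_formula(C = p$carbons, H = 2 * p$carbons - 2 * p$double_bonds, O = 2)
}

# ---- lipid classes -----------------------------------------------------------

# Head-group building blocks as free molecules; assembling a species
# condenses each head substituent and each acyl chain with loss of one H2O.
.head_formulas <- function() {
  list(
    PC       = elemental_formula(C = 5, H = 14, N = 1, O = 4, P = 1),  # phosphocholine
    PE       = elemental_formula(C = 2, H = 8, N = 1, O = 4, P = 1),   # phosphoethanolamine
    PG       = elemental_formula(C = 3, H = 9, O = 6, P = 1),          # glycerophosphate
    PI       = elemental_formula(C = 6, H = 13, O = 9, P = 1),         # inositolphosphate
    LPC      = elemental_formula(C = 5, H = 14, N = 1, O = 4, P = 1),
    MGDG     = elemental_formula(C = 6, H = 12, O = 6),                # galactose
    DGDG     = elemental_formula(C = 12, H = 22, O = 11),              # digalactose
    SQDG     = elemental_formula(C = 6, H = 12, O = 8, S = 1),         # sulfoquinovose
    DAG      = elemental_formula(),
    TAG      = elemental_formula(),
    FFA      = elemental_formula(),
    ACYL_COA = elemental_formula(C = 21, H = 36, N = 7, O = 16, P = 3, S = 1) # coenzyme A
  )
}

#' Glycerolipid class table
#'
#' One row per supported lipid class: expected acyl count, head-group
#' formula (free molecule), number of head condensation bonds, backbone,
#' and the scan modes in which the class is detected. Detection follows
#' triple-quadrupole practice for polar glycerolipids: PC by precursor-ion
#' scan of m/z 184 (phosphocholine) in positive mode; MGDG/DGDG by
#' neutral-loss scan of 162 (hexose) in positive mode; SQDG, PG, PI (and
#' PE, were it present) by Q1 survey in negative mode.
#'
#' @return A tibble with columns `class_id`, `n_acyl`, `head_formula`
#'   (list column), `head_bonds`, `backbone`, `detection_modes` (list
#'   column of mode keys).
#' @export
lipid_classes <- function() {
  heads <- .head_formulas()
  tibble::tibble(
    class_id = c("PC", "PE", "PG", "PI", "LPC", "MGDG", "DGDG", "SQDG",
                 "DAG", "TAG", "FFA", "ACYL_COA"),
    n_acyl = c(2L, 2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 3L, 1L, 1L),
    head_formula = heads[c("PC", "PE", "PG", "PI", "LPC", "MGDG", "DGDG",
                           "SQDG", "DAG", "TAG", "FFA", "ACYL_COA")],
    head_bonds = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    backbone = c(rep("glycerol", 10), "none", "coa"),
    detection_modes = list(
      "PIS184+", "Q1-", "Q1-", "Q1-", character(0), "NL162+", "NL162+",
      "Q1-", character(0), character(0), character(0), character(0)
    )
  )
}

.class_row <- function(class_id) {
  cls <- lipid_classes()
  i <- match(class_id, cls$class_id)
  if (is.na(i)) stop("unknown lipid class: ", class_id, call. = FALSE)
  cls[i, ]
}

#' Assemble the elemental formula of a lipid species
#'
#' Condenses a glycerol backbone, the class head group and the acyl chains
#' with loss of one water per ester/glycosidic/phosphodiester bond:
#' glycerol + head + sum(acyls) - (n_acyl + head_bonds) H2O. FFA species
#' are the free acid; acyl-CoA is a thioester of coenzyme A.
#'
#' @param class_id Lipid class, e.g. `"PC"`.
#' @param chains Character vector of acyl chains; its length must equal
#'   the class's expected acyl count.
#' @return An `elemental_formula`.
#' @examples
#' assemble_species_formula("PC", c("16:0", "16:0")) # C40H80NO8P
#' @export
assemble_species_formula <- function(class_id, chains) {
  row <- .class_row(class_id)
  if (length(chains) != row$n_acyl) {
    stop(class_id, " expects ", row$n_acyl, " acyl chain(s), got ",
         length(chains), call. = FALSE)
  }
  water <- elemental_formula(H = 2, O = 1)
  acyls <- Reduce(formula_add, lapply(chains, acyl_formula),
                  elemental_formula())
  head <- row$head_formula[[1]]
  if (row$backbone == "glycerol") {
    glycerol <- elemental_formula(C = 3, H = 8, O = 3)
    n_bonds <- row$n_acyl + row$head_bonds
    f <- formula_add(formula_add(glycerol, head), acyls)
    for (i in seq_len(n_bonds)) f <- formula_subtract(f, water)
    f
  } else if (row$backbone == "none") {
    acyls
  } else { # coa thioester
    formula_subtract(formula_add(head, acyls), water)
  }
}

# ---- adducts and ion m/z -----------------------------------------------------

#' Supported ESI adducts
#'
#' Singly charged adducts only; direct-infusion glycerolipids are
#' predominantly singly charged.
#'
#' @return A tibble with columns `name`, `polarity`, `delta` (list column
#'   of signed element counts), `charge`.
#' @export
adduct_table <- function() {
  tibble::tibble(
    name = c("[M+H]+", "[M+Na]+", "[M-H]-", "[M+HCOO]-"),
    polarity = c("+", "+", "-", "-"),
    delta = list(c(H = 1), c(Na = 1), c(H = -1), c(C = 1, H = 1, O = 2)),
    charge = c(1L, 1L, -1L, -1L)
  )
}

.adduct_row <- function(adduct) {
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (is.na(i)) stop("unknown adduct: ", adduct, call. = FALSE)
  tab[i, ]
}

#' m/z of an adduct ion
#'
#' `m/z = (mass(M) + mass(delta) - charge * electron mass) / |charge|`
#' with |charge| = 1. The electron mass is included so that reference
#' fragments (e.g. protonated phosphocholine at 184.0733) agree with
#' instrument-calibrated values at four decimals.
#'
#' @param formula `elemental_formula` of the neutral species M.
#' @param adduct Adduct name from [adduct_table()].
#' @return m/z (numeric scalar).
#' @examples
#' ion_mz(assemble_species_formula("PC", c("16:0", "16:0")), "[M+H]+")
#' @export
ion_mz <- function(formula, adduct) {
  row <- .adduct_row(adduct)
  delta <- row$delta[[1]]
  pos <- delta[delta > 0]
  neg <- -delta[delta < 0]
  f <- formula
  if (length(pos) > 0) f <- formula_add(f, do.call(elemental_formula, as.list(pos)))
  if (length(neg) > 0) f <- formula_subtract(f, do.call(elemental_formula, as.list(neg)))
  (monoisotopic_mass(f) - row$charge * ELECTRON_MASS) / abs(row$charge)
}

#' Diagnostic fragment and neutral-loss masses
#'
#' The three mass anchors of the scan-mode logic:
#' * `"phosphocholine_fragment"` - the C5H15NO4P+ cation monitored by the
#'   positive precursor-ion scan (m/z 184.0733, printed as 184.07);
#' * `"hexose_neutral_loss"` - the neutral C6H10O5 lost by galactolipids
#'   in the positive neutral-loss scan (162.0528, nominal 162);
#' * `"acyl_carboxylate"` - the `[RCOO]-` anion of a given chain seen in
#'   negative product-ion scans.
#'
#' @param name One of `"phosphocholine_fragment"`, `"hexose_neutral_loss"`,
#'   `"acyl_carboxylate"`.
#' @param chain Acyl chain string, required for `"acyl_carboxylate"`.
#' @return m/z of the ion, or neutral mass for the hexose loss.
#' @examples
#' diagnostic_mz("phosphocholine_fragment") # 184.0733
#' diagnostic_mz("acyl_carboxylate", "20:5") # 301.2173
#' @export
diagnostic_mz <- function(name, chain = NULL) {
  switch(name,
    phosphocholine_fragment = {
      f <- elemental_formula(C = 5, H = 15, N = 1, O = 4, P = 1)
      monoisotopic_mass(f) - ELECTRON_MASS
    },
    hexose_neutral_loss = monoisotopic_mass(elemental_formula(C = 6, H = 10, O = 5)),
    acyl_carboxylate = {
      if (is.null(chain)) stop("acyl_carboxylate needs a chain", call. = FALSE)
      ion_mz(acyl_formula(chain), "[M-H]-")
    },
    stop("unknown diagnostic: ", name, call. = FALSE)
  )
}
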