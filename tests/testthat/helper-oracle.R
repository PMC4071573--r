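# Reference masses computed independently (element-wise summation of
# standard monoisotopic atomic masses, cross-checked against a public
# proteomics mass calculator) and frozen here.
ORACLE <- list(
  h2o            = 18.010565,
  hexose_loss    = 162.052823,   # C6H10O5
  pchol_cation   = 184.073321,   # C5H15NO4P+
  pc32_0_mass    = 733.562155,   # PC(16:0/16:0) neutral
  pc32_0_mh_pos  = 734.569432,
  pc32_0_mh_neg  = 732.554879,
  carbox_20_5    = 301.217304,   # [20:5 - H]-
  carbox_16_0    = 255.232954,
  carbox_16_1    = 253.217304,
  sqdg32_0_neg   = 793.514122,   # SQDG(16:0/16:0) [M-H]-
  mgdg32_0_na    = 753.548719,   # MGDG(16:0/16:0) [M+Na]+
  ch2            = 14.015650,
  double_bond    = 2.015650,
  proton         = 1.007276
)

# brute-force linear scan over the candidate index; the oracle that
# index_lookup()/match_peaks() must agree with
linear_scan <- function(index, mz, tol) {
  index[abs(index$mz - mz) <= tol, , drop = FALSE]
}

# random valid elemental formulas for property tests
random_formula <- function() {
  n <- sample(1:5, 1)
  els <- sample(c("C", "H", "N", "O", "P", "S", "Na"), n)
  do.call(elemental_formula,
          stats::setNames(as.list(sample(0:40, n, replace = TRUE)), els))
}

# ---- independent route enumeration ------------------------------------------
# Exhaustive DFS over all applicable (operator, binding) sequences up to
# max_depth, written without the package's BFS machinery (it only reuses
# apply_reaction, whose algebra is tested separately). Returns every
# step-signature sequence that reaches the target, for minimality checks.

oracle_split_species <- function(s) {
  cls <- sub(" .*$", "", s)
  chains <- strsplit(sub("^\\S+ ", "", s), "/", fixed = TRUE)[[1]]
  list(class = cls, chains = chains)
}

oracle_applicable <- function(pool, ops) {
  cl <- vapply(pool$species, function(s) oracle_split_species(s)$class,
               character(1))
  of <- function(k) pool$species[cl == k]
  out <- list()
  add <- function(op, b) out[[length(out) + 1L]] <<- list(op = op, bindings = b)
  if ("PLA" %in% ops) for (pc in of("PC")) add("PLA", list(pc = pc))
  if ("ACS" %in% ops) for (ffa in of("FFA")) add("ACS", list(ffa = ffa))
  if ("LPCAT_fwd" %in% ops) for (lpc in of("LPC")) for (ch in pool$coa)
    add("LPCAT_fwd", list(lpc = lpc, chain = ch))
  if ("LPCAT_rev" %in% ops) for (pc in of("PC")) add("LPCAT_rev", list(pc = pc))
  if ("PDCT" %in% ops) for (pc in of("PC")) for (dag in of("DAG"))
    add("PDCT", list(pc = pc, dag = dag))
  if ("PDAT" %in% ops) for (pc in of("PC")) for (dag in of("DAG"))
    add("PDAT", list(pc = pc, dag = dag))
  if ("DGAT" %in% ops) for (dag in of("DAG")) for (ch in pool$coa)
    add("DGAT", list(dag = dag, chain = ch))
  if ("ELO" %in% ops) for (ch in pool$coa) add("ELO", list(chain = ch))
  if ("DES_PC" %in% ops) for (pc in of("PC")) for (pos in 1:2)
    add("DES_PC", list(pc = pc, position = pos))
  out
}

oracle_all_routes <- function(pool, target, max_depth, ops = reaction_ops()) {
  found <- list()
  recurse <- function(p, sig) {
    if (target %in% p$species) {
      found[[length(found) + 1L]] <<- sig
      return(invisible())
    }
    if (length(sig) >= max_depth) return(invisible())
    for (st in oracle_applicable(p, ops)) {
      p2 <- tryCatch(apply_reaction(st$op, p, st$bindings),
                     error = function(e) NULL)
      if (is.null(p2)) next
      subs <- paste(unlist(st$bindings[names(st$bindings) != "position"]),
                    collapse = "+")
      recurse(p2, c(sig, paste(st$op, subs)))
    }
  }
  recurse(pool, character(0))
  unique(found)
}

route_signature <- function(route) {
  paste(route$steps$op, route$steps$substrates, sep = " ", collapse = " ; ")
}
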