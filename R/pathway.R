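#' Classify glycerolipid assembly pathway from the sn-2 acyl
#'
#' Diatom glycerolipids assembled in the plastid (prokaryotic pathway)
#' carry a C16 (or shorter) fatty acid at sn-2; those assembled in the ER
#' (eukaryotic pathway) carry a C18 or longer acyl at sn-2. The label is
#' determined solely by the sn-2 chain; species without a resolved sn-2
#' are `"ambiguous"`. Lyso species, free fatty acids and acyl-CoAs are not
#' classifiable.
#'
#' @param species A tibble with a `class` column and either an `sn2`
#'   column of chain strings or a `positional` column of assignment
#'   strings (`"20:5/16:1"`; the chain after the final `/` is sn-2,
#'   `"ambiguous"`/NA gives an ambiguous call).
#' @return `species` with added columns `sn2_carbons` and `assembly`
#'   (`"prokaryotic"`, `"eukaryotic"` or `"ambiguous"`).
#' @examples
#' classify_assembly(tibble::tibble(class = "PC", positional = "20:5/16:1"))
#' @export
classify_assembly <- function(species) {
  species <- tibble::as_tibble(species)
  bad <- species$class %in% c("LPC", "FFA", "ACYL_COA")
  if (any(bad)) {
    stop("not classifiable (no sn-2 diacyl backbone): ",
         paste(unique(species$class[bad]), collapse = ", "), call. = FALSE)
  }
  sn2 <- if ("sn2" %in% names(species)) {
    species$sn2
  } else if ("positional" %in% names(species)) {
    vapply(species$positional, function(p) {
      if (is.na(p) || !grepl("/", p, fixed = TRUE)) return(NA_character_)
      parts <- strsplit(p, "/", fixed = TRUE)[[1]]
      parts[length(parts)]
    }, character(1), USE.NAMES = FALSE)
  } else {
    stop("species needs an 'sn2' or 'positional' column", call. = FALSE)
  }
  carbons <- rep(NA_integer_, length(sn2))
  okc <- !is.na(sn2) & grepl("^[0-9]+:[0-9]+$", sn2)
  if (any(okc)) carbons[okc] <- parse_acyl(sn2[okc])$carbons
  species$sn2_carbons <- carbons
  species$assembly <- dplyr::case_when(
    is.na(carbons) ~ "ambiguous",
    carbons <= 16 ~ "prokaryotic",
    TRUE ~ "eukaryotic"
  )
  species
}

# ---- lipid pools -------------------------------------------------------------

#' Construct a lipid pool
#'
#' A pool is the state of the reaction-network search: a multiset of
#' stoichiometric species (PC/LPC/DAG/TAG/FFA, written as resolved
#' species strings such as `"PC 20:5/16:1"`) plus an acyl-CoA reservoir.
#' The reservoir is treated as non-depleting (catalytic amounts are
#' unknown); PC/DAG/TAG/LPC/FFA are stoichiometric.
#'
#' @param species Character vector of species strings.
#' @param coa Character vector of acyl chains available as acyl-CoA.
#' @return A list of class `"lipid_pool"`.
#' @examples
#' lipid_pool(c("PC 20:5/20:5", "DAG 16:0/16:1"))
#' @export
lipid_pool <- function(species = character(0), coa = character(0)) {
  for (s in species) parse_species(s) # validates
  if (length(coa) > 0) parse_acyl(coa)
  structure(list(species = sort(species), coa = sort(unique(coa))),
            class = "lipid_pool")
}

#' @export
print.lipid_pool <- function(x, ...) {
  cat("<lipid_pool>\n  species:", paste(x$species, collapse = ", "), "\n")
  cat("  acyl-CoA:", if (length(x$coa)) paste(x$coa, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

parse_species <- function(s) {
  m <- regexec("^([A-Z_]+) (.+)$", s)
  parts <- regmatches(s, m)[[1]]
  if (length(parts) != 3) stop("malformed species string: ", s, call. = FALSE)
  class_id <- parts[2]
  chains <- strsplit(parts[3], "/", fixed = TRUE)[[1]]
  parse_acyl(chains)
  row <- .class_row(class_id)
  if (length(chains) != row$n_acyl) {
    stop("species string has wrong chain count for ", class_id, ": ", s,
         call. = FALSE)
  }
  list(class = class_id, chains = chains)
}

pool_key <- function(pool) {
  paste(paste(pool$species, collapse = "|"),
        paste(pool$coa, collapse = "|"), sep = " || ")
}

# multiset of chains over the stoichiometric species of a pool
pool_chain_multiset <- function(pool) {
  sort(unlist(lapply(pool$species, function(s) parse_species(s)$chains),
              use.names = FALSE))
}

# ---- reaction operators ------------------------------------------------------

des_cap <- function(carbons) {
  if (carbons == 18) 4L else if (carbons == 20) 5L else min(carbons %/% 2, 6L)
}

bump_chain <- function(chain, d_carbons = 0L, d_db = 0L) {
  p <- parse_acyl(chain)
  paste0(p$carbons + d_carbons, ":", p$double_bonds + d_db)
}

#' Reaction operator names
#'
#' The acyl-editing / head-group-exchange operator set:
#' * `PLA` - phospholipase A: PC(a/b) -> LPC(a) + FFA(b)
#' * `ACS` - acyl-CoA synthetase: FFA(x) -> acyl-CoA(x)
#' * `LPCAT_fwd` - lyso-PC acyltransferase: LPC(a) + CoA(x) -> PC(a/x)
#' * `LPCAT_rev` - its reverse: PC(a/b) -> LPC(a) + CoA(b)
#' * `PDCT` - head-group exchange: PC(a/b) + DAG(c/d) -> DAG(a/b) + PC(c/d)
#' * `PDAT` - PC(a/b) + DAG(c/d) -> TAG(c/d/b) + LPC(a)
#' * `DGAT` - DAG(c/d) + CoA(x) -> TAG(c/d/x)
#' * `ELO` - elongase on acyl-CoA: CoA(c:d) -> CoA(c+2:d)
#' * `DES_PC` - desaturase on a PC-bound chain: (c:d) -> (c:d+1),
#'   capped at 18:4 for C18 and 20:5 for C20
#'
#' Acyl chains are conserved across every operator except `DES_PC`
#' (+1 double bond) and `ELO` (+2 carbons).
#'
#' @return Character vector of operator names.
#' @export
reaction_ops <- function() {
  c("PLA", "ACS", "LPCAT_fwd", "LPCAT_rev", "PDCT", "PDAT", "DGAT",
    "ELO", "DES_PC")
}

#' Apply one reaction to a pool
#'
#' Returns a new pool (the input is not modified) with the bound
#' substrates consumed and the products added. Acyl-CoA is a
#' non-depleting reservoir: `LPCAT_fwd`, `DGAT` and `ELO` draw from it
#' without removing the chain, and `ACS`/`LPCAT_rev` add to it.
#'
#' @param op Operator name from [reaction_ops()].
#' @param pool A [lipid_pool()].
#' @param bindings Named list binding substrates, e.g.
#'   `list(pc = "PC 20:5/20:5", dag = "DAG 16:0/16:1")` for `PDAT`;
#'   `chain` binds a reservoir chain; `position` (1 or 2) selects the
#'   PC-bound chain for `DES_PC`.
#' @param pdat_position `"sn3"` (default) or `"sn1"`: which outer position
#'   PDAT/DGAT acylate.
#' @param elo_max_carbons Elongation cap on chain length (default 20).
#' @return A new `lipid_pool`.
#' @examples
#' apply_reaction("PDAT", lipid_pool(c("PC 20:5/20:5", "DAG 16:0/16:1")),
#'                list(pc = "PC 20:5/20:5", dag = "DAG 16:0/16:1"))
#' @export
apply_reaction <- function(op, pool, bindings, pdat_position = "sn3",
                           elo_max_carbons = 20L) {
  stopifnot(inherits(pool, "lipid_pool"))
  take <- function(s, class_want) {
    if (is.null(s)) stop(op, ": missing substrate binding", call. = FALSE)
    if (!s %in% pool$species) stop(op, ": substrate not in pool: ", s, call. = FALSE)
    p <- parse_species(s)
    if (!p$class %in% class_want) {
      stop(op, ": substrate class mismatch, need ",
           paste(class_want, collapse = "/"), " got ", p$class, call. = FALSE)
    }
    p
  }
  take_coa <- function(ch) {
    if (is.null(ch)) stop(op, ": missing chain binding", call. = FALSE)
    if (!ch %in% pool$coa) stop(op, ": chain not in acyl-CoA reservoir: ", ch,
                                call. = FALSE)
    ch
  }
  sp <- pool$species
  coa <- pool$coa
  drop1 <- function(v, x) v[-match(x, v)]
  lab <- function(class, chains) species_label(class, chains)
  switch(op,
    PLA = {
      pc <- take(bindings$pc, "PC")
      sp <- c(drop1(sp, bindings$pc), lab("LPC", pc$chains[1]),
              lab("FFA", pc$chains[2]))
    },
    ACS = {
      ffa <- take(bindings$ffa, "FFA")
      sp <- drop1(sp, bindings$ffa)
      coa <- c(coa, ffa$chains[1])
    },
    LPCAT_fwd = {
      lpc <- take(bindings$lpc, "LPC")
      ch <- take_coa(bindings$chain)
      sp <- c(drop1(sp, bindings$lpc), lab("PC", c(lpc$chains[1], ch)))
    },
    LPCAT_rev = {
      pc <- take(bindings$pc, "PC")
      sp <- c(drop1(sp, bindings$pc), lab("LPC", pc$chains[1]))
      coa <- c(coa, pc$chains[2])
    },
    PDCT = {
      pc <- take(bindings$pc, "PC")
      dag <- take(bindings$dag, "DAG")
      sp <- c(drop1(drop1(sp, bindings$pc), bindings$dag),
              lab("DAG", pc$chains), lab("PC", dag$chains))
    },
    PDAT = {
      pc <- take(bindings$pc, "PC")
      dag <- take(bindings$dag, "DAG")
      tag <- if (pdat_position == "sn3") {
        c(dag$chains, pc$chains[2])
      } else {
        c(pc$chains[2], dag$chains)
      }
      sp <- c(drop1(drop1(sp, bindings$pc), bindings$dag),
              lab("TAG", tag), lab("LPC", pc$chains[1]))
    },
    DGAT = {
      dag <- take(bindings$dag, "DAG")
      ch <- take_coa(bindings$chain)
      tag <- if (pdat_position == "sn3") c(dag$chains, ch) else c(ch, dag$chains)
      sp <- c(drop1(sp, bindings$dag), lab("TAG", tag))
    },
    ELO = {
      ch <- take_coa(bindings$chain)
      p <- parse_acyl(ch)
      if (p$carbons + 2 > elo_max_carbons) {
        stop("ELO: elongation beyond ", elo_max_carbons, " carbons", call. = FALSE)
      }
      coa <- c(coa, bump_chain(ch, d_carbons = 2L))
    },
    DES_PC = {
      pc <- take(bindings$pc, "PC")
      pos <- bindings$position
      if (is.null(pos) || !pos %in% c(1, 2)) {
        stop("DES_PC: bindings$position must be 1 or 2", call. = FALSE)
      }
      p <- parse_acyl(pc$chains[pos])
      if (p$double_bonds + 1 > des_cap(p$carbons)) {
        stop("DES_PC: desaturation cap exceeded for ", pc$chains[pos],
             call. = FALSE)
      }
      chains <- pc$chains
      chains[pos] <- bump_chain(chains[pos], d_db = 1L)
      sp <- c(drop1(sp, bindings$pc), lab("PC", chains))
    },
    stop("unknown reaction operator: ", op, call. = FALSE)
  )
  lipid_pool(sp, coa)
}

# All (op, bindings) applicable to a pool, in deterministic order.
enumerate_steps <- function(pool, ops, pdat_position = "sn3",
                            elo_max_carbons = 20L) {
  parsed <- lapply(pool$species, parse_species)
  classes <- vapply(parsed, `[[`, character(1), "class")
  of <- function(cl) pool$species[classes == cl]
  out <- list()
  add <- function(op, bindings) out[[length(out) + 1L]] <<- list(op = op, bindings = bindings)
  for (op in ops) {
    switch(op,
      PLA = for (pc in of("PC")) add("PLA", list(pc = pc)),
      ACS = for (ffa in of("FFA")) add("ACS", list(ffa = ffa)),
      LPCAT_fwd = for (lpc in of("LPC")) for (ch in pool$coa)
        add("LPCAT_fwd", list(lpc = lpc, chain = ch)),
      LPCAT_rev = for (pc in of("PC")) add("LPCAT_rev", list(pc = pc)),
      PDCT = for (pc in of("PC")) for (dag in of("DAG"))
        add("PDCT", list(pc = pc, dag = dag)),
      PDAT = for (pc in of("PC")) for (dag in of("DAG"))
        add("PDAT", list(pc = pc, dag = dag)),
      DGAT = for (dag in of("DAG")) for (ch in pool$coa)
        add("DGAT", list(dag = dag, chain = ch)),
      ELO = for (ch in pool$coa) {
        if (parse_acyl(ch)$carbons + 2 <= elo_max_carbons) add("ELO", list(chain = ch))
      },
      DES_PC = for (pc in of("PC")) for (pos in 1:2) {
        p <- parse_acyl(parse_species(pc)$chains[pos])
        if (p$double_bonds + 1 <= des_cap(p$carbons)) {
          add("DES_PC", list(pc = pc, position = pos))
        }
      }
    )
  }
  out
}

step_label <- function(op, bindings, pool_before, pool_after) {
  subs <- unlist(bindings[names(bindings) %in% c("pc", "dag", "lpc", "ffa", "chain")],
                 use.names = FALSE)
  gained <- c(setdiff(pool_after$species, pool_before$species),
              paste0("CoA ", setdiff(pool_after$coa, pool_before$coa)))
  gained <- gained[gained != "CoA "]
  tibble::tibble(op = op,
                 substrates = paste(subs, collapse = " + "),
                 products = paste(gained, collapse = " + "))
}

new_route <- function(steps, start, target) {
  structure(list(steps = steps, length = nrow(steps),
                 start = start, target = target),
            class = "lipid_route")
}

#' @export
print.lipid_route <- function(x, ...) {
  cat(sprintf("<lipid_route> %d step(s) to %s\n", x$length, x$target))
  if (x$length > 0) {
    cat(paste(sprintf("  %d. %s: %s -> %s", seq_len(x$length), x$steps$op,
                      x$steps$substrates, x$steps$products),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Tidy a route
#'
#' `tidy()` returns the step table (op, substrates, products);
#' `glance()` a one-row summary with route length, operator sequence,
#' and target.
#'
#' @param x A `lipid_route`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lipid_route
#' @export
tidy.lipid_route <- function(x, ...) x$steps

#' @rdname tidy.lipid_route
#' @method glance lipid_route
#' @export
glance.lipid_route <- function(x, ...) {
  tibble::tibble(length = x$length,
                 ops = paste(x$steps$op, collapse = " -> "),
                 target = x$target)
}

# Layered BFS. target_fn: pool -> logical. If all_minimal, keeps alternative
# equal-length paths (previous-layer state dedup only) and returns every
# minimal route; otherwise dedups states everywhere and returns the first hit.
bfs_routes <- function(start, target_fn, max_depth, ops, state_cap = 20000L,
                       pdat_position = "sn3", elo_max_carbons = 20L,
                       all_minimal = TRUE, target_desc = "") {
  stopifnot(max_depth >= 1)
  empty_steps <- tibble::tibble(op = character(0), substrates = character(0),
                                products = character(0))
  if (target_fn(start)) {
    return(list(new_route(empty_steps, start, target_desc)))
  }
  frontier <- list(list(pool = start, steps = empty_steps))
  visited <- pool_key(start)
  for (depth in seq_len(max_depth)) {
    hits <- list()
    nxt <- list()
    nxt_keys <- character(0)
    for (node in frontier) {
      cand <- enumerate_steps(node$pool, ops, pdat_position, elo_max_carbons)
      for (st in cand) {
        after <- apply_reaction(st$op, node$pool, st$bindings,
                                pdat_position, elo_max_carbons)
        key <- pool_key(after)
        if (key %in% visited) next
        steps <- dplyr::bind_rows(node$steps,
                                  step_label(st$op, st$bindings, node$pool, after))
        if (target_fn(after)) {
          hits[[length(hits) + 1L]] <- new_route(steps, start, target_desc)
          if (!all_minimal) return(hits)
          next
        }
        if (!all_minimal && key %in% nxt_keys) next
        nxt[[length(nxt) + 1L]] <- list(pool = after, steps = steps)
        nxt_keys <- c(nxt_keys, key)
      }
    }
    if (length(hits) > 0) {
      sigs <- vapply(hits, function(r) paste(r$steps$op, r$steps$substrates,
                                             collapse = " ; "), character(1))
      return(hits[!duplicated(sigs)])
    }
    if (length(nxt) > state_cap) {
      stop("route search truncated: state cap (", state_cap,
           ") exceeded at depth ", depth, call. = FALSE)
    }
    visited <- c(visited, unique(nxt_keys))
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  list()
}

#' Find shortest reaction routes to a target species
#'
#' Breadth-first search over canonicalized pool states with deterministic
#' operator and binding order. Returns every route of minimal length not
#' exceeding `max_depth` (an empty list if the target is unreachable, a
#' single zero-length route if the start pool already contains it).
#'
#' @param start A [lipid_pool()].
#' @param target Target species string, e.g. `"DAG 20:5/16:1"`.
#' @param max_depth Maximum number of reaction steps (>= 1).
#' @param ops Operator subset to enable (default all of [reaction_ops()]).
#' @param state_cap Abort with an error if a BFS layer exceeds this many
#'   states.
#' @param pdat_position,elo_max_carbons See [apply_reaction()].
#' @return A list of `lipid_route` objects.
#' @examples
#' find_routes(lipid_pool(c("PC 20:5/20:5", "DAG 16:0/16:1")),
#'             "TAG 16:0/16:1/20:5", max_depth = 2)
#' @export
find_routes <- function(start, target, max_depth, ops = reaction_ops(),
                        state_cap = 20000L, pdat_position = "sn3",
                        elo_max_carbons = 20L) {
  parse_species(target)
  bfs_routes(start, function(pool) target %in% pool$species, max_depth, ops,
             state_cap, pdat_position, elo_max_carbons,
             all_minimal = TRUE, target_desc = target)
}

#' Shortest route from an oleate-bearing PC to an EPA-bearing PC
#'
#' Searches the desaturation/elongation network under its compartment
#' constraint: desaturation acts only on PC-bound chains (`DES_PC`) and
#' elongation only on acyl-CoA (`ELO`), so the C18:1 -> ... -> 20:5 series
#' must shuttle through the acyl-editing cycle (PLA release, ACS
#' activation, elongation on CoA, LPCAT re-esterification). Returns one
#' shortest route to any PC carrying a 20:5 chain (a zero-length route if
#' the start PC already does), or errors if unreachable under the enabled
#' operators.
#'
#' @param start_pc A PC species string, e.g. `"PC 16:0/18:1"`.
#' @param max_depth Search depth (default 10).
#' @param ops Enabled operators (default: DES_PC, PLA, ACS, ELO and both
#'   LPCAT directions).
#' @param state_cap See [find_routes()].
#' @return A `lipid_route`.
#' @export
epa_synthesis_reachability <- function(start_pc,
                                       max_depth = 10,
                                       ops = c("DES_PC", "PLA", "ACS", "ELO",
                                               "LPCAT_fwd", "LPCAT_rev"),
                                       state_cap = 20000L) {
  sp <- parse_species(start_pc)
  if (sp$class != "PC") stop("start species must be a PC", call. = FALSE)
  has_epa_pc <- function(pool) {
    any(vapply(pool$species, function(s) {
      p <- parse_species(s)
      p$class == "PC" && "20:5" %in% p$chains
    }, logical(1)))
  }
  routes <- bfs_routes(lipid_pool(start_pc), has_epa_pc, max_depth, ops,
                       state_cap, all_minimal = FALSE,
                       target_desc = "PC bearing 20:5")
  if (length(routes) == 0) {
    stop("no EPA-bearing PC reachable from ", start_pc,
         " under the enabled operators within depth ", max_depth, call. = FALSE)
  }
  routes[[1]]
}

#' Serialize routes to JSON
#'
#' @param routes A `lipid_route` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_routes_json <- function(routes, path) {
  if (inherits(routes, "lipid_route")) routes <- list(routes)
  payload <- lapply(routes, function(r) {
    list(target = r$target, length = r$length,
         steps = lapply(seq_len(r$length), function(i) {
           list(op = r$steps$op[i], substrates = r$steps$substrates[i],
                products = r$steps$products[i])
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
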