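test_that("assembly classification follows the sn-2 carbon rule", {
  out <- classify_assembly(tibble::tibble(
    class = c("PC", "MGDG", "PC", "PC", "SQDG"),
    positional = c("20:5/16:1", "20:5/18:4", "ambiguous", NA, "14:0/14:0")
  ))
  expect_equal(out$assembly,
               c("prokaryotic", "eukaryotic", "ambiguous", "ambiguous",
                 "prokaryotic"))
  out2 <- classify_assembly(tibble::tibble(class = "PC", sn2 = c("22:6", "14:0")))
  expect_equal(out2$assembly, c("eukaryotic", "prokaryotic"))
  expect_error(classify_assembly(tibble::tibble(class = "LPC", sn2 = "16:0")),
               "not classifiable")
})

test_that("over the packaged fixtures eukaryotic calls occur only among PCs", {
  roster <- dplyr::bind_rows(packaged_fixtures()$fsolaris_pl$roster,
                             packaged_fixtures()$fsolaris_gl$roster)
  out <- classify_assembly(roster[, c("class", "sn2")])
  expect_true(all(out$assembly[out$class != "PC"] == "prokaryotic"))
  expect_true(any(out$assembly[out$class == "PC"] == "eukaryotic"))
  expect_true(all(out$assembly %in% c("prokaryotic", "eukaryotic")))
})

test_that("PDAT and PDCT rearrange chains as specified", {
  pool <- lipid_pool(c("PC 20:5/20:5", "DAG 16:0/16:1"))
  out <- apply_reaction("PDAT", pool,
                        list(pc = "PC 20:5/20:5", dag = "DAG 16:0/16:1"))
  expect_setequal(out$species, c("TAG 16:0/16:1/20:5", "LPC 20:5"))
  # input pool unmodified
  expect_setequal(pool$species, c("PC 20:5/20:5", "DAG 16:0/16:1"))

  pool2 <- lipid_pool(c("PC 20:5/16:1", "DAG 16:0/16:1"))
  out2 <- apply_reaction("PDCT", pool2,
                         list(pc = "PC 20:5/16:1", dag = "DAG 16:0/16:1"))
  expect_setequal(out2$species, c("DAG 20:5/16:1", "PC 16:0/16:1"))

  expect_error(apply_reaction("PLA", lipid_pool("DAG 16:0/16:1"),
                              list(pc = "PC 16:0/16:1")), "not in pool")
  expect_error(apply_reaction("PLA", pool2, list(pc = "DAG 16:0/16:1")),
               "class mismatch")
})

test_that("desaturation and elongation respect their caps and compartments", {
  pool <- lipid_pool("PC 16:0/18:1", coa = "18:4")
  d <- apply_reaction("DES_PC", pool, list(pc = "PC 16:0/18:1", position = 2))
  expect_true("PC 16:0/18:2" %in% d$species)
  expect_error(apply_reaction("DES_PC", lipid_pool("PC 16:0/18:4"),
                              list(pc = "PC 16:0/18:4", position = 2)),
               "cap exceeded")
  e <- apply_reaction("ELO", pool, list(chain = "18:4"))
  expect_true("20:4" %in% e$coa)
  expect_true("18:4" %in% e$coa) # reservoir is non-depleting
  expect_error(apply_reaction("ELO", e, list(chain = "20:4")), "beyond 20")
  expect_error(apply_reaction("ELO", pool, list(chain = "16:0")),
               "not in acyl-CoA reservoir")
})

test_that("acyl chains are conserved across transfer reactions", {
  set.seed(13)
  pool_chains <- function(p) {
    sort(unlist(lapply(p$species, function(s) {
      strsplit(sub("^\\S+ ", "", s), "/", fixed = TRUE)[[1]]
    })))
  }
  chains <- default_acyl_pool()[1:8]
  for (i in 1:25) {
    pc <- paste0("PC ", sample(chains, 1), "/", sample(chains, 1))
    dag <- paste0("DAG ", sample(chains, 1), "/", sample(chains, 1))
    pool <- lipid_pool(c(pc, dag))
    for (op in c("PLA", "PDCT", "PDAT")) {
      b <- switch(op, PLA = list(pc = pc), list(pc = pc, dag = dag))
      out <- apply_reaction(op, pool, b)
      expect_equal(pool_chains(out), pool_chains(pool), label = op)
    }
    # LPCAT_rev moves the sn-2 chain into the CoA reservoir, nothing is lost
    rev <- apply_reaction("LPCAT_rev", pool, list(pc = pc))
    sn2 <- strsplit(sub("^PC ", "", pc), "/", fixed = TRUE)[[1]][2]
    expect_true(sn2 %in% rev$coa)
    expect_equal(sort(c(pool_chains(rev), sn2)), pool_chains(pool))
  }
})

test_that("BFS finds the one-step PDAT route to the EPA-containing TAG", {
  start <- lipid_pool(c("PC 20:5/20:5", "DAG 16:0/16:1"))
  routes <- find_routes(start, "TAG 16:0/16:1/20:5", max_depth = 4)
  expect_equal(length(routes), 1)
  expect_equal(routes[[1]]$length, 1)
  expect_equal(routes[[1]]$steps$op, "PDAT")
  # agrees with exhaustive enumeration
  oracle <- oracle_all_routes(start, "TAG 16:0/16:1/20:5", 4)
  expect_equal(min(lengths(oracle)), 1)
  expect_equal(sum(lengths(oracle) == 1), 1)
})

test_that("BFS minimality matches exhaustive enumeration for acyl editing", {
  start <- lipid_pool(c("PC 20:5/18:2", "DAG 16:0/16:1"), coa = "16:1")
  routes <- find_routes(start, "DAG 20:5/16:1", max_depth = 4)
  expect_true(all(vapply(routes, function(r) r$length, numeric(1)) == 3))
  oracle <- oracle_all_routes(start, "DAG 20:5/16:1", 4)
  expect_equal(min(lengths(oracle)), 3)
  # the same set of minimal routes, compared as op/substrate signatures
  norm <- function(x) gsub(" \\+ ", "+", x)
  got <- vapply(routes, function(r) {
    paste(r$steps$op, norm(r$steps$substrates), collapse = " ; ")
  }, character(1))
  want <- vapply(oracle[lengths(oracle) == min(lengths(oracle))],
                 paste, character(1), collapse = " ; ")
  expect_setequal(got, unique(want))
  # the acyl-editing + head-group-exchange route is among them
  ops <- lapply(routes, function(r) r$steps$op)
  expect_true(any(vapply(ops, function(o) {
    identical(o, c("PLA", "LPCAT_fwd", "PDCT"))
  }, logical(1))))
})

test_that("unreachable targets and degenerate starts are handled", {
  start <- lipid_pool(c("PC 16:0/16:1"))
  expect_equal(find_routes(start, "TAG 16:0/16:1/20:5", max_depth = 2), list())
  # target already present: one zero-length route
  r0 <- find_routes(lipid_pool("DAG 16:0/16:1"), "DAG 16:0/16:1", max_depth = 2)
  expect_equal(length(r0), 1)
  expect_equal(r0[[1]]$length, 0)
  expect_error(find_routes(start, "TAG 16:0/16:1/20:5", max_depth = 0))
  expect_error(find_routes(lipid_pool(c("PC 20:5/18:2", "DAG 16:0/16:1"),
                                      coa = "16:1"),
                           "DAG 20:5/16:1", max_depth = 4, state_cap = 2L),
               "state cap")
})

test_that("EPA synthesis shuttles between PC desaturation and CoA elongation", {
  route <- epa_synthesis_reachability("PC 16:0/18:1")
  expect_s3_class(route, "lipid_route")
  expect_gt(route$length, 0)
  steps <- route$steps
  # desaturation only ever acts on PC-bound chains
  expect_true(all(grepl("^PC ", steps$substrates[steps$op == "DES_PC"])))
  # elongation only ever acts on reservoir (acyl-CoA) chains
  expect_true(all(grepl("^[0-9]+:[0-9]+$", steps$substrates[steps$op == "ELO"])))
  expect_true(any(steps$op == "ELO"))
  # final product is an EPA-bearing PC
  expect_match(steps$products[route$length], "PC .*20:5")

  expect_error(epa_synthesis_reachability("PC 16:0/18:1",
                                          ops = c("PLA", "ACS", "ELO",
                                                  "LPCAT_fwd", "LPCAT_rev")),
               "no EPA-bearing PC reachable")
  already <- epa_synthesis_reachability("PC 20:5/16:0")
  expect_equal(already$length, 0)
  expect_error(epa_synthesis_reachability("DAG 16:0/16:1"), "must be a PC")
})

test_that("routes serialize to JSON and tidy into step tables", {
  routes <- find_routes(lipid_pool(c("PC 20:5/20:5", "DAG 16:0/16:1")),
                        "TAG 16:0/16:1/20:5", max_depth = 2)
  f <- withr::local_tempfile()
  write_routes_json(routes, f)
  back <- jsonlite::read_json(f)
  expect_equal(back[[1]]$length, 1)
  expect_equal(back[[1]]$steps[[1]]$op, "PDAT")
  expect_equal(tidy(routes[[1]])$op, "PDAT")
  expect_equal(glance(routes[[1]])$length, 1)
})
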