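test_that("closed-form count matches its documented examples", {
  expect_equal(count_expected(1, 0, 1, 0), 1L)
  expect_equal(count_expected(2, 2, 3, 3), 24L)
  expect_equal(count_expected(10, 8, 16, 7), 414L)
  expect_equal(count_expected(10, 8, 16, 7, lengths = 2), 160L)
  expect_equal(count_expected(10, 8, 16, 7, lengths = 3), 198L)
  expect_equal(count_expected(10, 8, 16, 7, lengths = 4), 56L)
  expect_error(count_expected(-1, 0, 1, 0), "negative")
  expect_error(count_expected(1, 2, 1, 0), "exceed")
})

test_that("a single mono/mono pair admits only the two-unit topology", {
  set <- make_monomer_set(1, 0, 1, 0, seed = 3)
  lib <- enumerate_library(set$isos, set$ols)
  expect_length(lib, 1)
  expect_equal(lib$table$topology, "IA")
})

test_that("enumeration size equals the closed form on random configurations", {
  set.seed(42)
  for (rep in 1:40) {
    n_iso <- sample(1:3, 1); n_iso_di <- sample(0:n_iso, 1)
    n_ol <- sample(1:3, 1); n_ol_di <- sample(0:n_ol, 1)
    lengths <- sort(sample(2:4, sample(1:3, 1)))
    set <- make_monomer_set(n_iso, n_iso_di, n_ol, n_ol_di, seed = rep)
    lib <- enumerate_library(set$isos, set$ols, lengths = lengths)
    expect_equal(length(lib),
                 count_expected(n_iso, n_iso_di, n_ol, n_ol_di, lengths),
                 info = sprintf("config %d/%d/%d/%d lengths %s", n_iso,
                                n_iso_di, n_ol, n_ol_di,
                                paste(lengths, collapse = ",")))
  }
})

test_that("oligomer mass equals monomer masses plus capping deltas", {
  set <- make_monomer_set(2, 1, 2, 1, seed = 5)
  iso_mw <- vapply(set$isos, function(m) unname(mol_mw(m$mol)), numeric(1))
  ol_mw <- vapply(set$ols, function(m) unname(mol_mw(m$mol)), numeric(1))
  names(iso_mw) <- vapply(set$isos, `[[`, character(1), "id")
  names(ol_mw) <- vapply(set$ols, `[[`, character(1), "id")
  iso_fun <- stats::setNames(vapply(set$isos, `[[`, integer(1),
                                    "functionality"),
                             names(iso_mw))
  for (cap in c("amine", "methyl", "carbamate")) {
    lib <- enumerate_library(set$isos, set$ols, cap = cap)
    mws <- unname(mol_mw(lapply(lib$oligomers, `[[`, "mol")))
    for (i in seq_along(lib$oligomers)) {
      o <- lib$oligomers[[i]]
      n_iso_units <- switch(o$topology, IA = 1, IAI = 2, AIA = 1, IAIA = 2)
      n_ol_units <- switch(o$topology, IA = 1, IAI = 1, AIA = 2, IAIA = 2)
      n_capped <- iso_fun[[o$iso_id]] * n_iso_units - o$urethane_bonds
      expected <- iso_mw[[o$iso_id]] * n_iso_units +
        ol_mw[[o$ol_id]] * n_ol_units + n_capped * cap_mw_delta(cap)
      expect_equal(mws[i], expected, tolerance = 1e-4,
                   info = paste(cap, o$id))
    }
  }
})

test_that("every oligomer matches its topology contract", {
  lib <- default_library()
  mols <- lapply(lib$oligomers, `[[`, "mol")
  # urethane bond count follows the topology
  expect_equal(pf_smarts_count(mols, .pf_pat$urethane),
               lib$table$urethane_bonds)
  # no residual isocyanate groups after capping
  expect_equal(sum(pf_smarts_count(mols, .pf_pat$isocyanate)), 0L)
  # id prefixes encode the unit count
  prefix <- sub("_.*", "", lib$table$id)
  expect_equal(unname(c(dimer = 2L, trimer = 3L,
                        tetramer = 4L)[prefix]),
               lib$table$units)
  # no duplicate (isocyanate, alcohol, topology) triples
  expect_false(any(duplicated(lib$table[, c("isocyanate", "alcohol",
                                            "topology")])))
})

test_that("enumeration is deterministic", {
  set <- make_monomer_set(2, 1, 2, 1, seed = 9)
  lib1 <- enumerate_library(set$isos, set$ols)
  lib2 <- enumerate_library(set$isos, set$ols)
  expect_identical(mol_to_smiles(lapply(lib1$oligomers, `[[`, "mol")),
                   mol_to_smiles(lapply(lib2$oligomers, `[[`, "mol")))
  expect_identical(lib1$table, lib2$table)
})

test_that("empty monomer lists are rejected", {
  set <- make_monomer_set(1, 0, 1, 0, seed = 1)
  expect_error(enumerate_library(list(), set$ols), "empty isocyanate")
  expect_error(enumerate_library(set$isos, list()), "empty alcohol")
})

test_that("isocyanate classes group the default ids as published", {
  expect_equal(assign_isocyanate_class("2,4'-MDI"), "MDI")
  expect_equal(assign_isocyanate_class("2,4-MDI"), "MDI")
  expect_equal(assign_isocyanate_class("2,6-TDI"), "TDI")
  expect_equal(assign_isocyanate_class("HDI"), "HDI")
  expect_equal(assign_isocyanate_class("MIC"), "MIC")
  expect_error(assign_isocyanate_class("mystery"), "unknown isocyanate")
  lib <- default_library()
  cls <- vapply(lib$oligomers, assign_isocyanate_class, character(1))
  expect_setequal(unique(cls),
                  c("MIC", "BIC", "MDI", "TDI", "HDI", "IPDI", "HMDI"))
})
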