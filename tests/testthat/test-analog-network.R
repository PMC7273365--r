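# Members tables built directly (no chemistry) for combinatorial checks.
make_members <- function(core = "CORE", target = "T001", ids, subs, classes,
                         heavies = NULL, pkis = NULL, core_heavy = 10L) {
  n <- length(ids)
  tibble::tibble(
    target_id = target, core_smiles = core, compound_id = ids,
    canonical_smiles = paste0("SMI_", ids), sub_smiles = subs,
    position_class = as.integer(classes),
    sub_heavy = if (is.null(heavies)) rep(1L, n) else as.integer(heavies),
    core_heavy = core_heavy,
    pki = if (is.null(pkis)) rep(6, n) else pkis)
}

test_that("analog sets group by target and core, dropping singletons", {
  cpds <- tibble::tibble(
    compound_id = c("A1", "A2", "A3"),
    canonical_smiles = c(ob_canonical("Cc1ccccc1"),
                         ob_canonical("CCc1ccccc1"),
                         ob_canonical("Clc1ccccc1")))
  acts <- tibble::tibble(compound_id = rep(cpds$compound_id, 2),
                         canonical_smiles = rep(cpds$canonical_smiles, 2),
                         target_id = rep(c("T001", "T002"), each = 3),
                         pki = rep(6, 6))
  frags <- fragment_compounds(cpds)
  members <- build_analog_sets(frags, acts)
  benz <- ob_canonical("c1ccccc1")
  sets <- dplyr::count(members, target_id, core_smiles)
  # benzene core is shared by all three compounds on both targets...
  expect_equal(sort(sets$core_smiles), rep(benz, 2))
  expect_equal(sets$n, c(3L, 3L))
  # ...while the toluene core (only ethylbenzene has it) is a dropped
  # singleton
  expect_false(ob_canonical("Cc1ccccc1") %in% members$core_smiles)
})

test_that("pair enumeration needs distinct position classes within bounds", {
  # m x n members at two classes, all substituents distinct: m*n pairs
  mm <- make_members(ids = sprintf("A%d", 1:5),
                     subs = sprintf("*S%d", 1:5),
                     classes = c(1, 1, 2, 2, 2))
  pr <- enumerate_pairs(mm)
  expect_equal(nrow(pr), 2L * 3L)
  expect_true(all(pr$pair_type == "ds"))
  expect_true(all(pr$class_a != pr$class_b))

  # same substituent at two classes is an iso pair
  iso <- enumerate_pairs(make_members(ids = c("A1", "A2"),
                                      subs = c("*C", "*C"),
                                      classes = c(1, 2)))
  expect_equal(iso$pair_type, "iso")

  # single symmetry class (benzene-like core): no pairs
  expect_equal(nrow(enumerate_pairs(make_members(ids = c("A1", "A2"),
                                                 subs = c("*C", "*Cl"),
                                                 classes = c(1, 1)))), 0L)

  # size difference bound is inclusive at 8, exclusive at 9
  sz <- make_members(ids = c("A1", "A2"), subs = c("*BIG", "*C"),
                     classes = c(1, 2), heavies = c(9, 1))
  expect_equal(nrow(enumerate_pairs(sz)), 1L)
  expect_equal(enumerate_pairs(sz)$size_diff, 8L)
  sz9 <- make_members(ids = c("A1", "A2"), subs = c("*BIG", "*C"),
                      classes = c(1, 2), heavies = c(10, 1))
  expect_equal(nrow(enumerate_pairs(sz9)), 0L)

  # output is invariant to member ordering
  shuf <- mm[c(4, 1, 5, 2, 3), ]
  key <- function(p) sort(paste(p$cpd_a, p$cpd_b, p$pair_type))
  expect_identical(key(enumerate_pairs(shuf)), key(enumerate_pairs(mm)))
})

test_that("pair deduplication keeps the largest core with evidence", {
  p1 <- enumerate_pairs(make_members(core = "CORE_SMALL", core_heavy = 8L,
                                     ids = c("A1", "A2"),
                                     subs = c("*C", "*C"), classes = c(1, 2)))
  p2 <- enumerate_pairs(make_members(core = "CORE_BIG", core_heavy = 12L,
                                     ids = c("A1", "A2"),
                                     subs = c("*C", "*N"), classes = c(1, 2)))
  dd <- dedupe_pairs(dplyr::bind_rows(p1, p2))
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$core_smiles, "CORE_BIG")
  # classified by the retained core's decomposition; both cores in evidence
  expect_equal(dd$pair_type, "ds")
  expect_equal(dd$evidence_cores, "CORE_BIG;CORE_SMALL")
  expect_equal(dd$evidence_types, "ds;iso")

  # distinct compound pairs are both retained
  p3 <- enumerate_pairs(make_members(ids = c("A3", "A4"),
                                     subs = c("*C", "*N"), classes = c(1, 2)))
  dd2 <- dedupe_pairs(dplyr::bind_rows(p1, p3))
  expect_equal(nrow(dd2), 2L)
})

test_that("iso pairs arise only between constitutional isomers", {
  acts <- aggregate_potency(records_from(make_activity_table(
    c("A1", "A2", "A3"),
    c("Cc1cccc2ccccc12",    # 1-methylnaphthalene
      "Cc1ccc2ccccc2c1",    # 2-methylnaphthalene
      "Clc1ccc2ccccc2c1"),  # 2-chloronaphthalene
    c(1, 1000, 5))))
  members <- build_analog_sets(fragment_compounds(acts), acts)
  pairs <- dedupe_pairs(enumerate_pairs(members))
  # A2/A3 sit at the same 2-position class: excluded as single-site analogs
  expect_equal(nrow(pairs), 2L)
  iso <- pairs[pairs$pair_type == "iso", ]
  expect_equal(nrow(iso), 1L)
  expect_setequal(c(iso$cpd_a, iso$cpd_b), c("A1", "A2"))
  expect_identical(mol_formula(iso$smiles_a), mol_formula(iso$smiles_b))
  ds <- pairs[pairs$pair_type == "ds", ]
  expect_equal(nrow(ds), 1L)
  expect_setequal(c(ds$cpd_a, ds$cpd_b), c("A1", "A3"))
  expect_equal(ds$size_diff, 0L)
})
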