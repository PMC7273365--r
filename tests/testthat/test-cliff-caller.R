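make_pair <- function(pki_a, pki_b, core = "c1ccc2ccccc2c1",
                      sub_a = "*C", sub_b = "*Cl", type = "ds",
                      smiles_a = "Cc1cccc2ccccc12",
                      smiles_b = "Clc1ccc2ccccc2c1") {
  tibble::tibble(target_id = "T001", core_smiles = ob_canonical(core),
                 core_heavy = heavy_atom_count(core),
                 cpd_a = "A1", smiles_a = ob_canonical(smiles_a),
                 sub_a = sub_a, class_a = 1L, sub_heavy_a = 1L, pki_a = pki_a,
                 cpd_b = "A2", smiles_b = ob_canonical(smiles_b),
                 sub_b = sub_b, class_b = 2L, sub_heavy_b = 1L, pki_b = pki_b,
                 pair_type = type, size_diff = 0L,
                 evidence_cores = "", evidence_types = type)
}

test_that("the 100-fold criterion is inclusive and monotone in the threshold", {
  expect_equal(call_cliffs(make_pair(9.1, 5.0))$delta_pki, 4.1)
  expect_equal(nrow(call_cliffs(make_pair(7.99, 6.0))), 0L)  # delta 1.99
  at_edge <- call_cliffs(make_pair(8.0, 6.0))                # delta 2.00
  expect_equal(nrow(at_edge), 1L)
  expect_equal(at_edge$potent_cpd, "A1")
  expect_equal(at_edge$weak_cpd, "A2")
  # every cliff is a ds cliff; iso pairs carry both flags
  expect_true(at_edge$is_ds)
  expect_false(at_edge$is_iso)
  expect_true(call_cliffs(make_pair(8, 6, type = "iso"))$is_iso)
  # lowering the threshold can only add cliffs
  many <- dplyr::bind_rows(make_pair(9, 5), make_pair(7.5, 6.0),
                           make_pair(6.2, 6.0))
  strict <- call_cliffs(many, min_fold = 100)
  loose <- call_cliffs(many, min_fold = 1)
  expect_true(all(paste(strict$pki_a, strict$pki_b) %in%
                    paste(loose$pki_a, loose$pki_b)))
  expect_equal(nrow(loose), 3L)
  # a pair member without potency is a data-integrity error
  broken <- make_pair(NA_real_, 5.0)
  expect_error(call_cliffs(broken), "A1")
})

test_that("privileged-substructure annotation matches the shared core", {
  lib <- read_ps_library(starter_ps_path())
  # indole-core cliff: core contains the indole pattern
  ind <- call_cliffs(make_pair(9, 5, core = "c1ccc2[nH]ccc2c1",
                               smiles_a = "Cc1ccc2[nH]ccc2c1",
                               smiles_b = "Clc1cc2cc[nH]c2cc1"))
  ind <- annotate_privileged(ind, lib)
  expect_true(ind$is_ps)
  expect_match(ind$ps_evidence, "indole")
  # naphthalene core: no library pattern
  naph <- annotate_privileged(call_cliffs(make_pair(9, 5)), lib)
  expect_false(naph$is_ps)
  expect_equal(naph$ps_smarts, "")
  # pattern present only in the full molecule, not the core: not a PS
  # cliff under core scope, but found under "either" scope
  biphen <- call_cliffs(make_pair(
    9, 5, core = "c1ccccc1",
    smiles_a = "Cc1ccccc1", smiles_b = "Clc1ccccc1"))
  biphen$smiles_a <- ob_canonical("c1ccc(-c2ccccc2C)cc1")
  expect_false(annotate_privileged(biphen, lib)$is_ps)
  expect_true(annotate_privileged(biphen, lib, scope = "either")$is_ps)
  expect_false(annotate_privileged(biphen, lib, scope = "both")$is_ps)
  # multiple matches report the largest pattern, all in evidence
  carb <- call_cliffs(make_pair(9, 5, core = "c1ccc2c(c1)[nH]c1ccccc12",
                                smiles_a = "Cc1ccc2c(c1)[nH]c1ccccc12",
                                smiles_b = "Clc1ccc2c(c1)[nH]c1ccccc12"))
  carb <- annotate_privileged(carb, lib)
  expect_true(carb$is_ps)
  expect_equal(carb$ps_smarts,
               lib$pattern[lib$name == "carbazole"])
  expect_match(carb$ps_evidence, "indole")
  expect_match(carb$ps_evidence, "carbazole")
  # annotation is monotone in the library
  sub_lib <- lib[lib$name != "carbazole", ]
  carb2 <- annotate_privileged(call_cliffs(
    make_pair(9, 5, core = "c1ccc2c(c1)[nH]c1ccccc12",
              smiles_a = "Cc1ccc2c(c1)[nH]c1ccccc12",
              smiles_b = "Clc1ccc2c(c1)[nH]c1ccccc12")), sub_lib)
  expect_true(carb2$is_ps)   # still flagged through the indole pattern
})

test_that("isomer extension fills the four-compound data structure", {
  base <- fixture_spec(scaffolds = "naphthalene",
                       substituents = c("methyl", "chloro"),
                       noise_amp = 0, cliff_offset = 3,
                       potent_when = function(site, sub) {
                         site == "s1" && sub == "methyl"
                       })
  fx <- generate_fixture(base)
  cfg <- run_config()
  res_full <- run_pipeline(cfg, activity = fx$activity)
  ds <- res_full$cliffs[!res_full$cliffs$is_iso, ]
  iso <- res_full$cliffs[res_full$cliffs$is_iso, ]
  # the ds cliff (methyl@1 vs chloro@2) has both repositioned isomers
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$extension_status, "full")
  d <- fx$design
  expect_equal(ds$iso_of_potent_id,
               d$compound_id[d$site == "s2" & d$sub == "methyl"])
  expect_equal(ds$iso_of_weak_id,
               d$compound_id[d$site == "s1" & d$sub == "chloro"])
  # the extension isomers carry their own pKi
  expect_equal(ds$iso_of_potent_pki,
               d$pki[d$site == "s2" & d$sub == "methyl"])
  # an iso cliff's repositioned isomers coincide with the cliff compounds
  # themselves and are not eligible: never extended
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$extension_status, "none")
  expect_equal(iso$iso_of_potent_id, "")

  # removing one repositioned isomer downgrades to partial, both to none
  drop_ids <- function(ids) {
    act <- fx$activity[!fx$activity$molecule_chembl_id %in% ids, ]
    run_pipeline(cfg, activity = act)$cliffs
  }
  m2 <- d$compound_id[d$site == "s2" & d$sub == "methyl"]
  c1 <- d$compound_id[d$site == "s1" & d$sub == "chloro"]
  partial <- drop_ids(m2)
  partial_ds <- partial[!partial$is_iso, ]
  expect_equal(partial_ds$extension_status, "partial")
  expect_equal(partial_ds$iso_of_potent_id, "")
  expect_equal(partial_ds$iso_of_weak_id, c1)
  none <- drop_ids(c(m2, c1))
  expect_equal(none$extension_status, "none")
  # extension soundness: a filled slot fragments back to the cliff's core
  # at the expected (substituent, class)
  sl <- fragment_compound(
    d$smiles[d$compound_id == ds$iso_of_potent_id])
  a_potent <- ds$potent_cpd == ds$cpd_a
  expect_true(any(sl$core_smiles == ds$core_smiles &
                    sl$sub_smiles == (if (a_potent) ds$sub_a else ds$sub_b) &
                    sl$position_class ==
                      (if (a_potent) ds$class_b else ds$class_a)))
})
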