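test_that("anti-cholinesterase ester groups are detected", {
  cases <- list(
    # smiles, carbamate, organophosphate
    list("CCOP(=O)(OCC)OCC", FALSE, TRUE),   # triethyl phosphate
    list("CNC(=O)Oc1cccc2ccccc12", TRUE, FALSE), # carbaryl
    list("CCO", FALSE, FALSE),
    list("CNC(=O)CSP(=S)(OC)OC", FALSE, TRUE),  # dimethoate (thiophosphate)
    list("CNC(=O)Oc1ccccc1OC(C)C", TRUE, FALSE) # propoxur
  )
  for (cs in cases) {
    got <- detect_ache_groups(get_mol(cs[[1]]))
    expect_identical(unname(got["is_carbamate_ester"]), cs[[2]],
                     label = cs[[1]])
    expect_identical(unname(got["is_organophosphate_ester"]), cs[[3]],
                     label = cs[[1]])
  }
})

test_that("genotoxicity structural alerts fire on the classic classes", {
  hits <- list(
    "O=[N+]([O-])c1ccccc1" = "aromatic nitro",
    "CN(C)N=O" = "N-nitroso",
    "OCC1CO1" = "epoxide",
    "Nc1ccccc1" = "aromatic amine",
    "c1ccc(cc1)N=Nc1ccccc1" = "aromatic azo",
    "NNc1ccccc1" = "hydrazine",
    "ClCc1ccccc1" = "activated alkyl halide benzylic",
    "C=CC=O" = "alpha-beta unsaturated carbonyl",
    "COS(C)(=O)=O" = "alkyl sulfonate ester"
  )
  for (sm in names(hits)) {
    res <- detect_genotoxic_alerts(get_mol(sm))
    expect_true(res$flag, label = sm)
    expect_true(hits[[sm]] %in% res$alert_names, label = sm)
  }
  clean <- c("CCO", "CC(C)O", "O=C1CCCO1", "CCOP(=O)(OCC)OCC")
  for (sm in clean) {
    expect_false(detect_genotoxic_alerts(get_mol(sm))$flag, label = sm)
  }
})

test_that("the Kroes gate annotates but never drops", {
  expect_false(kroes_gate(get_mol("CCO"))$kroes_excluded)
  tel <- kroes_gate(get_mol("CC[Pb](CC)(CC)CC"))   # tetraethyllead
  expect_true(tel$kroes_excluded)
  expect_identical(tel$reason, "organometallic")
  tcdd <- kroes_gate(get_mol("Clc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl"))
  expect_true(tcdd$kroes_excluded)
  expect_identical(tcdd$reason, "high-potency carcinogen class")
  # unsubstituted dibenzodioxin core carries no halogens -> inside domain
  expect_false(kroes_gate(get_mol("c1ccc2c(c1)Oc1ccccc1O2"))$kroes_excluded)
  # Kroes-excluded chemicals still receive a TTC assignment
  chems <- data.frame(chem_id = "x", smiles = "CC[Pb](CC)(CC)CC",
                      stringsAsFactors = FALSE)
  prof <- classify_chemicals(chems)
  expect_true(prof$kroes_excluded)
  asg <- assign_ttc(prof, genotox_filter = TRUE)
  expect_identical(nrow(asg), 1L)
  expect_true(asg$kroes_excluded)
})

test_that("the Cramer tree reproduces known class assignments with traces", {
  cases <- c(
    "CCO" = "I", "CC(C)O" = "I", "CCCCCC" = "I", "Cc1ccccc1" = "I",
    "CCOC(=O)C" = "I", "OCc1ccccc1" = "I",
    "O=C1CCCO1" = "II", "CC1CCC(=O)O1" = "II", "C=CCO" = "II",
    "c1ccc2ncccc2c1" = "III", "c1ccncc1" = "III", "c1ccoc1" = "III",
    "Nc1ccccc1" = "III", "O=[N+]([O-])c1ccccc1" = "III",
    "CCOP(=O)(OCC)OCC" = "III", "Oc1ccc(O)cc1" = "III"
  )
  for (sm in names(cases)) {
    res <- classify_cramer(get_mol(sm))
    expect_identical(res$cramer_class, unname(cases[sm]), label = sm)
    expect_gt(nrow(res$trace), 0)
    expect_identical(res$trace$question_id[1], 1L)
  }
})

test_that("replaying a Cramer trace reproduces the recorded answers", {
  for (sm in c("CCO", "O=C1CCCO1", "CNC(=O)Oc1cccc2ccccc12", "c1ccncc1")) {
    mol <- get_mol(sm)
    tr <- classify_cramer(mol)$trace
    replay <- vapply(tr$question_id, function(id) cramer_answer(mol, id),
                     logical(1))
    expect_identical(replay, tr$answer, label = sm)
  }
})

test_that("every parseable structure receives exactly one Cramer class", {
  chems <- generate_chemicals(150, seed = 5)
  prof <- classify_chemicals(chems)
  expect_identical(nrow(prof), 150L)
  expect_true(all(prof$cramer_class %in% c("I", "II", "III")))
})

test_that("the volatility flag applies the bp/vp cutoffs", {
  expect_true(volatility_flag(100, NA))        # bp < 260 C
  expect_false(volatility_flag(300, 0.01))     # both on the involatile side
  expect_true(volatility_flag(NA, 0.5))        # vp > 0.1 mmHg
  expect_identical(volatility_flag(NA, NA), NA)
  expect_true(volatility_flag(100, 0.5))
  expect_error(volatility_flag(NA, -1), "vapor pressure")
})

test_that("unparsable rows are rejected without aborting the batch", {
  chems <- rbind(tiny_chemicals(),
                 data.frame(chem_id = "c_bad", smiles = "C1CC",
                            stringsAsFactors = FALSE))
  prof <- classify_chemicals(chems)
  expect_identical(nrow(prof), 5L)
  rej <- attr(prof, "rejects")
  expect_identical(rej$chem_id, "c_bad")
  expect_match(rej$reason, "parse|Babel")
})
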