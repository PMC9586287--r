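# Cramer structural-class decision tree.
#
# Table-driven rendition of the original 33-question oral-toxicity decision
# tree: every node is a named structural predicate over the SMARTS feature
# battery (plus small canonical-SMILES lookup lists for body constituents,
# common carbohydrates and common terpenes), and every parseable structure
# reaches exactly one of the leaves I (low), II (intermediate) or III (high).
# The wiring below follows the published question themes; the methods
# vignette documents the rendition and its validation on the curated
# exemplar panel.

.cramer_lookup_raw <- list(
  normal_body = c(
    "C(=O)(O)C(O)C",            # lactic acid
    "OC(=O)CC(O)(C(=O)O)CC(=O)O", # citric acid
    "NCC(=O)O",                 # glycine
    "CC(N)C(=O)O",              # alanine
    "NC(N)=O",                  # urea
    "NCCO",                     # ethanolamine
    "OCC(O)C(O)C(O)C(O)C=O"     # glucose (open chain)
  ),
  carbohydrate = c(
    "OCC1OC(O)C(O)C(O)C1O",     # glucopyranose
    "OCC(O)C(O)C(O)C(O)CO",     # sorbitol
    "OCC1OC(CO)(O)C(O)C1O",     # fructofuranose
    "OCC(O)CO"                  # glycerol
  ),
  terpene = c(
    "CC(=C)C1CCC(C)=CC1",       # limonene
    "CC(C)C1CCC(C)CC1O",        # menthol
    "CC1=CCC2CC1C2(C)C",        # alpha-pinene
    "CC(C)(O)C1CCC(C)=CC1"      # alpha-terpineol
  )
)

.cramer_env <- new.env(parent = emptyenv())

cramer_lookups <- function() {
  if (is.null(.cramer_env$lookups)) {
    .cramer_env$lookups <- lapply(.cramer_lookup_raw, canonical_smiles)
  }
  .cramer_env$lookups
}

# -- predicate helpers -------------------------------------------------------

.cnt <- function(feat, nm) unname(feat$counts[nm])

.elements_within <- function(feat, allowed) {
  length(setdiff(feat$elements, allowed)) == 0L
}

.metal_counterions <- c("Li", "Na", "K", "Ca", "Mg")

# Distinct common functional-group types present (acyclic branch).
.n_group_types <- function(feat) {
  has_ester <- .cnt(feat, "ester") > 0
  sum(
    .cnt(feat, "hydroxyl") > 0,
    .cnt(feat, "aldehyde") > 0,
    .cnt(feat, "ketone") > 0,
    .cnt(feat, "carboxylic_acid") > 0,
    has_ester,
    !has_ester && .cnt(feat, "ether") > 0,
    (.cnt(feat, "amine_prim_sec") + .cnt(feat, "amine_tert")) > 0,
    .cnt(feat, "amide") > 0,
    .cnt(feat, "nitrile") > 0,
    .cnt(feat, "thio_divalent") > 0
  )
}

# -- node table --------------------------------------------------------------
# yes/no entries are either the id of the next question or a leaf class.

cramer_nodes <- function() list(
  `1` = list(
    name = "normal_body_constituent",
    text = "Is the substance a normal constituent of the body?",
    pred = function(f, lk) f$cansmi %in% lk$normal_body,
    yes = "I", no = 2L),
  `2` = list(
    name = "enhanced_toxicity_groups",
    text = paste("Does it contain functional groups associated with enhanced",
                 "toxicity (N-nitroso, aliphatic azo, triazene, isocyanate,",
                 "acyl halide, quaternary nitrogen, peroxide, sulfonate/",
                 "sulfate alkyl ester)?"),
    pred = function(f, lk) {
      (.cnt(f, "n_nitroso") + .cnt(f, "azo_aliphatic") + .cnt(f, "triazene") +
         .cnt(f, "isocyanate") + .cnt(f, "acyl_halide") +
         .cnt(f, "quaternary_N") + .cnt(f, "peroxide") +
         .cnt(f, "sulfonate_ester")) > 0
    },
    yes = "III", no = 3L),
  `3` = list(
    name = "unusual_elements",
    text = "Does it contain elements other than C, H, O, N or divalent S?",
    pred = function(f, lk) {
      !.elements_within(f, c("C", "H", "O", "N", "S")) ||
        .cnt(f, "s_nondivalent") > 0
    },
    yes = 33L, no = 4L),
  `33` = list(
    name = "simple_sulfonate_or_carboxylate_salt",
    text = paste("Is it an alkali/alkaline-earth sulfonate, sulfamate or",
                 "carboxylate salt with no other unusual feature?"),
    pred = function(f, lk) {
      exotic <- setdiff(f$elements, c("C", "H", "O", "N", "S"))
      all(exotic %in% .metal_counterions) &&
        .cnt(f, "metal_on_carbon") == 0 &&
        (.cnt(f, "sulfonate_group") > 0 || .cnt(f, "carboxylate_anion") > 0) &&
        .cnt(f, "s_nondivalent") <= .cnt(f, "sulfonate_group")
    },
    yes = 4L, no = "III"),
  `4` = list(
    name = "open_chain",
    text = "Is it an open-chain (acyclic) structure?",
    pred = function(f, lk) .cnt(f, "ring_atom") == 0,
    yes = 5L, no = 7L),
  `5` = list(
    name = "simple_hydrocarbon_or_carbohydrate",
    text = paste("Is it a simply branched aliphatic hydrocarbon or a common",
                 "carbohydrate?"),
    pred = function(f, lk) {
      .elements_within(f, c("C", "H")) || f$cansmi %in% lk$carbohydrate
    },
    yes = "I", no = 6L),
  `6` = list(
    name = "common_oxygen_functions_only",
    text = paste("Are its functional groups limited to alcohol, aldehyde,",
                 "ketone, carboxylic acid, ester, acetal or ether?"),
    pred = function(f, lk) .elements_within(f, c("C", "H", "O")),
    yes = 30L, no = 19L),
  `30` = list(
    name = "aliphatic_unsaturation",
    text = "Does it contain non-aromatic carbon-carbon unsaturation?",
    pred = function(f, lk) (.cnt(f, "cc_unsat") + .cnt(f, "cc_triple")) > 0,
    yes = 31L, no = "I"),
  `31` = list(
    name = "conjugated_unsaturation",
    text = paste("Is the unsaturation conjugated with a carbonyl group or",
                 "another double bond?"),
    pred = function(f, lk) (.cnt(f, "conj_enone") + .cnt(f, "conj_diene")) > 0,
    yes = "III", no = "II"),
  `19` = list(
    name = "moderate_nitrogen_sulfur_only",
    text = paste("Are the nitrogen/sulfur functions limited to amine, amide,",
                 "nitrile, thiol or sulfide (no imine, aliphatic nitro or",
                 "higher-valent sulfur)?"),
    pred = function(f, lk) {
      .cnt(f, "imine_like") == 0 && .cnt(f, "nitro_aliphatic") == 0
    },
    yes = 20L, no = "III"),
  `20` = list(
    name = "many_functional_group_types",
    text = "Does it carry more than two distinct functional-group types?",
    pred = function(f, lk) .n_group_types(f) > 2,
    yes = "III", no = 21L),
  `21` = list(
    name = "simple_chain_size",
    text = "Is the carbon skeleton of modest size (MW <= 400 g/mol)?",
    pred = function(f, lk) f$mw <= 400,
    yes = "II", no = "III"),
  `7` = list(
    name = "heterocyclic",
    text = "Does it contain a heteroatom in a ring?",
    pred = function(f, lk) .cnt(f, "hetero_ring_atom") > 0,
    yes = 8L, no = 16L),
  `8` = list(
    name = "heteroaromatic",
    text = "Is any ring heteroaromatic?",
    pred = function(f, lk) .cnt(f, "heteroaromatic") > 0,
    yes = "III", no = 9L),
  `9` = list(
    name = "lactone",
    text = "Is it a lactone or cyclic diester?",
    pred = function(f, lk) .cnt(f, "lactone") > 0,
    yes = 10L, no = 11L),
  `10` = list(
    name = "unsaturated_or_fused_lactone",
    text = paste("Is the lactone alpha,beta-unsaturated or fused to another",
                 "ring?"),
    pred = function(f, lk) {
      .cnt(f, "lactone_unsat") > 0 || .cnt(f, "fused_ring_atom") > 0
    },
    yes = "III", no = "II"),
  `11` = list(
    name = "single_common_heteroatom_ring",
    text = paste("Is there a single O or N heteroatom in a saturated 5- or",
                 "6-membered ring?"),
    pred = function(f, lk) {
      .cnt(f, "hetero_ring_atom") == 1 &&
        (.cnt(f, "ring56_O") + .cnt(f, "ring56_N")) == 1
    },
    yes = 12L, no = 14L),
  `12` = list(
    name = "common_ring_substituents",
    text = paste("Are substituents limited to alkyl, hydroxyl, oxo,",
                 "carboxylic acid or simple ester?"),
    pred = function(f, lk) {
      .elements_within(f, c("C", "H", "O", "N")) &&
        .cnt(f, "amide") == 0 && .cnt(f, "nitrile") == 0 &&
        .cnt(f, "imine_like") == 0 && .cnt(f, "nitro_aliphatic") == 0 &&
        .cnt(f, "arylamine") == 0
    },
    yes = "II", no = 13L),
  `13` = list(
    name = "single_moderate_substituent",
    text = paste("Is there exactly one moderate-concern substituent (amide,",
                 "carbamate, nitrile or sulfide) and nothing more reactive?"),
    pred = function(f, lk) {
      ((.cnt(f, "amide") > 0) + (.cnt(f, "nitrile") > 0) +
         (.cnt(f, "thio_divalent") > 0)) == 1 &&
        .cnt(f, "imine_like") == 0 && .cnt(f, "nitro_aliphatic") == 0
    },
    yes = "II", no = "III"),
  `14` = list(
    name = "two_heteroatom_ring",
    text = paste("Are there exactly two O/N heteroatoms in saturated 5- or",
                 "6-membered rings (morpholine/piperazine-like)?"),
    pred = function(f, lk) {
      .cnt(f, "hetero_ring_atom") == 2 &&
        (.cnt(f, "ring56_O") + .cnt(f, "ring56_N")) == 2
    },
    yes = 15L, no = "III"),
  `15` = list(
    name = "plain_two_heteroatom_ring",
    text = "Are substituents limited to alkyl or oxo groups?",
    pred = function(f, lk) {
      .elements_within(f, c("C", "H", "O", "N")) &&
        .cnt(f, "imine_like") == 0 && .cnt(f, "nitro_aliphatic") == 0 &&
        .cnt(f, "nitrile") == 0
    },
    yes = "II", no = "III"),
  `16` = list(
    name = "common_terpene",
    text = "Is it a common terpene hydrocarbon, alcohol or related compound?",
    pred = function(f, lk) f$cansmi %in% lk$terpene,
    yes = "I", no = 17L),
  `17` = list(
    name = "readily_hydrolysable_ester",
    text = paste("Is it a readily hydrolysable ester of common alcohols and",
                 "acids (no aromatic ring, no conjugated carbonyl)?"),
    pred = function(f, lk) {
      .cnt(f, "ester") > 0 && .elements_within(f, c("C", "H", "O")) &&
        .cnt(f, "aromatic_atom") == 0 && .cnt(f, "conj_enone") == 0
    },
    yes = "I", no = 18L),
  `18` = list(
    name = "carbocyclic_aromatic",
    text = "Does it contain an aromatic (carbocyclic) ring?",
    pred = function(f, lk) .cnt(f, "aromatic_atom") > 0,
    yes = 23L, no = 22L),
  `22` = list(
    name = "simple_alicyclic",
    text = paste("Is it a monocyclic 5-membered or larger cycloalkane with",
                 "substituents limited to common oxygen functions?"),
    pred = function(f, lk) {
      .elements_within(f, c("C", "H", "O")) &&
        .cnt(f, "small_ring_carbon") == 0 && .cnt(f, "fused_ring_atom") == 0
    },
    yes = "I", no = 29L),
  `29` = list(
    name = "strained_or_bridged_ring",
    text = "Does it contain a 3-/4-membered carbocycle or a fused/bridged ring system?",
    pred = function(f, lk) {
      .cnt(f, "small_ring_carbon") > 0 || .cnt(f, "fused_ring_atom") > 0
    },
    yes = "III", no = 21L),
  `23` = list(
    name = "fused_aromatic_rings",
    text = "Does it contain fused aromatic rings (naphthalene-like core)?",
    pred = function(f, lk) .cnt(f, "arom_fused") > 0,
    yes = "III", no = 24L),
  `24` = list(
    name = "common_aromatic_substituents",
    text = paste("Are ring substituents limited to hydrocarbon, alkoxy,",
                 "hydroxyl, aldehyde, ketone, acid or simple ester groups?"),
    pred = function(f, lk) .elements_within(f, c("C", "H", "O")),
    yes = 25L, no = 26L),
  `25` = list(
    name = "polyphenolic",
    text = "Does it carry two or more phenolic hydroxyl groups?",
    pred = function(f, lk) .cnt(f, "phenol_OH") >= 2,
    yes = "III", no = "I"),
  `26` = list(
    name = "acid_derivative_substituent",
    text = "Does it carry a carbamate or sulfonate/sulfamate substituent?",
    pred = function(f, lk) {
      .cnt(f, "carbamate") > 0 || .cnt(f, "sulfonate_group") > 0
    },
    yes = "III", no = 27L),
  `27` = list(
    name = "sulfur_substituent",
    text = "Does it carry a thiol, sulfide or other sulfur substituent?",
    pred = function(f, lk) {
      .cnt(f, "thio_divalent") > 0 || .cnt(f, "s_nondivalent") > 0
    },
    yes = "III", no = 28L),
  `28` = list(
    name = "aromatic_amine_nitro_azo",
    text = "Does it carry an aromatic amine, nitro, nitroso or azo substituent?",
    pred = function(f, lk) {
      (.cnt(f, "arylamine") + .cnt(f, "arom_nitro") + .cnt(f, "arom_azo") +
         .cnt(f, "n_nitroso")) > 0
    },
    yes = "III", no = 32L),
  `32` = list(
    name = "other_nitrogen_substituent",
    text = paste("Does it carry any other nitrogen function (amide, nitrile,",
                 "amine, imine or aliphatic nitro)?"),
    pred = function(f, lk) {
      (.cnt(f, "amide") + .cnt(f, "nitrile") + .cnt(f, "amine_prim_sec") +
         .cnt(f, "amine_tert") + .cnt(f, "imine_like") +
         .cnt(f, "nitro_aliphatic")) > 0
    },
    yes = "III", no = "II")
)

#' Cramer decision-tree question table
#'
#' Returns the full node table of the Cramer classifier: question id, short
#' predicate name, question text and the yes/no targets (a question id or a
#' leaf class I/II/III). Useful for auditing a classification trace.
#'
#' @return A data frame with columns `id`, `name`, `text`, `yes`, `no`.
#' @export
cramer_questions <- function() {
  nodes <- cramer_nodes()
  data.frame(
    id   = as.integer(names(nodes)),
    name = vapply(nodes, `[[`, character(1), "name"),
    text = vapply(nodes, `[[`, character(1), "text"),
    yes  = vapply(nodes, function(n) as.character(n$yes), character(1)),
    no   = vapply(nodes, function(n) as.character(n$no), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Evaluate a single Cramer question against a molecule
#'
#' Re-evaluates the named structural predicate of one decision-tree question.
#' Replaying the questions listed in a classification trace reproduces the
#' recorded answers exactly.
#'
#' @param mol A `ttc_mol` from [parse_structure()].
#' @param id Question id (1-33).
#' @return Logical answer to the question.
#' @export
cramer_answer <- function(mol, id) {
  stopifnot(inherits(mol, "ttc_mol"))
  node <- cramer_nodes()[[as.character(as.integer(id))]]
  if (is.null(node)) stop("unknown Cramer question id: ", id)
  feat <- mol_features(mol)
  isTRUE(node$pred(feat, cramer_lookups()))
}

#' Classify a molecule into a Cramer structural class
#'
#' Walks the decision tree from question 1 and returns the class (I, II or
#' III) together with the full trace of questions visited and their answers.
#' Every parseable structure receives exactly one class.
#'
#' @param mol A `ttc_mol` from [parse_structure()].
#' @param features Optional precomputed feature list (internal batch use).
#' @return A list with `cramer_class` ("I", "II" or "III") and `trace`, a
#'   data frame with columns `question_id`, `question`, `answer`.
#' @examples
#' \donttest{
#' classify_cramer(parse_structure("CCO"))$cramer_class        # "I"
#' classify_cramer(parse_structure("c1ccc2ncccc2c1"))$cramer_class # "III"
#' }
#' @export
classify_cramer <- function(mol, features = NULL) {
  stopifnot(inherits(mol, "ttc_mol"))
  feat <- if (is.null(features)) mol_features(mol) else features
  nodes <- cramer_nodes()
  lk <- cramer_lookups()
  cur <- "1"
  ids <- integer(0); qs <- character(0); ans <- logical(0)
  for (step in seq_len(length(nodes) + 1L)) {
    node <- nodes[[cur]]
    a <- isTRUE(node$pred(feat, lk))
    ids <- c(ids, as.integer(cur)); qs <- c(qs, node$name); ans <- c(ans, a)
    nxt <- if (a) node$yes else node$no
    if (is.character(nxt) && nxt %in% c("I", "II", "III")) {
      return(list(
        cramer_class = nxt,
        trace = data.frame(question_id = ids, question = qs, answer = ans,
                           stringsAsFactors = FALSE)
      ))
    }
    cur <- as.character(nxt)
  }
  stop("Cramer tree did not terminate; node table is inconsistent")
}
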