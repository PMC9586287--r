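#' Parse a SMILES string into a molecule handle
#'
#' Sanitizes a single SMILES string through Open Babel and returns an opaque
#' molecule handle carrying the parsed molecular graph together with its
#' molecular weight, Hill formula and canonical SMILES. Aromaticity follows
#' Open Babel's default perception model; the same model is used for every
#' SMARTS match in the package, so classification is a pure function of the
#' canonical structure.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `ttc_mol` with fields `smiles` (input),
#'   `cansmi` (canonical SMILES), `mw` (g/mol), `formula`, `elements`
#'   (character vector of element symbols present, hydrogens included) and
#'   `obmol` (the Open Babel molecule reference).
#' @examples
#' \donttest{
#' m <- parse_structure("CCO")
#' m$mw       # ~46.07
#' m$elements # "C" "H" "O"
#' }
#' @export
parse_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop_parse(smiles, "SMILES must be a single non-empty string")
  }
  smiles <- trimws(smiles)
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) m),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) != 1L) {
    stop_parse(smiles, "Open Babel could not parse the SMILES string")
  }
  props <- ChemmineOB::prop_OB(mols[[1L]])
  mw <- as.numeric(props$MW)
  if (!is.finite(mw) || mw <= 0) {
    stop_parse(smiles, "parsed structure has no positive molecular weight")
  }
  structure(
    list(
      smiles   = smiles,
      cansmi   = sub("\\s+$", "", as.character(props$cansmiNS)),
      mw       = mw,
      formula  = as.character(props$formula),
      elements = formula_elements(as.character(props$formula)),
      obmol    = mols[[1L]]
    ),
    class = "ttc_mol"
  )
}

#' @export
print.ttc_mol <- function(x, ...) {
  cat("<ttc_mol> ", x$cansmi, "  (", x$formula, ", MW ",
      formatC(x$mw, format = "f", digits = 2), " g/mol)\n", sep = "")
  invisible(x)
}

# Structured parse error so callers can collect rejects instead of dying.
stop_parse <- function(smiles, msg) {
  cond <- structure(
    class = c("ttcmoe_parse_error", "error", "condition"),
    list(message = sprintf("%s [smiles: %s]", msg,
                           if (is.character(smiles)) smiles else "<non-string>"),
         call = sys.call(-1), smiles = smiles)
  )
  stop(cond)
}

# Element symbols from a Hill formula string such as "C7H8N2O" or "C2H6O".
formula_elements <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?", formula)[[1L]]
  if (m[1L] == -1L) return(character(0))
  sort(unique(regmatches(formula, gregexpr("[A-Z][a-z]?", formula))[[1L]]))
}

# Count matches of one SMARTS pattern across a list of ttc_mol handles.
smarts_count <- function(mols, pattern) {
  if (length(mols) == 0L) return(integer(0))
  obrefs <- lapply(mols, function(m) m$obmol)
  as.integer(ChemmineOB::smartsSearch_OB(obrefs, pattern, uniqueMatches = TRUE))
}

# The named SMARTS battery used by the functional-group detectors and the
# Cramer tree. Patterns are evaluated once per molecule set; predicates then
# work off the resulting count matrix.
feature_patterns <- function() {
  c(
    ring_atom          = "[R]",
    fused_ring_atom    = "[R2]",
    aromatic_atom      = "[a]",
    heteroaromatic     = "[a;!#6]",
    hetero_ring_atom   = "[!#6;!#1;R]",
    ring56_O           = "[#8X2;r5,r6]",
    ring56_N           = "[#7X3;r5,r6]",
    small_ring_carbon  = "[#6;r3,r4]",
    lactone            = "[#6;R](=[OX1])[#8;R]",
    lactone_unsat      = "[#8;R][#6;R](=[OX1])[#6X3]=[#6X3]",
    cc_unsat           = "[CX3]=[CX3]",
    cc_triple          = "[CX2]#[CX2]",
    conj_enone         = "[CX3]=[CX3][CX3]=[OX1]",
    conj_diene         = "[CX3]=[CX3][CX3]=[CX3]",
    hydroxyl           = "[OX2H]",
    phenol_OH          = "[c][OX2H]",
    aldehyde           = "[CX3H1]=[OX1]",
    ketone             = "[#6][CX3](=[OX1])[#6]",
    carboxylic_acid    = "[CX3](=[OX1])[OX2H]",
    carboxylate_anion  = "[CX3](=[OX1])[OX1-]",
    ester              = "[CX3](=[OX1])[OX2][#6]",
    ether              = "[OD2]([#6])[#6]",
    peroxide           = "[OX2][OX2]",
    amine_prim_sec     = "[NX3;H2,H1;!$(NC=O);!$(NN)]",
    amine_tert         = "[NX3;H0;!$(NC=O);!$(N=O);!$(NN);!$([N+])]",
    amide              = "[NX3][CX3]=[OX1]",
    carbamate          = "[NX3][CX3](=[OX1])[OX2][#6]",
    nitrile            = "[NX1]#[CX2]",
    imine_like         = "[NX2]=[#6]",
    nitro_aliphatic    = "[CX4][NX3+](=[OX1])[O-]",
    n_nitroso          = "[NX3][NX2]=[OX1]",
    azo_aliphatic      = "[C][NX2]=[NX2][C]",
    triazene           = "[#7][NX2]=[NX2]",
    isocyanate         = "[NX2]=[CX2]=[OX1]",
    acyl_halide        = "[CX3](=[OX1])[F,Cl,Br,I]",
    quaternary_N       = "[NX4+]",
    thio_divalent      = "[SX2]",
    s_nondivalent      = "[#16;!X2]",
    sulfonate_group    = "[SX4](=[OX1])(=[OX1])",
    sulfonate_ester    = "[SX4](=[OX1])(=[OX1])[OX2][#6]",
    sulfonamide        = "[SX4](=[OX1])(=[OX1])[NX3]",
    arom_fused         = "[a;R2]",
    arylamine          = "[NX3;H2,H1;!$(NC=O);!$(NN)][c]",
    arom_nitro         = "[c][NX3+](=[OX1])[O-]",
    arom_azo           = "[c][NX2]=[NX2][c]",
    phosphorus         = "[#15]",
    metal_on_carbon    = "[#3,#4,#5,#11,#12,#13,#14,#19,#20,#22,#24,#25,#26,#27,#28,#29,#30,#32,#33,#50,#51,#80,#82]~[#6]"
  )
}

# Batch-compute the feature count matrix (one row per molecule, one column
# per named pattern). Returns a plain integer matrix with pattern names.
compute_features <- function(mols) {
  pats <- feature_patterns()
  if (length(mols) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = length(pats),
                  dimnames = list(NULL, names(pats))))
  }
  counts <- vapply(pats, function(p) smarts_count(mols, p),
                   integer(length(mols)))
  if (length(mols) == 1L) counts <- matrix(counts, nrow = 1,
                                           dimnames = list(NULL, names(pats)))
  counts
}

# Per-molecule feature list handed to predicates: pattern counts, element
# set and canonical SMILES.
mol_features <- function(mol, counts = NULL) {
  if (is.null(counts)) counts <- compute_features(list(mol))[1L, ]
  list(
    counts   = counts,
    elements = mol$elements,
    cansmi   = mol$cansmi,
    mw       = mol$mw
  )
}

# Canonicalize a vector of SMILES (used for lookup-list membership so that
# users can write lists in any valid SMILES form).
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) parse_structure(s)$cansmi, character(1),
         USE.NAMES = FALSE)
}
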