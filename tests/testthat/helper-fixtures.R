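# Shared in-memory fixtures. Everything is generated at test time; no files
# are shipped.

mol_cache <- new.env(parent = emptyenv())

# Parse once per session; SMARTS batteries are rerun per call anyway.
get_mol <- function(smiles) {
  key <- smiles
  if (is.null(mol_cache[[key]])) mol_cache[[key]] <- parse_structure(smiles)
  mol_cache[[key]]
}

# A tiny chemical table spanning all five categories.
tiny_chemicals <- function() {
  data.frame(
    chem_id = c("c_eth", "c_quin", "c_gbl", "c_tep", "c_nb"),
    smiles = c("CCO", "c1ccc2ncccc2c1", "O=C1CCCO1",
               "CCOP(=O)(OCC)OCC", "O=[N+]([O-])c1ccccc1"),
    stringsAsFactors = FALSE
  )
}

# Minimal pod/exposure tables keyed by chem_id for MoE-level tests.
toy_moe_table <- function(ids, moes, category = NULL) {
  out <- data.frame(chem_id = ids, pod_type = "TTC", pod = moes,
                    exposure_upper95 = 1, moe = moes, lt1 = moes < 1,
                    stringsAsFactors = FALSE)
  if (!is.null(category)) out$ttc_category <- category
  out
}

# Write a full synthetic bundle and return its paths.
make_bundle_dir <- function(n = 60, seed = 7, ttc_consistent = TRUE,
                            dir = withr::local_tempdir(.local_envir =
                                                         parent.frame())) {
  write_bundle(dir, n = n, seed = seed, ttc_consistent = ttc_consistent)
  list(
    dir = dir,
    chemicals = file.path(dir, "chemicals.csv"),
    bioactivity = file.path(dir, "bioactivity.csv"),
    pk = file.path(dir, "pk.csv"),
    noael = file.path(dir, "noael.csv"),
    exposure = file.path(dir, "exposure.csv")
  )
}
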