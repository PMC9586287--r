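#' Default genotoxicity structural-alert table
#'
#' Loads the versioned alert table shipped with the package: named SMARTS
#' patterns covering the classic direct-acting and metabolically activated
#' genotoxin classes (nitroarenes, arylamines, N-nitroso compounds, epoxides,
#' azo dyes, hydrazines, activated halides, Michael acceptors, aromatic
#' N-oxides and alkylating sulfonate/sulfate/phosphonate esters). The table
#' is a documented subset of the full mutagenicity rulebooks used by
#' structure-alert screeners; users may supply their own table with the same
#' columns to any function that accepts `alerts`.
#'
#' @param path Optional path to an alternative alert CSV with columns
#'   `name`, `smarts` (and optionally `note`).
#' @return A data frame with columns `name`, `smarts`, `note`.
#' @export
default_genotox_alerts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "genotox_alerts.csv", package = "ttcmoe")
  }
  stopifnot(file.exists(path))
  al <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "smarts") %in% names(al))) {
    stop("alert table must have columns 'name' and 'smarts'")
  }
  al
}

#' Detect anti-cholinesterase functional groups
#'
#' Substructure detection of the two ester classes treated as cholinesterase
#' inhibitors: carbamate esters (N-C(=O)-O-C) and organophosphate esters
#' (phosphorus double-bonded to O or S and carrying at least one O- or
#' S-linked carbon ester arm; thiophosphates count).
#'
#' @param mol A `ttc_mol` from [parse_structure()].
#' @return Named logical vector `c(is_carbamate_ester, is_organophosphate_ester)`.
#' @examples
#' \donttest{
#' detect_ache_groups(parse_structure("CCOP(=O)(OCC)OCC")) # organophosphate
#' detect_ache_groups(parse_structure("CNC(=O)Oc1ccccc1")) # carbamate
#' }
#' @export
detect_ache_groups <- function(mol) {
  stopifnot(inherits(mol, "ttc_mol"))
  carb <- smarts_count(list(mol), "[NX3][CX3](=[OX1])[OX2][#6]") > 0
  op_pattern <- paste0(
    "[$([#15](=[OX1])[OX2][#6]),$([#15](=[OX1])[SX2][#6]),",
    "$([#15](=[SX1])[OX2][#6]),$([#15](=[SX1])[SX2][#6])]"
  )
  op <- smarts_count(list(mol), op_pattern) > 0
  c(is_carbamate_ester = unname(carb), is_organophosphate_ester = unname(op))
}

#' Detect genotoxicity structural alerts
#'
#' Matches the molecule against a named SMARTS alert table and reports
#' whether any alert fires, together with the names of the firing alerts.
#'
#' @param mol A `ttc_mol` from [parse_structure()].
#' @param alerts Alert table as returned by [default_genotox_alerts()].
#' @return A list with `flag` (logical) and `alert_names` (character).
#' @export
detect_genotoxic_alerts <- function(mol, alerts = default_genotox_alerts()) {
  stopifnot(inherits(mol, "ttc_mol"))
  hits <- vapply(alerts$smarts,
                 function(p) smarts_count(list(mol), p) > 0, logical(1))
  list(flag = any(hits), alert_names = alerts$name[hits])
}

# Dioxin-like / PCB-like cores used by the Kroes exclusion gate.
.kroes_cores <- list(
  dibenzodioxin = "c1ccc2c(c1)Oc1ccccc1O2",
  dibenzofuran  = "c1ccc2c(c1)oc1ccccc12",
  biphenyl      = "c1ccc(-c2ccccc2)cc1"
)

#' Kroes-domain exclusion gate
#'
#' Annotates structures that fall outside the chemical domain of the TTC
#' concept: organometallics (a metal or metalloid atom covalently bonded to
#' carbon) and high-potency carcinogen classes (polyhalogenated
#' dibenzo-p-dioxin, dibenzofuran and biphenyl cores). The gate is an
#' annotation only; excluded chemicals are carried through the workflow and
#' still receive a TTC assignment.
#'
#' @param mol A `ttc_mol` from [parse_structure()].
#' @return A list with `kroes_excluded` (logical) and `reason`
#'   (character scalar or `NA`).
#' @export
kroes_gate <- function(mol) {
  stopifnot(inherits(mol, "ttc_mol"))
  if (smarts_count(list(mol), feature_patterns()[["metal_on_carbon"]]) > 0) {
    return(list(kroes_excluded = TRUE, reason = "organometallic"))
  }
  n_halogen <- smarts_count(list(mol), "[F,Cl,Br,I]")
  if (n_halogen >= 2) {
    for (nm in c("dibenzodioxin", "dibenzofuran")) {
      if (smarts_count(list(mol), .kroes_cores[[nm]]) > 0) {
        return(list(kroes_excluded = TRUE,
                    reason = "high-potency carcinogen class"))
      }
    }
  }
  if (n_halogen >= 4 &&
      smarts_count(list(mol), .kroes_cores[["biphenyl"]]) > 0) {
    return(list(kroes_excluded = TRUE,
                reason = "high-potency carcinogen class"))
  }
  list(kroes_excluded = FALSE, reason = NA_character_)
}

#' Volatility flag from boiling point and/or vapor pressure
#'
#' A chemical is flagged volatile when its boiling point is below 260 degrees C
#' or its vapor pressure exceeds 0.1 mmHg. Returns `NA` when neither datum is
#' available. Volatile chemicals may be poor candidates for an oral-route
#' TTC screen and can be filtered out of large libraries.
#'
#' @param bp_celsius Boiling point in degrees Celsius, or `NA`.
#' @param vp_mmHg Vapor pressure in mmHg, or `NA`; must be non-negative.
#' @return `TRUE`, `FALSE` or `NA` (unknown).
#' @export
volatility_flag <- function(bp_celsius = NA_real_, vp_mmHg = NA_real_) {
  stopifnot(length(bp_celsius) == 1L, length(vp_mmHg) == 1L)
  if (!is.na(vp_mmHg) && vp_mmHg < 0) stop("vapor pressure must be >= 0")
  if (is.na(bp_celsius) && is.na(vp_mmHg)) return(NA)
  isTRUE(bp_celsius < 260) || isTRUE(vp_mmHg > 0.1)
}
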