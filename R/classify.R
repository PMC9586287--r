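#' Derive structural profiles for a chemical table
#'
#' Runs every structure-based step on a table of chemicals: anti-cholinesterase
#' functional-group detection (carbamate and organophosphate esters),
#' genotoxicity structural alerts, the Kroes-domain annotation, the Cramer
#' decision tree and the volatility flag. Rows whose SMILES cannot be parsed
#' are reported in the `rejects` attribute and omitted from the profile table;
#' they never abort the run.
#'
#' @param chemicals Data frame with columns `chem_id`, `smiles` and optionally
#'   `mw`, `bp_celsius`, `vp_mmHg`, `casrn`, `name`.
#' @param alerts Genotoxicity alert table, see [default_genotox_alerts()].
#' @return A data frame (one row per parseable chemical) with columns
#'   `chem_id`, `cansmi`, `mw`, `is_carbamate_ester`,
#'   `is_organophosphate_ester`, `genotoxic_alert`, `genotoxic_alert_names`
#'   (comma-joined), `kroes_excluded`, `kroes_reason`, `cramer_class`,
#'   `volatile_flag`. The per-chemical Cramer traces are attached as the
#'   `traces` attribute (a named list of data frames) and unparsable rows as
#'   the `rejects` attribute.
#' @export
classify_chemicals <- function(chemicals, alerts = default_genotox_alerts()) {
  stopifnot(is.data.frame(chemicals),
            all(c("chem_id", "smiles") %in% names(chemicals)))
  if (anyDuplicated(chemicals$chem_id)) {
    stop("chem_id values must be unique")
  }
  n <- nrow(chemicals)
  mols <- vector("list", n)
  reject_msg <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mols[i] <- list(tryCatch(parse_structure(chemicals$smiles[i]),
                             ttcmoe_parse_error = function(e) {
                               reject_msg[i] <<- conditionMessage(e)
                               NULL
                             }))
  }
  ok <- !vapply(mols, is.null, logical(1))
  rejects <- data.frame(chem_id = chemicals$chem_id[!ok],
                        smiles = chemicals$smiles[!ok],
                        reason = reject_msg[!ok], stringsAsFactors = FALSE)
  mols <- mols[ok]
  ids <- chemicals$chem_id[ok]
  if (length(mols) == 0L) {
    out <- empty_profile_table()
    attr(out, "rejects") <- rejects
    attr(out, "traces") <- list()
    return(out)
  }

  counts <- compute_features(mols)
  alert_hits <- vapply(alerts$smarts, function(p) smarts_count(mols, p) > 0,
                       logical(length(mols)))
  if (length(mols) == 1L) alert_hits <- matrix(alert_hits, nrow = 1)

  carb <- counts[, "carbamate"] > 0
  op <- smarts_count(mols, paste0(
    "[$([#15](=[OX1])[OX2][#6]),$([#15](=[OX1])[SX2][#6]),",
    "$([#15](=[SX1])[OX2][#6]),$([#15](=[SX1])[SX2][#6])]")) > 0

  cls <- character(length(mols))
  traces <- vector("list", length(mols))
  kroes_ex <- logical(length(mols))
  kroes_why <- rep(NA_character_, length(mols))
  for (i in seq_along(mols)) {
    feat <- mol_features(mols[[i]], counts[i, ])
    cr <- classify_cramer(mols[[i]], features = feat)
    cls[i] <- cr$cramer_class
    traces[[i]] <- cr$trace
    kg <- kroes_gate(mols[[i]])
    kroes_ex[i] <- kg$kroes_excluded
    kroes_why[i] <- kg$reason
  }
  names(traces) <- ids

  bp <- if ("bp_celsius" %in% names(chemicals)) {
    chemicals$bp_celsius[ok]
  } else rep(NA_real_, length(mols))
  vp <- if ("vp_mmHg" %in% names(chemicals)) {
    chemicals$vp_mmHg[ok]
  } else rep(NA_real_, length(mols))
  vol <- mapply(volatility_flag, bp, vp)

  out <- data.frame(
    chem_id = ids,
    cansmi = vapply(mols, function(m) m$cansmi, character(1)),
    mw = vapply(mols, function(m) m$mw, numeric(1)),
    is_carbamate_ester = unname(carb),
    is_organophosphate_ester = unname(op),
    genotoxic_alert = apply(alert_hits, 1L, any),
    genotoxic_alert_names = apply(alert_hits, 1L, function(h) {
      paste(alerts$name[h], collapse = "; ")
    }),
    kroes_excluded = kroes_ex,
    kroes_reason = kroes_why,
    cramer_class = cls,
    volatile_flag = as.logical(vol),
    stringsAsFactors = FALSE
  )
  attr(out, "rejects") <- rejects
  attr(out, "traces") <- traces
  out
}

empty_profile_table <- function() {
  data.frame(
    chem_id = character(0), cansmi = character(0), mw = numeric(0),
    is_carbamate_ester = logical(0), is_organophosphate_ester = logical(0),
    genotoxic_alert = logical(0), genotoxic_alert_names = character(0),
    kroes_excluded = logical(0), kroes_reason = character(0),
    cramer_class = character(0), volatile_flag = logical(0),
    stringsAsFactors = FALSE
  )
}
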