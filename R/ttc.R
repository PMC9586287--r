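#' Threshold-of-toxicological-concern category values
#'
#' The five TTC categories and their human exposure thresholds in
#' micrograms per kg body weight per day. Cramer classes I/II/III carry
#' 30/9/1.5; structures flagged as cholinesterase inhibitors
#' (organophosphate or carbamate esters) carry 0.3; structures with a
#' genotoxicity alert carry 0.0025 when the genotoxicity filter is applied.
#' The thresholds derive from the 5th percentiles of per-class NOAEL
#' distributions divided by a 100-fold safety factor.
#'
#' @return A data frame with columns `category` and `ttc_ug_per_kg_d`,
#'   ordered from most to least conservative.
#' @export
ttc_values <- function() {
  data.frame(
    category = c("GENOTOXIC", "ANTICHOLINESTERASE", "CRAMER_III",
                 "CRAMER_II", "CRAMER_I"),
    ttc_ug_per_kg_d = c(0.0025, 0.3, 1.5, 9, 30),
    stringsAsFactors = FALSE
  )
}

#' Look up the TTC value for a category
#'
#' @param category One of `GENOTOXIC`, `ANTICHOLINESTERASE`, `CRAMER_III`,
#'   `CRAMER_II`, `CRAMER_I` (vectorized).
#' @return TTC value(s) in ug/kg-bw/d.
#' @examples
#' ttc_value("CRAMER_II")  # 9
#' @export
ttc_value <- function(category) {
  tab <- ttc_values()
  idx <- match(category, tab$category)
  if (anyNA(idx)) {
    stop("unknown TTC category: ",
         paste(unique(category[is.na(idx)]), collapse = ", "))
  }
  tab$ttc_ug_per_kg_d[idx]
}

#' Assign TTC categories and values from structural profiles
#'
#' Maps each structural profile to a TTC category under the stated
#' genotoxicity-filter setting. Precedence is most-conservative-first:
#' GENOTOXIC (only when the filter is on and an alert fired), then
#' ANTICHOLINESTERASE (either ester flag), then the Cramer class.
#' Kroes-excluded chemicals are still assigned (the exclusion is an
#' annotation, not a drop). Turning the filter off never changes the
#' assignment of chemicals without alerts.
#'
#' @param profiles Profile table from [classify_chemicals()].
#' @param genotox_filter Logical; apply the genotoxicity filter?
#' @return A data frame with columns `chem_id`, `category`,
#'   `ttc_ug_per_kg_d`, `genotox_filter_applied`, `kroes_excluded`.
#' @export
assign_ttc <- function(profiles, genotox_filter = TRUE) {
  stopifnot(is.data.frame(profiles),
            all(c("chem_id", "is_carbamate_ester", "is_organophosphate_ester",
                  "genotoxic_alert", "cramer_class") %in% names(profiles)))
  if (any(is.na(profiles$cramer_class)) ||
      !all(profiles$cramer_class %in% c("I", "II", "III"))) {
    stop("every profile must carry a Cramer class of I, II or III")
  }
  category <- paste0("CRAMER_", profiles$cramer_class)
  ache <- profiles$is_carbamate_ester | profiles$is_organophosphate_ester
  category[ache] <- "ANTICHOLINESTERASE"
  if (isTRUE(genotox_filter)) {
    category[profiles$genotoxic_alert] <- "GENOTOXIC"
  }
  data.frame(
    chem_id = profiles$chem_id,
    category = category,
    ttc_ug_per_kg_d = ttc_value(category),
    genotox_filter_applied = isTRUE(genotox_filter),
    kroes_excluded = if ("kroes_excluded" %in% names(profiles)) {
      profiles$kroes_excluded
    } else FALSE,
    stringsAsFactors = FALSE
  )
}
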