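#' Filter NOAEL records to the usable subset
#'
#' Keeps rows whose `type` is "NOAEL", `units` is "mg/kg-day" and `route` is
#' "oral". Matching is case-insensitive and whitespace-trimmed; an empty
#' result is valid.
#'
#' @param records Data frame with columns `chem_id`, `type`, `value`,
#'   `units`, `route`.
#' @return The conforming rows.
#' @export
filter_noael_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("chem_id", "type", "value", "units", "route") %in%
                  names(records)))
  norm <- function(x) tolower(trimws(as.character(x)))
  keep <- norm(records$type) == "noael" &
    norm(records$units) == "mg/kg-day" &
    norm(records$route) == "oral"
  records[keep, , drop = FALSE]
}

#' NOAEL-based point of departure for one chemical
#'
#' With 20 or more NOAEL values the PoD is the type-2 5th percentile of the
#' collection; with fewer it is the lowest available value. Duplicate values
#' are retained.
#'
#' @param values Positive NOAEL values in mg/kg-day (already filtered).
#' @return A list with `pod` (mg/kg-bw/d), `n_records_used` and
#'   `method_note` ("p5_type2" or "minimum").
#' @examples
#' noael_pod(c(3, 1, 4, 1, 5))$pod   # 1 (minimum branch)
#' noael_pod(1:20)$pod               # 1.5 (5th-percentile branch)
#' @export
noael_pod <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("NOAEL values must be positive")
  }
  if (length(values) >= 20L) {
    list(pod = quantile_type2(values, 0.05), n_records_used = length(values),
         method_note = "p5_type2")
  } else {
    list(pod = min(values), n_records_used = length(values),
         method_note = "minimum")
  }
}

#' NOAEL points of departure for a record table
#'
#' Applies [filter_noael_records()] and then [noael_pod()] per chemical.
#' Chemicals with no conforming records are omitted (their ids are returned
#' in the `omitted` attribute).
#'
#' @param records Raw NOAEL record table.
#' @return Data frame with `chem_id`, `pod_type` ("NOAEL"), `pod`,
#'   `n_records_used`, `method_note`.
#' @export
noael_pod_table <- function(records) {
  kept <- filter_noael_records(records)
  ids <- sort(unique(records$chem_id))
  res <- lapply(ids, function(id) {
    v <- kept$value[kept$chem_id == id]
    if (length(v) == 0L) return(NULL)
    p <- noael_pod(v)
    data.frame(chem_id = id, pod_type = "NOAEL", pod = p$pod,
               n_records_used = p$n_records_used,
               method_note = p$method_note, stringsAsFactors = FALSE)
  })
  omitted <- ids[vapply(res, is.null, logical(1))]
  out <- do.call(rbind, c(res[!vapply(res, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(chem_id = character(0), pod_type = character(0),
                      pod = numeric(0), n_records_used = integer(0),
                      method_note = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "omitted") <- omitted
  out
}

#' TTC points of departure in mg/kg-bw/d
#'
#' Converts TTC assignments (ug/kg-bw/d) to mg/kg-bw/d points of departure.
#' The microgram-to-milligram division by 1000 happens here, exactly once in
#' the workflow.
#'
#' @param assignments Table from [assign_ttc()].
#' @return Data frame with `chem_id`, `pod_type` ("TTC"), `pod`,
#'   `ttc_category`.
#' @export
ttc_pod_table <- function(assignments) {
  stopifnot(all(c("chem_id", "category", "ttc_ug_per_kg_d") %in%
                  names(assignments)))
  data.frame(chem_id = assignments$chem_id, pod_type = "TTC",
             pod = assignments$ttc_ug_per_kg_d / 1000,
             ttc_category = assignments$category, stringsAsFactors = FALSE)
}

#' OED points of departure
#'
#' @param oed Table from [derive_oed()].
#' @return Data frame with `chem_id`, `pod_type` ("OED"), `pod`.
#' @export
oed_pod_table <- function(oed) {
  stopifnot(all(c("chem_id", "oed_mg_kg_d") %in% names(oed)))
  data.frame(chem_id = oed$chem_id, pod_type = "OED",
             pod = oed$oed_mg_kg_d, stringsAsFactors = FALSE)
}
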