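#' Select the exposure estimate for each chemical
#'
#' Prefers the newer consensus model (SEEM3) and falls back to SEEM2 when a
#' chemical has no SEEM3 row. Chemicals with neither are excluded from MoE
#' tables; their ids are returned in the `excluded` attribute.
#'
#' @param exposures Data frame with columns `chem_id`,
#'   `source` ("SEEM3"/"SEEM2"), `median`, `upper95` (mg/kg-bw/d).
#' @return One row per chemical with the selected source, median and
#'   upper95.
#' @export
select_exposure <- function(exposures) {
  stopifnot(all(c("chem_id", "source", "median", "upper95") %in%
                  names(exposures)))
  if (!all(exposures$source %in% c("SEEM3", "SEEM2"))) {
    stop("exposure source must be SEEM3 or SEEM2")
  }
  if (any(exposures$upper95 < exposures$median, na.rm = TRUE)) {
    stop("upper95 must be >= median for every exposure row")
  }
  ids <- sort(unique(exposures$chem_id))
  pick <- lapply(ids, function(id) {
    rows <- exposures[exposures$chem_id == id, , drop = FALSE]
    s3 <- rows[rows$source == "SEEM3", , drop = FALSE]
    if (nrow(s3) > 0) return(s3[1L, c("chem_id", "source", "median", "upper95")])
    s2 <- rows[rows$source == "SEEM2", , drop = FALSE]
    if (nrow(s2) > 0) return(s2[1L, c("chem_id", "source", "median", "upper95")])
    NULL
  })
  out <- do.call(rbind, c(pick[!vapply(pick, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  attr(out, "excluded") <- ids[vapply(pick, is.null, logical(1))]
  out
}

#' Margins of exposure for a PoD table
#'
#' MoE = PoD / upper-95 exposure. Chemicals without an exposure row are
#' dropped (counted in the `n_no_exposure` attribute). A chemical is flagged
#' (`lt1`) when its MoE is strictly below one; MoE exactly 1 is not flagged.
#'
#' @param pods PoD table with `chem_id`, `pod_type`, `pod` (and optionally
#'   `ttc_category`).
#' @param exposures Selected exposure table from [select_exposure()].
#' @return Data frame with `chem_id`, `pod_type`, `pod`, `exposure_upper95`,
#'   `exposure_source`, `moe`, `lt1` (+ `ttc_category` when present),
#'   ordered by ascending MoE with `rank` filled in.
#' @export
compute_moe_table <- function(pods, exposures) {
  stopifnot(all(c("chem_id", "pod_type", "pod") %in% names(pods)),
            all(c("chem_id", "upper95") %in% names(exposures)))
  if (any(pods$pod <= 0)) stop("every PoD must be > 0")
  if (any(exposures$upper95 <= 0)) stop("exposure upper95 must be > 0")
  idx <- match(pods$chem_id, exposures$chem_id)
  miss <- is.na(idx)
  out <- data.frame(
    chem_id = pods$chem_id[!miss],
    pod_type = pods$pod_type[!miss],
    pod = pods$pod[!miss],
    exposure_upper95 = exposures$upper95[idx[!miss]],
    exposure_source = exposures$source[idx[!miss]],
    stringsAsFactors = FALSE
  )
  if ("ttc_category" %in% names(pods)) {
    out$ttc_category <- pods$ttc_category[!miss]
  }
  out$moe <- out$pod / out$exposure_upper95
  out$lt1 <- out$moe < 1
  ord <- order(out$moe, out$chem_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_no_exposure") <- sum(miss)
  out
}

#' Top-ranked chemicals by smallest MoE
#'
#' Ascending MoE, ties broken by chem_id; the first `top_n` rows are
#' returned (all rows when `top_n` exceeds the table size).
#'
#' @param results MoE table from [compute_moe_table()].
#' @param top_n Number of chemicals to return (>= 1).
#' @return The `top_n` highest-priority rows.
#' @export
rank_by_moe <- function(results, top_n = 25L) {
  if (nrow(results) == 0L) stop("'results' must be non-empty")
  if (top_n < 1L) stop("top_n must be >= 1")
  ord <- order(results$moe, results$chem_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Per-category MoE summary
#'
#' Counts, percentages, MoE<1 counts and median MoEs (type-2 quantile at
#' p = 0.5) per TTC category, plus a Total row.
#'
#' @param results MoE table carrying a `ttc_category` column.
#' @return Data frame with columns `category`, `n`, `pct_of_total`,
#'   `n_lt1`, `pct_lt1_in_class`, `median_moe`.
#' @export
summarize_by_category <- function(results) {
  stopifnot("ttc_category" %in% names(results))
  cats <- c("GENOTOXIC", "ANTICHOLINESTERASE", "CRAMER_III", "CRAMER_II",
            "CRAMER_I")
  cats <- cats[cats %in% results$ttc_category]
  total <- nrow(results)
  one_row <- function(label, rows) {
    data.frame(
      category = label,
      n = nrow(rows),
      pct_of_total = 100 * nrow(rows) / total,
      n_lt1 = sum(rows$lt1),
      pct_lt1_in_class = if (nrow(rows) > 0) 100 * mean(rows$lt1) else NA_real_,
      median_moe = if (nrow(rows) > 0) quantile_type2(rows$moe, 0.5) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  per_cat <- lapply(cats, function(cc) {
    one_row(cc, results[results$ttc_category == cc, , drop = FALSE])
  })
  do.call(rbind, c(per_cat, list(one_row("Total", results)),
                   list(make.row.names = FALSE)))
}
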