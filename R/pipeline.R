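#' Build a pipeline run configuration
#'
#' Collects the input paths, requested PoD types and switches for one
#' reproducible prioritization run. All randomness in the run flows from the
#' single seed, which is echoed in the run report.
#'
#' @param chemicals,bioactivity,pk,noael,exposure Input CSV paths (only the
#'   tables needed by the requested PoD types are required: `bioactivity` and
#'   `pk` for "OED", `noael` for "NOAEL").
#' @param pod_types Subset of c("TTC", "OED", "NOAEL").
#' @param genotox_filter Apply the genotoxicity filter when assigning TTCs?
#' @param top_n Size of the priority list.
#' @param seed Integer seed.
#' @param n_samples Monte Carlo size for the population Css.
#' @param physiology A `ttc_physiology` list (or path to a YAML file).
#' @param alerts_file Optional path to an alternative genotoxicity alert CSV.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `ttc_run_config`.
#' @export
pipeline_config <- function(chemicals, bioactivity = NULL, pk = NULL,
                            noael = NULL, exposure = NULL,
                            pod_types = c("TTC", "OED", "NOAEL"),
                            genotox_filter = FALSE, top_n = 25L, seed = 1L,
                            n_samples = 1000L,
                            physiology = default_physiology(),
                            alerts_file = NULL, out_dir = NULL) {
  pod_types <- match.arg(pod_types, c("TTC", "OED", "NOAEL"),
                         several.ok = TRUE)
  if (is.character(physiology)) physiology <- read_physiology(physiology)
  need <- list(chemicals = chemicals, exposure = exposure)
  if ("OED" %in% pod_types) {
    need <- c(need, list(bioactivity = bioactivity, pk = pk))
  }
  if ("NOAEL" %in% pod_types) need <- c(need, list(noael = noael))
  for (nm in names(need)) {
    if (is.null(need[[nm]])) {
      stop("configuration error: requested PoD types need the '", nm,
           "' table, but no path was given")
    }
    if (!file.exists(need[[nm]])) {
      stop("configuration error: '", nm, "' file not found: ", need[[nm]])
    }
  }
  structure(list(
    paths = list(chemicals = chemicals, bioactivity = bioactivity, pk = pk,
                 noael = noael, exposure = exposure),
    pod_types = pod_types, genotox_filter = isTRUE(genotox_filter),
    top_n = as.integer(top_n), seed = as.integer(seed),
    n_samples = as.integer(n_samples), physiology = physiology,
    alerts_file = alerts_file, out_dir = out_dir
  ), class = "ttc_run_config")
}

#' Run the full margin-of-exposure prioritization pipeline
#'
#' Executes classify -> assign TTC -> (OED derivation) -> (NOAEL PoD) ->
#' exposure selection -> MoE -> ranking -> per-category summary, tracking
#' chemical counts at every stage. When `config$out_dir` is set, the MoE
#' tables, summary, priority list and a JSON run report are written with
#' deterministic formatting, so identical configurations give byte-identical
#' outputs.
#'
#' @param config A `ttc_run_config` from [pipeline_config()].
#' @return A list with `moe` (named list of MoE tables per PoD type),
#'   `summary`, `top`, `assignments`, `profiles` and `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ttc_run_config"))
  chems <- read_chemicals(config$paths$chemicals)
  alerts <- default_genotox_alerts(config$alerts_file)
  profiles <- classify_chemicals(chems, alerts = alerts)
  rejects <- attr(profiles, "rejects")
  assignments <- assign_ttc(profiles, genotox_filter = config$genotox_filter)

  exposure_raw <- read_table_csv(config$paths$exposure,
                                 c("chem_id", "source", "median", "upper95"))
  exposure <- select_exposure(exposure_raw)

  counts <- list(
    n_input = nrow(chems) + nrow(rejects),
    n_rejected = nrow(rejects),
    n_classified = nrow(profiles),
    n_with_exposure = sum(profiles$chem_id %in% exposure$chem_id)
  )

  pods <- list()
  pods$TTC <- ttc_pod_table(assignments)
  if ("OED" %in% config$pod_types) {
    bio <- read_table_csv(config$paths$bioactivity, c("chem_id", "ac50_uM"))
    pk <- read_table_csv(config$paths$pk, c("chem_id", "fup", "clint"))
    mw <- profiles[, c("chem_id", "mw")]
    oed <- derive_oed(bio, pk, mw, phys = config$physiology,
                      n_samples = config$n_samples, seed = config$seed)
    pods$OED <- oed_pod_table(oed)
    counts$n_oed <- nrow(pods$OED)
  }
  if ("NOAEL" %in% config$pod_types) {
    noael <- read_table_csv(config$paths$noael,
                            c("chem_id", "type", "value", "units", "route"))
    pods$NOAEL <- noael_pod_table(noael)
    counts$n_noael <- nrow(pods$NOAEL)
  }
  pods <- pods[intersect(c("TTC", "OED", "NOAEL"), config$pod_types)]

  cat_lookup <- assignments[, c("chem_id", "category")]
  moe <- lapply(pods, function(p) {
    if (!"ttc_category" %in% names(p)) {
      p$ttc_category <- cat_lookup$category[match(p$chem_id,
                                                  cat_lookup$chem_id)]
    }
    compute_moe_table(p, exposure)
  })

  summary_tab <- summarize_by_category(moe$TTC)
  top_tab <- rank_by_moe(moe[[1L]], config$top_n)

  report <- list(
    package_version = as.character(utils::packageVersion("ttcmoe")),
    seed = config$seed,
    genotox_filter = config$genotox_filter,
    pod_types = config$pod_types,
    n_samples = config$n_samples,
    aromaticity_model = "openbabel-default",
    inputs = config$paths[!vapply(config$paths, is.null, logical(1))],
    counts = counts,
    n_no_exposure = vapply(moe, function(m) attr(m, "n_no_exposure"),
                           numeric(1))
  )

  result <- list(moe = moe, summary = summary_tab, top = top_tab,
                 assignments = assignments, profiles = profiles,
                 report = report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(moe)) {
      write_table_csv(moe[[nm]],
                      file.path(config$out_dir,
                                paste0("moe_", tolower(nm), ".csv")))
    }
    write_table_csv(summary_tab, file.path(config$out_dir, "summary.csv"))
    write_table_csv(top_tab, file.path(config$out_dir, "top_n.csv"))
    write_table_csv(assignments,
                    file.path(config$out_dir, "ttc_assignments.csv"))
    jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
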