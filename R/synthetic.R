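# Synthetic study-data generators.
#
# The template panel below is the ground truth of the whole synthetic
# workflow: a hand-curated set of SMILES exemplars per TTC category, each
# validated against a manual walk of the classifier before inclusion, so
# that running the structure pipeline on generated libraries recovers the
# label exactly. Generation samples panel members verbatim (no structural
# perturbation, which could silently change the class).

.template_panel_raw <- list(
  GENOTOXIC = c(
    nitrobenzene              = "O=[N+]([O-])c1ccccc1",
    `2,4-dinitrotoluene`      = "Cc1ccc(cc1[N+](=O)[O-])[N+](=O)[O-]",
    `4-nitroaniline`          = "Nc1ccc(cc1)[N+](=O)[O-]",
    aniline                   = "Nc1ccccc1",
    `o-toluidine`             = "Cc1ccccc1N",
    `N-nitrosodimethylamine`  = "CN(C)N=O",
    `N-nitrosodiethylamine`   = "CCN(CC)N=O",
    glycidol                  = "OCC1CO1",
    `styrene oxide`           = "C1(c2ccccc2)CO1",
    azobenzene                = "c1ccc(cc1)N=Nc1ccccc1",
    phenylhydrazine           = "NNc1ccccc1",
    acrolein                  = "C=CC=O",
    `methyl methanesulfonate` = "COS(C)(=O)=O",
    `benzyl chloride`         = "ClCc1ccccc1"
  ),
  ANTICHOLINESTERASE = c(
    `triethyl phosphate`  = "CCOP(=O)(OCC)OCC",
    `trimethyl phosphate` = "COP(=O)(OC)OC",
    `tributyl phosphate`  = "CCCCOP(=O)(OCCCC)OCCCC",
    malathion             = "CCOC(=O)CC(SP(=S)(OC)OC)C(=O)OCC",
    dimethoate            = "CNC(=O)CSP(=S)(OC)OC",
    chlorpyrifos          = "CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl",
    carbaryl              = "CNC(=O)Oc1cccc2ccccc12",
    carbofuran            = "CNC(=O)Oc1cccc2c1OC(C)(C)C2",
    propoxur              = "CNC(=O)Oc1ccccc1OC(C)C"
  ),
  CRAMER_I = c(
    ethanol           = "CCO",
    isopropanol       = "CC(C)O",
    `1-butanol`       = "CCCCO",
    `acetic acid`     = "CC(=O)O",
    `hexanoic acid`   = "CCCCCC(=O)O",
    `ethyl acetate`   = "CCOC(=O)C",
    `butyl butyrate`  = "CCCC(=O)OCCCC",
    acetone           = "CC(C)=O",
    glycerol          = "OCC(O)CO",
    hexane            = "CCCCCC",
    toluene           = "Cc1ccccc1",
    `benzyl alcohol`  = "OCc1ccccc1",
    anisole           = "COc1ccccc1",
    `benzoic acid`    = "OC(=O)c1ccccc1"
  ),
  CRAMER_II = c(
    `gamma-butyrolactone`  = "O=C1CCCO1",
    `gamma-valerolactone`  = "CC1CCC(=O)O1",
    `gamma-hexalactone`    = "CCC1CCC(=O)O1",
    `gamma-octalactone`    = "CCCCC1CCC(=O)O1",
    `delta-valerolactone`  = "O=C1CCCCO1",
    `delta-hexalactone`    = "CC1CCCC(=O)O1",
    `delta-decalactone`    = "CCCCCC1CCCC(=O)O1",
    `epsilon-caprolactone` = "O=C1CCCCCO1"
  ),
  CRAMER_III = c(
    quinoline          = "c1ccc2ncccc2c1",
    isoquinoline       = "c1ccc2cnccc2c1",
    pyridine           = "c1ccncc1",
    pyrimidine         = "c1cncnc1",
    pyrazine           = "c1cnccn1",
    quinoxaline        = "c1ccc2nccnc2c1",
    `2-methylpyridine` = "Cc1ccccn1",
    furan              = "c1ccoc1",
    thiophene          = "c1ccsc1",
    caffeine           = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    indole             = "c1ccc2[nH]ccc2c1"
  )
)

.panel_env <- new.env(parent = emptyenv())

#' Template panel of SMILES exemplars with known TTC categories
#'
#' @return Data frame with columns `name`, `smiles`, `truth_category`, `mw`.
#' @export
template_panel <- function() {
  if (is.null(.panel_env$panel)) {
    rows <- lapply(names(.template_panel_raw), function(cat) {
      sm <- .template_panel_raw[[cat]]
      data.frame(name = names(sm), smiles = unname(sm), truth_category = cat,
                 stringsAsFactors = FALSE)
    })
    panel <- do.call(rbind, rows)
    panel$mw <- vapply(panel$smiles, function(s) parse_structure(s)$mw,
                       numeric(1), USE.NAMES = FALSE)
    rownames(panel) <- NULL
    .panel_env$panel <- panel
  }
  .panel_env$panel
}

#' Default category mix for synthetic libraries
#'
#' Dominated by Cramer Class III (as environmental libraries are), with
#' smaller Cramer I/II, anti-cholinesterase and genotoxic fractions.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_category_mix <- function() {
  c(GENOTOXIC = 0.10, ANTICHOLINESTERASE = 0.10, CRAMER_I = 0.25,
    CRAMER_II = 0.10, CRAMER_III = 0.45)
}

#' Generate a synthetic chemical library
#'
#' Samples `n` chemicals from the template panel according to the category
#' mix. Each chemical carries a unique id, its SMILES, molecular weight and
#' truth labels. Fully deterministic under a fixed seed.
#'
#' @param n Number of chemicals (>= 1).
#' @param category_mix Named proportions over the five TTC categories
#'   (must sum to 1 within 1e-9).
#' @param seed Integer seed.
#' @return Data frame with columns `chem_id`, `name`, `smiles`, `mw`,
#'   `truth_category`, `truth_kroes_excluded`.
#' @export
generate_chemicals <- function(n, category_mix = default_category_mix(),
                               seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  cats <- names(.template_panel_raw)
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% cats)) {
    stop("category_mix must be named with TTC categories")
  }
  if (any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix proportions must be non-negative and sum to 1")
  }
  panel <- template_panel()
  withr::with_seed(as.integer(seed), {
    drawn_cat <- sample(names(category_mix), n, replace = TRUE,
                        prob = category_mix)
    idx <- vapply(drawn_cat, function(cc) {
      pool <- which(panel$truth_category == cc)
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
  })
  data.frame(
    chem_id = sprintf("chem_%05d", seq_len(n)),
    name = panel$name[idx],
    smiles = panel$smiles[idx],
    mw = panel$mw[idx],
    truth_category = panel$truth_category[idx],
    truth_kroes_excluded = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic AC50 bioactivity rows
#'
#' Per chemical, a uniform-random number of assays in `n_assays_range`, each
#' with a lognormal AC50 (uM).
#'
#' @param chems Chemical table from [generate_chemicals()].
#' @param n_assays_range Integer range (within 1..200) for assays per
#'   chemical.
#' @param logmean,logsd Lognormal parameters of the AC50 distribution
#'   (defaults: median 1 uM, logsd 1.5).
#' @param seed Integer seed.
#' @return Data frame with `chem_id`, `assay_id`, `ac50_uM`.
#' @export
generate_bioactivity <- function(chems, n_assays_range = c(5L, 60L),
                                 logmean = log(1), logsd = 1.5, seed = 1L) {
  if (!is.data.frame(chems) || nrow(chems) == 0L) {
    stop("'chems' must be a non-empty chemical table")
  }
  if (!all(is.finite(c(logmean, logsd))) || logsd < 0) {
    stop("lognormal parameters must be finite with logsd >= 0")
  }
  r <- as.integer(n_assays_range)
  if (length(r) != 2L || r[1] < 1L || r[2] > 200L || r[1] > r[2]) {
    stop("n_assays_range must lie within [1, 200]")
  }
  withr::with_seed(as.integer(seed), {
    n_assay <- sample.int(r[2] - r[1] + 1L, nrow(chems), replace = TRUE) +
      r[1] - 1L
    rows <- lapply(seq_len(nrow(chems)), function(i) {
      k <- n_assay[i]
      data.frame(chem_id = chems$chem_id[i],
                 assay_id = sprintf("assay_%03d", seq_len(k)),
                 ac50_uM = stats::rlnorm(k, logmean, logsd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate synthetic in vitro PK rows
#'
#' Fraction unbound is logit-normal on (0, 1]; intrinsic clearance is
#' lognormal with a configurable point mass at zero representing
#' non-metabolized chemicals.
#'
#' @param chems Chemical table.
#' @param fup_logit_mean,fup_logit_sd Logit-scale parameters for fup
#'   (default centre ~0.1).
#' @param clint_logmean,clint_logsd Lognormal parameters for Clint
#'   (uL/min/10^6 cells).
#' @param p_clint_zero Probability of Clint = 0.
#' @param seed Integer seed.
#' @return Data frame with `chem_id`, `fup`, `clint`.
#' @export
generate_pk <- function(chems, fup_logit_mean = stats::qlogis(0.1),
                        fup_logit_sd = 1.5, clint_logmean = log(10),
                        clint_logsd = 1, p_clint_zero = 0.1, seed = 1L) {
  if (!is.data.frame(chems) || nrow(chems) == 0L) {
    stop("'chems' must be a non-empty chemical table")
  }
  stopifnot(p_clint_zero >= 0, p_clint_zero <= 1)
  n <- nrow(chems)
  withr::with_seed(as.integer(seed), {
    fup <- stats::plogis(stats::rnorm(n, fup_logit_mean, fup_logit_sd))
    clint <- stats::rlnorm(n, clint_logmean, clint_logsd)
    clint[stats::runif(n) < p_clint_zero] <- 0
  })
  data.frame(chem_id = chems$chem_id, fup = fup, clint = clint,
             stringsAsFactors = FALSE)
}

#' Generate synthetic NOAEL record collections
#'
#' Per chemical, 1-40 conforming NOAEL records (type "NOAEL", units
#' "mg/kg-day", route "oral") plus a configurable fraction of decoy rows
#' with a wrong type, unit or route, to exercise the record filter. With
#' `ttc_consistent = TRUE` each chemical's generating lognormal is anchored
#' so that its 5th percentile equals 100 times the chemical's truth TTC
#' value (in mg/kg-bw/d) — the construction under which a TTC divided by
#' the 100-fold safety factor sits below the NOAEL-based point of
#' departure up to sampling noise.
#'
#' @param chems Chemical table with `truth_category`.
#' @param ttc_consistent Anchor NOAEL distributions to the truth TTC?
#' @param n_range Integer range of conforming records per chemical.
#' @param sdlog Lognormal log-scale SD of the NOAEL distribution.
#' @param logmean Log-mean used when `ttc_consistent = FALSE`.
#' @param decoy_fraction Decoy rows as a fraction of conforming rows.
#' @param seed Integer seed.
#' @return Data frame with `chem_id`, `type`, `value`, `units`, `route`.
#' @export
generate_noael_sets <- function(chems, ttc_consistent = TRUE,
                                n_range = c(1L, 40L), sdlog = 1,
                                logmean = log(50), decoy_fraction = 0.2,
                                seed = 1L) {
  if (!is.data.frame(chems) || nrow(chems) == 0L) {
    stop("'chems' must be a non-empty chemical table")
  }
  stopifnot(decoy_fraction >= 0)
  r <- as.integer(n_range)
  stopifnot(length(r) == 2L, r[1] >= 1L, r[1] <= r[2])
  decoy_pool <- list(
    list(type = "LOAEL", units = "mg/kg-day", route = "oral"),
    list(type = "NOAEL", units = "ppm", route = "oral"),
    list(type = "NOAEL", units = "mg/kg-day", route = "inhalation")
  )
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(chems)), function(i) {
      k <- sample(seq.int(r[1], r[2]), 1L)
      if (ttc_consistent) {
        target_p5 <- 100 * ttc_value(chems$truth_category[i]) / 1000
        mu <- log(target_p5) - sdlog * stats::qnorm(0.05)
      } else {
        mu <- logmean
      }
      vals <- stats::rlnorm(k, mu, sdlog)
      good <- data.frame(chem_id = chems$chem_id[i], type = "NOAEL",
                         value = vals, units = "mg/kg-day", route = "oral",
                         stringsAsFactors = FALSE)
      n_decoy <- round(decoy_fraction * k)
      if (n_decoy > 0) {
        which_decoy <- sample.int(length(decoy_pool), n_decoy, replace = TRUE)
        decoys <- do.call(rbind, lapply(which_decoy, function(d) {
          data.frame(chem_id = chems$chem_id[i],
                     type = decoy_pool[[d]]$type,
                     value = stats::rlnorm(1, mu, sdlog),
                     units = decoy_pool[[d]]$units,
                     route = decoy_pool[[d]]$route, stringsAsFactors = FALSE)
        }))
        good <- rbind(good, decoys)
      }
      good
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate synthetic exposure rows
#'
#' One row per chemical: a lognormal median intake with a fixed
#' upper95/median factor; a configurable fraction of chemicals is labeled
#' as covered only by the older consensus model (SEEM2).
#'
#' @param chems Chemical table.
#' @param logmean,logsd Lognormal parameters of the median intake
#'   (mg/kg-bw/d); defaults span the orders of magnitude typical of
#'   population exposure estimates.
#' @param upper95_factor Multiplier (>= 1) from median to upper-95 bound.
#' @param seem2_fraction Fraction of chemicals labeled SEEM2.
#' @param seed Integer seed.
#' @return Data frame with `chem_id`, `source`, `median`, `upper95`.
#' @export
generate_exposures <- function(chems, logmean = log(1e-6), logsd = 2,
                               upper95_factor = 10, seem2_fraction = 0.2,
                               seed = 1L) {
  if (!is.data.frame(chems) || nrow(chems) == 0L) {
    stop("'chems' must be a non-empty chemical table")
  }
  if (upper95_factor < 1) stop("upper95_factor must be >= 1")
  stopifnot(seem2_fraction >= 0, seem2_fraction <= 1)
  n <- nrow(chems)
  withr::with_seed(as.integer(seed), {
    med <- stats::rlnorm(n, logmean, logsd)
    is2 <- stats::runif(n) < seem2_fraction
  })
  data.frame(chem_id = chems$chem_id,
             source = ifelse(is2, "SEEM2", "SEEM3"),
             median = med, upper95 = med * upper95_factor,
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates the chemical library and all four downstream tables and writes
#' them as CSVs plus a JSON truth sidecar mapping chem_id to truth labels.
#'
#' @param out_dir Output directory (created if missing).
#' @param n Number of chemicals.
#' @param seed Integer master seed; table-specific seeds are derived from it.
#' @param ttc_consistent Passed to [generate_noael_sets()].
#' @param category_mix Passed to [generate_chemicals()].
#' @return Invisibly, the list of generated tables.
#' @export
write_bundle <- function(out_dir, n = 100L, seed = 1L, ttc_consistent = TRUE,
                         category_mix = default_category_mix()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  chems <- generate_chemicals(n, category_mix, seed = seed)
  tabs <- list(
    chemicals = chems,
    bioactivity = generate_bioactivity(chems, seed = seed + 1L),
    pk = generate_pk(chems, seed = seed + 2L),
    noael = generate_noael_sets(chems, ttc_consistent = ttc_consistent,
                                seed = seed + 3L),
    exposure = generate_exposures(chems, seed = seed + 4L)
  )
  for (nm in names(tabs)) {
    write_table_csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  truth <- stats::setNames(
    lapply(seq_len(nrow(chems)), function(i) {
      list(truth_category = chems$truth_category[i],
           truth_kroes_excluded = chems$truth_kroes_excluded[i])
    }),
    chems$chem_id
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tabs)
}
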