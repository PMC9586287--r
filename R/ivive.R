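#' Default human physiology for the steady-state model
#'
#' Parameter set for the steady-state in vitro-to-in vivo extrapolation
#' model: glomerular filtration rate, liver blood flow, hepatocellularity
#' and liver mass, each with a coefficient of variation used by the
#' population Monte Carlo, plus CVs for the chemical-specific fraction
#' unbound and intrinsic clearance and the fraction-unbound floor.
#'
#' Defaults describe a reference adult: GFR 0.1 L/h/kg bw (about 110 mL/min
#' per 70 kg), liver blood flow 1.45 L/h/kg bw, hepatocellularity 110 million
#' cells per gram of liver, liver mass 25.7 g/kg bw; 20% population CV on
#' each physiological parameter and 30% on the in vitro PK measurements.
#'
#' @param gfr Glomerular filtration rate, L/h/kg bw.
#' @param q_liver Liver blood flow, L/h/kg bw.
#' @param hepatocellularity Million hepatocytes per gram of liver.
#' @param liver_mass Gram liver per kg bw.
#' @param cv_gfr,cv_q_liver,cv_hepatocellularity,cv_liver_mass,cv_fup,cv_clint
#'   Coefficients of variation for the population Monte Carlo (>= 0).
#' @param fup_floor Minimum fraction unbound substituted (with a warning)
#'   when the reported value is zero or below the floor.
#' @return A list of class `ttc_physiology`.
#' @export
default_physiology <- function(gfr = 0.1,
                               q_liver = 1.45,
                               hepatocellularity = 110,
                               liver_mass = 25.7,
                               cv_gfr = 0.2, cv_q_liver = 0.2,
                               cv_hepatocellularity = 0.2,
                               cv_liver_mass = 0.2,
                               cv_fup = 0.3, cv_clint = 0.3,
                               fup_floor = 0.005) {
  vals <- c(gfr, q_liver, hepatocellularity, liver_mass)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("physiological parameters must be strictly positive")
  }
  cvs <- c(cv_gfr, cv_q_liver, cv_hepatocellularity, cv_liver_mass,
           cv_fup, cv_clint)
  if (any(!is.finite(cvs)) || any(cvs < 0)) stop("CVs must be >= 0")
  structure(list(
    gfr = gfr, q_liver = q_liver, hepatocellularity = hepatocellularity,
    liver_mass = liver_mass, cv_gfr = cv_gfr, cv_q_liver = cv_q_liver,
    cv_hepatocellularity = cv_hepatocellularity,
    cv_liver_mass = cv_liver_mass, cv_fup = cv_fup, cv_clint = cv_clint,
    fup_floor = fup_floor
  ), class = "ttc_physiology")
}

#' Read a physiology configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [default_physiology()].
#' @return A `ttc_physiology` list.
#' @export
read_physiology <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_physiology, cfg)
}

#' 5th (or other) percentile of an AC50 set
#'
#' Type-2 empirical quantile of a chemical's AC50 values; the lower tail of
#' the bioactivity distribution is the in vitro point of departure.
#'
#' @param ac50s Positive AC50 values in uM.
#' @param p Probability, default 0.05.
#' @return Percentile in uM.
#' @export
ac50_percentile <- function(ac50s, p = 0.05) {
  if (length(ac50s) == 0L) stop("'ac50s' must be non-empty")
  if (any(!is.finite(ac50s)) || any(ac50s <= 0)) {
    stop("AC50 values must be positive and finite")
  }
  quantile_type2(ac50s, p)
}

#' Scale intrinsic clearance to the whole liver
#'
#' Converts a hepatocyte-suspension intrinsic clearance (uL/min per million
#' cells) to a whole-body clearance capacity (L/h per kg bw):
#' `clint * hepatocellularity * liver_mass * 60 * 1e-6`.
#'
#' @param clint Intrinsic clearance, uL/min/10^6 hepatocytes (>= 0).
#' @param phys A `ttc_physiology` list.
#' @return Whole-liver intrinsic clearance, L/h/kg bw.
#' @examples
#' scale_clint(10, default_physiology(hepatocellularity = 110,
#'                                    liver_mass = 25))  # 1.65
#' @export
scale_clint <- function(clint, phys = default_physiology()) {
  if (any(!is.finite(clint)) || any(clint < 0)) stop("clint must be >= 0")
  clint * phys$hepatocellularity * phys$liver_mass * 60 * 1e-6
}

#' Steady-state plasma concentration per unit oral dose rate
#'
#' Analytical steady-state concentration for a continuous oral dose of
#' 1 mg/kg bw/d with 100% absorption, cleared by renal filtration of unbound
#' chemical (GFR x fup) in parallel with restrictive well-stirred hepatic
#' metabolism:
#' `Css = (1/24) / (gfr*fup + q_liver*fup*clint_whole / (q_liver + fup*clint_whole))`.
#' Fractions unbound at or below the configured floor are raised to the
#' floor with a warning.
#'
#' @param fup Fraction unbound in plasma (0, 1].
#' @param clint_whole Whole-liver intrinsic clearance, L/h/kg bw
#'   (see [scale_clint()]).
#' @param phys A `ttc_physiology` list.
#' @return Css in mg/L per (mg/kg-bw/d). Vectorized over `fup`/`clint_whole`.
#' @examples
#' css_unit_dose(1, 0, default_physiology(gfr = 0.1))  # (1/24)/0.1
#' @export
css_unit_dose <- function(fup, clint_whole, phys = default_physiology()) {
  if (any(!is.finite(fup)) || any(fup < 0) || any(fup > 1)) {
    stop("fup must lie in [0, 1]")
  }
  if (any(!is.finite(clint_whole)) || any(clint_whole < 0)) {
    stop("clint_whole must be >= 0")
  }
  low <- fup < phys$fup_floor
  if (any(low)) {
    warning(sum(low), " fraction-unbound value(s) raised to the floor of ",
            phys$fup_floor)
    fup[low] <- phys$fup_floor
  }
  cl_hep <- phys$q_liver * fup * clint_whole / (phys$q_liver + fup * clint_whole)
  cl_tot <- phys$gfr * fup + cl_hep
  (1 / 24) / cl_tot
}

# Lognormal draws with mean m and coefficient of variation cv (cv = 0 gives
# the constant m).
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Population 95th-percentile steady-state concentration
#'
#' Monte Carlo over physiological and in vitro PK variability: draws
#' `n_samples` parameter vectors (lognormal around the configured means with
#' the configured CVs; sampled fractions unbound truncated to 1), computes
#' the steady-state concentration for each virtual individual and returns
#' the 95th percentile (type-2 quantile). The upper tail represents the
#' sensitive end of the population and makes the oral equivalent dose
#' conservative.
#'
#' @param fup Measured fraction unbound (0, 1].
#' @param clint Measured intrinsic clearance, uL/min/10^6 cells.
#' @param phys A `ttc_physiology` list.
#' @param n_samples Number of virtual individuals (>= 100).
#' @param seed Integer seed; the draw is fully reproducible.
#' @param p Upper percentile, default 0.95.
#' @return Css percentile in mg/L per (mg/kg-bw/d).
#' @export
css_population_p95 <- function(fup, clint, phys = default_physiology(),
                               n_samples = 1000L, seed = 1L, p = 0.95) {
  if (n_samples < 100L) stop("n_samples must be >= 100")
  stopifnot(length(fup) == 1L, length(clint) == 1L)
  withr::with_seed(as.integer(seed), {
    gfr <- rlnorm_cv(n_samples, phys$gfr, phys$cv_gfr)
    ql <- rlnorm_cv(n_samples, phys$q_liver, phys$cv_q_liver)
    hep <- rlnorm_cv(n_samples, phys$hepatocellularity,
                     phys$cv_hepatocellularity)
    lm_ <- rlnorm_cv(n_samples, phys$liver_mass, phys$cv_liver_mass)
    fup_i <- pmin(rlnorm_cv(n_samples, max(fup, phys$fup_floor), phys$cv_fup), 1)
    cl_i <- rlnorm_cv(n_samples, clint, phys$cv_clint)
    clw <- cl_i * hep * lm_ * 60 * 1e-6
    fup_i <- pmax(fup_i, phys$fup_floor)
    cl_hep <- ql * fup_i * clw / (ql + fup_i * clw)
    css <- (1 / 24) / (gfr * fup_i + cl_hep)
    quantile_type2(css, p)
  })
}

#' Oral equivalent dose from an AC50 percentile
#'
#' Reverse dosimetry: the daily oral dose whose steady-state plasma
#' concentration equals the in vitro bioactive concentration,
#' `OED = (ac50_p5 * mw / 1000) / css95` (uM -> mg/L conversion via the
#' molecular weight, then division by the concentration achieved per unit
#' dose rate).
#'
#' @param ac50_p5 AC50 percentile, uM (> 0).
#' @param mw Molecular weight, g/mol (> 0).
#' @param css95 Steady-state concentration per unit dose, mg/L per
#'   (mg/kg-bw/d) (> 0).
#' @return OED in mg/kg-bw/d.
#' @examples
#' oed_from_ac50(1, 100, 0.1)  # 1
#' @export
oed_from_ac50 <- function(ac50_p5, mw, css95) {
  if (any(!is.finite(c(ac50_p5, mw))) || any(c(ac50_p5, mw) <= 0)) {
    stop("ac50_p5 and mw must be positive")
  }
  if (any(!is.finite(css95)) || any(css95 <= 0)) {
    stop("css95 must be positive")
  }
  (ac50_p5 * mw / 1000) / css95
}

#' Derive oral equivalent doses for a chemical set
#'
#' Joins the bioactivity and in vitro PK tables, takes the 5th percentile of
#' each chemical's AC50 distribution, runs the population Monte Carlo for the
#' 95th-percentile steady-state concentration and converts to an oral
#' equivalent dose. Chemicals missing PK rows or molecular weights are
#' dropped with a message.
#'
#' @param bioactivity Data frame with `chem_id`, `ac50_uM`.
#' @param pk Data frame with `chem_id`, `fup`, `clint`.
#' @param mw Data frame with `chem_id`, `mw` (g/mol).
#' @param phys A `ttc_physiology` list.
#' @param n_samples Monte Carlo size per chemical.
#' @param seed Integer seed; per-chemical seeds are derived deterministically.
#' @return Data frame with `chem_id`, `n_ac50`, `ac50_p5_uM`, `css95`,
#'   `oed_mg_kg_d`.
#' @export
derive_oed <- function(bioactivity, pk, mw, phys = default_physiology(),
                       n_samples = 1000L, seed = 1L) {
  stopifnot(all(c("chem_id", "ac50_uM") %in% names(bioactivity)),
            all(c("chem_id", "fup", "clint") %in% names(pk)),
            all(c("chem_id", "mw") %in% names(mw)))
  ids <- intersect(intersect(unique(bioactivity$chem_id), pk$chem_id),
                   mw$chem_id[!is.na(mw$mw)])
  dropped <- setdiff(unique(bioactivity$chem_id), ids)
  if (length(dropped) > 0) {
    message(length(dropped),
            " chemical(s) lack PK or MW data and get no OED")
  }
  ids <- sort(ids)
  res <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    ac <- bioactivity$ac50_uM[bioactivity$chem_id == id]
    p5 <- ac50_percentile(ac, 0.05)
    row_pk <- pk[match(id, pk$chem_id), ]
    css <- css_population_p95(
      fup = row_pk$fup, clint = row_pk$clint, phys = phys,
      n_samples = n_samples,
      seed = (as.integer(seed) + i * 1009L) %% .Machine$integer.max
    )
    data.frame(chem_id = id, n_ac50 = length(ac), ac50_p5_uM = p5,
               css95 = css,
               oed_mg_kg_d = oed_from_ac50(p5, mw$mw[match(id, mw$chem_id)],
                                           css),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
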