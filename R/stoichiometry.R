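#' Round half away from zero
#'
#' Reporting convention for percentages and retention times: 0.5 rounds
#' up (in magnitude), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hydraulic retention time
#'
#' Reactor volume divided by flow. The reporting helper rounds half away
#' from zero to one decimal, so a 7.5 L reactor at 1.2 L/h has HRT 6.25 h,
#' reported as 6.3 h.
#'
#' @param volume_L Reactor volume (litres).
#' @param flow_L_per_h Influent flow (litres per hour, > 0).
#' @param report If TRUE, return the value rounded to one decimal.
#' @return HRT in hours.
#' @export
hrt <- function(volume_L, flow_L_per_h, report = FALSE) {
  if (any(flow_L_per_h <= 0)) stop("flow must be positive")
  h <- volume_L / flow_L_per_h
  if (report) round_half_up(h, 1) else h
}

#' Reactor nitrogen record
#'
#' Influent/effluent nitrogen species and flow for mass-balance
#' operations. All concentrations in mg N per litre.
#'
#' @param volume_L Reactor volume (litres).
#' @param flow_L_per_h Flow (litres per hour).
#' @param influent_nh4 Influent ammonium (mg N/L).
#' @param effluent_nh4,effluent_no2,effluent_no3 Effluent ammonium,
#'   nitrite and nitrate (mg N/L).
#' @return Object of class `reactor_record`.
#' @export
reactor_record <- function(volume_L, flow_L_per_h, influent_nh4,
                           effluent_nh4, effluent_no2, effluent_no3) {
  vals <- c(volume_L, flow_L_per_h, influent_nh4, effluent_nh4,
            effluent_no2, effluent_no3)
  if (any(!is.finite(vals)) || any(vals[-(1:2)] < 0) || flow_L_per_h <= 0 ||
      volume_L <= 0)
    stop("concentrations must be >= 0 and volume/flow > 0")
  structure(list(volume_L = volume_L, flow_L_per_h = flow_L_per_h,
                 influent_nh4 = influent_nh4, effluent_nh4 = effluent_nh4,
                 effluent_no2 = effluent_no2, effluent_no3 = effluent_no3),
            class = "reactor_record")
}

#' Nitrogen mass balance
#'
#' Computes total inorganic nitrogen removal and the nitrate-production to
#' ammonium-removal ratio from a reactor record:
#' `removal% = (influent NH4 - sum of effluent N species) / influent NH4 x 100`,
#' `ratio% = effluent NO3 / (influent NH4 - effluent NH4) x 100`.
#' The ratio is the key diagnostic for a nitritation-anammox process: a
#' value near the stoichiometric 11% (see
#' [anammox_stoichiometric_ratio()]) indicates that aerobic nitrite
#' oxidation is negligible.
#'
#' @param record A [reactor_record()].
#' @return List with `removal_percent` and
#'   `nitrate_to_ammonium_removal_percent`.
#' @export
nitrogen_balance <- function(record) {
  stopifnot(inherits(record, "reactor_record"))
  if (record$influent_nh4 <= record$effluent_nh4)
    stop("zero ammonia removal: nitrate-to-ammonium ratio undefined")
  eff <- record$effluent_nh4 + record$effluent_no2 + record$effluent_no3
  removal <- (record$influent_nh4 - eff) / record$influent_nh4 * 100
  ratio <- record$effluent_no3 /
    (record$influent_nh4 - record$effluent_nh4) * 100
  list(removal_percent = removal,
       nitrate_to_ammonium_removal_percent = ratio)
}

#' Anammox reaction stoichiometry
#'
#' Molar coefficients of the anammox reaction per mol ammonium:
#' `NH4+ + 1.32 NO2- -> 1.02 N2 + 0.26 NO3- + ...` (standard literature
#' values; only the nitrite and nitrate coefficients matter here).
#'
#' @param nitrite_consumed_per_ammonium Mol NO2- consumed per mol NH4+
#'   (default 1.32).
#' @param nitrate_produced_per_ammonium Mol NO3- produced per mol NH4+
#'   (default 0.26).
#' @return Object of class `anammox_stoichiometry`.
#' @export
anammox_stoichiometry <- function(nitrite_consumed_per_ammonium = 1.32,
                                  nitrate_produced_per_ammonium = 0.26) {
  stopifnot(nitrite_consumed_per_ammonium > 0,
            nitrate_produced_per_ammonium > 0)
  structure(list(nitrite_consumed_per_ammonium = nitrite_consumed_per_ammonium,
                 nitrate_produced_per_ammonium = nitrate_produced_per_ammonium),
            class = "anammox_stoichiometry")
}

#' Stoichiometric nitrate ratio of combined nitritation-anammox
#'
#' In a combined process where AOB oxidize exactly the ammonium needed to
#' supply the nitrite anammox consumes, each mol of anammox-processed
#' ammonium is accompanied by `nitrite_consumed` mol of AOB-processed
#' ammonium. The expected nitrate production per total ammonium removed is
#' therefore `nitrate_produced / (1 + nitrite_consumed)` — 11% for the
#' default coefficients. An observed reactor ratio near this value rules
#' out substantial aerobic nitrite oxidation.
#'
#' @param stoich An [anammox_stoichiometry()].
#' @param report If TRUE (default), round half away from zero to an
#'   integer percent.
#' @return Percent nitrate produced per ammonium removed.
#' @export
anammox_stoichiometric_ratio <- function(stoich = anammox_stoichiometry(),
                                         report = TRUE) {
  stopifnot(inherits(stoich, "anammox_stoichiometry"))
  r <- stoich$nitrate_produced_per_ammonium /
    (1 + stoich$nitrite_consumed_per_ammonium) * 100
  if (report) round_half_up(r) else r
}

#' Depth coverage of the analyzed sections
#'
#' Fraction of the maximum analyzable biofilm depth reached by the deepest
#' section, as an integer percent. Because sectioning proceeds from each
#' carrier surface toward the mid-plane (the carrier has a slight "waist"
#' at its centre), the maximum biofilm depth is half the carrier
#' compartment depth: an 800 um section covers 80% of a 2 mm carrier and
#' 53% of a 3 mm carrier.
#'
#' @param section_depth_um Deepest analyzed section depth (um, > 0).
#' @param carrier_compartment_depth_um Full carrier compartment depth
#'   (um, > 0).
#' @return Integer percent, capped at 100 (with a warning when the
#'   section depth exceeds the half-depth).
#' @export
depth_coverage_percent <- function(section_depth_um,
                                   carrier_compartment_depth_um) {
  stopifnot(section_depth_um > 0, carrier_compartment_depth_um > 0)
  pct <- section_depth_um / (carrier_compartment_depth_um / 2) * 100
  if (pct > 100) {
    warning("section depth exceeds half the carrier depth; capped at 100%")
    pct <- 100
  }
  round_half_up(pct)
}
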