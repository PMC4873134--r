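lv_extdata <- function(name) {
  path <- system.file("extdata", name, package = "lurevp")
  if (path == "")
    lv_stop(paste("fixture", name, "not found"), "lurevp_config_error")
  path
}

#' Published Antoine parameter sets for the nine lure compounds
#'
#' Antoine coefficients and validity ranges determined by nonlinear
#' regression of DSC boiling data for raspberry ketone (RK), cuelure
#' (CL), melolure (ML) and six further analogs, shipped as a fixture.
#'
#' @param compound optional abbreviation (e.g. `"CL"`); if given, that
#'   compound's parameters are returned as an [antoine_params()] object,
#'   otherwise the full table as a data frame.
#' @return data frame (columns `abbrev`, `compound`, `A`, `B`, `C`,
#'   `T_valid_low`, `T_valid_high`) or one [antoine_params()].
#' @examples
#' lure_antoine_params("RK")
#' @export
lure_antoine_params <- function(compound = NULL) {
  d <- utils::read.csv(lv_extdata("table2_params.csv"))
  if (is.null(compound)) return(d)
  row <- d[d$abbrev == compound, ]
  if (nrow(row) != 1L)
    lv_stop(paste("unknown compound abbreviation:", compound),
            "lurevp_config_error")
  antoine_params(row$A, row$B, row$C, row$T_valid_low, row$T_valid_high,
                 compound = row$abbrev)
}

#' Published room-temperature vapour pressures and enthalpies
#'
#' Vapour pressure (kPa), enthalpy of vaporisation (kJ/mol) and vapour
#' pressure relative to raspberry ketone, all at 298.15 K, as printed
#' for the nine lure compounds. Used as the golden reference in
#' [reproduce_tables()].
#'
#' @return data frame with columns `abbrev`, `P_kPa`, `dHvap_kJmol`,
#'   `relative_vp_vs_RK`.
#' @export
lure_vp_reference <- function() {
  utils::read.csv(lv_extdata("table3_values.csv"))
}

#' Published response-kinetics fits for the eight bioassayed lures
#'
#' Fitted `p_max`, pre-exponential magnitude `A`, time constant `k` and
#' reduced r-squared (with 95 percent confidence half-widths) for each
#' lure's cage bioassay.
#'
#' @return data frame with columns `abbrev`, `p_max`, `ci_pmax`,
#'   `A_mag`, `ci_A`, `k_s`, `ci_k`, `reduced_r2`.
#' @export
lure_response_reference <- function() {
  utils::read.csv(lv_extdata("table4_fits.csv"))
}

#' Compound registry with structural flags and cluster labels
#'
#' One row per compound: name, abbreviation, whether the phenolic ester
#' group is present, whether the 2-butanone side chain is intact,
#' whether the compound was bioassayed, and the derived structural
#' cluster (see [assign_cluster()]).
#'
#' @return data frame with columns `abbrev`, `compound`,
#'   `has_phenolic_ester`, `has_butanone_chain`, `in_bioassay`,
#'   `cluster`.
#' @export
lure_registry <- function() {
  d <- utils::read.csv(lv_extdata("compound_registry.csv"))
  d$cluster <- assign_cluster(d$has_phenolic_ester, d$has_butanone_chain)
  d
}
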