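#' Pfaffl efficiency-corrected relative expression
#'
#' Relative expression of a target transcript in a sample versus a control
#' condition, normalized to a reference transcript, with per-primer
#' amplification efficiencies:
#' `ratio = e_target^(dCt_target) / e_ref^(dCt_ref)` where
#' `dCt = Ct_control - Ct_sample`. With equal efficiencies this reduces to
#' the classic `e^(-ddCt)` form. Efficiency 2 corresponds to perfect
#' doubling per cycle; real primers sit in (1, 2].
#'
#' @param target_ct_control,target_ct_sample cycle thresholds of the target
#'   amplicon in the control and sample conditions
#' @param ref_ct_control,ref_ct_sample cycle thresholds of the reference
#'   (housekeeping) amplicon
#' @param e_target,e_ref amplification efficiencies in (1, 2]
#' @return relative expression ratio (1 = unchanged)
#' @examples
#' pfaffl_ratio(21, 20, 18, 18)                    # 2
#' pfaffl_ratio(22, 20, 19, 18, e_target = 1.9)    # 1.9^2 / 2 = 1.805
#' @export
pfaffl_ratio <- function(target_ct_control, target_ct_sample,
                         ref_ct_control, ref_ct_sample,
                         e_target = 2, e_ref = 2) {
  cts <- c(target_ct_control, target_ct_sample, ref_ct_control,
           ref_ct_sample)
  if (any(cts <= 0)) stop("Ct values must be positive")
  if (e_target <= 1 || e_target > 2 || e_ref <= 1 || e_ref > 2)
    stop("efficiencies must lie in (1, 2]")
  e_target^(target_ct_control - target_ct_sample) /
    e_ref^(ref_ct_control - ref_ct_sample)
}

#' qChIP signal as percent of input
#'
#' Quantifies immunoprecipitated DNA relative to the non-immunoprecipitated
#' input chromatin. The input aliquot is a known fraction of the chromatin
#' that went into the immunoprecipitation, so the measured input Ct is first
#' put on the 100%-input scale and the ratio follows from the amplification
#' efficiency: `percent = 100 * input_fraction * efficiency^(input_ct -
#' ip_ct)`. Equal Cts with a 10% input aliquot therefore report 10% of
#' input.
#'
#' @param ip_ct Ct of the immunoprecipitated sample
#' @param input_ct Ct measured on the input aliquot
#' @param input_fraction fraction of chromatin used as input, in (0, 1]
#' @param efficiency amplification efficiency in (1, 2]
#' @return percent of input (0-100 scale, may exceed 100 for enriched
#'   regions with generous input fractions)
#' @examples
#' chip_relative_to_input(25, 25, input_fraction = 1)    # 100
#' chip_relative_to_input(25, 25, input_fraction = 0.1)  # 10
#' @export
chip_relative_to_input <- function(ip_ct, input_ct, input_fraction,
                                   efficiency = 2) {
  if (input_fraction <= 0 || input_fraction > 1)
    stop("'input_fraction' must lie in (0, 1]")
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must lie in (1, 2]")
  if (any(c(ip_ct, input_ct) <= 0)) stop("Ct values must be positive")
  100 * input_fraction * efficiency^(input_ct - ip_ct)
}
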