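# Published reference values from the controlled cold-stress experiment on
# 'Toyonoka' strawberry that this package models. These printed group means
# and percentage relations are consumed as inputs: they anchor the synthetic
# generator and provide a fully recomputable worked example for the index
# arithmetic (see reference_consistency()).

#' Reference physiology of the cold-stress factorial
#'
#' Returns the published treatment-level anchors used throughout the package:
#' the severe-stress (10/0 degC, 9 d) physiology (P_max 8.601 umol m^-2 s^-1,
#' REC 0.384, Chl 2.163 mg g^-1), the percentage relations tying them to the
#' unstressed control, and the PPPI group means for every treatment cell.
#'
#' @return A list with elements:
#'   `t4d3` (named vector of severe-stress physiology),
#'   `pct` (named vector of printed percentage relations),
#'   `aux` (named vector of auxiliary printed means),
#'   `pppi_mean` (named vector: PPPI mean per treatment cell, incl. CK).
#' @export
reference_physiology <- function() {
  list(
    t4d3 = c(p_max = 8.601, rec = 0.384, chl = 2.163),
    pct = c(
      pmax_t4d3_vs_ck  = 48.18,  # P_max decrease at T4D3 vs control (%)
      pmax_t4d3_vs_t4d2 = 35.89, # P_max decrease at T4D3 vs T4D2 (%)
      rec_t4_vs_ck     = 108.66, # REC excess of the T4 plateau over control (%)
      rec_t3_vs_ck     = 91.29,  # REC excess of the T3 plateau over control (%)
      chl_t4d3_vs_ck   = 26.26,  # Chl decrease at T4D3 vs control (%)
      chl_d3_mid_vs_ck = 79.40,  # Chl at T2D3/T3D3 as a share of control (%)
      chl_t4d1_vs_ck   = 11.15,  # Chl excess at T4D1 over control (%)
      chl_t4d1_vs_t4d2 = 7.77,   # Chl excess at T4D1 over T4D2 (%)
      pppi_t2d2_vs_ck  = 47.37,  # PPPI decrease at T2D2 vs control (%)
      pppi_t2d2_vs_t2d1 = 30.40, # PPPI decrease at T2D2 vs T2D1 (%)
      pppi_t4d2_vs_t4d1 = 12.61  # PPPI increase at T4D2 vs T4D1 (%)
    ),
    aux = c(
      rec_t3_plateau = 0.352,  # mean REC, T3 at 6-9 d
      rec_t4_plateau = 0.384,  # mean REC, T4 at 6-9 d
      rec_d1_mean    = 0.324,  # mean REC across T2-T4 at 3 d
      chl_d3_mid     = 2.329,  # mean Chl, T2D3/T3D3
      chl_t4d1       = 3.26    # Chl at T4D1
    ),
    pppi_mean = c(
      CK = 4.545,
      T1D1 = 4.268, T1D2 = 3.539, T1D3 = 3.699,
      T2D1 = 3.437, T2D2 = 2.392, T2D3 = 3.352,
      T3D1 = 3.200, T3D2 = 2.876, T3D3 = 2.025,
      T4D1 = 2.593, T4D2 = 2.920, T4D3 = 0.142)
  )
}

#' Reconstruct the control-group physiology from the printed relations
#'
#' The control means are not printed directly; they are implied by the
#' severe-stress values and their printed percentage relations:
#' `P_max_CK = 8.601 / (1 - 0.4818)`, `REC_CK = 0.384 / (1 + 1.0866)`,
#' `Chl_CK = 2.163 / (1 - 0.2626)`.
#'
#' @return Named vector with `p_max`, `rec`, `chl` for the control group.
#' @export
reconstruct_control <- function() {
  ref <- reference_physiology()
  c(p_max = unname(ref$t4d3["p_max"] / (1 - ref$pct["pmax_t4d3_vs_ck"] / 100)),
    rec   = unname(ref$t4d3["rec"]   / (1 + ref$pct["rec_t4_vs_ck"] / 100)),
    chl   = unname(ref$t4d3["chl"]   / (1 - ref$pct["chl_t4d3_vs_ck"] / 100)))
}

#' Worked-example acceptance report
#'
#' Compares every quantity recomputed by [reference_consistency()] against
#' its printed reference value at the documented tolerance.
#'
#' @return data.frame with `id`, `quantity`, `computed`, `reference`,
#'   `tolerance`, `pass`.
#' @export
acceptance_report <- function() {
  rc <- reference_consistency()
  ref <- reference_physiology()
  tab <- data.frame(
    id = paste0("t", 1:8),
    quantity = c("ck_pppi", "pppi_drop_t2d2_vs_ck", "pppi_drop_t2d2_vs_t2d1",
                 "pppi_gain_t4d2_vs_t4d1", "rec_t3_excess", "rec_t4_excess",
                 "chl_d3_mid_share", "chl_t4d1_excess"),
    computed = c(rc$ck_pppi, rc$pppi_drop_t2d2_vs_ck,
                 rc$pppi_drop_t2d2_vs_t2d1, rc$pppi_gain_t4d2_vs_t4d1,
                 rc$rec_t3_excess, rc$rec_t4_excess, rc$chl_d3_mid_share,
                 rc$chl_t4d1_excess),
    reference = unname(c(ref$pppi_mean["CK"], ref$pct["pppi_t2d2_vs_ck"],
                         ref$pct["pppi_t2d2_vs_t2d1"],
                         ref$pct["pppi_t4d2_vs_t4d1"], ref$pct["rec_t3_vs_ck"],
                         ref$pct["rec_t4_vs_ck"], ref$pct["chl_d3_mid_vs_ck"],
                         ref$pct["chl_t4d1_vs_ck"])),
    tolerance = c(0.01, 0.05, 0.05, 0.05, 0.1, 0.1, 0.1, 0.1))
  tab$pass <- abs(tab$computed - tab$reference) <= tab$tolerance
  tab
}

#' Recompute the published worked-example arithmetic
#'
#' Re-derives, from the reconstructed control physiology and the printed
#' group means, every percentage relation and the control PPPI of the
#' reference experiment. Used by the acceptance suite: each returned value
#' should match its printed counterpart.
#'
#' @return Named list of recomputed quantities:
#'   `ck_pppi` (control PPPI via the score formulas),
#'   `pppi_drop_t2d2_vs_ck`, `pppi_drop_t2d2_vs_t2d1`,
#'   `pppi_gain_t4d2_vs_t4d1` (percent),
#'   `rec_t3_excess`, `rec_t4_excess`, `chl_d3_mid_share`,
#'   `chl_t4d1_excess` (percent).
#' @export
reference_consistency <- function() {
  ref <- reference_physiology()
  ck  <- reconstruct_control()
  pp  <- ref$pppi_mean
  list(
    ck_pppi = unname(pppi(ck["p_max"], ck["rec"], ck["chl"])),
    pppi_drop_t2d2_vs_ck   = unname((1 - pp["T2D2"] / pp["CK"])   * 100),
    pppi_drop_t2d2_vs_t2d1 = unname((1 - pp["T2D2"] / pp["T2D1"]) * 100),
    pppi_gain_t4d2_vs_t4d1 = unname((pp["T4D2"] / pp["T4D1"] - 1) * 100),
    rec_t3_excess    = unname((ref$aux["rec_t3_plateau"] / ck["rec"] - 1) * 100),
    rec_t4_excess    = unname((ref$aux["rec_t4_plateau"] / ck["rec"] - 1) * 100),
    chl_d3_mid_share = unname(ref$aux["chl_d3_mid"] / ck["chl"] * 100),
    chl_t4d1_excess  = unname((ref$aux["chl_t4d1"] / ck["chl"] - 1) * 100)
  )
}
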