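#' Worked-example mortality percentages
#'
#' Measured cell-death percentages (DiOC6(3)/PI flow cytometry) for a
#' human bronchial epithelial cell line exposed to four TiO2-based
#' nanomaterials with or without 4 Gy gamma irradiation, used throughout
#' the package examples and acceptance checks. One row per nanomaterial,
#' timepoint and dose, with the single-agent mortalities (`p_nm_alone`,
#' NM only; `p_ir_alone`, 4 Gy only at the same timepoint) and the
#' observed combined mortality (`p_observed`), all in percent. The
#' double-coated material is reported at 32 ug/cm2, the dose beyond which
#' its own toxicity saturates the assay.
#'
#' These are the inputs of the worked example: predicting the combined
#' mortality under independent action via [transfer_impulse()] and
#' comparing it with `p_observed` reproduces the direction of the
#' synergy call at each timepoint.
#'
#' @return data frame with columns `nm_type`, `timepoint_h`,
#'   `dose_surface`, `p_nm_alone`, `p_ir_alone`, `p_observed` (percent).
#' @export
#' @examples
#' ref <- reference_mortality()
#' q <- ir_impulse(ref$p_ir_alone / 100, 0)
#' pred <- 100 * transfer_impulse(ref$p_nm_alone / 100, q)
#' cbind(ref, predicted = round(pred, 2))
reference_mortality <- function() {
  data.frame(
    nm_type = c("TiO2", "SiO2TiO2", "Al2O3TiO2", "AlSiTiO2",
                "TiO2", "SiO2TiO2", "Al2O3TiO2"),
    timepoint_h = c(72, 72, 72, 72, 168, 168, 168),
    dose_surface = c(64, 64, 64, 32, 64, 64, 64),
    p_nm_alone = c(27.95, 36.5, 41.55, 60, 68, 70.57, 52.65),
    p_ir_alone = c(25.5, 25.5, 25.5, 25.5, 63.4, 63.4, 63.4),
    p_observed = c(46.9, 54.3, 59.2, 65.22, 84.87, 86.27, 88.93))
}
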