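#' Parameters of the areal carbon-export estimate
#'
#' Defaults describe golden kelp forests: mean detrital production of
#' 2.15 g fresh weight per kelp per day, 6.3 kelp individuals per m^2, a
#' fresh-to-dry weight ratio of 0.20, and 30% carbon content of dry weight.
#'
#' @param production detrital production (g fresh weight / kelp / day).
#' @param density kelp density (individuals / m^2).
#' @param fw_to_dw fresh-to-dry weight ratio, in (0, 1].
#' @param carbon_content carbon fraction of dry weight, in (0, 1].
#' @param exported_fraction fraction of detritus exported past the shelf
#'   edge (dimensionless).
#' @param days_per_year days in the production year.
#' @return An object of class `carbon_params`.
#' @export
carbon_params <- function(production = 2.15, density = 6.3, fw_to_dw = 0.20,
                          carbon_content = 0.30, exported_fraction,
                          days_per_year = 365) {
  stopifnot(production > 0, density > 0,
            fw_to_dw > 0, fw_to_dw <= 1,
            carbon_content > 0, carbon_content <= 1,
            exported_fraction >= 0, days_per_year > 0)
  structure(list(production = production, density = density,
                 fw_to_dw = fw_to_dw, carbon_content = carbon_content,
                 exported_fraction = exported_fraction,
                 days_per_year = days_per_year),
            class = "carbon_params")
}

#' Areal carbon export of a kelp forest
#'
#' Converts detrital production into carbon exported past the continental
#' shelf edge per hectare of kelp forest per year:
#' production x density x fresh-to-dry x carbon content x days/year
#' x 10^4 m^2/ha x exported fraction, converted from grams to megagrams.
#' Linear in every parameter.
#'
#' @param params a [carbon_params()] (or `exported_fraction` given directly
#'   with all other parameters at their defaults).
#' @return export in Mg C / ha / year.
#' @export
areal_carbon_export <- function(params) {
  if (is.numeric(params)) params <- carbon_params(exported_fraction = params)
  stopifnot(inherits(params, "carbon_params"))
  with(params,
       production * density * fw_to_dw * carbon_content * days_per_year *
         1e4 * exported_fraction * 1e-6)
}
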