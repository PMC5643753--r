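PRESETS <- list(
  "default" = list(
    diameter_um = 0.6,
    density_per_um2 = 0.6 * 50 / 1.2,
    target_velocity_m_per_s = 1.0,
    description = "mid-range axon: D = 0.6 um, Cd = alpha * D = 25 /um^2, 1 m/s reference"
  ),
  "small-axon" = list(
    diameter_um = 0.2,
    density_per_um2 = 5,
    target_velocity_m_per_s = 1.0,
    description = "lower bounds of the typical ranges: D = 0.2 um, Cd = 5 /um^2"
  ),
  "large-axon" = list(
    diameter_um = 1.2,
    density_per_um2 = 50,
    target_velocity_m_per_s = 1.0,
    description = "upper bounds of the typical ranges: D = 1.2 um, Cd = 50 /um^2"
  )
)

#' Parameter presets
#'
#' Named parameter bundles covering the typical unmyelinated-axon ranges:
#' `"default"` (mid-range, D = 0.6 um with the diameter-coupled density
#' Cd = 25 channels/um^2), `"small-axon"` (D = 0.2 um, Cd = 5) and
#' `"large-axon"` (D = 1.2 um, Cd = 50). All anchor the reference velocity
#' at 1 m/s.
#'
#' @param name Preset id.
#' @return A named list with `diameter_um`, `density_per_um2`,
#'   `target_velocity_m_per_s` and a `description`.
#' @examples
#' load_presets("small-axon")$density_per_um2  # 5
#' @export
load_presets <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(PRESETS)) {
    abort(sprintf(
      "unknown preset %s; available presets: %s",
      if (is.character(name) && length(name) == 1) sQuote(name) else "<not a string>",
      paste(sQuote(names(PRESETS)), collapse = ", ")
    ))
  }
  PRESETS[[name]]
}
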