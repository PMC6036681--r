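# Physical configuration of a closed serum-bottle run.

#' Universal gas constant in bottle units
#'
#' `0.0831446` ml·bar·mmol^-1·K^-1, the value used for every ideal-gas
#' conversion in the package.
#' @export
R_GAS <- 0.0831446

#' Gas species tracked by the pipeline
#'
#' The fixed species set, in canonical column order: `h2`, `o2`, `n2`, `co`,
#' `co2`. All composition and amount vectors in the package are named with
#' these keys.
#' @export
GAS_SPECIES <- c("h2", "o2", "n2", "co", "co2")

#' Describe a closed serum bottle
#'
#' Captures the physical configuration of one cultivation: bottle and liquid
#' volumes and the two temperature regimes. Bottles are filled at ambient
#' temperature and pressure, then incubated warm; pressure readings taken
#' during incubation are interpreted at `incubation_temperature`, while the
#' nominal fill state (used to construct initial amounts) is interpreted at
#' `fill_temperature` and `fill_pressure`.
#'
#' @param total_volume total bottle volume (ml).
#' @param initial_liquid_volume medium volume at inoculation (ml); the initial
#'   headspace is `total_volume - initial_liquid_volume`.
#' @param fill_temperature temperature at which the gas phase was set (K).
#' @param incubation_temperature cultivation temperature (K).
#' @param fill_pressure total pressure at filling (bar).
#' @return An object of class `bottle_spec`.
#' @examples
#' bottle_spec()  # 250 ml bottle, 50 ml medium: 200 ml headspace
#' @export
bottle_spec <- function(total_volume = 250, initial_liquid_volume = 50,
                        fill_temperature = 298.15,
                        incubation_temperature = 333.15,
                        fill_pressure = 1.0) {
  if (!is.numeric(total_volume) || total_volume <= 0)
    stop("total_volume must be positive")
  if (!is.numeric(initial_liquid_volume) || initial_liquid_volume <= 0 ||
      initial_liquid_volume >= total_volume)
    stop("initial_liquid_volume must satisfy 0 < liquid < total_volume")
  if (fill_temperature <= 0 || incubation_temperature <= 0)
    stop("temperatures must be positive (kelvin)")
  if (fill_pressure <= 0) stop("fill_pressure must be positive")
  structure(
    list(total_volume = total_volume,
         initial_liquid_volume = initial_liquid_volume,
         fill_temperature = fill_temperature,
         incubation_temperature = incubation_temperature,
         fill_pressure = fill_pressure,
         gas_constant = R_GAS),
    class = "bottle_spec")
}

#' @export
print.bottle_spec <- function(x, ...) {
  cat(sprintf("Serum bottle: %.0f ml total, %.0f ml liquid (%.0f ml headspace)\n",
              x$total_volume, x$initial_liquid_volume,
              x$total_volume - x$initial_liquid_volume))
  cat(sprintf("  fill: %.2f bar at %.2f K; incubation at %.2f K\n",
              x$fill_pressure, x$fill_temperature, x$incubation_temperature))
  invisible(x)
}

#' Initial headspace amounts implied by the fill state
#'
#' Converts the nominal fill composition into molar amounts using the ideal
#' gas law at the fill temperature and pressure, e.g. a 200 ml headspace at
#' 1 bar and 298.15 K holds 8.07 mmol of gas in total.
#'
#' @param bottle a [bottle_spec()].
#' @param composition named mole fractions over [GAS_SPECIES] (normalized
#'   internally).
#' @return Named numeric vector of amounts (mmol) over [GAS_SPECIES].
#' @examples
#' # 50% CO / 50% air: x_O2 = 0.5 * 0.21
#' initial_headspace_amounts(bottle_spec(),
#'   c(co = 0.5, o2 = 0.105, n2 = 0.395))
#' @export
initial_headspace_amounts <- function(bottle, composition) {
  stopifnot(inherits(bottle, "bottle_spec"))
  vh <- bottle$total_volume - bottle$initial_liquid_volume
  headspace_amounts(normalize_composition(composition),
                    pressure = bottle$fill_pressure,
                    headspace_volume = vh,
                    temperature = bottle$fill_temperature)
}

# coerce a partial named vector to the full species set (missing -> 0)
as_species <- function(x) {
  out <- setNames(numeric(length(GAS_SPECIES)), GAS_SPECIES)
  if (is.null(names(x)) && length(x) == length(GAS_SPECIES)) {
    out[] <- as.numeric(x)
    return(out)
  }
  nm <- tolower(names(x))
  bad <- setdiff(nm, GAS_SPECIES)
  if (length(bad)) stop("unknown gas species: ", paste(bad, collapse = ", "))
  out[nm] <- as.numeric(x)
  out
}
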