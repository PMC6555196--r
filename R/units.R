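#' Unit conventions and conversion constants
#'
#' All quantities in ephapsis use one fixed system of units, chosen to match
#' common practice in compartmental modelling:
#'
#' * geometry: micrometres (um)
#' * specific membrane capacitance: uF/cm^2
#' * specific membrane conductance: mS/cm^2
#' * axial resistivity: Ohm cm
#' * membrane potential: mV
#' * time: ms
#' * point currents: nA
#' * ionic current density: uA/cm^2 (mS/cm^2 times mV, no extra factor)
#' * synaptic / gap-junction conductances: nS
#' * extracellular conductivity: S/m
#'
#' Every cross-unit conversion in the package goes through the constants in
#' this table; nothing else hard-codes a power of ten.
#'
#' @format A named list of conversion factors:
#' \describe{
#'   \item{iion_to_nA}{multiply uA/cm^2 by area in um^2 and this factor to get nA}
#'   \item{cap_to_nF}{multiply uF/cm^2 by area in um^2 and this factor to get nF;
#'     nF and uS then give membrane time constants directly in ms}
#'   \item{gdens_to_uS}{multiply mS/cm^2 by area in um^2 and this factor to get uS}
#'   \item{raxial_to_MOhm}{multiply Ohm cm times um / um^2 by this factor to get
#'     MOhm; mV / MOhm = nA}
#'   \item{nS_to_uS}{nS conductance times mV gives pA; this factor rescales
#'     nS to uS so products with mV are nA}
#'   \item{field_prefactor}{V[mV] = I[nA] / (4 pi sigma[S/m] d[um]) times this
#'     factor (which is exactly 1 in these units)}
#' }
#' @export
eph_units <- list(
  iion_to_nA     = 1e-5,  # uA/cm^2 * um^2 -> nA
  cap_to_nF      = 1e-5,  # uF/cm^2 * um^2 -> nF
  gdens_to_uS    = 1e-5,  # mS/cm^2 * um^2 -> uS
  raxial_to_MOhm = 1e-2,  # Ohm*cm * um / um^2 -> MOhm
  nS_to_uS       = 1e-3,  # nS -> uS
  field_prefactor = 1     # nA / (S/m * um) -> mV
)

# internal shorthands
.u <- function(name) eph_units[[name]]
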