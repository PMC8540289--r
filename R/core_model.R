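## Domain types and physical relations: Helfrich bending energy, osmotic
## bookkeeping of the 1:1 stopped-flow mixing step, and the empirical
## pore-opening delay law linking the osmotic pressure difference, temperature
## and membrane mechanics to the deflection time t0.

#' Lipid composition of a membrane
#'
#' A labelled list of lipid components with mole fractions. Mole fractions must
#' lie in \[0, 1\] and sum to 1.
#'
#' @param label Short text label, e.g. `"PC/chol 7:3"`.
#' @param lipids Character vector of lipid names.
#' @param mol_fractions Numeric vector of mole fractions, same length as
#'   `lipids`.
#' @return An object of class `"composition"`.
#' @examples
#' composition("PC/chol 7:3", c("PC", "chol"), c(0.7, 0.3))
#' @export
composition <- function(label, lipids, mol_fractions) {
  if (length(lipids) < 1L || length(lipids) != length(mol_fractions)) {
    stop_invalid("composition needs at least one lipid and matching fractions")
  }
  if (any(mol_fractions < 0 | mol_fractions > 1)) {
    stop_invalid("mole fractions must lie in [0, 1]")
  }
  if (abs(sum(mol_fractions) - 1) > 1e-9) {
    stop_invalid("mole fractions must sum to 1 (tolerance 1e-9)")
  }
  structure(
    list(label = as.character(label), lipids = as.character(lipids),
         mol_fractions = as.numeric(mol_fractions)),
    class = "composition"
  )
}

#' @export
print.composition <- function(x, ...) {
  cat("Membrane composition:", x$label, "\n")
  for (i in seq_along(x$lipids)) {
    cat(sprintf("  %-10s %5.1f mol%%\n", x$lipids[i], 100 * x$mol_fractions[i]))
  }
  invisible(x)
}

#' Continuum mechanical parameters of a lipid bilayer
#'
#' Parameters of the Helfrich description of membrane elasticity: bending
#' rigidity `kappa_b` and Gaussian modulus `kappa_g` (both in units of
#' \eqn{k_B T}) and spontaneous curvature `c0` (1/nm), together with the
#' absolute temperature.
#'
#' `kappa_g` defaults to \eqn{-0.8 \kappa_b}, a common continuum estimate; it
#' enters only the bending energy density, never the delay law.
#'
#' @param kappa_b Bending rigidity, \eqn{k_B T} units; must be positive.
#' @param kappa_g Gaussian curvature modulus, \eqn{k_B T} units.
#' @param c0 Spontaneous curvature, 1/nm.
#' @param temperature Absolute temperature, K; must be positive.
#' @return An object of class `"membrane_mechanics"`.
#' @examples
#' membrane_mechanics(kappa_b = 25)
#' @export
membrane_mechanics <- function(kappa_b, kappa_g = -0.8 * kappa_b, c0 = 0,
                               temperature = 298.15) {
  if (!is.finite(kappa_b) || kappa_b <= 0) stop_invalid("kappa_b must be > 0")
  if (!is.finite(temperature) || temperature <= 0) {
    stop_invalid("temperature must be > 0")
  }
  structure(
    list(kappa_b = kappa_b, kappa_g = kappa_g, c0 = c0,
         temperature = temperature),
    class = "membrane_mechanics"
  )
}

#' @export
print.membrane_mechanics <- function(x, ...) {
  cat(sprintf(
    "Membrane mechanics: kappa_b = %.3g kT, kappa_G = %.3g kT, c0 = %.3g /nm, T = %.2f K\n",
    x$kappa_b, x$kappa_g, x$c0, x$temperature))
  invisible(x)
}

#' Osmotic and pH condition across the vesicle membrane
#'
#' @param delta_pi Osmotic pressure difference (external minus internal), mOsm;
#'   must be non-negative in shrinkage experiments.
#' @param delta_ph pH difference (external minus internal), signed.
#' @param solute Label of the osmotically active compound (`"KCl"`, `"NaCl"`
#'   or `"sucrose"`). The label never enters any computation: the deflection
#'   position does not depend on the compound used, only on the osmolality.
#' @return An object of class `"osmotic_condition"`.
#' @export
osmotic_condition <- function(delta_pi, delta_ph = 0, solute = "KCl") {
  if (!is.finite(delta_pi) || delta_pi < 0) {
    stop_invalid("delta_pi must be >= 0 (mOsm)")
  }
  structure(
    list(delta_pi = delta_pi, delta_ph = delta_ph,
         solute = as.character(solute)),
    class = "osmotic_condition"
  )
}

#' Calibration of the pore-opening delay law
#'
#' The delay time of the deflection point scales as \eqn{1/\Delta\pi};
#' the proportionality constant `k_scale` (mOsm s) is the product
#' \eqn{t_0 \Delta\pi} at reference mechanics and temperature. `rigidity_coeff`
#' (s mOsm per \eqn{k_B T}) is the linear sensitivity of that constant to the
#' bending rigidity about `kappa_ref`; `temp_coeff` (per K) the fractional
#' decrease per kelvin above `t_ref` (membranes soften and reorganize faster
#' when warm).
#'
#' The default `k_scale = 2` mOsm s places the delay below a 10 ms instrument
#' dead time whenever \eqn{\Delta\pi > 200} mOsm, the regime where the plain
#' osmotic-flux law applies from time zero.
#'
#' @param k_scale Delay scale, mOsm s; positive.
#' @param rigidity_coeff Sensitivity to bending rigidity, s mOsm per kT.
#' @param temp_coeff Fractional decrease of the delay scale per K above
#'   `t_ref`.
#' @param t_ref Reference temperature, K.
#' @param kappa_ref Reference bending rigidity, kT.
#' @return An object of class `"delay_calibration"`.
#' @export
delay_calibration <- function(k_scale = 2, rigidity_coeff = 0.04,
                              temp_coeff = 0.01, t_ref = 298.15,
                              kappa_ref = 25) {
  if (!is.finite(k_scale) || k_scale <= 0) stop_invalid("k_scale must be > 0")
  structure(
    list(k_scale = k_scale, rigidity_coeff = rigidity_coeff,
         temp_coeff = temp_coeff, t_ref = t_ref, kappa_ref = kappa_ref),
    class = "delay_calibration"
  )
}

#' Helfrich bending energy density
#'
#' Local elastic energy per unit area of a membrane patch with principal
#' curvatures `c1`, `c2`:
#' \deqn{E = \tfrac{1}{2}\kappa_b (c_1 + c_2 - C_0)^2 + \kappa_G c_1 c_2}
#' in \eqn{k_B T} per nm squared when curvatures are in 1/nm and moduli in
#' \eqn{k_B T}.
#'
#' @param c1,c2 Principal curvatures, 1/nm.
#' @param mech A [membrane_mechanics()] object.
#' @return Energy per unit area, \eqn{k_B T}/nm^2.
#' @examples
#' m <- membrane_mechanics(kappa_b = 25, kappa_g = -20, c0 = 0)
#' helfrich_energy_density(0.01, 0.01, m)  # 3e-3 kT/nm^2
#' @export
helfrich_energy_density <- function(c1, c2, mech) {
  stopifnot(inherits(mech, "membrane_mechanics"))
  0.5 * mech$kappa_b * (c1 + c2 - mech$c0)^2 + mech$kappa_g * c1 * c2
}

#' Osmotic pressure difference generated by stopped-flow mixing
#'
#' In the stopped-flow experiment a vesicle suspension of low osmolality is
#' mixed with an osmotically active stock solution, normally in 1:1 volume
#' ratio. Under the `"paper"` convention the internal (suspension) osmolality
#' is treated as negligible, so the difference equals the diluted stock
#' osmolality; `"exact"` uses the volume-weighted external mean minus the
#' suspension osmolality.
#'
#' @param c_stock Stock osmolality, mOsm (>= 0).
#' @param c_suspension Suspension osmolality, mOsm (>= 0).
#' @param mix_ratio Two positive numbers, parts of stock and suspension;
#'   default `c(1, 1)`.
#' @param convention `"paper"` (negligible internal osmolality) or `"exact"`.
#' @return Osmotic pressure difference, mOsm.
#' @examples
#' delta_pi_from_mixing(300, 10)                        # 150
#' delta_pi_from_mixing(300, 10, convention = "exact")  # 145
#' @export
delta_pi_from_mixing <- function(c_stock, c_suspension, mix_ratio = c(1, 1),
                                 convention = c("paper", "exact")) {
  convention <- match.arg(convention)
  if (any(!is.finite(c(c_stock, c_suspension))) || c_stock < 0 ||
      c_suspension < 0) {
    stop_invalid("concentrations must be non-negative")
  }
  if (length(mix_ratio) != 2L || any(mix_ratio <= 0)) {
    stop_invalid("mix_ratio must be two positive parts")
  }
  total <- sum(mix_ratio)
  if (convention == "paper") {
    c_stock * mix_ratio[1] / total
  } else {
    (c_stock * mix_ratio[1] + c_suspension * mix_ratio[2]) / total - c_suspension
  }
}

#' Predicted pore-opening delay time
#'
#' Empirical delay law for the deflection time \eqn{t_0} of the scattered-light
#' trace: \eqn{t_0} is proportional to \eqn{1/\Delta\pi}, increases with
#' bending rigidity, and decreases with temperature:
#' \deqn{t_0 = [k + a(\kappa_b - \kappa_{ref})]\,
#'       \max(0,\, 1 - b(T - T_{ref}))/\Delta\pi}
#' A delay below the instrument dead time cannot be resolved by the
#' stopped-flow measurement and is flagged.
#'
#' @param cond An [osmotic_condition()]; `delta_pi = 0` yields the distinct
#'   infinite-delay outcome (no pore-driven flux predicted), not an error.
#' @param mech A [membrane_mechanics()].
#' @param cal A [delay_calibration()].
#' @param dead_time Instrument dead time, s (default 0.01).
#' @return A list with `t0` (seconds; `Inf` for `delta_pi = 0`), `resolvable`
#'   (logical, `NA` when infinite) and `status` (`"ok"` or
#'   `"infinite-delay"`).
#' @examples
#' cond <- osmotic_condition(20)
#' mech <- membrane_mechanics(25)
#' pore_delay_time(cond, mech, delay_calibration(k_scale = 2,
#'   rigidity_coeff = 0, temp_coeff = 0))$t0  # 0.1 s
#' @export
pore_delay_time <- function(cond, mech, cal = delay_calibration(),
                            dead_time = 0.01) {
  stopifnot(inherits(cond, "osmotic_condition"),
            inherits(mech, "membrane_mechanics"),
            inherits(cal, "delay_calibration"))
  if (cond$delta_pi == 0) {
    return(list(t0 = Inf, resolvable = NA, status = "infinite-delay"))
  }
  scale <- cal$k_scale + cal$rigidity_coeff * (mech$kappa_b - cal$kappa_ref)
  temp_att <- max(0, 1 - cal$temp_coeff * (mech$temperature - cal$t_ref))
  t0 <- max(0, scale) * temp_att / cond$delta_pi
  list(t0 = t0, resolvable = t0 >= dead_time, status = "ok")
}

#' Expected pore-opening waiting time from an energy barrier
#'
#' Arrhenius/Kramers mapping from the pore-opening energy barrier to a mean
#' waiting time: `tau_attempt * exp(e_pore)`. Interprets the delay
#' mechanistically: spontaneous pore opening against a barrier of a few tens
#' of \eqn{k_B T} is rare but feasible without external stress.
#'
#' @param e_pore Barrier height, \eqn{k_B T} units.
#' @param tau_attempt Attempt time, s; positive.
#' @return Expected delay, s.
#' @examples
#' barrier_to_delay(10, 1e-6)  # ~2.2e-2 s
#' @export
barrier_to_delay <- function(e_pore, tau_attempt) {
  if (any(!is.finite(tau_attempt)) || any(tau_attempt <= 0)) {
    stop_invalid("tau_attempt must be > 0")
  }
  tau_attempt * exp(e_pore)
}
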