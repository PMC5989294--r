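# Closed-form contact stresses at the hip--femur junction.
#
# Unit convention: forces in newtons, lengths in millimeters, stresses in
# MPa (N/mm^2); the torque arm k2 is specified in meters (as in the gait
# literature) and converted explicitly at the N.m -> N.mm boundary.
# g = 9.81 m/s^2 throughout.

#' Implant cross-section geometry at the hip--femur contact
#'
#' For the circular contact section the radius of gyration `i_x` and the
#' maximal boundary distance `y_max` both equal the section radius `R`,
#' and the polar moment is `I0 = 2 A i_x^2`; those are the defaults.
#'
#' @param A cross-sectional area, mm^2.
#' @param R section radius at the contact point, mm.
#' @param i_x radius of gyration about the principal axis, mm.
#' @param y_max maximal distance from the principal axis to the section
#'   boundary, mm.
#' @param I0 polar moment of inertia, mm^4.
#' @return A `stress_geometry` list.
#' @export
stress_geometry <- function(A, R, i_x = R, y_max = R, I0 = 2 * A * i_x^2) {
  stopifnot(A > 0, R > 0, i_x > 0, y_max > 0, I0 > 0)
  structure(list(A = A, R = R, i_x = i_x, y_max = y_max, I0 = I0),
            class = "stress_geometry")
}

#' Loading constants for one activity pattern
#'
#' @param k1 dimensionless force multiplier (vertical hip force in
#'   multiples of body weight).
#' @param k2 torque arm per unit weight, meters (0 = torsion neglected).
#' @param g gravitational acceleration, m/s^2.
#' @param T_step duration of one step, seconds (1.11 s for a normal gait).
#' @return A `load_coefficients` list.
#' @export
load_coefficients <- function(k1, k2 = 0, g = 9.81, T_step = 1.11) {
  stopifnot(k1 > 0, k2 >= 0, g > 0, T_step > 0)
  structure(list(k1 = k1, k2 = k2, g = g, T_step = T_step),
            class = "load_coefficients")
}

#' Effective vertical hip force
#'
#' `F = k1 * Q * g`: the patient's weight amplified by the activity
#' multiplier `k1`.
#'
#' @param Q body mass, kg (> 0).
#' @param k1 dimensionless force multiplier.
#' @param g gravitational acceleration, m/s^2.
#' @return Force in newtons.
#' @export
effective_force <- function(Q, k1, g = 9.81) {
  if (any(Q <= 0)) stop("body mass Q must be positive")
  k1 * Q * g
}

#' Normal stress under eccentric compression
#'
#' Compression plus the bending contribution of the femoral offset:
#' `sigma = (F / A) * (1 + h * y_max / i_x^2)`.
#'
#' @param F vertical force, N.
#' @param geom a [stress_geometry()].
#' @param h femoral offset (load eccentricity), mm.
#' @return Stress in MPa.
#' @export
normal_stress <- function(F, geom, h) {
  stopifnot(inherits(geom, "stress_geometry"))
  (F / geom$A) * (1 + h * geom$y_max / geom$i_x^2)
}

#' Torsional shear stress
#'
#' The horizontal force component twists the stem with torque
#' `Mtr = k2 * W` (N.m); the shear stress is `tau = Mtr * R / I0` after
#' converting the torque to N.mm.
#'
#' @param Q body mass, kg.
#' @param k2 torque arm per unit weight, meters.
#' @param geom a [stress_geometry()].
#' @param g gravitational acceleration, m/s^2.
#' @return Shear stress in MPa.
#' @export
shear_stress <- function(Q, k2, geom, g = 9.81) {
  stopifnot(inherits(geom, "stress_geometry"))
  if (geom$I0 <= 0) stop("polar moment I0 must be positive")
  Mtr_Nmm <- k2 * Q * g * 1000   # N.m -> N.mm
  Mtr_Nmm * geom$R / geom$I0
}

#' Principal (equivalent) normal stress
#'
#' Combines normal and shear stress into the largest principal stress:
#' `sigma_eq = sigma/2 + sqrt(sigma^2 + 4 tau^2)/2`.  Reduces to `sigma`
#' when `tau = 0` and to `tau` when `sigma = 0`, and always dominates
#' both.
#'
#' @param sigma normal stress (>= 0), MPa.
#' @param tau shear stress, MPa.
#' @return Equivalent stress, MPa.
#' @export
equivalent_stress <- function(sigma, tau) {
  stopifnot(all(sigma >= 0))
  sigma / 2 + sqrt(sigma^2 + 4 * tau^2) / 2
}

#' Torsion-adjusted load coefficient
#'
#' Folding the torsional shear into the principal stress turns the force
#' multiplier `k1` into the modified load coefficient
#' `K = (k1 / 2) * (1 + sqrt(1 + X^2))` with
#' `X = 4 k2 R / (k1 i_x^2 (1 + h y_max / i_x^2))` (`k2` converted to mm).
#' With torsion neglected (`k2 = 0`), `K = k1` exactly; in general
#' `K >= k1`.
#'
#' @param k1 dimensionless force multiplier (> 0).
#' @param k2 torque arm per unit weight, meters.
#' @param geom a [stress_geometry()].
#' @param h femoral offset, mm.
#' @return The modified load coefficient `K`, dimensionless.
#' @export
torsion_adjusted_K <- function(k1, k2, geom, h) {
  stopifnot(inherits(geom, "stress_geometry"))
  if (any(k1 <= 0)) stop("force multiplier k1 must be positive")
  k2_mm <- 1000 * k2
  X <- 4 * k2_mm * geom$R /
    (k1 * geom$i_x^2 * (1 + h * geom$y_max / geom$i_x^2))
  (k1 / 2) * (1 + sqrt(1 + X^2))
}

#' Strain-life and stress-life amplitudes
#'
#' The strain-life decomposition at `N` cycles: elastic amplitude
#' `(sigma_f'/E) N^b`, plastic amplitude `eps_f' N^c_eps`, total their
#' sum; plus the Basquin stress amplitude `sigma_f' N^c_eps`.  Setting
#' `eps_f' = 0` collapses the total onto the elastic branch.
#'
#' @param N cycles to failure (> 0).
#' @param sigma_f_prime fatigue strength (stress ductility) coefficient,
#'   MPa.
#' @param E elastic modulus, MPa.
#' @param b elastic (fatigue strength) exponent.
#' @param eps_f_prime fatigue (plastic strain) ductility coefficient.
#' @param c_eps fatigue ductility exponent.
#' @return List with `elastic`, `plastic`, `total` strain amplitudes and
#'   the `basquin_stress` amplitude.
#' @export
strain_life_amplitude <- function(N, sigma_f_prime, E, b,
                                  eps_f_prime = 0, c_eps = b) {
  if (any(N <= 0)) stop("cycle count N must be positive")
  elastic <- (sigma_f_prime / E) * N^b
  plastic <- eps_f_prime * N^c_eps
  list(elastic = elastic, plastic = plastic, total = elastic + plastic,
       basquin_stress = sigma_f_prime * N^c_eps)
}
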