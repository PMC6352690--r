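#' Principal stretch triplet for incompressible uniaxial extension
#'
#' For an isochoric (volume-preserving) uniaxial deformation the lateral
#' stretches are equal and fixed by the axial stretch:
#' \eqn{(\lambda, \lambda^{-1/2}, \lambda^{-1/2})}, so that
#' \eqn{\lambda_1\lambda_2\lambda_3 = 1}.
#'
#' @param lambda Numeric vector of axial stretch ratios, all `> 0`.
#'
#' @return A tibble with columns `lambda1`, `lambda2`, `lambda3`, one row per
#'   input stretch.
#' @examples
#' uniaxial_stretch_triplet(c(1, 4))
#' @export
uniaxial_stretch_triplet <- function(lambda) {
  check_positive(lambda, "lambda")
  tibble(lambda1 = lambda, lambda2 = lambda^(-1 / 2), lambda3 = lambda^(-1 / 2))
}

#' Cauchy-Green invariants from principal stretches
#'
#' Computes the three invariants of the right Cauchy-Green tensor,
#' \eqn{I_1 = \sum_i \lambda_i^2},
#' \eqn{I_2 = \sum_{i<j} \lambda_i^2 \lambda_j^2} (one term per unordered
#' pair), and \eqn{I_3 = \prod_i \lambda_i^2}. On any incompressible path
#' \eqn{I_3 = 1}.
#'
#' @param stretches A data frame with columns `lambda1`, `lambda2`, `lambda3`
#'   (as returned by [uniaxial_stretch_triplet()]), or a numeric vector of
#'   length 3.
#'
#' @return A tibble with columns `I1`, `I2`, `I3`.
#' @examples
#' stretch_invariants(c(1, 1, 1))
#' stretch_invariants(uniaxial_stretch_triplet(1.5))
#' @export
stretch_invariants <- function(stretches) {
  if (is.numeric(stretches) && is.null(dim(stretches))) {
    if (length(stretches) != 3L) {
      abort("A numeric `stretches` input must have exactly 3 components.")
    }
    stretches <- tibble(
      lambda1 = stretches[[1]], lambda2 = stretches[[2]], lambda3 = stretches[[3]]
    )
  }
  for (nm in c("lambda1", "lambda2", "lambda3")) {
    if (!nm %in% names(stretches)) {
      abort(paste0("`stretches` is missing component `", nm, "`."))
    }
    check_positive(stretches[[nm]], nm)
  }
  l1 <- stretches$lambda1^2
  l2 <- stretches$lambda2^2
  l3 <- stretches$lambda3^2
  tibble(
    I1 = l1 + l2 + l3,
    I2 = l1 * l2 + l1 * l3 + l2 * l3,
    I3 = l1 * l2 * l3
  )
}

#' Veronda-Westmann strain-energy density
#'
#' Evaluates the two-parameter exponential strain-energy function used for
#' strain-stiffening soft tissue,
#' \deqn{\psi = c_1\left(e^{c_2 (I_1 - 3)} - 1\right) - \frac{c_1 c_2}{2}(I_2 - 3),}
#' which vanishes identically in the undeformed reference state
#' (\eqn{I_1 = I_2 = 3}).
#'
#' @param invariants A data frame with columns `I1` and `I2` (see
#'   [stretch_invariants()]).
#' @param c1 Stress-like material constant (MPa), `> 0` for physical fits.
#' @param c2 Dimensionless exponential stiffening constant, `> 0`.
#'
#' @return Numeric vector of energy densities in MPa.
#' @examples
#' vw_energy(stretch_invariants(c(1, 1, 1)), c1 = 13.1, c2 = 0.21)
#' @export
vw_energy <- function(invariants, c1, c2) {
  if (!all(c("I1", "I2") %in% names(invariants))) {
    abort("`invariants` must have columns `I1` and `I2`.")
  }
  c1 * (exp(c2 * (invariants$I1 - 3)) - 1) - (c1 * c2 / 2) * (invariants$I2 - 3)
}

#' Veronda-Westmann uniaxial true stress (closed form)
#'
#' True (Cauchy) stress under incompressible uniaxial extension at stretch
#' \eqn{\lambda}, where \eqn{I_1 = \lambda^2 + 2/\lambda}:
#' \deqn{\sigma = 2\left(\lambda^2 - \tfrac{1}{\lambda}\right) c_1 c_2
#'   \left(e^{c_2 (I_1 - 3)} - \tfrac{1}{2\lambda}\right).}
#' The algebraic prefactor makes \eqn{\sigma(1) = 0} exactly. This closed form
#' is the derivative of [vw_energy()] along the incompressible path; the
#' agreement is asserted against the finite-difference oracle
#' [uniaxial_stress_numeric()] in the test suite rather than assumed.
#'
#' @param lambda Numeric vector of axial stretch ratios, all `> 0`.
#' @inheritParams vw_energy
#'
#' @return Numeric vector of true stresses in MPa.
#' @examples
#' vw_uniaxial_stress(c(1, 1.5, 2), c1 = 13.1, c2 = 0.21)
#' @export
vw_uniaxial_stress <- function(lambda, c1, c2) {
  check_positive(lambda, "lambda")
  I1 <- lambda^2 + 2 / lambda
  2 * (lambda^2 - 1 / lambda) * c1 * c2 * (exp(c2 * (I1 - 3)) - 1 / (2 * lambda))
}

#' Strain-energy model objects
#'
#' A minimal container for an invariant-based strain-energy function
#' \eqn{\psi(I_1, I_2)}, used to drive the model-agnostic numerical stress
#' oracle. `vw_model()` wraps [vw_energy()]; `neo_hookean_model()`
#' (\eqn{\psi = c (I_1 - 3)}) exists purely as a closed-form test fixture.
#'
#' @param name Identifier string.
#' @param parameters Named numeric vector of model constants.
#' @param energy A function of `(I1, I2)` returning energy density in MPa.
#'
#' @return An object of class `strain_energy_model`.
#' @examples
#' m <- vw_model(c1 = 13.1, c2 = 0.21)
#' m$energy(I1 = 3, I2 = 3)
#' @export
strain_energy_model <- function(name, parameters, energy) {
  stopifnot(is.character(name), length(name) == 1L, is.function(energy))
  if (abs(energy(3, 3)) > 1e-12) {
    abort("Strain energy must vanish in the reference state (I1 = I2 = 3).")
  }
  structure(
    list(name = name, parameters = parameters, energy = energy),
    class = "strain_energy_model"
  )
}

#' @rdname strain_energy_model
#' @inheritParams vw_energy
#' @export
vw_model <- function(c1, c2) {
  strain_energy_model(
    name = "veronda-westmann",
    parameters = c(c1 = c1, c2 = c2),
    energy = function(I1, I2) {
      c1 * (exp(c2 * (I1 - 3)) - 1) - (c1 * c2 / 2) * (I2 - 3)
    }
  )
}

#' @rdname strain_energy_model
#' @param c Neo-Hookean shear-like constant (MPa).
#' @export
neo_hookean_model <- function(c) {
  strain_energy_model(
    name = "neo-hookean",
    parameters = c(c = c),
    energy = function(I1, I2) c * (I1 - 3)
  )
}

#' Uniaxial true stress by numerical differentiation of the strain energy
#'
#' Independent oracle for closed-form stress laws: restricts a strain-energy
#' model to the incompressible uniaxial path
#' \eqn{\hat\psi(\lambda) = \psi(\lambda^2 + 2/\lambda,\; 2\lambda + 1/\lambda^2)}
#' and returns \eqn{\sigma = \lambda\, d\hat\psi/d\lambda} by central finite
#' difference. This is the principal-stress relation
#' \eqn{\sigma_1 = \lambda_1 \partial\psi/\partial\lambda_1 -
#' \lambda_3 \partial\psi/\partial\lambda_3} evaluated without any
#' model-specific algebra, so it can certify [vw_uniaxial_stress()].
#'
#' @param model A [strain_energy_model()].
#' @param lambda Numeric vector of stretches, all `> 0`.
#' @param step Relative finite-difference step; the absolute step is
#'   `step * lambda`. The default `1e-6` balances truncation against round-off
#'   in double precision.
#'
#' @return Numeric vector of true stresses in MPa.
#' @examples
#' uniaxial_stress_numeric(vw_model(13.1, 0.21), 1.5)
#' @export
uniaxial_stress_numeric <- function(model, lambda, step = 1e-6) {
  stopifnot(inherits(model, "strain_energy_model"))
  check_positive(lambda, "lambda")
  check_positive(step, "step")
  h <- step * lambda
  if (any(lambda - h <= 0)) {
    abort("`step` is too large: lambda - step * lambda must stay positive.")
  }
  psi_hat <- function(lam) model$energy(lam^2 + 2 / lam, 2 * lam + 1 / lam^2)
  lambda * (psi_hat(lambda + h) - psi_hat(lambda - h)) / (2 * h)
}

# Shared domain guard: every component must be finite and strictly positive;
# the error names the first offending element.
check_positive <- function(x, name) {
  if (length(x) == 0L || !is.numeric(x)) {
    abort(paste0("`", name, "` must be a non-empty numeric vector."))
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "`%s` must be strictly positive and finite; element %d is %s.",
      name, bad[[1]], format(x[bad[[1]]])
    ))
  }
  invisible(x)
}
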