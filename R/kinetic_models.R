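#' Kinetic model families
#'
#' The three empirical models used to describe osmotic-dehydration mass
#' transfer, addressable by string key:
#' \describe{
#'   \item{`"peleg"`}{\eqn{Y = Y_0 \pm \tau/(k_1 + k_2 \tau)}: two-parameter
#'     hyperbola; \eqn{1/k_1} is the initial rate, \eqn{Y_0 \pm 1/k_2} the
#'     equilibrium value.}
#'   \item{`"kelvin_voigt"`}{\eqn{Y = A (1 - e^{-\tau/B})}: single-
#'     exponential saturation towards the equilibrium A with time constant
#'     B (min).}
#'   \item{`"burgers"`}{\eqn{Y = A (1 - e^{-\tau/B}) + C \tau}: the
#'     Kelvin-Voigt saturation plus a constant-rate term with velocity C,
#'     capturing a sustained uptake/loss phase.}
#' }
#'
#' @return character vector of valid family keys.
#' @export
model_families <- function() c("peleg", "kelvin_voigt", "burgers")

#' Evaluate the Peleg model
#'
#' \eqn{Y(\tau) = Y_0 + d \cdot \tau/(k_1 + k_2 \tau)} with direction
#' \eqn{d = +1} for responses that grow from \eqn{Y_0} (WL, SG, WL_T) and
#' \eqn{d = -1} for responses that decay (water content from its fresh
#' value; the dehydration ratio from 1).
#'
#' @param tau immersion time(s), min, >= 0.
#' @param Y0 value of the response at tau = 0.
#' @param k1 Peleg rate constant (> 0); the initial rate is 1/k1.
#' @param k2 Peleg capacity constant (> 0); the total change is 1/k2.
#' @param direction +1 or -1.
#' @return numeric vector of model values.
#' @export
eval_peleg <- function(tau, Y0, k1, k2, direction = 1) {
  stopifnot(is.numeric(tau), all(tau >= 0))
  if (!direction %in% c(-1, 1)) stop("`direction` must be +1 or -1", call. = FALSE)
  if (k1 < 0 || k2 < 0 || (k1 == 0 && k2 == 0)) {
    stop("`k1` and `k2` must be non-negative and not both zero", call. = FALSE)
  }
  frac <- ifelse(tau == 0, 0, tau / (k1 + k2 * tau))
  Y0 + direction * frac
}

#' Evaluate the Kelvin-Voigt saturation model
#'
#' \eqn{Y(\tau) = A (1 - e^{-\tau/B})}. The rate-constant form
#' \eqn{A (1 - e^{-K\tau})} with \eqn{K = 1/B} is identical; pass
#' `K =` instead of `B =` to use it.
#'
#' @param tau immersion time(s), min, >= 0.
#' @param A equilibrium value of the response.
#' @param B time constant (min, > 0): 63.2\% of A is attained at tau = B.
#' @param K optional rate constant (1/min); exactly one of `B`, `K`.
#' @return numeric vector of model values.
#' @export
eval_kelvin_voigt <- function(tau, A, B = NULL, K = NULL) {
  stopifnot(is.numeric(tau), all(tau >= 0))
  if (is.null(B) == is.null(K)) {
    stop("supply exactly one of `B` or `K`", call. = FALSE)
  }
  if (is.null(B)) {
    if (K <= 0) stop("`K` must be positive", call. = FALSE)
    B <- 1 / K
  }
  if (B <= 0) stop("`B` must be positive", call. = FALSE)
  A * (1 - exp(-tau / B))
}

#' Evaluate the Burgers model
#'
#' \eqn{Y(\tau) = A (1 - e^{-\tau/B}) + C \tau}: Kelvin-Voigt saturation
#' plus a linear constant-rate period. With C = 0 it reduces exactly to the
#' Kelvin-Voigt model.
#'
#' @inheritParams eval_kelvin_voigt
#' @param A retardation value of the saturating component.
#' @param C constant-rate velocity (response units per min).
#' @return numeric vector of model values.
#' @export
eval_burgers <- function(tau, A, B, C) {
  eval_kelvin_voigt(tau, A = A, B = B) + C * tau
}

#' Initial mass-transfer rate implied by Peleg's k1
#'
#' The derivative of the Peleg model at tau = 0 is
#' \eqn{d/k_1} (direction-signed): the initial dehydration or uptake rate
#' in response units per minute. Low k1 means fast initial transfer.
#'
#' @inheritParams eval_peleg
#' @return signed initial rate, `direction / k1`.
#' @export
peleg_initial_rate <- function(k1, direction = 1) {
  if (!direction %in% c(-1, 1)) stop("`direction` must be +1 or -1", call. = FALSE)
  if (any(k1 <= 0)) stop("`k1` must be positive", call. = FALSE)
  direction / k1
}

#' Equilibrium value implied by Peleg's k2
#'
#' As tau grows, the Peleg model approaches \eqn{Y_0 + d/k_2}; 1/k2 is the
#' total attainable change of the response. Low k2 means a large
#' equilibrium change (for water content: more water removed).
#'
#' @inheritParams eval_peleg
#' @return asymptotic value `Y0 + direction / k2`.
#' @export
peleg_equilibrium <- function(Y0, k2, direction = 1) {
  if (!direction %in% c(-1, 1)) stop("`direction` must be +1 or -1", call. = FALSE)
  if (any(k2 <= 0)) stop("`k2` must be positive", call. = FALSE)
  Y0 + direction / k2
}

# shared forward evaluation used by the fitter: params is a named list
eval_family <- function(family, tau, params) {
  switch(family,
    peleg = eval_peleg(tau, Y0 = params$Y0, k1 = params$k1, k2 = params$k2,
                       direction = params$direction),
    kelvin_voigt = eval_kelvin_voigt(tau, A = params$A, B = params$B),
    burgers = eval_burgers(tau, A = params$A, B = params$B, C = params$C),
    stop("unknown model family '", family, "'; valid keys: ",
         paste(model_families(), collapse = ", "), call. = FALSE)
  )
}
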