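#' Fixed biophysical constants of the conductance-based microcircuit
#'
#' Units convention used throughout the package: membrane potentials in mV,
#' time in ms (so channel time constants are in ms and frequencies supplied
#' in Hz are converted internally to rad/ms), conductances relative to the
#' fixed leak conductance `gL = 1`.
#'
#' @param VL,VAMPA,VGABA,VNMDA Reversal potentials (mV) of the leak, AMPA,
#'   GABA-A and NMDA channels. Must satisfy `VGABA < VL < VAMPA <= VNMDA`.
#' @param alpha_nmda Slope (1/mV) of the voltage-dependent magnesium switch
#'   gating the NMDA channel, `m(V) = 1 / (1 + 0.2 exp(-alpha_nmda * V))`.
#' @param sigmoid_threshold Depolarisation (mV) at which the population
#'   firing-rate sigmoid reaches one half.
#' @param sigmoid_slope Slope (1/mV) of the firing-rate sigmoid. The default
#'   is chosen so that prior-mean 1/2/4-region networks have a stable,
#'   resonant fixed point (see the methods vignette).
#' @param gL Fixed leak conductance (dimensionless, reference scale).
#' @param nmda_intrinsic_ratio Fixed fraction of each intrinsic excitatory
#'   connection routed to the (slow) NMDA conductance in addition to AMPA.
#' @return An object of class `"model_constants"`.
#' @export
model_constants <- function(VL = -70, VAMPA = 60, VGABA = -90, VNMDA = 60,
                            alpha_nmda = 0.06,
                            sigmoid_threshold = -40, sigmoid_slope = 1/4,
                            gL = 1, nmda_intrinsic_ratio = 0.25) {
  stopifnot(is.numeric(VL), is.numeric(VAMPA), is.numeric(VGABA),
            is.numeric(VNMDA))
  if (!(VGABA < VL && VL < VAMPA && VAMPA <= VNMDA))
    stop("reversal potentials must satisfy VGABA < VL < VAMPA <= VNMDA")
  if (alpha_nmda <= 0) stop("alpha_nmda must be positive")
  if (sigmoid_slope <= 0) stop("sigmoid_slope must be positive")
  if (gL <= 0) stop("gL must be positive")
  structure(list(VL = VL, VAMPA = VAMPA, VGABA = VGABA, VNMDA = VNMDA,
                 alpha_nmda = alpha_nmda,
                 sigmoid_threshold = sigmoid_threshold,
                 sigmoid_slope = sigmoid_slope,
                 gL = gL, nmda_intrinsic_ratio = nmda_intrinsic_ratio),
            class = "model_constants")
}

#' Voltage-dependent magnesium switch of the NMDA channel
#'
#' `m(V) = 1 / (1 + 0.2 exp(-alpha_nmda * V))`; a total, strictly increasing
#' map from depolarisation to the open fraction of magnesium-blocked NMDA
#' channels.
#'
#' @param V Membrane depolarisation (mV); any finite numeric vector.
#' @param constants A [model_constants()] object.
#' @return Gate values in (0, 1).
#' @export
magnesium_switch <- function(V, constants = model_constants()) {
  stopifnot(is.numeric(V))
  1 / (1 + 0.2 * exp(-constants$alpha_nmda * V))
}

# derivative of the magnesium switch; m' = alpha * m * (1 - m)
magnesium_switch_grad <- function(V, constants) {
  m <- magnesium_switch(V, constants)
  constants$alpha_nmda * m * (1 - m)
}

#' Population firing-rate sigmoid
#'
#' Logistic squashing of mean depolarisation into a normalised firing rate,
#' `sigma(V) = 1 / (1 + exp(-slope * (V - threshold)))`. The rate is 1/2 at
#' the threshold and its derivative is maximal there.
#'
#' @inheritParams magnesium_switch
#' @return Normalised rates in \[0, 1\].
#' @export
firing_rate <- function(V, constants = model_constants()) {
  stopifnot(is.numeric(V))
  1 / (1 + exp(-constants$sigmoid_slope * (V - constants$sigmoid_threshold)))
}

firing_rate_grad <- function(V, constants) {
  s <- firing_rate(V, constants)
  constants$sigmoid_slope * s * (1 - s)
}
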