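# Worm-like chain elasticity of the ssDNA adjuster: Marko-Siggia
# interpolation force and its closed-form integral.

#' WLC parameter set
#'
#' @param Lp persistence length in nm (default 1.0 nm, ssDNA in ~20 mM Mg).
#' @param Lc contour length in nm.
#' @param kT thermal energy in pN nm (default 4.114, 298 K).
#' @return list of class parameters.
#' @export
wlcParams <- function(Lc, Lp = 1.0, kT = 4.114) {
    if (Lp <= 0 || Lc <= 0 || kT <= 0)
        stop("Lp, Lc and kT must all be positive")
    list(Lp = Lp, Lc = Lc, kT = kT)
}

#' WLC entropic tension at a given extension
#'
#' Marko-Siggia interpolation
#' \deqn{F(x) = (kT/Lp)\,[\,1/(4(1-x/Lc)^2) - 1/4 + x/Lc\,]}
#' strictly increasing on `[0, Lc)` and diverging at full extension.
#'
#' @param x extension in nm, `0 <= x < Lc`.
#' @param params from [wlcParams()].
#' @return force in pN.
#' @export
wlcForce <- function(x, params) {
    if (any(x < 0)) stop("range error: extension must be non-negative")
    if (any(x >= params$Lc))
        stop("divergence error: extension reached the contour length")
    t <- x / params$Lc
    (params$kT / params$Lp) * (1 / (4 * (1 - t)^2) - 0.25 + t)
}

#' WLC stretching energy at a given extension
#'
#' Closed form of the Marko-Siggia integral,
#' \deqn{E(x) = (kT/Lp)\,[\,Lc/(4(1-x/Lc)) - Lc/4 - x/4 + x^2/(2 Lc)\,],}
#' so that `E(0) = 0` and `dE/dx = wlcForce(x)`.
#'
#' @inheritParams wlcForce
#' @return energy in pN nm.
#' @export
wlcEnergy <- function(x, params) {
    if (any(x < 0)) stop("range error: extension must be non-negative")
    if (any(x >= params$Lc))
        stop("divergence error: extension reached the contour length")
    Lc <- params$Lc
    t <- x / Lc
    (params$kT / params$Lp) * (Lc / (4 * (1 - t)) - Lc / 4 - x / 4 +
                               x^2 / (2 * Lc))
}
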