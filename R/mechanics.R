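# Torsional-spring hinge + adjuster strain-energy model: the total strain
# energy of a hinge design as a function of included angle is the hinge
# spring energy plus the entropic energy of the ssDNA adjuster, other
# modules being treated as rigid.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Torsional hinge parameters
#'
#' Harmonic bending model `E = k/2 (theta - theta0)^2` with `theta` in
#' radians.
#'
#' @param stiffness k in pN nm / rad (>= 0).
#' @param rest_angle_deg unstrained included angle (default 180: the
#'   reference folds straight).
#' @return parameter list.
#' @export
torsionalHinge <- function(stiffness, rest_angle_deg = 180) {
    if (stiffness < 0) stop("stiffness must be >= 0")
    if (rest_angle_deg <= 0 || rest_angle_deg > 180)
        stop("rest angle must be in (0, 180] degrees")
    list(k = stiffness, theta0_deg = rest_angle_deg)
}

#' Hinge arm geometry
#'
#' Distances from the hinge pivot to the two points where the adjuster
#' leaves the arms. The default 42.84 nm (126 nt x 0.34 nm) on both arms
#' maps the full fold range onto 252 nt of adjuster, i.e. 21 nt per 15
#' degrees on average.
#'
#' @param r1,r2 anchor distances in nm (> 0).
#' @return parameter list.
#' @export
hingeGeometry <- function(r1 = 42.84, r2 = 42.84) {
    if (r1 <= 0 || r2 <= 0) stop("r1 and r2 must be positive")
    list(r1 = r1, r2 = r2)
}

#' Adjuster end-to-end extension at a given included angle
#'
#' Law-of-cosines chord between the two anchors:
#' `x = sqrt(r1^2 + r2^2 - 2 r1 r2 cos(theta))`.
#'
#' @param theta_deg included angle in degrees, in `[0, 180]`.
#' @param geom from [hingeGeometry()].
#' @return extension in nm.
#' @export
adjusterExtension <- function(theta_deg, geom) {
    th <- .deg2rad(theta_deg)
    sqrt(pmax(geom$r1^2 + geom$r2^2 - 2 * geom$r1 * geom$r2 * cos(th), 0))
}

#' Strain-energy landscape over the included angle
#'
#' `E_total(theta) = k/2 (theta - theta0)^2 + E_wlc(x(theta))`, with grid
#' points where the adjuster extension reaches its contour length flagged
#' infeasible. Both terms are zero at their own unstrained configuration.
#'
#' @param hinge from [torsionalHinge()].
#' @param geom from [hingeGeometry()].
#' @param wlc from [wlcParams()] describing the ssDNA adjuster, or `NULL`
#'   for a bare hinge.
#' @param theta_deg angle grid in degrees (default 0.25-degree steps on
#'   (0, 180]).
#' @return an [EnergyLandscape-class].
#' @export
energyLandscape <- function(hinge, geom, wlc,
                            theta_deg = seq(0.25, 180, by = 0.25)) {
    x <- adjusterExtension(theta_deg, geom)
    # a chain able to span the rest-angle opening without nearing full
    # extension is slack (reservoir regime) and treated as force-free
    if (!is.null(wlc) && wlc$Lc >= adjusterExtension(hinge$theta0_deg, geom))
        wlc <- NULL
    feas <- if (is.null(wlc)) rep(TRUE, length(x)) else x < wlc$Lc
    if (!any(feas)) stop("all grid points infeasible: adjuster shorter ",
                         "than the minimum anchor distance")
    Eh <- hinge$k / 2 * (.deg2rad(theta_deg - hinge$theta0_deg))^2
    Ea <- rep(0, length(x))
    if (!is.null(wlc)) Ea[feas] <- wlcEnergy(x[feas], wlc)
    Ea[!feas] <- NA_real_
    new("EnergyLandscape", theta_deg = theta_deg, E_hinge = Eh,
        E_adjuster = Ea, E_total = Eh + Ea, feasible = feas,
        params = list(hinge = hinge, geom = geom, wlc = wlc))
}

#' Predict the equilibrium included angle
#'
#' Locates the minimum of the total strain energy by a coarse grid search
#' followed by bracketed 1-D minimization (to well below 0.1 degree). When
#' the minimum sits on the feasible boundary the result carries a
#' `"boundary"` attribute.
#'
#' @inheritParams energyLandscape
#' @return predicted angle in degrees.
#' @export
predictAngle <- function(hinge, geom, wlc) {
    if (!is.null(wlc) && wlc$Lc >= adjusterExtension(hinge$theta0_deg, geom))
        wlc <- NULL  # slack adjuster: no tension, equilibrium at theta0
    if (is.null(wlc)) return(hinge$theta0_deg)
    Etot <- function(th) {
        Eh <- hinge$k / 2 * (.deg2rad(th - hinge$theta0_deg))^2
        if (is.null(wlc)) return(Eh)
        x <- adjusterExtension(th, geom)
        if (x >= wlc$Lc) return(Inf)
        Eh + wlcEnergy(x, wlc)
    }
    grid <- seq(0.05, 180, by = 0.05)
    Eg <- vapply(grid, Etot, numeric(1))
    if (!any(is.finite(Eg)))
        stop("infeasible landscape: no angle admits the adjuster")
    # ties broken toward the rest angle
    finite <- which(is.finite(Eg))
    best <- finite[order(Eg[finite], -grid[finite])][1]
    lo <- grid[max(best - 1L, 1L)]
    hi <- grid[min(best + 1L, length(grid))]
    opt <- stats::optimize(Etot, lower = lo, upper = hi, tol = 1e-3)
    out <- opt$minimum
    if (abs(out - 180) < 0.06 || out < 0.11)
        attr(out, "boundary") <- TRUE
    out
}

#' Included angle set geometrically by a duplex adjuster
#'
#' A strut-bound (dsDNA) adjuster behaves as a rigid chord: the included
#' angle solves `adjusterExtension(theta) = 0.34 * n_bridge`, independent of
#' the hinge stiffness. `n_bridge` is the number of adjuster nucleotides
#' bridging the hinge opening (for a design, total adjuster length minus
#' the arm-stored part; see [bridgeNt()]).
#'
#' @param n_bridge bridging adjuster length in nt.
#' @param geom from [hingeGeometry()].
#' @return included angle in degrees.
#' @export
predictAngleDs <- function(n_bridge, geom) {
    x <- contourNm(n_bridge, "duplex")
    lohi <- c(abs(geom$r1 - geom$r2), geom$r1 + geom$r2)
    if (x > lohi[2] + 1e-9 || x < lohi[1] - 1e-9)
        stop("infeasible error: chord of ", round(x, 2),
             " nm is outside the reachable range [", round(lohi[1], 2),
             ", ", round(lohi[2], 2), "] nm")
    x <- min(max(x, lohi[1]), lohi[2])
    cosv <- (geom$r1^2 + geom$r2^2 - x^2) / (2 * geom$r1 * geom$r2)
    .rad2deg(acos(pmin(pmax(cosv, -1), 1)))
}

#' Bridging adjuster length of a design
#'
#' Number of adjuster nucleotides spanning the hinge opening. The part of
#' the adjuster anchored along the arms is fixed; every shortened unit comes
#' out of the bridge. At full length the bridge equals the straight chord
#' `(r1 + r2) / 0.34` nt, so
#' `bridge = length_nt - (full_length_nt - (r1 + r2)/0.34)`.
#'
#' @param length_nt adjuster length in nt (or an [OrigamiDesign-class],
#'   from which length and full length are taken).
#' @param geom from [hingeGeometry()].
#' @param full_length_nt full (reference) adjuster length in nt.
#' @return bridging length in nt.
#' @export
bridgeNt <- function(length_nt, geom = hingeGeometry(),
                     full_length_nt = 504L) {
    if (is(length_nt, "OrigamiDesign")) {
        full_length_nt <- length_nt@adjuster$full_length_nt
        length_nt <- length_nt@adjuster$length_nt
    }
    bridge <- length_nt - (full_length_nt - (geom$r1 + geom$r2) / .RISE_DS)
    if (any(bridge < 0)) stop("adjuster shorter than the arm-stored length")
    bridge
}

#' Boltzmann statistics of an energy landscape
#'
#' Thermal distribution `p(theta) proportional to exp(-E_total/kT)` on the
#' feasible grid; returns the mean and standard deviation of the included
#' angle.
#'
#' @param landscape an [EnergyLandscape-class].
#' @param kT thermal energy in pN nm.
#' @return list with `mean_deg`, `sd_deg` and the normalized density.
#' @export
boltzmannStats <- function(landscape, kT = 4.114) {
    ok <- landscape@feasible & is.finite(landscape@E_total)
    if (!any(ok)) stop("all grid points infeasible")
    th <- landscape@theta_deg[ok]
    E <- landscape@E_total[ok]
    w <- exp(-(E - min(E)) / kT)
    dth <- diff(th)
    dth <- c(dth[1], dth)
    p <- w / sum(w * dth)
    m <- sum(p * th * dth)
    s <- sqrt(sum(p * (th - m)^2 * dth))
    list(mean_deg = m, sd_deg = s,
         density = data.frame(theta_deg = th, p = p))
}
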