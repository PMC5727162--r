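# Hinge torsional-stiffness estimation: torque balance between the hinge
# spring and the WLC tension of the ssDNA adjuster at the measured mean
# angle, plus the equipartition (PCA) estimator for angle trajectories.

#' Estimate hinge stiffness from angle observations
#'
#' For each observation the hinge is modeled as a torsional spring loaded
#' by the adjuster tension: at equilibrium
#' `k (theta0 - theta) = F(x) * r1 r2 sin(theta) / x`, where `x` is the
#' adjuster extension at the measured angle and the right-hand side is the
#' torque of the WLC tension about the pivot. Observations with a slack
#' adjuster (contour length at least the rest-angle extension, so no
#' bending torque) or extension beyond the contour length are skipped with
#' a warning; an observation at the rest angle is an error (zero
#' deflection, indeterminate k).
#'
#' @param observations data.frame with column `mean_angle_deg` (plus
#'   anything else, echoed through, e.g. `adjuster_nt`, `sd_deg`, `n`).
#' @param geom from [hingeGeometry()].
#' @param wlc_per_observation a single [wlcParams()] list or a list of them,
#'   one per observation.
#' @param theta0_deg hinge rest angle in degrees (default 180).
#' @return a [StiffnessEstimate-class].
#' @export
estimateStiffness <- function(observations, geom, wlc_per_observation,
                              theta0_deg = 180) {
    if (!nrow(observations)) stop("no observations")
    if (!is.null(wlc_per_observation$Lc))
        wlc_per_observation <- rep(list(wlc_per_observation),
                                   nrow(observations))
    if (length(wlc_per_observation) != nrow(observations))
        stop("need one WLC parameter set per observation")
    k <- rep(NA_real_, nrow(observations))
    status <- rep("ok", nrow(observations))
    for (i in seq_len(nrow(observations))) {
        th <- observations$mean_angle_deg[i]
        wlc <- wlc_per_observation[[i]]
        if (abs(th - theta0_deg) < 1e-9)
            stop("indeterminate error: observation ", i,
                 " sits at the rest angle (zero deflection)")
        if (wlc$Lc >= adjusterExtension(theta0_deg, geom)) {
            warning("observation ", i, " skipped: slack adjuster")
            status[i] <- "slack"
            next
        }
        x <- adjusterExtension(th, geom)
        if (x >= wlc$Lc) {
            warning("observation ", i, " skipped: extension beyond the ",
                    "adjuster contour length")
            status[i] <- "infeasible"
            next
        }
        torque <- wlcForce(x, wlc) * geom$r1 * geom$r2 * sin(.deg2rad(th)) / x
        k[i] <- torque / .deg2rad(theta0_deg - th)
    }
    if (!any(is.finite(k))) stop("no usable observations")
    obs <- observations
    obs$k <- k
    obs$status <- status
    new("StiffnessEstimate", k_per_obs = k,
        mean = mean(k, na.rm = TRUE), min = min(k, na.rm = TRUE),
        max = max(k, na.rm = TRUE), observations = obs)
}

#' Equipartition stiffness from an angle trajectory
#'
#' For a univariate included-angle time series the torsional stiffness is
#' `k = kT / var(theta)` (theta in radians, mean removed). For a
#' multivariate trajectory (columns = coordinates) the stiffness per
#' principal mode is `k_i = kT / lambda_i` with `lambda_i` the covariance
#' eigenvalues in decreasing order, so the softest mode comes first.
#'
#' @param angle_trajectory numeric vector of angles in degrees, or a matrix
#'   with one coordinate per column.
#' @param kT thermal energy in pN nm.
#' @return stiffness in pN nm / rad (vector for multivariate input);
#'   `Inf` with a warning for a constant trajectory.
#' @export
pcaStiffness <- function(angle_trajectory, kT = 4.114) {
    if (is.matrix(angle_trajectory)) {
        if (nrow(angle_trajectory) < 100L)
            stop("trajectory must have at least 100 samples")
        lam <- eigen(stats::cov(.deg2rad(angle_trajectory)),
                     symmetric = TRUE, only.values = TRUE)$values
        lam <- pmax(lam, 0)
        k <- ifelse(lam > 0, kT / lam, Inf)
        if (any(!is.finite(k))) warning("zero-variance mode: infinite stiffness")
        return(k)
    }
    if (length(angle_trajectory) < 100L)
        stop("trajectory must have at least 100 samples")
    v <- stats::var(.deg2rad(angle_trajectory))
    if (v == 0) {
        warning("zero variance: infinite stiffness")
        return(Inf)
    }
    kT / v
}

#' Read angle observations from CSV
#'
#' Expected columns: `hinge_class`, `adjuster_nt`, `mean_angle_deg`,
#' `sd_deg`, `n` (extra columns pass through).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readObservations <- function(path) {
    obs <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("mean_angle_deg")
    if (!all(need %in% names(obs)))
        stop("observations CSV must contain column(s): ",
             paste(setdiff(need, names(obs)), collapse = ", "))
    obs
}

#' Write an energy landscape to CSV
#'
#' Columns `theta_deg`, `E_hinge`, `E_adjuster`, `E_total`, `feasible`.
#'
#' @param landscape an [EnergyLandscape-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeLandscapeCsv <- function(landscape, path) {
    utils::write.csv(data.frame(theta_deg = landscape@theta_deg,
                                E_hinge = landscape@E_hinge,
                                E_adjuster = landscape@E_adjuster,
                                E_total = landscape@E_total,
                                feasible = landscape@feasible),
                     path, row.names = FALSE)
    invisible(path)
}
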