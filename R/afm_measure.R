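# Particle segmentation, classification, included-angle measurement and
# yield reporting on AFM-like height maps.

#' Segment particles from a height map
#'
#' Thresholds the image and labels connected components, dropping
#' components below a minimum area.
#'
#' @param hm a [HeightMap-class].
#' @param height_threshold height cutoff in nm (default half the nominal
#'   2-nm rod height).
#' @param min_area_nm2 minimum particle area (default 300 nm^2).
#' @return list of particle masks; each is a list with `id`, `px` (matrix
#'   of row/col pixel indices), `area_nm2` and the pixel size.
#' @export
segmentParticles <- function(hm, height_threshold = 1.0,
                             min_area_nm2 = 300) {
    if (height_threshold <= 0 || min_area_nm2 <= 0)
        stop("thresholds must be positive")
    mask <- hm@heights > height_threshold
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(lab)
    ids <- setdiff(unique(as.vector(lab)), 0)
    px_area <- hm@pixel_size^2
    out <- list()
    for (id in ids) {
        w <- which(lab == id, arr.ind = TRUE)
        if (nrow(w) * px_area < min_area_nm2) next
        out[[length(out) + 1L]] <-
            list(id = length(out) + 1L, px = w,
                 area_nm2 = nrow(w) * px_area,
                 pixel_nm = hm@pixel_size)
    }
    out
}

#' Classify a particle mask
#'
#' Area-band classification against the expected monomer footprint:
#' `monomer` within `[0.4, 1.6] x expected`, `fragment` below,
#' `aggregate` above. The lower edge admits fully folded monomers (whose
#' two overlapping arms halve the footprint) while still rejecting
#' half-length fragments at 0.25 x expected.
#'
#' @param particle a mask from [segmentParticles()].
#' @param expected_area_nm2 expected monomer footprint area.
#' @param band lower/upper relative band (default `c(0.4, 1.6)`).
#' @return `"monomer"`, `"aggregate"` or `"fragment"`.
#' @export
classifyParticle <- function(particle, expected_area_nm2,
                             band = c(0.4, 1.6)) {
    if (!nrow(particle$px)) stop("empty mask")
    rel <- particle$area_nm2 / expected_area_nm2
    if (rel < band[1]) "fragment"
    else if (rel > band[2]) "aggregate"
    else "monomer"
}

#' Expected monomer footprint area
#'
#' Footprint of two dilated rods: `2 * L * w` with the effective width
#' `rod_width + 2 * tip_radius`.
#'
#' @param arm_nm arm lengths (nm).
#' @param rod_width_nm rod width (nm).
#' @param tip_radius_nm tip dilation radius (nm).
#' @return area in nm^2.
#' @export
expectedMonomerArea <- function(arm_nm = c(95.2, 95.2), rod_width_nm = 6,
                                tip_radius_nm = 2) {
    sum(arm_nm) * (rod_width_nm + 2 * tip_radius_nm)
}

# fraction of sample points along segment a->b that fall on mask pixels
.segmentCoverage <- function(inmask, a, b, pixel_nm, nr, nc) {
    t <- seq(0.08, 0.92, length.out = 15)
    px <- a[1] + t * (b[1] - a[1])
    py <- a[2] + t * (b[2] - a[2])
    ri <- pmin(pmax(round(py / pixel_nm + 0.5), 1L), nr)
    ci <- pmin(pmax(round(px / pixel_nm + 0.5), 1L), nc)
    mean(inmask[cbind(ri, ci)])
}

.armDirection <- function(pts, vertex, tip) {
    if (nrow(pts) < 5L) return(NULL)
    pc <- stats::prcomp(pts, center = TRUE)
    d <- pc$rotation[, 1]
    if (sum(d * (tip - vertex)) < 0) d <- -d
    d / sqrt(sum(d^2))
}

.pointSegDist <- function(pts, a, b) {
    d <- b - a
    L2 <- sum(d^2)
    t <- if (L2 > 0)
        pmin(pmax(((pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2]) / L2,
                  0), 1) else 0
    sqrt((pts[, 1] - (a[1] + t * d[1]))^2 + (pts[, 2] - (a[2] + t * d[2]))^2)
}

#' Measure the included angle of a monomer particle
#'
#' Landmark-based re-implementation of an AFM angle-measurement script:
#' the two arm tips are found as the mask's farthest point pair, the vertex
#' candidate as the point farthest from the tip-tip chord; among the three
#' landmarks the hinge vertex is the one whose connecting segments to the
#' other two stay inside the mask. Arm pixels are then split by proximity
#' to the two vertex-tip segments and each arm direction is fitted as the
#' arm's first principal component; the included angle is the angle between
#' the two directions.
#'
#' Straight rods (no off-chord point beyond the rod width) are reported as
#' 180 degrees with a `straight` flag, or as 0 degrees with a `folded` flag
#' when the rod is much shorter than the two arms laid out straight.
#'
#' @param particle a mask from [segmentParticles()].
#' @param pixel_nm pixel size (defaults to the mask's).
#' @param rod_width_nm nominal dilated rod width used as the straightness
#'   scale (default 10).
#' @param expected_arm_nm arm lengths for fold detection (NULL disables).
#' @return list with `particle_id`, `included_angle_deg`, `arm_nm`
#'   (two fitted arm lengths) and `flag` (`ok`, `straight`, `folded`,
#'   `ambiguous`).
#' @export
measureIncludedAngle <- function(particle, pixel_nm = particle$pixel_nm,
                                 rod_width_nm = 10,
                                 expected_arm_nm = NULL) {
    px <- particle$px
    if (is.null(px) || nrow(px) < 10L)
        return(list(particle_id = particle$id,
                    included_angle_deg = NA_real_,
                    arm_nm = c(NA_real_, NA_real_), flag = "ambiguous"))
    pts <- cbind(x = (px[, "col"] - 0.5) * pixel_nm,
                 y = (px[, "row"] - 0.5) * pixel_nm)
    nr <- max(px[, "row"]) + 2L
    nc <- max(px[, "col"]) + 2L
    inmask <- matrix(FALSE, nr, nc)
    inmask[px] <- TRUE
    # pad one pixel so rounding at segment samples tolerates the lattice
    inmask <- inmask | rbind(inmask[-1, ], FALSE) |
        rbind(FALSE, inmask[-nr, ]) |
        cbind(inmask[, -1], FALSE) | cbind(FALSE, inmask[, -nc])
    ctr <- colMeans(pts)
    t1 <- pts[which.max((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2), ]
    t2 <- pts[which.max((pts[, 1] - t1[1])^2 + (pts[, 2] - t1[2])^2), ]
    chord <- sqrt(sum((t2 - t1)^2))
    dchord <- abs((t2[1] - t1[1]) * (t1[2] - pts[, 2]) -
                  (t1[1] - pts[, 1]) * (t2[2] - t1[2])) / max(chord, 1e-9)
    if (max(dchord) < rod_width_nm) {
        folded <- !is.null(expected_arm_nm) &&
            chord < 0.7 * sum(expected_arm_nm)
        return(list(particle_id = particle$id,
                    included_angle_deg = if (folded) 0 else 180,
                    arm_nm = if (folded) rep(chord, 2) else c(chord / 2,
                                                              chord / 2),
                    flag = if (folded) "folded" else "straight"))
    }
    t3 <- pts[which.max(dchord), ]
    land <- rbind(t1, t2, t3)
    cov <- vapply(1:3, function(i) {
        oth <- setdiff(1:3, i)
        (.segmentCoverage(inmask, land[i, ], land[oth[1], ], pixel_nm,
                          nr, nc) +
         .segmentCoverage(inmask, land[i, ], land[oth[2], ], pixel_nm,
                          nr, nc)) / 2
    }, numeric(1))
    vi <- which.max(cov)
    vertex <- land[vi, ]
    tips <- land[setdiff(1:3, vi), , drop = FALSE]
    dv <- sqrt((pts[, 1] - vertex[1])^2 + (pts[, 2] - vertex[2])^2)
    keep <- dv > rod_width_nm
    d1 <- .pointSegDist(pts, vertex, tips[1, ])
    d2 <- .pointSegDist(pts, vertex, tips[2, ])
    arm1 <- pts[keep & d1 <= d2, , drop = FALSE]
    arm2 <- pts[keep & d1 > d2, , drop = FALSE]
    u1 <- .armDirection(arm1, vertex, tips[1, ])
    u2 <- .armDirection(arm2, vertex, tips[2, ])
    if (is.null(u1) || is.null(u2))
        return(list(particle_id = particle$id,
                    included_angle_deg = NA_real_,
                    arm_nm = c(NA_real_, NA_real_), flag = "ambiguous"))
    ang <- .rad2deg(acos(pmin(pmax(sum(u1 * u2), -1), 1)))
    list(particle_id = particle$id, included_angle_deg = ang,
         arm_nm = c(sqrt(sum((tips[1, ] - vertex)^2)),
                    sqrt(sum((tips[2, ] - vertex)^2))),
         flag = "ok")
}

#' Measure every particle in a height map
#'
#' Segmentation, classification and angle measurement in one pass.
#'
#' @param hm a [HeightMap-class].
#' @param expected_area_nm2 expected monomer footprint (default from
#'   [expectedMonomerArea()] with the scene's own spec when available).
#' @param expected_arm_nm arm lengths for fold detection.
#' @param height_threshold,min_area_nm2 passed to [segmentParticles()].
#' @return data.frame with `particle_id`, `class`, `area_nm2`,
#'   `included_angle_deg`, `flag`.
#' @export
measureHeightMap <- function(hm, expected_area_nm2 = NULL,
                             expected_arm_nm = NULL,
                             height_threshold = 1.0, min_area_nm2 = 300) {
    spec <- hm@meta$spec
    if (is.null(expected_area_nm2))
        expected_area_nm2 <- if (!is.null(spec))
            expectedMonomerArea(spec$arm_nm, spec$rod_width_nm,
                                spec$tip_radius_nm)
        else expectedMonomerArea()
    if (is.null(expected_arm_nm) && !is.null(spec))
        expected_arm_nm <- spec$arm_nm
    parts <- segmentParticles(hm, height_threshold, min_area_nm2)
    if (!length(parts))
        return(data.frame(particle_id = integer(), class = character(),
                          area_nm2 = numeric(),
                          included_angle_deg = numeric(),
                          flag = character()))
    do.call(rbind, lapply(parts, function(p) {
        cls <- classifyParticle(p, expected_area_nm2)
        m <- if (cls == "monomer")
            measureIncludedAngle(p, expected_arm_nm = expected_arm_nm)
        else list(included_angle_deg = NA_real_, flag = cls)
        data.frame(particle_id = p$id, class = cls, area_nm2 = p$area_nm2,
                   included_angle_deg = m$included_angle_deg,
                   flag = m$flag, stringsAsFactors = FALSE)
    }))
}

#' Yield report: histogram, Gaussian fit and structural yield
#'
#' Fits a Gaussian to the monomer angle distribution (robust trimmed MLE:
#' median/MAD start, then mean/sd of the observations within 4 sigma) and
#' counts as well formed the monomers whose angle falls within
#' `target_angle +/- window` (default 3 fitted sigma).
#'
#' @param measurements data.frame from [measureHeightMap()] (rows with
#'   `class == "monomer"` and a finite angle are used for the fit), or a
#'   numeric vector of angles.
#' @param target_angle target included angle in degrees.
#' @param bin_width histogram bin width (degrees).
#' @param window half-width of the well-formed window in degrees (NULL:
#'   3 fitted sigma).
#' @return a [YieldReport-class].
#' @export
yieldAndHistogram <- function(measurements, target_angle, bin_width = 5,
                              window = NULL) {
    if (is.numeric(measurements))
        measurements <- data.frame(particle_id = seq_along(measurements),
                                   class = "monomer", area_nm2 = NA_real_,
                                   included_angle_deg = measurements,
                                   flag = "ok", stringsAsFactors = FALSE)
    if (!nrow(measurements)) stop("no measurements")
    mono <- measurements$class == "monomer"
    ang <- measurements$included_angle_deg[mono]
    ang <- ang[is.finite(ang)]
    if (!length(ang)) stop("no monomer angle measurements")
    med <- stats::median(ang)
    scale <- max(stats::mad(ang), bin_width / 4)
    core <- ang[abs(ang - med) <= 4 * scale]
    fit <- list(mean = mean(core), sd = stats::sd(core))
    if (!is.finite(fit$sd) || fit$sd == 0) fit$sd <- 0
    if (is.null(window)) window <- 3 * max(fit$sd, 1e-6)
    wf <- sum(abs(ang - target_angle) <= window)
    breaks <- seq(floor(min(ang) / bin_width) * bin_width,
                  ceiling(max(ang) / bin_width) * bin_width + bin_width,
                  by = bin_width)
    hh <- hist(ang, breaks = breaks, plot = FALSE)
    new("YieldReport",
        n_total = as.integer(nrow(measurements)),
        n_monomer = as.integer(sum(mono)),
        n_well_formed = as.integer(wf),
        structural_yield = wf / max(sum(mono), 1L),
        fit = fit,
        histogram = data.frame(mid = hh$mids, count = hh$counts),
        measurements = measurements)
}

#' Simulate scenes and measure a cohort of particles
#'
#' Generates as many seeded scenes as needed to reach `n` monomers, runs
#' the measurement pipeline on each and pools the per-particle
#' measurements.
#'
#' @param n number of monomer particles wanted.
#' @param angle_deg target included angle.
#' @param seed integer seed (scene i uses `seed + i`).
#' @param ... passed to [sceneSpec()].
#' @return data.frame of pooled measurements.
#' @export
simulateCohort <- function(n, angle_deg, seed = 1L, ...) {
    spec1 <- sceneSpec(n_particles = 1L, angle_deg = angle_deg, ...)
    cap <- .sceneCapacity(spec1)
    per <- max(cap, 1L)
    n_scene <- ceiling(n / per)
    out <- list()
    placed <- 0L
    for (i in seq_len(n_scene)) {
        ni <- min(per, n - placed)
        spec <- sceneSpec(n_particles = ni, angle_deg = angle_deg, ...)
        hm <- synthesizeScene(spec, seed = seed + i)
        out[[i]] <- measureHeightMap(hm)
        placed <- placed + ni
    }
    res <- do.call(rbind, out)
    res$particle_id <- seq_len(nrow(res))
    res
}
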