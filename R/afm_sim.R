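# Synthetic AFM scene generation: hinge particles rendered as two rod
# segments meeting at the hinge vertex, tip-radius dilation, additive
# Gaussian noise. Stands in for deposited samples; every scene carries its
# ground truth in the metadata.

#' Describe a synthetic AFM scene
#'
#' @param n_particles number of particles to place.
#' @param angle_deg target included angle (degrees).
#' @param angle_sd_deg particle-to-particle spread of the true angle
#'   (degrees; assembly heterogeneity, default 5).
#' @param frac_malformed fraction of monomers rendered with a grossly
#'   off-target angle (25-70 degrees away).
#' @param n_aggregate,n_fragment counts of fused particle pairs and
#'   half-length fragments to add.
#' @param arm_nm arm lengths in nm (default both 95.2, the two halves of
#'   the 560-nt bundle hinged at M2).
#' @param rod_width_nm,rod_height_nm bundle width and height (6 x 2 nm).
#' @param tip_radius_nm AFM tip dilation radius (2 nm).
#' @param noise_sd_nm additive Gaussian height noise (0.15 nm).
#' @param image_px image edge length in pixels (512).
#' @param pixel_nm physical pixel size (2 nm/px).
#' @return spec list for [synthesizeScene()].
#' @export
sceneSpec <- function(n_particles, angle_deg, angle_sd_deg = 5,
                      frac_malformed = 0, n_aggregate = 0L, n_fragment = 0L,
                      arm_nm = c(95.2, 95.2), rod_width_nm = 6,
                      rod_height_nm = 2, tip_radius_nm = 2,
                      noise_sd_nm = 0.15, image_px = 512L, pixel_nm = 2) {
    if (angle_deg < 0 || angle_deg > 180)
        stop("included angle must be in [0, 180] degrees")
    list(n_particles = as.integer(n_particles), angle_deg = angle_deg,
         angle_sd_deg = angle_sd_deg, frac_malformed = frac_malformed,
         n_aggregate = as.integer(n_aggregate),
         n_fragment = as.integer(n_fragment),
         arm_nm = arm_nm, rod_width_nm = rod_width_nm,
         rod_height_nm = rod_height_nm, tip_radius_nm = tip_radius_nm,
         noise_sd_nm = noise_sd_nm, image_px = as.integer(image_px),
         pixel_nm = pixel_nm)
}

# How many particle sites fit into one scene.
.sceneCapacity <- function(spec) {
    extent_nm <- 2 * max(spec$arm_nm) + spec$rod_width_nm +
        2 * spec$tip_radius_nm + 16
    cell_px <- ceiling(extent_nm / spec$pixel_nm)
    max(floor(spec$image_px / cell_px), 0L)^2
}

# Render one rod segment (vertex v, direction angle phi, length L) into the
# height matrix: height h within half-width of the segment.
.renderArm <- function(heights, v, phi, L, halfw, h, pixel_nm) {
    e <- v + L * c(cos(phi), sin(phi))
    xr <- range(v[1], e[1]) + c(-1, 1) * (halfw + pixel_nm)
    yr <- range(v[2], e[2]) + c(-1, 1) * (halfw + pixel_nm)
    ci <- max(1L, floor(xr[1] / pixel_nm)):min(ncol(heights),
                                               ceiling(xr[2] / pixel_nm))
    ri <- max(1L, floor(yr[1] / pixel_nm)):min(nrow(heights),
                                               ceiling(yr[2] / pixel_nm))
    if (!length(ci) || !length(ri)) return(heights)
    px <- (ci - 0.5) * pixel_nm
    py <- (ri - 0.5) * pixel_nm
    d <- e - v
    L2 <- sum(d^2)
    X <- matrix(px, nrow = length(ri), ncol = length(ci), byrow = TRUE)
    Y <- matrix(py, nrow = length(ri), ncol = length(ci))
    t <- if (L2 > 0) pmin(pmax(((X - v[1]) * d[1] + (Y - v[2]) * d[2]) / L2,
                               0), 1) else 0
    dist <- sqrt((X - (v[1] + t * d[1]))^2 + (Y - (v[2] + t * d[2]))^2)
    blk <- heights[ri, ci, drop = FALSE]
    blk[dist <= halfw] <- pmax(blk[dist <= halfw], h)
    heights[ri, ci] <- blk
    heights
}

.renderParticle <- function(heights, v, orient, angle_deg, arms, spec) {
    halfw <- spec$rod_width_nm / 2 + spec$tip_radius_nm
    half <- .deg2rad(angle_deg) / 2
    heights <- .renderArm(heights, v, orient + half, arms[1], halfw,
                          spec$rod_height_nm, spec$pixel_nm)
    .renderArm(heights, v, orient - half, arms[2], halfw,
               spec$rod_height_nm, spec$pixel_nm)
}

#' Render a synthetic AFM height map
#'
#' Particles are placed on a jittered grid (no two particles can touch;
#' aggregates are deliberate fused pairs inside one site) and rendered as
#' two rods of the bundle cross-section meeting at the hinge vertex at the
#' particle's true included angle, followed by tip-radius dilation and
#' Gaussian height noise. The same spec and seed always produce the same
#' grid.
#'
#' @param spec from [sceneSpec()].
#' @param seed integer seed.
#' @return a [HeightMap-class] whose `meta$truth` holds the per-particle
#'   ground truth.
#' @export
synthesizeScene <- function(spec, seed = 1L) {
    n_sites <- spec$n_particles + spec$n_aggregate + spec$n_fragment
    cap <- .sceneCapacity(spec)
    if (n_sites > cap)
        stop("placement error: ", n_sites, " particles do not fit (",
             cap, " sites at this image size)")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    grid_n <- floor(sqrt(cap))
    cell_nm <- spec$image_px * spec$pixel_nm / grid_n
    sites <- expand.grid(ix = seq_len(grid_n), iy = seq_len(grid_n))
    sites <- sites[sample(nrow(sites), n_sites), , drop = FALSE]
    heights <- matrix(0, spec$image_px, spec$image_px)
    jit <- 0.08 * cell_nm
    truth <- list()
    kinds <- c(rep("monomer", spec$n_particles),
               rep("aggregate", spec$n_aggregate),
               rep("fragment", spec$n_fragment))
    n_mal <- round(spec$frac_malformed * spec$n_particles)
    malformed <- rep(FALSE, n_sites)
    if (n_mal > 0)
        malformed[sample(which(kinds == "monomer"), n_mal)] <- TRUE
    for (i in seq_len(n_sites)) {
        v <- c((sites$ix[i] - 0.5) * cell_nm + runif(1, -jit, jit),
               (sites$iy[i] - 0.5) * cell_nm + runif(1, -jit, jit))
        orient <- runif(1, 0, 2 * pi)
        ang <- spec$angle_deg + rnorm(1, 0, spec$angle_sd_deg)
        if (malformed[i])
            ang <- spec$angle_deg +
                sample(c(-1, 1), 1) * runif(1, 25, 70)
        ang <- min(max(ang, 0), 180)
        if (kinds[i] == "monomer") {
            heights <- .renderParticle(heights, v, orient, ang,
                                       spec$arm_nm, spec)
        } else if (kinds[i] == "aggregate") {
            heights <- .renderParticle(heights, v, orient, ang,
                                       spec$arm_nm, spec)
            v2 <- v + 0.35 * spec$arm_nm[1] * c(cos(orient), sin(orient))
            heights <- .renderParticle(heights, v2, orient + pi / 3, ang,
                                       spec$arm_nm, spec)
        } else {
            heights <- .renderArm(heights, v, orient, spec$arm_nm[1] / 2,
                                  spec$rod_width_nm / 2 + spec$tip_radius_nm,
                                  spec$rod_height_nm, spec$pixel_nm)
        }
        truth[[i]] <- data.frame(site = i, kind = kinds[i],
                                 malformed = malformed[i],
                                 angle_deg = ang, x_nm = v[1], y_nm = v[2],
                                 orient_rad = orient)
    }
    if (spec$noise_sd_nm > 0)
        heights <- heights + matrix(rnorm(length(heights), 0,
                                          spec$noise_sd_nm),
                                    nrow(heights))
    heights[heights < 0] <- 0
    new("HeightMap", heights = heights, pixel_size = spec$pixel_nm,
        meta = list(seed = seed, spec = spec,
                    truth = do.call(rbind, truth),
                    instrument = "synthetic-afm"))
}

#' Write a height map to file
#'
#' `format = "tiff"` writes a 32-bit float TIFF normalized to the z range
#' (stored value = height / `z_range_nm`, the usual AFM full-scale
#' convention); `format = "text"` a whitespace-delimited numeric grid in nm.
#'
#' @param hm a [HeightMap-class].
#' @param path output path.
#' @param format `"tiff"` or `"text"` (default from the file extension).
#' @param z_range_nm TIFF full-scale height (default 10 nm).
#' @return `path`, invisibly.
#' @export
writeHeightMap <- function(hm, path, format = c("auto", "tiff", "text"),
                           z_range_nm = 10) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
                  else "text"
    if (format == "tiff") {
        tiff::writeTIFF(pmin(hm@heights / z_range_nm, 1), path,
                        bits.per.sample = 32L, reduce = FALSE)
    } else {
        utils::write.table(hm@heights, path, row.names = FALSE,
                           col.names = FALSE)
    }
    invisible(path)
}

#' Read a height map from file
#'
#' @param path TIFF (32-bit float, full scale = `z_range_nm`) or
#'   whitespace-delimited numeric grid in nm.
#' @param pixel_nm physical pixel size in nm/px.
#' @param z_range_nm TIFF full-scale height (default 10 nm).
#' @return a [HeightMap-class].
#' @export
readHeightMap <- function(path, pixel_nm = 2, z_range_nm = 10) {
    h <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        m <- tiff::readTIFF(path)
        if (length(dim(m)) == 3L) m <- m[, , 1]
        m * z_range_nm
    } else {
        as.matrix(utils::read.table(path))
    }
    dimnames(h) <- NULL
    new("HeightMap", heights = h, pixel_size = pixel_nm,
        meta = list(source = path))
}
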