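#' @import methods
#' @importFrom stats optimize prcomp rnorm runif sd var setNames dnorm
#'   median mad cov
#' @importFrom graphics hist
#' @importFrom utils head tail read.csv write.csv
NULL

#' OrigamiDesign: a seam-partitioned honeycomb-lattice origami bundle
#'
#' Central container of the design engine. Holds the helix layout on the
#' honeycomb lattice, the scaffold routing, the seam-bounded module
#' partition, the staple set and the adjuster-strand state. Created by
#' [buildReference()] and modified only through the edit operations
#' ([applyHinge()], [setAdjuster()], ...), which guarantees that every
#' design stays a valid derivative of the reference.
#'
#' @slot layout data.frame with one row per helix: \code{helix_id} (0-based;
#'   the adjuster strand is carried as pseudo-helix 12), honeycomb
#'   \code{row}/\code{col}, \code{length_nt}, logical \code{is_adjuster}.
#' @slot partition data.frame of the nine named modules (\code{name},
#'   \code{start}, \code{end} half-open 0-based, \code{role}).
#' @slot seams data.frame of seam intervals (\code{start}, \code{end}).
#' @slot staples data.frame with \code{staple_id}, \code{class} (body, seam,
#'   strut, hinge), \code{sequence} (empty until [assignSequences()]) and a
#'   list-column \code{footprint} of per-segment data.frames
#'   (\code{helix}, \code{start}, \code{end}).
#' @slot adjuster list: \code{length_nt}, \code{duplex_fraction},
#'   \code{reservoir_nt}, \code{full_length_nt}, and optional second-adjuster
#'   bookkeeping.
#' @slot scaffold_length integer, length of the scaffold the design budgets
#'   against (default 7249, M13mp18).
#' @slot meta list of free-form metadata (variant label, applied edits).
#' @export
setClass("OrigamiDesign", representation(
    layout = "data.frame",
    partition = "data.frame",
    seams = "data.frame",
    staples = "data.frame",
    adjuster = "list",
    scaffold_length = "integer",
    meta = "list"
))

#' StapleDiff: replaced/removed/shared staple accounting
#'
#' Result of [diffStaples()]. Sequences are compared against the reference
#' staple pool: a variant staple is "replaced" when its sequence does not
#' occur in the reference pool; a reference staple is "removed" when its
#' sequence is absent from the variant.
#'
#' @slot n_reference,n_variant,n_replaced,n_removed,n_shared integers.
#' @slot replaced_fraction numeric, \code{n_replaced / n_reference}.
#' @export
setClass("StapleDiff", representation(
    n_reference = "integer", n_variant = "integer",
    n_replaced = "integer", n_removed = "integer", n_shared = "integer",
    replaced_fraction = "numeric"
))

#' EnergyLandscape: strain energy versus included angle
#'
#' @slot theta_deg numeric grid of included angles (degrees).
#' @slot E_hinge,E_adjuster,E_total numeric energies (pN nm), with
#'   \code{E_total = E_hinge + E_adjuster} pointwise.
#' @slot feasible logical; FALSE where the adjuster extension would reach or
#'   exceed its contour length.
#' @slot params list of the hinge/geometry/WLC parameters used.
#' @export
setClass("EnergyLandscape", representation(
    theta_deg = "numeric", E_hinge = "numeric", E_adjuster = "numeric",
    E_total = "numeric", feasible = "logical", params = "list"
))

#' StiffnessEstimate: per-observation and aggregated torsional stiffness
#'
#' @slot k_per_obs numeric vector of per-observation stiffness values
#'   (pN nm / rad), NA where an observation was skipped.
#' @slot mean,min,max numeric aggregates over the usable observations.
#' @slot observations data.frame echo of the input observations with a
#'   \code{k} column and a \code{status} flag.
#' @export
setClass("StiffnessEstimate", representation(
    k_per_obs = "numeric", mean = "numeric", min = "numeric", max = "numeric",
    observations = "data.frame"
))

#' HeightMap: an AFM-like topography image
#'
#' @slot heights numeric matrix of heights in nm (row = y, col = x).
#' @slot pixel_size numeric, nm per pixel.
#' @slot meta list (seed, generator parameters, ground truth when synthetic).
#' @export
setClass("HeightMap", representation(
    heights = "matrix", pixel_size = "numeric", meta = "list"
))

#' YieldReport: angle histogram, Gaussian fit and structural yield
#'
#' @slot n_total,n_monomer,n_well_formed integers.
#' @slot structural_yield numeric in [0, 1].
#' @slot fit list with Gaussian \code{mean} and \code{sd} (degrees).
#' @slot histogram data.frame of bin \code{mid} and \code{count}.
#' @slot measurements data.frame of per-particle angle measurements.
#' @export
setClass("YieldReport", representation(
    n_total = "integer", n_monomer = "integer", n_well_formed = "integer",
    structural_yield = "numeric", fit = "list", histogram = "data.frame",
    measurements = "data.frame"
))

setValidity("OrigamiDesign", function(object) {
    msg <- character()
    lay <- object@layout
    bundle <- lay[!lay$is_adjuster, , drop = FALSE]
    if (nrow(bundle) != 12L)
        msg <- c(msg, "layout must contain exactly 12 bundle helices")
    if (length(unique(bundle$length_nt)) > 1L)
        msg <- c(msg, "all bundle helices must span the same base range")
    nb <- honeycombNeighborCount(lay$row, lay$col)
    if (any(nb[!lay$is_adjuster] > 3L))
        msg <- c(msg, "honeycomb adjacency violated: helix with >3 neighbors")
    if (nrow(object@partition) != 9L)
        msg <- c(msg, "partition must contain exactly 9 modules")
    tile <- rbind(object@partition[, c("start", "end")],
                  object@seams[, c("start", "end")])
    tile <- tile[order(tile$start), ]
    if (any(tile$end[-nrow(tile)] != tile$start[-1]) ||
        tile$start[1] != 0L || tile$end[nrow(tile)] != bundle$length_nt[1])
        msg <- c(msg, "modules and seams must tile the bundle span without gaps or overlap")
    occ <- stapleOccupancy(object)
    if (any(occ > 1L))
        msg <- c(msg, "double occupancy: a (helix, base) is bound by more than one staple")
    bad <- stapleCrossoverViolations(object)
    if (length(bad))
        msg <- c(msg, paste0("staple crossover between non-neighbor helices: ",
                             paste(bad, collapse = ", ")))
    if (scaffoldUsage(object) > object@scaffold_length)
        msg <- c(msg, "scaffold budget exceeded")
    adj <- object@adjuster
    if (adj$length_nt + adj$reservoir_nt != adj$full_length_nt)
        msg <- c(msg, "adjuster length + reservoir must equal the full adjuster length")
    if (length(msg)) msg else TRUE
})

setMethod("show", "OrigamiDesign", function(object) {
    cls <- table(factor(object@staples$class,
                        levels = c("body", "seam", "strut", "hinge")))
    cat("OrigamiDesign:", if (!is.null(object@meta$label)) object@meta$label
        else "unnamed", "\n")
    cat("  12-helix honeycomb bundle,", object@layout$length_nt[1], "nt span,",
        nrow(object@partition), "modules /", nrow(object@seams), "seams\n")
    cat("  staples:", nrow(object@staples),
        sprintf("(%d body, %d seam, %d strut, %d hinge)",
                cls["body"], cls["seam"], cls["strut"], cls["hinge"]), "\n")
    cat("  adjuster:", object@adjuster$length_nt, "nt (duplex fraction",
        object@adjuster$duplex_fraction, "), reservoir",
        object@adjuster$reservoir_nt, "nt\n")
    cat("  scaffold usage:", scaffoldUsage(object), "/",
        object@scaffold_length, "nt;",
        if (nchar(object@staples$sequence[1])) "sequences assigned"
        else "sequences not assigned", "\n")
})

setMethod("show", "StapleDiff", function(object) {
    cat("StapleDiff: ", object@n_replaced, " replaced (",
        sprintf("%.1f%%", 100 * object@replaced_fraction), " of ",
        object@n_reference, " reference staples), ",
        object@n_removed, " removed, ", object@n_shared, " shared\n", sep = "")
})

setMethod("show", "EnergyLandscape", function(object) {
    ok <- object@feasible
    cat("EnergyLandscape:", length(object@theta_deg), "grid points,",
        sum(ok), "feasible\n")
    if (any(ok)) {
        i <- which(ok)[which.min(object@E_total[ok])]
        cat("  minimum E_total =", signif(object@E_total[i], 4),
            "pN nm at", round(object@theta_deg[i], 1), "deg\n")
    }
})

setMethod("show", "StiffnessEstimate", function(object) {
    cat("StiffnessEstimate:", sum(!is.na(object@k_per_obs)), "observations\n")
    cat(sprintf("  k = %.1f pN nm/rad (min %.1f, max %.1f)\n",
                object@mean, object@min, object@max))
})

setMethod("show", "HeightMap", function(object) {
    cat("HeightMap:", nrow(object@heights), "x", ncol(object@heights),
        "px at", object@pixel_size, "nm/px; height range",
        sprintf("[%.2f, %.2f] nm\n", min(object@heights), max(object@heights)))
})

setMethod("show", "YieldReport", function(object) {
    cat("YieldReport:", object@n_total, "particles,", object@n_monomer,
        "monomers,", object@n_well_formed, "well formed\n")
    cat(sprintf("  structural yield %.3f; Gaussian fit mean %.1f deg, sd %.1f deg\n",
                object@structural_yield, object@fit$mean, object@fit$sd))
})
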