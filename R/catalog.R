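# The 24-variant demonstration catalog and the 11-design included-angle
# series, built exclusively through the edit operations.

.CATALOG_CASES <- list(
    # single-hinged structures, various hinge locations and included angles
    list(hinges = list(L2 = "ds0hb"), k = 3),
    list(hinges = list(L3 = "ds0hb"), k = 5),
    list(hinges = list(M1 = "ds0hb"), k = 7),
    list(hinges = list(M2 = "ds0hb"), k = 9),
    list(hinges = list(M3 = "ds0hb"), k = 7),
    list(hinges = list(R1 = "ds0hb"), k = 5),
    list(hinges = list(R2 = "ds0hb"), k = 3),
    list(hinges = list(M2 = "ds0hb"), k = 11),
    # double/triple-hinged structures with a single adjuster
    list(hinges = list(L3 = "ds0hb", M3 = "ds0hb"), k = 7),
    list(hinges = list(L3 = "ds0hb", M3 = "ds0hb"), k = 9),
    list(hinges = list(L2 = "ds0hb", M2 = "ds0hb", R2 = "ds0hb"), k = 7),
    list(hinges = list(L3 = "ds0hb", M2 = "ds0hb", M3 = "ds0hb"), k = 5),
    list(hinges = list(L3 = "ds2hb", M3 = "ds2hb"), k = 7),
    list(hinges = list(L3 = "ds0hb", M3 = "ds2hb"), k = 7),
    list(hinges = list(L2 = "ds2hb", M2 = "ds0hb", R2 = "ds2hb"), k = 7),
    list(hinges = list(M1 = "ds3hb", M3 = "ds0hb"), k = 7),
    # closed-form and double/asymmetric-adjuster structures
    list(hinges = list(M2 = "ds0hb"), k = 4, closed = TRUE),
    list(hinges = list(L3 = "ds0hb", M3 = "ds0hb"), k = 7, closed = TRUE),
    list(hinges = list(L3 = "ds2hb", M3 = "ds2hb"), k = 7, closed = TRUE),
    list(hinges = list(M1 = "ds0hb"), k = 7, second = 210),
    list(hinges = list(L2 = "ds2hb", R2 = "ds2hb"), k = 9, second = 189),
    list(hinges = list(L3 = "ds2hb", M3 = "ds2hb"), k = 7, second = 210),
    list(hinges = list(L3 = "ds2hb", M3 = "ds2hb"), k = 7, second = 210,
         closed = TRUE),
    list(hinges = list(L2 = "ds2hb", R1 = "ds2hb"), k = 7, second = 168,
         closed = TRUE)
)

.buildCase <- function(reference, case, label) {
    d <- reference
    for (m in names(case$hinges)) d <- applyHinge(d, m, case$hinges[[m]])
    full <- reference@adjuster$full_length_nt
    d <- setAdjuster(d, full - 21L * case$k, 1.0)
    if (!is.null(case$second)) d <- addSecondAdjuster(d, case$second)
    if (isTRUE(case$closed)) d <- makeClosed(d)
    d@meta$label <- label
    d
}

#' Build the 24-variant polymorphic catalog
#'
#' Cases 1-8 are single-hinged structures with various hinge locations and
#' included angles, 9-16 double/triple-hinged structures sharing a single
#' adjuster, and 17-24 closed-form and double/asymmetric-adjuster
#' structures. All are derived from the reference by hinge and adjuster
#' edits only.
#'
#' @param reference the reference design from [buildReference()].
#' @return a named list of 24 [OrigamiDesign-class] objects.
#' @export
buildVariantCatalog <- function(reference) {
    stats::setNames(
        lapply(seq_along(.CATALOG_CASES), function(i)
            .buildCase(reference, .CATALOG_CASES[[i]],
                       sprintf("case%02d", i))),
        sprintf("case%02d", seq_along(.CATALOG_CASES)))
}

#' Build the 11-design included-angle series
#'
#' A ds2hb hinge at the central M2 module, with the dsDNA adjuster
#' shortened on a 21-nt basis (483, 462, ..., 273 nt), targeting nominal
#' included angles from 150 to 0 degrees in 15-degree steps.
#'
#' @param reference the reference design.
#' @param hinge hinge class for the series (default `"ds2hb"`).
#' @return a named list of 11 designs; names give the nominal target angle.
#' @export
angleSeries <- function(reference, hinge = "ds2hb") {
    full <- reference@adjuster$full_length_nt
    ks <- 1:11
    targets <- seq(150, 0, by = -15)
    stats::setNames(
        lapply(seq_along(ks), function(i) {
            d <- applyHinge(reference, "M2", hinge)
            d <- setAdjuster(d, full - 21L * ks[i], 1.0)
            d@meta$label <- sprintf("series_%03ddeg", targets[i])
            d@meta$target_angle_deg <- targets[i]
            d
        }),
        sprintf("deg%03d", targets))
}
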