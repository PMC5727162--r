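# Variant edits. Every polymorphic variant is derived from the reference by
# these operations only, which is what keeps the replaced-staple count small:
# seam staples are never touched, and a hinge is pure staple removal (plus
# 2-6 hinge staples for the stiffer classes).

#' Hinge classes
#'
#' `ds0hb` removes all structural staples of the module and leaves only the
#' unbound scaffold single strands; `dsNhb` (N = 2, 3, 4, 6) additionally
#' adds N hinge staples that keep N helices duplexed at the hinge
#' cross-section. The retained helices are placed symmetrically around the
#' cross-section ring.
#'
#' @param name hinge class name.
#' @return list with `name`, `n_duplex_helices`, `n_hinge_staples` and the
#'   retained `helices`.
#' @export
hingeClass <- function(name = c("ds0hb", "ds2hb", "ds3hb", "ds4hb", "ds6hb")) {
    name <- match.arg(name)
    helices <- switch(name,
        ds0hb = integer(0),
        ds2hb = c(0L, 6L),
        ds3hb = c(0L, 4L, 8L),
        ds4hb = c(0L, 3L, 6L, 9L),
        ds6hb = c(0L, 2L, 4L, 6L, 8L, 10L))
    list(name = name, n_duplex_helices = length(helices),
         n_hinge_staples = length(helices), helices = helices)
}

.dropStaples <- function(design, ids) {
    design@staples <- design@staples[!design@staples$staple_id %in% ids, ,
                                     drop = FALSE]
    design
}

.addStaples <- function(design, st) {
    design@staples <- rbind(design@staples, st)
    design@staples <-
        design@staples[order(design@staples$staple_id), , drop = FALSE]
    rownames(design@staples) <- NULL
    design
}

.logEdit <- function(design, what) {
    design@meta$edits <- c(design@meta$edits, what)
    design@meta$label <- paste0(design@meta$label, " + ", what)
    design
}

#' Turn a structure module into a hinge
#'
#' Removes every structural (body/hinge) staple whose footprint lies inside
#' the module and, for `dsNhb` with N > 0, adds N full-width hinge staples
#' keeping N helices duplexed. Seam staples and the scaffold path are
#' untouched.
#'
#' @param design an [OrigamiDesign-class].
#' @param module_name one of L2, L3, M1, M2, M3, R1, R2.
#' @param hinge a class name or the result of [hingeClass()].
#' @return the edited design.
#' @export
applyHinge <- function(design, module_name, hinge = "ds0hb") {
    if (is.character(hinge)) hinge <- hingeClass(hinge)
    p <- design@partition
    m <- p[p$name == module_name, ]
    if (!nrow(m)) stop("unknown module: ", module_name)
    if (m$role != "structure" || module_name %in% c("L1", "R3"))
        stop("invalid-target error: hinges can only replace the interior ",
             "structure modules L2..R2, not ", module_name)
    old <- staplesInModule(design, module_name)
    design <- .dropStaples(design, old$staple_id)
    if (hinge$n_hinge_staples > 0L) {
        st <- do.call(rbind, lapply(hinge$helices, function(h)
            .newStaple(sprintf("hinge_%s_%s_h%02d", module_name, hinge$name, h),
                       "hinge", list(.seg(h, m$start, m$end)))))
        design <- .addStaples(design, st)
    }
    design@staples$sequence <- rep("", nrow(design@staples))
    design <- .logEdit(design, paste0(module_name, ":", hinge$name))
    validObject(design)
    design
}

#' Refill a hinge module with its reference structure staples
#'
#' Inverse of [applyHinge()]: removes any hinge staples in the module and
#' restores the reference brick staples, so
#' `fillModule(applyHinge(ref, m, "ds0hb"), m)` has the reference staple
#' set again.
#'
#' @param design an [OrigamiDesign-class].
#' @param module_name interior module name.
#' @return the edited design.
#' @export
fillModule <- function(design, module_name) {
    p <- design@partition
    m <- p[p$name == module_name, ]
    if (!nrow(m) || module_name %in% c("L1", "R3"))
        stop("invalid-target error: ", module_name)
    old <- staplesInModule(design, module_name)
    design <- .dropStaples(design, old$staple_id)
    design <- .addStaples(design,
                          .brickStaples(module_name, m$start, m$end - m$start))
    design@staples$sequence <- rep("", nrow(design@staples))
    design <- .logEdit(design, paste0(module_name, ":fill"))
    validObject(design)
    design
}

#' Set the adjuster length and duplex fraction
#'
#' Shortens (or restores) the adjuster strand on a 21-nt basis. The removed
#' scaffold bases are stored in the reservoir at the structure end
#' (`length_nt + reservoir_nt` is conserved). Strut staples beyond the new
#' duplex extent are eliminated, a >= 21-nt remainder becomes one shortened
#' strut, and the six reservoir-junction staples in R3 are re-broken (their
#' footprints shift with the reservoir anchor), which is what an adjuster
#' edit costs in new staples.
#'
#' @param design an [OrigamiDesign-class].
#' @param length_nt new adjuster length, 0 < length_nt <= full length.
#' @param duplex_fraction fraction of the adjuster kept duplexed by struts
#'   (1 = fully duplexed dsDNA adjuster, 0 = bare ssDNA adjuster).
#' @return the edited design.
#' @export
setAdjuster <- function(design, length_nt, duplex_fraction = 1.0) {
    full <- design@adjuster$full_length_nt
    if (length_nt <= 0L || length_nt > full)
        stop("range error: adjuster length must be in (0, ", full, "]")
    if (duplex_fraction < 0 || duplex_fraction > 1)
        stop("range error: duplex_fraction must be in [0, 1]")
    length_nt <- as.integer(length_nt)
    shift <- as.integer(ceiling((full - length_nt) / 21))
    st <- design@staples
    drop <- st$staple_id[st$class == "strut" & grepl("^strut_", st$staple_id) |
                         grepl("^R3_j", st$staple_id)]
    design <- .dropStaples(design, drop)
    duplex_nt <- as.integer(round(duplex_fraction * length_nt))
    add <- .junctionStaples(design@partition$start[design@partition$name == "R3"],
                            shift)
    if (duplex_nt >= 21L) add <- rbind(add, .strutStaples(duplex_nt))
    design <- .addStaples(design, add)
    design@adjuster$length_nt <- length_nt
    design@adjuster$duplex_fraction <- duplex_fraction
    design@adjuster$reservoir_nt <- full - length_nt
    design@adjuster$shift <- shift
    design@staples$sequence <- rep("", nrow(design@staples))
    design <- .logEdit(design, sprintf("adjuster:%d@%.2f", length_nt,
                                       duplex_fraction))
    validObject(design)
    design
}

#' Add a second, independent adjuster
#'
#' Converts the L1 end into an anchor for a second adjuster strand so two
#' hinges can be modulated independently (the double/asymmetric-adjuster
#' variants). The five L1 pair staples are replaced by six anchor staples,
#' and two mid-anchor staples split the adjuster scaffold at the primary
#' adjuster's end. Requires a reservoir of at least 42 nt (shorten the
#' primary adjuster first).
#'
#' @param design an [OrigamiDesign-class].
#' @param length_nt length of the second adjuster segment (metadata for the
#'   mechanics stage; the staple cost does not depend on it).
#' @return the edited design.
#' @export
addSecondAdjuster <- function(design, length_nt) {
    adj <- design@adjuster
    if (adj$reservoir_nt < 42L)
        stop("second adjuster needs >= 42 nt of reservoir; shorten the ",
             "primary adjuster first")
    l1 <- design@partition[design@partition$name == "L1", ]
    design <- .dropStaples(design, sprintf("L1_p%02d", 0:4))
    # re-broken anchor lane: pairing phase shifted by one helix relative to
    # the reference L1 pair staples, so all six anchors are new sequences
    pairs5 <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10))
    anchors <- rbind(
        .pairStaples("adjB", pairs5, l1$start + 14L, l1$start + 35L,
                     class = "strut"),
        .newStaple("adjB_s00", "strut",
                   list(.seg(0L, l1$start + 14L, l1$start + 35L))))
    la <- adj$length_nt
    mids <- rbind(
        .newStaple("adjB_mid0", "strut", list(.seg(12L, la, la + 21L))),
        .newStaple("adjB_mid1", "strut", list(.seg(12L, la + 21L, la + 42L))))
    design <- .addStaples(design, rbind(anchors, mids))
    design@adjuster$second <- list(length_nt = as.integer(length_nt))
    design@staples$sequence <- rep("", nrow(design@staples))
    design <- .logEdit(design, sprintf("adjusterB:%d", length_nt))
    validObject(design)
    design
}

#' Close the structure into a loop
#'
#' Adds four 21-nt closure staples on the stored reservoir scaffold, joining
#' the two ends of the bundle into a closed form. Requires a reservoir of at
#' least 84 nt and must be applied after any adjuster edit.
#'
#' @param design an [OrigamiDesign-class].
#' @return the edited design.
#' @export
makeClosed <- function(design) {
    adj <- design@adjuster
    full <- adj$full_length_nt
    if (adj$reservoir_nt < 84L)
        stop("closed form needs >= 84 nt of reservoir")
    st <- do.call(rbind, lapply(0:3, function(i)
        .newStaple(sprintf("close_%d", i), "strut",
                   list(.seg(12L, full - 84L + 21L * i,
                             full - 84L + 21L * (i + 1L))))))
    design <- .addStaples(design, st)
    design@staples$sequence <- rep("", nrow(design@staples))
    design <- .logEdit(design, "closed")
    validObject(design)
    design
}

#' Compare two designs for structural identity
#'
#' TRUE when layout, partition, seams, adjuster state and the staple set
#' (ids, classes, footprints, sequences) agree; staple order is ignored.
#'
#' @param a,b two [OrigamiDesign-class] objects.
#' @return logical.
#' @export
designIdentical <- function(a, b) {
    norm <- function(d) {
        st <- d@staples[order(d@staples$staple_id), ]
        rownames(st) <- NULL
        st$footprint <- lapply(st$footprint, function(fp) {
            rownames(fp) <- NULL
            fp
        })
        list(layout = d@layout, partition = d@partition, seams = d@seams,
             staples = st[, c("staple_id", "class", "sequence")],
             footprints = st$footprint,
             adjuster = d@adjuster[c("length_nt", "duplex_fraction",
                                     "reservoir_nt", "full_length_nt")])
    }
    isTRUE(all.equal(norm(a), norm(b), check.attributes = FALSE))
}
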