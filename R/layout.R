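# Honeycomb lattice geometry, default layout configuration and the
# geometric validators used by the OrigamiDesign validity method.

# Duplex rise per base pair (nm) and single-strand rise per nucleotide (nm).
.RISE_DS <- 0.34
.RISE_SS <- 0.63

#' Default layout configuration of the 12-helix reference bundle
#'
#' Nine seam-bounded modules (L1, L2, L3, M1, M2, M3, R1, R2, R3) separated
#' by eight 28-nt seams. L1 and R3 are 63 nt, the central hinge module M2 is
#' 42 nt, the remaining interior modules 28 nt, giving a 560-nt bundle span.
#' With twelve full-length helices plus the 504-nt adjuster strand the
#' design occupies 7,224 of the 7,249 scaffold bases.
#'
#' @param seam_nt seam length in nt (default 28).
#' @param end_module_nt length of L1 and R3 (default 63).
#' @param mid_module_nt length of the interior modules other than M2
#'   (default 28).
#' @param hinge_module_nt length of M2 (default 42).
#' @param adjuster_nt full adjuster length (default 504).
#' @param scaffold_length scaffold budget in nt (default 7249, M13mp18).
#' @return a list understood by [buildReference()].
#' @export
defaultLayoutConfig <- function(seam_nt = 28L, end_module_nt = 63L,
                                mid_module_nt = 28L, hinge_module_nt = 42L,
                                adjuster_nt = 504L,
                                scaffold_length = 7249L) {
    list(seam_nt = as.integer(seam_nt),
         end_module_nt = as.integer(end_module_nt),
         mid_module_nt = as.integer(mid_module_nt),
         hinge_module_nt = as.integer(hinge_module_nt),
         adjuster_nt = as.integer(adjuster_nt),
         scaffold_length = as.integer(scaffold_length))
}

# Honeycomb adjacency, caDNAno-like: same row, adjacent column always;
# same column, adjacent row only when (row + col) is odd. Gives <= 3
# neighbors for every lattice position.
.honeycombAdjacent <- function(r1, c1, r2, c2) {
    (r1 == r2 & abs(c1 - c2) == 1L) |
        (c1 == c2 & abs(r1 - r2) == 1L & (pmin(r1, r2) + c1) %% 2L == 1L)
}

honeycombNeighborCount <- function(row, col) {
    n <- length(row)
    cnt <- integer(n)
    for (i in seq_len(n)) {
        cnt[i] <- sum(.honeycombAdjacent(row[i], col[i], row[-i], col[-i]))
    }
    cnt
}

#' Are two lattice positions honeycomb neighbors?
#'
#' @param design an [OrigamiDesign-class].
#' @param h1,h2 helix ids.
#' @return logical.
#' @export
isLatticeNeighbor <- function(design, h1, h2) {
    lay <- design@layout
    p1 <- lay[match(h1, lay$helix_id), ]
    p2 <- lay[match(h2, lay$helix_id), ]
    .honeycombAdjacent(p1$row, p1$col, p2$row, p2$col)
}

# Flat (helix, base) occupancy counts over all staples.
stapleOccupancy <- function(design) {
    fp <- do.call(rbind, design@staples$footprint)
    if (is.null(fp) || !nrow(fp)) return(integer())
    keys <- unlist(mapply(function(h, s, e) {
        if (e > s) paste0(h, ":", s:(e - 1L)) else character()
    }, fp$helix, fp$start, fp$end, SIMPLIFY = FALSE))
    table(keys)
}

# staple ids whose consecutive footprint segments cross between
# non-neighboring helices.
stapleCrossoverViolations <- function(design) {
    bad <- character()
    for (i in seq_len(nrow(design@staples))) {
        fp <- design@staples$footprint[[i]]
        if (nrow(fp) < 2L) next
        for (j in seq_len(nrow(fp) - 1L)) {
            h1 <- fp$helix[j]; h2 <- fp$helix[j + 1L]
            if (h1 != h2 && !isLatticeNeighbor(design, h1, h2))
                bad <- c(bad, design@staples$staple_id[i])
        }
    }
    unique(bad)
}

#' Convert a number of bases to a contour length in nm
#'
#' Duplex DNA rises 0.34 nm per base pair; single-stranded DNA is taken at
#' 0.63 nm per nucleotide.
#'
#' @param n_bases number of bases (>= 0).
#' @param form `"duplex"` or `"single"`.
#' @return contour length in nm.
#' @examples
#' contourNm(63, "duplex")   # 21.42 nm, the L1/R3 module length
#' contourNm(28, "duplex")   # ~9.5 nm, one seam
#' @export
contourNm <- function(n_bases, form = c("duplex", "single")) {
    form <- match.arg(form)
    if (any(n_bases < 0)) stop("n_bases must be non-negative")
    n_bases * if (form == "duplex") .RISE_DS else .RISE_SS
}

# internal: block table of the bundle (modules and seams in order).
.layoutBlocks <- function(config) {
    widths <- c(L1 = config$end_module_nt,
                S1 = config$seam_nt, L2 = config$mid_module_nt,
                S2 = config$seam_nt, L3 = config$mid_module_nt,
                S3 = config$seam_nt, M1 = config$mid_module_nt,
                S4 = config$seam_nt, M2 = config$hinge_module_nt,
                S5 = config$seam_nt, M3 = config$mid_module_nt,
                S6 = config$seam_nt, R1 = config$mid_module_nt,
                S7 = config$seam_nt, R2 = config$mid_module_nt,
                S8 = config$seam_nt, R3 = config$end_module_nt)
    end <- cumsum(widths)
    data.frame(name = names(widths),
               start = as.integer(end - widths), end = as.integer(end),
               is_seam = grepl("^S", names(widths)),
               stringsAsFactors = FALSE)
}

#' Query the seam-bounded module partition of a design
#'
#' Returns the nine named modules with their half-open spans and roles,
#' after checking the tiling property (modules plus seams cover the bundle
#' span exactly once).
#'
#' @param design an [OrigamiDesign-class].
#' @return data.frame with columns `name`, `start`, `end`, `role`,
#'   `width_nt`.
#' @export
partitionModules <- function(design) {
    p <- design@partition
    tile <- rbind(p[, c("start", "end")], design@seams[, c("start", "end")])
    tile <- tile[order(tile$start), ]
    if (any(tile$end[-nrow(tile)] != tile$start[-1]))
        stop("partition error: module/seam spans overlap or leave gaps")
    p$width_nt <- p$end - p$start
    p
}
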