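# Construction of the 12-helix honeycomb reference design.
#
# The printed staple accounting of the reference structure (180 staples =
# 108 body + 60 seam + 12 strut; 11 structural staples per interior module;
# 12 x 42-nt struts = 504-nt adjuster) is treated as a layout constraint;
# the exact break positions within those constraints are free design
# variables and are laid out here as a regular brick pattern.

.seg <- function(helix, start, end)
    data.frame(helix = as.integer(helix), start = as.integer(start),
               end = as.integer(end))

.newStaple <- function(id, class, segs) {
    fp <- do.call(rbind, segs)
    data.frame(staple_id = id, class = class, sequence = "",
               footprint = I(list(fp)), stringsAsFactors = FALSE)
}

.stapleLength <- function(fp) sum(fp$end - fp$start)

# Brick pattern filling a module [a, a+w) on 12 helices with 11 staples:
# staple i binds helix i on the distal half and helix i+1 on the proximal
# half. Leaves one half-lane free at helix 0 and helix 11.
.brickStaples <- function(prefix, a, w) {
    h <- w %/% 2L
    do.call(rbind, lapply(0:10, function(i) {
        .newStaple(sprintf("%s_b%02d", prefix, i), "body",
                   list(.seg(i, a + h, a + w), .seg(i + 1L, a, a + h)))
    }))
}

# Pair staples: one staple per helix pair (2j, 2j+1) over [a, b).
.pairStaples <- function(prefix, pairs, a, b, class = "body") {
    do.call(rbind, lapply(seq_along(pairs), function(j) {
        p <- pairs[[j]]
        .newStaple(sprintf("%s_p%02d", prefix, j - 1L), class,
                   list(.seg(p[1], a, b), .seg(p[2], a, b)))
    }))
}

# R3 junction staples: six single-helix 21-nt staples on helices 0..5 whose
# footprint shifts with the adjuster-reservoir anchor (shift = number of
# 21-nt units removed from the adjuster). Shifting re-breaks them, which is
# what makes an adjuster edit cost new staple sequences.
.junctionStaples <- function(r3_start, shift) {
    do.call(rbind, lapply(0:5, function(h) {
        .newStaple(sprintf("R3_j%02d", h), "body",
                   list(.seg(h, r3_start + shift, r3_start + 21L + shift)))
    }))
}

# Strut staples hybridizing the adjuster strand (pseudo-helix 12) into
# duplex form: full struts are 42 nt; a trailing >= 21-nt remainder becomes
# one shortened strut.
.strutStaples <- function(duplex_nt) {
    n_full <- duplex_nt %/% 42L
    rem <- duplex_nt - 42L * n_full
    st <- lapply(seq_len(n_full), function(i) {
        .newStaple(sprintf("strut_%02d", i - 1L), "strut",
                   list(.seg(12L, 42L * (i - 1L), 42L * i)))
    })
    if (rem >= 21L)
        st <- c(st, list(.newStaple(sprintf("strut_%02d_part", n_full),
                                    "strut",
                                    list(.seg(12L, 42L * n_full,
                                              42L * n_full + rem)))))
    do.call(rbind, st)
}

.referenceBodyStaples <- function(blocks) {
    pairs5 <- list(c(0, 1), c(2, 3), c(4, 5), c(6, 7), c(8, 9))
    out <- list()
    for (i in seq_len(nrow(blocks))) {
        b <- blocks[i, ]
        if (b$is_seam) next
        if (b$name == "L1") {
            # 16 staples: 5 pair staples + 11 brick staples
            out[[length(out) + 1L]] <-
                .pairStaples("L1", pairs5, b$start + 14L, b$start + 35L)
            out[[length(out) + 1L]] <-
                .brickStaples("L1", b$start + 35L, b$end - (b$start + 35L))
        } else if (b$name == "R3") {
            # 15 staples: 6 singles + 3 pairs + 6 junction staples
            out[[length(out) + 1L]] <- do.call(rbind, lapply(6:11, function(h)
                .newStaple(sprintf("R3_s%02d", h), "body",
                           list(.seg(h, b$start, b$start + 28L)))))
            out[[length(out) + 1L]] <-
                .pairStaples("R3", list(c(6, 7), c(8, 9), c(10, 11)),
                             b$start + 28L, b$start + 49L)
            out[[length(out) + 1L]] <- .junctionStaples(b$start, 0L)
        } else {
            out[[length(out) + 1L]] <-
                .brickStaples(b$name, b$start, b$end - b$start)
        }
    }
    do.call(rbind, out)
}

.referenceSeamStaples <- function(blocks, span) {
    pairs6 <- list(c(0, 1), c(2, 3), c(4, 5), c(6, 7), c(8, 9), c(10, 11))
    out <- list(
        # terminal cap staples, seam class: they pin the scaffold turns at
        # the bundle ends and are never touched by any edit
        .pairStaples("capL", pairs6, 0L, 14L, class = "seam"),
        .pairStaples("capR", pairs6, span - 14L, span, class = "seam")
    )
    for (i in which(blocks$is_seam)) {
        b <- blocks[i, ]
        out[[length(out) + 1L]] <-
            .pairStaples(b$name, pairs6, b$start + 3L, b$start + 24L,
                         class = "seam")
    }
    do.call(rbind, out)
}

#' Build the straight 12-helix reference design
#'
#' Constructs the reference bundle: 12 honeycomb-packed helices spanning
#' nine seam-bounded modules, 180 staples (108 body, 60 seam, 12 strut) and
#' a fully duplexed 504-nt adjuster strand with an empty reservoir.
#'
#' @param config layout configuration from [defaultLayoutConfig()].
#' @return an [OrigamiDesign-class] (sequences unassigned).
#' @examples
#' ref <- buildReference()
#' table(stapleSet(ref)$class)
#' @export
buildReference <- function(config = defaultLayoutConfig()) {
    blocks <- .layoutBlocks(config)
    span <- blocks$end[nrow(blocks)]
    usage <- 12L * span + config$adjuster_nt
    if (usage > config$scaffold_length)
        stop("scaffold budget error: design needs ", usage,
             " nt but the scaffold is ", config$scaffold_length, " nt")
    # 12 bundle helices as a serpentine ring on a 2 x 6 honeycomb block,
    # plus the adjuster strand as pseudo-helix 12 below the ring.
    layout <- data.frame(
        helix_id = 0:12,
        row = c(rep(0L, 6), rep(1L, 6), 2L),
        col = c(0:5, 5:0, 0L),
        length_nt = c(rep(span, 12), config$adjuster_nt),
        is_adjuster = c(rep(FALSE, 12), TRUE))
    mods <- blocks[!blocks$is_seam, ]
    partition <- data.frame(
        name = mods$name, start = mods$start, end = mods$end,
        role = ifelse(mods$name == "R3", "adjuster", "structure"),
        stringsAsFactors = FALSE)
    seams <- blocks[blocks$is_seam, c("name", "start", "end")]
    staples <- rbind(.referenceBodyStaples(blocks),
                     .referenceSeamStaples(blocks, span),
                     .strutStaples(config$adjuster_nt))
    rownames(staples) <- NULL
    new("OrigamiDesign",
        layout = layout, partition = partition, seams = seams,
        staples = staples,
        adjuster = list(length_nt = config$adjuster_nt,
                        duplex_fraction = 1.0, reservoir_nt = 0L,
                        full_length_nt = config$adjuster_nt,
                        shift = 0L, second = NULL),
        scaffold_length = config$scaffold_length,
        meta = list(label = "reference", config = config, edits = list()))
}

#' Staples whose footprint lies entirely within a module
#'
#' @param design an [OrigamiDesign-class].
#' @param module_name one of the nine module names.
#' @return the subset of the staple data.frame fully contained in the
#'   module span (on bundle helices).
#' @export
staplesInModule <- function(design, module_name) {
    p <- design@partition
    m <- p[p$name == module_name, ]
    if (!nrow(m)) stop("unknown module: ", module_name)
    inside <- vapply(design@staples$footprint, function(fp) {
        all(fp$helix <= 11L) && all(fp$start >= m$start & fp$end <= m$end)
    }, logical(1))
    design@staples[inside, , drop = FALSE]
}
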