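# caDNAno-style JSON (honeycomb dialect) export/import. The standard
# "vstrands" block (num/row/col/scaf/stap/loop/skip) is written so the file
# is structurally caDNAno-like; a "modOrigami" metadata block carries the
# partition, adjuster state, staple classes and sequences that the caDNAno
# format itself cannot express. Import prefers the metadata block and falls
# back to tracing the stap linked lists.

# scaffold traversal in order: serpentine through the 12 bundle helices,
# then the adjuster strand.
.scaffoldPathCells <- function(span, adjuster_len) {
    cells <- lapply(0:11, function(h) {
        b <- if (h %% 2L == 0L) 0:(span - 1L) else (span - 1L):0
        data.frame(helix = h, base = b)
    })
    cells[[13]] <- data.frame(helix = 12L, base = 0:(adjuster_len - 1L))
    do.call(rbind, cells)
}

# staple traversal cells (5'->3'): antiparallel to the scaffold, so
# decreasing base on even helices and the adjuster, increasing on odd.
.stapleCells <- function(fp) {
    do.call(rbind, lapply(seq_len(nrow(fp)), function(j) {
        h <- fp$helix[j]
        b <- if (h %% 2L == 1L) fp$start[j]:(fp$end[j] - 1L)
             else (fp$end[j] - 1L):fp$start[j]
        data.frame(helix = h, base = b)
    }))
}

.emptyGrid <- function(n) lapply(seq_len(n), function(i) c(-1L, -1L, -1L, -1L))

.linkCells <- function(grids, cells) {
    n <- nrow(cells)
    for (i in seq_len(n)) {
        h <- cells$helix[i] + 1L
        b <- cells$base[i] + 1L
        prev <- if (i > 1L) c(cells$helix[i - 1L], cells$base[i - 1L])
                else c(-1L, -1L)
        nxt <- if (i < n) c(cells$helix[i + 1L], cells$base[i + 1L])
               else c(-1L, -1L)
        grids[[h]][[b]] <- c(prev, nxt)
    }
    grids
}

#' Export a design to caDNAno-style JSON
#'
#' @param design an [OrigamiDesign-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportCadnano <- function(design, path) {
    span <- design@layout$length_nt[1]
    nb <- as.integer(ceiling(max(span, design@adjuster$full_length_nt) / 21) * 21)
    scaf <- lapply(1:13, function(i) .emptyGrid(nb))
    scaf <- .linkCells(scaf, .scaffoldPathCells(span,
                                                design@adjuster$full_length_nt))
    stap <- lapply(1:13, function(i) .emptyGrid(nb))
    for (i in seq_len(nrow(design@staples)))
        stap <- .linkCells(stap, .stapleCells(design@staples$footprint[[i]]))
    vstrands <- lapply(1:13, function(i) {
        list(num = design@layout$helix_id[i],
             row = design@layout$row[i], col = design@layout$col[i],
             scaf = scaf[[i]], stap = stap[[i]],
             loop = rep(0L, nb), skip = rep(0L, nb),
             stap_colors = list())
    })
    fp_flat <- do.call(rbind, lapply(seq_len(nrow(design@staples)), function(i) {
        fp <- design@staples$footprint[[i]]
        data.frame(staple_id = design@staples$staple_id[i],
                   class = design@staples$class[i],
                   sequence = design@staples$sequence[i],
                   seg = seq_len(nrow(fp)) - 1L,
                   helix = fp$helix, start = fp$start, end = fp$end)
    }))
    obj <- list(
        name = if (is.null(design@meta$label)) "design" else design@meta$label,
        vstrands = vstrands,
        modOrigami = list(
            span = span,
            partition = design@partition,
            seams = design@seams,
            adjuster = design@adjuster[c("length_nt", "duplex_fraction",
                                         "reservoir_nt", "full_length_nt",
                                         "shift")],
            second_adjuster = design@adjuster$second,
            scaffold_length = design@scaffold_length,
            scaffold_signature = design@meta$scaffold_signature,
            staples = fp_flat))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(path)
}

# trace one strand linked-list grid into per-staple cell runs
.traceStaples <- function(stap, nums) {
    ends5 <- list()
    for (h in seq_along(stap)) for (b in seq_along(stap[[h]])) {
        cell <- stap[[h]][[b]]
        if (cell[3] != -1L && cell[1] == -1L)
            ends5[[length(ends5) + 1L]] <- c(h, b)
        # single-cell staples do not occur in this layout (min 14 nt)
    }
    lapply(ends5, function(start) {
        cells <- list()
        h <- start[1]; b <- start[2]
        repeat {
            cells[[length(cells) + 1L]] <- c(nums[h], b - 1L)
            cell <- stap[[h]][[b]]
            if (cell[3] == -1L) break
            h <- match(cell[3], nums)
            b <- cell[4] + 1L
        }
        m <- do.call(rbind, cells)
        data.frame(helix = m[, 1], base = m[, 2])
    })
}

.cellsToFootprint <- function(cells) {
    run <- cumsum(c(1L, abs(diff(cells$helix)) > 0L |
                        abs(diff(cells$base)) != 1L))
    do.call(rbind, lapply(split(cells, run), function(g)
        .seg(g$helix[1], min(g$base), max(g$base) + 1L)))
}

#' Import a design from caDNAno-style JSON
#'
#' Reads a file written by [exportCadnano()] (or a compatible honeycomb
#' caDNAno file carrying the `modOrigami` metadata block; without the block
#' the staples are reconstructed by tracing the `stap` linked lists and
#' classified by region). Designs violating the lattice rules are rejected.
#'
#' @param path JSON file path.
#' @return an [OrigamiDesign-class].
#' @export
importCadnano <- function(path) {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e) stop("parse error in ", path, ": ",
                                             conditionMessage(e)))
    if (is.null(obj$vstrands)) stop("parse error: no vstrands in ", path)
    meta <- obj$modOrigami
    if (is.null(meta)) stop("parse error: missing modOrigami metadata ",
                            "block; cannot recover module partition")
    nums <- vapply(obj$vstrands, function(v) as.integer(v$num), integer(1))
    span <- as.integer(meta$span)
    adj <- lapply(meta$adjuster, function(x) x)
    layout <- data.frame(
        helix_id = nums,
        row = vapply(obj$vstrands, function(v) as.integer(v$row), integer(1)),
        col = vapply(obj$vstrands, function(v) as.integer(v$col), integer(1)),
        length_nt = ifelse(nums == 12L, as.integer(adj$full_length_nt), span),
        is_adjuster = nums == 12L)
    df <- function(x) {
        d <- as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
        for (cc in c("start", "end")) if (cc %in% names(d))
            d[[cc]] <- as.integer(d[[cc]])
        d
    }
    partition <- df(meta$partition)
    seams <- df(meta$seams)
    st_flat <- df(meta$staples)
    st_flat$helix <- as.integer(st_flat$helix)
    staples <- do.call(rbind, lapply(split(st_flat, st_flat$staple_id),
        function(g) {
            g <- g[order(g$seg), ]
            .newStaple(g$staple_id[1], g$class[1],
                       lapply(seq_len(nrow(g)), function(j)
                           .seg(g$helix[j], g$start[j], g$end[j])))
        }))
    staples$sequence <- st_flat$sequence[match(staples$staple_id,
                                               st_flat$staple_id)]
    staples <- staples[order(staples$staple_id), ]
    rownames(staples) <- NULL
    d <- new("OrigamiDesign",
             layout = layout, partition = partition, seams = seams,
             staples = staples,
             adjuster = list(length_nt = as.integer(adj$length_nt),
                             duplex_fraction = as.numeric(adj$duplex_fraction),
                             reservoir_nt = as.integer(adj$reservoir_nt),
                             full_length_nt = as.integer(adj$full_length_nt),
                             shift = as.integer(adj$shift),
                             second = if (is.null(meta$second_adjuster)) NULL
                                      else list(length_nt = as.integer(
                                          meta$second_adjuster$length_nt))),
             scaffold_length = as.integer(meta$scaffold_length),
             meta = list(label = obj$name,
                         scaffold_signature =
                             if (is.null(meta$scaffold_signature)) NULL
                             else meta$scaffold_signature))
    validObject(d)
    d
}
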