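test_that("duplex contour conversion reproduces the printed module lengths", {
    expect_equal(round(contourNm(63, "duplex"), 1), 21.4)
    expect_equal(round(contourNm(28, "duplex"), 1), 9.5)
    expect_identical(contourNm(0, "duplex"), 0)
    expect_error(contourNm(-1, "duplex"), "non-negative")
})

test_that("module partition tiles the bundle with the expected spans", {
    ref <- refDesign()
    p <- partitionModules(ref)
    expect_identical(p$name,
                     c("L1", "L2", "L3", "M1", "M2", "M3", "R1", "R2", "R3"))
    expect_equal(p$width_nt[p$name == "L1"], 63)
    expect_equal(p$width_nt[p$name == "R3"], 63)
    expect_true(all(designSeams(ref)$end - designSeams(ref)$start == 28))
    # tiling: union of module + seam spans is the bundle span, disjoint
    tile <- rbind(p[, c("start", "end")],
                  designSeams(ref)[, c("start", "end")])
    tile <- tile[order(tile$start), ]
    expect_equal(tile$start[1], 0)
    expect_equal(tile$end[nrow(tile)], helixLayout(ref)$length_nt[1])
    expect_true(all(tile$end[-nrow(tile)] == tile$start[-1]))
})

test_that("helix coordinates obey honeycomb adjacency (brute-force check)", {
    lay <- helixLayout(refDesign())
    # independent neighbor enumeration: same row adjacent col, or same col
    # adjacent row with odd row+col parity
    for (i in seq_len(nrow(lay))) {
        nb <- 0L
        for (j in seq_len(nrow(lay))[-i]) {
            dr <- abs(lay$row[i] - lay$row[j])
            dc <- abs(lay$col[i] - lay$col[j])
            same_row <- dr == 0 && dc == 1
            same_col <- dc == 0 && dr == 1 &&
                (min(lay$row[i], lay$row[j]) + lay$col[i]) %% 2 == 1
            if (same_row || same_col) nb <- nb + 1L
        }
        expect_lte(nb, 3L)
    }
    # consecutive helices of the serpentine ring are neighbors
    for (h in 0:10)
        expect_true(isLatticeNeighbor(refDesign(), h, h + 1L))
})

test_that("layout configs that overrun the scaffold are rejected", {
    cfg <- defaultLayoutConfig(mid_module_nt = 42L)
    expect_error(buildReference(cfg), "budget")
})
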