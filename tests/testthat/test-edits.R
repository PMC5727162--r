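test_that("ds0hb hinge removes the 11 module staples and adds none", {
    ref <- refDesign()
    h <- applyHinge(ref, "M2", "ds0hb")
    expect_equal(nrow(stapleSet(h)), 180 - 11)
    expect_equal(nrow(staplesInModule(h, "M2")), 0)
})

test_that("dsNhb hinges keep N helices duplexed at the cross-section", {
    ref <- refDesign()
    for (cls in c("ds2hb", "ds3hb", "ds4hb", "ds6hb")) {
        hc <- hingeClass(cls)
        h <- applyHinge(ref, "M2", cls)
        hs <- staplesInModule(h, "M2")
        expect_equal(nrow(hs), hc$n_hinge_staples, info = cls)
        expect_true(all(hs$class == "hinge"))
        # each hinge staple spans the full module on one helix -> one
        # duplexed helix per staple
        expect_equal(sort(vapply(hs$footprint, function(fp) fp$helix[1],
                                 integer(1))),
                     sort(hc$helices), info = cls)
    }
})

test_that("refilling a hinge restores the reference staple set", {
    ref <- refDesign()
    back <- fillModule(applyHinge(ref, "M1", "ds0hb"), "M1")
    expect_true(designIdentical(back, ref))
})

test_that("hinges cannot target seams, end modules or the adjuster module", {
    ref <- refDesign()
    expect_error(applyHinge(ref, "L1", "ds0hb"), "invalid-target")
    expect_error(applyHinge(ref, "R3", "ds0hb"), "invalid-target")
    expect_error(applyHinge(ref, "S1", "ds0hb"), "unknown module")
})

test_that("setAdjuster at full length is the identity", {
    ref <- refDesign()
    expect_true(designIdentical(setAdjuster(ref, 504, 1.0), ref))
})

test_that("adjuster length + reservoir is conserved across edits", {
    ref <- refDesign()
    for (k in c(1L, 2L, 7L, 12L, 23L)) {
        d <- setAdjuster(ref, 504L - 21L * k)
        adj <- adjusterState(d)
        expect_equal(adj$length_nt + adj$reservoir_nt, 504L)
        expect_equal(scaffoldUsage(d), scaffoldUsage(ref))
    }
    expect_error(setAdjuster(ref, 505), "range error")
    expect_error(setAdjuster(ref, 0), "range error")
})

test_that("strut staples track the duplexed extent of the adjuster", {
    ref <- refDesign()
    d <- setAdjuster(ref, 420, 1.0)          # 10 full struts
    expect_equal(sum(stapleSet(d)$class == "strut"), 10)
    d <- setAdjuster(ref, 357, 1.0)          # 8 full + one 21-nt remainder
    expect_equal(sum(stapleSet(d)$class == "strut"), 9)
    d <- setAdjuster(ref, 357, 0)            # bare ssDNA adjuster
    expect_equal(sum(stapleSet(d)$class == "strut"), 0)
})

test_that("second adjuster and closed form enforce their reservoir needs", {
    ref <- refDesign()
    expect_error(addSecondAdjuster(ref, 210), "reservoir")
    expect_error(makeClosed(ref), "reservoir")
    d <- makeClosed(addSecondAdjuster(setAdjuster(ref, 357), 210))
    expect_true(validObject(d))
})

test_that("every edited design still satisfies the design invariants", {
    ref <- refDesign()
    d <- applyHinge(applyHinge(ref, "L3", "ds2hb"), "M3", "ds0hb")
    d <- setAdjuster(d, 294)
    occ <- modOrigami:::stapleOccupancy(d)
    expect_true(all(occ == 1L))
    expect_length(modOrigami:::stapleCrossoverViolations(d), 0)
})
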