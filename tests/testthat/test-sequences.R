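test_that("sequence assignment is deterministic and Watson-Crick", {
    ref <- refDesign()
    scaf <- testScaffold()
    a <- assignSequences(ref, scaf)
    b <- assignSequences(ref, scaf)
    expect_identical(stapleSet(a)$sequence, stapleSet(b)$sequence)
    # every staple base complements the scaffold base it binds
    chars <- strsplit(toupper(as.character(scaf)), "")[[1]]
    span <- helixLayout(ref)$length_nt[1]
    compl <- c(A = "T", C = "G", G = "C", T = "A")
    st <- stapleSet(a)
    for (i in sample(nrow(st), 25)) {
        fp <- st$footprint[[i]]
        expected <- paste(vapply(seq_len(nrow(fp)), function(j) {
            pos <- modOrigami:::.scaffoldPos(fp$helix[j],
                                             fp$start[j]:(fp$end[j] - 1L),
                                             span)
            paste(rev(compl[chars[pos + 1L]]), collapse = "")
        }, character(1)), collapse = "")
        expect_identical(st$sequence[i], expected)
    }
})

test_that("scaffolds shorter than the design are rejected", {
    expect_error(assignSequences(refDesign(), randomScaffold(7000L)),
                 "budget")
})

test_that("diff requires sequenced designs from the same scaffold", {
    ref <- refDesign()
    expect_error(diffStaples(ref, ref), "state error")
    a <- assignSequences(ref, testScaffold())
    b <- assignSequences(ref, randomScaffold(seed = 99L))
    expect_error(diffStaples(a, b), "different scaffolds")
})

test_that("a design diffed against itself has no replaced staples", {
    d <- diffStaples(refSequenced(), refSequenced())
    expect_equal(d@n_replaced, 0)
    expect_equal(d@n_removed, 0)
    expect_equal(d@n_shared, 180)
    expect_equal(d@replaced_fraction, 0)
})

test_that("a single hinge plus shortened adjuster replaces exactly 7 staples", {
    v <- setAdjuster(applyHinge(refDesign(), "M2", "ds0hb"), 357)
    d <- diffStaples(assignSequences(v, testScaffold()), refSequenced())
    expect_equal(d@n_replaced, 7)
    expect_equal(round(100 * d@replaced_fraction, 1), 3.9)
})

test_that("adding a hinge never decreases the replaced + removed count", {
    ref <- refDesign()
    scaf <- testScaffold()
    refs <- refSequenced()
    base <- setAdjuster(ref, 399)
    mods <- c("L2", "M1", "M3", "R2")
    d <- base
    prev <- -1L
    for (m in mods) {
        d <- applyHinge(d, m, "ds0hb")
        di <- diffStaples(assignSequences(d, scaf), refs)
        expect_gte(di@n_replaced + di@n_removed, prev)
        prev <- di@n_replaced + di@n_removed
    }
})
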