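test_that("caDNAno export/import round-trips the reference design", {
    f <- withr::local_tempfile(fileext = ".json")
    exportCadnano(refSequenced(), f)
    expect_true(designIdentical(importCadnano(f), refSequenced()))
})

test_that("round-trip identity holds for edited designs", {
    scaf <- testScaffold()
    f <- withr::local_tempfile(fileext = ".json")
    for (d in sequencedCatalog()[c(1, 13, 20, 23)]) {
        exportCadnano(d, f)
        expect_true(designIdentical(importCadnano(f), d))
    }
})

test_that("malformed JSON and illegal crossovers are rejected", {
    f <- withr::local_tempfile(fileext = ".json")
    writeLines("{ not json", f)
    expect_error(importCadnano(f), "parse error")
    writeLines("{\"name\": \"x\"}", f)
    expect_error(importCadnano(f), "vstrands")
    # a staple crossover between non-neighbor helices must fail validation:
    # helix 0 at (0,0) and helix 7 at (1,4) are not lattice neighbors
    exportCadnano(refSequenced(), f)
    obj <- jsonlite::read_json(f, simplifyVector = FALSE)
    st <- obj$modOrigami$staples
    i <- which(unlist(st$staple_id) == "L1_p00")
    st$helix[i] <- list(0L, 7L)
    obj$modOrigami$staples <- st
    jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
    expect_error(importCadnano(f), "non-neighbor")
})

test_that("exported helix coordinates obey honeycomb adjacency", {
    f <- withr::local_tempfile(fileext = ".json")
    exportCadnano(refSequenced(), f)
    obj <- jsonlite::read_json(f, simplifyVector = TRUE)
    vs <- obj$vstrands
    # brute-force neighbor enumeration on the honeycomb lattice
    for (i in seq_len(nrow(vs))) {
        nb <- sum(vapply(seq_len(nrow(vs))[-i], function(j) {
            dr <- abs(vs$row[i] - vs$row[j]); dc <- abs(vs$col[i] - vs$col[j])
            (dr == 0 && dc == 1) ||
                (dc == 0 && dr == 1 &&
                 (min(vs$row[i], vs$row[j]) + vs$col[i]) %% 2 == 1)
        }, logical(1)))
        expect_lte(nb, 3)
    }
})
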