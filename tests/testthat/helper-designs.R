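# Shared, lazily built design objects so the expensive constructions run
# once per test session.

.cache <- new.env(parent = emptyenv())

refDesign <- function() {
    if (is.null(.cache$ref)) .cache$ref <- buildReference()
    .cache$ref
}

testScaffold <- function() {
    if (is.null(.cache$scaf)) .cache$scaf <- randomScaffold(seed = 42L)
    .cache$scaf
}

refSequenced <- function() {
    if (is.null(.cache$refseq))
        .cache$refseq <- assignSequences(refDesign(), testScaffold())
    .cache$refseq
}

sequencedCatalog <- function() {
    if (is.null(.cache$cat))
        .cache$cat <- lapply(buildVariantCatalog(refDesign()),
                             assignSequences, scaffold = testScaffold())
    .cache$cat
}
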