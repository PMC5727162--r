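# Scaffold sequence handling. The bundled scaffold is a seeded synthetic
# 7,249-nt stand-in for M13mp18 (the staple-count bookkeeping never depends
# on sequence identity, only staple strings do); a real M13mp18 FASTA can be
# supplied to any function that takes a scaffold.

#' Generate a seeded random scaffold sequence
#'
#' @param length_nt scaffold length (default 7249, the M13mp18 length).
#' @param seed integer seed; the same seed always yields the same sequence.
#' @return a [Biostrings::DNAString].
#' @export
randomScaffold <- function(length_nt = 7249L, seed = 7249L) {
    rs <- .seededSample(seed, c("A", "C", "G", "T"), length_nt)
    Biostrings::DNAString(paste(rs, collapse = ""))
}

.seededSample <- function(seed, x, n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sample(x, n, replace = TRUE)
}

#' Read a scaffold from FASTA
#'
#' @param path FASTA file with a single scaffold record.
#' @return a [Biostrings::DNAString].
#' @export
readScaffold <- function(path) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) < 1L) stop("no sequence in ", path)
    set[[1L]]
}

#' The bundled synthetic scaffold
#'
#' Reads `inst/extdata/scaffold_7249_synthetic.fasta`, a deterministic
#' synthetic 7,249-nt sequence standing in for M13mp18.
#'
#' @return a [Biostrings::DNAString] of length 7,249.
#' @export
defaultScaffold <- function() {
    path <- system.file("extdata", "scaffold_7249_synthetic.fasta",
                        package = "modOrigami")
    if (nzchar(path)) readScaffold(path) else randomScaffold()
}
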