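# Sequence assignment. The scaffold is routed as a serpentine through the
# 12 bundle helices (even helices forward, odd helices backward, turns at
# the bundle ends) and then continues into the adjuster strand; the unused
# scaffold tail is the slack loop. Every staple base is the Watson-Crick
# complement of the scaffold base it binds.

# scaffold position (0-based) of a (helix, base) cell; helix is scalar,
# base may be a vector
.scaffoldPos <- function(helix, base, span) {
    if (helix == 12L) 12L * span + base
    else if (helix %% 2L == 0L) helix * span + base
    else helix * span + (span - 1L - base)
}

.COMPL <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.stapleSequence <- function(fp, scaf_chars, span) {
    paste(vapply(seq_len(nrow(fp)), function(j) {
        b <- fp$start[j]:(fp$end[j] - 1L)
        pos <- .scaffoldPos(fp$helix[j], b, span)
        paste(rev(.COMPL[scaf_chars[pos + 1L]]), collapse = "")
    }, character(1)), collapse = "")
}

#' Assign staple sequences from a scaffold
#'
#' Deterministically maps the design onto a scaffold sequence and fills in
#' every staple as the reverse complement of the scaffold stretch it binds.
#'
#' @param design an [OrigamiDesign-class].
#' @param scaffold a [Biostrings::DNAString], character string, or path to
#'   a FASTA file; defaults to the bundled synthetic scaffold.
#' @return the design with sequences assigned.
#' @export
assignSequences <- function(design, scaffold = defaultScaffold()) {
    if (is.character(scaffold) && length(scaffold) == 1L &&
        file.exists(scaffold))
        scaffold <- readScaffold(scaffold)
    scaf <- toupper(as.character(scaffold))
    if (nchar(scaf) < scaffoldUsage(design))
        stop("scaffold budget error: scaffold has ", nchar(scaf),
             " nt but the design needs ", scaffoldUsage(design))
    chars <- strsplit(scaf, "")[[1]]
    span <- design@layout$length_nt[1]
    design@staples$sequence <- vapply(design@staples$footprint,
                                      .stapleSequence, character(1),
                                      scaf_chars = chars, span = span)
    design@meta$scaffold_signature <-
        paste0(nchar(scaf), ":", substr(scaf, 1, 24))
    design
}

#' Diff a variant's staples against the reference pool
#'
#' Counts variant staples whose sequences are absent from the reference
#' staple pool ("replaced"), reference staples whose sequences are absent
#' from the variant ("removed") and the shared remainder. The replaced
#' fraction is reported on the reference pool size.
#'
#' @param variant,reference two sequence-assigned [OrigamiDesign-class]
#'   objects derived from the same scaffold.
#' @return a [StapleDiff-class].
#' @export
diffStaples <- function(variant, reference) {
    vs <- variant@staples$sequence
    rs <- reference@staples$sequence
    if (any(!nzchar(vs)) || any(!nzchar(rs)))
        stop("state error: both designs must be sequence-assigned ",
             "(run assignSequences first)")
    sv <- variant@meta$scaffold_signature
    sr <- reference@meta$scaffold_signature
    if (!is.null(sv) && !is.null(sr) && !identical(sv, sr))
        stop("state error: designs were sequenced from different scaffolds")
    n_rep <- sum(!vs %in% rs)
    n_rem <- sum(!rs %in% vs)
    n_shr <- sum(vs %in% rs)
    new("StapleDiff",
        n_reference = length(rs), n_variant = length(vs),
        n_replaced = as.integer(n_rep), n_removed = as.integer(n_rem),
        n_shared = as.integer(n_shr),
        replaced_fraction = n_rep / length(rs))
}
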