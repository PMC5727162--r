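# Deterministic fixture bundle: everything the test surfaces need,
# regenerated bit-identically from a seed.

#' Write the deterministic fixture bundle
#'
#' Writes, under `output_dir`: the synthetic scaffold FASTA, the default
#' layout config (YAML), an angle-observation CSV generated from the
#' strain-energy model at a known hinge stiffness (25.3 pN nm/rad), and a
#' small synthetic AFM scene as a text grid. The same seed always yields a
#' byte-identical bundle.
#'
#' @param output_dir output directory (created if needed).
#' @param seed integer seed.
#' @return list of the written paths, invisibly.
#' @export
makeFixtures <- function(output_dir, seed = 1L) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    # scaffold
    scaf <- randomScaffold(7249L, seed = seed)
    paths$scaffold <- file.path(output_dir, "scaffold_synthetic.fasta")
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(list(scaf),
                                                 "synthetic_scaffold_7249nt")),
        paths$scaffold)
    # layout config
    paths$layout <- file.path(output_dir, "layout_default.yaml")
    yaml::write_yaml(defaultLayoutConfig(), paths$layout)
    # angle observations generated at a known stiffness
    geom <- hingeGeometry()
    k_true <- 25.3
    adj_nt <- c(273L, 294L, 315L, 336L, 357L)
    obs <- do.call(rbind, lapply(adj_nt, function(l) {
        wlc <- wlcParams(contourNm(bridgeNt(l, geom), "single"))
        th <- predictAngle(torsionalHinge(k_true), geom, wlc)
        data.frame(hinge_class = "ds0hb", adjuster_nt = l,
                   mean_angle_deg = round(as.numeric(th), 2),
                   sd_deg = 5, n = 250L)
    }))
    paths$observations <- file.path(output_dir, "observations_k25.3.csv")
    utils::write.csv(obs, paths$observations, row.names = FALSE)
    # small synthetic AFM scene
    spec <- sceneSpec(n_particles = 4L, angle_deg = 90, image_px = 256L)
    hm <- synthesizeScene(spec, seed = seed)
    paths$scene <- file.path(output_dir, "scene_90deg.txt")
    writeHeightMap(hm, paths$scene, format = "text")
    paths$scene_spec <- file.path(output_dir, "scene_90deg.yaml")
    yaml::write_yaml(c(spec, list(seed = seed)), paths$scene_spec)
    invisible(paths)
}
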