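test_that("noise-free scenes render the expected particles", {
    spec <- sceneSpec(n_particles = 6, angle_deg = 90, angle_sd_deg = 0,
                      noise_sd_nm = 0)
    hm <- synthesizeScene(spec, seed = 5)
    expect_equal(max(heights(hm)), 2)          # rod height
    parts <- segmentParticles(hm)
    expect_length(parts, 6)
    hm2 <- synthesizeScene(spec, seed = 5)
    expect_identical(heights(hm), heights(hm2))  # seeded determinism
    expect_error(synthesizeScene(sceneSpec(500, 90), 1), "placement")
})

test_that("a noise-only image segments to nothing at 3 sigma", {
    spec <- sceneSpec(n_particles = 0, angle_deg = 90, noise_sd_nm = 0.15,
                      image_px = 256L)
    hm <- synthesizeScene(spec, seed = 9)
    expect_length(segmentParticles(hm, height_threshold = 3 * 0.15), 0)
})

test_that("classification separates monomers, aggregates and fragments", {
    spec <- sceneSpec(n_particles = 4, angle_deg = 75, angle_sd_deg = 0,
                      n_aggregate = 2, n_fragment = 2, noise_sd_nm = 0)
    hm <- synthesizeScene(spec, seed = 21)
    meas <- measureHeightMap(hm)
    expect_equal(sum(meas$class == "monomer"), 4)
    expect_equal(sum(meas$class == "aggregate"), 2)
    expect_equal(sum(meas$class == "fragment"), 2)
    # yield conservation over all masks
    expect_equal(nrow(meas), 8)
})

test_that("included angles are measured to 2 degrees on clean particles", {
    for (a in c(45, 90, 135)) {
        spec <- sceneSpec(n_particles = 5, angle_deg = a, angle_sd_deg = 0,
                          noise_sd_nm = 0)
        meas <- measureHeightMap(synthesizeScene(spec, seed = a))
        expect_true(all(abs(meas$included_angle_deg - a) < 2), info = a)
    }
})

test_that("straight and folded rods are flagged, not mis-measured", {
    spec <- sceneSpec(n_particles = 4, angle_deg = 180, angle_sd_deg = 0,
                      noise_sd_nm = 0)
    meas <- measureHeightMap(synthesizeScene(spec, seed = 2))
    expect_true(all(meas$included_angle_deg == 180))
    expect_true(all(meas$flag == "straight"))
    spec0 <- sceneSpec(n_particles = 4, angle_deg = 0, angle_sd_deg = 0,
                       noise_sd_nm = 0)
    meas0 <- measureHeightMap(synthesizeScene(spec0, seed = 2))
    expect_true(all(meas0$included_angle_deg == 0))
    expect_true(all(meas0$flag == "folded"))
})

test_that("the measured angle is invariant to rotation and pixel size", {
    base <- sceneSpec(n_particles = 1, angle_deg = 70, angle_sd_deg = 0,
                      noise_sd_nm = 0, image_px = 256L)
    angs <- vapply(1:8, function(s) {
        m <- measureHeightMap(synthesizeScene(base, seed = s))
        m$included_angle_deg[1]
    }, numeric(1))   # random orientation/translation per seed
    expect_lt(max(angs) - min(angs), 1)
    fine <- sceneSpec(n_particles = 1, angle_deg = 70, angle_sd_deg = 0,
                      noise_sd_nm = 0, image_px = 512L, pixel_nm = 1)
    mf <- measureHeightMap(synthesizeScene(fine, seed = 3))
    mc <- measureHeightMap(synthesizeScene(base, seed = 3))
    expect_lt(abs(mf$included_angle_deg[1] - mc$included_angle_deg[1]), 1)
})

test_that("the Gaussian fit recovers mean and sd from large samples", {
    set.seed(31)
    ang <- rnorm(1e4, 75, 8)
    rep <- yieldAndHistogram(ang, target_angle = 75)
    expect_lt(abs(rep@fit$mean - 75), 0.5)
    expect_lt(abs(rep@fit$sd - 8) / 8, 0.05)
    expect_equal(sum(rep@histogram$count), 1e4)
    # all-identical measurements: zero sd, full yield inside the window
    rep0 <- yieldAndHistogram(rep(60, 20), target_angle = 60, window = 5)
    expect_equal(rep0@fit$sd, 0)
    expect_equal(rep0@structural_yield, 1)
})

test_that("height maps survive TIFF and text round trips", {
    spec <- sceneSpec(n_particles = 2, angle_deg = 120, image_px = 256L)
    hm <- synthesizeScene(spec, seed = 4)
    ft <- withr::local_tempfile(fileext = ".tif")
    writeHeightMap(hm, ft)
    back <- readHeightMap(ft, pixel_nm = pixelSize(hm))
    expect_equal(heights(back), heights(hm), tolerance = 1e-6)
    fx <- withr::local_tempfile(fileext = ".txt")
    writeHeightMap(hm, fx)
    backx <- readHeightMap(fx, pixel_nm = pixelSize(hm))
    expect_equal(heights(backx), heights(hm), tolerance = 1e-12)
})
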