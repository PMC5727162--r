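test_that("stiffness is recovered exactly from noise-free predicted angles", {
    geom <- hingeGeometry()
    for (k_true in c(25.3, 33.8, 49.6)) {
        adj <- c(273L, 294L, 315L, 336L, 357L)
        wlcs <- lapply(adj, function(l)
            wlcParams(contourNm(bridgeNt(l, geom), "single")))
        th <- mapply(function(l, w)
            predictAngle(torsionalHinge(k_true), geom, w), adj, wlcs)
        est <- estimateStiffness(
            data.frame(adjuster_nt = adj, mean_angle_deg = as.numeric(th)),
            geom, wlcs)
        expect_lt(abs(est@mean - k_true) / k_true, 0.01)
        expect_lte(est@min, est@mean)
        expect_lte(est@mean, est@max)
    }
})

test_that("stiffness recovery tolerates 5-degree particle noise at n = 250", {
    geom <- hingeGeometry()
    k_true <- 25.3
    adj <- c(273L, 294L, 315L, 336L, 357L)
    wlcs <- lapply(adj, function(l)
        wlcParams(contourNm(bridgeNt(l, geom), "single")))
    set.seed(101)
    obs <- do.call(rbind, lapply(seq_along(adj), function(i) {
        th <- predictAngle(torsionalHinge(k_true), geom, wlcs[[i]])
        ang <- as.numeric(th) + rnorm(250, 0, 5)
        data.frame(adjuster_nt = adj[i],
                   mean_angle_deg = mean(pmax(ang, 0.5)),
                   sd_deg = sd(ang), n = 250L)
    }))
    est <- estimateStiffness(obs, geom, wlcs)
    expect_lt(abs(est@mean - k_true) / k_true, 0.10)
})

test_that("degenerate observations are flagged", {
    geom <- hingeGeometry()
    wlc <- wlcParams(Lc = 40)
    expect_error(
        estimateStiffness(data.frame(mean_angle_deg = 180), geom, wlc),
        "indeterminate")
    expect_warning(
        est <- estimateStiffness(
            data.frame(mean_angle_deg = c(30, 100)), geom,
            list(wlcParams(Lc = 40), wlcParams(Lc = 200))),
        "slack")
    expect_equal(sum(is.finite(est@k_per_obs)), 1)
})

test_that("equipartition recovers stiffness from a sampled trajectory", {
    kT <- 4.114
    k_true <- 30
    set.seed(7)
    traj <- rnorm(1e4, 120, sqrt(kT / k_true) * 180 / pi)
    expect_lt(abs(pcaStiffness(traj, kT) - k_true) / k_true, 0.05)
    expect_warning(kinf <- pcaStiffness(rep(90, 200), kT), "infinite")
    expect_identical(kinf, Inf)
    expect_error(pcaStiffness(rnorm(50)), "100 samples")
})

test_that("multivariate modes order softest first", {
    set.seed(8)
    kT <- 4.114
    m <- cbind(rnorm(5000, 0, 10), rnorm(5000, 0, 2)) # degrees
    k <- pcaStiffness(m, kT)
    expect_length(k, 2)
    expect_lte(k[1], k[2])
})
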