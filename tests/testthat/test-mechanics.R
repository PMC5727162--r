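test_that("adjuster extension follows the law of cosines", {
    expect_equal(adjusterExtension(180, hingeGeometry(5, 5)), 10)
    expect_equal(adjusterExtension(0, hingeGeometry(5, 5)), 0)
    expect_equal(adjusterExtension(90, hingeGeometry(3, 4)), 5)
})

test_that("landscape decomposes into hinge and adjuster terms", {
    geom <- hingeGeometry()
    wlc <- wlcParams(Lc = 60)
    ls0 <- energyLandscape(torsionalHinge(0), geom, wlc)
    expect_equal(ls0@E_total, ls0@E_adjuster)
    ls <- energyLandscape(torsionalHinge(25.3), geom, wlc)
    ok <- ls@feasible
    expect_equal(ls@E_total[ok], ls@E_hinge[ok] + ls@E_adjuster[ok])
    expect_true(all(ls@E_total[ok] >= 0))
    expect_false(all(ls@feasible))   # taut chain caps the angle range
})

test_that("slack adjusters leave the equilibrium at the rest angle", {
    geom <- hingeGeometry()
    # Lc >= r1 + r2: chain spans the full opening without tension
    expect_equal(predictAngle(torsionalHinge(25.3), geom,
                              wlcParams(Lc = 200)), 180)
    ls <- energyLandscape(torsionalHinge(25.3), geom, wlcParams(Lc = 200))
    expect_true(all(ls@E_adjuster == 0))
})

test_that("the predicted angle is the grid-search energy minimum", {
    geom <- hingeGeometry()
    for (Lc in c(25, 40, 55)) {
        wlc <- wlcParams(Lc = Lc)
        th <- predictAngle(torsionalHinge(25.3), geom, wlc)
        ls <- energyLandscape(torsionalHinge(25.3), geom, wlc,
                              seq(0.05, 180, by = 0.05))
        grid_min <- ls@theta_deg[ls@feasible][
            which.min(ls@E_total[ls@feasible])]
        expect_lt(abs(th - grid_min), 0.1)
        # minimum lies strictly between 0 and the geometric cap (x = Lc)
        cap <- 2 * asin(Lc / (geom$r1 + geom$r2)) * 180 / pi
        expect_gt(th, 0)
        expect_lt(th, cap)
    }
})

test_that("stiffer hinges open the angle monotonically toward the cap", {
    geom <- hingeGeometry()
    wlc <- wlcParams(Lc = 40)
    th <- vapply(c(5, 25.3, 33.8, 49.6, 200, 2000),
                 function(k) predictAngle(torsionalHinge(k), geom, wlc),
                 numeric(1))
    expect_true(all(diff(th) > 0))
    cap <- 2 * asin(40 / (geom$r1 + geom$r2)) * 180 / pi
    expect_lt(max(th), cap)
    # without an adjuster the stiff limit is the rest angle itself
    expect_equal(predictAngle(torsionalHinge(1e6), geom, NULL), 180)
})

test_that("shorter adjusters close the predicted angle monotonically", {
    geom <- hingeGeometry()
    lens <- seq(357, 273, by = -21)
    th <- vapply(lens, function(l)
        predictAngle(torsionalHinge(25.3), geom,
                     wlcParams(contourNm(bridgeNt(l, geom), "single"))),
        numeric(1))
    expect_true(all(diff(th) < 0))
})

test_that("a duplex adjuster sets the angle geometrically, independent of k", {
    geom <- hingeGeometry()
    expect_equal(predictAngleDs(252, geom), 180)  # 0.34*252 = r1 + r2
    expect_equal(predictAngleDs(0, geom), 0)      # chord |r1 - r2| = 0
    expect_error(predictAngleDs(300, geom), "infeasible")
    # the geometric angle involves no stiffness at all; the strain-energy
    # route must agree for any k once the chord is pinned
    th_geo <- predictAngleDs(bridgeNt(399, geom), geom)
    expect_true(th_geo > 0 && th_geo < 180)
})

test_that("21-nt decrements step the ds-adjuster angle by roughly 15 degrees", {
    geom <- hingeGeometry()
    lens <- seq(483, 273, by = -21)
    th <- vapply(lens, function(l) predictAngleDs(bridgeNt(l, geom), geom),
                 numeric(1))
    expect_true(all(diff(th) < 0))
    steps <- -diff(c(th, predictAngleDs(bridgeNt(252, geom), geom)))
    expect_true(all(steps > 5 & steps < 25))
    expect_lt(abs(mean(steps) - 15), 5)
})

test_that("Boltzmann statistics of a harmonic landscape give sd = sqrt(kT/k)", {
    geom <- hingeGeometry()
    for (k in c(25.3, 49.6)) {
        ls <- energyLandscape(torsionalHinge(k, 90), geom, NULL,
                              seq(0.25, 180, by = 0.05))
        bs <- boltzmannStats(ls, kT = 4.114)
        expect_lt(abs(bs$sd_deg - sqrt(4.114 / k) * 180 / pi), 0.2)
        expect_lt(abs(bs$mean_deg - 90), 0.1)
        # normalization on the grid
        dth <- 0.05
        expect_equal(sum(bs$density$p * dth), 1, tolerance = 1e-6)
    }
})

test_that("ds-adjusted structures fluctuate less than ss-adjusted ones", {
    geom <- hingeGeometry()
    wlc <- wlcParams(Lc = 40)
    th_ss <- predictAngle(torsionalHinge(25.3), geom, wlc)
    ls_ss <- energyLandscape(torsionalHinge(25.3), geom, wlc,
                             seq(0.25, 180, by = 0.05))
    sd_ss <- boltzmannStats(ls_ss)$sd_deg
    # duplex adjuster at the same mean: a stiff chord constraint modeled as
    # a steep harmonic well around the geometric angle
    k_ds <- 2000
    ls_ds <- energyLandscape(torsionalHinge(k_ds, th_ss), geom, NULL,
                             seq(0.25, 180, by = 0.05))
    sd_ds <- boltzmannStats(ls_ds)$sd_deg
    expect_lt(sd_ds, sd_ss)
})
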