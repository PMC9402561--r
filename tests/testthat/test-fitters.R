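vol <- function(x, d = c(3, 3, 3)) array(x, d)

test_that("VFA fitting inverts the spoiled-GRE model exactly", {
    t <- tissueParams(1.0, 0.08, 0.05, 1000)
    flips <- c(6, 20); tr <- 0.015
    vols <- lapply(flips, function(f) vol(spgrSignal(t, tr, f)))
    fit <- fitVFA(vols, flips, tr)
    expect_lt(max(abs(fittedMap(fit, "T1map") - 1.0)), 1e-6)
    expect_lt(max(abs(fittedMap(fit, "M0map") - 1000) / 1000), 1e-6)
    expect_true(all(fitMask(fit)))
    ## degenerate voxel: all-zero signal is masked NaN
    z <- lapply(flips, function(f) vol(0))
    fz <- fitVFA(z, flips, tr)
    expect_false(any(fitMask(fz)))
    expect_true(all(is.nan(fittedMap(fz, "T1map"))))
    expect_error(fitVFA(vols[1], 6, tr), "at least 2 distinct")
})

test_that("VFA transmit-field correction removes the B1 bias", {
    t <- tissueParams(1.0, 0.08, 0.05, 1000, b1_rel = 0.8)
    flips <- c(6, 20); tr <- 0.015
    vols <- lapply(flips, function(f) vol(spgrSignal(t, tr, f)))
    withB1 <- fitVFA(vols, flips, tr, b1map = vol(80))
    expect_lt(max(abs(fittedMap(withB1, "T1map") - 1.0)), 1e-6)
    without <- fitVFA(vols, flips, tr)
    ## uncorrected fit is biased (toward b1^2 * T1, here downward)
    expect_true(all(fittedMap(without, "T1map") < 1.0))
})

test_that("IR fitting recovers T1 from signed and magnitude data", {
    t <- tissueParams(0.8, 0.08, 0.05, 500)
    tis <- c(0.1, 0.4, 0.9, 2.0); tr <- 5.0
    vols <- lapply(tis, function(ti) vol(irSignal(t, ti, tr)))
    fit <- fitIR(vols, tis, tr)
    expect_lt(max(abs(fittedMap(fit, "T1map") - 0.8) / 0.8), 1e-6)
    fitM <- fitIR(lapply(vols, abs), tis, tr, magnitude = TRUE)
    expect_equal(fittedMap(fitM, "T1map"), fittedMap(fit, "T1map"),
                 tolerance = 1e-9)
    ## constant signals carry no decay information
    fc <- fitIR(lapply(tis, function(i) vol(100)), tis, tr)
    expect_false(any(fitMask(fc)))
    expect_error(fitIR(vols[1:2], tis[1:2], tr), "at least 3")
})

test_that("monoexponential fitting is exact on noiseless decays", {
    tes <- c(0.01, 0.02, 0.03, 0.04)
    vols <- lapply(tes, function(te) vol(monoexpSignal(100, 0.05, te)))
    fit <- fitMonoexp(vols, tes, "T2map")
    expect_lt(max(abs(fittedMap(fit, "T2map") - 0.05)), 1e-9)
    expect_lt(max(abs(fittedMap(fit, "M0map") - 100)), 1e-7)
    ## two echoes: determined two-point solution
    fit2 <- fitMonoexp(vols[c(1, 3)], tes[c(1, 3)], "T2starmap")
    expect_lt(max(abs(fittedMap(fit2, "T2starmap") - 0.05)), 1e-12)
    ## non-positive signal masks the voxel
    bad <- vols; bad[[2]][1, 1, 1] <- 0
    fitB <- fitMonoexp(bad, tes, "T2map")
    expect_false(fitMask(fitB)[1, 1, 1])
    expect_true(is.nan(fittedMap(fitB, "T2map")[1, 1, 1]))
    expect_identical(sum(!fitMask(fitB)), 1L)
})

test_that("noisy T2* recovery stays within 2% median error", {
    set.seed(303)
    d <- c(25, 20, 20)
    tes <- seq(0.006, 0.06, by = 0.006)
    vols <- lapply(tes, function(te)
        array(monoexpSignal(1000, 0.05, te) +
                  rnorm(prod(d), sd = 10), d))
    fit <- fitMonoexp(vols, tes, "T2starmap")
    relerr <- abs(fittedMap(fit, "T2starmap") / 0.05 - 1)
    expect_lt(median(relerr[fitMask(fit)]), 0.02)
})

test_that("MTR is the percent signal drop with division guard", {
    fit <- computeMTR(vol(100), vol(80))
    expect_equal(fittedMap(fit, "MTRmap"), vol(20))
    expect_equal(fittedMap(computeMTR(vol(100), vol(100)), "MTRmap"),
                 vol(0))
    f0 <- computeMTR(vol(0), vol(10))
    expect_false(any(fitMask(f0)))
    expect_error(computeMTR(vol(1), array(1, c(2, 2, 2))), "mismatch")
})

test_that("MTsat recovery matches the forward model exactly", {
    p <- mtsProtocol(flipMT = 6, trMT = 0.025, flipPD = 6, trPD = 0.025,
                     flipT1 = 20, trT1 = 0.011)
    t <- tissueParams(1.0, 0.08, 0.05, 1000, mtsat_delta = 0.04)
    sg <- mtsSignals(t, p)
    fit <- computeMTsat(vol(sg$sMT), vol(sg$sPD), vol(sg$sT1), p)
    expect_lt(max(abs(fittedMap(fit, "R1map") - 1.0)), 1e-6)
    expect_lt(max(abs(fittedMap(fit, "M0map") - 1000) / 1000), 1e-6)
    expect_lt(max(abs(fittedMap(fit, "MTsat") - 4.0) / 4.0), 1e-6)
    ## delta = 0 phantom gives zero MTsat
    t0 <- tissueParams(1.0, 0.08, 0.05, 1000, mtsat_delta = 0)
    sg0 <- mtsSignals(t0, p)
    fit0 <- computeMTsat(vol(sg0$sMT), vol(sg0$sPD), vol(sg0$sT1), p)
    expect_lt(max(abs(fittedMap(fit0, "MTsat"))), 1e-9)
    ## degenerate arm pair
    expect_error(mtsProtocol(6, 0.025, 6, 0.025, 6, 0.011), "flipT1")
})

test_that("MP2RAGE lookup inversion recovers T1 within the grid step", {
    p <- mp2rageProtocol(trPrep = 5.0, trExc = 0.0062, ti = c(0.7, 2.5),
                         flipsDeg = c(4, 5), nExc = 160L)
    t1true <- c(0.6337, 1.2114, 2.7039)   # off-grid values
    tp <- tissueParams(t1true, pmin(t1true, 0.1), pmin(t1true, 0.05), 800)
    sg <- mp2rageBlockSignals(tp, p)
    d <- c(3, 1, 1)
    fit <- suppressWarnings(
        fitMP2RAGE(array(sg$s1, d), array(sg$s2, d), p))
    expect_true(all(fitMask(fit)))
    expect_lt(max(abs(fittedMap(fit, "T1map") - t1true)), 0.001)
    ## common complex factor leaves the map unchanged
    cfac <- 3 * exp(1i * pi / 7)
    fit2 <- suppressWarnings(
        fitMP2RAGE(array(cfac * sg$s1, d), array(cfac * sg$s2, d), p))
    expect_equal(fittedMap(fit2, "T1map"), fittedMap(fit, "T1map"),
                 tolerance = 1e-12)
    ## UNI at the boundary of the combination range is masked
    fitB <- suppressWarnings(
        fitMP2RAGE(p = p, uni = array(0.5, c(1, 1, 1))))
    expect_false(any(fitMask(fitB)))
})

test_that("double-angle fitting returns relative percent with clamping", {
    fit <- fitDAM(vol(sin(pi / 3)), vol(sin(2 * pi / 3)), nominalDeg = 60)
    expect_equal(fittedMap(fit, "TB1map"), vol(100))
    t9 <- tissueParams(1, 0.08, 0.05, 1000, b1_rel = 0.9)
    sg <- damSignals(t9, 60)
    fit9 <- fitDAM(vol(sg$s1), vol(sg$s2), 60)
    expect_lt(max(abs(fittedMap(fit9, "TB1map") - 90)), 1e-9)
    ## noise pushing the ratio beyond 1 clamps to flip 0 and is counted
    fitC <- fitDAM(vol(1), vol(2.4), 60)
    expect_equal(fittedMap(fitC, "TB1map"), vol(0))
    expect_identical(fitDiagnostics(fitC)$n_clipped, 27L)
    expect_false(any(fitMask(fitDAM(vol(0), vol(0), 60))))
})

test_that("AFI fitting inverts the dual-TR ratio", {
    p <- afiProtocol(0.02, 0.1, 60)
    fit <- fitAFI(vol(1), vol(3.5 / 5.5), p)
    expect_lt(max(abs(fittedMap(fit, "TB1map") - 100)), 1e-9)
    t11 <- tissueParams(1, 0.08, 0.05, 1000, b1_rel = 1.1)
    s1 <- 1000 * sin(1.1 * pi / 3)
    fit11 <- fitAFI(vol(s1), vol(s1 * afiRatio(t11, p)), p)
    expect_lt(max(abs(fittedMap(fit11, "TB1map") - 110)), 1e-6)
    ## degenerate ratio r = n is masked
    fitD <- fitAFI(vol(1), vol(5), p)
    expect_false(any(fitMask(fitD)))
    expect_error(fitAFI(vol(1), vol(1), afiProtocol(0.02, 0.1, 60),
                        nominalDeg = 60), NA)
})

test_that("fitters are pure: identical inputs give identical maps", {
    t <- tissueParams(1.0, 0.08, 0.05, 1000)
    vols <- lapply(c(6, 20), function(f) vol(spgrSignal(t, 0.015, f)))
    f1 <- fitVFA(vols, c(6, 20), 0.015)
    f2 <- fitVFA(vols, c(6, 20), 0.015)
    expect_identical(fittedMap(f1, "T1map"), fittedMap(f2, "T1map"))
})

test_that("maps carry registry units and physical-range sanity", {
    ds <- phantomDataset()
    truth <- phantomTruth()
    inReg <- truth$m0 > 0
    for (sfx in c("VFA", "MESE", "MEGRE", "MTR")) {
        res <- fitCollection(collectionOf(ds, sfx))
        fit <- res$fit
        for (ms in names(fit@maps))
            expect_identical(fit@units[[ms]], unitsForMap(ms))
        m <- fittedMap(fit)
        ok <- fitMask(fit) & inReg
        expect_true(all(m[ok] > 0 | names(fit@maps)[1] == "MTRmap"))
        if ("MTRmap" %in% names(fit@maps))
            expect_true(all(m[ok] >= -100 & m[ok] <= 100))
    }
})
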