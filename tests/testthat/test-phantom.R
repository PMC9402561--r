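test_that("regions rasterize with later-wins precedence", {
    tp1 <- tissueParams(1.0, 0.1, 0.05, 100)
    spec <- phantomSpec(shape = c(16L, 16L, 16L),
                        regions = list(
                            phantomRegion("sphere", tp1,
                                          center = c(8.5, 8.5, 8.5),
                                          radius = 5)))
    vols <- makePhantom(spec)
    inside <- vols$m0 > 0
    expect_true(all(vols$t1[inside] == 1.0))
    expect_true(all(vols$t1[!inside] == spec$background$t1))
    expect_true(all(vols$m0[!inside] == 0))

    ## overlapping boxes: overlap takes the later region's values
    tpA <- tissueParams(1.0, 0.1, 0.05, 100)
    tpB <- tissueParams(2.0, 0.2, 0.1, 200)
    spec2 <- phantomSpec(shape = c(10L, 10L, 10L),
                         regions = list(
                             phantomRegion("box", tpA, lo = c(1, 1, 1),
                                           hi = c(6, 6, 6)),
                             phantomRegion("box", tpB, lo = c(4, 4, 4),
                                           hi = c(10, 10, 10))))
    v2 <- makePhantom(spec2)
    expect_identical(v2$t1[5, 5, 5], 2.0)
    expect_identical(v2$t1[2, 2, 2], 1.0)
    expect_error(phantomSpec(shape = c(8L, 8L, 8L), regions = list()),
                 "at least one region")
    expect_error(
        phantomSpec(shape = c(8L, 8L, 8L),
                    regions = list(phantomRegion("sphere", tpA,
                                                 center = c(4, 4, 4),
                                                 radius = 10))),
        "outside the grid")
})

test_that("default phantom voxel counts match the nested-sphere volumes", {
    vols <- makePhantom(defaultPhantom())
    counts <- table(vols$t1)
    ## nested spheres: count voxels inside each radius directly
    ctr <- c(16.5, 16.5, 16.5)
    g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
    r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
    nWM <- sum(r2 <= 36); nGM <- sum(r2 <= 100) - nWM
    nCSF <- sum(r2 <= 196) - nWM - nGM
    expect_identical(as.integer(counts[["0.85"]]), nWM)
    expect_identical(as.integer(counts[["1.35"]]), nGM)
    expect_identical(as.integer(counts[["3.5"]]), nCSF)
})

test_that("generation is deterministic: identical seeds, identical bytes", {
    protos <- defaultProtocols(c("VFA", "MP2RAGE"))
    r1 <- file.path(tempdir(), "det1"); r2 <- file.path(tempdir(), "det2")
    unlink(c(r1, r2, paste0(r1, "_truth"), paste0(r2, "_truth")),
           recursive = TRUE)
    ph <- defaultPhantom(noise = list(model = "gaussian", sigma = 2,
                                      seed = 7L))
    generateDataset(ph, protos, r1)
    generateDataset(ph, protos, r2)
    f1 <- list.files(r1, recursive = TRUE)
    f2 <- list.files(r2, recursive = TRUE)
    expect_identical(f1, f2)
    for (f in f1) {
        if (grepl("\\.json$", f)) {
            expect_identical(readLines(file.path(r1, f)),
                             readLines(file.path(r2, f)), label = f)
        } else {
            expect_identical(readVolume(file.path(r1, f))$voxels,
                             readVolume(file.path(r2, f))$voxels,
                             label = f)
        }
    }
    unlink(c(r1, r2, paste0(r1, "_truth"), paste0(r2, "_truth")),
           recursive = TRUE)
})

test_that("gaussian noise reproduces the requested standard deviation", {
    tp <- tissueParams(1.0, 0.1, 0.05, 1000)
    spec <- phantomSpec(shape = c(24L, 24L, 24L),
                        regions = list(phantomRegion(
                            "box", tp, lo = c(1, 1, 1),
                            hi = c(24, 24, 24))),
                        noise = list(model = "gaussian", sigma = 5,
                                     seed = 99L))
    root <- file.path(tempdir(), "noise-ds")
    unlink(c(root, paste0(root, "_truth")), recursive = TRUE)
    generateDataset(spec, defaultProtocols("MEGRE"), root)
    fc <- collectionOf(root, "MEGRE")
    v <- readVolume(collectionPaths(fc)[1])$voxels
    te <- parameterTable(fc)$EchoTime[1]
    resid <- v - monoexpSignal(1000, 0.05, te)
    expect_gte(length(resid), 10000)
    expect_lt(abs(stats::sd(resid) - 5) / 5, 0.05)
    unlink(c(root, paste0(root, "_truth")), recursive = TRUE)
})

test_that("generated datasets expose the documented file layout", {
    ds <- phantomDataset()
    expect_true(file.exists(file.path(ds, "dataset_description.json")))
    dd <- readSidecarJSON(file.path(ds, "dataset_description.json"))
    expect_identical(dd$BIDSVersion, "1.5.0")
    ## MP2RAGE: 4 images ({inv-1,inv-2} x {mag,phase}) under anat/
    mp <- list.files(file.path(ds, "sub-01", "anat"),
                     pattern = "MP2RAGE\\.nii\\.gz$")
    expect_length(mp, 4)
    ## TB1DAM: flip-1 at the nominal angle, flip-2 at its double, in fmap/
    dam <- collectionOf(ds, "TB1DAM")
    tab <- parameterTable(dam)
    expect_identical(getSuffixSpec("TB1DAM")$folder, "fmap")
    expect_identical(basename(dirname(collectionPaths(dam)[1])), "fmap")
    fa <- tab$FlipAngle[order(as.integer(tab$flip))]
    expect_identical(fa[2], 2 * fa[1])
    ## ground truth lives outside the BIDS tree
    expect_true(dir.exists(paste0(ds, "_truth")))
    expect_length(list.files(ds, pattern = "^t1\\.nii\\.gz$",
                             recursive = TRUE), 0)
})

test_that("phantom recovery holds end-to-end for every fitted suffix", {
    ds <- phantomDataset()
    truth <- phantomTruth()
    inReg <- truth$m0 > 0
    relerr <- function(fit, map, tru) {
        ok <- inReg & fitMask(fit)
        max(abs(fittedMap(fit, map)[ok] - tru[ok]) / abs(tru[ok]))
    }
    fit <- fitCollection(collectionOf(ds, "VFA"))$fit
    expect_lt(relerr(fit, "T1map", truth$t1), 1e-6)
    fit <- fitCollection(collectionOf(ds, "IRT1"))$fit
    expect_lt(relerr(fit, "T1map", truth$t1), 1e-6)
    fit <- fitCollection(collectionOf(ds, "MTS"))$fit
    expect_lt(relerr(fit, "R1map", 1 / truth$t1), 1e-6)
    expect_lt(relerr(fit, "MTsat", 100 * truth$mtsat_delta), 1e-6)
    fit <- fitCollection(collectionOf(ds, "TB1AFI"))$fit
    expect_lt(relerr(fit, "TB1map", 100 * truth$b1_rel), 1e-6)
    fit <- fitCollection(collectionOf(ds, "MESE"))$fit
    expect_lt(relerr(fit, "T2map", truth$t2), 1e-9)
    fit <- fitCollection(collectionOf(ds, "MEGRE"))$fit
    expect_lt(relerr(fit, "T2starmap", truth$t2star), 1e-9)
    fit <- fitCollection(collectionOf(ds, "TB1DAM"))$fit
    expect_lt(relerr(fit, "TB1map", 100 * truth$b1_rel), 1e-9)
    fit <- fitCollection(collectionOf(ds, "MTR"))$fit
    ok <- inReg & fitMask(fit)
    expect_equal(fittedMap(fit, "MTRmap")[ok],
                 (100 * truth$mtr_frac)[ok], tolerance = 1e-12)
    fit <- suppressWarnings(fitCollection(collectionOf(ds, "MP2RAGE")))$fit
    ok <- inReg & fitMask(fit)
    expect_gt(sum(ok), 0.99 * sum(inReg))
    expect_lt(max(abs(fittedMap(fit, "T1map")[ok] - truth$t1[ok])), 0.001)
})
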