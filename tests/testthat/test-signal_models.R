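wm <- function(...) tissueParams(t1 = 1.0, t2 = 0.08, t2star = 0.05,
                                 m0 = 1000, ...)

test_that("spoiled-GRE steady state matches the Bloch recursion oracle", {
    t <- wm()
    ## limits
    expect_equal(spgrSignal(wm(), tr = 10, flipDeg = 30),
                 1000 * sin(30 * pi / 180), tolerance = 1e-4)
    expect_lt(spgrSignal(wm(), tr = 0.015, flipDeg = 1e-9), 1e-4)
    ## pulse-by-pulse iteration to steady state
    for (cfg in list(list(t1 = 1.0, tr = 0.015, a = 20, b1 = 1),
                     list(t1 = 0.85, tr = 0.03, a = 5, b1 = 0.9),
                     list(t1 = 3.5, tr = 0.015, a = 6, b1 = 1.1))) {
        tis <- tissueParams(cfg$t1, 0.08, 0.05, 1000, b1_rel = cfg$b1)
        s <- spgrSignal(tis, cfg$tr, cfg$a)
        o <- blochSpgrOracle(1000, cfg$t1, cfg$tr, cfg$a, cfg$b1)
        expect_lt(abs(s - o) / abs(o), 1e-9)
    }
    ## TE weighting
    expect_equal(spgrSignal(t, 0.015, 20, te = 0.01),
                 spgrSignal(t, 0.015, 20) * exp(-0.01 / 0.05))
})

test_that("inversion-recovery signal matches its closed form and oracle", {
    t <- tissueParams(0.8, 0.08, 0.05, 500)
    ## full inversion and null point
    expect_equal(irSignal(t, ti = 1e-9, tr = 50), -500, tolerance = 1e-4)
    expect_equal(irSignal(t, ti = 0.8 * log(2), tr = 50), 0,
                 tolerance = 1e-4)
    ## steady-state cycle oracle
    s <- irSignal(t, ti = 0.4, tr = 5.0)
    o <- blochIrOracle(500, 0.8, ti = 0.4, tr = 5.0)
    expect_lt(abs(s - o) / abs(o), 1e-12)
})

test_that("monoexponential decay behaves at its anchors", {
    expect_identical(monoexpSignal(100, 0.08, 0), 100)
    expect_equal(monoexpSignal(100, 0.08, 0.08), 100 / exp(1))
    expect_equal(monoexpSignal(100, 0.08, 0.04), 100 * exp(-0.5))
})

test_that("MP2RAGE closed-form steady state equals cycle iteration", {
    p <- mp2rageProtocol(trPrep = 5.0, trExc = 0.0062, ti = c(0.7, 2.5),
                         flipsDeg = c(4, 5), nExc = 160L)
    ## 20-point grid over T1 and transmit scale
    grid <- expand.grid(t1 = seq(0.3, 4.5, length.out = 10),
                        b1 = c(0.85, 1.1))
    for (i in seq_len(nrow(grid))) {
        t1 <- grid$t1[i]; b1 <- grid$b1[i]
        tis <- tissueParams(t1, min(t1, 0.1), min(t1, 0.05), 1,
                            b1_rel = b1)
        sg <- mp2rageBlockSignals(tis, p)
        o <- mp2rageIterOracle(t1, p, b1 = b1, ncycle = 500L)
        expect_lt(abs(Re(sg$s1) - o$s1), 1e-10)
        expect_lt(abs(Re(sg$s2) - o$s2), 1e-10)
    }
})

test_that("MP2RAGE blocks are symmetric when the inversion has no effect", {
    ## equal flips and recovery intervals much longer than T1: the
    ## magnetization forgets the inversion before either block, so both
    ## blocks read the same driven equilibrium
    p <- mp2rageProtocol(trPrep = 4.0, trExc = 0.005, ti = c(1.0, 2.5),
                         flipsDeg = c(5, 5), nExc = 100L)
    t <- tissueParams(0.05, 0.04, 0.03, 1000)
    sg <- mp2rageBlockSignals(t, p)
    expect_equal(Re(sg$s1), Re(sg$s2), tolerance = 1e-6)
    ## linearity in M0
    t1x <- wm()
    t2x <- tissueParams(1.0, 0.08, 0.05, 2000)
    s1x <- mp2rageBlockSignals(t1x, p)
    s2x <- mp2rageBlockSignals(t2x, p)
    expect_equal(as.complex(s2x$s1), 2 * as.complex(s1x$s1))
    expect_equal(Re(s2x$s2) / Re(s1x$s2), 2)
})

test_that("UNI combination is bounded and scale invariant", {
    expect_identical(mp2rageUni(1 + 0i, 1 + 0i), 0.5)
    expect_identical(mp2rageUni(1 + 0i, -1 + 0i), -0.5)
    expect_true(is.nan(mp2rageUni(0 + 0i, 0 + 0i)))
    set.seed(11)
    n <- 1000
    s1 <- complex(real = rnorm(n), imaginary = rnorm(n))
    s2 <- complex(real = rnorm(n), imaginary = rnorm(n))
    u <- mp2rageUni(s1, s2)
    expect_true(all(u >= -0.5 & u <= 0.5))
    cc <- complex(real = rnorm(n), imaginary = rnorm(n))
    cc[Mod(cc) < 1e-6] <- 1
    expect_lt(max(abs(mp2rageUni(cc * s1, cc * s2) - u)), 1e-12)
})

test_that("UNI decreases monotonically in T1 over the working range", {
    p <- mp2rageProtocol(trPrep = 5.0, trExc = 0.0062, ti = c(0.7, 2.5),
                         flipsDeg = c(4, 5), nExc = 160L)
    grid <- seq(0.3, 5, by = 0.01)
    tp <- tissueParams(grid, pmin(grid, 0.1), pmin(grid, 0.05), 1)
    sg <- mp2rageBlockSignals(tp, p)
    u <- mp2rageUni(sg$s1, sg$s2)
    expect_true(all(diff(u) < 0))
})

test_that("double-angle signals satisfy the half-angle identity", {
    t <- wm()
    sg <- damSignals(t, 60)
    expect_equal(sg$s2 / (2 * sg$s1), cos(60 * pi / 180))
    t0 <- tissueParams(1, 0.08, 0.05, 1000, b1_rel = 1e-12)
    sg0 <- damSignals(t0, 60)
    expect_equal(sg0$s1, 0, tolerance = 1e-6)
    t9 <- tissueParams(1, 0.08, 0.05, 1000, b1_rel = 0.9)
    sg9 <- damSignals(t9, 60)
    expect_equal(sg9$s1, 1000 * sin(0.9 * pi / 3))
    expect_equal(sg9$s2, 1000 * sin(1.8 * pi / 3))
})

test_that("AFI ratio follows the dual-TR closed form", {
    p <- afiProtocol(tr1 = 0.02, tr2 = 0.1, flipDeg = 60)
    expect_equal(p$n, 5)
    t <- wm()
    expect_equal(afiRatio(t, p), (1 + 5 * cos(pi / 3)) / (5 + cos(pi / 3)))
    t90 <- tissueParams(1, 0.08, 0.05, 1000, b1_rel = 1.5)  # 90 deg actual
    expect_equal(afiRatio(t90, p), 1 / 5)
    p1 <- afiProtocol(tr1 = 0.02, tr2 = 0.0200001, flipDeg = 60)
    expect_equal(afiRatio(t, p1), 1, tolerance = 1e-5)
    expect_error(afiProtocol(tr1 = 0.1, tr2 = 0.02, flipDeg = 60),
                 "tr2 > tr1")
})

test_that("MTsat arms follow the rational small-angle model", {
    p <- mtsProtocol(flipMT = 6, trMT = 0.025, flipPD = 6, trPD = 0.025,
                     flipT1 = 20, trT1 = 0.011)
    t <- tissueParams(1.0, 0.08, 0.05, 1000, mtsat_delta = 0.04)
    sg <- mtsSignals(t, p)
    a <- 6 * pi / 180
    expect_equal(sg$sPD, 1000 * a * 0.025 / (a^2 / 2 + 0.025))
    expect_equal(sg$sMT, 1000 * a * 0.025 / (a^2 / 2 + 0.04 + 0.025))
    ## no saturation: MT arm equals a PD arm with identical settings
    t0 <- tissueParams(1.0, 0.08, 0.05, 1000, mtsat_delta = 0)
    sg0 <- mtsSignals(t0, p)
    expect_equal(sg0$sMT, sg0$sPD)
    ## linear small-angle limit
    pSmall <- mtsProtocol(flipMT = 1e-4, trMT = 0.025, flipPD = 1e-4,
                          trPD = 0.025, flipT1 = 2e-4, trT1 = 0.025)
    sgS <- mtsSignals(t0, pSmall)
    expect_equal(sgS$sPD, 1000 * 1e-4 * pi / 180, tolerance = 1e-6)
})

test_that("signal models are homogeneous of degree one in M0", {
    t1x <- wm(); t2x <- tissueParams(1.0, 0.08, 0.05, 3000)
    expect_equal(spgrSignal(t2x, 0.015, 20), 3 * spgrSignal(t1x, 0.015, 20))
    expect_equal(irSignal(t2x, 0.4, 5), 3 * irSignal(t1x, 0.4, 5))
    expect_equal(monoexpSignal(3000, 0.05, 0.02),
                 3 * monoexpSignal(1000, 0.05, 0.02))
    d1 <- damSignals(t1x, 60); d3 <- damSignals(t2x, 60)
    expect_equal(d3$s1, 3 * d1$s1)
    ## ratios are degree zero
    p <- afiProtocol(0.02, 0.1, 60)
    expect_equal(afiRatio(t2x, p), afiRatio(t1x, p))
})

test_that("protocol constructors enforce timing invariants", {
    expect_error(mp2rageProtocol(5, 0.0062, c(2.5, 0.7), c(4, 5), 160L),
                 "ti1 < ti2")
    expect_error(mp2rageProtocol(5, 0.0062, c(0.7, 1.0), c(4, 5), 160L),
                 "do not fit")
    expect_error(mp2rageProtocol(5, 0.0062, c(0.7, 2.5), c(4, 5), 160L,
                                 invEff = 1.5), "invEff")
    expect_error(tissueParams(1, 2, 0.05, 100), "T2 must not exceed")
    expect_error(tissueParams(1, 0.08, 0.1, 100), "T2\\* must not exceed")
    expect_error(mtsProtocol(6, 0.025, 20, 0.025, 6, 0.011),
                 "flipT1 > flipPD")
})
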