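# Shared fixtures: the full phantom dataset is generated once per test run
# and reused read-only; tests that mutate a dataset copy it first.

.fixture_env <- new.env(parent = emptyenv())

# full synthetic dataset covering every registered suffix (noiseless)
phantomDataset <- function() {
    if (is.null(.fixture_env$root)) {
        root <- file.path(tempdir(), "qmribids-fixture-ds")
        unlink(root, recursive = TRUE)
        unlink(paste0(root, "_truth"), recursive = TRUE)
        generateDataset(outRoot = root)
        .fixture_env$root <- root
    }
    .fixture_env$root
}

phantomTruth <- function() {
    if (is.null(.fixture_env$truth))
        .fixture_env$truth <- readTruth(phantomDataset())
    .fixture_env$truth
}

# writable copy of the fixture dataset
copyDataset <- function() {
    src <- phantomDataset()
    dst <- file.path(tempdir(), paste0("qmribids-mut-",
                                       as.integer(stats::runif(1, 1, 1e8))))
    dir.create(dst, recursive = TRUE)
    ok <- file.copy(list.files(src, full.names = TRUE), dst,
                    recursive = TRUE)
    stopifnot(all(ok))
    dst
}

collectionOf <- function(root, suffix) {
    colls <- groupCollections(root)
    colls[[which(vapply(colls, collectionSuffix, "") == suffix)]]
}

# independent discrete Bloch recursion oracle for the spoiled-GRE steady
# state: iterate pulse + relaxation explicitly and read the signal once the
# longitudinal magnetization has converged
blochSpgrOracle <- function(m0, t1, tr, flipDeg, b1 = 1, npulse = 10000L) {
    a <- flipDeg * pi / 180 * b1
    e1 <- exp(-tr / t1)
    mz <- 1
    for (i in seq_len(npulse))
        mz <- (mz * cos(a)) * e1 + (1 - e1)
    m0 * sin(a) * mz
}

# inversion-recovery steady state by explicit cycle iteration: invert, read
# (saturating 90-degree pulse) at ti, recover for tr - ti
blochIrOracle <- function(m0, t1, ti, tr, ncycle = 10000L) {
    mz <- 1
    sig <- NA_real_
    for (i in seq_len(ncycle)) {
        mz <- -mz
        mzti <- 1 - (1 - mz) * exp(-ti / t1)
        sig <- mzti
        mz <- 1 - exp(-(tr - ti) / t1)   # recovery from saturation
    }
    m0 * sig
}

# explicit per-pulse iteration of the MP2RAGE cycle; returns the steady-state
# normalized mz at cycle start and the two central-excitation signals
mp2rageIterOracle <- function(t1, p, b1 = 1, ncycle = 500L) {
    relax <- function(mz, dt) mz * exp(-dt / t1) + (1 - exp(-dt / t1))
    a1 <- p$flipsDeg[1] * pi / 180 * b1
    a2 <- p$flipsDeg[2] * pi / 180 * b1
    n <- p$nExc; kc <- ceiling(n / 2)
    blk <- n * p$trExc
    mz <- 1
    s1 <- s2 <- NA_real_
    for (cyc in seq_len(ncycle)) {
        mz <- -p$invEff * mz
        mz <- relax(mz, p$ti[1])
        for (k in seq_len(n)) {
            if (k == kc) s1 <- sin(a1) * mz
            mz <- relax(mz * cos(a1), p$trExc)
        }
        mz <- relax(mz, p$ti[2] - p$ti[1] - blk)
        for (k in seq_len(n)) {
            if (k == kc) s2 <- sin(a2) * mz
            mz <- relax(mz * cos(a2), p$trExc)
        }
        mz <- relax(mz, p$trPrep - p$ti[2] - blk)
    }
    list(mz = mz, s1 = s1, s2 = s2)
}

sortEnts <- function(e) if (length(e)) e[order(names(e))] else list()

# random valid parsed-name records for round-trip property tests
randomParsedName <- function() {
    suffixes <- listSuffixes()
    sfx <- sample(suffixes, 1)
    spec <- getSuffixSpec(sfx)
    defs <- entityDefs()
    ents <- list()
    for (k in names(spec$entity_req)) {
        lev <- spec$entity_req[[k]]
        if (lev == "forbidden") next
        if (lev == "optional" && stats::runif(1) < 0.5) next
        ents[[k]] <- if (defs[[k]]$value_kind == "index")
            sample(1:9, 1) else sample(defs[[k]]$allowed_labels, 1)
    }
    list(sub = sprintf("%02d", sample(1:20, 1)),
         ses = if (stats::runif(1) < 0.3) sprintf("%02d", sample(1:3, 1)),
         entities = ents,
         extra = if (stats::runif(1) < 0.3) c(acq = "test"),
         suffix = sfx,
         ext = sample(c(".nii.gz", ".nii", ".json"), 1))
}
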