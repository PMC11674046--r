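test_that("population sampling honors degenerate proportions", {
    p <- SceneParams(nCells = 30L, imageSize = c(300L, 300L),
                     fractionPositive = 0, seed = 2L)
    specs <- sampleCellPopulation(p)
    expect_equal(nrow(specs), 30L)
    expect_false(any(specs$positive))
    expect_true(all(specs$true_ratio == 1.0))
})

test_that("positive count falls in the exact binomial 99% interval", {
    p <- SceneParams(nCells = 200L, imageSize = c(900L, 900L),
                     fractionTransfected = 1, fractionPositive = 0.65,
                     seed = 1L)
    specs <- sampleCellPopulation(p)
    ci <- qbinom(c(0.005, 0.995), 200, 0.65)
    expect_gte(sum(specs$positive), ci[1])
    expect_lte(sum(specs$positive), ci[2])
})

test_that("sampling is deterministic given the seed", {
    p <- SceneParams(nCells = 25L, imageSize = c(300L, 300L), seed = 9L)
    a <- sampleCellPopulation(p)
    b <- sampleCellPopulation(p)
    expect_identical(a, b)
    expect_false(identical(a$cy,
                           sampleCellPopulation(p, seed = 10L)$cy))
})

test_that("population geometry invariants hold across seeds", {
    for (s in 1:4) {
        p <- SceneParams(nCells = 20L, imageSize = c(300L, 300L),
                         seed = s)
        specs <- sampleCellPopulation(p)
        # cell ellipse contains nucleus ellipse (same centre and aspect)
        expect_true(all(specs$cell_ry > specs$nuc_ry))
        expect_true(all(specs$cell_rx > specs$nuc_rx))
        # negative cells have ratio exactly 1
        expect_true(all(specs$true_ratio[!specs$positive] == 1.0))
        expect_true(all(specs$true_ratio[specs$positive] >= 1.0))
        # no two cells overlap (conservative circumradius check is what
        # the sampler guarantees)
        n <- nrow(specs)
        maxAx <- pmax(specs$cell_ry, specs$cell_rx)
        for (i in seq_len(n - 1)) {
            d <- sqrt((specs$cy[-(1:i)] - specs$cy[i])^2 +
                      (specs$cx[-(1:i)] - specs$cx[i])^2)
            expect_true(all(d > maxAx[i] + maxAx[-(1:i)]))
        }
        # foci strictly inside the nucleus ellipse
        for (i in seq_len(n)) {
            fo <- specs$foci[[i]]
            if (!nrow(fo)) next
            u <- ((fo[, "fy"] - specs$cy[i]) / specs$nuc_ry[i])^2 +
                 ((fo[, "fx"] - specs$cx[i]) / specs$nuc_rx[i])^2
            expect_true(all(u < 1))
        }
    }
})

test_that("infeasible packing raises a scene-overcrowded error", {
    p <- SceneParams(nCells = 80L, imageSize = c(128L, 128L), seed = 1L)
    expect_error(sampleCellPopulation(p), "overcrowded")
})

test_that("rendering is piecewise constant and analytically exact", {
    p <- noiseless(nCells = 1L, imageSize = c(120L, 120L))
    spec <- makeSpec(60, 60, yfp = 100, ratio = 2,
                     cargoNuc = 50, cargoCyto = 100)
    sc <- renderScene(spec, p)
    img <- sceneImage(sc)
    focus <- fociMask(sc) == 1
    nucleoplasm <- nucleusMask(sc) == 1 & !focus
    cyto <- cellMask(sc) == 1 & nucleusMask(sc) == 0
    expect_equal(mean(img[, , 2][focus]), 200.0)
    expect_equal(mean(img[, , 2][nucleoplasm]), 100.0)
    # true N/C recoverable by masked means
    nc <- mean(img[, , 4][nucleusMask(sc) == 1]) / mean(img[, , 4][cyto])
    expect_equal(nc, 0.5)
    # background everywhere outside cells, all channels
    out <- cellMask(sc) == 0
    for (ch in 1:4)
        expect_true(all(img[, , ch][out] == 20))
})

test_that("an empty scene renders as uniform background", {
    p <- noiseless(nCells = 0L, imageSize = c(64L, 64L))
    sc <- renderScene(sampleCellPopulation(p), p)
    expect_true(all(sceneImage(sc) == 20))
})

test_that("noise model is unbiased, seedable, and has a noiseless limit", {
    x <- matrix(100, 32, 32)
    expect_identical(applyNoise(x, c(Inf, 0)), x)
    expect_identical(applyNoise(x, c(1, 2), seed = 4L),
                     applyNoise(x, c(1, 2), seed = 4L))
    expect_error(applyNoise(x, c(-1, 2)), "noise")
    expect_error(applyNoise(x - 200, c(1, 2)), "non-negative")
    # law of large numbers: mean over 1000 realizations within 1% of 100
    withr::with_seed(7L, {
        m <- mean(replicate(1000, mean(applyNoise(x, c(1, 2)))))
    })
    expect_lt(abs(m - 100) / 100, 0.01)
})

test_that("condition suites are countable and byte-stable on disk", {
    manifest <- list(conditions = list(ref = "wt", low = "a541k"),
                     nExperiments = 3L,
                     base = list(nCells = 8L, imageSize = c(220L, 220L)))
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    idx <- makeConditionSuite(manifest, d1, masterSeed = 5L)
    expect_equal(nrow(idx), 6L)
    expect_true(all(file.exists(idx$image)))
    expect_true(all(file.exists(idx$truth)))
    makeConditionSuite(manifest, d2, masterSeed = 5L)
    for (f in basename(idx$truth))
        expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                         readBin(file.path(d2, f), "raw", 1e6))
    expect_error(makeConditionSuite(list(conditions = list(a = "wt")), d1),
                 "nExperiments")
})

test_that("per-experiment seeds are stable and distinct", {
    expect_identical(seedForExperiment(1L, "wt", 1L),
                     seedForExperiment(1L, "wt", 1L))
    s <- c(seedForExperiment(1L, "wt", 1L),
           seedForExperiment(1L, "wt", 2L),
           seedForExperiment(1L, "a541k", 1L),
           seedForExperiment(2L, "wt", 1L))
    expect_equal(length(unique(s)), 4L)
})
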