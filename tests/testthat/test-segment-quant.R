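test_that("nuclei are recovered from noiseless scenes with Jaccard >= 0.99", {
    p <- noiseless(nCells = 10L, imageSize = c(300L, 300L), seed = 6L)
    sc <- renderScene(sampleCellPopulation(p), p)
    lab <- segmentNuclei(sceneImage(sc)[, , 1])
    expect_equal(max(lab), 10L)
    map <- matchLabelsToTruth(lab, nucleusMask(sc))
    for (L in seq_len(10)) {
        expect_gte(jaccard(lab == L, nucleusMask(sc) == map[[as.character(L)]]),
                   0.99)
    }
})

test_that("blank images yield an empty mask with a warning", {
    expect_warning(lab <- segmentNuclei(matrix(7, 50, 50)), "blank")
    expect_true(all(lab == 0))
})

test_that("border-touching nuclei are flagged and dropped by default", {
    p <- noiseless(nCells = 1L, imageSize = c(120L, 120L))
    spec <- makeSpec(60, 60)
    spec2 <- makeSpec(3, 60, id = 2L)      # nucleus crosses the top border
    spec2$foci <- list(cbind(fy = numeric(0), fx = numeric(0),
                             radius = numeric(0)))
    sc <- renderScene(rbind(spec, spec2), p)
    lab <- segmentNuclei(sceneImage(sc)[, , 1])
    expect_equal(max(lab), 1L)             # only the interior nucleus kept
    expect_equal(attr(lab, "qc")$nEdgeDropped, 1L)
    labKeep <- segmentNuclei(sceneImage(sc)[, , 1], dropEdge = FALSE)
    expect_equal(max(labKeep), 2L)
    expect_true(any(attr(labKeep, "edgeTouching")))
})

test_that("cytoplasm means are exact on noiseless isolated cells", {
    p <- noiseless(nCells = 1L, imageSize = c(120L, 120L))
    sc <- renderScene(makeSpec(60, 60, cargoNuc = 40, cargoCyto = 100), p)
    nuc <- segmentNuclei(sceneImage(sc)[, , 1])
    bodies <- segmentCellBodies(sceneImage(sc), nuc)
    foci <- detectCompartments(sceneImage(sc)[, , 3], nuc)
    m <- measureCells(sceneImage(sc), nuc, foci, bodies)
    expect_equal(m$cargo_cyto_mean, 100, tolerance = 1e-12)
    expect_equal(m$cargo_nuc_mean, 40, tolerance = 1e-12)
})

test_that("clustered mode produces no cytoplasm and N/C errors out", {
    p <- noiseless(nCells = 1L, imageSize = c(120L, 120L))
    sc <- renderScene(makeSpec(60, 60), p)
    nuc <- segmentNuclei(sceneImage(sc)[, , 1])
    bodies <- segmentCellBodies(sceneImage(sc), nuc, mode = "clustered")
    expect_null(bodies$cytoplasmLabels)
    foci <- detectCompartments(sceneImage(sc)[, , 3], nuc)
    m <- measureCells(sceneImage(sc), nuc, foci, bodies)
    expect_true(all(is.na(m$cargo_cyto_mean)))
    expect_error(computeNCRatio(m, mode = "clustered"), "clustered")
})

test_that("seeded watershed partitions foreground between adjacent cells", {
    p <- noiseless(nCells = 2L, imageSize = c(140L, 140L))
    specs <- rbind(makeSpec(70, 53, cellR = 16),
                   makeSpec(70, 86, cellR = 16, id = 2L))
    sc <- renderScene(specs, p)
    nuc <- segmentNuclei(sceneImage(sc)[, , 1])
    bodies <- segmentCellBodies(sceneImage(sc), nuc)
    fg <- cellMask(sc) > 0
    # every cell pixel is assigned to exactly one label
    expect_true(all(bodies$cellLabels[fg] > 0))
    expect_setequal(unique(as.vector(bodies$cellLabels[fg])), c(1L, 2L))
    # cytoplasm and nucleus masks are disjoint
    expect_true(all(bodies$cytoplasmLabels[nuc > 0] == 0))
})

test_that("the selected focus is the one with the highest marker mean", {
    p <- noiseless(nCells = 1L, imageSize = c(120L, 120L))
    img <- sceneImage(renderScene(makeSpec(
        60, 60, foci = cbind(fy = c(54, 60, 66), fx = c(54, 63, 55),
                             radius = c(2.5, 2.5, 2.5))), p))
    nuc <- segmentNuclei(img[, , 1])
    # overwrite marker foci with distinct levels 300/400/500
    marker <- img[, , 3]
    sc2 <- renderScene(makeSpec(
        60, 60, foci = cbind(fy = c(54, 60, 66), fx = c(54, 63, 55),
                             radius = c(2.5, 2.5, 2.5))), p)
    fm <- fociMask(sc2)
    for (k in 1:3) marker[fm == k] <- 200 + 100 * k
    foci <- detectCompartments(marker, nuc)
    sel <- foci$table[foci$table$selected, ]
    expect_equal(nrow(sel), 1L)
    expect_equal(sel$marker_mean, 500)
})

test_that("no marker contrast means no detected foci", {
    p <- noiseless(nCells = 3L, imageSize = c(220L, 220L),
                   markerEnrichment = 1, seed = 2L)
    sc <- renderScene(sampleCellPopulation(p), p)
    nuc <- segmentNuclei(sceneImage(sc)[, , 1])
    foci <- detectCompartments(sceneImage(sc)[, , 3], nuc)
    expect_equal(nrow(foci$table), 0L)
    expect_equal(foci$qc$nNucleiNoFocus, 3L)
    m <- measureCells(sceneImage(sc), nuc, foci)
    expect_true(all(is.na(m$compartment_ratio)))
    expect_true(all(m$exclude_reason == "no_focus"))
})

test_that("detected foci match generating disks with Jaccard >= 0.9", {
    p <- noiseless(nCells = 8L, imageSize = c(300L, 300L), seed = 8L)
    sc <- renderScene(sampleCellPopulation(p), p)
    nuc <- segmentNuclei(sceneImage(sc)[, , 1])
    foci <- detectCompartments(sceneImage(sc)[, , 3], nuc)
    expect_gt(nrow(foci$table), 0)
    truth <- fociMask(sc)
    for (fid in foci$table$focus_id) {
        det <- foci$fociLabels == fid
        owners <- truth[det]
        owner <- as.integer(names(which.max(table(owners[owners > 0]))))
        expect_gte(jaccard(det, truth == owner), 0.9)
    }
})

test_that("measured ratios are exact on noiseless scenes", {
    p <- noiseless(nCells = 1L, imageSize = c(120L, 120L))
    sc <- renderScene(makeSpec(60, 60, ratio = 2.5), p)
    res <- measureScene(sc)
    expect_equal(res$cells$compartment_ratio, 2.5, tolerance = 1e-9)
    # all-background region never divides by zero: blank scene
    blank <- renderScene(makeSpec(60, 60, ratio = 2.5)[0, ], p)
    expect_warning(res0 <- measureScene(blank), "blank")
    expect_equal(nrow(res0$cells), 0L)
})

test_that("transfection windows select as specified", {
    m <- data.frame(yfp_nuc_mean = c(10, 50, 100, 500, 5000))
    all <- selectTransfected(m, c(0, Inf))
    expect_equal(nrow(all), 5L)
    expect_warning(none <- selectTransfected(m, c(1e6, 1e7)), "zero cells")
    expect_equal(nrow(none), 0L)
    expect_error(selectTransfected(m, c(10, 10)), "low < high")
    mid <- selectTransfected(m, c(40, 600))
    expect_equal(attr(mid, "nExcludedLow"), 1L)
    expect_equal(attr(mid, "nExcludedHigh"), 1L)
})

test_that("selected transfected fraction matches the binomial oracle", {
    p <- SceneParams(nCells = 110L, imageSize = c(640L, 640L),
                     fractionTransfected = 0.3, seed = 1L)
    res <- measureScene(simulateScene(p))
    sel <- selectTransfected(res$cells, c(60, Inf))
    n <- nrow(res$cells)
    ci <- qbinom(c(0.005, 0.995), n, 0.3)
    expect_gte(nrow(sel), ci[1])
    expect_lte(nrow(sel), ci[2])
})

test_that("positivity uses a strict >= threshold boundary", {
    m <- data.frame(compartment_ratio = c(1.49, 1.5, NA))
    out <- classifyPositive(m, 1.5)
    expect_identical(out$positive, c(FALSE, TRUE, NA))
    expect_equal(attr(out, "ratio_threshold"), 1.5)
    expect_error(classifyPositive(m, -1), "positive number")
})

test_that("ratios and positivity are invariant to global rescaling", {
    p <- SceneParams(nCells = 12L, imageSize = c(300L, 300L), seed = 4L)
    sc <- simulateScene(p)
    a <- measureScene(sceneImage(sc))$cells
    b <- measureScene(sceneImage(sc) * 3.7)$cells
    expect_equal(b$compartment_ratio, a$compartment_ratio,
                 tolerance = 1e-12)
    expect_identical(b$positive, a$positive)
    expect_equal(b$cargo_nuc_mean / b$cargo_cyto_mean,
                 a$cargo_nuc_mean / a$cargo_cyto_mean, tolerance = 1e-12)
})

test_that("mask algebra holds on measured scenes", {
    p <- SceneParams(nCells = 10L, imageSize = c(300L, 300L), seed = 12L)
    sc <- simulateScene(p)
    img <- sceneImage(sc)
    nuc <- segmentNuclei(img[, , 1])
    bodies <- segmentCellBodies(img, nuc)
    foci <- detectCompartments(img[, , 3], nuc)
    # compartments inside nuclei, cytoplasm outside
    expect_true(all(nuc[foci$fociLabels > 0] > 0))
    expect_true(all(nuc[bodies$cytoplasmLabels > 0] == 0))
    # cytoplasm label agrees with the nucleus label of its cell
    expect_true(all(bodies$cellLabels[nuc > 0] == nuc[nuc > 0]))
})
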