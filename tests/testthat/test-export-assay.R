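test_that("N/C ratios follow the per-cell definition with guarded cases", {
    m <- data.frame(cargo_nuc_mean = c(50, 80, 60),
                    cargo_cyto_mean = c(100, 80, NA))
    out <- computeNCRatio(m)
    expect_equal(out$nc_ratio, c(0.5, 1.0, NA))
    expect_equal(out$nc_ratio_reason[3], "no_cytoplasm_mask")
})

test_that("N/C ratio recovers the generating truth on noiseless cells", {
    p <- noiseless(nCells = 1L, imageSize = c(120L, 120L))
    sc <- renderScene(makeSpec(60, 60, cargoNuc = 40, cargoCyto = 100), p)
    res <- measureScene(sc)
    out <- computeNCRatio(res$cells)
    expect_equal(out$nc_ratio, 0.4, tolerance = 1e-9)
})

test_that("N/total ratios use the whole-micrograph mean", {
    m <- data.frame(cargo_nuc_mean = c(80, 40))
    expect_equal(computeNTotalRatio(m, 40)$n_total_ratio, c(2.0, 1.0))
    expect_error(computeNTotalRatio(m, 0), "positive")
    # globally uniform channel: every cell's ratio is 1
    img <- array(20, c(60, 60, 4))
    img[, , 4] <- 55
    expect_equal(cargoFieldMean(img), 55)
    u <- computeNTotalRatio(data.frame(cargo_nuc_mean = rep(55, 3)),
                            cargoFieldMean(img))
    expect_equal(u$n_total_ratio, rep(1.0, 3))
    # scale equivariance
    expect_equal(computeNTotalRatio(m * 2, 80)$n_total_ratio,
                 computeNTotalRatio(m, 40)$n_total_ratio)
})

test_that("clustered-mode records carry N/total and never N/C", {
    cells <- data.frame(cell_id = 1:30, condition = "wt",
                        yfp_nuc_mean = rlnorm(30, log(200), 0.3),
                        cargo_nuc_mean = rlnorm(30, log(60), 0.2))
    out <- suppressWarnings(assayCondition(
        cells, mode = "clustered", fieldMeans = c(wt = 50)))
    expect_true("n_total_ratio" %in% names(out$records))
    expect_false("nc_ratio" %in% names(out$records))
    expect_equal(out$records$mode[1], "clustered")
    expect_error(assayCondition(cells, mode = "clustered"), "fieldMeans")
})

test_that("the expression control is calibrated and powered", {
    # type-I: identical YFP distributions flagged < 10% of the time
    withr::with_seed(5L, {
        flags <- replicate(200, {
            cells <- data.frame(
                cell_id = 1:200,
                condition = rep(c("wt", "mut"), each = 100),
                yfp_nuc_mean = rlnorm(200, log(200), log(1.8)),
                cargo_nuc_mean = 60, cargo_cyto_mean = 100)
            ctl <- assayCondition(cells, reference = "wt")$expressionControl
            !ctl$comparable[ctl$condition == "mut"]
        })
    })
    expect_lt(mean(flags), 0.10)
    # power: doubled median is flagged non-comparable
    withr::with_seed(6L, {
        cells <- data.frame(
            cell_id = 1:200,
            condition = rep(c("wt", "hi"), each = 100),
            yfp_nuc_mean = c(rlnorm(100, log(200), log(1.8)),
                             rlnorm(100, log(400), log(1.8))),
            cargo_nuc_mean = 60, cargo_cyto_mean = 100)
    })
    ctl <- assayCondition(cells, reference = "wt")$expressionControl
    expect_false(ctl$comparable[ctl$condition == "hi"])
    expect_true(ctl$comparable[ctl$condition == "wt"])
})

test_that("export and localization agree per cell on the same scene", {
    p <- SceneParams(nCells = 20L, imageSize = c(320L, 320L), seed = 13L)
    sc <- simulateScene(p)
    res <- measureScene(sc)
    rec <- computeNCRatio(res$cells)
    # join consistency: same cells, same YFP levels, one record per cell
    expect_identical(rec$cell_id, res$cells$cell_id)
    expect_identical(rec$yfp_nuc_mean, res$cells$yfp_nuc_mean)
})

test_that("condition means order with simulated export activity", {
    # stronger export -> lower N/C; ordering must be recovered
    mkCond <- function(cond, med, seed) {
        p <- SceneParams(nCells = 40L, imageSize = c(340L, 340L),
                         cargoNCRatio = c(med, 1.35), seed = seed)
        res <- measureScene(simulateScene(p), yfpWindow = c(60, Inf))
        cells <- computeNCRatio(res$cells)
        data.frame(condition = cond, nc = cells$nc_ratio)
    }
    recs <- rbind(mkCond("strong", 0.4, 31L), mkCond("mid", 0.8, 32L),
                  mkCond("weak", 1.6, 33L))
    means <- tapply(recs$nc, recs$condition, mean, na.rm = TRUE)
    expect_true(means[["strong"]] < means[["mid"]])
    expect_true(means[["mid"]] < means[["weak"]])
})
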