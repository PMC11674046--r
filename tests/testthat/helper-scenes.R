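# shared fixtures: all scenes are generated in code, nothing on disk

noiseless <- function(...) SceneParams(noise = c(Inf, 0), ...)

# hand-built single-cell (or few-cell) ground-truth spec rows, matching the
# sampleCellPopulation schema
makeSpec <- function(cy, cx, nucR = 10, cellR = 16, transfected = TRUE,
                     yfp = 100, positive = TRUE, ratio = 2,
                     cargoNuc = 50, cargoCyto = 100,
                     foci = cbind(fy = cy, fx = cx, radius = 2.5),
                     id = 1L) {
    d <- data.frame(cell_id = id, cy = cy, cx = cx,
                    nuc_ry = nucR, nuc_rx = nucR,
                    cell_ry = cellR, cell_rx = cellR,
                    transfected = transfected, yfp_true = yfp,
                    positive = positive, true_ratio = ratio,
                    cargo_nuc_true = cargoNuc, cargo_cyto_true = cargoCyto,
                    n_foci = if (length(foci)) nrow(foci) else 0L)
    d$foci <- list(foci)
    d
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
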