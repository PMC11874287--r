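test_that("generated masks hit the stromal fraction and are seed-stable", {
  m <- generate_mask(1000, 1000, 0.3, seed = 1)
  frac <- mean(m$labels == 2L)
  expect_gte(frac, 0.28); expect_lte(frac, 0.32)

  m2 <- generate_mask(1000, 1000, 0.3, seed = 1)
  expect_identical(m$labels, m2$labels)
  m3 <- generate_mask(1000, 1000, 0.3, seed = 2)
  expect_false(identical(m$labels, m3$labels))

  expect_true(all(generate_mask(200, 200, 0, seed = 1)$labels == 1L))
  expect_true(all(generate_mask(200, 200, 1, seed = 1)$labels == 2L))

  # other fractions, tighter than the +/-0.02 contract
  for (f in c(0.1, 0.5, 0.8)) {
    mf <- generate_mask(500, 500, f, seed = 3)
    expect_lt(abs(mean(mf$labels == 2L) - f), 0.02)
  }
})

test_that("realised cell counts follow the scenario intensities", {
  m <- generate_mask(1000, 1000, 0, seed = 5, roi_id = "R1")
  sc <- scenario("custom",
                 intensities = data.frame(cell_type = "CD8 T-cell",
                                          compartment = "parenchyma",
                                          intensity = 300),
                 pfs_median = 6)
  cells <- generate_cells(m, sc, seed = 7, roi_id = "R1")
  n <- sum(cells$cell_type == "CD8 T-cell")
  expect_lt(abs(n - 300), 3 * sqrt(300))  # 99.7% Poisson envelope
  expect_identical(n, 339L)               # fixed-seed regression value

  # zero intensity: no cells of that type
  expect_false("NK" %in% cells$cell_type)

  # positions respect their compartment
  m2 <- generate_mask(600, 600, 0.5, seed = 8, roi_id = "R2")
  sc2 <- scenario("custom",
                  intensities = data.frame(cell_type = "CD8 T-cell",
                                           compartment = "stroma",
                                           intensity = 400),
                  pfs_median = 6)
  cells2 <- generate_cells(m2, sc2, seed = 9, roi_id = "R2")
  expect_true(all(cells2$compartment == "stroma"))
})

test_that("realised densities are unbiased estimates of the intensity", {
  m <- generate_mask(400, 400, 0.4, seed = 11, roi_id = "R1")
  a <- compartment_areas(m)
  sc <- scenario("compartmentalised")
  lambda_p <- 80; lambda_s <- 600
  counts_p <- counts_s <- numeric(60)
  for (r in 1:60) {
    cells <- generate_cells(m, sc, seed = 1000 + r, roi_id = "R1")
    cd8 <- cells[cells$cell_type == "CD8 T-cell", ]
    counts_p[r] <- sum(cd8$compartment == "parenchyma")
    counts_s[r] <- sum(cd8$compartment == "stroma")
  }
  dens_p <- counts_p / unname(a["parenchyma"])
  dens_s <- counts_s / unname(a["stroma"])
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(dens_p) - lambda_p), 2 * se(dens_p))
  expect_lt(abs(mean(dens_s) - lambda_s), 2 * se(dens_s))
})

test_that("planted co-clustering raises the interaction score", {
  cc <- data.frame(type_a = "CD8 T-cell", type_b = "APC",
                   radius_um = 10, offspring = 2)
  base_int <- data.frame(cell_type = c("CD8 T-cell", "APC"),
                         compartment = "parenchyma",
                         intensity = c(150, 150))
  m <- generate_mask(500, 500, 0, seed = 21, roi_id = "R1")
  higher <- 0
  n_rep <- 25
  for (r in 1:n_rep) {
    on <- scenario("custom", intensities = base_int, co_cluster = cc,
                   pfs_median = 6)
    off <- scenario("custom", intensities = base_int, pfs_median = 6)
    score <- sapply(list(on, off), function(s) {
      cells <- generate_cells(m, s, seed = 3000 + r, roi_id = "R1")
      tbl <- cell_table(cells,
                        roi_meta = data.frame(roi_id = "R1",
                                              patient_id = "P1",
                                              roi_kind = "tumour",
                                              roi_area_um2 = 2.5e5,
                                              pixel_size_um = 1),
                        type_vocabulary = default_type_vocabulary(),
                        immune_types = default_immune_types())
      g <- build_expansion_graph(cells, roi_id = "R1")
      interaction_score(g, tbl, "CD8 T-cell", "APC")
    })
    if (!anyNA(score) && score[1] > score[2]) higher <- higher + 1
  }
  expect_gte(higher / n_rep, 0.95)
})

test_that("cohorts are deterministic, labelled, and survival-calibrated", {
  co <- generate_cohort(n_patients = c(depleted = 3, enriched = 3),
                        rois_per_patient = 2, heterogeneity_rate = 0,
                        width = 300, height = 300, seed = 31)
  co2 <- generate_cohort(n_patients = c(depleted = 3, enriched = 3),
                         rois_per_patient = 2, heterogeneity_rate = 0,
                         width = 300, height = 300, seed = 31)
  expect_identical(co$cells$cells, co2$cells$cells)
  expect_identical(co$clinical, co2$clinical)

  # heterogeneity 0: all of a patient's ROIs share the truth label
  per_pat <- split(co$truth$scenario, co$truth$patient_id)
  expect_true(all(vapply(per_pat, function(s) length(unique(s)) == 1,
                         logical(1))))

  # heterogeneity 1 with 2 ROIs: every patient has two distinct labels
  ch <- generate_cohort(n_patients = c(depleted = 4, enriched = 4),
                        rois_per_patient = 2, heterogeneity_rate = 1,
                        width = 300, height = 300, seed = 33)
  per_pat <- split(ch$truth$scenario, ch$truth$patient_id)
  expect_true(all(vapply(per_pat, function(s) length(unique(s)) == 2,
                         logical(1))))

  # exponential PFS: empirical median within 15% of the target at n=200
  big <- generate_cohort(n_patients = c(enriched = 200),
                         rois_per_patient = 1, heterogeneity_rate = 0,
                         width = 100, height = 100, seed = 35,
                         scenarios = list(enriched = scenario("enriched",
                                                              censor_rate = 0)))
  expect_lt(abs(median(big$clinical$time) - 8.3) / 8.3, 0.15)
  expect_true(all(big$clinical$event))

  # censoring rate honoured on average
  cens <- generate_cohort(n_patients = c(depleted = 200),
                          rois_per_patient = 1, heterogeneity_rate = 0,
                          width = 100, height = 100, seed = 37)
  expect_lt(abs(mean(!cens$clinical$event) - 0.2), 0.08)
})

test_that("a cohort round-trips losslessly through the text formats", {
  co <- generate_cohort(n_patients = c(enriched = 2), rois_per_patient = 1,
                        heterogeneity_rate = 0, width = 200, height = 200,
                        seed = 41)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  cells <- read_cell_table(file.path(dir, "cells.csv"),
                           roi_meta = file.path(dir, "roi_meta.csv"),
                           type_vocabulary = default_type_vocabulary(),
                           immune_types = default_immune_types())
  expect_identical(cells$cells[, names(co$cells$cells)], co$cells$cells)
  for (rid in names(co$masks)) {
    back <- read_region_mask(file.path(dir, "masks",
                                       paste0(rid, ".tiff")),
                             co$masks[[rid]]$semantics, roi_id = rid)
    expect_identical(back$labels, co$masks[[rid]]$labels)
  }
})
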