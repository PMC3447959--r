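planted_peak_tracks <- function(seed = 1, n = 6000, retention = 1,
                                n_blocks = 12) {
  set.seed(seed)
  noise_sd <- 0.3
  v <- rnorm(n, 0, noise_sd)
  starts <- round(seq(200, n - 300, length.out = n_blocks))
  for (b in starts) v[b:(b + 19)] <- v[b:(b + 19)] + 3 * noise_sd
  mut <- rnorm(n, 0, noise_sd)
  for (b in starts) {
    mut[b:(b + 19)] <- mut[b:(b + 19)] + retention * 3 * noise_sd
  }
  list(
    wt = grid_track(v), mut = grid_track(mut),
    block_pos = starts
  )
}

test_that("peak retention is near 0 for identical tracks, near 1 for loss", {
  tr <- planted_peak_tracks(seed = 21, retention = 1)
  wt_sm <- smooth_track(tr$wt)
  wt_regions <- call_enriched_regions(wt_sm, fdr = 1e-3)
  expect_gt(nrow(wt_regions), 5)
  same <- peak_retention(wt_regions, wt_sm)
  expect_lt(same$fraction_reduced, 0.1)
  lost <- planted_peak_tracks(seed = 21, retention = 0)
  gone <- peak_retention(wt_regions, smooth_track(lost$mut))
  expect_gt(gone$fraction_reduced, 0.95)
  expect_error(peak_retention(wt_regions[0, ], wt_sm), "empty")
})

test_that("strongly retained peaks at 5% residual signal count as reduced", {
  tr <- planted_peak_tracks(seed = 22, retention = 0.05)
  wt_regions <- call_enriched_regions(smooth_track(tr$wt), fdr = 1e-3)
  pr <- peak_retention(wt_regions, smooth_track(tr$mut))
  expect_gte(pr$fraction_reduced, 0.95)
})

test_that("change summary is zero for identical conditions", {
  cfg <- small_cfg(seed = 61)
  ann <- generate_annotation(cfg)
  tr <- generate_tracks(cfg, ann, marks = "HP1a", conditions = "WT")
  active <- ann$genes$expression > (10^0.6 - 1)
  sm <- smooth_track(tr[["HP1a.WT"]])
  cs <- enrichment_change_summary(sm, sm, ann$genes, ann$domains,
    active = active
  )
  expect_true(all(abs(cs$level$percent_change) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(cs$extent$percent_extent_change) < 1e-9,
    na.rm = TRUE
  ))
})

test_that("planted retention appears in the level change, domain-specific", {
  cfg <- small_cfg(seed = 67)
  ann <- generate_annotation(cfg)
  tr <- generate_tracks(cfg, ann,
    marks = "H3K9me3",
    conditions = c("WT", "hp1a_mut")
  )
  active <- ann$genes$expression > (10^0.6 - 1)
  sc <- scale_mutant_to_wt(tr[["H3K9me3.WT"]], tr[["H3K9me3.hp1a_mut"]])
  cs <- enrichment_change_summary(
    smooth_track(tr[["H3K9me3.WT"]]),
    smooth_track(sc$track), ann$genes, ann$domains,
    active = active
  )
  lv <- cs$level
  chr4_body <- lv$percent_change[lv$domain == "chr4" &
    lv$class == "active_body"]
  peri_body <- lv$percent_change[lv$domain == "pericentric_heterochromatin" &
    lv$class == "active_body"]
  # chr4 retention 0.333 -> strong body loss; pericentric retention is
  # 0.5 there, so the chr4 loss must dominate (domain specificity)
  expect_gt(chr4_body, 50)
  expect_gt(chr4_body, peri_body + 10)
})

test_that("mutant comparisons are invariant to raw mutant rescaling", {
  tr <- planted_peak_tracks(seed = 23, retention = 0.6)
  rescaled_input <- tr$mut
  rescaled_input$probes$m <- rescaled_input$probes$m * 3.7
  sc1 <- scale_mutant_to_wt(tr$wt, tr$mut)
  sc2 <- scale_mutant_to_wt(tr$wt, rescaled_input)
  expect_equal(sc1$track$probes$m, sc2$track$probes$m, tolerance = 1e-9)
})

test_that("distances to repeats are exact on constructed fixtures", {
  repeats <- data.frame(start = c(100, 1000), end = c(200, 1200))
  peaks <- data.frame(start = c(120, 300, 700), end = c(150, 400, 900))
  d <- hetdomain:::nearest_repeat_distance(
    peaks$start, peaks$end,
    repeats$start, repeats$end
  )
  expect_equal(d, c(0, 100, 100))
})

test_that("repeat-adjacent peaks give small p; uniform peaks do not", {
  set.seed(24)
  dom <- c(0, 300000)
  # ~30% repeat density
  r_start <- seq(0, 299000, 1000)
  r_start <- r_start[runif(length(r_start)) < 0.45]
  repeats <- data.frame(start = r_start, end = r_start + 300)
  # peaks planted within 40 bp of repeats
  pick <- sample(nrow(repeats), 30)
  gap <- sample(0:40, 30, replace = TRUE)
  peaks <- data.frame(
    start = repeats$end[pick] + gap,
    end = repeats$end[pick] + gap + 150
  )
  out <- distance_to_repeat_test(peaks, repeats, dom,
    n_perm = 1000,
    seed = 2
  )
  expect_lt(out$p_value, 0.01)
  expect_lte(out$observed_median, 40)
  # uniformly placed peaks: p not extreme, observed near expected
  u_start <- sort(sample(seq(0, 299000, 50), 30))
  upeaks <- data.frame(start = u_start, end = u_start + 150)
  out2 <- distance_to_repeat_test(upeaks, repeats, dom,
    n_perm = 500,
    seed = 3
  )
  expect_gt(out2$p_value, 0.05)
  expect_error(
    distance_to_repeat_test(peaks, repeats[0, ], dom),
    "no repeats"
  )
})

test_that("expression contrast handles identity, symmetry and planting", {
  ids <- sprintf("g%03d", 1:40)
  wt <- expression_table(ids, rlnorm(40, 2, 1), unit = "FPKM")
  same <- expression_change(wt, wt, domain = setNames(
    rep("chr4", 40),
    ids
  ))
  expect_true(all(same$genes$lfc == 0))
  expect_equal(same$groups$p_value, 1)
  # swap symmetry: fold changes negate, p unchanged
  set.seed(25)
  mut <- expression_table(ids, wt$value * exp(rnorm(40, -0.3, 0.2)),
    unit = "FPKM"
  )
  ab <- expression_change(wt, mut, domain = setNames(rep("chr4", 40), ids))
  ba <- expression_change(mut, wt, domain = setNames(rep("chr4", 40), ids))
  expect_equal(ab$genes$lfc, -ba$genes$lfc)
  expect_equal(ab$groups$p_value, ba$groups$p_value)
  # single gene halved
  one <- expression_change(
    expression_table("g", 10, unit = "FPKM"),
    expression_table("g", 5, unit = "FPKM")
  )
  expect_equal(one$genes$lfc, log2(6 / 11))
  # planted 80% down-scaling recovered with a small chr4 p-value
  cfg <- small_cfg(seed = 71)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(cfg, ann)
  dom <- setNames(
    assign_domain(ann$genes, ann$domains),
    ann$genes$gene_id
  )
  ec <- expression_change(ex$wt, ex$mut, domain = dom)
  chr4 <- ec$groups[ec$groups$group == "chr4", ]
  expect_lt(chr4$p_value, 0.01)
  expect_lt(abs(chr4$n_down / chr4$n - 0.8), 0.2)
  eu <- ec$groups[ec$groups$group == "euchromatin", ]
  expect_gt(eu$p_value, 0.01) # control arm stays null
})

test_that("PI-change correlations recover planted structure", {
  set.seed(26)
  n <- 80
  ratios <- setNames(2^rnorm(n, 0.5, 1), sprintf("g%03d", 1:n))
  x <- log2(ratios)
  marks <- cbind(
    self = x,
    corr04 = 0.4 * scale(x)[, 1] + sqrt(1 - 0.16) * rnorm(n),
    indep = rnorm(n)
  )
  rownames(marks) <- names(ratios)
  out <- pi_change_correlation(ratios, marks)
  expect_equal(out$r[out$mark == "self"], 1)
  expect_lt(abs(out$r[out$mark == "corr04"] - 0.4), 0.2)
  expect_lt(abs(out$r[out$mark == "indep"]), 0.3)
  expect_error(pi_change_correlation(ratios[1:5], marks[1:5, ]), ">= 10")
})
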