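test_that("moving-average smoothing preserves constants and local means", {
  const <- grid_track(rep(1.5, 20))
  expect_equal(smooth_track(const)$probes$m, rep(1.5, 20))
  single <- grid_track(2.7)
  expect_equal(smooth_track(single)$probes$m, 2.7)
  three <- probe_track("c", c(0, 100, 200), c(0, 3, 6))
  sm <- smooth_track(three, window_bp = 250)
  expect_equal(sm$probes$m[2], 3) # window spans exactly the 3 probes
  empty <- probe_track(character(0), numeric(0), numeric(0))
  expect_equal(nrow(smooth_track(empty)$probes), 0)
})

test_that("smoothing is shift-equivariant", {
  set.seed(1)
  v <- rnorm(60)
  a <- smooth_track(grid_track(v), 500)$probes$m
  shifted <- probe_track("c", seq(50, by = 100, length.out = 60) + 12345, v)
  b <- smooth_track(shifted, 500)$probes$m
  expect_equal(a, b)
})

test_that("region caller is quiet on pure noise and degenerate input", {
  set.seed(101)
  noise <- grid_track(rnorm(10000, 0, 0.3))
  reg <- call_enriched_regions(smooth_track(noise), fdr = 1e-3)
  expect_lte(nrow(reg), 1)
  const <- grid_track(rep(2, 100))
  expect_equal(nrow(call_enriched_regions(const)), 0)
  expect_error(call_enriched_regions(grid_track(rnorm(5))), "few probes")
})

test_that("region caller recovers planted blocks with low false calls", {
  set.seed(202)
  n <- 10000
  v <- rnorm(n, 0, 0.3)
  # 8 blocks of 2 kb (20 probes) at +3 sigma, well separated
  block_starts <- seq(500, 9500, length.out = 8)
  truth <- rep(FALSE, n)
  for (b in block_starts) {
    idx <- seq(b, b + 19)
    v[idx] <- v[idx] + 3 * 0.3
    truth[idx] <- TRUE
  }
  track <- grid_track(v)
  reg <- call_enriched_regions(smooth_track(track), fdr = 1e-3)
  hit <- logical(length(block_starts))
  for (k in seq_along(block_starts)) {
    s <- track$probes$pos[block_starts[k]]
    e <- track$probes$pos[block_starts[k] + 19]
    hit[k] <- any(reg$start <= e & reg$end >= s)
  }
  expect_gte(mean(hit), 0.95)
  called <- rep(FALSE, n)
  for (i in seq_len(nrow(reg))) {
    called <- called | (track$probes$pos >= reg$start[i] &
      track$probes$pos < reg$end[i])
  }
  expect_lte(mean(called & !truth), 0.01)
})

test_that("replicate consistency applies the two published rules", {
  mk <- function(starts, scores) {
    region_set("c", starts, starts + 500, scores)
  }
  starts <- seq(0, 198000, 2000)
  a <- mk(starts, rnorm(100) + 3)
  expect_true(replicate_consistency(a, a)$pass)
  expect_equal(replicate_consistency(a, a)$overlap, 1)
  b <- mk(starts + 700, rnorm(100) + 3) # falls in the gaps of a
  rc <- replicate_consistency(a, b)
  expect_false(rc$pass)
  expect_equal(rc$overlap, 0)
  # 76 of 100 targets shared -> passes by the 75% rule
  shared <- mk(starts, rep(3, 100))
  shifted <- shared
  shifted$start[77:100] <- shifted$start[77:100] + 700
  shifted$end[77:100] <- shifted$end[77:100] + 700
  rc2 <- replicate_consistency(shared, shifted)
  expect_equal(rc2$overlap, 0.76)
  expect_true(rc2$pass)
  empty <- region_set(character(0), numeric(0), numeric(0), numeric(0))
  expect_false(replicate_consistency(a, empty)$pass)
})

test_that("binning averages probes per 500 bp bin", {
  t1 <- probe_track("c", c(250, 750), c(1, 2), mark = "m1")
  bm <- bin_enrichment(list(t1), width = 500)
  expect_equal(unname(bm$m[, 1]), c(1, 2))
  t2 <- probe_track("c", c(100, 400, 600), c(1, 3, 5), mark = "m2")
  bm2 <- bin_enrichment(list(t2), width = 500)
  expect_equal(unname(bm2$m[, 1]), c(2, 5)) # mean of 1,3 then 5
  expect_error(bin_enrichment(list(t1), width = 0), "width")
})

test_that("mark correlations have unit diagonal and exact extremes", {
  set.seed(3)
  v <- rnorm(100)
  doms <- domain_partition("chrT", 0, 100 * 100, "chr4")
  t1 <- grid_track(v, mark = "a")
  t2 <- grid_track(-v, mark = "b")
  t3 <- grid_track(v + rnorm(100, 0, 0.2), mark = "c")
  cc <- mark_correlation(bin_enrichment(list(t1, t2, t3), 500), "chr4", doms)
  expect_equal(diag(cc), c(a = 1, b = 1, c = 1))
  expect_equal(cc["a", "b"], -1)
  expect_gt(cc["a", "c"], 0.9)
  expect_true(isSymmetric(cc))
})

test_that("planted gene-body marks correlate positively on chr4", {
  cfg <- small_cfg(seed = 31)
  ann <- generate_annotation(cfg)
  tr <- generate_tracks(cfg, ann,
    marks = c("HP1a", "H3K9me3", "POF"),
    conditions = "WT"
  )
  bm <- bin_enrichment(setNames(tr, c("HP1a", "H3K9me3", "POF")), 500)
  cc <- mark_correlation(bm, "chr4", ann$domains)
  expect_gt(cc["HP1a", "H3K9me3"], 0)
  expect_gt(cc["HP1a", "POF"], 0)
  expect_gt(cc["H3K9me3", "POF"], 0)
})

test_that("MAD scaling factor inverts multiplicative changes exactly", {
  set.seed(4)
  wt <- grid_track(rnorm(500))
  ident <- scale_mutant_to_wt(wt, wt)
  expect_identical(ident$factor, 1)
  # pure scaling is inverted bit-exactly
  pure <- wt
  pure$probes$m <- 2 * wt$probes$m
  expect_identical(scale_mutant_to_wt(wt, pure)$factor, 0.5)
  # an additive offset cancels in the lagged differences (machine precision)
  doubled <- wt
  doubled$probes$m <- 7 + 2 * wt$probes$m
  sc <- scale_mutant_to_wt(wt, doubled)
  expect_equal(sc$factor, 0.5, tolerance = 1e-12)
  shifted_wt <- wt
  shifted_wt$probes$m <- wt$probes$m - 11
  expect_equal(scale_mutant_to_wt(shifted_wt, doubled)$factor, 0.5,
    tolerance = 1e-12
  )
})

test_that("MAD scaling recovers a noisy halving within 5%", {
  set.seed(5)
  wt <- grid_track(rnorm(5000))
  mut <- wt
  mut$probes$m <- 0.5 * wt$probes$m + rnorm(5000, 0, 0.01)
  sc <- scale_mutant_to_wt(wt, mut)
  expect_lt(abs(sc$factor - 2) / 2, 0.05)
})

test_that("degenerate or mismatched tracks are scaling errors", {
  wt <- grid_track(rnorm(50))
  const <- grid_track(rep(1, 50))
  expect_error(scale_mutant_to_wt(wt, const), "degenerate")
  other <- grid_track(rnorm(50), spacing = 50)
  expect_error(scale_mutant_to_wt(wt, other), "probe grid")
})

test_that("quantile normalization matches its defining identities", {
  t1 <- probe_track("c", c(0, 100, 200), c(1, 2, 3), mark = "a")
  t2 <- probe_track("c", c(0, 100, 200), c(4, 5, 6), mark = "b")
  qn <- quantile_normalize(list(t1, t2))
  expect_equal(qn[[1]]$probes$m, c(2.5, 3.5, 4.5))
  expect_equal(qn[[2]]$probes$m, c(2.5, 3.5, 4.5))
  # identical inputs unchanged; sorted outputs identical; idempotent
  same <- quantile_normalize(list(t1, t1))
  expect_equal(same[[1]]$probes$m, t1$probes$m)
  set.seed(6)
  r1 <- grid_track(rnorm(200), mark = "a")
  r2 <- grid_track(rexp(200), mark = "b")
  out <- quantile_normalize(list(r1, r2))
  expect_identical(
    sort(out[[1]]$probes$m),
    sort(out[[2]]$probes$m)
  )
  again <- quantile_normalize(out)
  expect_equal(again[[1]]$probes$m, out[[1]]$probes$m)
  expect_error(
    quantile_normalize(list(r1, grid_track(rnorm(10)))),
    "same number"
  )
})
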