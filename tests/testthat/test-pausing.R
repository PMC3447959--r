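make_rd <- function(plus, minus = integer(length(plus)), chrom = "chrT") {
  read_density(setNames(
    list(list(plus = as.integer(plus), minus = as.integer(minus))),
    chrom
  ))
}

test_that("eligibility filter removes short and overlapping genes", {
  g <- gene_models(
    gene_id = c("short", "iso", "ov1", "ov2"),
    chrom = "chrT",
    start = c(0, 2000, 10000, 11999),
    end = c(499, 4000, 12000, 14000),
    strand = c("+", "+", "+", "-")
  )
  kept <- filter_genes_for_pi(g)
  expect_equal(kept$gene_id, "iso") # 499 bp gone; 1 bp overlap removes both
  g2 <- gene_models("lonely", "chrT", 0, 2000)
  expect_equal(nrow(filter_genes_for_pi(g2)), 1)
})

test_that("run-on PI matches its definition on constructed densities", {
  # uniform density -> PI = 1
  g <- gene_models("u", "chrT", 100, 2600)
  rd <- make_rd(c(rep(0L, 100), rep(4L, 2500), rep(0L, 400)))
  expect_equal(pi_groseq(rd, g[1, ]), 1)
  # L = 2500: head 500 bp holds 100 reads, next 500 bp holds 10 -> PI = 10
  v <- integer(3000)
  v[101:600] <- rep(c(1L, 0L), c(100, 400))[order(runif(500))]
  v[101:600] <- 0L
  v[101:200] <- 1L # 100 reads in first 500 bp
  v[601:1100] <- 0L
  v[601:610] <- 1L # 10 reads in next 500 bp (25% of remaining 2000)
  rd2 <- make_rd(v)
  expect_equal(pi_groseq(rd2, g[1, ]), 10)
  # all reads 5' -> infinite PI; no reads at all -> undefined
  v3 <- integer(3000)
  v3[101:600] <- 2L
  expect_equal(pi_groseq(make_rd(v3), g[1, ]), Inf)
  expect_true(is.na(pi_groseq(make_rd(integer(3000)), g[1, ])))
})

test_that("run-on PI equals the brute-force per-base oracle exactly", {
  cfg <- small_cfg(seed = 47)
  ann <- generate_annotation(cfg)
  rd <- generate_readdensity(cfg, ann)
  genes <- filter_genes_for_pi(ann$genes)
  for (i in seq_len(nrow(genes))) {
    got <- pi_groseq(rd, genes[i, ])
    want <- pi_groseq_oracle(rd, genes[i, ])
    if (is.na(want)) {
      expect_true(is.na(got))
    } else if (is.infinite(want)) {
      expect_equal(got, want)
    } else {
      expect_lt(abs(got - want) / max(want, 1e-300), 1e-12)
    }
  }
})

test_that("run-on PI is invariant to uniform scaling of the density", {
  g <- gene_models("u", "chrT", 0, 4000)
  set.seed(9)
  v <- rpois(4000, 0.5)
  pi1 <- pi_groseq(make_rd(v), g[1, ])
  pi3 <- pi_groseq(make_rd(v * 7L), g[1, ])
  expect_equal(pi1, pi3)
})

test_that("minus-strand genes read the minus-strand density 5' to 3'", {
  g <- gene_models("m", "chrT", 1000, 3500, strand = "-")
  minus <- integer(5000)
  minus[3001:3500] <- 5L # last 500 bp in genomic coords = first 500 from TSS
  rd <- make_rd(integer(5000), minus)
  expect_equal(pi_groseq(rd, g[1, ]), Inf)
  minus[1001:3000] <- 1L
  expect_equal(pi_groseq(make_rd(integer(5000), minus), g[1, ]), 5)
})

test_that("ChIP PI follows the max/median definition on the linear scale", {
  # constant track -> PI = 1
  g <- gene_models("c", "chrT", 2000, 8000)
  const <- grid_track(rep(1.5, 100))
  expect_equal(pi_chip(const, g[1, ]), 1)
  # TSS max M=2 (linear 4), body median M=0 (linear 1) -> PI = 4
  pos <- seq(50, 9950, 100)
  m <- rep(0, length(pos))
  m[pos == 1950] <- 2
  tr <- probe_track("chrT", pos, m)
  expect_equal(pi_chip(tr, g[1, ]), 4)
  expect_equal(pi_chip(tr, g[1, ], scale = "log"), Inf) # 2 / 0 on log scale
  # body median above the TSS max -> PI < 1
  m2 <- rep(2, length(pos))
  m2[abs(pos - 2000) <= 300] <- 0.5
  expect_lt(pi_chip(probe_track("chrT", pos, m2), g[1, ]), 1)
  # insufficient probes -> NA
  sparse <- probe_track("chrT", c(1900, 5000), c(1, 1))
  expect_true(is.na(pi_chip(sparse, g[1, ])))
})

test_that("paused fractions use associated genes and are monotone", {
  res <- data.frame(
    gene_id = sprintf("g%02d", 1:12),
    pi = c(1, 2, 5, 11, 20, NA, 0.5, 3, 12, NA, 1, 9),
    method = "groseq", paused = FALSE, threshold = 10,
    domain = rep(c("euchromatin", "chr4"), each = 6),
    stringsAsFactors = FALSE
  )
  class(res) <- c("pausing_result", "data.frame")
  pf <- paused_fraction(res, threshold = 10)
  expect_equal(pf$n_associated, c(5, 5))
  expect_equal(pf$fraction[pf$domain == "euchromatin"], 2 / 5)
  expect_equal(pf$fraction[pf$domain == "chr4"], 1 / 5)
  sweep <- paused_fraction_sweep(res, thresholds = c(0, 2, 5, 10, 50))
  for (d in unique(sweep$domain)) {
    expect_true(all(diff(sweep$fraction[sweep$domain == d]) <= 0))
  }
  expect_equal(sweep$fraction[sweep$threshold == 0], c(1, 1))
})

test_that("permutation p-value follows the add-one construction", {
  # extreme separation: observed always exceeds every permuted value
  res <- data.frame(
    gene_id = sprintf("g%03d", 1:60),
    pi = c(rep(100, 15), rep(1, 15), rep(1, 30)),
    method = "groseq", paused = FALSE, threshold = 10,
    domain = rep(c("euchromatin", "chr4"), each = 30),
    stringsAsFactors = FALSE
  )
  class(res) <- c("pausing_result", "data.frame")
  out <- pausing_domain_test(res, "euchromatin", "chr4",
    n_perm = 100,
    seed = 1
  )
  expect_equal(out$observed, 0.5)
  expect_gte(out$p_value, 1 / 101)
  expect_lt(out$p_value, 0.05)
  expect_error(
    pausing_domain_test(res, "euchromatin", "chr4", n_perm = 50),
    "n_perm"
  )
})

test_that("mutant PI ratios exclude undefined pairs and count increases", {
  mk <- function(pi) {
    r <- data.frame(
      gene_id = sprintf("g%02d", seq_along(pi)), pi = pi,
      method = "chip", paused = FALSE, threshold = 4,
      domain = "chr4", stringsAsFactors = FALSE
    )
    class(r) <- c("pausing_result", "data.frame")
    r
  }
  wt <- mk(c(1, 2, 4, Inf, NA, 3))
  mut <- mk(c(2, 1, 4, 5, 2, NA))
  out <- pi_ratio_mutant(wt, mut)
  expect_equal(out$n_total, 3) # Inf and NA pairs dropped
  expect_equal(out$n_excluded, 3)
  expect_equal(out$n_increase, 1)
  same <- pi_ratio_mutant(wt, wt)
  expect_true(all(same$ratios$ratio == 1))
  expect_equal(same$n_increase, 0)
})

test_that("TSS peak offsets are strand-oriented with deterministic ties", {
  pos <- seq(50, 19950, 100)
  g <- gene_models("p", "chrT", 9000, 12000)
  peak <- exp(-((pos - 9000)^2) / (2 * 150^2))
  # the grid has no probe exactly at the TSS: probes at -50/+50 tie and
  # the tie rule picks the smaller signed offset
  expect_equal(
    tss_peak_position(probe_track("chrT", pos, peak), g[1, ]),
    -50
  )
  # planted asymmetric max downstream
  peak2 <- exp(-((pos - 9250)^2) / (2 * 150^2))
  expect_equal(
    tss_peak_position(probe_track("chrT", pos, peak2), g[1, ]),
    250
  )
  # minus-strand gene: downstream means decreasing coordinate
  gm <- gene_models("m", "chrT", 6000, 9001, strand = "-")
  peak3 <- exp(-((pos - (9000 - 250))^2) / (2 * 150^2))
  expect_equal(
    tss_peak_position(probe_track("chrT", pos, peak3), gm[1, ]),
    250
  )
  # flat window -> smallest signed offset by the tie rule
  flat <- probe_track("chrT", pos, rep(1, length(pos)))
  expect_equal(tss_peak_position(flat, g[1, ]), -450)
  sparse <- probe_track("chrT", c(8900, 9100), c(1, 2))
  expect_true(is.na(tss_peak_position(sparse, g[1, ])))
})

test_that("planted mutant peak shift is recovered within probe spacing", {
  cfg <- small_cfg(seed = 53)
  cfg$polii$tss_shift[["hp1a_mut"]] <- 70
  ann <- generate_annotation(cfg)
  tr <- generate_tracks(cfg, ann,
    marks = "PolII",
    conditions = c("WT", "hp1a_mut")
  )
  active <- ann$genes$expression > (10^0.6 - 1)
  dom <- assign_domain(ann$genes, ann$domains)
  chr4_active <- ann$genes[active & dom == "chr4", ]
  shift <- tss_peak_shift(
    smooth_track(tr[["PolII.WT"]], 300),
    smooth_track(tr[["PolII.hp1a_mut"]], 300), chr4_active
  )
  expect_lt(abs(shift - 70), cfg$probe_spacing)
})

test_that("method overlap reduces transcripts by max PI and is calibrated", {
  mk <- function(ids, pi) {
    r <- data.frame(
      gene_id = ids, pi = pi, method = "x", paused = FALSE,
      threshold = 10, domain = "d", stringsAsFactors = FALSE
    )
    class(r) <- c("pausing_result", "data.frame")
    r
  }
  ids <- sprintf("g%03d", 1:100)
  a <- mk(ids, seq(100, 1, length.out = 100))
  expect_equal(method_overlap(a, a, top_n = c(10, 50))$overlap, c(1, 1))
  b <- mk(ids, seq(1, 100, length.out = 100)) # reversed ranking
  expect_equal(method_overlap(a, b, top_n = 10)$overlap, 0)
  # transcript-level input: gene g001 keeps its maximal PI
  tr <- mk(c("g001", "g001", "g002"), c(5, 50, 10))
  ov <- method_overlap(tr, mk(c("g001", "g002"), c(50, 10)), top_n = 2)
  expect_equal(ov$overlap, 1)
  expect_warning(method_overlap(a, b, top_n = 1000), "capped")
})
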