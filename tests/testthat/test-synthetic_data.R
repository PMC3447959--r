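test_that("generators are fully deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 11)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$repeats, a2$repeats)
  t1 <- generate_tracks(cfg, a1, marks = "HP1a", conditions = "WT")
  t2 <- generate_tracks(cfg, a2, marks = "HP1a", conditions = "WT")
  expect_identical(t1[["HP1a.WT"]]$probes, t2[["HP1a.WT"]]$probes)
  r1 <- generate_readdensity(cfg, a1)
  r2 <- generate_readdensity(cfg, a2)
  expect_identical(r1$counts, r2$counts)
  s1 <- generate_sequences(cfg, a1)
  s2 <- generate_sequences(cfg, a2)
  expect_identical(as.character(s1), as.character(s2))
  e1 <- generate_expression(cfg, a1)
  e2 <- generate_expression(cfg, a2)
  expect_identical(e1$mut$value, e2$mut$value)
})

test_that("annotation matches the configured counts and size structure", {
  cfg <- sim_config(seed = 3) # full-size study conditions
  ann <- generate_annotation(cfg)
  dom <- assign_domain(ann$genes, ann$domains)
  expect_equal(sum(dom == "chr4"), 80)
  expect_equal(sum(dom == "euchromatin"), 2000)
  g4 <- ann$genes[dom == "chr4", ]
  ge <- ann$genes[dom == "euchromatin", ]
  # medians drawn around the configured values (log-normal sampling noise)
  expect_lt(abs(median(g4$end - g4$start) - 8001) / 8001, 0.25)
  expect_lt(abs(median(ge$end - ge$start) - 1907) / 1907, 0.15)
  ex4 <- vapply(gene_exons(ann$genes)[g4$gene_id], nrow, numeric(1))
  exe <- vapply(gene_exons(ann$genes)[ge$gene_id], nrow, numeric(1))
  expect_lte(abs(median(ex4) - 6), 1)
  expect_lte(abs(median(exe) - 3), 1)
  # chr4 genes larger and more exon-rich than euchromatic ones
  expect_gt(median(g4$end - g4$start), median(ge$end - ge$start))
  expect_gt(median(ex4), median(exe))
  # repeat density within 5 points of the target on chr4
  arm <- ann$domains[ann$domains$label == "chr4", ]
  r4 <- ann$repeats[ann$repeats$chrom == "chr4" &
    ann$repeats$start >= arm$start, ]
  dens <- sum(r4$end - r4$start) / (arm$end - arm$start)
  expect_lt(abs(dens - 0.30), 0.05)
  # genes are non-overlapping within each chromosome
  for (chrom in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("zero repeat density yields an empty repeat set", {
  cfg <- small_cfg(repeat_density = c(
    chr4 = 0, chr4_proximal = 0,
    euchromatin = 0, pericentric_heterochromatin = 0
  ))
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$repeats), 0)
})

test_that("infeasible gene packing raises a config error", {
  cfg <- small_cfg()
  cfg$gene_params$n_genes[cfg$gene_params$domain == "chr4"] <- 2000
  expect_error(generate_annotation(cfg), "infeasible packing")
})

test_that("track class means follow the planted architecture and retention", {
  cfg <- small_cfg(seed = 5)
  ann <- generate_annotation(cfg)
  tracks <- generate_tracks(cfg, ann,
    marks = c("HP1a", "H3K9me2", "H3K9me3"),
    conditions = c("WT", "hp1a_mut")
  )
  thr <- 10^0.6 - 1
  active <- ann$genes$expression > thr
  dom <- assign_domain(ann$genes, ann$domains)
  body_mean <- function(track) {
    sel <- which(dom == "chr4" & active)
    vals <- numeric(0)
    p <- track$probes[track$probes$chrom == "chr4", ]
    for (i in sel) {
      g <- ann$genes[i, ]
      inb <- p$pos >= g$start + 600 & p$pos < g$end - 600 &
        abs(p$pos - g$tss) > 500
      vals <- c(vals, p$m[inb])
    }
    mean(vals)
  }
  wt <- body_mean(tracks[["HP1a.WT"]])
  expect_lt(abs(wt - 2.0), 0.15) # planted body mean 2.0
  # paper-derived retention factors recovered as mutant/WT mean ratios
  r2 <- body_mean(tracks[["H3K9me2.hp1a_mut"]]) /
    body_mean(tracks[["H3K9me2.WT"]])
  r3 <- body_mean(tracks[["H3K9me3.hp1a_mut"]]) /
    body_mean(tracks[["H3K9me3.WT"]])
  expect_lt(abs(r2 - 0.111), 0.1)
  expect_lt(abs(r3 - 0.333), 0.1)
})

test_that("retention 1 leaves the mutant at wildtype level; 0 removes it", {
  cfg <- small_cfg(seed = 9)
  eff <- cfg$mutant_effects
  eff$retention[eff$condition == "hp1a_mut" & eff$mark == "HP1a"] <- 1
  eff <- rbind(eff, data.frame(
    condition = "hp1a_mut", mark = "POF",
    domain = "chr4", feature_class = "all", retention = 0
  ))
  cfg$mutant_effects <- eff
  ann <- generate_annotation(cfg)
  tracks <- generate_tracks(cfg, ann,
    marks = c("HP1a", "POF"),
    conditions = c("WT", "hp1a_mut")
  )
  p_wt <- tracks[["HP1a.WT"]]$probes
  p_mut <- tracks[["HP1a.hp1a_mut"]]$probes
  expect_lt(abs(mean(p_mut$m) - mean(p_wt$m)), 0.02)
  pof_mut <- tracks[["POF.hp1a_mut"]]$probes
  on_chr4 <- pof_mut$chrom == "chr4" & pof_mut$pos >= 70000
  expect_lt(abs(mean(pof_mut$m[on_chr4])), 0.05) # background only
})

test_that("unknown mark or condition is a config error", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  expect_error(generate_tracks(cfg, ann, marks = "H4K20me3"), "unknown mark")
  expect_error(
    generate_tracks(cfg, ann, conditions = "xyz_mut"),
    "unknown condition"
  )
})

test_that("read-density pause planting matches the closed-form PI", {
  cfg <- small_cfg(seed = 13)
  cfg$pausing$fraction <- c(
    euchromatin = 0.5, chr4 = 0.5,
    pericentric_heterochromatin = 0.5, chr4_proximal = 0.5
  )
  ann <- generate_annotation(cfg)
  rd <- generate_readdensity(cfg, ann)
  paused <- attr(rd, "paused_genes")
  eligible <- filter_genes_for_pi(ann$genes)
  res <- pausing_indices(eligible, rd = rd, method = "groseq")
  # pause window 50 bp at rate lambda*(1+mult) inside the 500 bp head:
  # E[PI] = 1 + window * multiplier / 500
  expected <- 1 + cfg$pausing$window * cfg$pausing$multiplier / 500
  got <- mean(res$pi[res$gene_id %in% paused], na.rm = TRUE)
  expect_lt(abs(got - expected) / expected, 0.15)
  non_paused <- setdiff(attr(rd, "active_genes"), paused)
  got0 <- median(res$pi[res$gene_id %in% non_paused], na.rm = TRUE)
  expect_lt(abs(got0 - 1), 0.25)
})

test_that("zero pause fraction gives a near-zero downstream paused fraction", {
  cfg <- small_cfg(seed = 17)
  cfg$pausing$fraction[] <- 0
  ann <- generate_annotation(cfg)
  rd <- generate_readdensity(cfg, ann)
  res <- pausing_indices(filter_genes_for_pi(ann$genes),
    rd = rd,
    method = "groseq", domains = ann$domains
  )
  pf <- paused_fraction(res)
  expect_true(all(pf$fraction[pf$n_associated > 0] <= 0.02))
})

test_that("pause multiplier below 1 is rejected", {
  cfg <- small_cfg()
  cfg$pausing$multiplier <- 0.5
  ann <- generate_annotation(cfg)
  expect_error(generate_readdensity(cfg, ann), "multiplier")
  expect_error(sim_config(pausing = cfg$pausing), "multiplier")
})

test_that("motif planting rate 1 puts an instance in every promoter", {
  cfg <- small_cfg(seed = 19)
  cfg$motifs$PB$rates[] <- 1
  ann <- generate_annotation(cfg)
  seqs <- generate_sequences(cfg, ann)
  pb <- motif_spec("PB", "KCGRWCG", c(-60, 60))
  win <- substr(as.character(seqs), 201 - 60, 201 + 60)
  hits <- vapply(
    win, function(s) length(scan_motif(s, pb)) > 0,
    logical(1)
  )
  expect_true(all(hits))
})

test_that("promoter GC difference depresses the chr4 melting profile", {
  cfg <- small_cfg(seed = 23)
  ann <- generate_annotation(cfg)
  seqs <- generate_sequences(cfg, ann)
  dom <- attr(seqs, "domains")
  down <- substr(as.character(seqs), 201, 300)
  tm4 <- tm_profile(down[dom[names(seqs)] == "chr4"])
  tme <- tm_profile(down[dom[names(seqs)] == "euchromatin"])
  expect_lt(tm4$summary[["mean"]], tme$summary[["mean"]])
})

test_that("mutant expression plants the configured down-regulated fraction", {
  cfg <- small_cfg(seed = 29)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(cfg, ann)
  dom <- assign_domain(ann$genes, ann$domains)
  chr4_ids <- ann$genes$gene_id[dom == "chr4"]
  dec <- ex$mut$value[match(chr4_ids, ex$mut$gene_id)] <
    ex$wt$value[match(chr4_ids, ex$wt$gene_id)]
  expect_lt(abs(mean(dec) - 0.8), 0.2) # n = 20 genes here
  expect_true(all(ex$down_genes %in% ann$genes$gene_id))
})
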