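#' Fraction of wildtype peaks reduced in a mutant
#'
#' A wildtype peak counts as "reduced" when no mutant enriched region
#' (called on the rescaled mutant track with the same FDR) covers at
#' least `min_coverage` of the peak. Results are additionally binned by
#' the wildtype peak M-value.
#'
#' @param wt_regions wildtype [region_set] (from
#'   [call_enriched_regions()]).
#' @param mut_track the mutant [probe_track], already rescaled via
#'   [scale_mutant_to_wt()] and smoothed.
#' @param fdr FDR for the mutant call (defaults to the wildtype set's).
#' @param min_coverage minimal fraction of the WT peak that a mutant
#'   region must cover for the peak to count as retained (default 0.5).
#' @param score_breaks breaks for the per-score summary.
#' @param ... further arguments to [call_enriched_regions()].
#' @return List with `fraction_reduced`, `peaks` (per-peak flags),
#'   `by_score` (binned summary) and `mut_regions`.
#' @export
peak_retention <- function(wt_regions, mut_track, fdr = NULL,
                           min_coverage = 0.5,
                           score_breaks = c(-Inf, 1, 2, 3, Inf), ...) {
  if (nrow(wt_regions) == 0) stop("empty wildtype region set")
  if (is.null(fdr)) fdr <- attr(wt_regions, "fdr")
  if (is.null(fdr) || is.na(fdr)) fdr <- 1e-3
  mut_regions <- call_enriched_regions(mut_track, fdr = fdr, ...)
  covered <- numeric(nrow(wt_regions))
  for (chrom in unique(wt_regions$chrom)) {
    wi <- which(wt_regions$chrom == chrom)
    mr <- mut_regions[mut_regions$chrom == chrom, , drop = FALSE]
    for (k in wi) {
      if (nrow(mr) == 0) next
      ov <- pmin(mr$end, wt_regions$end[k]) -
        pmax(mr$start, wt_regions$start[k])
      covered[k] <- sum(pmax(0, ov)) /
        (wt_regions$end[k] - wt_regions$start[k])
    }
  }
  reduced <- covered < min_coverage
  bin <- cut(wt_regions$score, breaks = score_breaks)
  by_score <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- bin == b
    data.frame(
      score_bin = b, n = sum(sel),
      fraction_reduced = if (any(sel)) mean(reduced[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  list(
    fraction_reduced = mean(reduced),
    peaks = data.frame(
      chrom = wt_regions$chrom, start = wt_regions$start,
      end = wt_regions$end, score = wt_regions$score,
      coverage = covered, reduced = reduced, stringsAsFactors = FALSE
    ),
    by_score = by_score, mut_regions = mut_regions
  )
}

#' Mutant-vs-wildtype enrichment change summary
#'
#' Two complementary summaries per mark and domain: the change in
#' enrichment level, from feature-class means (active TSS, active gene
#' body, silent region), and the change in enrichment extent, from the
#' total bp covered by enriched regions called at `fdr` in each
#' condition. Percent change is `100 * (1 - mut / wt)` where the
#' wildtype mean is positive (undefined otherwise).
#'
#' @param wt_track wildtype [probe_track] (smoothed for the extent call).
#' @param mut_track rescaled mutant [probe_track].
#' @param genes a [gene_models] collection.
#' @param domains a [domain_partition].
#' @param active optional logical activity vector (see
#'   [feature_class_means()]).
#' @param fdr FDR for the extent calls (default 1e-3).
#' @return List with `level` (per domain x class) and `extent`
#'   (per domain: enriched bp and region counts in both conditions).
#' @export
enrichment_change_summary <- function(wt_track, mut_track, genes, domains,
                                      active = NULL, fdr = 1e-3) {
  fw <- feature_class_means(wt_track, genes, domains, active = active)
  fm <- feature_class_means(mut_track, genes, domains, active = active)
  level <- data.frame(
    domain = fw$domain, class = fw$class, wt_mean = fw$mean,
    mut_mean = fm$mean,
    percent_change = ifelse(
      !is.na(fw$mean) & fw$mean > 0,
      100 * (1 - fm$mean / fw$mean), NA_real_
    ),
    stringsAsFactors = FALSE
  )
  rw <- call_enriched_regions(wt_track, fdr = fdr)
  rm_ <- call_enriched_regions(mut_track, fdr = fdr)
  domain_bp <- function(regions, d) {
    sel <- regions$chrom == d$chrom
    if (!any(sel)) {
      return(c(bp = 0, n = 0))
    }
    r <- regions[sel, , drop = FALSE]
    ov <- pmax(0, pmin(r$end, d$end) - pmax(r$start, d$start))
    c(bp = sum(ov), n = sum(ov > 0))
  }
  extent <- do.call(rbind, lapply(unique(domains$label), function(lab) {
    d_rows <- domains[domains$label == lab, , drop = FALSE]
    wt <- colSums(do.call(rbind, lapply(
      seq_len(nrow(d_rows)),
      function(i) domain_bp(rw, d_rows[i, ])
    )))
    mu <- colSums(do.call(rbind, lapply(
      seq_len(nrow(d_rows)),
      function(i) domain_bp(rm_, d_rows[i, ])
    )))
    data.frame(
      domain = lab, wt_bp = wt[["bp"]], mut_bp = mu[["bp"]],
      wt_regions = wt[["n"]], mut_regions = mu[["n"]],
      percent_extent_change = if (wt[["bp"]] > 0) {
        100 * (1 - mu[["bp"]] / wt[["bp"]])
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }))
  rownames(extent) <- NULL
  list(level = level, extent = extent)
}

# bp gap from each peak to its nearest repeat (0 when overlapping)
nearest_repeat_distance <- function(p_start, p_end, r_start, r_end) {
  o <- order(r_start)
  r_start <- r_start[o]
  r_end <- r_end[o]
  vapply(seq_along(p_start), function(i) {
    j <- findInterval(p_start[i], r_start)
    cand <- c(
      if (j >= 1) max(0, p_start[i] - r_end[j]),
      if (j < length(r_start)) max(0, r_start[j + 1] - p_end[i]),
      if (j >= 2) max(0, p_start[i] - r_end[j - 1])
    )
    # overlap check: any repeat intersecting the peak
    if (j >= 1 && r_end[j] > p_start[i]) {
      return(0)
    }
    if (j < length(r_start) && r_start[j + 1] < p_end[i]) {
      return(0)
    }
    min(cand)
  }, numeric(1))
}

#' Permutation test on peak-to-repeat distances
#'
#' The observed statistic is the median bp gap from each peak to its
#' nearest repeat. The null preserves the peak count and lengths and
#' places them uniformly at random (non-overlapping) within the domain;
#' `p = (1 + #{null median <= observed}) / (1 + n_perm)`, one-sided for
#' repeat proximity.
#'
#' @param peaks a [region_set] (or data frame with `start`/`end`).
#' @param repeats repeat intervals (data frame with `start`/`end`),
#'   within the domain.
#' @param domain single interval `c(start, end)` or a one-row data frame.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return List with `observed_median`, `expected_median`, `p_value`,
#'   `distances`.
#' @export
distance_to_repeat_test <- function(peaks, repeats, domain, n_perm = 1000,
                                    seed = 1) {
  if (is.data.frame(domain)) domain <- c(domain$start[1], domain$end[1])
  if (nrow(repeats) == 0) stop("no repeats in domain")
  if (nrow(peaks) == 0) stop("no peaks to test")
  obs <- nearest_repeat_distance(
    peaks$start, peaks$end, repeats$start,
    repeats$end
  )
  lens <- peaks$end - peaks$start
  dom_len <- domain[2] - domain[1]
  free <- dom_len - sum(lens)
  if (free < 0) stop("peaks exceed domain length; cannot place null sets")
  set.seed(seed)
  n <- length(lens)
  null_medians <- vapply(seq_len(n_perm), function(k) {
    u <- runif(n + 1)
    gaps <- diff(c(0, floor(free * cumsum(u) / sum(u))))
    starts <- domain[1] + cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n]))
    d <- nearest_repeat_distance(
      starts, starts + lens, repeats$start,
      repeats$end
    )
    median(d)
  }, numeric(1))
  p <- (1 + sum(null_medians <= median(obs))) / (1 + n_perm)
  list(
    observed_median = median(obs),
    expected_median = mean(null_medians), p_value = p, distances = obs
  )
}

#' Mutant-vs-wildtype expression contrast
#'
#' Per-gene log2 fold change on expression with pseudocount 1, a paired
#' Wilcoxon signed-rank test per group (domain or supplied gene set) and
#' counts of decreased/increased genes. Groups with fewer than 6 paired
#' genes are flagged unreliable.
#'
#' @param wt,mut [expression_table]s with matched gene ids.
#' @param domain named character vector gene id -> domain label.
#' @param gene_sets optional named list of gene-id vectors tested as
#'   additional groups.
#' @return List with `genes` (per-gene data frame) and `groups`
#'   (per-group data frame with `n`, `n_down`, `n_up`, `median_lfc`,
#'   `p_value`, `reliable`).
#' @export
expression_change <- function(wt, mut, domain = NULL, gene_sets = NULL) {
  common <- intersect(wt$gene_id, mut$gene_id)
  if (length(common) == 0) stop("no shared genes")
  w <- wt$value[match(common, wt$gene_id)]
  m <- mut$value[match(common, mut$gene_id)]
  lfc <- log2((m + 1) / (w + 1))
  genes <- data.frame(
    gene_id = common, wt = w, mut = m, lfc = lfc,
    stringsAsFactors = FALSE
  )
  groups <- list()
  if (!is.null(domain)) {
    for (dom in unique(domain[common])) {
      if (is.na(dom)) next
      groups[[dom]] <- common[!is.na(domain[common]) &
        domain[common] == dom]
    }
  }
  if (!is.null(gene_sets)) {
    for (nm in names(gene_sets)) {
      groups[[nm]] <- intersect(gene_sets[[nm]], common)
    }
  }
  res <- do.call(rbind, lapply(names(groups), function(nm) {
    ids <- groups[[nm]]
    i <- match(ids, common)
    n <- length(i)
    p <- if (n >= 2 && any(w[i] != m[i])) {
      suppressWarnings(wilcox.test(w[i], m[i], paired = TRUE)$p.value)
    } else if (n >= 2) {
      1 # identical tables: no evidence of change
    } else {
      NA_real_
    }
    data.frame(
      group = nm, n = n, n_down = sum(m[i] < w[i]),
      n_up = sum(m[i] > w[i]), median_lfc = median(lfc[i]),
      p_value = p, reliable = n >= 6, stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  list(genes = genes, groups = res)
}

#' Correlate mutant PI changes with wildtype mark enrichment
#'
#' Pearson correlation, per mark, between per-gene PI ratios
#' (mutant/wildtype) and the wildtype mean enrichment of the mark over
#' each gene. Genes are returned ordered by PI change for heatmap export.
#'
#' @param pi_ratios named numeric vector (gene id -> PI ratio), e.g. from
#'   [pi_ratio_mutant()].
#' @param mark_enrichment matrix or data frame (genes x marks) of
#'   wildtype per-gene mean M-values, with gene-id rownames.
#' @param log_ratio correlate on log2 ratios (default TRUE).
#' @return Data frame `mark`, `r`, `n`, with attribute `gene_order`.
#' @export
pi_change_correlation <- function(pi_ratios, mark_enrichment,
                                  log_ratio = TRUE) {
  common <- intersect(names(pi_ratios), rownames(mark_enrichment))
  if (length(common) < 10) stop("need >= 10 matched genes")
  x <- pi_ratios[common]
  if (log_ratio) x <- log2(x)
  me <- as.matrix(mark_enrichment[common, , drop = FALSE])
  res <- do.call(rbind, lapply(colnames(me), function(mk) {
    y <- me[, mk]
    ok <- is.finite(x) & is.finite(y)
    r <- if (sum(ok) >= 10 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      cor(x[ok], y[ok])
    } else {
      NA_real_
    }
    data.frame(mark = mk, r = r, n = sum(ok), stringsAsFactors = FALSE)
  }))
  attr(res, "gene_order") <- common[order(x)]
  res
}

#' Per-gene mean enrichment of a track
#'
#' @param track a [probe_track].
#' @param genes a [gene_models] collection.
#' @return Named numeric vector (gene id -> mean M over the gene body).
#' @export
gene_mean_enrichment <- function(track, genes) {
  p <- track$probes
  out <- setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  for (chrom in unique(genes$chrom)) {
    pp <- p[p$chrom == chrom, , drop = FALSE]
    gi <- which(genes$chrom == chrom)
    for (i in gi) {
      a <- findInterval(genes$start[i] - 0.5, pp$pos) + 1
      b <- findInterval(genes$end[i] - 0.5, pp$pos)
      if (b >= a) out[i] <- mean(pp$m[a:b])
    }
  }
  out
}
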