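#' Classify genes as expressed (active) or silent
#'
#' RPKM tables use `log10(RPKM + 1) > 0.6` for cell lines and `> 0.4` for
#' third-instar larvae; FPKM tables use `log2(FPKM + 1) > 1.4`.
#'
#' @param tbl an [expression_table].
#' @param context `"cell_line"` or `"larvae"`.
#' @return Logical vector (`TRUE` = active) named by gene id.
#' @export
classify_expressed <- function(tbl, context = c("cell_line", "larvae")) {
  context <- match.arg(context)
  unit <- attr(tbl, "unit")
  active <- if (identical(unit, "FPKM")) {
    log2(tbl$value + 1) > 1.4
  } else if (context == "cell_line") {
    log10(tbl$value + 1) > 0.6
  } else {
    log10(tbl$value + 1) > 0.4
  }
  setNames(active, tbl$gene_id)
}

# Per-gene scaled profile: upstream flank, scaled body, downstream flank.
# Returns a numeric vector of length 2*flank_bins + body_bins, NA where no
# probe fell in a bin (filled afterwards by interpolation).
gene_profile_vector <- function(probes, gene, body_bins, flank_bp,
                                flank_step) {
  flank_bins <- flank_bp / flank_step
  minus <- gene$strand == "-"
  p5 <- if (minus) gene$end else gene$start # 5' gene edge coordinate
  p3 <- if (minus) gene$start else gene$end
  bin_means <- function(pos_rel, vals, breaks) {
    idx <- findInterval(pos_rel, breaks, rightmost.closed = FALSE)
    ok <- idx >= 1 & idx <= length(breaks) - 1
    out <- rep(NA_real_, length(breaks) - 1)
    if (any(ok)) {
      agg <- tapply(vals[ok], idx[ok], mean)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  # strand-oriented relative coordinate: 0 at TSS edge, increasing 3'
  rel <- if (minus) p5 - probes$pos - 1 else probes$pos - p5
  L <- gene$end - gene$start
  up <- bin_means(
    rel[rel < 0], probes$m[rel < 0],
    seq(-flank_bp, 0, flank_step)
  )
  body_sel <- rel >= 0 & rel < L
  body <- bin_means(
    rel[body_sel] / L, probes$m[body_sel],
    seq(0, 1, length.out = body_bins + 1)
  )
  down_rel <- rel - L
  down_sel <- down_rel >= 0 & down_rel < flank_bp
  down <- bin_means(
    down_rel[down_sel], probes$m[down_sel],
    seq(0, flank_bp, flank_step)
  )
  c(up, body, down)
}

fill_na_linear <- function(v) {
  na <- is.na(v)
  if (!any(na)) {
    return(v)
  }
  if (all(na)) {
    return(v)
  }
  idx <- which(!na)
  stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}

#' Scaled metagene profile of an enrichment track
#'
#' Each gene body is interpolated onto `body_bins` equal-width positions
#' (a 3 kb scale by convention); flanks of `flank_bp` upstream of the TSS
#' and downstream of the TES are sampled at fixed `flank_step` bp. Minus-
#' strand genes are orientation-reversed. Bins without probes are filled
#' by linear interpolation between neighbours; genes whose body holds
#' fewer than two probes are skipped. The profile reports the mean and
#' the standard error of the mean across genes at each position.
#'
#' @param track a [probe_track].
#' @param genes a [gene_models] subset (non-empty).
#' @param body_bins scaled body bins (default 60, i.e. 50 bp at 3 kb).
#' @param flank_bp flank extent (default 2000).
#' @param flank_step flank sampling step (default 50).
#' @return Object of class `metagene_profile`: data frame with `position`
#'   (bp on the 3 kb body scale, flanks negative/beyond), `mean`, `sem`,
#'   and attribute `n_genes`.
#' @export
metagene_profile <- function(track, genes, body_bins = 60,
                             flank_bp = 2000, flank_step = 50) {
  if (nrow(genes) == 0) stop("no genes supplied")
  flank_bins <- flank_bp / flank_step
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    p <- track$probes[track$probes$chrom == g$chrom, , drop = FALSE]
    n_body <- sum(p$pos >= g$start & p$pos < g$end)
    if (n_body < 2) next
    v <- gene_profile_vector(p, g, body_bins, flank_bp, flank_step)
    rows[[g$gene_id]] <- fill_na_linear(v)
  }
  if (length(rows) == 0) {
    stop("all genes skipped (fewer than 2 probes in every gene body)")
  }
  if (length(rows) < nrow(genes)) {
    message(nrow(genes) - length(rows), " gene(s) skipped (< 2 body probes)")
  }
  mat <- do.call(rbind, rows)
  mean_v <- colMeans(mat)
  sem_v <- if (nrow(mat) > 1) {
    apply(mat, 2, sd) / sqrt(nrow(mat))
  } else {
    rep(0, ncol(mat))
  }
  body_scale <- 3000
  position <- c(
    seq(-flank_bp + flank_step / 2, -flank_step / 2, flank_step),
    seq(body_scale / body_bins / 2, body_scale - body_scale / body_bins / 2,
      length.out = body_bins
    ),
    seq(body_scale + flank_step / 2, body_scale + flank_bp - flank_step / 2,
      flank_step
    )
  )
  out <- data.frame(position = position, mean = mean_v, sem = sem_v)
  attr(out, "n_genes") <- nrow(mat)
  attr(out, "segment") <- rep(
    c("upstream", "body", "downstream"),
    c(flank_bins, body_bins, flank_bins)
  )
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Per-gene metagene matrix (heatmap layout)
#'
#' Rows are genes (only genes of at least `min_length` bp, 1 kb by
#' default, are included because the TSS/TES anchors are unscaled);
#' columns are unscaled TSS +/- `anchor_bp` bins, a scaled interior, and
#' unscaled TES +/- `anchor_bp` bins. No aggregation across genes.
#'
#' @param track a [probe_track].
#' @param genes a [gene_models] collection.
#' @param anchor_bp unscaled half-window at TSS and TES (default 500).
#' @param interior_bins scaled interior bins (default 20).
#' @param step anchor bin width (default 50).
#' @param min_length minimum gene length (default 1000).
#' @return Numeric matrix genes x positions with attribute `segment`.
#' @export
metagene_heatmap <- function(track, genes, anchor_bp = 500,
                             interior_bins = 20, step = 50,
                             min_length = 1000) {
  keep <- (genes$end - genes$start) >= min_length
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0) stop("no genes of sufficient length")
  anchor_bins <- 2 * anchor_bp / step
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    p <- track$probes[track$probes$chrom == g$chrom, , drop = FALSE]
    minus <- g$strand == "-"
    rel <- if (minus) (g$end - 1) - p$pos else p$pos - g$start
    L <- g$end - g$start
    bin_means <- function(x, vals, breaks) {
      idx <- findInterval(x, breaks)
      ok <- idx >= 1 & idx <= length(breaks) - 1
      out <- rep(NA_real_, length(breaks) - 1)
      if (any(ok)) {
        agg <- tapply(vals[ok], idx[ok], mean)
        out[as.integer(names(agg))] <- agg
      }
      out
    }
    tss_block <- bin_means(rel, p$m, seq(-anchor_bp, anchor_bp, step))
    interior <- c(anchor_bp, L - anchor_bp)
    inner <- bin_means(
      (rel - interior[1]) / max(1, diff(interior)), p$m,
      seq(0, 1, length.out = interior_bins + 1)
    )
    tes_block <- bin_means(rel - L, p$m, seq(-anchor_bp, anchor_bp, step))
    rows[[g$gene_id]] <- fill_na_linear(c(tss_block, inner, tes_block))
  }
  mat <- do.call(rbind, rows)
  attr(mat, "segment") <- rep(
    c("tss", "interior", "tes"),
    c(anchor_bins, interior_bins, anchor_bins)
  )
  mat
}

#' Feature-class mean enrichment per domain
#'
#' Mean M-value with SEM for three feature classes within each domain:
#' TSSs of active genes (TSS +/- `tss_halfwin`), bodies of active genes
#' (gene minus the TSS window) and silent regions (everything else in the
#' domain). For the gene-anchored classes, SEM is computed across genes
#' (per-gene probe means); for silent regions, across contiguous silent
#' segments.
#'
#' @param track a [probe_track].
#' @param genes a [gene_models] collection.
#' @param domains a [domain_partition].
#' @param active logical vector parallel to `genes` rows (default: the
#'   expression column against the cell-line RPKM rule).
#' @param tss_halfwin TSS half-window (default 500).
#' @return Data frame `domain`, `class`, `mean` (gene-weighted, as in
#'   figure-style summaries), `sem`, `n`, plus `probe_mean` and
#'   `n_probes` (probe-weighted mean and probe count, the
#'   precision-weighted summary for ratio estimates); empty classes
#'   appear with `NA` mean and `n = 0`.
#' @export
feature_class_means <- function(track, genes, domains, active = NULL,
                                tss_halfwin = 500) {
  if (is.null(active)) {
    active <- classify_expressed(
      expression_table(genes$gene_id, genes$expression, unit = "RPKM"),
      context = "cell_line"
    )
  }
  gene_dom <- assign_domain(genes, domains)
  p <- track$probes
  chrom_idx <- split(seq_len(nrow(p)), p$chrom)
  range_idx <- function(chrom, lo, hi) {
    # probe indices with lo <= pos < hi on chrom (positions sorted)
    ci <- chrom_idx[[chrom]]
    if (is.null(ci)) {
      return(integer(0))
    }
    pos <- p$pos[ci]
    a <- findInterval(lo - 0.5, pos) + 1
    b <- findInterval(hi - 0.5, pos)
    if (b < a) integer(0) else ci[a:b]
  }
  out <- list()
  for (dom in unique(domains$label)) {
    gsel <- which(gene_dom == dom & active)
    tss_means <- numeric(0)
    body_means <- numeric(0)
    tss_probes <- integer(0)
    body_probes <- integer(0)
    covered <- rep(FALSE, nrow(p))
    for (i in gsel) {
      g <- genes[i, ]
      i_tss <- range_idx(g$chrom, g$tss - tss_halfwin, g$tss + tss_halfwin + 1)
      i_gene <- range_idx(g$chrom, g$start, g$end)
      i_body <- setdiff(i_gene, i_tss)
      if (length(i_tss) > 0) tss_means <- c(tss_means, mean(p$m[i_tss]))
      if (length(i_body) > 0) body_means <- c(body_means, mean(p$m[i_body]))
      tss_probes <- c(tss_probes, i_tss)
      body_probes <- c(body_probes, i_body)
      covered[i_tss] <- TRUE
      covered[i_body] <- TRUE
    }
    # silent region: domain probes not in any active gene or TSS window
    d <- domains[domains$label == dom, , drop = FALSE]
    in_dom <- rep(FALSE, nrow(p))
    for (k in seq_len(nrow(d))) {
      in_dom <- in_dom | (p$chrom == d$chrom[k] & p$pos >= d$start[k] &
        p$pos < d$end[k])
    }
    sil <- which(in_dom & !covered)
    sil_stats <- if (length(sil) > 0) {
      runs <- cumsum(c(1, diff(sil) > 1))
      seg_means <- tapply(p$m[sil], runs, mean)
      c(
        mean(seg_means),
        if (length(seg_means) > 1) {
          sd(seg_means) / sqrt(length(seg_means))
        } else {
          0
        },
        length(seg_means)
      )
    } else {
      c(NA_real_, NA_real_, 0)
    }
    cls_stats <- function(v) {
      if (length(v) == 0) {
        c(NA_real_, NA_real_, 0)
      } else {
        c(
          mean(v), if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
          length(v)
        )
      }
    }
    st <- rbind(
      cls_stats(tss_means), cls_stats(body_means),
      sil_stats
    )
    pmean <- function(idx) if (length(idx) > 0) mean(p$m[idx]) else NA_real_
    out[[dom]] <- data.frame(
      domain = dom,
      class = c("active_tss", "active_body", "silent"),
      mean = st[, 1], sem = st[, 2], n = st[, 3],
      probe_mean = c(pmean(tss_probes), pmean(body_probes), pmean(sil)),
      n_probes = c(length(tss_probes), length(body_probes), length(sil)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
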