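#' Filter genes eligible for pausing-index analysis
#'
#' Removes genes shorter than `min_length` bp (500 by default) and genes
#' overlapping any other gene by at least one bp on either strand (both
#' members of an overlapping pair are removed).
#'
#' @param genes a [gene_models] collection.
#' @param min_length minimum gene length in bp.
#' @return The eligible [gene_models] subset.
#' @export
filter_genes_for_pi <- function(genes, min_length = 500) {
  keep <- (genes$end - genes$start) >= min_length
  overlapping <- rep(FALSE, nrow(genes))
  for (chrom in unique(genes$chrom)) {
    i <- which(genes$chrom == chrom)
    o <- i[order(genes$start[i])]
    if (length(o) < 2) next
    ends <- cummax(genes$end[o])
    ov <- genes$start[o][-1] < ends[-length(o)]
    # overlap marks both partners
    for (k in which(ov)) {
      overlapping[o[k + 1]] <- TRUE
      prev <- o[seq_len(k)]
      overlapping[prev[genes$end[prev] > genes$start[o[k + 1]]]] <- TRUE
    }
  }
  sub <- genes[keep & !overlapping, , drop = FALSE]
  ex <- gene_exons(genes)[sub$gene_id]
  attr(sub, "exons") <- ex
  class(sub) <- c("gene_models", "data.frame")
  sub
}

strand_counts <- function(rd, gene) {
  x <- rd$counts[[gene$chrom]]
  if (is.null(x)) stop("no read-density data for ", gene$chrom)
  v <- if (gene$strand == "-") x$minus else x$plus
  if (gene$end > length(v)) {
    stop("gene '", gene$gene_id, "' extends past chromosome end")
  }
  counts <- v[(gene$start + 1):gene$end]
  if (gene$strand == "-") rev(counts) else counts
}

#' Run-on (GRO-seq style) pausing index
#'
#' PI is the ratio of mean read density in the first 500 bp downstream of
#' the TSS (gene strand only) to the mean density over the next
#' `ceiling(0.25 * (L - 500))` bp. A zero denominator with a nonzero
#' numerator yields `Inf`; a 0/0 gene has no defined PI (`NA`, not
#' polymerase-associated).
#'
#' @param rd a [read_density] track.
#' @param gene a single-row [gene_models] subset.
#' @param head_bp 5' window (default 500).
#' @return Numeric PI (possibly `Inf` or `NA`).
#' @export
pi_groseq <- function(rd, gene, head_bp = 500) {
  counts <- strand_counts(rd, gene)
  L <- length(counts)
  if (L <= head_bp) {
    return(NA_real_)
  }
  body_len <- ceiling(0.25 * (L - head_bp))
  if (body_len == 0) {
    return(NA_real_)
  }
  num <- mean(counts[seq_len(head_bp)])
  den <- mean(counts[(head_bp + 1):(head_bp + body_len)])
  if (den == 0) {
    if (num == 0) NA_real_ else Inf
  } else {
    num / den
  }
}

#' ChIP-style pausing index for RNA Pol II
#'
#' PI is the maximum enrichment in the TSS +/- 300 bp window divided by
#' the median enrichment over the gene body (600 bp downstream of the TSS
#' to the gene end). By default the ratio is taken on the linear intensity
#' scale (`2^M`), which keeps it positive; set `scale = "log"` for a ratio
#' of raw M-values and `body_stat = "mean"` for a mean-based body summary.
#'
#' @param track a smoothed Pol II [probe_track].
#' @param gene a single-row [gene_models] subset.
#' @param tss_halfwin TSS window half-width (default 300).
#' @param body_offset body start downstream of TSS (default 600).
#' @param scale `"linear"` (default) or `"log"`.
#' @param body_stat `"median"` (default) or `"mean"`.
#' @return Numeric PI, or `NA` if the probe support is insufficient
#'   (needs >= 1 TSS probe and >= 2 body probes).
#' @export
pi_chip <- function(track, gene, tss_halfwin = 300, body_offset = 600,
                    scale = c("linear", "log"),
                    body_stat = c("median", "mean")) {
  scale <- match.arg(scale)
  body_stat <- match.arg(body_stat)
  p <- track$probes[track$probes$chrom == gene$chrom, , drop = FALSE]
  in_tss <- abs(p$pos - gene$tss) <= tss_halfwin
  minus <- gene$strand == "-"
  in_body <- if (minus) {
    p$pos >= gene$start & p$pos <= gene$tss - body_offset
  } else {
    p$pos >= gene$tss + body_offset & p$pos < gene$end
  }
  if (sum(in_tss) < 1 || sum(in_body) < 2) {
    return(NA_real_)
  }
  f <- if (scale == "linear") function(x) 2^x else identity
  num <- max(f(p$m[in_tss]))
  den <- if (body_stat == "median") {
    median(f(p$m[in_body]))
  } else {
    mean(f(p$m[in_body]))
  }
  if (den == 0) {
    if (num == 0) NA_real_ else Inf
  } else {
    num / den
  }
}

#' Pausing indices for a gene collection
#'
#' @param genes an eligible [gene_models] collection (see
#'   [filter_genes_for_pi()]).
#' @param rd a [read_density] (method `"groseq"`).
#' @param track a smoothed Pol II [probe_track] (method `"chip"`).
#' @param method `"groseq"` or `"chip"`.
#' @param domains optional [domain_partition] for domain labels.
#' @param threshold paused threshold (default 10 for groseq, 4 for chip).
#' @param ... passed to [pi_groseq()] / [pi_chip()].
#' @return Data frame of class `pausing_result`: `gene_id`, `pi`,
#'   `method`, `paused`, `threshold`, `domain`.
#' @export
pausing_indices <- function(genes, rd = NULL, track = NULL,
                            method = c("groseq", "chip"), domains = NULL,
                            threshold = NULL, ...) {
  method <- match.arg(method)
  if (is.null(threshold)) threshold <- if (method == "groseq") 10 else 4
  pi <- vapply(seq_len(nrow(genes)), function(i) {
    if (method == "groseq") {
      pi_groseq(rd, genes[i, ], ...)
    } else {
      pi_chip(track, genes[i, ], ...)
    }
  }, numeric(1))
  dom <- if (is.null(domains)) {
    rep(NA_character_, nrow(genes))
  } else {
    assign_domain(genes, domains)
  }
  out <- data.frame(
    gene_id = genes$gene_id, pi = pi, method = method,
    paused = !is.na(pi) & pi > threshold, threshold = threshold,
    domain = dom, stringsAsFactors = FALSE
  )
  class(out) <- c("pausing_result", "data.frame")
  out
}

#' Per-domain paused fractions
#'
#' The denominator is the set of polymerase-associated genes (defined PI);
#' the fraction is the share of those with PI above the threshold.
#'
#' @param results a [pausing_indices()] result.
#' @param threshold PI threshold (defaults to the one stored in
#'   `results`).
#' @return Data frame `domain`, `n_associated`, `n_paused`, `fraction`.
#' @export
paused_fraction <- function(results, threshold = NULL) {
  if (is.null(threshold)) threshold <- results$threshold[1]
  assoc <- results[!is.na(results$pi), , drop = FALSE]
  doms <- unique(results$domain)
  out <- do.call(rbind, lapply(doms, function(dom) {
    sub <- assoc[assoc$domain == dom, , drop = FALSE]
    data.frame(
      domain = dom, n_associated = nrow(sub),
      n_paused = sum(sub$pi > threshold),
      fraction = if (nrow(sub) > 0) {
        mean(sub$pi > threshold)
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Paused fraction over a sweep of thresholds
#'
#' @param results a [pausing_indices()] result.
#' @param thresholds numeric vector of PI thresholds.
#' @return Long data frame `threshold` x `domain` with paused fractions
#'   (monotone non-increasing in the threshold).
#' @export
paused_fraction_sweep <- function(results, thresholds) {
  do.call(rbind, lapply(thresholds, function(th) {
    cbind(threshold = th, paused_fraction(results, threshold = th))
  }))
}

#' Permutation test for a paused-fraction contrast between domains
#'
#' The statistic is `fraction(domainA) - fraction(domainB)` over
#' polymerase-associated genes; the null shuffles domain labels. The
#' two-sided p-value uses the add-one construction
#' `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)`, which is valid
#' (conservative) under the null.
#'
#' @param results a [pausing_indices()] result.
#' @param domainA,domainB domain labels to contrast.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param threshold PI threshold (defaults to the stored one).
#' @return List with `p_value`, `observed`, `fractions` and `n`.
#' @export
pausing_domain_test <- function(results, domainA, domainB, n_perm = 1000,
                                seed = 1, threshold = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(threshold)) threshold <- results$threshold[1]
  sub <- results[!is.na(results$pi) &
    results$domain %in% c(domainA, domainB), , drop = FALSE]
  nA <- sum(sub$domain == domainA)
  nB <- sum(sub$domain == domainB)
  if (nA < 5 || nB < 5) {
    warning("fewer than 5 polymerase-associated genes in a domain")
  }
  if (nA == 0 || nB == 0) stop("empty domain in pausing contrast")
  paused <- as.numeric(sub$pi > threshold)
  obs <- sum(paused[sub$domain == domainA]) / nA -
    sum(paused[sub$domain == domainB]) / nB
  set.seed(seed)
  n <- length(paused)
  tot <- sum(paused)
  null <- vapply(seq_len(n_perm), function(k) {
    a <- sum(paused[sample.int(n, nA)])
    a / nA - (tot - a) / nB
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  list(
    p_value = p, observed = obs,
    fractions = c(
      setNames(sum(paused[sub$domain == domainA]) / nA, domainA),
      setNames(sum(paused[sub$domain == domainB]) / nB, domainB)
    ),
    n = c(setNames(nA, domainA), setNames(nB, domainB))
  )
}

#' Per-gene mutant/wildtype PI ratios
#'
#' Genes with an undefined or infinite PI in either condition are
#' excluded (and counted); reports the number with a PI increase
#' (ratio > 1).
#'
#' @param wt,mut [pausing_indices()] results for matched genes and the
#'   same method.
#' @return List with `ratios` (data frame `gene_id`, `pi_wt`, `pi_mut`,
#'   `ratio`), `n_increase`, `n_total`, `n_excluded`.
#' @export
pi_ratio_mutant <- function(wt, mut) {
  common <- intersect(wt$gene_id, mut$gene_id)
  if (length(common) == 0) stop("no genes shared between conditions")
  w <- wt[match(common, wt$gene_id), ]
  m <- mut[match(common, mut$gene_id), ]
  usable <- is.finite(w$pi) & is.finite(m$pi) & w$pi > 0
  df <- data.frame(
    gene_id = common[usable], pi_wt = w$pi[usable], pi_mut = m$pi[usable],
    ratio = m$pi[usable] / w$pi[usable], stringsAsFactors = FALSE
  )
  list(
    ratios = df, n_increase = sum(df$ratio > 1), n_total = nrow(df),
    n_excluded = sum(!usable)
  )
}

#' Strand-oriented offset of the Pol II maximum near the TSS
#'
#' Returns the signed bp offset (downstream positive) of the maximal
#' probe within TSS +/- `halfwin`; ties take the smallest signed offset.
#' Genes with fewer than 3 probes in the window are skipped (`NA`).
#'
#' @param track a smoothed Pol II [probe_track].
#' @param gene a single-row [gene_models] subset.
#' @param halfwin window half-width (default 500).
#' @return Signed offset in bp, or `NA`.
#' @export
tss_peak_position <- function(track, gene, halfwin = 500) {
  p <- track$probes[track$probes$chrom == gene$chrom, , drop = FALSE]
  sel <- abs(p$pos - gene$tss) <= halfwin
  if (sum(sel) < 3) {
    return(NA_real_)
  }
  sgn <- if (gene$strand == "-") -1 else 1
  off <- (p$pos[sel] - gene$tss) * sgn
  v <- p$m[sel]
  o <- order(off)
  off <- off[o]
  v <- v[o]
  off[which.max(v)]
}

#' Mean TSS-peak shift between two conditions
#'
#' @param wt_track,mut_track smoothed Pol II [probe_track]s.
#' @param genes a [gene_models] collection.
#' @param halfwin window half-width passed to [tss_peak_position()].
#' @return `mean(mutant offsets) - mean(wildtype offsets)` over genes with
#'   a defined offset in both conditions.
#' @export
tss_peak_shift <- function(wt_track, mut_track, genes, halfwin = 500) {
  off_w <- vapply(seq_len(nrow(genes)), function(i) {
    tss_peak_position(wt_track, genes[i, ], halfwin)
  }, numeric(1))
  off_m <- vapply(seq_len(nrow(genes)), function(i) {
    tss_peak_position(mut_track, genes[i, ], halfwin)
  }, numeric(1))
  ok <- !is.na(off_w) & !is.na(off_m)
  mean(off_m[ok]) - mean(off_w[ok])
}

#' Overlap of top-ranked paused genes between the two PI methods
#'
#' Transcript-level run-on results are reduced to gene level by taking
#' the maximal PI per gene; for each N the overlap is
#' `|top-N(groseq) intersect top-N(chip)| / N`.
#'
#' @param groseq,chip [pausing_indices()] results (the `gene_id` of the
#'   groseq result may contain repeated gene ids for multi-transcript
#'   genes).
#' @param top_n integer vector of list sizes.
#' @return Data frame `n`, `overlap`.
#' @export
method_overlap <- function(groseq, chip, top_n = c(1000, 1500, 2000)) {
  reduce_max <- function(r) {
    ok <- !is.na(r$pi)
    v <- tapply(r$pi[ok], r$gene_id[ok], max)
    sort(v, decreasing = TRUE)
  }
  a <- reduce_max(groseq)
  b <- reduce_max(chip)
  avail <- min(length(a), length(b))
  do.call(rbind, lapply(top_n, function(N) {
    if (N > avail) {
      warning("top_n ", N, " exceeds available genes; capped at ", avail)
      N <- avail
    }
    ov <- length(intersect(names(a)[seq_len(N)], names(b)[seq_len(N)])) / N
    data.frame(n = N, overlap = ov)
  }))
}
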