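#' Fit combinatorial chromatin states by K-means with centroid merging
#'
#' Bins with any missing mark are excluded; marks are z-scored before
#' clustering. K-means is run with `k_initial` clusters (fixed seed,
#' `nstart` restarts); clusters whose centroids (mapped back to the
#' original M-value scale, so the shared mark signature rather than the
#' standardized residual drives the decision) have Pearson correlation
#' above `merge_threshold` are merged iteratively, highest pair first,
#' until no pair exceeds the threshold. Final states are ordered by
#' decreasing mean of the silencing-mark centroid component and renamed
#' `A`, `B`, ... Merging by centroid correlation needs at least three
#' marks to be meaningful (with two marks every correlation is +/-1).
#'
#' @param bm a [bin_enrichment()] result.
#' @param k_initial initial cluster count (default 10).
#' @param merge_threshold centroid correlation above which clusters merge
#'   (default 0.8).
#' @param seed RNG seed for the K-means restarts.
#' @param nstart K-means restarts (default 10).
#' @param silencing_mark mark whose centroid value orders the state
#'   labels; defaults to a mark matching `"H3K9me2"`, else the first
#'   column.
#' @return Object of class `state_assignment`: `labels` (per-bin state or
#'   `NA` for incomplete bins), `centroids` (states x marks, original
#'   scale), `k_initial`, `k_final`, `sizes`, `bins`.
#' @export
fit_states <- function(bm, k_initial = 10, merge_threshold = 0.8,
                       seed = 1, nstart = 10, silencing_mark = NULL) {
  if (k_initial < 2) stop("k_initial must be >= 2")
  complete <- complete.cases(bm$m)
  x <- bm$m[complete, , drop = FALSE]
  if (nrow(x) < k_initial) {
    stop("fewer complete bins (", nrow(x), ") than k_initial")
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  set.seed(seed)
  km <- kmeans(z, centers = k_initial, nstart = nstart, iter.max = 100)
  cluster <- km$cluster
  # centroids on the original M-value scale
  cent <- t(vapply(
    seq_len(k_initial),
    function(k) colMeans(x[cluster == k, , drop = FALSE]),
    numeric(ncol(x))
  ))
  sizes <- tabulate(cluster, k_initial)
  repeat {
    k <- nrow(cent)
    if (k <= 1) break
    cc <- suppressWarnings(cor(t(cent)))
    cc[!is.finite(cc)] <- -Inf
    diag(cc) <- -Inf
    if (max(cc) <= merge_threshold) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    i <- min(ij)
    j <- max(ij)
    w <- sizes[c(i, j)]
    cent[i, ] <- colSums(cent[c(i, j), ] * w) / sum(w)
    sizes[i] <- sum(w)
    cluster[cluster == j] <- i
    cluster[cluster > j] <- cluster[cluster > j] - 1
    cent <- cent[-j, , drop = FALSE]
    sizes <- sizes[-j]
  }
  k_final <- nrow(cent)
  if (is.null(silencing_mark)) {
    hit <- grep("H3K9me2", colnames(bm$m), value = TRUE)
    silencing_mark <- if (length(hit) > 0) hit[1] else colnames(bm$m)[1]
  }
  ord <- order(-cent[, silencing_mark])
  relabel <- integer(k_final)
  relabel[ord] <- seq_len(k_final)
  cluster <- relabel[cluster]
  cent <- cent[ord, , drop = FALSE]
  sizes <- sizes[ord]
  rownames(cent) <- LETTERS[seq_len(k_final)]
  labels <- rep(NA_character_, nrow(bm$m))
  labels[complete] <- LETTERS[cluster]
  structure(
    list(
      labels = labels, centroids = cent, k_initial = k_initial,
      k_final = k_final, sizes = sizes, bins = bm$bins,
      silencing_mark = silencing_mark, tot_withinss = km$tot.withinss
    ),
    class = "state_assignment"
  )
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf(
    "<state_assignment> %d states (from k=%d) over %d bins\n",
    x$k_final, x$k_initial, sum(!is.na(x$labels))
  ))
  print(round(x$centroids, 3))
  invisible(x)
}

#' Per-domain state composition and fold enrichment
#'
#' Fold-enrichment of a state in a domain is its bin fraction in the
#' domain divided by its genome-wide bin fraction; fractions within each
#' domain sum to 1.
#'
#' @param sa a [fit_states()] result.
#' @param domains a [domain_partition].
#' @return Data frame with `domain`, `state`, `fraction`, `fold`. Empty
#'   domains are flagged via the `empty_domains` attribute.
#' @export
state_chrom_enrichment <- function(sa, domains) {
  ok <- !is.na(sa$labels)
  states <- rownames(sa$centroids)
  overall <- table(factor(sa$labels[ok], levels = states))
  overall <- as.numeric(overall) / sum(ok)
  bm_like <- list(bins = sa$bins)
  out <- list()
  empty <- character(0)
  for (dom in unique(domains$label)) {
    inside <- bins_in_domain(bm_like, domains, dom) & ok
    if (!any(inside)) {
      empty <- c(empty, dom)
      next
    }
    frac <- table(factor(sa$labels[inside], levels = states))
    frac <- as.numeric(frac) / sum(inside)
    out[[dom]] <- data.frame(
      domain = dom, state = states, fraction = frac,
      fold = ifelse(overall > 0, frac / overall, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "empty_domains") <- empty
  res
}

#' Per-state gene-feature composition
#'
#' Each bin is assigned one feature class (TSS +/- 500 bp, exon, intron,
#' intergenic) by majority bp, ties resolved by the priority
#' TSS > exon > intron > intergenic (per-base classes are drawn with the
#' same priority). Per-state fractions over feature classes sum to 1.
#'
#' @param sa a [fit_states()] result.
#' @param genes a [gene_models] collection.
#' @param tss_halfwin TSS window half-width (bp).
#' @return Data frame `state` x feature-class fractions.
#' @export
state_feature_association <- function(sa, genes, tss_halfwin = 500) {
  bins <- sa$bins
  gr_bins <- GenomicRanges::GRanges(
    bins$chrom,
    IRanges::IRanges(bins$start + 1, bins$end)
  )
  if (nrow(genes) > 0) {
    gr_tss <- GenomicRanges::reduce(GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(
        pmax(0, genes$tss - tss_halfwin) + 1,
        genes$tss + tss_halfwin + 1
      )
    ))
    exons <- gene_exons(genes)
    ex <- do.call(rbind, lapply(names(exons), function(id) {
      cbind(
        data.frame(chrom = genes$chrom[genes$gene_id == id]),
        as.data.frame(exons[[id]])
      )
    }))
    gr_exon <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ex$chrom,
      IRanges::IRanges(ex$start + 1, ex$end)
    ))
    gr_gene <- GenomicRanges::reduce(GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(genes$start + 1, genes$end)
    ))
    gr_intron <- GenomicRanges::setdiff(gr_gene, gr_exon)
    gr_exon <- GenomicRanges::setdiff(gr_exon, gr_tss)
    gr_intron <- GenomicRanges::setdiff(gr_intron, gr_tss)
  } else {
    gr_tss <- gr_exon <- gr_intron <- GenomicRanges::GRanges()
  }
  cover_bp <- function(gr) {
    w <- numeric(length(gr_bins))
    if (length(gr) == 0) {
      return(w)
    }
    hits <- GenomicRanges::findOverlaps(gr_bins, gr)
    ov <- IRanges::width(IRanges::pintersect(
      gr_bins[S4Vectors::queryHits(hits)],
      gr[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    w[as.integer(names(agg))] <- agg
    w
  }
  bp <- cbind(
    tss = cover_bp(gr_tss), exon = cover_bp(gr_exon),
    intron = cover_bp(gr_intron)
  )
  bp <- cbind(bp, intergenic = (bins$end - bins$start) - rowSums(bp))
  # majority bp; max.col with ties.method "first" respects column priority
  cls <- colnames(bp)[max.col(bp, ties.method = "first")]
  ok <- !is.na(sa$labels)
  states <- rownames(sa$centroids)
  out <- t(vapply(states, function(s) {
    sel <- ok & sa$labels == s
    tab <- table(factor(cls[sel], levels = colnames(bp)))
    as.numeric(tab) / max(1, sum(sel))
  }, numeric(ncol(bp))))
  colnames(out) <- colnames(bp)
  res <- data.frame(
    state = states, out,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "bin_class") <- cls
  res
}
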