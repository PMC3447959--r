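#' Smooth an enrichment track with a centered moving average
#'
#' Each probe's M-value is replaced by the mean of all probes within
#' +/- `window_bp / 2` of its position (itself included); the probe set is
#' unchanged. The operator preserves constants and is shift-equivariant.
#'
#' @param track a [probe_track].
#' @param window_bp full window width in bp (default 500).
#' @return A smoothed [probe_track].
#' @export
smooth_track <- function(track, window_bp = 500) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  p <- track$probes
  if (nrow(p) == 0) {
    return(track)
  }
  half <- window_bp / 2
  out <- p$m
  for (chrom in unique(p$chrom)) {
    i <- which(p$chrom == chrom)
    pos <- p$pos[i]
    v <- p$m[i]
    cs <- c(0, cumsum(v))
    lo <- findInterval(pos - half - 0.5, pos) + 1
    hi <- findInterval(pos + half + 0.5, pos)
    out[i] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  res <- track
  res$probes$m <- out
  res
}

# Half-sample mode: robust location of the bulk of an M distribution.
half_sample_mode <- function(x) {
  x <- sort(x)
  while (length(x) > 3) {
    n <- length(x)
    k <- ceiling(n / 2)
    w <- x[k:n] - x[1:(n - k + 1)]
    j <- which.min(w)
    x <- x[j:(j + k - 1)]
  }
  mean(x)
}

#' Call significantly enriched regions from a smoothed track
#'
#' A null Gaussian is fitted to the mode-centred bulk of the M-value
#' distribution (half-sample mode; robust SD from the left half of the
#' distribution, which is unaffected by the enriched right tail). Per-probe
#' upper-tail p-values undergo Benjamini-Hochberg step-up control at
#' `fdr`; significant probes within `merge_gap` bp are joined into regions
#' and regions with fewer than `min_probes` significant probes are
#' dropped.
#'
#' @param track a smoothed [probe_track].
#' @param fdr false discovery rate for probe calls (default 1e-3).
#' @param merge_gap maximum gap (bp) between significant probes joined
#'   into one region.
#' @param min_probes minimum significant probes per reported region.
#' @return A [region_set] (score = mean smoothed M of the region's
#'   significant probes).
#' @export
call_enriched_regions <- function(track, fdr = 1e-3, merge_gap = 1000,
                                  min_probes = 3) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  p <- track$probes
  if (nrow(p) < 10) stop("too few probes (< 10) to fit a null model")
  mu0 <- half_sample_mode(p$m)
  left <- p$m[p$m <= mu0]
  sd0 <- 1.4826 * median(mu0 - left)
  if (!is.finite(sd0) || sd0 <= 0) {
    # degenerate null (e.g. constant track): nothing callable
    return(region_set(character(0), numeric(0), numeric(0), numeric(0),
      fdr = fdr
    ))
  }
  pv <- pnorm(p$m, mean = mu0, sd = sd0, lower.tail = FALSE)
  sig <- p.adjust(pv, method = "BH") <= fdr
  if (!any(sig)) {
    return(region_set(character(0), numeric(0), numeric(0), numeric(0),
      fdr = fdr
    ))
  }
  out <- list()
  for (chrom in unique(p$chrom[sig])) {
    i <- which(sig & p$chrom == chrom)
    pos <- p$pos[i]
    grp <- cumsum(c(1, diff(pos) > merge_gap))
    for (g in split(seq_along(i), grp)) {
      if (length(g) < min_probes) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = pos[g[1]], end = pos[g[length(g)]] + 1,
        score = mean(p$m[i[g]]), n_probes = length(g),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(region_set(character(0), numeric(0), numeric(0), numeric(0),
      fdr = fdr
    ))
  }
  df <- do.call(rbind, out)
  region_set(df$chrom, df$start, df$end, df$score,
    fdr = fdr,
    n_probes = df$n_probes
  )
}

overlaps_any <- function(a, b) {
  # for each interval in a, does any interval in b overlap it?
  res <- logical(nrow(a))
  for (chrom in unique(a$chrom)) {
    ai <- which(a$chrom == chrom)
    bb <- b[b$chrom == chrom, , drop = FALSE]
    if (nrow(bb) == 0) next
    o <- order(bb$start)
    bs <- bb$start[o]
    be <- bb$end[o]
    cummax_end <- cummax(be)
    for (k in ai) {
      j <- findInterval(a$end[k] - 1, bs)
      res[k] <- j >= 1 && cummax_end[j] > a$start[k]
    }
  }
  res
}

#' Replicate-consistency check for enriched-region sets
#'
#' Two replicates pass if their target (region) lists overlap by more than
#' 75%, or if the top 40% of targets by score in each replicate have more
#' than 80% in common. Targets are matched by any genomic overlap. A
#' base-pair variant of the first rule (Jaccard of covered bp) is
#' available via `by = "bp"`.
#'
#' @param a,b [region_set]s called on the same genome.
#' @param by `"targets"` (default) or `"bp"` for the primary overlap rule.
#' @return List with `pass`, `overlap`, `top40_overlap` and `reason`.
#' @export
replicate_consistency <- function(a, b, by = c("targets", "bp")) {
  by <- match.arg(by)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(
      pass = FALSE, overlap = 0, top40_overlap = 0,
      reason = "empty region set in one replicate"
    ))
  }
  overlap <- if (by == "targets") {
    (sum(overlaps_any(a, b)) + sum(overlaps_any(b, a))) / (nrow(a) + nrow(b))
  } else {
    ga <- GenomicRanges::reduce(GenomicRanges::GRanges(
      a$chrom,
      IRanges::IRanges(a$start + 1, a$end)
    ))
    gb <- GenomicRanges::reduce(GenomicRanges::GRanges(
      b$chrom,
      IRanges::IRanges(b$start + 1, b$end)
    ))
    inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
    uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
    inter / uni
  }
  top <- function(x) {
    n <- max(1, ceiling(0.4 * nrow(x)))
    x[order(-x$score), , drop = FALSE][seq_len(n), , drop = FALSE]
  }
  ta <- top(a)
  tb <- top(b)
  top40 <- (sum(overlaps_any(ta, tb)) + sum(overlaps_any(tb, ta))) /
    (nrow(ta) + nrow(tb))
  pass <- overlap > 0.75 || top40 > 0.80
  list(
    pass = pass, overlap = overlap, top40_overlap = top40,
    reason = if (pass) "consistent" else "overlap below both thresholds"
  )
}

#' Average enrichment tracks into fixed-width bins
#'
#' Bins tile each chromosome without overlap; each cell is the mean
#' M-value of the probes falling in the bin, `NA` where a bin holds no
#' probe (excluded pairwise downstream).
#'
#' @param tracks list of [probe_track]s on a shared genome.
#' @param width bin width in bp (default 500).
#' @param chrom_lengths optional named vector; defaults to the maximal
#'   probe position per chromosome (rounded up to a full bin).
#' @return A list of class `bin_matrix` with elements `bins` (data frame
#'   `chrom`, `start`, `end`), `m` (matrix bins x marks) and `width`.
#' @export
bin_enrichment <- function(tracks, width = 500, chrom_lengths = NULL) {
  if (width <= 0) stop("bin width must be > 0")
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    names(tracks) <- vapply(tracks, function(t) t$mark, character(1))
  }
  if (is.null(chrom_lengths)) {
    pos_max <- list()
    for (t in tracks) {
      mx <- tapply(t$probes$pos, t$probes$chrom, max)
      for (chrom in names(mx)) {
        pos_max[[chrom]] <- max(pos_max[[chrom]] %||% 0, mx[[chrom]] + 1)
      }
    }
    chrom_lengths <- unlist(pos_max)
  }
  chroms <- sort(names(chrom_lengths))
  bins <- do.call(rbind, lapply(chroms, function(chrom) {
    n <- ceiling(chrom_lengths[[chrom]] / width)
    data.frame(
      chrom = chrom, start = (seq_len(n) - 1) * width,
      end = seq_len(n) * width, stringsAsFactors = FALSE
    )
  }))
  offsets <- cumsum(c(0, vapply(chroms, function(chrom) {
    ceiling(chrom_lengths[[chrom]] / width)
  }, numeric(1))))
  names(offsets) <- c(chroms, "_end")
  m <- matrix(NA_real_,
    nrow = nrow(bins), ncol = length(tracks),
    dimnames = list(NULL, names(tracks))
  )
  for (j in seq_along(tracks)) {
    p <- tracks[[j]]$probes
    for (chrom in intersect(unique(p$chrom), chroms)) {
      i <- p$chrom == chrom
      idx <- floor(p$pos[i] / width) + 1
      ok <- idx <= ceiling(chrom_lengths[[chrom]] / width)
      means <- tapply(p$m[i][ok], idx[ok], mean)
      m[offsets[[chrom]] + as.integer(names(means)), j] <- means
    }
  }
  structure(list(bins = bins, m = m, width = width), class = "bin_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf(
    "<bin_matrix> %d bins x %d marks (width %d bp)\n",
    nrow(x$m), ncol(x$m), x$width
  ))
  invisible(x)
}

bins_in_domain <- function(bm, domains, label) {
  d <- domains[domains$label == label, , drop = FALSE]
  inside <- rep(FALSE, nrow(bm$bins))
  for (i in seq_len(nrow(d))) {
    inside <- inside | (bm$bins$chrom == d$chrom[i] &
      bm$bins$start >= d$start[i] & bm$bins$end <= d$end[i])
  }
  inside
}

#' Pairwise mark correlations within one genomic domain
#'
#' Pearson correlation over the bins whose interval lies entirely inside
#' the domain, computed pairwise-complete. Marks with zero variance in
#' the domain produce `NA` entries (flagged via the `degenerate`
#' attribute), never propagated NaNs.
#'
#' @param bm a [bin_enrichment()] result.
#' @param domain domain label.
#' @param domains a [domain_partition].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
mark_correlation <- function(bm, domain, domains) {
  if (ncol(bm$m) < 2) stop("need at least two marks")
  sel <- bins_in_domain(bm, domains, domain)
  x <- bm$m[sel, , drop = FALSE]
  if (sum(complete.cases(x)) < 10) {
    stop("fewer than 10 complete bins in domain '", domain, "'")
  }
  vars <- apply(x, 2, function(v) var(v, na.rm = TRUE))
  degenerate <- names(vars)[!is.finite(vars) | vars == 0]
  cc <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  cc[degenerate, ] <- NA_real_
  cc[, degenerate] <- NA_real_
  diag(cc) <- 1
  attr(cc, "degenerate") <- degenerate
  cc
}

#' Scale a mutant track to its wildtype reference
#'
#' The scaling factor is the ratio of the median absolute deviations of
#' the lagged probe-to-probe differences:
#' `median|d_WT - median(d_WT)| / median|d_mut - median(d_mut)|` with
#' `d_i = x_{i+1} - x_i` per chromosome. This noise-level normalization is
#' invariant to additive offsets in either track and exactly inverts a
#' multiplicative rescaling of the mutant.
#'
#' @param wt,mut [probe_track]s on identical probe grids.
#' @return List with `factor`, `wt_mad`, `mut_mad` and `track` (the mutant
#'   with M-values multiplied by `factor`).
#' @export
scale_mutant_to_wt <- function(wt, mut) {
  pw <- wt$probes
  pm <- mut$probes
  if (nrow(pw) != nrow(pm) || any(pw$chrom != pm$chrom) ||
    any(pw$pos != pm$pos)) {
    stop("wildtype and mutant tracks must share the same probe grid")
  }
  lagged <- function(p) {
    unlist(lapply(split(p$m, p$chrom), diff), use.names = FALSE)
  }
  raw_mad <- function(d) median(abs(d - median(d)))
  wt_mad <- raw_mad(lagged(pw))
  mut_mad <- raw_mad(lagged(pm))
  if (!is.finite(mut_mad) || mut_mad == 0) {
    stop("degenerate mutant track: MAD of lagged differences is zero")
  }
  factor <- wt_mad / mut_mad
  out <- mut
  out$probes$m <- pm$m * factor
  list(factor = factor, wt_mad = wt_mad, mut_mad = mut_mad, track = out)
}

#' Quantile-normalize a set of probe tracks
#'
#' All tracks (which must share a probe count) are mapped onto the mean of
#' the sorted input vectors; ties are resolved by averaging the reference
#' values over the tied ranks, so output sorted vectors are identical
#' across tracks and the operation is idempotent.
#'
#' @param tracks list of [probe_track]s with equal probe counts.
#' @return List of quantile-normalized [probe_track]s.
#' @export
quantile_normalize <- function(tracks) {
  ns <- vapply(tracks, function(t) nrow(t$probes), numeric(1))
  if (length(unique(ns)) != 1) {
    stop("all tracks must have the same number of probes")
  }
  x <- vapply(tracks, function(t) t$probes$m, numeric(ns[1]))
  xn <- limma::normalizeQuantiles(x, ties = TRUE)
  out <- tracks
  for (j in seq_along(out)) out[[j]]$probes$m <- xn[, j]
  out
}
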