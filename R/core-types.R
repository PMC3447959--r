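#' Genomic interval constructor
#'
#' Creates a validated data frame of genomic intervals in the package-wide
#' coordinate convention: 0-based, half-open `[start, end)`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled). The unstranded `"."`
#'   is treated as `"+"` wherever an orientation is required.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand` and
#'   class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(!strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("interval coordinates must be finite")
  }
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start (half-open)")
  out <- data.frame(
    chrom = chrom, start = start, end = end, strand = strand,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Gene model collection constructor
#'
#' A gene model bundles the gene interval, its strand, an ordered
#' non-overlapping exon list, the transcription start/end sites and an
#' optional expression value. The TSS is `start` for `+`/`.` genes and
#' `end - 1` for `-` genes; the TES is the opposite end.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom,start,end,strand gene interval (0-based half-open).
#' @param exons named list (one element per gene) of two-column matrices
#'   `cbind(start, end)`, sorted, non-overlapping, contained in the gene
#'   interval. Defaults to single-exon genes spanning the interval.
#' @param expression optional non-negative expression values (RPKM/FPKM).
#' @return A `data.frame` with class `gene_models`; columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `tes`, `expression`, plus an
#'   `exons` list attribute keyed by `gene_id`. Rows are ordered by
#'   `(chrom, start, gene_id)`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = "+",
                        exons = NULL, expression = NA_real_) {
  iv <- genomic_intervals(chrom, start, end, strand)
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (length(gene_id) != nrow(iv)) stop("gene_id length mismatch")
  expression <- rep_len(as.numeric(expression), nrow(iv))
  if (any(expression < 0, na.rm = TRUE)) stop("expression must be >= 0")
  if (is.null(exons)) {
    exons <- lapply(seq_len(nrow(iv)), function(i) {
      cbind(start = iv$start[i], end = iv$end[i])
    })
    names(exons) <- gene_id
  }
  if (!all(gene_id %in% names(exons))) stop("exons must be named by gene_id")
  exons <- exons[gene_id]
  for (i in seq_along(gene_id)) {
    ex <- exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) {
      stop("gene '", gene_id[i], "' has zero exons")
    }
    if (any(ex[, 1] >= ex[, 2])) stop("exon end must be > start")
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("exons of gene '", gene_id[i], "' overlap or are unsorted")
    }
    if (ex[1, 1] < iv$start[i] || ex[nrow(ex), 2] > iv$end[i]) {
      stop("exons of gene '", gene_id[i], "' extend outside the gene")
    }
  }
  tss <- ifelse(iv$strand == "-", iv$end - 1, iv$start)
  tes <- ifelse(iv$strand == "-", iv$start, iv$end - 1)
  out <- data.frame(
    gene_id = gene_id, chrom = iv$chrom, start = iv$start, end = iv$end,
    strand = iv$strand, tss = tss, tes = tes, expression = expression,
    stringsAsFactors = FALSE
  )
  ord <- order(out$chrom, out$start, out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exons") <- exons[out$gene_id]
  class(out) <- c("gene_models", "data.frame")
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d genes on %d chromosome(s)\n",
    nrow(x), length(unique(x$chrom))
  ))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Exon list of a gene model collection
#' @param genes a `gene_models` object.
#' @return Named list of exon matrices (`start`, `end` columns).
#' @export
gene_exons <- function(genes) attr(genes, "exons")

#' Probe track constructor
#'
#' An ordered set of (position, M-value) probes for one mark in one
#' condition; M is the log2 ChIP/input ratio. Positions are 0-based bp and
#' must be strictly increasing within each chromosome.
#'
#' @param chrom,pos,m parallel vectors of probe chromosome, position (bp)
#'   and M-value (finite).
#' @param mark,condition track labels (e.g. `"HP1a"`, `"WT"`).
#' @return A list with class `probe_track` holding `mark`, `condition` and a
#'   `probes` data frame sorted by `(chrom, pos)`.
#' @export
probe_track <- function(chrom, pos, m, mark = "mark", condition = "WT") {
  chrom <- rep_len(as.character(chrom), length(pos))
  stopifnot(length(pos) == length(m))
  if (any(!is.finite(m))) stop("probe M-values must be finite")
  if (any(!is.finite(pos)) || any(pos < 0)) stop("probe positions invalid")
  p <- data.frame(
    chrom = as.character(chrom), pos = as.numeric(pos), m = as.numeric(m),
    stringsAsFactors = FALSE
  )
  p <- p[order(p$chrom, p$pos), , drop = FALSE]
  dup <- unlist(tapply(p$pos, p$chrom, function(v) c(FALSE, diff(v) <= 0)),
    use.names = FALSE
  )
  if (any(dup)) stop("probe positions must be strictly increasing per chrom")
  rownames(p) <- NULL
  structure(
    list(mark = mark, condition = condition, probes = p),
    class = "probe_track"
  )
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf(
    "<probe_track> %s [%s]: %d probes on %d chromosome(s)\n",
    x$mark, x$condition, nrow(x$probes), length(unique(x$probes$chrom))
  ))
  invisible(x)
}

#' Stranded per-base read-density track
#'
#' Run-on style read counts per bp, stored densely per chromosome and
#' strand.
#'
#' @param counts named list (per chromosome) of lists with integer vectors
#'   `plus` and `minus` of equal length (the chromosome length in bp).
#' @return Object of class `read_density`.
#' @export
read_density <- function(counts) {
  for (chrom in names(counts)) {
    x <- counts[[chrom]]
    if (!all(c("plus", "minus") %in% names(x))) {
      stop("each chromosome needs 'plus' and 'minus' count vectors")
    }
    if (length(x$plus) != length(x$minus)) {
      stop("strand vectors must have equal length for ", chrom)
    }
    if (any(x$plus < 0) || any(x$minus < 0)) stop("counts must be >= 0")
  }
  structure(list(counts = counts), class = "read_density")
}

#' @export
print.read_density <- function(x, ...) {
  for (chrom in names(x$counts)) {
    cat(sprintf(
      "<read_density> %s: %d bp, %d (+) / %d (-) reads\n", chrom,
      length(x$counts[[chrom]]$plus), sum(x$counts[[chrom]]$plus),
      sum(x$counts[[chrom]]$minus)
    ))
  }
  invisible(x)
}

#' Domain partition constructor
#'
#' Maps non-overlapping genomic intervals to domain labels. Genes are
#' assigned to the domain containing their TSS.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param label domain labels, conventionally from
#'   `c("euchromatin", "pericentric_heterochromatin", "chr4",
#'   "chr4_proximal")`.
#' @return A `data.frame` with class `domain_partition`.
#' @export
domain_partition <- function(chrom, start, end, label) {
  iv <- genomic_intervals(chrom, start, end)
  iv$strand <- NULL
  iv$label <- as.character(label)
  ord <- order(iv$chrom, iv$start)
  iv <- iv[ord, , drop = FALSE]
  by_chrom <- split(iv, iv$chrom)
  for (b in by_chrom) {
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("domain intervals must not overlap")
    }
  }
  rownames(iv) <- NULL
  class(iv) <- c("domain_partition", "data.frame")
  iv
}

#' Enriched region set constructor
#'
#' @param chrom,start,end region coordinates (0-based half-open), sorted and
#'   non-overlapping per chromosome.
#' @param score mean smoothed M-value of the region.
#' @param fdr FDR level the regions were called at.
#' @param n_probes optional number of significant probes per region.
#' @return A `data.frame` with class `region_set` and attribute `fdr`.
#' @export
region_set <- function(chrom, start, end, score, fdr = NA_real_,
                       n_probes = NA_integer_) {
  if (length(chrom) == 0) {
    out <- data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      score = numeric(), n_probes = integer(), stringsAsFactors = FALSE
    )
  } else {
    iv <- genomic_intervals(chrom, start, end)
    out <- data.frame(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      score = as.numeric(rep_len(score, nrow(iv))),
      n_probes = as.integer(rep_len(n_probes, nrow(iv))),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    by_chrom <- split(out, out$chrom)
    for (b in by_chrom) {
      if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
        stop("regions must be non-overlapping")
      }
    }
    rownames(out) <- NULL
  }
  attr(out, "fdr") <- fdr
  class(out) <- c("region_set", "data.frame")
  out
}

#' Expression table constructor
#'
#' @param gene_id gene identifiers.
#' @param value non-negative expression values.
#' @param unit `"RPKM"` or `"FPKM"`.
#' @return A `data.frame` with class `expression_table` and attribute
#'   `unit`.
#' @export
expression_table <- function(gene_id, value, unit = c("RPKM", "FPKM")) {
  unit <- match.arg(unit)
  value <- as.numeric(value)
  if (any(value < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  out <- data.frame(
    gene_id = as.character(gene_id), value = value,
    stringsAsFactors = FALSE
  )
  attr(out, "unit") <- unit
  class(out) <- c("expression_table", "data.frame")
  out
}
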