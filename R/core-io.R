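#' Read gene models from GFF3 or BED12
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention at the boundary; BED12 is already 0-based
#' half-open. Exons are assembled per gene (GFF3 `exon` features via their
#' `Parent` attribute, possibly through an mRNA level; BED12 blocks).
#' Genes are returned in deterministic `(chrom, start, gene_id)` order.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"gff3"` or `"bed"`.
#' @return A [gene_models] collection.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) {
      "gff3"
    } else "bed"
  }
  if (format == "gff3") read_gene_models_gff3(path) else read_gene_models_bed12(path)
}

read_gene_models_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in '", path, "': ",
      conditionMessage(e),
      call. = FALSE
    )
  )
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$strand[df$strand == "*"] <- "."
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no 'gene' features in ", path)
  # Map exon Parent -> gene: directly, or through an mRNA/transcript layer.
  parent_of <- function(x) vapply(x, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_gene <- setNames(parent_of(mrna$Parent), mrna$ID)
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(exons) > 0) {
    ep <- parent_of(exons$Parent)
    via_mrna <- ep %in% names(mrna_gene)
    ep[via_mrna] <- mrna_gene[ep[via_mrna]]
    exons$gene <- ep
  }
  exon_list <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    ex <- exons[!is.na(exons$gene) & exons$gene == gid, , drop = FALSE]
    if (nrow(ex) == 0) {
      stop("gene '", gid, "' has zero exons in ", path)
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    # GFF3 1-based inclusive -> 0-based half-open
    exon_list[[gid]] <- cbind(start = ex$start - 1, end = ex$end)
  }
  expr <- if ("expression" %in% names(genes)) {
    suppressWarnings(as.numeric(genes$expression))
  } else NA_real_
  gene_models(
    gene_id = genes$ID, chrom = genes$seqnames,
    start = genes$start - 1, end = genes$end, strand = genes$strand,
    exons = exon_list, expression = expr
  )
}

read_gene_models_bed12 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("BED parse error in '", path, "': ",
      conditionMessage(e),
      call. = FALSE
    )
  )
  df <- as.data.frame(gr)
  if (is.null(gr$name)) stop("BED12 input requires a name column")
  start0 <- df$start - 1 # rtracklayer converts BED to 1-based GRanges
  strand <- as.character(df$strand)
  strand[strand == "*"] <- "."
  exon_list <- list()
  has_blocks <- !is.null(gr$blocks)
  for (i in seq_len(nrow(df))) {
    if (has_blocks && length(gr$blocks[[i]]) > 0) {
      bl <- as.data.frame(gr$blocks[[i]]) # 1-based within gene
      bs <- start0[i] + bl$start - 1
      exon_list[[df$name[i]]] <- cbind(start = bs, end = bs + bl$width)
    } else {
      exon_list[[df$name[i]]] <-
        cbind(start = start0[i], end = df$end[i])
    }
  }
  gene_models(
    gene_id = df$name, chrom = as.character(df$seqnames),
    start = start0, end = df$end, strand = strand, exons = exon_list
  )
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature and its `exon` children per gene, 1-based
#' inclusive coordinates, records sorted by `(chrom, start, gene_id)`.
#'
#' @param genes a [gene_models] collection.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  exons <- gene_exons(genes)
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    strand <- if (g$strand == ".") "." else g$strand
    attrs <- sprintf("ID=%s", g$gene_id)
    if (!is.na(g$expression)) {
      attrs <- paste0(attrs, sprintf(";expression=%.17g", g$expression))
    }
    lines <- c(lines, paste(g$chrom, "hetdomain", "gene",
      format(g$start + 1, scientific = FALSE),
      format(g$end, scientific = FALSE),
      ".", strand, ".", attrs,
      sep = "\t"
    ))
    ex <- exons[[g$gene_id]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(g$chrom, "hetdomain", "exon",
        format(ex[j, 1] + 1, scientific = FALSE),
        format(ex[j, 2], scientific = FALSE),
        ".", strand, ".",
        sprintf("ID=%s.e%d;Parent=%s", g$gene_id, j, g$gene_id),
        sep = "\t"
      ))
    }
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read an enrichment track from bedGraph or WIG
#'
#' Interval-valued records (bedGraph, fixedStep/variableStep WIG with span)
#' are reduced to point probes at the interval midpoint (floor). Positions
#' must be strictly increasing per chromosome and values finite.
#'
#' @param path file path (`.bedgraph`/`.bg` or `.wig`).
#' @param mark,condition labels stored on the returned track.
#' @param format `"bedGraph"` or `"wig"`; inferred from the extension by
#'   default.
#' @return A [probe_track].
#' @export
read_track <- function(path, mark = "mark", condition = "WT",
                       format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop(
      "track parse error in '", path, "': ", conditionMessage(e),
      call. = FALSE
    )
  )
  df <- as.data.frame(gr)
  if (any(!is.finite(df$score))) stop("track contains non-finite values")
  # GRanges is 1-based inclusive; midpoint in 0-based coordinates
  pos <- floor(((df$start - 1) + df$end) / 2)
  probe_track(as.character(df$seqnames), pos, df$score,
    mark = mark, condition = condition
  )
}

#' Write a probe track as bedGraph
#'
#' Each probe becomes a 1-bp interval `[pos, pos + 1)` so that
#' write-then-read returns the identical track; values are printed with 17
#' significant digits (bit-exact decimal round-trip for doubles).
#'
#' @param track a [probe_track].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  p <- track$probes
  lines <- sprintf(
    "%s\t%s\t%s\t%.17g", p$chrom,
    format(p$pos, scientific = FALSE, trim = TRUE),
    format(p$pos + 1, scientific = FALSE, trim = TRUE), p$m
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read stranded read-density tracks from a bedGraph pair
#'
#' @param plus_path,minus_path bedGraph files of per-bp (or run-length
#'   compressed) counts for each strand.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return A [read_density] object.
#' @export
read_read_density <- function(plus_path, minus_path, chrom_lengths) {
  expand <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    df <- as.data.frame(gr)
    out <- lapply(names(chrom_lengths), function(chrom) {
      v <- integer(chrom_lengths[[chrom]])
      sub <- df[df$seqnames == chrom, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        v[sub$start[i]:sub$end[i]] <- as.integer(sub$score[i])
      }
      v
    })
    names(out) <- names(chrom_lengths)
    out
  }
  plus <- expand(plus_path)
  minus <- expand(minus_path)
  read_density(setNames(lapply(names(chrom_lengths), function(chrom) {
    list(plus = plus[[chrom]], minus = minus[[chrom]])
  }), names(chrom_lengths)))
}

#' Write stranded read-density tracks as a bedGraph pair
#'
#' Runs of equal counts are collapsed; zero runs are omitted.
#'
#' @param rd a [read_density] object.
#' @param plus_path,minus_path output file paths.
#' @return The two paths, invisibly.
#' @export
write_read_density <- function(rd, plus_path, minus_path) {
  emit <- function(get_strand, path) {
    lines <- character(0)
    for (chrom in names(rd$counts)) {
      v <- get_strand(rd$counts[[chrom]])
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        lines <- c(lines, sprintf(
          "%s\t%d\t%d\t%d", chrom, starts[keep], ends[keep],
          r$values[keep]
        ))
      }
    }
    writeLines(lines, path)
  }
  emit(function(x) x$plus, plus_path)
  emit(function(x) x$minus, minus_path)
  invisible(c(plus_path, minus_path))
}

#' Read or write a domain partition as BED
#'
#' @param path BED file with the domain label in the name column.
#' @return A [domain_partition].
#' @export
read_domains <- function(path) {
  df <- read.delim(path,
    header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE
  )
  domain_partition(df[[1]], df[[2]], df[[3]], df[[4]])
}

#' @rdname read_domains
#' @param domains a [domain_partition].
#' @export
write_domains <- function(domains, path) {
  lines <- sprintf(
    "%s\t%s\t%s\t%s", domains$chrom,
    format(domains$start, scientific = FALSE, trim = TRUE),
    format(domains$end, scientific = FALSE, trim = TRUE), domains$label
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write an enriched region set as BED with score column
#'
#' @param regions a [region_set].
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  lines <- sprintf(
    "%s\t%s\t%s\tregion_%d\t%.6g", regions$chrom,
    format(regions$start, scientific = FALSE, trim = TRUE),
    format(regions$end, scientific = FALSE, trim = TRUE),
    seq_len(nrow(regions)), regions$score
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read/write an expression table (TSV: gene_id, value)
#'
#' @param path TSV path with header `gene_id<TAB>value`.
#' @param unit `"RPKM"` or `"FPKM"`.
#' @return An [expression_table].
#' @export
read_expression <- function(path, unit = c("RPKM", "FPKM")) {
  unit <- match.arg(unit)
  df <- read.delim(path, stringsAsFactors = FALSE)
  expression_table(df$gene_id, df$value, unit = unit)
}

#' @rdname read_expression
#' @param tbl an [expression_table].
#' @export
write_expression <- function(tbl, path) {
  out <- data.frame(gene_id = tbl$gene_id, value = sprintf("%.17g", tbl$value))
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("gene_id", "value")
  )
  invisible(path)
}

#' Assign each gene to the domain containing its TSS
#'
#' Containment follows the half-open rule: a TSS equal to an interval start
#' belongs to that interval. A TSS covered by no interval yields the
#' explicit label `"unassigned"`.
#'
#' @param genes a [gene_models] collection.
#' @param domains a [domain_partition].
#' @return Character vector of domain labels parallel to `genes` rows.
#' @export
assign_domain <- function(genes, domains) {
  labels <- rep("unassigned", nrow(genes))
  for (chrom in unique(genes$chrom)) {
    gi <- which(genes$chrom == chrom)
    d <- domains[domains$chrom == chrom, , drop = FALSE]
    if (nrow(d) == 0) next
    idx <- findInterval(genes$tss[gi], d$start)
    hit <- idx >= 1 & genes$tss[gi] < ifelse(idx >= 1, d$end[pmax(idx, 1)], 0)
    labels[gi[hit]] <- d$label[idx[hit]]
  }
  labels
}
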