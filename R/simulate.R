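#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generators. The defaults
#' emulate the genomic structure the analysis assumes: a 1.2 Mb
#' repeat-rich autosomal arm (`chr4`, ~80 large multi-exon genes, ~30%
#' repeat density) preceded by a 70 kb pericentric-like proximal block, a
#' euchromatic arm (`chrE`, 2,000 smaller genes, low repeat density) and a
#' pericentric heterochromatin region (`chrH`). Mark architecture plants
#' gene-body enrichment of HP1a/H3K9me3/POF on active `chr4` genes with TSS
#' depletion; mutant conditions apply feature-class-specific multiplicative
#' retention factors (e.g. H3K9me2 retained at 11.1% and H3K9me3 at 33.3%
#' of wildtype on `chr4` under HP1a loss).
#'
#' @param seed master integer seed; each generator derives a labelled
#'   sub-stream (`seed + k`) so stages are reproducible independently.
#' @param ... overrides for any top-level configuration element.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    domains = data.frame(
      chrom = c("chr4", "chr4", "chrE", "chrH"),
      start = c(0, 70000, 0, 0),
      end = c(70000, 1281640, 8e6, 8e5),
      label = c(
        "chr4_proximal", "chr4", "euchromatin",
        "pericentric_heterochromatin"
      ),
      stringsAsFactors = FALSE
    ),
    gene_params = data.frame(
      domain = c(
        "chr4", "euchromatin", "pericentric_heterochromatin",
        "chr4_proximal"
      ),
      n_genes = c(80, 2000, 120, 6),
      median_length = c(8001, 1907, 1844, 1844),
      sdlog = c(0.45, 0.55, 0.55, 0.45),
      median_exons = c(6, 3, 2, 2),
      active_fraction = c(0.55, 0.5, 0.45, 0.4),
      stringsAsFactors = FALSE
    ),
    repeat_density = c(
      chr4 = 0.30, chr4_proximal = 0.45, euchromatin = 0.05,
      pericentric_heterochromatin = 0.45
    ),
    repeat_mean_length = 400,
    min_gene_length = 600,
    probe_spacing = 100,
    noise_sd = 0.3, # background M-value noise SD (free parameter)
    marks = c("HP1a", "H3K9me2", "H3K9me3", "POF", "H3K36me3", "PolII"),
    mark_architecture = default_mark_architecture(),
    mutant_effects = default_mutant_effects(),
    polii = list(
      peak_height = 2, peak_sd = 150,
      tss_shift = c(WT = 0, hp1a_mut = 68, pof_mut = 50, egg_mut = 0)
    ),
    pausing = list(
      fraction = c(
        euchromatin = 0.15, pericentric_heterochromatin = 0.125,
        chr4 = 0.02, chr4_proximal = 0.05
      ),
      multiplier = 150, window = 50, offset = 25,
      lambda_body = 0.2, background = 0
    ),
    motifs = list(
      TRL = list(pattern = "GAGAG", window = c(-200, 200), rates = c(
        chr4 = 0.11, euchromatin = 0.24,
        pericentric_heterochromatin = 0.20, chr4_proximal = 0.15
      )),
      iTRL = list(pattern = "CTCTC", window = c(-200, 200), rates = c(
        chr4 = 0.13, euchromatin = 0.25,
        pericentric_heterochromatin = 0.20, chr4_proximal = 0.15
      )),
      PB = list(pattern = "KCGRWCG", window = c(-60, 60), rates = c(
        chr4 = 0.35, euchromatin = 0.35,
        pericentric_heterochromatin = 0.35, chr4_proximal = 0.35
      )),
      Inr = list(pattern = "TCAGTY", window = c(-200, 200), rates = c(
        chr4 = 0.40, euchromatin = 0.40,
        pericentric_heterochromatin = 0.40, chr4_proximal = 0.40
      ))
    ),
    gc_content = c(
      chr4 = 0.35, chr4_proximal = 0.38, euchromatin = 0.45,
      pericentric_heterochromatin = 0.42
    ),
    promoter_flank = 200,
    expression = list(
      unit = "RPKM", context = "cell_line",
      active_meanlog = 0.5, active_sdlog = 1
    ),
    mutant_expression = list(
      condition = "hp1a_mut",
      down_fraction = c(
        chr4 = 0.8, chr4_proximal = 0.0, euchromatin = 0.0,
        pericentric_heterochromatin = 0.0
      ),
      down_factor_range = c(0.3, 0.7),
      up_factor_range = c(1.05, 1.6),
      noise_sdlog = 0.05
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config element(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (any(cfg$repeat_density < 0 | cfg$repeat_density > 1)) {
    stop("repeat densities must lie in [0, 1]")
  }
  pf <- cfg$pausing$fraction
  if (any(pf < 0 | pf > 1)) stop("pausing fractions must lie in [0, 1]")
  if (cfg$pausing$multiplier < 1) {
    stop("pause multiplier must be >= 1 (a pause elevates 5' density)")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (any(cfg$mutant_effects$retention < 0)) {
    stop("retention factors must be >= 0")
  }
  for (m in names(cfg$motifs)) {
    r <- cfg$motifs[[m]]$rates
    if (any(r < 0 | r > 1)) stop("motif planting rates must lie in [0, 1]")
    w <- cfg$motifs[[m]]$window
    if (diff(w) < nchar(cfg$motifs[[m]]$pattern)) {
      stop("motif scan window shorter than motif: ", m)
    }
  }
  af <- cfg$gene_params$active_fraction
  if (any(af < 0 | af > 1)) stop("active fractions must lie in [0, 1]")
  invisible(cfg)
}

# Planted per-(mark, domain, feature-class) M-value means. Classes: tss
# (TSS +/- 500 bp of active genes), body (active gene body), silent
# (silent genes and intergenic non-repeat), repeat.
default_mark_architecture <- function() {
  arch <- function(mark, domain, tss, body, silent, rep_) {
    data.frame(
      mark = mark, domain = domain,
      feature_class = c("tss", "body", "silent", "repeat"),
      mean = c(tss, body, silent, rep_), stringsAsFactors = FALSE
    )
  }
  peri <- function(mark, tss, body, silent, rep_) {
    rbind(
      arch(mark, "pericentric_heterochromatin", tss, body, silent, rep_),
      arch(mark, "chr4_proximal", tss, body, silent, rep_)
    )
  }
  rbind(
    # chr4: silencing marks over active gene bodies, depleted at TSS
    arch("HP1a", "chr4", 0.2, 2.0, 0.5, 1.5),
    arch("H3K9me3", "chr4", 0.2, 1.5, 0.5, 1.2),
    arch("H3K9me2", "chr4", 0.1, 0.4, 1.0, 1.5),
    arch("POF", "chr4", 0.4, 1.8, 0.0, 0.0),
    arch("H3K36me3", "chr4", 0.2, 1.5, 0.0, 0.0),
    arch("PolII", "chr4", 1.2, 1.0, 0.0, 0.0),
    # pericentric-like domains: classical heterochromatin everywhere
    peri("HP1a", 0.3, 0.8, 1.8, 2.0),
    peri("H3K9me3", 0.3, 1.5, 1.8, 2.0),
    peri("H3K9me2", 0.3, 1.5, 1.8, 2.0),
    peri("POF", 0, 0, 0, 0),
    peri("H3K36me3", 0.2, 1.2, 0.0, 0.0),
    peri("PolII", 1.2, 1.0, 0.0, 0.0),
    # euchromatin: no silencing marks, active marks on expressed genes
    arch("HP1a", "euchromatin", 0, 0, 0, 0),
    arch("H3K9me3", "euchromatin", 0, 0, 0, 0),
    arch("H3K9me2", "euchromatin", 0, 0, 0, 0),
    arch("POF", "euchromatin", 0, 0, 0, 0),
    arch("H3K36me3", "euchromatin", 0.2, 1.5, 0.0, 0.0),
    arch("PolII", "euchromatin", 1.2, 1.0, 0.0, 0.0)
  )
}

# Multiplicative retention of the planted class mean in each mutant;
# "all" matches any domain / feature class; the most specific row wins.
default_mutant_effects <- function() {
  eff <- function(condition, mark, domain, feature_class, retention) {
    data.frame(
      condition = condition, mark = mark, domain = domain,
      feature_class = feature_class, retention = retention,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    # HP1a-null: HP1a gone; H3K9me2 to 11.1% and H3K9me3 to 33.3% of WT
    # on chr4; POF unaffected; Pol II lost from chr4 gene bodies only.
    eff("hp1a_mut", "HP1a", "all", "all", 0.06),
    eff("hp1a_mut", "H3K9me2", "chr4", "all", 0.111),
    eff("hp1a_mut", "H3K9me3", "chr4", "all", 0.333),
    eff("hp1a_mut", "H3K9me2", "pericentric_heterochromatin", "all", 0.5),
    eff("hp1a_mut", "H3K9me3", "pericentric_heterochromatin", "all", 0.5),
    eff("hp1a_mut", "PolII", "chr4", "body", 0.3),
    # pof-null: gene-body HP1a lost, repeat-associated HP1a retained;
    # H3K9me2/3 reduced on active chr4 regions, unchanged when silent.
    eff("pof_mut", "POF", "all", "all", 0.15),
    eff("pof_mut", "HP1a", "chr4", "tss", 0.1),
    eff("pof_mut", "HP1a", "chr4", "body", 0.1),
    eff("pof_mut", "HP1a", "chr4", "silent", 0.3),
    eff("pof_mut", "HP1a", "chr4", "repeat", 1.0),
    eff("pof_mut", "H3K9me2", "chr4", "tss", 0.63),
    eff("pof_mut", "H3K9me2", "chr4", "body", 0.63),
    eff("pof_mut", "H3K9me3", "chr4", "tss", 0.51),
    eff("pof_mut", "H3K9me3", "chr4", "body", 0.51),
    eff("pof_mut", "PolII", "chr4", "body", 0.3),
    # egg-null: POF, HP1a and H3K9 methylation lost from chr4 genes but
    # retained at repeats and in the proximal pericentric-like block.
    eff("egg_mut", "POF", "chr4", "all", 0.37),
    eff("egg_mut", "HP1a", "chr4", "tss", 0.21),
    eff("egg_mut", "HP1a", "chr4", "body", 0.21),
    eff("egg_mut", "HP1a", "chr4", "silent", 0.21),
    eff("egg_mut", "H3K9me2", "chr4", "tss", 0.39),
    eff("egg_mut", "H3K9me2", "chr4", "body", 0.39),
    eff("egg_mut", "H3K9me3", "chr4", "tss", 0.16),
    eff("egg_mut", "H3K9me3", "chr4", "body", 0.16)
  )
}

domain_lengths <- function(cfg) {
  setNames(cfg$domains$end - cfg$domains$start, cfg$domains$label)
}

#' Chromosome lengths implied by a simulation config
#' @param cfg a [sim_config].
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
sim_chrom_lengths <- function(cfg) {
  tapply(cfg$domains$end, cfg$domains$chrom, max)
}

expressed_threshold_value <- function(unit, context) {
  if (unit == "FPKM") {
    2^1.4 - 1
  } else if (context == "larvae") {
    10^0.4 - 1
  } else {
    10^0.6 - 1
  }
}

#' Generate a synthetic annotation
#'
#' Places non-overlapping multi-exon genes by sequential packing with
#' uniform random gaps within each domain, then fills intergenic space
#' (and, if the target density requires it, introns) with repeat
#' intervals. Wildtype expression values are drawn per gene so that the
#' configured active fraction exceeds the expressed threshold.
#'
#' @param cfg a [sim_config].
#' @return List with elements `genes` ([gene_models] with expression),
#'   `repeats` ([genomic_intervals]), `domains` ([domain_partition]) and
#'   `seed`.
#' @export
generate_annotation <- function(cfg) {
  set.seed(cfg$seed + 1L)
  doms <- cfg$domains
  thr <- expressed_threshold_value(
    cfg$expression$unit,
    cfg$expression$context
  )
  all_genes <- list()
  rep_chrom <- character(0)
  rep_start <- numeric(0)
  rep_end <- numeric(0)
  for (di in seq_len(nrow(doms))) {
    dom <- doms[di, ]
    gp <- cfg$gene_params[cfg$gene_params$domain == dom$label, ]
    if (nrow(gp) == 0) next
    n <- gp$n_genes
    dom_len <- dom$end - dom$start
    lens <- pmax(
      cfg$min_gene_length,
      round(rlnorm(n, log(gp$median_length), gp$sdlog))
    )
    free <- dom_len - sum(lens)
    if (free < 0) {
      stop(
        "infeasible packing in domain '", dom$label,
        "': genes exceed domain length"
      )
    }
    gaps <- floor(free * {
      u <- runif(n + 1)
      cumsum(u) / sum(u)
    })
    gaps <- diff(c(0, gaps))
    starts <- dom$start + cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n]))
    ends <- starts + lens
    strands <- sample(c("+", "-"), n, replace = TRUE)
    prefix <- c(
      chr4 = "four", euchromatin = "eu",
      pericentric_heterochromatin = "het", chr4_proximal = "prox"
    )[dom$label]
    ids <- sprintf("%s_g%04d", prefix, seq_len(n))
    n_ex <- pmax(1L, 1L + rpois(n, gp$median_exons - 1))
    exon_list <- list()
    for (i in seq_len(n)) {
      k <- n_ex[i]
      L <- lens[i]
      k <- min(k, floor((L + 1) / 2)) # need 2k-1 segments of >= 1 bp
      if (k == 1) {
        exon_list[[ids[i]]] <- cbind(start = starts[i], end = ends[i])
      } else {
        cuts <- sort(sample(seq_len(L - 1), 2 * k - 2))
        bounds <- c(0, cuts, L)
        seg_start <- starts[i] + bounds[-length(bounds)]
        seg_end <- starts[i] + bounds[-1]
        keep <- seq(1, 2 * k - 1, by = 2) # odd segments are exons
        exon_list[[ids[i]]] <-
          cbind(start = seg_start[keep], end = seg_end[keep])
      }
    }
    active <- runif(n) < gp$active_fraction
    expr <- numeric(n)
    expr[active] <- thr * (1 + rlnorm(
      sum(active),
      cfg$expression$active_meanlog, cfg$expression$active_sdlog
    ))
    expr[!active] <- thr * runif(sum(!active))^2
    all_genes[[dom$label]] <- list(
      ids = ids, chrom = dom$chrom, starts = starts, ends = ends,
      strands = strands, exons = exon_list, expr = expr
    )
    # Repeats: fill intergenic gaps first, then introns if needed.
    target <- cfg$repeat_density[[dom$label]] * dom_len
    if (is.null(target) || is.na(target)) target <- 0
    placed <- 0
    gap_start <- c(dom$start, ends)
    gap_end <- c(starts, dom$end)
    slots <- data.frame(start = gap_start, end = gap_end)
    slots <- slots[slots$end - slots$start >= 50, , drop = FALSE]
    add_repeats_into <- function(slots, placed, target) {
      slots <- slots[sample(nrow(slots)), , drop = FALSE]
      for (si in seq_len(nrow(slots))) {
        if (placed >= target) break
        at <- slots$start[si]
        slot_end <- slots$end[si]
        while (placed < target && at < slot_end - 50) {
          spacer <- floor(rexp(1, 1 / 100))
          L <- max(50, min(
            round(rexp(1, 1 / cfg$repeat_mean_length)),
            slot_end - at - spacer
          ))
          s <- at + spacer
          if (s + L > slot_end) break
          rep_chrom <<- c(rep_chrom, dom$chrom)
          rep_start <<- c(rep_start, s)
          rep_end <<- c(rep_end, s + L)
          placed <- placed + L
          at <- s + L
        }
      }
      placed
    }
    if (target > 0 && nrow(slots) > 0) {
      placed <- add_repeats_into(slots, placed, target)
    }
    if (placed < target * 0.95) {
      # introns as secondary space
      introns <- do.call(rbind, lapply(ids, function(id) {
        ex <- exon_list[[id]]
        if (nrow(ex) < 2) {
          return(NULL)
        }
        data.frame(start = ex[-nrow(ex), 2], end = ex[-1, 1])
      }))
      if (!is.null(introns)) {
        introns <- introns[introns$end - introns$start >= 100, , drop = FALSE]
        if (nrow(introns) > 0) {
          placed <- add_repeats_into(introns, placed, target)
        }
      }
    }
  }
  ids <- unlist(lapply(all_genes, `[[`, "ids"), use.names = FALSE)
  genes <- gene_models(
    gene_id = ids,
    chrom = unlist(lapply(all_genes, function(g) {
      rep(g$chrom, length(g$ids))
    }), use.names = FALSE),
    start = unlist(lapply(all_genes, `[[`, "starts"), use.names = FALSE),
    end = unlist(lapply(all_genes, `[[`, "ends"), use.names = FALSE),
    strand = unlist(lapply(all_genes, `[[`, "strands"), use.names = FALSE),
    exons = do.call(c, unname(lapply(all_genes, `[[`, "exons"))),
    expression = unlist(lapply(all_genes, `[[`, "expr"), use.names = FALSE)
  )
  repeats <- if (length(rep_chrom) > 0) {
    iv <- genomic_intervals(rep_chrom, rep_start, rep_end)
    iv[order(iv$chrom, iv$start), , drop = FALSE]
  } else {
    genomic_intervals(character(0), numeric(0), numeric(0))[0, ]
  }
  rownames(repeats) <- NULL
  domains <- domain_partition(doms$chrom, doms$start, doms$end, doms$label)
  list(genes = genes, repeats = repeats, domains = domains, seed = cfg$seed)
}

# Per-probe feature class with priority tss > body > repeat > silent.
classify_positions <- function(pos, chrom, annotation, threshold,
                               tss_halfwin = 500) {
  genes <- annotation$genes
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  active <- g$expression > threshold
  cls <- rep("silent", length(pos))
  reps <- annotation$repeats
  reps <- reps[reps$chrom == chrom, , drop = FALSE]
  if (nrow(reps) > 0) {
    idx <- findInterval(pos, reps$start)
    inrep <- idx >= 1 & pos < c(0, reps$end)[idx + 1]
    cls[inrep] <- "repeat"
  }
  ga <- g[active, , drop = FALSE]
  if (nrow(ga) > 0) {
    o <- order(ga$start)
    ga <- ga[o, , drop = FALSE]
    idx <- findInterval(pos, ga$start)
    inbody <- idx >= 1 & pos < c(0, ga$end)[idx + 1]
    cls[inbody] <- "body"
    ts <- sort(pmax(0, ga$tss - tss_halfwin))
    te <- sort(ga$tss + tss_halfwin + 1)
    # tss windows may overlap; use coverage counting
    ev <- rbind(
      data.frame(p = ts, d = 1),
      data.frame(p = te, d = -1)
    )
    ev <- ev[order(ev$p), , drop = FALSE]
    cum <- cumsum(ev$d)
    idx2 <- findInterval(pos, ev$p)
    intss <- idx2 >= 1 & cum[pmax(idx2, 1)] > 0
    cls[intss] <- "tss"
  }
  cls
}

lookup_retention <- function(effects, condition, mark, domain, classes) {
  ret <- rep(1, length(classes))
  e <- effects[effects$condition == condition & effects$mark == mark, ,
    drop = FALSE
  ]
  if (nrow(e) == 0) {
    return(ret)
  }
  e <- e[e$domain %in% c("all", domain), , drop = FALSE]
  if (nrow(e) == 0) {
    return(ret)
  }
  # generic rows first, specific feature-class rows override
  for (i in order(e$feature_class != "all")) {
    if (e$feature_class[i] == "all") {
      ret[] <- e$retention[i]
    } else {
      ret[classes == e$feature_class[i]] <- e$retention[i]
    }
  }
  ret
}

#' Generate enrichment probe tracks
#'
#' Probe M-values are the planted feature-class mean plus Gaussian noise;
#' mutant conditions multiply the class mean by the configured retention
#' factor. The Pol II track additionally carries a Gaussian TSS-proximal
#' peak whose centre can shift downstream in mutants (the planted
#' peak-shift architecture).
#'
#' @param cfg a [sim_config].
#' @param annotation output of [generate_annotation()].
#' @param marks marks to generate (default all configured).
#' @param conditions conditions to generate (default `"WT"` plus all
#'   conditions appearing in `cfg$mutant_effects`).
#' @return Named list of [probe_track] objects, keyed `"<mark>.<condition>"`.
#' @export
generate_tracks <- function(cfg, annotation, marks = cfg$marks,
                            conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- c("WT", unique(cfg$mutant_effects$condition))
  }
  known <- c("WT", unique(cfg$mutant_effects$condition))
  if (any(!conditions %in% known)) {
    stop(
      "unknown condition(s): ",
      paste(setdiff(conditions, known), collapse = ", ")
    )
  }
  if (any(!marks %in% cfg$marks)) {
    stop(
      "unknown mark(s): ",
      paste(setdiff(marks, cfg$marks), collapse = ", ")
    )
  }
  set.seed(cfg$seed + 2L)
  thr <- expressed_threshold_value(
    cfg$expression$unit,
    cfg$expression$context
  )
  lens <- sim_chrom_lengths(cfg)
  arch <- cfg$mark_architecture
  # probe grid + class/domain labels, shared across tracks
  grid <- list()
  for (chrom in names(lens)) {
    pos <- seq(cfg$probe_spacing / 2, lens[[chrom]] - 1, cfg$probe_spacing)
    cls <- classify_positions(pos, chrom, annotation, thr)
    d <- annotation$domains[annotation$domains$chrom == chrom, ,
      drop = FALSE
    ]
    idx <- findInterval(pos, d$start)
    dom <- rep(NA_character_, length(pos))
    hit <- idx >= 1 & pos < c(0, d$end)[idx + 1]
    dom[hit] <- d$label[idx[hit]]
    grid[[chrom]] <- list(pos = pos, cls = cls, dom = dom)
  }
  # per-gene TSS peak support for Pol II
  genes <- annotation$genes
  active_genes <- genes[genes$expression > thr, , drop = FALSE]
  gene_dom <- assign_domain(active_genes, annotation$domains)
  out <- list()
  for (mark in marks) {
    for (condition in conditions) {
      chroms <- names(lens)
      vals <- list()
      for (chrom in chroms) {
        g <- grid[[chrom]]
        mu <- numeric(length(g$pos))
        for (dlab in unique(g$dom[!is.na(g$dom)])) {
          a <- arch[arch$mark == mark & arch$domain == dlab, , drop = FALSE]
          if (nrow(a) == 0) next
          m <- setNames(a$mean, a$feature_class)
          sel <- !is.na(g$dom) & g$dom == dlab
          base <- unname(m[g$cls[sel]])
          base[is.na(base)] <- 0
          ret <- if (condition == "WT") {
            rep(1, sum(sel))
          } else {
            lookup_retention(
              cfg$mutant_effects, condition, mark, dlab,
              g$cls[sel]
            )
          }
          mu[sel] <- base * ret
        }
        if (mark == "PolII" && nrow(active_genes) > 0) {
          ag <- active_genes[active_genes$chrom == chrom, , drop = FALSE]
          agd <- gene_dom[active_genes$chrom == chrom]
          shift <- cfg$polii$tss_shift[[condition]]
          if (is.null(shift) || is.na(shift)) shift <- 0
          for (i in seq_len(nrow(ag))) {
            sgn <- if (ag$strand[i] == "-") -1 else 1
            sh <- if (!is.na(agd[i]) && agd[i] %in% c("chr4", "chr4_proximal")) {
              shift
            } else {
              0
            }
            win <- which(abs(g$pos - ag$tss[i]) <= 800)
            if (length(win) == 0) next
            d <- (g$pos[win] - ag$tss[i]) * sgn
            mu[win] <- mu[win] + cfg$polii$peak_height *
              exp(-(d - sh)^2 / (2 * cfg$polii$peak_sd^2))
          }
        }
        vals[[chrom]] <- mu + rnorm(length(mu), 0, cfg$noise_sd)
      }
      key <- paste(mark, condition, sep = ".")
      out[[key]] <- probe_track(
        chrom = rep(chroms, vapply(chroms, function(ch) {
          length(grid[[ch]]$pos)
        }, numeric(1))),
        pos = unlist(lapply(chroms, function(ch) grid[[ch]]$pos),
          use.names = FALSE
        ),
        m = unlist(vals[chroms], use.names = FALSE),
        mark = mark, condition = condition
      )
    }
  }
  out
}

#' Generate a stranded run-on read-density track
#'
#' Active genes receive Poisson per-bp counts at the body rate on the gene
#' strand; genes planted as paused additionally receive
#' `Poisson(lambda_body * multiplier)` counts over the pause window
#' (default 50 bp starting 25 bp downstream of the TSS). Silent genes and
#' intergenic positions carry only the background rate.
#'
#' @param cfg a [sim_config].
#' @param annotation output of [generate_annotation()].
#' @return A [read_density] with attributes `paused_genes` (planted paused
#'   gene ids) and `active_genes`.
#' @export
generate_readdensity <- function(cfg, annotation) {
  if (cfg$pausing$multiplier < 1) {
    stop("pause multiplier must be >= 1")
  }
  set.seed(cfg$seed + 3L)
  thr <- expressed_threshold_value(
    cfg$expression$unit,
    cfg$expression$context
  )
  lens <- sim_chrom_lengths(cfg)
  genes <- annotation$genes
  dom <- assign_domain(genes, annotation$domains)
  active <- genes$expression > thr
  frac <- cfg$pausing$fraction
  paused <- active & runif(nrow(genes)) <
    ifelse(dom %in% names(frac), frac[dom], 0)
  counts <- list()
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    bg <- cfg$pausing$background
    plus <- if (bg > 0) rpois(L, bg) else integer(L)
    minus <- if (bg > 0) rpois(L, bg) else integer(L)
    gi <- which(genes$chrom == chrom & active)
    for (i in gi) {
      gl <- genes$end[i] - genes$start[i]
      body <- rpois(gl, cfg$pausing$lambda_body)
      if (paused[i]) {
        w0 <- cfg$pausing$offset
        w1 <- min(gl, w0 + cfg$pausing$window)
        if (w1 > w0) {
          body[(w0 + 1):w1] <- body[(w0 + 1):w1] +
            rpois(w1 - w0, cfg$pausing$lambda_body * cfg$pausing$multiplier)
        }
      }
      span <- (genes$start[i] + 1):genes$end[i]
      if (genes$strand[i] == "-") {
        minus[span] <- minus[span] + rev(body)
      } else {
        plus[span] <- plus[span] + body
      }
    }
    counts[[chrom]] <- list(plus = plus, minus = minus)
  }
  rd <- read_density(counts)
  attr(rd, "paused_genes") <- genes$gene_id[paused]
  attr(rd, "active_genes") <- genes$gene_id[active]
  rd
}

iupac_table <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G")
  )
}

sample_iupac_instance <- function(pattern) {
  tab <- iupac_table()
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- tab[[ch]]
    if (is.null(opts)) stop("invalid IUPAC code: ", ch)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Generate promoter sequences
#'
#' Promoters are TSS +/- `promoter_flank` bp, strand-oriented (position
#' `promoter_flank + 1` of each sequence is the TSS base). Background is
#' i.i.d. at the domain GC content; each promoter independently receives a
#' planted instance of each configured motif with its domain's rate, at a
#' uniform position inside the motif's scan window.
#'
#' @param cfg a [sim_config].
#' @param annotation output of [generate_annotation()].
#' @return A `Biostrings::DNAStringSet` named by gene id, with a
#'   `domains` attribute (named character vector gene -> domain label).
#' @export
generate_sequences <- function(cfg, annotation) {
  set.seed(cfg$seed + 4L)
  genes <- annotation$genes
  dom <- assign_domain(genes, annotation$domains)
  flank <- cfg$promoter_flank
  seq_len_total <- 2 * flank
  seqs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gc <- cfg$gc_content[[dom[i]]]
    if (is.null(gc) || is.na(gc)) gc <- 0.45
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- sample(names(p), seq_len_total, replace = TRUE, prob = p)
    occupied <- logical(seq_len_total)
    for (mname in names(cfg$motifs)) {
      m <- cfg$motifs[[mname]]
      rate <- m$rates[[dom[i]]]
      if (is.null(rate) || is.na(rate)) rate <- 0
      if (runif(1) >= rate) next
      inst <- strsplit(sample_iupac_instance(m$pattern), "")[[1]]
      # window in TSS-relative coordinates; sequence index = offset + flank + 1
      lo <- max(m$window[1], -flank)
      hi <- min(m$window[2], flank) - length(inst)
      if (hi < lo) next
      # avoid clobbering a previously planted instance
      for (try in 1:50) {
        at <- sample(lo:hi, 1) + flank + 1
        idx <- at:(at + length(inst) - 1)
        if (!any(occupied[idx])) {
          s[idx] <- inst
          occupied[idx] <- TRUE
          break
        }
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  out <- Biostrings::DNAStringSet(setNames(seqs, genes$gene_id))
  attr(out, "domains") <- setNames(dom, genes$gene_id)
  out
}

#' Generate wildtype and mutant expression tables
#'
#' Wildtype values come from the annotation (log-normal, with the
#' configured active fraction above the expressed threshold). The mutant
#' table multiplies a configurable fraction of `chr4` genes by a
#' down-scaling factor; the remaining genes in affected domains receive a
#' mild up-scaling (matching the observed minority of increased genes),
#' and all mutant values carry small log-normal measurement noise.
#'
#' @param cfg a [sim_config].
#' @param annotation output of [generate_annotation()].
#' @return List with `wt` and `mut` [expression_table]s, the mutant
#'   `condition`, and `down_genes` (ids planted as down-regulated).
#' @export
generate_expression <- function(cfg, annotation) {
  set.seed(cfg$seed + 5L)
  genes <- annotation$genes
  dom <- assign_domain(genes, annotation$domains)
  me <- cfg$mutant_expression
  downf <- ifelse(dom %in% names(me$down_fraction),
    me$down_fraction[dom], 0
  )
  is_down <- runif(nrow(genes)) < downf
  factor <- rep(1, nrow(genes))
  factor[is_down] <- runif(
    sum(is_down), me$down_factor_range[1],
    me$down_factor_range[2]
  )
  affected_dom <- names(me$down_fraction)[me$down_fraction > 0]
  is_up <- !is_down & dom %in% affected_dom
  factor[is_up] <- runif(
    sum(is_up), me$up_factor_range[1],
    me$up_factor_range[2]
  )
  noise <- exp(rnorm(nrow(genes), 0, me$noise_sdlog))
  unit <- cfg$expression$unit
  list(
    wt = expression_table(genes$gene_id, genes$expression, unit = unit),
    mut = expression_table(genes$gene_id, genes$expression * factor * noise,
      unit = unit
    ),
    condition = me$condition,
    down_genes = genes$gene_id[is_down]
  )
}

#' Run every generator for one configuration
#'
#' @param cfg a [sim_config].
#' @param tracks,readdensity,sequences,expression logical switches to skip
#'   individual generators.
#' @return List with `config`, `annotation`, `tracks`, `readdensity`,
#'   `sequences`, `expression`.
#' @export
simulate_dataset <- function(cfg = sim_config(), tracks = TRUE,
                             readdensity = TRUE, sequences = TRUE,
                             expression = TRUE) {
  ann <- generate_annotation(cfg)
  list(
    config = cfg,
    annotation = ann,
    tracks = if (tracks) generate_tracks(cfg, ann),
    readdensity = if (readdensity) generate_readdensity(cfg, ann),
    sequences = if (sequences) generate_sequences(cfg, ann),
    expression = if (expression) generate_expression(cfg, ann)
  )
}
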