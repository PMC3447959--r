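#' Read a pipeline/simulation configuration from YAML
#'
#' Top-level keys must be known [sim_config()] elements (plus the
#' optional `stages` list); unknown keys are rejected. Data-frame-valued
#' elements (`domains`, `gene_params`, `mark_architecture`,
#' `mutant_effects`) may be given as lists of records.
#'
#' @param path YAML file path.
#' @return List with `cfg` (a [sim_config]) and `stages`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  stages <- raw$stages
  raw$stages <- NULL
  df_keys <- c("domains", "gene_params", "mark_architecture", "mutant_effects")
  for (k in intersect(names(raw), df_keys)) {
    if (!is.data.frame(raw[[k]])) {
      raw[[k]] <- do.call(rbind, lapply(raw[[k]], function(rec) {
        as.data.frame(rec, stringsAsFactors = FALSE)
      }))
    }
  }
  # YAML maps of scalars come back as lists; restore named vectors
  simplify_leaves <- function(x) {
    if (!is.list(x)) {
      return(x)
    }
    if (length(x) > 0 && all(vapply(x, function(e) {
      is.atomic(e) && length(e) == 1 && !is.list(e)
    }, logical(1)))) {
      return(unlist(x))
    }
    lapply(x, simplify_leaves)
  }
  for (k in c(
    "repeat_density", "gc_content", "marks", "pausing", "polii",
    "mutant_expression", "expression", "motifs"
  )) {
    if (k %in% names(raw)) raw[[k]] <- simplify_leaves(raw[[k]])
  }
  cfg <- do.call(sim_config, raw)
  list(cfg = cfg, stages = stages)
}

#' Write the resolved configuration next to pipeline outputs
#'
#' @param cfg a [sim_config].
#' @param path output YAML path.
#' @export
write_sim_config <- function(cfg, path) {
  named_to_map <- function(x) {
    if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    } else if (is.list(x)) {
      lapply(x, named_to_map)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x) # keep names: YAML map instead of a bare sequence
    } else {
      x
    }
  }
  ser <- named_to_map(unclass(cfg))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stages run in dependency order: simulate, normalize (mutant scaling +
#' quantile normalization of Pol II), callregions, states, metagene,
#' pause, motifs/tm, mutant comparisons. All outputs are plain text
#' (GFF3/BED/bedGraph/FASTA/TSV) under `out_dir`, listed in a manifest
#' with md5 checksums; deterministic stages reproduce checksums under the
#' same configuration.
#'
#' @param cfg a [sim_config] (or path to a YAML config).
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to run; default all. The
#'   `simulate` stage is always run (it feeds every other stage).
#' @return List with `status` (0 on success), `manifest` (data frame
#'   `file`, `md5`) and `results` (in-memory stage results).
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = "hetdomain_out",
                         stages = c(
                           "simulate", "normalize", "callregions",
                           "states", "metagene", "pause", "motifs",
                           "mutant"
                         )) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)$cfg
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
  manifest <- character(0)
  results <- list()
  add <- function(path) manifest <<- c(manifest, path)

  sim <- simulate_dataset(cfg)
  ann <- sim$annotation
  write_gene_models(ann$genes, file.path(out_dir, "genes.gff3"))
  add(file.path(out_dir, "genes.gff3"))
  if (nrow(ann$repeats) > 0) {
    writeLines(sprintf(
      "%s\t%d\t%d\trepeat", ann$repeats$chrom,
      ann$repeats$start, ann$repeats$end
    ), file.path(out_dir, "repeats.bed"))
    add(file.path(out_dir, "repeats.bed"))
  }
  write_domains(ann$domains, file.path(out_dir, "domains.bed"))
  add(file.path(out_dir, "domains.bed"))
  for (key in names(sim$tracks)) {
    f <- file.path(out_dir, "tracks", paste0(key, ".bedGraph"))
    write_track(sim$tracks[[key]], f)
    add(f)
  }
  write_read_density(
    sim$readdensity,
    file.path(out_dir, "groseq.plus.bedGraph"),
    file.path(out_dir, "groseq.minus.bedGraph")
  )
  add(file.path(out_dir, "groseq.plus.bedGraph"))
  add(file.path(out_dir, "groseq.minus.bedGraph"))
  Biostrings::writeXStringSet(
    sim$sequences,
    file.path(out_dir, "promoters.fasta")
  )
  add(file.path(out_dir, "promoters.fasta"))
  write_expression(sim$expression$wt, file.path(out_dir, "expression.wt.tsv"))
  write_expression(
    sim$expression$mut,
    file.path(out_dir, "expression.mut.tsv")
  )
  add(file.path(out_dir, "expression.wt.tsv"))
  add(file.path(out_dir, "expression.mut.tsv"))
  write_sim_config(cfg, file.path(out_dir, "config.resolved.yaml"))
  add(file.path(out_dir, "config.resolved.yaml"))
  results$simulate <- sim

  active <- classify_expressed(
    sim$expression$wt,
    context = if (cfg$expression$context == "larvae") "larvae" else "cell_line"
  )[ann$genes$gene_id]
  smoothed <- lapply(sim$tracks, smooth_track)

  if ("normalize" %in% stages) {
    mut_cond <- unique(cfg$mutant_effects$condition)
    scaled <- list()
    for (mk in setdiff(cfg$marks, "PolII")) {
      for (cond in mut_cond) {
        key <- paste(mk, cond, sep = ".")
        if (!key %in% names(sim$tracks)) next
        sc <- scale_mutant_to_wt(
          sim$tracks[[paste(mk, "WT", sep = ".")]],
          sim$tracks[[key]]
        )
        scaled[[key]] <- sc
      }
    }
    polii_keys <- grep("^PolII\\.", names(sim$tracks), value = TRUE)
    qn <- quantile_normalize(sim$tracks[polii_keys])
    names(qn) <- polii_keys
    factors <- data.frame(
      track = names(scaled),
      factor = vapply(scaled, `[[`, numeric(1), "factor")
    )
    write.table(factors, file.path(out_dir, "scaling_factors.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "scaling_factors.tsv"))
    results$normalize <- list(scaled = scaled, polii_qn = qn)
  }

  if ("callregions" %in% stages) {
    regions <- lapply(smoothed, call_enriched_regions, fdr = 1e-3)
    for (key in names(regions)) {
      if (nrow(regions[[key]]) == 0) next
      f <- file.path(out_dir, paste0("regions.", key, ".bed"))
      write_regions(regions[[key]], f)
      add(f)
    }
    results$callregions <- regions
  }

  if ("states" %in% stages) {
    wt_keys <- paste(cfg$marks, "WT", sep = ".")
    bm <- bin_enrichment(setNames(
      smoothed[wt_keys],
      cfg$marks
    ), width = 500)
    sa <- fit_states(bm, seed = cfg$seed)
    lab <- ifelse(is.na(sa$labels), "NA", sa$labels)
    writeLines(sprintf(
      "%s\t%d\t%d\t%s", bm$bins$chrom, bm$bins$start,
      bm$bins$end, lab
    ), file.path(out_dir, "states.bed"))
    add(file.path(out_dir, "states.bed"))
    write.table(
      data.frame(state = rownames(sa$centroids), sa$centroids),
      file.path(out_dir, "state_centroids.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "state_centroids.tsv"))
    results$states <- list(bin_matrix = bm, assignment = sa)
  }

  if ("metagene" %in% stages) {
    chr4_active <- ann$genes[active &
      assign_domain(ann$genes, ann$domains) == "chr4", , drop = FALSE]
    prof <- metagene_profile(smoothed[["HP1a.WT"]], chr4_active)
    write.table(prof, file.path(out_dir, "metagene.HP1a.chr4_active.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "metagene.HP1a.chr4_active.tsv"))
    fcm <- feature_class_means(
      smoothed[["HP1a.WT"]], ann$genes,
      ann$domains,
      active = active
    )
    write.table(fcm, file.path(out_dir, "feature_class_means.HP1a.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "feature_class_means.HP1a.tsv"))
    results$metagene <- list(profile = prof, feature_class_means = fcm)
  }

  if ("pause" %in% stages) {
    eligible <- filter_genes_for_pi(ann$genes)
    pr <- pausing_indices(eligible,
      rd = sim$readdensity, method = "groseq",
      domains = ann$domains
    )
    write.table(pr, file.path(out_dir, "pausing.groseq.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "pausing.groseq.tsv"))
    pf <- paused_fraction(pr)
    write.table(pf, file.path(out_dir, "paused_fraction.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "paused_fraction.tsv"))
    results$pause <- list(indices = pr, fractions = pf)
  }

  if ("motifs" %in% stages) {
    doms <- attr(sim$sequences, "domains")
    motif_rows <- list()
    for (mname in names(cfg$motifs)) {
      spec <- motif_spec(
        mname, cfg$motifs[[mname]]$pattern,
        cfg$motifs[[mname]]$window
      )
      mf <- promoter_motif_fractions(sim$sequences, spec,
        domains = doms,
        domainA = "euchromatin", domainB = "chr4",
        n_perm = 1000, seed = cfg$seed
      )
      motif_rows[[mname]] <- cbind(motif = mname, mf$fractions,
        p_eu_vs_chr4 = mf$p_value
      )
    }
    mot <- do.call(rbind, motif_rows)
    write.table(mot, file.path(out_dir, "motif_fractions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "motif_fractions.tsv"))
    flank <- cfg$promoter_flank
    downstream <- substr(as.character(sim$sequences), flank + 1, flank + 100)
    tm_by_dom <- lapply(
      split(downstream, doms[names(sim$sequences)]),
      tm_profile
    )
    tm_out <- do.call(rbind, lapply(names(tm_by_dom), function(d) {
      cbind(domain = d, tm_by_dom[[d]]$profile)
    }))
    write.table(tm_out, file.path(out_dir, "tm_profiles.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "tm_profiles.tsv"))
    results$motifs <- list(fractions = mot, tm = tm_by_dom)
  }

  if ("mutant" %in% stages && "normalize" %in% stages) {
    gene_dom <- assign_domain(ann$genes, ann$domains)
    ec <- expression_change(
      sim$expression$wt, sim$expression$mut,
      domain = setNames(gene_dom, ann$genes$gene_id)
    )
    write.table(ec$groups, file.path(out_dir, "expression_change.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "expression_change.tsv"))
    key <- paste0("HP1a.", unique(cfg$mutant_effects$condition)[1])
    sc <- results$normalize$scaled[[key]]
    summary_hp1a <- enrichment_change_summary(
      smoothed[["HP1a.WT"]], smooth_track(sc$track), ann$genes,
      ann$domains,
      active = active
    )
    write.table(
      summary_hp1a$level,
      file.path(out_dir, "change_level.HP1a.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write.table(
      summary_hp1a$extent,
      file.path(out_dir, "change_extent.HP1a.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    add(file.path(out_dir, "change_level.HP1a.tsv"))
    add(file.path(out_dir, "change_extent.HP1a.tsv"))
    results$mutant <- list(
      expression = ec,
      change_summary = summary_hp1a
    )
  }

  md5 <- tools::md5sum(manifest)
  man <- data.frame(
    file = basename(manifest), md5 = unname(md5),
    stringsAsFactors = FALSE
  )
  write.table(man, file.path(out_dir, "manifest.tsv"),
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  list(status = 0L, manifest = man, results = results)
}
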