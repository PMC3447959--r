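# Shared fixtures and independent oracles used across the suite.

# Down-scaled simulation config: same structure as the defaults, smaller
# chromosomes so individual tests stay fast.
small_cfg <- function(seed = 7, ...) {
  sim_config(
    seed = seed,
    domains = data.frame(
      chrom = c("chr4", "chr4", "chrE", "chrH"),
      start = c(0, 70000, 0, 0),
      end = c(70000, 400000, 600000, 200000),
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
      n_genes = c(20, 120, 20, 3),
      median_length = c(8001, 1907, 1844, 1844),
      sdlog = c(0.45, 0.55, 0.55, 0.45),
      median_exons = c(6, 3, 2, 2),
      active_fraction = c(0.55, 0.5, 0.45, 0.4),
      stringsAsFactors = FALSE
    ),
    ...
  )
}

# A flat probe grid track on one chromosome.
grid_track <- function(values, spacing = 100, chrom = "chrT",
                       mark = "mark", condition = "WT") {
  probe_track(
    chrom = rep(chrom, length(values)),
    pos = seq(spacing / 2, by = spacing, length.out = length(values)),
    m = values, mark = mark, condition = condition
  )
}

# Brute-force run-on PI: literal per-base summation, no shared code with
# pi_groseq beyond the published definition.
pi_groseq_oracle <- function(rd, gene, head_bp = 500) {
  x <- rd$counts[[gene$chrom]]
  v <- if (gene$strand == "-") x$minus else x$plus
  counts <- v[(gene$start + 1):gene$end]
  if (gene$strand == "-") counts <- rev(counts)
  L <- length(counts)
  if (L <= head_bp) {
    return(NA_real_)
  }
  body_len <- ceiling(0.25 * (L - head_bp))
  num <- 0
  for (i in 1:head_bp) num <- num + counts[i]
  den <- 0
  for (i in (head_bp + 1):(head_bp + body_len)) den <- den + counts[i]
  num <- num / head_bp
  den <- den / body_len
  if (den == 0) {
    if (num == 0) NA_real_ else Inf
  } else {
    num / den
  }
}

# Brute-force IUPAC scan: per-position character-class comparison.
scan_motif_oracle <- function(seq, pattern) {
  classes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G")
  )
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  hits <- integer(0)
  if (length(s) < length(p)) {
    return(hits)
  }
  for (i in 0:(length(s) - length(p))) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!s[i + j] %in% classes[[p[j]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Hand-summed nearest-neighbor Tm oracle with its own copy of the
# unified parameter table.
tm_oracle <- function(seq, Na = 0.05, Ct = 5e-8) {
  dH <- c(
    AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
    GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
    CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
  )
  dS <- c(
    AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
    TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
    GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
    CC = -19.9
  )
  ch <- strsplit(toupper(seq), "")[[1]]
  h <- 0
  s <- 0
  for (i in seq_len(length(ch) - 1)) {
    nn <- paste0(ch[i], ch[i + 1])
    h <- h + dH[[nn]]
    s <- s + dS[[nn]]
  }
  for (term in ch[c(1, length(ch))]) {
    if (term %in% c("G", "C")) {
      h <- h + 0.1
      s <- s - 2.8
    } else {
      h <- h + 2.3
      s <- s + 4.1
    }
  }
  s <- s + 0.368 * (length(ch) - 1) * log(Na)
  1000 * h / (s + 1.987 * log(Ct / 4)) - 273.15
}

# Adjusted Rand index between two labelings (closed-form contingency
# computation; mclust gives the same value and is used as a cross-check
# where available).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Bin matrix with k planted mark-signature clusters separated by >= sep
# noise SDs, for state-recovery tests.
planted_state_bins <- function(n_bins = 600, seed = 1, sep = 3,
                               noise_sd = 0.3) {
  set.seed(seed)
  centers <- rbind(
    c(2.0, 2.0, 1.5, 0.0, 0.0), # classic heterochromatin
    c(0.2, 0.3, 1.5, 1.8, 1.6), # gene-body state
    c(0.0, 0.0, 0.1, 0.2, 1.8), # tss-active state
    c(2.0, 0.3, 0.2, 1.6, 0.0), # mixed state
    c(0.1, 1.8, 0.1, 0.0, 0.3) # me2-dominated state
  ) * sep * noise_sd / 0.9 * 3
  colnames(centers) <- c("H3K9me2", "H3K9me3", "HP1a", "POF", "H3K36me3")
  truth <- sample(rep(1:5, length.out = n_bins))
  m <- centers[truth, ] + matrix(
    rnorm(n_bins * 5, 0, noise_sd),
    n_bins, 5
  )
  bins <- data.frame(
    chrom = "chrT", start = (seq_len(n_bins) - 1) * 500,
    end = seq_len(n_bins) * 500, stringsAsFactors = FALSE
  )
  list(
    bm = structure(list(bins = bins, m = m, width = 500),
      class = "bin_matrix"
    ),
    truth = truth
  )
}
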