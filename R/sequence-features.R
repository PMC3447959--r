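#' Motif specification
#'
#' @param name motif name (e.g. `"PB"`, `"TRL"`).
#' @param pattern IUPAC degenerate pattern (A/C/G/T plus
#'   R,Y,S,W,K,M,B,D,H,V). `N` is deliberately not allowed in patterns,
#'   and an `N` in the subject sequence never matches.
#' @param window TSS-relative scan window, `c(lo, hi)` in bp.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(name, pattern, window = c(-60, 60)) {
  pattern <- toupper(pattern)
  valid <- names(iupac_table())
  chars <- strsplit(pattern, "")[[1]]
  if (any(!chars %in% valid)) {
    stop(
      "invalid IUPAC code(s) in pattern: ",
      paste(unique(chars[!chars %in% valid]), collapse = ", ")
    )
  }
  if (window[1] > window[2]) stop("scan window must be ordered")
  structure(list(name = name, pattern = pattern, window = window),
    class = "motif_spec"
  )
}

iupac_regex <- function(pattern) {
  tab <- iupac_table()
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- tab[[ch]]
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for an IUPAC motif (forward strand)
#'
#' All forward-strand start positions (0-based) where every base matches
#' the IUPAC class are reported, overlapping hits included. `N` in the
#' subject never matches. Inverted motifs are scanned as their own
#' explicit pattern, not by reverse-complementing.
#'
#' @param seq a single DNA string over A/C/G/T/N.
#' @param motif a [motif_spec] or IUPAC pattern string.
#' @return Integer vector of 0-based hit positions (possibly empty).
#' @export
scan_motif <- function(seq, motif) {
  pattern <- if (inherits(motif, "motif_spec")) motif$pattern else {
    motif_spec("anon", motif)$pattern
  }
  seq <- toupper(as.character(seq))
  if (nchar(seq) < nchar(pattern)) {
    return(integer(0))
  }
  rx <- paste0("(?=", iupac_regex(pattern), ")") # lookahead: overlapping hits
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Per-domain promoter motif fractions with a permutation contrast
#'
#' Scans each promoter's strand-oriented TSS window for the motif and
#' reports, per domain, the fraction of promoters with at least one hit,
#' plus a two-sided label-permutation p-value for the contrast between
#' two domains (`p = (1 + #{|null| >= |obs|}) / (1 + n_perm)`).
#'
#' @param promoters `DNAStringSet` or named character vector of
#'   fixed-length promoter sequences with the TSS at position
#'   `tss_index` (1-based).
#' @param domains named character vector mapping promoter name to domain
#'   (defaults to the `domains` attribute of `promoters`).
#' @param motif a [motif_spec].
#' @param domainA,domainB the two domains contrasted (defaults: the two
#'   most frequent).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param tss_index 1-based position of the TSS base in each sequence.
#' @return List with `fractions` (per-domain data frame), `p_value`,
#'   `observed`, `contrast`.
#' @export
promoter_motif_fractions <- function(promoters, motif, domains = NULL,
                                     domainA = NULL, domainB = NULL,
                                     n_perm = 1000, seed = 1,
                                     tss_index = NULL) {
  if (is.null(domains)) domains <- attr(promoters, "domains")
  seqs <- as.character(promoters)
  if (is.null(names(seqs))) names(seqs) <- names(promoters)
  domains <- domains[names(seqs)]
  if (is.null(tss_index)) tss_index <- nchar(seqs[1]) / 2 + 1
  lo <- max(1, tss_index + motif$window[1])
  hi <- min(nchar(seqs[1]), tss_index + motif$window[2])
  if (hi - lo + 1 < nchar(motif$pattern)) {
    warning("scan window shorter than motif; fractions are 0")
    hits <- rep(FALSE, length(seqs))
  } else {
    win <- substr(seqs, lo, hi)
    hits <- vapply(
      win, function(s) length(scan_motif(s, motif)) > 0,
      logical(1)
    )
  }
  tab <- tapply(hits, domains, mean)
  fractions <- data.frame(
    domain = names(tab), fraction = as.numeric(tab),
    n = as.numeric(table(domains)[names(tab)]), stringsAsFactors = FALSE
  )
  if (is.null(domainA) || is.null(domainB)) {
    top2 <- names(sort(table(domains), decreasing = TRUE))[1:2]
    if (is.null(domainA)) domainA <- top2[1]
    if (is.null(domainB)) domainB <- top2[2]
  }
  sel <- domains %in% c(domainA, domainB)
  h <- as.numeric(hits[sel])
  is_a <- domains[sel] == domainA
  nA <- sum(is_a)
  nB <- sum(!is_a)
  if (nA == 0 || nB == 0) {
    warning("empty domain in contrast; p-value undefined")
    return(list(
      fractions = fractions, p_value = NA_real_,
      observed = NA_real_, contrast = c(domainA, domainB)
    ))
  }
  obs <- sum(h[is_a]) / nA - sum(h[!is_a]) / nB
  set.seed(seed)
  tot <- sum(h)
  null <- vapply(seq_len(n_perm), function(k) {
    a <- sum(h[sample.int(length(h), nA)])
    a / nA - (tot - a) / nB
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  list(
    fractions = fractions, p_value = p, observed = obs,
    contrast = c(domainA, domainB)
  )
}

# Nearest-neighbor duplex parameters (unified table): dH in kcal/mol,
# dS in cal/(mol K). Initiation terms per terminal base pair.
nn_parameters <- function() {
  list(
    dH = c(
      AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
      CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
      CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
      CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
    ),
    dS = c(
      AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
      CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
      CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
      CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
    ),
    init_dH = c(G = 0.1, C = 0.1, A = 2.3, T = 2.3),
    init_dS = c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
  )
}

#' Nearest-neighbor melting temperature of short duplexes
#'
#' Two-state nearest-neighbor thermodynamics with the unified parameter
#' set, entropic salt correction `dS + 0.368 (n-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15`. Absolute values depend on
#' the parameter table and the salt/strand concentrations (recorded in
#' the result attributes); comparative analyses are insensitive to that
#' choice.
#'
#' @param seqs character vector of equal-length DNA words (A/C/G/T only;
#'   words containing other letters give `NA`).
#' @param Na monovalent salt concentration, mol/L (default 0.05).
#' @param Ct total strand concentration, mol/L (default 5e-8).
#' @return Numeric vector of Tm in degrees Celsius.
#' @export
melting_temperature <- function(seqs, Na = 0.05, Ct = 5e-8) {
  par <- nn_parameters()
  r_gas <- 1.987
  out <- vapply(toupper(seqs), function(s) {
    ch <- strsplit(s, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) {
      return(NA_real_)
    }
    nn <- paste0(ch[-length(ch)], ch[-1])
    dH <- sum(par$dH[nn]) + par$init_dH[ch[1]] + par$init_dH[ch[length(ch)]]
    dS <- sum(par$dS[nn]) + par$init_dS[ch[1]] + par$init_dS[ch[length(ch)]]
    dS <- dS + 0.368 * (length(ch) - 1) * log(Na)
    1000 * dH / (dS + r_gas * log(Ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
  attr(out, "salt_Na") <- Na
  attr(out, "strand_Ct") <- Ct
  out
}

#' Sliding-window 9-mer melting-temperature profile
#'
#' For each 100-bp TSS-downstream sequence, the Tm of each of the 92
#' overlapping 9-mers is computed by nearest-neighbor thermodynamics;
#' the profile averages across sequences at each offset. Sequences not
#' exactly 100 bp are skipped (with a message); windows containing `N`
#' are skipped.
#'
#' @param seqs character vector or `DNAStringSet` of 100-bp sequences.
#' @param k word size (default 9).
#' @param width expected sequence length (default 100).
#' @param ... passed to [melting_temperature()].
#' @return List of class `tm_profile` with `profile` (data frame
#'   `offset` 1..92, `tm`, `n`), `summary` (min/median/mean/max over all
#'   window Tm values) and `n_sequences`.
#' @export
tm_profile <- function(seqs, k = 9, width = 100, ...) {
  seqs <- as.character(seqs)
  ok <- nchar(seqs) == width
  if (!all(ok)) {
    message(sum(!ok), " sequence(s) skipped (length != ", width, ")")
  }
  seqs <- toupper(seqs[ok])
  if (length(seqs) == 0) stop("all sequences skipped")
  n_win <- width - k + 1
  tm_mat <- matrix(NA_real_, nrow = length(seqs), ncol = n_win)
  for (i in seq_along(seqs)) {
    words <- substring(seqs[i], seq_len(n_win), seq_len(n_win) + k - 1)
    tm_mat[i, ] <- melting_temperature(words, ...)
  }
  profile <- data.frame(
    offset = seq_len(n_win),
    tm = colMeans(tm_mat, na.rm = TRUE),
    n = colSums(!is.na(tm_mat))
  )
  vals <- tm_mat[!is.na(tm_mat)]
  structure(
    list(
      profile = profile,
      summary = c(
        min = min(vals), median = median(vals),
        mean = mean(vals), max = max(vals)
      ),
      n_sequences = length(seqs)
    ),
    class = "tm_profile"
  )
}

#' @export
print.tm_profile <- function(x, ...) {
  cat(sprintf(
    "<tm_profile> %d sequences, %d offsets; mean Tm %.2f C\n",
    x$n_sequences, nrow(x$profile), x$summary[["mean"]]
  ))
  invisible(x)
}
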