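#' Base composition and strand-asymmetry statistics
#'
#' Computes sequence length, per-base and A+T percentages, and the strand
#' asymmetry skews
#' \deqn{AT\mbox{-}skew = (A - T)/(A + T), \qquad
#'       GC\mbox{-}skew = (G - C)/(G + C).}
#' N bases are ignored in both skew numerators and denominators (and in the
#' percentage denominators).  When a skew denominator is zero the skew is
#' reported as \code{NA} with the corresponding \code{*_defined} flag set to
#' \code{FALSE}, never as 0.
#'
#' @param seq non-empty DNA character string (A/C/G/T/N, case-insensitive).
#' @return object of class \code{composition_stats}: list with length,
#'   pct_AT, pct_each_base (named A/C/G/T), at_skew, gc_skew (raw),
#'   at_skew_3dp / gc_skew_3dp / pct rounded to the conventional report
#'   precision (skews 3 decimals, percentages 1), and defined-ness flags.
#' @examples
#' composition_stats("AAAT")$at_skew   # 0.5
#' @export
composition_stats <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(x), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("non-DNA characters: ", paste(bad, collapse = ", "))
  cnt <- c(A = sum(x == "A"), C = sum(x == "C"),
           G = sum(x == "G"), T = sum(x == "T"))
  acgt <- sum(cnt)
  at <- cnt[["A"]] + cnt[["T"]]
  gc <- cnt[["G"]] + cnt[["C"]]
  at_skew <- if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NA_real_
  gc_skew <- if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NA_real_
  structure(list(
    length = length(x),
    n_count = sum(x == "N"),
    pct_AT = if (acgt > 0) 100 * at / acgt else NA_real_,
    pct_each_base = if (acgt > 0) 100 * cnt / acgt else cnt * NA_real_,
    at_skew = at_skew, gc_skew = gc_skew,
    at_skew_defined = at > 0, gc_skew_defined = gc > 0,
    at_skew_3dp = round(at_skew, 3), gc_skew_3dp = round(gc_skew, 3),
    pct_AT_1dp = round(if (acgt > 0) 100 * at / acgt else NA_real_, 1)),
    class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("%d bp | A+T %.1f%% | AT-skew %s | GC-skew %s\n", x$length,
              x$pct_AT,
              if (x$at_skew_defined) sprintf("%.3f", x$at_skew) else "undef",
              if (x$gc_skew_defined) sprintf("%.3f", x$gc_skew) else "undef"))
  invisible(x)
}

## class label for a gene feature row used by strandwise pooling
feature_class <- function(feat) {
  if (feat$kind == "PCG") paste0(feat$strand, "-PCG")
  else if (feat$kind == "control") "CR"
  else feat$kind
}

#' Composition statistics pooled by gene class on the coding strand
#'
#' Each feature's sequence is taken on its coding strand (N-strand features
#' reverse-complemented first), concatenated within its class, and summarised
#' with [composition_stats()].  Default classes are J-strand PCGs, N-strand
#' PCGs, rRNAs, tRNAs and the control region.
#'
#' @param genome a [mitogenome()].
#' @param features optional subset of \code{genome$features} rows to pool as
#'   one group (overrides class pooling); must be non-empty.
#' @return named list of \code{composition_stats} per class, or a single
#'   \code{composition_stats} when \code{features} is given.
#' @export
strandwise_stats <- function(genome, features = NULL) {
  if (!is.null(features)) {
    if (nrow(features) == 0L) stop("empty feature subset")
    s <- paste(vapply(seq_len(nrow(features)),
                      function(i) feature_seq(genome, features[i, ]), ""),
               collapse = "")
    return(composition_stats(s))
  }
  f <- genome$features
  if (nrow(f) == 0L) stop("genome has no features")
  cls <- vapply(seq_len(nrow(f)), function(i) feature_class(f[i, ]), "")
  out <- lapply(split(seq_len(nrow(f)), cls), function(idx) {
    s <- paste(vapply(idx, function(i) feature_seq(genome, f[i, ]), ""),
               collapse = "")
    composition_stats(s)
  })
  out
}

#' Junction table of a circular annotated genome
#'
#' For each adjacent feature pair on the circle reports the signed gap
#' \code{downstream start - upstream end} (negative values are overlaps,
#' with the overlapping sequence extracted).  The signed gaps satisfy the
#' circular closure identity: feature lengths plus gaps sum to the genome
#' length.
#'
#' @param genome a [mitogenome()] with at least two features.
#' @return data.frame with columns upstream, downstream, gap_bp,
#'   overlap_seq (NA when gap_bp >= 0).
#' @export
gene_junctions <- function(genome) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  n <- nchar(genome$sequence)
  if (nrow(f) < 2L) stop("need at least two features")
  ## nested features break the adjacency model
  for (i in seq_len(nrow(f) - 1L))
    for (j in (i + 1L):nrow(f))
      if (f$start[j] >= f$start[i] && f$end[j] <= f$end[i])
        stop("feature ", f$name[j], " is nested inside ", f$name[i])
  up <- seq_len(nrow(f))
  dn <- c(2:nrow(f), 1L)
  gap <- f$start[dn] - f$end[up]
  if (genome$circular) gap[length(gap)] <- gap[length(gap)] + n
  ov <- rep(NA_character_, length(gap))
  neg <- which(gap < 0)
  for (i in neg) {
    st <- f$start[dn[i]] %% n
    ov[i] <- region_seq(genome, st, st - gap[i])
  }
  data.frame(upstream = f$name[up], downstream = f$name[dn],
             gap_bp = as.integer(gap), overlap_seq = ov,
             stringsAsFactors = FALSE)
}

## --- codon classification --------------------------------------------------

## invertebrate mitochondrial genetic code (NCBI translation table 5)
invert_mito_code <- function() Biostrings::getGeneticCode("5")

START_CODONS <- c("ATA", "ATT", "ATC", "ATG", "GTG", "TTG")

#' Classify start and stop codons of the protein-coding genes
#'
#' Extracts each PCG on its coding strand, reads the first triplet as the
#' start codon (standard set: ATN, GTG, TTG) and resolves the stop: a
#' trailing TAA/TAG when the length is a multiple of three, else a trailing
#' T or TA flagged as an incomplete stop (completed to TAA by transcript
#' polyadenylation).  An incomplete stop is only accepted when the next
#' feature on the coding side begins within 2 bp; otherwise the gene is
#' flagged unresolved.
#'
#' @param genome a [mitogenome()].
#' @return data.frame with columns gene, strand, length_bp, start_codon,
#'   start_standard, stop_codon, stop_complete, stop_flag.
#' @export
classify_codons <- function(genome) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  pcg_idx <- which(f$kind == "PCG")
  if (length(pcg_idx) == 0L) stop("no protein-coding genes annotated")
  n <- nchar(genome$sequence)
  rows <- lapply(pcg_idx, function(i) {
    s <- feature_seq(genome, f[i, ])
    len <- nchar(s)
    if (len < 6L) stop("PCG ", f$name[i], " shorter than 6 bp")
    start <- substr(s, 1L, 3L)
    rem <- len %% 3L
    ## distance from the coding-strand 3' end to the next feature
    next_gap <- {
      k <- nrow(f)
      if (f$strand[i] == "J") {
        j <- if (i == k) 1L else i + 1L
        d <- f$start[j] - f$end[i]
        if (j == 1L && genome$circular) d <- d + n
        d
      } else {
        j <- if (i == 1L) k else i - 1L
        d <- f$start[i] - f$end[j]
        if (j == k && genome$circular) d <- d + n
        d
      }
    }
    stp <- if (rem == 0L) {
      last3 <- substr(s, len - 2L, len)
      if (last3 %in% c("TAA", "TAG"))
        list(stop = last3, complete = TRUE, flag = "complete")
      else list(stop = last3, complete = FALSE, flag = "nonstandard")
    } else {
      tail_s <- substr(s, len - rem + 1L, len)
      if (tail_s %in% c("T", "TA") && next_gap <= 2L)
        list(stop = tail_s, complete = FALSE, flag = "incomplete")
      else list(stop = tail_s, complete = FALSE, flag = "unresolved")
    }
    data.frame(gene = f$name[i], strand = f$strand[i], length_bp = len,
               start_codon = start,
               start_standard = start %in% START_CODONS,
               stop_codon = stp$stop, stop_complete = stp$complete,
               stop_flag = stp$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## --- codon usage / RSCU ----------------------------------------------------

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

#' Codon usage and RSCU over the 13 protein-coding genes
#'
#' Counts complete codons on the coding strands of all PCGs (incomplete
#' terminal codons are excluded) and computes the relative synonymous codon
#' usage under the invertebrate mitochondrial genetic code (table 5; AUA is
#' Met, UGA is Trp, AGR is Ser):
#' \deqn{RSCU_c = n_c \cdot |F_c| / \sum_{c' \in F_c} n_{c'}}
#' where \eqn{F_c} is the synonymous family of codon \eqn{c}.  Stop codons
#' are counted but excluded from amino-acid percentages and carry no RSCU.
#'
#' @param genome a [mitogenome()].
#' @param warn_internal_stops warn when an in-frame stop occurs before the
#'   terminal codon of a gene.
#' @return list of class \code{codon_usage_table}: \code{codons}
#'   (data.frame codon, codon_rna, aa, count, rscu), \code{aa_percent}
#'   (named vector summing to 100), \code{per_gene} (the
#'   [classify_codons()] table).
#' @export
codon_usage <- function(genome, warn_internal_stops = TRUE) {
  cc <- classify_codons(genome)
  code <- invert_mito_code()
  f <- genome$features
  counts <- stats::setNames(integer(64L), all_codons())
  for (i in which(f$kind == "PCG")) {
    s <- feature_seq(genome, f[i, ])
    n3 <- (nchar(s) %/% 3L) * 3L
    cod <- substring(s, seq(1L, n3, 3L), seq(3L, n3, 3L))
    cod <- cod[!grepl("N", cod)]
    if (warn_internal_stops) {
      internal <- utils::head(cod, -1L)
      st <- which(code[internal] == "*")
      if (length(st))
        warning("internal stop codon in ", f$name[i], " at codon ",
                paste(st, collapse = ", "))
    }
    tb <- table(cod)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  aa <- code[names(counts)]
  sense <- aa != "*"
  fam_size <- table(aa[sense])
  fam_tot <- tapply(counts[sense], aa[sense], sum)
  rscu <- rep(NA_real_, 64L)
  rscu[sense] <- ifelse(fam_tot[aa[sense]] > 0,
                        counts[sense] * fam_size[aa[sense]] /
                          fam_tot[aa[sense]],
                        NA_real_)
  aa_counts <- tapply(counts[sense], aa[sense], sum)
  aa_pct <- 100 * aa_counts / sum(aa_counts)
  structure(list(
    codons = data.frame(codon = names(counts),
                        codon_rna = chartr("T", "U", names(counts)),
                        aa = unname(aa), count = unname(counts),
                        rscu = rscu, stringsAsFactors = FALSE),
    aa_percent = aa_pct,
    per_gene = cc), class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  top <- x$codons[order(-x$codons$rscu), ][1:5, c("codon_rna", "aa", "count",
                                                  "rscu")]
  cat("codon usage over", sum(x$codons$count), "codons; top RSCU:\n")
  print.data.frame(top, row.names = FALSE, digits = 3)
  invisible(x)
}

## --- NCR homology ----------------------------------------------------------

#' Scan a non-coding region for homology to mitochondrial genes
#'
#' Aligns the NCR locally (match +1, mismatch -1, gap open 2, gap extend 1)
#' against each candidate gene on both strands and reports hits ranked by
#' alignment score.  Identity is matches divided by alignment columns.
#' Supports the hypothesis that an intergenic spacer is a degraded duplicate
#' of a neighbouring gene (a TDRL remnant).
#'
#' @param genome a [mitogenome()].
#' @param ncr one-row feature data.frame, or c(start, end) 0-based half-open
#'   span on the genome strand; must be at least 30 bp.
#' @param candidates character vector of gene names to scan (default: all
#'   13 PCGs present).
#' @param min_identity identity floor in percent (default 55); hits below it
#'   are dropped.  An empty result is not an error.
#' @return data.frame of hits sorted by score: gene, strand, score,
#'   identity, aln_length, ncr_start, ncr_end.
#' @export
ncr_homology_scan <- function(genome, ncr, candidates = NULL,
                              min_identity = 55) {
  if (is.numeric(ncr)) {
    ncr_s <- region_seq(genome, ncr[1L], ncr[2L])
  } else {
    ncr_s <- region_seq(genome, ncr$start, ncr$end)
  }
  if (nchar(ncr_s) < 30L) stop("NCR shorter than 30 bp")
  if (is.null(candidates))
    candidates <- genome$features$name[genome$features$kind == "PCG"]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  hits <- list()
  for (g in candidates) {
    gs <- feature_seq(genome, g)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") ncr_s else revcomp(ncr_s)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(gs),
        type = "local", substitutionMatrix = mat,
        gapOpening = 2, gapExtension = 1)
      cols <- nchar(as.character(Biostrings::pattern(aln)))
      if (cols == 0L) next
      ident <- 100 * Biostrings::nmatch(aln) / cols
      hits[[length(hits) + 1L]] <- data.frame(
        gene = g, strand = strand,
        score = Biostrings::score(aln), identity = ident,
        aln_length = cols, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  out <- out[out$identity >= min_identity, , drop = FALSE]
  out <- out[order(-out$score, -out$identity, out$gene), , drop = FALSE]
  ## keep the best strand per gene
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
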