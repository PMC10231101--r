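#' Configuration for the synthetic mitogenome generator
#'
#' Defaults emulate a typical stick-insect mitogenome: a circular, AT-rich
#' (~75% A+T) genome of roughly 15.5 kb carrying the 37 canonical genes in
#' the ancestral insect order plus one control region, with the shared
#' junction motifs (a 4 bp ATAA overlap at ATP8/ATP6 and an 8 bp AAGCCTTA
#' overlap at trnW/trnC) planted by default.  Whole-genome strand asymmetry
#' defaults to a positive AT-skew (0.16) and negative GC-skew (-0.24).
#'
#' @param seed integer RNG seed; the generator is byte-reproducible under
#'   it.
#' @param genome_length_target advisory total length in bp; generation
#'   fails if the gene complement alone exceeds it.
#' @param at_content,at_skew,gc_skew genome-strand base composition
#'   targets; per-base probabilities are derived from them.
#' @param gene_lengths named bp table overriding the built-in defaults
#'   (tRNAs 65 bp, rRNAs 780/1280 bp, PCGs at typical insect lengths).
#' @param events ordered list of rearrangement specs applied to the
#'   ancestral order: \code{list(type = "tdrl", window = c(genes),
#'   retention = c(gene = "first"/"second"))}, \code{list(type =
#'   "inversion", gene = )}, \code{list(type = "translocation", gene = ,
#'   after = )}.
#' @param split_cr optional \code{list(embedded = c(genes))}: the control
#'   region is emitted as CR1, the embedded genes (removed from their
#'   slots), then CR2.
#' @param cr_spec named list per control segment ("CR", or "CR1"/"CR2"
#'   when split): \code{list(spacers = c(bp, ...), arrays =
#'   list(list(unit_length = , copies = , divergence = )))}; segments are
#'   laid out spacer, array, spacer, ...  Divergence is the per-base
#'   substitution rate between copies, at most 0.2.
#' @param start_codons,incomplete_stops per-gene start-codon overrides and
#'   the genes emitted with an incomplete terminal T (default COX1, COX2).
#' @param junction_motifs default gap in bp between adjacent features plus
#'   planted overlap motifs.
#' @param ncr optional planted non-coding region:
#'   \code{list(after = "trnS2", length = 198, source = "ND1",
#'   divergence = 0.25)}; the spacer is a degraded copy of a substring of
#'   the source gene.
#' @param id genome identifier (default derived from the seed).
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(seed = 1L,
                             genome_length_target = 15500L,
                             at_content = 0.75,
                             at_skew = 0.16,
                             gc_skew = -0.24,
                             gene_lengths = NULL,
                             events = list(),
                             split_cr = NULL,
                             cr_spec = list(CR = list(spacers = c(400L, 500L),
                                                      arrays = list())),
                             start_codons = c(ND1 = "ATA"),
                             incomplete_stops = c("COX1", "COX2"),
                             junction_motifs = list(
                               default_gap = 2L,
                               overlaps = list(
                                 c("ATP8", "ATP6", "ATAA"),
                                 c("trnW", "trnC", "AAGCCTTA"))),
                             ncr = NULL,
                             id = NULL) {
  gl <- default_gene_lengths()
  if (!is.null(gene_lengths)) gl[names(gene_lengths)] <- gene_lengths
  for (ev in events) {
    gs <- c(ev$gene, ev$window, ev$after)
    bad <- setdiff(gs[!is.na(gs)], c(CANONICAL_GENES, CONTROL_SYMBOLS))
    if (length(bad)) stop("unknown gene in event: ",
                          paste(bad, collapse = ", "))
  }
  for (seg in cr_spec) for (a in seg$arrays)
    if (!is.null(a$divergence) && (a$divergence < 0 || a$divergence > 0.2))
      stop("array divergence must be in [0, 0.2]")
  structure(list(seed = as.integer(seed),
                 genome_length_target = as.integer(genome_length_target),
                 at_content = at_content, at_skew = at_skew,
                 gc_skew = gc_skew, gene_lengths = gl, events = events,
                 split_cr = split_cr, cr_spec = cr_spec,
                 start_codons = start_codons,
                 incomplete_stops = incomplete_stops,
                 junction_motifs = junction_motifs, ncr = ncr,
                 id = if (is.null(id)) sprintf("synthetic_seed%d", seed)
                      else id),
            class = "generator_config")
}

default_gene_lengths <- function() {
  trn <- stats::setNames(rep(65L, length(TRNA_SYMBOLS)), TRNA_SYMBOLS)
  c(trn,
    rrnS = 780L, rrnL = 1280L,
    ND2 = 1023L, COX1 = 1536L, COX2 = 684L, ATP8 = 159L, ATP6 = 678L,
    COX3 = 786L, ND3 = 351L, ND5 = 1716L, ND4 = 1338L, ND4L = 288L,
    ND6 = 501L, CYTB = 1134L, ND1 = 939L)
}

## base-probability vector (A, C, G, T) from composition targets
base_probs <- function(at, at_skew, gc_skew) {
  c(A = at * (1 + at_skew) / 2,
    C = (1 - at) * (1 - gc_skew) / 2,
    G = (1 - at) * (1 + gc_skew) / 2,
    T = at * (1 - at_skew) / 2)
}

draw_bases <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

## codon draws on the coding strand avoiding in-frame stops (TAA/TAG)
draw_codons <- function(n_codons, probs) {
  if (n_codons <= 0L) return("")
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- paste(sample(names(probs), 3L, replace = TRUE, prob = probs),
                   collapse = "")
      if (!(cod %in% c("TAA", "TAG"))) break
    }
    out[i] <- cod
  }
  paste(out, collapse = "")
}

## resolve the configured events against the ancestral order
apply_config_events <- function(config) {
  ord <- ancestral_order()
  resolved <- list()
  for (ev in config$events) {
    if (ev$type == "tdrl") {
      idx <- match(ev$window, ord$symbols)
      if (anyNA(idx)) stop("tdrl window gene absent from current order")
      event <- tdrl_event(c(min(idx), max(idx) + 1L), ev$retention)
      ord <- apply_tdrl(ord, event)
      resolved[[length(resolved) + 1L]] <-
        list(type = "tdrl", event = event)
    } else if (ev$type == "inversion") {
      i <- match(ev$gene, ord$symbols)
      if (is.na(i)) stop("inversion gene absent: ", ev$gene)
      ord$signs[i] <- -ord$signs[i]
      resolved[[length(resolved) + 1L]] <-
        list(type = "inversion", gene = ev$gene)
    } else if (ev$type == "translocation") {
      i <- match(ev$gene, ord$symbols)
      j0 <- match(ev$after, ord$symbols)
      if (is.na(i) || is.na(j0))
        stop("translocation gene/destination absent")
      sym <- ord$symbols; sgn <- ord$signs
      g <- sym[i]; s <- sgn[i]
      sym <- sym[-i]; sgn <- sgn[-i]
      j <- match(ev$after, sym)
      sym <- append(sym, g, after = j)
      sgn <- append(sgn, s, after = j)
      ord <- gene_order(sym, sgn)
      resolved[[length(resolved) + 1L]] <-
        list(type = "translocation", gene = ev$gene, after = ev$after)
    } else stop("unknown event type: ", ev$type)
  }
  if (!is.null(config$split_cr)) {
    emb <- config$split_cr$embedded
    sym <- ord$symbols; sgn <- ord$signs
    keep <- !(sym %in% emb)
    emb_signs <- sgn[match(emb, sym)]
    sym <- sym[keep]; sgn <- sgn[keep]
    i <- match("CR", sym)
    if (is.na(i)) stop("split_cr requires a CR marker in the order")
    sym <- c(sym[seq_len(i - 1L)], "CR1", emb, "CR2",
             if (i < length(sym)) sym[(i + 1L):length(sym)])
    sgn <- c(sgn[seq_len(i - 1L)], 1L, emb_signs, 1L,
             if (i < length(sgn)) sgn[(i + 1L):length(sgn)])
    ord <- gene_order(sym, sgn)
  }
  list(order = ord, resolved = resolved)
}

## assemble one control segment; returns sequence plus array truth rows
build_cr_segment <- function(seg_name, spec, probs) {
  arrays <- spec$arrays
  spacers <- spec$spacers
  if (is.null(spacers)) spacers <- integer()
  need <- length(arrays) + 1L
  if (length(spacers) < need)
    spacers <- c(spacers, rep(100L, need - length(spacers)))
  seqs <- character()
  truth <- list()
  pos <- 0L
  for (k in seq_along(arrays)) {
    sp <- draw_bases(spacers[k], probs)
    seqs <- c(seqs, sp); pos <- pos + nchar(sp)
    a <- arrays[[k]]
    div <- if (is.null(a$divergence)) 0 else a$divergence
    unit <- draw_bases(a$unit_length, probs)
    copies <- vapply(seq_len(a$copies), function(i) {
      if (i == 1L) return(unit)
      mutate_seq(unit, div)
    }, "")
    arr <- paste(copies, collapse = "")
    truth[[length(truth) + 1L]] <- data.frame(
      segment = seg_name, seg_start = pos, seg_end = pos + nchar(arr),
      unit_length = a$unit_length, copies = a$copies, divergence = div,
      stringsAsFactors = FALSE)
    seqs <- c(seqs, arr); pos <- pos + nchar(arr)
  }
  ## remaining spacers are appended after the last array
  for (k in (length(arrays) + 1L):length(spacers))
    seqs <- c(seqs, draw_bases(spacers[k], probs))
  list(seq = paste(seqs, collapse = ""),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

## per-base substitution to a uniformly chosen different base
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  paste(x, collapse = "")
}

## draw the coding-strand sequence of one gene
draw_gene_seq <- function(g, sign, config, probs) {
  len <- config$gene_lengths[[g]]
  kind <- gene_kind(g)
  ## N-strand features are reverse-complemented into the genome; drawing
  ## them from the base-swapped distribution keeps the genome strand at the
  ## configured composition
  p <- if (sign < 0) stats::setNames(probs[c("T", "G", "C", "A")],
                                     c("A", "C", "G", "T")) else probs
  if (kind != "PCG") return(draw_bases(len, p))
  start <- if (g %in% names(config$start_codons))
    config$start_codons[[g]] else "ATG"
  incomplete <- g %in% config$incomplete_stops
  if (incomplete) {
    len <- (len %/% 3L) * 3L + 1L          # 3k + 1 for a trailing T
    body <- draw_codons((len - 1L) %/% 3L - 1L, p)
    s <- paste0(start, body, "T")
  } else {
    len <- (len %/% 3L) * 3L
    body <- draw_codons(len %/% 3L - 2L, p)
    s <- paste0(start, body, "TAA")
  }
  ## planted junction motifs constrain gene ends (coding strand)
  if (g == "ATP8") {
    ## last four coding bases ATAA: stop TAA preceded by A; redraw the
    ## final body codon to end in A without forming a stop
    repeat {
      cod <- paste0(draw_bases(2L, p), "A")
      if (!(cod %in% c("TAA", "TAG"))) break
    }
    substr(s, nchar(s) - 5L, nchar(s) - 3L) <- cod
  }
  if (g == "ATP6") {
    ## starts ATA (a valid ATN start) continued by A: first four bases ATAA
    s <- paste0("ATAA", substr(s, 5L, nchar(s)))
  }
  s
}

#' Generate an annotated mitogenome with a ground-truth manifest
#'
#' Builds the ancestral gene order, applies the configured rearrangement
#' events through the same TDRL/inversion/translocation operations the
#' analysis modules test, draws gene sequences from an AT-biased i.i.d.
#' model with enforced start/stop codons for the protein-coding genes,
#' plants the configured junction motifs, non-coding region and
#' control-region repeat arrays, and assembles the circular genome.  The
#' pseudo-random stream is consumed in a fixed documented order (genes in
#' ancestral order, then control-region segments, then the NCR), so the
#' same config always reproduces the same genome byte for byte.
#'
#' @param config a [generator_config()].
#' @return list with elements \code{genome} (a [mitogenome()]) and
#'   \code{truth}: seed, final order string, resolved events, planted
#'   arrays with genome coordinates, NCR span, realized composition.
#' @export
generate_mitogenome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  glen <- sum(config$gene_lengths)
  if (glen > config$genome_length_target)
    stop("gene lengths (", glen, " bp) exceed genome_length_target (",
         config$genome_length_target, " bp)")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  probs <- base_probs(config$at_content, config$at_skew, config$gc_skew)
  oc <- apply_config_events(config)
  ord <- oc$order

  ## 1. gene sequences, drawn in ancestral order (coding strand)
  sign_of <- stats::setNames(ord$signs, ord$symbols)
  gene_seqs <- list()
  for (g in ANCESTRAL_SYMBOLS) {
    if (g %in% CONTROL_SYMBOLS) next
    gene_seqs[[g]] <- draw_gene_seq(g, sign_of[[g]], config, probs)
  }

  ## plant junction overlap motifs on the participating gene ends
  ## (PCG ends are codon-constrained and handled during drawing)
  for (m in config$junction_motifs$overlaps) {
    mot <- m[3L]; d <- nchar(mot)
    for (side in 1:2) {
      g <- m[side]
      if (!(g %in% names(gene_seqs))) next
      if (gene_kind(g) == "PCG") {
        if (mot != "ATAA" || !(g %in% c("ATP8", "ATP6")))
          stop("PCG overlap motifs are only supported at ATP8/ATP6 (ATAA)")
        next
      }
      s <- gene_seqs[[g]]
      if (side == 1L) {          # upstream gene: genome-strand suffix
        if (sign_of[[g]] > 0) substr(s, nchar(s) - d + 1L, nchar(s)) <- mot
        else substr(s, 1L, d) <- revcomp(mot)
      } else {                   # downstream gene: genome-strand prefix
        if (sign_of[[g]] > 0) substr(s, 1L, d) <- mot
        else substr(s, nchar(s) - d + 1L, nchar(s)) <- revcomp(mot)
      }
      gene_seqs[[g]] <- s
    }
  }

  ## 2. control-region segments, in final-order position order
  cr_tokens <- ord$symbols[ord$symbols %in% CONTROL_SYMBOLS]
  cr_seqs <- list(); cr_truths <- list()
  for (ct in cr_tokens) {
    spec <- config$cr_spec[[ct]]
    if (is.null(spec)) spec <- list(spacers = c(200L, 200L), arrays = list())
    built <- build_cr_segment(ct, spec, probs)
    cr_seqs[[ct]] <- built$seq
    if (!is.null(built$truth)) cr_truths[[ct]] <- built$truth
  }

  ## 3. planted NCR (degraded copy of a substring of its source gene)
  ncr_seq <- NULL
  if (!is.null(config$ncr)) {
    src <- gene_seqs[[config$ncr$source]]
    L <- config$ncr$length
    if (nchar(src) < L) stop("NCR source gene shorter than NCR length")
    off <- sample(nchar(src) - L + 1L, 1L)
    frag <- substr(src, off, off + L - 1L)
    ## uniform randomization of a fraction of positions
    x <- strsplit(frag, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(L) < config$ncr$divergence)
    x[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    ncr_seq <- paste(x, collapse = "")
  }

  ## 4. assembly along the final order
  motifs <- config$junction_motifs
  overlap_of <- function(a, b) {
    for (m in motifs$overlaps) if (m[1L] == a && m[2L] == b) return(m[3L])
    NULL
  }
  seq_parts <- character()
  cursor <- 0L
  feats <- list()
  syms <- ord$symbols
  n_tok <- length(syms)
  for (k in seq_len(n_tok)) {
    g <- syms[k]
    body <- if (g %in% CONTROL_SYMBOLS) cr_seqs[[g]] else {
      s <- gene_seqs[[g]]
      if (sign_of[[g]] < 0) revcomp(s) else s
    }
    full_len <- nchar(body)
    start <- cursor
    if (k > 1L) {
      prev <- syms[k - 1L]
      ov <- overlap_of(prev, g)
      if (!is.null(ov)) {
        ## planted overlap: previous suffix must equal next prefix
        d <- nchar(ov)
        whole <- paste(seq_parts, collapse = "")
        stopifnot(substr(whole, cursor - d + 1L, cursor) ==
                    substr(body, 1L, d))
        body <- substr(body, d + 1L, full_len)
        start <- cursor - d
      } else {
        is_ncr <- !is.null(config$ncr) && prev == config$ncr$after &&
          g == config$ncr$source
        gap <- if (is_ncr) config$ncr$length
               else if (prev %in% config$incomplete_stops) 1L
               else motifs$default_gap
        if (gap > 0L) {
          spacer <- if (is_ncr) ncr_seq else draw_bases(gap, probs)
          seq_parts <- c(seq_parts, spacer)
          cursor <- cursor + nchar(spacer)
        }
        start <- cursor
      }
    }
    seq_parts <- c(seq_parts, body)
    cursor <- start + full_len
    feats[[k]] <- gene_feature(
      g, start, start + full_len,
      strand = if (!(g %in% CONTROL_SYMBOLS) && sign_of[[g]] < 0) "N"
               else "J")
  }
  ## trailing spacer closing the circle back to token 1
  tail_sp <- draw_bases(motifs$default_gap, probs)
  seq_parts <- c(seq_parts, tail_sp)
  sequence <- paste(seq_parts, collapse = "")

  features <- do.call(rbind, feats)
  genome <- mitogenome(config$id, sequence, features, circular = TRUE)

  ## genome coordinates of planted arrays
  arr_truth <- NULL
  if (length(cr_truths)) {
    arr_truth <- do.call(rbind, unname(cr_truths))
    seg_start <- features$start[match(arr_truth$segment, features$name)]
    arr_truth$start <- seg_start + arr_truth$seg_start
    arr_truth$end <- seg_start + arr_truth$seg_end
  }
  ncr_truth <- NULL
  if (!is.null(config$ncr)) {
    after_end <- features$end[features$name == config$ncr$after]
    ncr_truth <- list(start = after_end,
                      end = after_end + config$ncr$length,
                      source = config$ncr$source,
                      divergence = config$ncr$divergence)
  }

  truth <- list(seed = config$seed, id = config$id,
                final_order = format_gene_order(ord),
                events = oc$resolved,
                split_cr = config$split_cr,
                arrays = arr_truth,
                ncr = ncr_truth,
                genome_length = nchar(sequence),
                composition = composition_stats(sequence))
  list(genome = genome, truth = truth)
}

#' Nudge genome composition toward a target A+T content
#'
#' Resamples third codon positions of protein-coding genes (never the
#' start or stop codon, never a position where a substitution could create
#' an in-frame stop, never a position shared with another feature) and
#' non-coding/control-region bases until the realized A+T percentage is
#' within one percentage point of the target.  Annotations, starts and
#' stops are untouched.  Consumes the caller's RNG stream.
#'
#' @param genome a [mitogenome()].
#' @param at_content target A+T fraction, in [0.5, 0.9].
#' @return the adjusted [mitogenome()].
#' @export
perturb_composition <- function(genome, at_content) {
  stopifnot(at_content >= 0.5, at_content <= 0.9)
  x <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  n <- length(x)
  f <- genome$features
  cover <- integer(n)
  for (i in seq_len(nrow(f))) {
    idx <- ((f$start[i]:(f$end[i] - 1L)) %% n) + 1L
    cover[idx] <- cover[idx] + 1L
  }
  eligible <- rep(FALSE, n)
  eligible[cover == 0L] <- TRUE                      # intergenic
  for (i in which(f$kind == "control")) {
    idx <- ((f$start[i]:(f$end[i] - 1L)) %% n) + 1L
    eligible[idx[cover[idx] == 1L]] <- TRUE
  }
  for (i in which(f$kind == "PCG")) {
    len <- f$end[i] - f$start[i]
    n_cod <- len %/% 3L
    if (n_cod <= 2L) next
    third <- (2:(n_cod - 1L)) * 3L                   # coding positions
    gpos <- if (f$strand[i] == "J") f$start[i] + third - 1L
            else f$end[i] - third
    gpos <- (gpos %% n) + 1L
    ## skip codons whose first two coding bases are TA (stop risk)
    first2 <- vapply(third, function(tp) {
      cpos <- c(tp - 2L, tp - 1L)
      gp <- if (f$strand[i] == "J") f$start[i] + cpos - 1L
            else f$end[i] - cpos
      gp <- (gp %% n) + 1L
      b <- x[gp]
      if (f$strand[i] == "N") b <- chartr("ACGT", "TGCA", b)
      paste(b, collapse = "")
    }, "")
    ok <- first2 != "TA" & cover[gpos] == 1L
    eligible[gpos[ok]] <- TRUE
  }
  target <- 100 * at_content
  repeat {
    at_now <- 100 * sum(x %in% c("A", "T")) / sum(x != "N")
    if (abs(at_now - target) <= 1) break
    if (at_now < target) {
      pool <- which(eligible & x %in% c("G", "C"))
      to <- c("A", "T")
    } else {
      pool <- which(eligible & x %in% c("A", "T"))
      to <- c("G", "C")
    }
    need <- ceiling(abs(at_now - target) / 100 * sum(x != "N"))
    if (length(pool) == 0L)
      stop("target A+T content infeasible under codon constraints")
    pick <- if (length(pool) <= need) pool
            else sample(pool, need)
    x[pick] <- sample(to, length(pick), replace = TRUE)
  }
  genome$sequence <- paste(x, collapse = "")
  genome
}

#' Write a generator truth manifest as JSON
#' @param truth the \code{truth} element of [generate_mitogenome()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth$composition <- unclass(truth$composition)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
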