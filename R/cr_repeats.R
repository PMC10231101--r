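#' Detect tandem-repeat arrays in a DNA sequence
#'
#' Period detection works from the distance spectrum of repeated 8-mers:
#' any distance at which identical 8-mers recur often enough becomes a
#' candidate period.  Each candidate period p is then screened with the
#' self-match vector (base i compared with base i+p); maximal
#' high-identity segments, allowing short mismatch gaps from point
#' divergence between copies, delimit candidate arrays.  Candidate arrays
#' are refined by realigning successive unit-sized frames against their
#' column-majority consensus, scored by copies times identity, and
#' overlapping candidates are resolved greedily by score with ties going to
#' the smaller (primitive) unit and then the leftmost start.  Copy number
#' is reported both as a real (span / unit length) and rounded to the
#' nearest integer, matching the conventional "N x L bp" description of
#' control-region repeats.
#'
#' @param seq DNA character string; at least \code{2 * min_unit} long.
#' @param min_unit,max_unit unit-length bounds in bp (defaults 8 and 700).
#' @param min_copies minimum copy number (default 2).
#' @param min_identity unit-vs-consensus identity floor in percent
#'   (default 80).
#' @param circular treat \code{seq} as circular: detection runs on the
#'   doubled sequence and arrays are reported modulo its length.
#' @return data.frame with columns start, end (0-based half-open),
#'   unit_length, copies (real), copies_int, identity, consensus, sorted by
#'   start.  Zero rows when nothing is found.
#' @examples
#' find_tandem_repeats(strrep("ACGTACGTTG", 8), min_unit = 8)
#' @export
find_tandem_repeats <- function(seq, min_unit = 8L, max_unit = 700L,
                                min_copies = 2L, min_identity = 80,
                                circular = FALSE) {
  if (min_unit < 2L || max_unit < min_unit || min_copies < 2L ||
      min_identity <= 0 || min_identity > 100)
    stop("parameter bounds violated")
  seq <- toupper(seq)
  n0 <- nchar(seq)
  if (n0 < 2L * min_unit) stop("sequence shorter than 2 * min_unit")
  work <- if (circular) paste0(seq, seq) else seq
  x <- strsplit(work, "", fixed = TRUE)[[1]]
  n <- length(x)

  periods <- candidate_periods(work, min_unit, min(max_unit, n %/% 2L))
  cands <- list()
  for (p in periods) {
    segs <- period_segments(x, p, min_copies)
    for (s in segs) {
      arr <- refine_array(x, s[1L], s[2L], p)
      if (is.null(arr)) next
      if (arr$copies < min_copies - 0.1 || arr$identity < min_identity)
        next
      ## a two-copy array has little internal evidence; demand
      ## near-identical units (as real control-region duplications are)
      if (arr$copies < 2.5 && arr$identity < 95) next
      cands[[length(cands) + 1L]] <- arr
    }
  }
  if (length(cands) == 0L) return(empty_repeat_table())

  tab <- do.call(rbind, lapply(cands, as.data.frame,
                               stringsAsFactors = FALSE))
  ## greedy overlap resolution by score; ties: smaller unit, then leftmost
  tab$score <- tab$copies * tab$identity
  tab <- tab[order(-tab$score, tab$unit_length, tab$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    if (i < nrow(tab)) for (j in (i + 1L):nrow(tab)) {
      if (!keep[j]) next
      ov <- min(tab$end[i], tab$end[j]) - max(tab$start[i], tab$start[j])
      if (ov > 0.5 * min(tab$end[i] - tab$start[i],
                         tab$end[j] - tab$start[j]))
        keep[j] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]

  if (circular) {
    tab <- tab[tab$start < n0, , drop = FALSE]
    over <- tab$end - tab$start > n0
    tab$end[over] <- tab$start[over] + n0
    tab$copies[over] <- (tab$end[over] - tab$start[over]) /
      tab$unit_length[over]
    tab$copies_int[over] <- round(tab$copies[over])
  }
  tab <- tab[order(tab$start), , drop = FALSE]
  tab$score <- NULL
  rownames(tab) <- NULL
  tab
}

empty_repeat_table <- function() {
  data.frame(start = integer(), end = integer(), unit_length = integer(),
             copies = numeric(), copies_int = integer(),
             identity = numeric(), consensus = character(),
             stringsAsFactors = FALSE)
}

## distances at which identical 8-mers recur; a distance is a candidate
## period when at least 3 distinct 8-mer positions repeat at it
candidate_periods <- function(s, min_unit, max_unit) {
  k <- 8L
  n <- nchar(s)
  if (n < k + min_unit) return(integer())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  grp <- split(starts, kmers)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) == 0L) return(integer())
  d <- unlist(lapply(grp, function(pos) diff(pos)), use.names = FALSE)
  d <- d[d >= min_unit & d <= max_unit]
  if (length(d) == 0L) return(integer())
  tb <- table(d)
  sort(as.integer(names(tb)[tb >= 3L]))
}

## maximal segments of the self-match vector m[i] = (x[i] == x[i+p]) with
## sustained high local match density.  Point divergence between copies
## punches short mismatch gaps into m; a sliding-window density threshold
## bridges them while random flanking sequence (~25% matches) stays below
## it.  Segment boundaries are trimmed back to matching positions.
period_segments <- function(x, p, min_copies) {
  n <- length(x)
  if (n < 2L * p) return(list())
  m <- x[seq_len(n - p)] == x[(p + 1L):n]
  L <- length(m)
  w <- max(5L, min(p, 20L))
  if (L < w) return(list())
  cs <- cumsum(c(0L, m))
  dens <- (cs[(w + 1L):(L + 1L)] - cs[seq_len(L - w + 1L)]) / w
  good <- dens >= 0.55
  if (!any(good)) return(list())
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    a <- starts[k]
    b <- min(ends[k] + w - 1L, L)          # window end back to m-space
    while (a <= b && !m[a]) a <- a + 1L
    while (b >= a && !m[b]) b <- b - 1L
    if (b <= a) next
    len <- b - a + 1L
    if (len >= max(8L, (min_copies - 1L) * p - as.integer(0.25 * p)) &&
        (cs[b + 1L] - cs[a]) / len >= 0.7)
      segs[[length(segs) + 1L]] <- c(a, b)
  }
  segs
}

## consensus realignment of the candidate span [a, b]+p (1-based match
## coordinates); returns the refined array or NULL
refine_array <- function(x, a, b, p) {
  n <- length(x)
  arr_start <- a                       # 1-based inclusive
  arr_end <- min(b + p, n)             # 1-based inclusive
  span <- arr_end - arr_start + 1L
  nf <- span %/% p
  if (nf < 2L) return(NULL)
  frames <- matrix(x[arr_start:(arr_start + nf * p - 1L)], nrow = p)
  cons <- apply(frames, 1L, function(col) {
    tb <- table(col)
    names(tb)[which.max(tb)]
  })
  ident <- 100 * mean(frames == cons)
  list(start = arr_start - 1L,                  # 0-based half-open
       end = arr_start - 1L + span,
       unit_length = as.integer(p),
       copies = span / p,
       copies_int = as.integer(round(span / p)),
       identity = ident,
       consensus = paste(cons, collapse = ""))
}

#' Lay out a control region as a schematic of segments
#'
#' Tiles each control-region feature (CR, or CR1/CR2 for a split control
#' region) with its detected repeat arrays and unique segments, and
#' interleaves genes embedded between control-region segments (e.g. a tRNA
#' translocated into the middle of the CR).  Segments tile each CR span
#' without overlap.
#'
#' @param genome a [mitogenome()] with at least one control feature.
#' @param ... passed to [find_tandem_repeats()].
#' @return data.frame of class \code{cr_schematic} with columns segment
#'   (the CR feature name or "embedded"), kind (unique / repeat_array /
#'   embedded_gene), label, start, end (genome 0-based half-open),
#'   unit_length, copies_int.
#' @export
cr_schematic <- function(genome, ...) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  cr_idx <- which(f$kind == "control" & f$name %in% c("CR", "CR1", "CR2"))
  if (length(cr_idx) == 0L) stop("no control-region feature annotated")
  rows <- list()
  add <- function(segment, kind, label, start, end, unit = NA_integer_,
                  copies = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      segment = segment, kind = kind, label = label,
      start = as.integer(start), end = as.integer(end),
      unit_length = unit, copies_int = copies, stringsAsFactors = FALSE)
  }
  for (i in cr_idx) {
    cr <- f[i, ]
    s <- region_seq(genome, cr$start, cr$end)
    reps <- if (nchar(s) >= 16L) find_tandem_repeats(s, ...) else
      empty_repeat_table()
    pos <- 0L
    if (nrow(reps)) for (r in seq_len(nrow(reps))) {
      if (reps$start[r] > pos)
        add(cr$name, "unique", "unique", cr$start + pos,
            cr$start + reps$start[r])
      add(cr$name, "repeat_array",
          sprintf("%d x %d bp", reps$copies_int[r], reps$unit_length[r]),
          cr$start + reps$start[r], cr$start + reps$end[r],
          reps$unit_length[r], reps$copies_int[r])
      pos <- reps$end[r]
    }
    if (pos < nchar(s))
      add(cr$name, "unique", "unique", cr$start + pos, cr$end)
    ## genes embedded after this CR segment and before the next feature
    ## belong to the schematic when another CR segment follows them
  }
  ## embedded genes: at most two genes lying between two control segments
  ## along the circle (e.g. CR1 - trnI - CR2)
  if (length(cr_idx) > 1L) {
    nf <- nrow(f)
    for (k in seq_along(cr_idx)) {
      i <- cr_idx[k]
      j <- cr_idx[if (k == length(cr_idx)) 1L else k + 1L]
      between <- if (j > i) setdiff(seq(i, j), c(i, j))
                 else setdiff(c(seq(i, nf), seq_len(j)), c(i, j))
      between <- between[f$kind[between] != "control"]
      if (length(between) >= 1L && length(between) <= 2L)
        for (e in between)
          add("embedded", "embedded_gene", f$name[e], f$start[e], f$end[e])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cr_schematic", "data.frame")
  out
}

#' Render a control-region schematic as text
#'
#' One token per segment, in genome order, e.g.
#' \code{"CR1[unique 420 bp] | trnI | CR2[5 x 109 bp]"}.
#' @param x a [cr_schematic()].
#' @return character string.
#' @export
format_cr_schematic <- function(x) {
  toks <- vapply(seq_len(nrow(x)), function(i) {
    if (x$kind[i] == "embedded_gene") x$label[i]
    else if (x$kind[i] == "repeat_array")
      sprintf("%s[%s]", x$segment[i], x$label[i])
    else sprintf("%s[unique %d bp]", x$segment[i], x$end[i] - x$start[i])
  }, "")
  paste(toks, collapse = " | ")
}

#' Plot a control-region schematic
#'
#' Simple base-graphics rendering: one horizontal track with unique
#' segments in grey, repeat arrays in orange (labelled "N x L bp") and
#' embedded genes in steel blue.
#'
#' @param x a [cr_schematic()].
#' @param ... ignored.
#' @return invisibly, \code{x}.
#' @export
plot.cr_schematic <- function(x, ...) {
  rng <- range(c(x$start, x$end))
  graphics::plot(NULL, xlim = rng, ylim = c(0, 2), axes = FALSE,
                 xlab = "position (bp)", ylab = "",
                 main = "control-region layout")
  graphics::axis(1)
  cols <- c(unique = "grey80", repeat_array = "darkorange",
            embedded_gene = "steelblue")
  for (i in seq_len(nrow(x))) {
    graphics::rect(x$start[i], 0.6, x$end[i], 1.4,
                   col = cols[[x$kind[i]]], border = "grey30")
    if (x$kind[i] != "unique")
      graphics::text((x$start[i] + x$end[i]) / 2, 1.7, x$label[i],
                     cex = 0.8, srt = 45, adj = 0)
  }
  invisible(x)
}
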