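#' Signed circular gene orders
#'
#' A \code{gene_order} is a circular signed permutation over a gene
#' vocabulary (normally the canonical 37 mitochondrial genes), with
#' control-region markers (CR, CR1, CR2, NCR) carried as positional tokens
#' that are excluded from permutation arithmetic but retained for display.
#' Sign + means J-strand, - means N-strand.  Orders are linearized to begin
#' at trnI's slot when trnI is present; equality is rotation-invariant.
#'
#' @param symbols character vector of gene symbols/markers in circular
#'   positional order.
#' @param signs integer vector of +1/-1, same length.
#' @return object of class \code{gene_order}.
#' @export
gene_order <- function(symbols, signs = rep(1L, length(symbols))) {
  stopifnot(length(symbols) == length(signs), all(signs %in% c(-1L, 1L)))
  genes <- symbols[!(symbols %in% CONTROL_SYMBOLS)]
  if (anyDuplicated(genes))
    stop("duplicate gene in order: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  x <- structure(list(symbols = symbols, signs = as.integer(signs)),
                 class = "gene_order")
  canonical_rotation(x)
}

## rotate so trnI occupies the first slot (identity if trnI absent)
canonical_rotation <- function(x) {
  i <- match("trnI", x$symbols)
  if (is.na(i) || i == 1L) return(x)
  idx <- c(i:length(x$symbols), seq_len(i - 1L))
  x$symbols <- x$symbols[idx]
  x$signs <- x$signs[idx]
  x
}

## permutation view: markers dropped
order_genes <- function(x) {
  keep <- !(x$symbols %in% CONTROL_SYMBOLS)
  list(symbols = x$symbols[keep], signs = x$signs[keep])
}

#' The ancestral insect mitochondrial gene order
#'
#' Returns the embedded pancrustacean ground pattern (the Drosophila-type
#' arrangement of the 37 genes plus the control region) as a signed order:
#' trnI(+), trnQ(-), trnM(+), ND2(+), ... , rrnS(-), CR.
#'
#' @return a [gene_order()].
#' @export
ancestral_order <- function() {
  gene_order(ANCESTRAL_SYMBOLS, ANCESTRAL_SIGNS)
}

#' Format a signed gene order as a token line
#'
#' N-strand genes carry a leading \code{-}, e.g.
#' \code{"trnI -trnQ trnM ND2 ..."}.
#' @param x a [gene_order()].
#' @param markers include control-region markers (default TRUE).
#' @return single character string.
#' @export
format_gene_order <- function(x, markers = TRUE) {
  symbols <- x$symbols; signs <- x$signs
  if (!markers) {
    keep <- !(symbols %in% CONTROL_SYMBOLS)
    symbols <- symbols[keep]; signs <- signs[keep]
  }
  paste(ifelse(signs < 0, paste0("-", symbols), symbols), collapse = " ")
}

#' Parse a gene-order token line
#' @param line whitespace-separated tokens; leading "-" marks N-strand.
#' @return a [gene_order()].
#' @export
parse_gene_order <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
  gene_order(sub("^-", "", toks), signs)
}

#' @export
print.gene_order <- function(x, ...) {
  cat(format_gene_order(x), "\n")
  invisible(x)
}

#' Test two gene orders for (rotation-invariant) equality
#' @param a,b [gene_order()] objects.
#' @param markers compare marker positions too (default FALSE: permutation
#'   view only).
#' @return logical.
#' @export
orders_equal <- function(a, b, markers = FALSE) {
  if (markers) {
    identical(canonical_rotation(a)$symbols, canonical_rotation(b)$symbols) &&
      identical(canonical_rotation(a)$signs, canonical_rotation(b)$signs)
  } else {
    ga <- order_genes(canonical_rotation(a))
    gb <- order_genes(canonical_rotation(b))
    identical(ga$symbols, gb$symbols) && identical(ga$signs, gb$signs)
  }
}

#' Extract the signed gene order of an annotated genome
#'
#' Genes are taken in circular positional order with sign from strand
#' (J = +, N = -); control-region markers are interleaved at their
#' positions.  The result is linearized to begin at trnI's slot, so the
#' choice of sequence origin never changes the order.
#'
#' @param genome a [mitogenome()]; must validate with no errors.
#' @return a [gene_order()].
#' @export
extract_gene_order <- function(genome) {
  rep <- validate_annotation(genome)
  dup <- rep$code == "duplicate_gene"
  if (any(dup))
    stop("cannot form permutation: ",
         paste(rep$message[dup], collapse = "; "))
  if (n_errors(rep) > 0L)
    stop("genome fails validation: ",
         paste(rep$message[rep$severity == "error"], collapse = "; "))
  f <- genome$features
  f <- f[f$name %in% c(CANONICAL_GENES, CONTROL_SYMBOLS), , drop = FALSE]
  n <- nchar(genome$sequence)
  pos <- f$start %% n
  o <- order(pos)
  gene_order(f$name[o], ifelse(f$strand[o] == "N", -1L, 1L))
}

## --- breakpoints ------------------------------------------------------------

## circular signed adjacency list of the permutation view:
## rows "a|b" meaning signed gene a immediately followed by signed gene b
signed_adjacencies <- function(x) {
  g <- order_genes(x)
  n <- length(g$symbols)
  s <- ifelse(g$signs < 0, paste0("-", g$symbols), g$symbols)
  paste(s, s[c(2:n, 1L)], sep = "|")
}

## an adjacency (a,b) is present in an order if it reads (a,b) or (-b,-a)
adjacency_present <- function(adj, in_order_adjs) {
  parts <- strsplit(adj, "|", fixed = TRUE)[[1]]
  flip <- function(t) if (startsWith(t, "-")) substring(t, 2L) else
    paste0("-", t)
  rev_adj <- paste(flip(parts[2L]), flip(parts[1L]), sep = "|")
  (adj %in% in_order_adjs) || (rev_adj %in% in_order_adjs)
}

#' Breakpoint distance between two signed circular gene orders
#'
#' Counts signed adjacencies of \code{a} absent from \code{b}, circular and
#' orientation-aware: adjacency (x, y) also matches (-y, -x), the same
#' junction read from the other strand.  Control-region markers are
#' excluded.  Symmetric in its arguments.
#'
#' @param a,b [gene_order()] objects over the same gene set.
#' @return integer count.
#' @export
breakpoint_distance <- function(a, b) {
  ga <- order_genes(a); gb <- order_genes(b)
  if (!setequal(ga$symbols, gb$symbols))
    stop("gene-set mismatch: ",
         paste(c(setdiff(ga$symbols, gb$symbols),
                 setdiff(gb$symbols, ga$symbols)), collapse = ", "))
  aa <- signed_adjacencies(a)
  bb <- signed_adjacencies(b)
  sum(!vapply(aa, adjacency_present, TRUE, in_order_adjs = bb))
}

## --- translocation detection ------------------------------------------------

## display tokens for the translocation test: signs dropped, all CR-like
## markers collapsed to "CR"
transloc_tokens <- function(x) {
  s <- x$symbols
  s[s %in% CONTROL_SYMBOLS] <- "CR"
  s
}

## remove genes `rm`, collapse runs of consecutive CR tokens (circularly),
## return rotation-canonical token vector
reduced_tokens <- function(tokens, rm) {
  t <- tokens[!(tokens %in% rm)]
  if (length(t) > 1L) {
    keep <- !(t == "CR" & c(t[length(t)], t[-length(t)]) == "CR")
    t <- t[keep]
  }
  ## canonical rotation: anchor at the lexicographically smallest gene token
  genes <- t[t != "CR"]
  if (length(genes) == 0L) return(t)
  anchor <- min(genes)
  i <- which(t == anchor)[1L]
  c(t[i:length(t)], if (i > 1L) t[seq_len(i - 1L)])
}

## does removing gene set `rm` make the marker-inclusive token sequences
## circularly identical?
removal_fixes <- function(tok_a, tok_b, rm) {
  identical(reduced_tokens(tok_a, rm), reduced_tokens(tok_b, rm))
}

#' Compare two signed gene orders and report rearrangements
#'
#' Reports inverted genes (sign flipped between the orders), translocated
#' genes (a minimal set whose removal makes the remaining orders identical;
#' exact search over candidate subsets up to size 4, greedy beyond, flagged
#' heuristic), the breakpoint count, and the affected cluster: the named
#' rearrangement hot-spot block (e.g. ARNS1EF) containing all events, or
#' the minimal contiguous ancestral block otherwise.  Translocation is
#' judged on the marker-inclusive token sequence with split control regions
#' collapsed, so a gene moved into the middle of the control region (as in
#' a CR1-gene-CR2 arrangement) is detected even though the gene permutation
#' itself is unchanged.
#'
#' @param observed,reference [gene_order()] objects over the same gene set.
#' @return list of class \code{rearrangement_report}: identical,
#'   translocated (data.frame gene, ref_context, obs_context), inverted,
#'   breakpoints, affected_cluster, transloc_heuristic.
#' @export
compare_orders <- function(observed, reference) {
  go <- order_genes(observed); gr <- order_genes(reference)
  if (!setequal(go$symbols, gr$symbols))
    stop("gene-set mismatch: ",
         paste(c(setdiff(go$symbols, gr$symbols),
                 setdiff(gr$symbols, go$symbols)), collapse = ", "))

  inv <- go$symbols[go$signs != gr$signs[match(go$symbols, gr$symbols)]]
  bp <- breakpoint_distance(observed, reference)

  tok_o <- transloc_tokens(canonical_rotation(observed))
  tok_r <- transloc_tokens(canonical_rotation(reference))

  heur <- FALSE
  if (removal_fixes(tok_o, tok_r, character())) {
    transloc <- character()
  } else {
    ## candidates: genes flanking a changed adjacency, plus genes adjacent
    ## to a control marker in either order
    adj_o <- signed_adjacencies(observed)
    adj_r <- signed_adjacencies(reference)
    chg <- c(adj_o[!vapply(adj_o, adjacency_present, TRUE, adj_r)],
             adj_r[!vapply(adj_r, adjacency_present, TRUE, adj_o)])
    cand <- unique(sub("^-", "", unlist(strsplit(chg, "|", fixed = TRUE))))
    near_cr <- function(tok) {
      i <- which(tok == "CR")
      unique(tok[c((i %% length(tok)) + 1L,
                   ((i - 2L) %% length(tok)) + 1L)])
    }
    cand <- unique(c(cand, near_cr(tok_o), near_cr(tok_r)))
    cand <- setdiff(cand, "CR")
    ## deterministic order: by ancestral position, then name
    cand <- cand[order(match(cand, ANCESTRAL_SYMBOLS), cand)]
    transloc <- NULL
    for (k in 1:min(4L, length(cand))) {
      subsets <- utils::combn(cand, k, simplify = FALSE)
      for (s in subsets) {
        if (removal_fixes(tok_o, tok_r, s)) { transloc <- s; break }
      }
      if (!is.null(transloc)) break
    }
    if (is.null(transloc)) {
      ## greedy fallback for deep rearrangements
      heur <- TRUE
      transloc <- character()
      pool <- cand
      while (length(pool) > 0L &&
             !removal_fixes(tok_o, tok_r, transloc)) {
        scores <- vapply(pool, function(g) {
          ra <- reduced_tokens(tok_o, c(transloc, g))
          rb <- reduced_tokens(tok_r, c(transloc, g))
          if (length(ra) != length(rb)) return(0)
          sum(ra == rb)
        }, 0)
        best <- pool[which.max(scores)]
        transloc <- c(transloc, best)
        pool <- setdiff(pool, best)
      }
    }
  }

  context_of <- function(ord, g) {
    tok <- transloc_tokens(canonical_rotation(ord))
    i <- which(tok == g)[1L]
    n <- length(tok)
    paste(tok[((i - 2L) %% n) + 1L], tok[(i %% n) + 1L], sep = "|")
  }
  transloc_df <- if (length(transloc)) data.frame(
    gene = transloc,
    ref_context = vapply(transloc, context_of, "", ord = reference),
    obs_context = vapply(transloc, context_of, "", ord = observed),
    stringsAsFactors = FALSE) else
    data.frame(gene = character(), ref_context = character(),
               obs_context = character(), stringsAsFactors = FALSE)

  affected <- unique(c(inv, transloc))
  ident <- length(affected) == 0L && bp == 0L
  structure(list(
    identical = ident,
    translocated = transloc_df,
    inverted = inv,
    breakpoints = bp,
    affected_cluster = if (ident) "" else cluster_label(affected),
    transloc_heuristic = heur), class = "rearrangement_report")
}

## smallest named hot-spot cluster containing all affected genes, else the
## minimal contiguous ancestral block, rendered with short letter codes
cluster_label <- function(genes) {
  genes <- genes[genes %in% ANCESTRAL_SYMBOLS]
  if (length(genes) == 0L) return("")
  for (nm in names(HOTSPOT_CLUSTERS))
    if (all(genes %in% HOTSPOT_CLUSTERS[[nm]])) return(nm)
  idx <- sort(match(genes, ANCESTRAL_SYMBOLS))
  block <- ANCESTRAL_SYMBOLS[idx[1L]:idx[length(idx)]]
  lab <- ifelse(block %in% names(TRNA_LETTER), TRNA_LETTER[block], block)
  paste(lab, collapse = "-")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  if (x$identical) { cat("orders identical\n"); return(invisible(x)) }
  cat("breakpoints:", x$breakpoints, "\n")
  if (length(x$inverted))
    cat("inverted:", paste(x$inverted, collapse = ", "), "\n")
  if (nrow(x$translocated))
    cat("translocated:", paste(x$translocated$gene, collapse = ", "),
        if (x$transloc_heuristic) "(heuristic)", "\n")
  if (nzchar(x$affected_cluster))
    cat("affected cluster:", x$affected_cluster, "\n")
  invisible(x)
}
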