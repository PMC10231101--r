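#' Construct a gene feature record
#'
#' Features use 0-based half-open coordinates on the linearized circle;
#' \code{end} may exceed the sequence length to encode a feature that wraps
#' around the origin.  Strand is \code{"J"} (majority) or \code{"N"}
#' (minority); control features carry strand \code{"J"} by convention.
#'
#' @param name canonical symbol (see [map_feature_name()]) or free text for
#'   \code{noncoding} features.
#' @param kind one of \code{"PCG"}, \code{"tRNA"}, \code{"rRNA"},
#'   \code{"control"}, \code{"noncoding"}; defaults to the kind implied by
#'   the canonical symbol.
#' @param strand \code{"J"} or \code{"N"}.
#' @param start,end 0-based half-open span, \code{end > start}.
#' @return one-row data.frame with columns name, kind, strand, start, end.
#' @export
gene_feature <- function(name, start, end, strand = "J", kind = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            start >= 0, end > start, strand %in% c("J", "N"))
  if (is.null(kind)) kind <- gene_kind(name)
  stopifnot(kind %in% c("PCG", "tRNA", "rRNA", "control", "noncoding"))
  data.frame(name = name, kind = kind, strand = strand,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome
#'
#' @param id free-text identifier.
#' @param sequence uppercase DNA string over A, C, G, T, N.
#' @param features data.frame of feature rows as produced by
#'   [gene_feature()] (rbind-ed); sorted by start on construction.
#' @param circular logical; coordinate arithmetic is modulo sequence length
#'   when \code{TRUE}.
#' @return object of class \code{mitogenome}.
#' @export
mitogenome <- function(id, sequence, features, circular = TRUE) {
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0L,
            grepl("^[ACGTN]+$", sequence),
            is.data.frame(features))
  features <- features[order(features$start, features$name), , drop = FALSE]
  rownames(features) <- NULL
  if (anyDuplicated(features[, c("name", "start")]))
    stop("duplicate (name, start) feature pair")
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp, %s, %d features\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' @export
length.mitogenome <- function(x) nchar(x$sequence)

## reverse complement on plain character strings (N-safe)
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a feature's sequence on its coding strand
#'
#' Wraparound features (end > genome length) are resolved modulo the
#' sequence length; N-strand features are reverse-complemented.
#'
#' @param genome a [mitogenome()].
#' @param feature one-row feature data.frame (or list with name/strand/
#'   start/end), or a feature name to look up.
#' @return DNA character string, 5' to 3' on the coding strand.
#' @export
feature_seq <- function(genome, feature) {
  if (is.character(feature)) {
    i <- which(genome$features$name == feature)
    if (length(i) != 1L)
      stop("feature '", feature, "' matches ", length(i), " annotations")
    feature <- genome$features[i, ]
  }
  s <- region_seq(genome, feature$start, feature$end)
  if (feature$strand == "N") revcomp(s) else s
}

## genome-strand sequence of [start, end), modulo length when circular
region_seq <- function(genome, start, end) {
  n <- nchar(genome$sequence)
  stopifnot(end > start, start >= 0)
  if (end <= n) return(substr(genome$sequence, start + 1L, end))
  if (!genome$circular || end > 2L * n)
    stop("span [", start, ",", end, ") outside a ", n, " bp genome")
  paste0(substr(genome$sequence, start + 1L, n),
         substr(genome$sequence, 1L, end - n))
}

#' Validate the structural annotation of a mitogenome
#'
#' Checks the canonical 37-gene complement (13 PCGs, 22 tRNAs, 2 rRNAs):
#' errors for missing or duplicated canonical genes (duplicate control
#' regions are allowed but flagged as a "split control region" warning),
#' same-strand protein-coding overlaps longer than 50 bp, and features
#' lying outside the sequence; warnings for intergenic non-coding stretches
#' of 50 bp or more.  Always returns a report; an empty issue table means
#' the genome passes every structural check.
#'
#' @param genome a [mitogenome()].
#' @return object of class \code{validation_report}: a data.frame with
#'   columns severity, code, message, feature.
#' @export
validate_annotation <- function(genome) {
  iss <- list()
  add <- function(severity, code, message, feature = "-") {
    iss[[length(iss) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      feature = feature, stringsAsFactors = FALSE)
  }
  f <- genome$features
  n <- nchar(genome$sequence)

  counts <- table(f$name[f$name %in% CANONICAL_GENES])
  for (g in CANONICAL_GENES) {
    k <- if (g %in% names(counts)) counts[[g]] else 0L
    if (k == 0L) add("error", "missing_gene", paste("missing gene", g), g)
    if (k > 1L) add("error", "duplicate_gene", paste("duplicated gene", g), g)
  }
  n_cr <- sum(f$name %in% c("CR", "CR1", "CR2"))
  if (n_cr > 1L)
    add("warning", "split_cr", "split control region", "CR")
  if (n_cr == 0L)
    add("warning", "no_cr", "no control region annotated", "CR")

  for (i in seq_len(nrow(f))) {
    if (f$start[i] >= n || f$end[i] > 2L * n ||
        (!genome$circular && f$end[i] > n))
      add("error", "outside_sequence",
          sprintf("feature %s [%d,%d) outside %d bp sequence",
                  f$name[i], f$start[i], f$end[i], n), f$name[i])
  }

  ## same-strand PCG overlaps > 50 bp
  pcg <- f[f$kind == "PCG", , drop = FALSE]
  if (nrow(pcg) > 1L) {
    for (i in seq_len(nrow(pcg) - 1L)) {
      for (j in (i + 1L):nrow(pcg)) {
        if (pcg$strand[i] != pcg$strand[j]) next
        ov <- min(pcg$end[i], pcg$end[j]) - max(pcg$start[i], pcg$start[j])
        if (ov > 50L)
          add("error", "pcg_overlap",
              sprintf("same-strand PCGs %s and %s overlap by %d bp",
                      pcg$name[i], pcg$name[j], ov), pcg$name[i])
      }
    }
  }

  ## long unannotated stretches (candidate NCRs)
  if (nrow(f) > 1L) {
    o <- f[order(f$start), , drop = FALSE]
    gaps <- c(o$start[-1L], o$start[1L] + n) -
      c(o$end[-nrow(o)], o$end[nrow(o)])
    long <- which(gaps >= 50L)
    for (i in long)
      add("warning", "long_ncr",
          sprintf("%d bp non-coding region after %s", gaps[i], o$name[i]),
          o$name[i])
  }

  rep <- if (length(iss)) do.call(rbind, iss) else
    data.frame(severity = character(), code = character(),
               message = character(), feature = character(),
               stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("annotation OK: no issues\n")
  else print.data.frame(x, ...)
  invisible(x)
}

#' Count validation errors
#' @param report a [validate_annotation()] result.
#' @return integer number of error-severity issues.
#' @export
n_errors <- function(report) sum(report$severity == "error")

## --- GenBank flat-file I/O ------------------------------------------------
## Minimal single-record reader/writer for the feature-table subset this
## package emits: LOCUS, FEATURES (CDS/tRNA/rRNA/D-loop/misc_feature with
## complement()/join() locations), ORIGIN.  Coordinates are converted
## between GenBank 1-based inclusive and internal 0-based half-open at this
## boundary only.

feature_to_gb <- function(feat, seqlen) {
  loc <- if (feat$end <= seqlen) {
    sprintf("%d..%d", feat$start + 1L, feat$end)
  } else {
    sprintf("join(%d..%d,1..%d)", feat$start + 1L, seqlen, feat$end - seqlen)
  }
  if (feat$strand == "N") loc <- sprintf("complement(%s)", loc)
  key <- switch(feat$kind,
                PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                control = "D-loop", noncoding = "misc_feature")
  quals <- character()
  q <- function(k, v) sprintf('                     /%s="%s"', k, v)
  if (feat$kind == "PCG") {
    quals <- c(q("gene", feat$name))
  } else if (feat$kind == "tRNA") {
    aa <- names(AA3_TO_TRN)[match(substr(feat$name, 1, 4), AA3_TO_TRN)]
    prod <- if (!is.na(aa)) paste0("tRNA-", aa) else switch(
      substr(feat$name, 1, 5),
      trnL1 = "tRNA-Leu", trnL2 = "tRNA-Leu",
      trnS1 = "tRNA-Ser", trnS2 = "tRNA-Ser", feat$name)
    note <- switch(feat$name, trnL1 = "(CUN)", trnL2 = "(UUR)",
                   trnS1 = "(AGN)", trnS2 = "(UCN)", NULL)
    quals <- c(q("product", prod), q("gene", feat$name),
               if (!is.null(note)) q("note", note))
  } else if (feat$kind == "rRNA") {
    prod <- if (feat$name == "rrnS") "12S ribosomal RNA"
            else "16S ribosomal RNA"
    quals <- c(q("product", prod), q("gene", feat$name))
  } else if (feat$kind == "control") {
    quals <- q("note", switch(feat$name,
                              CR1 = "control region 1",
                              CR2 = "control region 2",
                              "control region"))
  } else {
    quals <- q("note", feat$name)
  }
  c(sprintf("     %-16s%s", key, loc), quals)
}

#' Write an annotated mitogenome as a GenBank flat file
#'
#' Emits a single-record flat file that [read_genbank()] parses back to an
#' equal genome.  Wraparound features are written as \code{join()}
#' locations; N-strand features as \code{complement()}.
#'
#' @param genome a [mitogenome()]; must validate with no errors except that
#'   gene-complement errors are tolerated for partial/toy genomes.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  if (any(genome$features$end > 2L * n))
    stop("feature extends past twice the sequence length")
  topo <- if (genome$circular) "circular" else "linear"
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s INV 01-JAN-2024",
            gsub("[^A-Za-z0-9_.-]", "_", genome$id), n, topo),
    sprintf("DEFINITION  %s mitochondrion.", genome$id),
    sprintf("ACCESSION   %s", gsub("[^A-Za-z0-9_.-]", "_", genome$id)),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    '                     /organelle="mitochondrion"')
  for (i in seq_len(nrow(genome$features)))
    lines <- c(lines, feature_to_gb(genome$features[i, ], n))
  lines <- c(lines, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

parse_gb_location <- function(loc, seqlen, line_no) {
  strand <- "J"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    m <- regmatches(parts, regexec("^([0-9]+)\\.\\.([0-9]+)$", parts))
    if (any(lengths(m) != 3L))
      stop("cannot parse location at line ", line_no, ": ", loc)
    a <- as.integer(vapply(m, `[`, "", 2L))
    b <- as.integer(vapply(m, `[`, "", 3L))
    if (length(parts) == 2L && b[1L] == seqlen && a[2L] == 1L) {
      ## wraparound across the origin -> end > seqlen convention
      return(list(start = a[1L] - 1L, end = seqlen + b[2L], strand = strand))
    }
    ## contiguous join segments collapse into one span
    if (all(utils::head(b, -1L) + 1L == a[-1L]))
      return(list(start = a[1L] - 1L, end = b[length(b)], strand = strand))
    stop("unsupported join() location at line ", line_no, ": ", loc)
  }
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3L)
    stop("cannot parse location at line ", line_no, ": ", loc)
  list(start = as.integer(m[2L]) - 1L, end = as.integer(m[3L]),
       strand = strand)
}

#' Read a single-record GenBank flat file
#'
#' Parses LOCUS, the feature table and ORIGIN of one circular or linear DNA
#' record, and maps feature names onto the canonical vocabulary
#' (e.g. \code{"tRNA-Ile"} to \code{trnI}, \code{"s-rRNA"} to \code{rrnS},
#' \code{"D-loop"} to \code{CR}).  \code{join()} locations that wrap the
#' origin collapse into a single feature with \code{end} greater than the
#' sequence length.  Features whose names cannot be mapped are retained
#' with kind \code{noncoding} and a warning.
#'
#' @param path GenBank flat file with exactly one record.
#' @return a [mitogenome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term <- which(trimws(lines) == "//")
  if (length(term) > 1L)
    stop("multiple records in ", path, "; supply one record per file")

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L)
    stop("malformed record: expected one LOCUS line, found ",
         length(locus_i), " (line ",
         if (length(locus_i)) locus_i[1] else NA, ")")
  locus <- lines[locus_i]
  lm <- regmatches(locus,
                   regexec("^LOCUS\\s+(\\S+)\\s+([0-9]+)\\s+bp", locus))[[1]]
  if (length(lm) != 3L) stop("malformed LOCUS line at line ", locus_i)
  id <- lm[2L]
  seqlen <- as.integer(lm[3L])
  circular <- grepl("circular", locus)

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(feat_i) != 1L || length(orig_i) != 1L)
    stop("malformed record: FEATURES/ORIGIN section missing in ", path)

  ## sequence
  seq_lines <- lines[(orig_i + 1L):(if (length(term)) term[1L] - 1L
                                    else length(lines))]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != seqlen)
    stop("sequence length ", nchar(sequence),
         " does not match LOCUS length ", seqlen)

  ## feature table
  rows <- list()
  i <- feat_i + 1L
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || cur$key == "source") return(NULL)
    sym <- map_feature_name(cur$quals[["gene"]], cur$quals[["product"]],
                            cur$quals[["note"]])
    if (is.na(sym)) {
      nm <- cur$quals[["gene"]]
      if (is.null(nm) || is.na(nm)) nm <- cur$quals[["product"]]
      if (is.null(nm) || is.na(nm)) nm <- cur$quals[["note"]]
      if (is.null(nm) || is.na(nm)) nm <- cur$key
      warning("unmapped feature '", nm, "' retained as noncoding")
      return(gene_feature(nm, cur$loc$start, cur$loc$end, cur$loc$strand,
                          kind = "noncoding"))
    }
    kind <- switch(cur$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   "D-loop" = "control", misc_feature = gene_kind(sym),
                   gene = gene_kind(sym), gene_kind(sym))
    gene_feature(sym, cur$loc$start, cur$loc$end, cur$loc$strand, kind = kind)
  }
  while (i < orig_i) {
    ln <- lines[i]
    if (grepl("^ {5}\\S", ln)) {            # new feature
      r <- flush(cur)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
      key <- trimws(substr(ln, 1L, 20L))
      loc <- trimws(substr(ln, 21L, nchar(ln)))
      j <- i + 1L                            # continuation of the location
      while (j < orig_i && grepl("^ {21}", lines[j]) &&
             !grepl("^ {21}/", lines[j])) {
        loc <- paste0(loc, trimws(lines[j])); j <- j + 1L
      }
      cur <- list(key = key, loc = parse_gb_location(loc, seqlen, i),
                  quals = list())
      i <- j
    } else if (grepl("^ {21}/", ln)) {      # qualifier
      qm <- regmatches(ln, regexec('^\\s+/([A-Za-z_]+)=?"?([^"]*)"?', ln))[[1]]
      if (length(qm) == 3L && !is.null(cur)) {
        ## keep the first occurrence of each qualifier key
        if (is.null(cur$quals[[qm[2L]]])) cur$quals[[qm[2L]]] <- qm[3L]
      }
      i <- i + 1L
    } else i <- i + 1L
  }
  r <- flush(cur)
  if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  features <- if (length(rows)) do.call(rbind, rows) else
    gene_feature("CR", 0, 1)[0, ]
  mitogenome(id, sequence, features, circular = circular)
}

#' Read a mitogenome from FASTA plus a TSV feature table
#'
#' The feature table has columns name, kind, strand, start, end with
#' 0-based half-open coordinates (header row required).
#'
#' @param fasta_path single-sequence FASTA file.
#' @param features_path tab-separated feature table.
#' @return a [mitogenome()].
#' @export
read_fasta_tsv <- function(fasta_path, features_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L)
    stop("expected one sequence in ", fasta_path, ", found ", length(dna))
  tab <- utils::read.delim(features_path, stringsAsFactors = FALSE)
  need <- c("name", "kind", "strand", "start", "end")
  if (!all(need %in% names(tab)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  feats <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    gene_feature(tab$name[i], tab$start[i], tab$end[i], tab$strand[i],
                 kind = tab$kind[i])))
  mitogenome(sub("\\s.*", "", names(dna)[1L]), as.character(dna[[1L]]), feats)
}

#' Write a validation report as JSON
#' @param report a [validate_annotation()] result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(unclass(report)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
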