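#' Run the full comparative-mitogenomics analysis over a set of genomes
#'
#' For each input genome (a file path to a GenBank record or a
#' [mitogenome()] object) runs, in dependency order: annotation
#' validation, whole-genome and per-class composition statistics, the
#' junction table, codon usage/RSCU, signed gene-order extraction, the
#' rearrangement mechanism call against a reference order, and
#' control-region repeat detection.  A failure in one genome quarantines
#' that genome (its section records the error) and never affects the
#' others; the cross-genome summary is computed over the successes.
#'
#' @param inputs list (or character vector) of GenBank file paths and/or
#'   \code{mitogenome} objects; at least one.
#' @param reference reference [gene_order()] for mechanism calls (default
#'   [ancestral_order()]).
#' @param repeat_args list of arguments passed on to
#'   [find_tandem_repeats()].
#' @return list of class \code{mito_run_report}: \code{genomes} (named
#'   per-genome sections), \code{summary} (length/skew/A+T ranges, shared
#'   junction motifs, mechanism tally), \code{provenance},
#'   \code{n_failed}.
#' @export
run_pipeline <- function(inputs, reference = ancestral_order(),
                         repeat_args = list()) {
  if (length(inputs) == 0L) stop("no inputs supplied")
  if (is.character(inputs)) inputs <- as.list(inputs)
  sections <- list()
  for (inp in inputs) {
    sec <- analyze_genome(inp, reference, repeat_args)
    nm <- if (!is.null(sec$id)) sec$id else paste0("input", length(sections) + 1L)
    while (nm %in% names(sections)) nm <- paste0(nm, "_dup")
    sections[[nm]] <- sec
  }
  ok <- vapply(sections, function(s) is.null(s$error), TRUE)
  if (!any(ok)) stop("zero parseable inputs")

  lens <- vapply(sections[ok], function(s) s$composition$length, 0)
  ats <- vapply(sections[ok], function(s) s$composition$pct_AT, 0)
  atsk <- vapply(sections[ok], function(s) s$composition$at_skew, 0)
  gcsk <- vapply(sections[ok], function(s) s$composition$gc_skew, 0)
  mech <- vapply(sections[ok], function(s)
    if (is.null(s$mechanism)) "unavailable" else s$mechanism$label, "")
  juncs <- lapply(sections[ok], function(s) s$junctions)
  shared <- if (sum(ok) >= 2L) shared_junction_motifs(juncs) else NULL

  report <- list(
    genomes = sections,
    summary = list(
      n_genomes = length(sections), n_ok = sum(ok),
      length_range = range(lens),
      pct_AT_range = range(ats),
      at_skew_range = range(atsk),
      gc_skew_range = range(gcsk),
      mechanism_tally = as.list(table(mech)),
      shared_junction_motifs = shared),
    provenance = list(
      tool = "mitocomp",
      version = as.character(utils::packageVersion("mitocomp")),
      n_inputs = length(inputs)),
    n_failed = sum(!ok))
  class(report) <- "mito_run_report"
  report
}

## one genome's sections; any stage error quarantines the genome
analyze_genome <- function(input, reference, repeat_args) {
  out <- tryCatch({
    genome <- if (inherits(input, "mitogenome")) input
              else suppressWarnings(read_genbank(input))
    val <- validate_annotation(genome)
    sec <- list(id = genome$id,
                validation = as.data.frame(unclass(val)),
                composition = unclass(composition_stats(genome$sequence)))
    sec$by_class <- lapply(strandwise_stats(genome), unclass)
    sec$junctions <- gene_junctions(genome)
    cu <- suppressWarnings(codon_usage(genome))
    sec$codon_usage <- list(codons = cu$codons,
                            aa_percent = as.list(cu$aa_percent),
                            per_gene = cu$per_gene)
    if (n_errors(val) == 0L) {
      ord <- extract_gene_order(genome)
      sec$gene_order <- format_gene_order(ord)
      cmp <- compare_orders(ord, reference)
      mc <- classify_mechanism(cmp, reference, ord)
      sec$mechanism <- list(label = mc$label, narrative = mc$narrative,
                            n_scenarios = length(mc$scenarios))
    } else {
      sec$gene_order <- NULL
      sec$mechanism <- NULL
    }
    cr <- genome$features[genome$features$kind == "control", , drop = FALSE]
    sec$cr_repeats <- if (nrow(cr)) do.call(rbind, lapply(
      seq_len(nrow(cr)), function(i) {
        s <- region_seq(genome, cr$start[i], cr$end[i])
        if (nchar(s) < 16L) return(empty_repeat_table())
        r <- do.call(find_tandem_repeats, c(list(s), repeat_args))
        if (nrow(r)) r$segment <- cr$name[i] else r$segment <- character()
        r
      })) else empty_repeat_table()
    sec
  }, error = function(e) {
    list(id = if (inherits(input, "mitogenome")) input$id
              else as.character(input),
         error = conditionMessage(e))
  })
  out
}

#' Junction motifs shared across genomes
#'
#' For each junction (upstream/downstream feature pair) present in every
#' genome's junction table, reports the overlap length and sequence when
#' identical across all genomes, else marks the junction variable.
#'
#' @param junction_tables list (length at least 2) of [gene_junctions()]
#'   tables.
#' @return data.frame: junction, status ("shared" or "variable"),
#'   overlap_bp, motif.
#' @export
shared_junction_motifs <- function(junction_tables) {
  stopifnot(length(junction_tables) >= 2L)
  keys <- lapply(junction_tables, function(j)
    paste(j$upstream, j$downstream, sep = "/"))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L)
    return(data.frame(junction = character(), status = character(),
                      overlap_bp = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(common, function(k) {
    gaps <- vapply(seq_along(junction_tables), function(i) {
      j <- junction_tables[[i]]
      j$gap_bp[keys[[i]] == k][1L]
    }, 0L)
    seqs <- vapply(seq_along(junction_tables), function(i) {
      j <- junction_tables[[i]]
      s <- j$overlap_seq[keys[[i]] == k][1L]
      if (is.na(s)) "" else s
    }, "")
    if (length(unique(gaps)) == 1L && length(unique(seqs)) == 1L)
      data.frame(junction = k, status = "shared", overlap_bp = -gaps[1L],
                 motif = if (nzchar(seqs[1L])) seqs[1L] else NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(junction = k, status = "variable", overlap_bp = NA_integer_,
                 motif = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mito_run_report <- function(x, ...) {
  cat(sprintf("<mito_run_report> %d genome(s), %d failed\n",
              x$summary$n_genomes, x$n_failed))
  cat(sprintf("  length %d-%d bp | A+T %.1f-%.1f%% | AT-skew %.3f-%.3f\n",
              x$summary$length_range[1L], x$summary$length_range[2L],
              x$summary$pct_AT_range[1L], x$summary$pct_AT_range[2L],
              x$summary$at_skew_range[1L], x$summary$at_skew_range[2L]))
  cat("  mechanisms:",
      paste(names(x$summary$mechanism_tally),
            unlist(x$summary$mechanism_tally), sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

#' Write a run report as JSON
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(path)
}
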