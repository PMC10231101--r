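#' @title Canonical mitochondrial gene vocabulary
#' @description Internal constants: the 37 canonical metazoan mitochondrial
#'   gene symbols, control-region markers, the ancestral insect
#'   (Drosophila-type) signed gene order, and the GenBank name-mapping table.
#' @name vocab
#' @keywords internal
NULL

## 13 protein-coding genes
PCG_SYMBOLS <- c("ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3", "ND3",
                 "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1")

## 22 tRNAs; leucine and serine each have two isoacceptors:
## trnL1 = Leu(CUN), trnL2 = Leu(UUR), trnS1 = Ser(AGN), trnS2 = Ser(UCN)
TRNA_SYMBOLS <- c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY", "trnL2",
                  "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS1",
                  "trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1",
                  "trnV")

RRNA_SYMBOLS <- c("rrnS", "rrnL")

CANONICAL_GENES <- c(PCG_SYMBOLS, TRNA_SYMBOLS, RRNA_SYMBOLS)

## control-region / non-coding markers (not part of the 37-gene permutation)
CONTROL_SYMBOLS <- c("CR", "CR1", "CR2", "NCR")

gene_kind <- function(symbol) {
  ifelse(symbol %in% PCG_SYMBOLS, "PCG",
  ifelse(symbol %in% TRNA_SYMBOLS, "tRNA",
  ifelse(symbol %in% RRNA_SYMBOLS, "rRNA",
  ifelse(symbol %in% CONTROL_SYMBOLS, "control", "noncoding"))))
}

## Ancestral insect (pancrustacean ground pattern) gene order, linearized at
## trnI, with the control region at the end.  Sign + = J-strand (majority),
## - = N-strand (minority).
ANCESTRAL_SYMBOLS <- c(
  "trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY", "COX1", "trnL2",
  "COX2", "trnK", "trnD", "ATP8", "ATP6", "COX3", "trnG", "ND3", "trnA",
  "trnR", "trnN", "trnS1", "trnE", "trnF", "ND5", "trnH", "ND4", "ND4L",
  "trnT", "trnP", "ND6", "CYTB", "trnS2", "ND1", "trnL1", "rrnL", "trnV",
  "rrnS", "CR")

ANCESTRAL_SIGNS <- c(
  +1, -1, +1, +1, +1, -1, -1, +1, +1,
  +1, +1, +1, +1, +1, +1, +1, +1, +1,
  +1, +1, +1, +1, -1, -1, -1, -1, -1,
  +1, -1, +1, +1, +1, -1, -1, -1, -1,
  -1, +1)

## Named rearrangement hot-spot clusters (contiguous ancestral blocks that
## the literature refers to by a letter code).
HOTSPOT_CLUSTERS <- list(
  ARNS1EF = c("trnA", "trnR", "trnN", "trnS1", "trnE", "trnF"),
  IQM     = c("trnI", "trnQ", "trnM")
)

## one-letter display codes for tRNAs, used when rendering cluster labels
TRNA_LETTER <- c(
  trnI = "I", trnQ = "Q", trnM = "M", trnW = "W", trnC = "C", trnY = "Y",
  trnL2 = "L2", trnK = "K", trnD = "D", trnG = "G", trnA = "A", trnR = "R",
  trnN = "N", trnS1 = "S1", trnE = "E", trnF = "F", trnH = "H", trnT = "T",
  trnP = "P", trnS2 = "S2", trnL1 = "L1", trnV = "V")

## amino-acid 3-letter codes -> tRNA symbol stems (GenBank "tRNA-Xxx")
AA3_TO_TRN <- c(
  Ala = "trnA", Arg = "trnR", Asn = "trnN", Asp = "trnD", Cys = "trnC",
  Gln = "trnQ", Glu = "trnE", Gly = "trnG", His = "trnH", Ile = "trnI",
  Lys = "trnK", Met = "trnM", Phe = "trnF", Pro = "trnP", Thr = "trnT",
  Trp = "trnW", Tyr = "trnY", Val = "trnV")

## GenBank product / gene qualifier strings -> canonical symbols.
## Leucine/serine tRNAs are resolved by anticodon-class annotations
## (UUR/CUN/AGN/UCN), handled in map_feature_name().
NAME_MAP <- c(
  "nd1" = "ND1", "nad1" = "ND1", "nadh dehydrogenase subunit 1" = "ND1",
  "nd2" = "ND2", "nad2" = "ND2", "nadh dehydrogenase subunit 2" = "ND2",
  "nd3" = "ND3", "nad3" = "ND3", "nadh dehydrogenase subunit 3" = "ND3",
  "nd4" = "ND4", "nad4" = "ND4", "nadh dehydrogenase subunit 4" = "ND4",
  "nd4l" = "ND4L", "nad4l" = "ND4L",
  "nadh dehydrogenase subunit 4l" = "ND4L",
  "nd5" = "ND5", "nad5" = "ND5", "nadh dehydrogenase subunit 5" = "ND5",
  "nd6" = "ND6", "nad6" = "ND6", "nadh dehydrogenase subunit 6" = "ND6",
  "cox1" = "COX1", "coi" = "COX1", "co1" = "COX1",
  "cytochrome c oxidase subunit i" = "COX1",
  "cytochrome c oxidase subunit 1" = "COX1",
  "cox2" = "COX2", "coii" = "COX2", "co2" = "COX2",
  "cytochrome c oxidase subunit ii" = "COX2",
  "cytochrome c oxidase subunit 2" = "COX2",
  "cox3" = "COX3", "coiii" = "COX3", "co3" = "COX3",
  "cytochrome c oxidase subunit iii" = "COX3",
  "cytochrome c oxidase subunit 3" = "COX3",
  "atp6" = "ATP6", "atpase6" = "ATP6", "atp synthase f0 subunit 6" = "ATP6",
  "atp8" = "ATP8", "atpase8" = "ATP8", "atp synthase f0 subunit 8" = "ATP8",
  "cytb" = "CYTB", "cob" = "CYTB", "cytochrome b" = "CYTB",
  "12s" = "rrnS", "12s rrna" = "rrnS", "12s ribosomal rna" = "rrnS",
  "s-rrna" = "rrnS", "rrns" = "rrnS", "small subunit ribosomal rna" = "rrnS",
  "16s" = "rrnL", "16s rrna" = "rrnL", "16s ribosomal rna" = "rrnL",
  "l-rrna" = "rrnL", "rrnl" = "rrnL", "large subunit ribosomal rna" = "rrnL",
  "d-loop" = "CR", "control region" = "CR", "cr" = "CR",
  "control region 1" = "CR1", "cr1" = "CR1",
  "control region 2" = "CR2", "cr2" = "CR2",
  "ncr" = "NCR", "non-coding region" = "NCR")

#' Map a GenBank feature description onto the canonical gene vocabulary
#'
#' Resolves GenBank \code{/gene}, \code{/product} and \code{/note} qualifier
#' strings to one of the canonical symbols (13 PCGs, 22 tRNAs including the
#' two leucine and two serine isoacceptors, rrnS, rrnL, and the
#' control-region markers CR/CR1/CR2/NCR).  Unknown names return
#' \code{NA_character_}; callers degrade such features to kind
#' \code{noncoding} with a warning rather than failing.
#'
#' @param gene,product,note character scalars (may be \code{NA}); any GenBank
#'   qualifier text describing the feature.
#' @return canonical symbol or \code{NA_character_}.
#' @examples
#' map_feature_name(product = "tRNA-Leu", note = "(UUR)")  # "trnL2"
#' map_feature_name(gene = "COI")                          # "COX1"
#' @export
map_feature_name <- function(gene = NA, product = NA, note = NA) {
  txts <- tolower(stats::na.omit(c(gene, product, note)))
  if (length(txts) == 0L) return(NA_character_)
  all_txt <- paste(txts, collapse = " ")

  ## canonical symbols used directly (e.g. in our own output, or "trnL1")
  for (t in txts) {
    t0 <- sub("^trn", "trn", t)
    hit <- CANONICAL_GENES[tolower(CANONICAL_GENES) == t0]
    if (length(hit)) return(hit[1L])
    if (t0 %in% tolower(CONTROL_SYMBOLS))
      return(CONTROL_SYMBOLS[tolower(CONTROL_SYMBOLS) == t0][1L])
  }

  ## tRNA-Xxx forms
  m <- regmatches(all_txt, regexpr("trna-[a-z]{3}", all_txt))
  if (length(m)) {
    aa <- paste0(toupper(substr(m, 6, 6)), substr(m, 7, 8))
    if (aa == "Leu") {
      if (grepl("uur|taa|l2", all_txt)) return("trnL2")
      if (grepl("cun|tag|l1", all_txt)) return("trnL1")
      return(NA_character_)           # ambiguous leucine
    }
    if (aa == "Ser") {
      if (grepl("agn|gct|tct|s1", all_txt)) return("trnS1")
      if (grepl("ucn|tga|s2", all_txt)) return("trnS2")
      return(NA_character_)           # ambiguous serine
    }
    if (aa %in% names(AA3_TO_TRN)) return(unname(AA3_TO_TRN[aa]))
  }

  for (t in txts) if (t %in% names(NAME_MAP)) return(unname(NAME_MAP[t]))
  NA_character_
}
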