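test_that("skews follow their definitions and undefined guards", {
  expect_equal(composition_stats("AATT")$at_skew, 0)
  expect_equal(composition_stats("AAAT")$at_skew, 0.5)        # (3-1)/4
  expect_equal(composition_stats("GGGC")$gc_skew, 0.5)
  s <- composition_stats("GGCC")
  expect_false(s$at_skew_defined)
  expect_true(is.na(s$at_skew))
  expect_equal(s$gc_skew, 0)
  # N ignored in numerators, denominators and percentages
  expect_equal(composition_stats("AANNT")$at_skew, 1 / 3)
  expect_equal(composition_stats("AANNT")$pct_AT, 100)
})

test_that("skew antisymmetry under reverse complement", {
  set.seed(11)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(50:300, 1),
                      replace = TRUE, prob = c(.4, .15, .1, .35)),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- composition_stats(s); b <- composition_stats(rc)
    expect_equal(b$at_skew, -a$at_skew, tolerance = 1e-12)
    expect_equal(b$gc_skew, -a$gc_skew, tolerance = 1e-12)
    expect_true(abs(a$at_skew) <= 1 && abs(a$gc_skew) <= 1)
  }
})

test_that("strandwise stats pool classes on the coding strand", {
  g <- generate_mitogenome(generator_config(seed = 110))$genome
  by_class <- strandwise_stats(g)
  expect_setequal(names(by_class),
                  c("J-PCG", "N-PCG", "rRNA", "tRNA", "CR"))
  # single J-strand feature equals plain composition of its sequence
  f <- g$features[g$features$name == "COX1", ]
  single <- strandwise_stats(g, features = f)
  expect_equal(single$at_skew,
               composition_stats(feature_seq(g, f))$at_skew)
  # N-strand pooling reverse-complements first: a gene moved from J to N
  # placement with the same coding sequence gives identical stats
  fn <- g$features[g$features$name == "ND1", ]     # N strand
  cod <- feature_seq(g, fn)
  expect_equal(strandwise_stats(g, features = fn)$at_skew,
               composition_stats(cod)$at_skew)
  expect_error(strandwise_stats(g, features = g$features[0, ]), "empty")
})

test_that("junction table closes the circle and extracts overlaps", {
  g <- generate_mitogenome(generator_config(seed = 111))$genome
  j <- gene_junctions(g)
  lens <- sum(g$features$end - g$features$start)
  expect_equal(lens + sum(j$gap_bp), nchar(g$sequence))
  atp <- j[j$upstream == "ATP8" & j$downstream == "ATP6", ]
  expect_equal(atp$gap_bp, -4L)
  expect_equal(atp$overlap_seq, "ATAA")
  wc <- j[j$upstream == "trnW" & j$downstream == "trnC", ]
  expect_equal(wc$gap_bp, -8L)
  expect_equal(wc$overlap_seq, "AAGCCTTA")
  # abutting features have gap 0
  toy <- mitogenome("toy", strrep("ACGT", 30),
                    rbind(gene_feature("trnI", 0, 40),
                          gene_feature("trnQ", 40, 80, strand = "N"),
                          gene_feature("CR", 80, 120, kind = "control")))
  expect_true(all(gene_junctions(toy)$gap_bp == 0L))
  # nested features are an error
  bad <- mitogenome("bad", strrep("ACGT", 30),
                    rbind(gene_feature("trnI", 0, 100),
                          gene_feature("trnQ", 10, 50)))
  expect_error(gene_junctions(bad), "nested")
})

test_that("start/stop classification handles complete and incomplete stops", {
  g <- generate_mitogenome(generator_config(seed = 112))$genome
  cc <- classify_codons(g)
  expect_setequal(cc$gene, c("ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
                             "ND3", "ND5", "ND4", "ND4L", "ND6", "CYTB",
                             "ND1"))
  expect_true(all(cc$start_standard))
  inc <- cc[cc$gene %in% c("COX1", "COX2"), ]
  expect_true(all(inc$stop_flag == "incomplete" & inc$stop_codon == "T"))
  expect_true(all(cc$stop_flag[!(cc$gene %in% c("COX1", "COX2"))] ==
                  "complete"))
  # configured start codon override is observed
  expect_equal(cc$start_codon[cc$gene == "ND1"], "ATA")
  g2 <- generate_mitogenome(
    generator_config(seed = 113, start_codons = c(ND1 = "TTG")))$genome
  expect_equal(classify_codons(g2)$start_codon[
    classify_codons(g2)$gene == "ND1"], "TTG")
})

test_that("RSCU identities hold and degenerate usages are exact", {
  g <- generate_mitogenome(generator_config(seed = 114))$genome
  cu <- codon_usage(g)
  sense <- cu$codons[cu$codons$aa != "*", ]
  for (f in split(sense, sense$aa)) {
    if (sum(f$count) > 0)
      expect_equal(sum(f$rscu), nrow(f), tolerance = 1e-9)
  }
  expect_equal(sum(cu$aa_percent), 100, tolerance = 0.1)
  # all-UUA leucine: RSCU = family size 6
  leu6 <- paste0("ATG", strrep("TTA", 20), "TAA")
  toyseq <- paste0(leu6, strrep("A", 20))
  toy <- mitogenome("toy", toyseq,
                    rbind(gene_feature("ND2", 0, nchar(leu6)),
                          gene_feature("CR", nchar(leu6), nchar(toyseq),
                                       kind = "control")))
  cu2 <- suppressWarnings(codon_usage(toy))
  expect_equal(cu2$codons$rscu[cu2$codons$codon == "TTA"], 6)
  # uniform synonymous usage: all RSCU 1 within the family
  unif <- paste0("ATG", "TTATTGCTTCTCCTACTG", "TAA")   # each Leu codon once
  toy2seq <- paste0(unif, strrep("A", 20))
  toy2 <- mitogenome("toy2", toy2seq,
                     rbind(gene_feature("ND2", 0, nchar(unif)),
                           gene_feature("CR", nchar(unif), nchar(toy2seq),
                                        kind = "control")))
  cu3 <- suppressWarnings(codon_usage(toy2))
  leu <- cu3$codons[cu3$codons$aa == "L", ]
  expect_true(all(abs(leu$rscu - 1) < 1e-12))
  # internal stop triggers a warning naming the gene
  badseq0 <- paste0("ATG", "TAA", "CCC", "TAA")
  badseq <- paste0(badseq0, strrep("A", 20))
  bad <- mitogenome("bad", badseq,
                    rbind(gene_feature("ND2", 0, nchar(badseq0)),
                          gene_feature("CR", nchar(badseq0), nchar(badseq),
                                       kind = "control")))
  expect_warning(codon_usage(bad), "internal stop codon in ND2")
})

test_that("NCR homology scan finds the donor gene", {
  # exact substring: 100% identity
  g <- generate_mitogenome(
    generator_config(seed = 115,
                     ncr = list(after = "trnS2", length = 120,
                                source = "ND1", divergence = 0)))
  tr <- g$truth$ncr
  hits <- ncr_homology_scan(g$genome, c(tr$start, tr$end))
  expect_equal(hits$gene[1], "ND1")
  expect_equal(hits$identity[1], 100)
  # diverged copy: identity near the uniform-mismatch expectation
  # (randomizing a fraction d of positions leaves 1 - 3d/4 identity)
  idents <- vapply(1:20, function(i) {
    gi <- generate_mitogenome(
      generator_config(seed = 200 + i,
                       ncr = list(after = "trnS2", length = 198,
                                  source = "ND1", divergence = 0.25)))
    h <- ncr_homology_scan(gi$genome, c(gi$truth$ncr$start,
                                        gi$truth$ncr$end))
    h$identity[h$gene == "ND1"][1]
  }, 0)
  expect_true(all(!is.na(idents)))
  # local alignment trims noisy ends, so observed identity sits at or just
  # above the global expectation of 81.25%
  expect_gt(mean(idents), 78)
  expect_lt(mean(idents), 90)
  expect_error(ncr_homology_scan(g$genome, c(0, 20)), "30 bp")
})
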