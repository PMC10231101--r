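test_that("feature name mapping resolves GenBank conventions", {
  expect_equal(map_feature_name(product = "tRNA-Ile"), "trnI")
  expect_equal(map_feature_name(product = "tRNA-Leu", note = "(UUR)"),
               "trnL2")
  expect_equal(map_feature_name(product = "tRNA-Leu", note = "(CUN)"),
               "trnL1")
  expect_equal(map_feature_name(product = "tRNA-Ser", note = "(AGN)"),
               "trnS1")
  expect_equal(map_feature_name(gene = "COI"), "COX1")
  expect_equal(map_feature_name(product = "12S ribosomal RNA"), "rrnS")
  expect_equal(map_feature_name(product = "s-rRNA"), "rrnS")
  expect_equal(map_feature_name(note = "control region"), "CR")
  expect_equal(map_feature_name(gene = "ND4L"), "ND4L")
  expect_true(is.na(map_feature_name(product = "hypothetical protein")))
  # ambiguous leucine without an anticodon class stays unmapped
  expect_true(is.na(map_feature_name(product = "tRNA-Leu")))
})

test_that("GenBank write/read round-trips generated genomes", {
  g <- generate_mitogenome(generator_config(seed = 101))$genome
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features, g$features)
  expect_identical(g2$circular, g$circular)
})

test_that("wraparound features are emitted as join() and reparsed", {
  seq <- strrep("ACGT", 30)                      # 120 bp
  f <- rbind(gene_feature("trnI", 10, 75),
             gene_feature("CR", 110, 130, kind = "control"))  # wraps
  g <- mitogenome("toy_wrap", seq, f)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  txt <- readLines(path)
  expect_true(any(grepl("join\\(111\\.\\.120,1\\.\\.10\\)", txt)))
  g2 <- read_genbank(path)
  cr <- g2$features[g2$features$name == "CR", ]
  expect_equal(cr$start, 110L)
  expect_equal(cr$end, 130L)
})

test_that("reader rejects malformed and multi-record files", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("garbage", "more garbage"), path)
  expect_error(read_genbank(path), "LOCUS")

  g <- generate_mitogenome(generator_config(seed = 102))$genome
  p1 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, p1)
  two <- c(readLines(p1), readLines(p1))
  p2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(two, p2)
  expect_error(read_genbank(p2), "one record per file")
})

test_that("unmappable features degrade to noncoding with a warning", {
  g <- generate_mitogenome(generator_config(seed = 103))$genome
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  txt <- readLines(path)
  ins <- c("     misc_feature    5..40",
           '                     /note="mystery element"')
  i <- grep("^ORIGIN", txt)
  writeLines(c(txt[1:(i - 1)], ins, txt[i:length(txt)]), path)
  expect_warning(g2 <- read_genbank(path), "unmapped feature")
  expect_true(any(g2$features$kind == "noncoding" &
                  g2$features$name == "mystery element"))
})

test_that("validation flags the canonical checks", {
  g <- generate_mitogenome(generator_config(seed = 104))$genome
  expect_equal(n_errors(validate_annotation(g)), 0L)

  # missing trnI
  g_miss <- g
  g_miss$features <- g_miss$features[g_miss$features$name != "trnI", ]
  rep <- validate_annotation(g_miss)
  expect_true(any(rep$severity == "error" & rep$code == "missing_gene" &
                  grepl("trnI", rep$message)))

  # split control region: warning, not an error
  g_split <- generate_mitogenome(split_cr_config(seed = 105))$genome
  rep2 <- validate_annotation(g_split)
  expect_equal(n_errors(rep2), 0L)
  expect_true(any(rep2$code == "split_cr" &
                  rep2$message == "split control region"))

  # feature outside the sequence
  g_out <- g
  g_out$features$end[1] <- 2L * nchar(g$sequence) + 5L
  expect_true(any(validate_annotation(g_out)$code == "outside_sequence"))
})

test_that("FASTA + TSV feature-table input builds the same genome", {
  g <- generate_mitogenome(generator_config(seed = 106))$genome
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste0(">", g$id), g$sequence), fa)
  utils::write.table(g$features, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g2 <- read_fasta_tsv(fa, tsv)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features, g$features)
})
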