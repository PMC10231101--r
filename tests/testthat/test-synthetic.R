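test_that("generation is byte-deterministic under a seed", {
  a <- generate_mitogenome(generator_config(seed = 150))
  b <- generate_mitogenome(generator_config(seed = 150))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genome$features, b$genome$features)
  expect_identical(a$truth$final_order, b$truth$final_order)
  c <- generate_mitogenome(generator_config(seed = 151))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
  # the generator does not disturb the caller's RNG stream
  set.seed(9); x1 <- stats::runif(1)
  set.seed(9); invisible(generate_mitogenome(generator_config(seed = 150)))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("default output is ancestral, valid, and compositionally on target", {
  g <- generate_mitogenome(generator_config(seed = 152))
  expect_equal(n_errors(validate_annotation(g$genome)), 0L)
  expect_true(orders_equal(extract_gene_order(g$genome), ancestral_order()))
  st <- composition_stats(g$genome$sequence)
  expect_gt(st$pct_AT, 72); expect_lt(st$pct_AT, 78)
  expect_gt(st$at_skew, 0)
  expect_lt(st$gc_skew, 0)
  expect_gte(st$length, 15011L * 0.9)        # within the observed size class
})

test_that("generate -> write -> read -> truth survives the round trip", {
  g <- generate_mitogenome(split_cr_config(seed = 153))
  gb <- withr::local_tempfile(fileext = ".gb")
  js <- withr::local_tempfile(fileext = ".json")
  write_genbank(g$genome, gb)
  write_truth_json(g$truth, js)
  g2 <- read_genbank(gb)
  expect_identical(g2$sequence, g$genome$sequence)
  expect_identical(g2$features, g$genome$features)
  truth <- jsonlite::read_json(js)
  expect_equal(truth$final_order, g$truth$final_order)
  expect_equal(truth$arrays[[1]]$unit_length, 109L)
})

test_that("planted rearrangements surface in the extracted order", {
  g <- generate_mitogenome(tdrl_swap_config(seed = 154))
  ord <- extract_gene_order(g$genome)
  line <- format_gene_order(ord)
  expect_match(line, "ND3 trnR trnA trnN")
  expect_equal(g$truth$events[[1]]$type, "tdrl")
  # a planted translocation moves the gene next to its destination
  cfg <- generator_config(seed = 155,
                          events = list(list(type = "translocation",
                                             gene = "trnF", after = "trnC")))
  gt <- generate_mitogenome(cfg)
  expect_match(format_gene_order(extract_gene_order(gt$genome)),
               "-trnC -trnF")
})

test_that("oversized gene tables are rejected", {
  expect_error(
    generate_mitogenome(generator_config(seed = 156,
                                         genome_length_target = 10000L)),
    "exceed")
})

test_that("composition perturbation hits the target without touching codons", {
  g <- generate_mitogenome(generator_config(seed = 157))$genome
  before <- classify_codons(g)
  set.seed(1)
  g80 <- perturb_composition(g, 0.80)
  expect_lt(abs(composition_stats(g80$sequence)$pct_AT - 80), 1)
  after <- classify_codons(g80)
  expect_identical(before$start_codon, after$start_codon)
  expect_identical(before$stop_codon, after$stop_codon)
  expect_identical(g80$features, g$features)
  # no internal stops introduced
  expect_silent(codon_usage(g80))
  # a target equal to the current content changes little
  cur <- composition_stats(g$sequence)$pct_AT / 100
  g_same <- perturb_composition(g, cur)
  expect_lt(abs(composition_stats(g_same$sequence)$pct_AT - 100 * cur), 1)
  expect_error(perturb_composition(g, 0.95), "at_content")
})
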