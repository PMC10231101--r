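test_that("ancestral order constant satisfies the canonical facts", {
  ao <- ancestral_order()
  genes <- ao$symbols[!(ao$symbols %in% c("CR", "CR1", "CR2", "NCR"))]
  expect_length(genes, 37L)
  expect_setequal(genes[startsWith(genes, "trn")],
                  c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY", "trnL2",
                    "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS1",
                    "trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1",
                    "trnV"))
  sgn <- stats::setNames(ao$signs, ao$symbols)
  j_pcg <- c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYTB", "ND2", "ND3",
             "ND6")
  n_pcg <- c("ND1", "ND4", "ND4L", "ND5")
  expect_true(all(sgn[j_pcg] == 1L))
  expect_true(all(sgn[n_pcg] == -1L))
  # the trnA..trnF hot-spot cluster is contiguous
  i <- match(c("trnA", "trnR", "trnN", "trnS1", "trnE", "trnF"), ao$symbols)
  expect_equal(i, seq(min(i), max(i)))
})

test_that("gene-order extraction is rotation invariant", {
  g <- generate_mitogenome(generator_config(seed = 120))$genome
  ord <- extract_gene_order(g)
  expect_true(orders_equal(ord, ancestral_order()))
  # rotate the genome by 5 kb: same order
  n <- nchar(g$sequence)
  k <- 5000L
  g2 <- g
  g2$sequence <- paste0(substr(g$sequence, k + 1L, n),
                        substr(g$sequence, 1L, k))
  f <- g$features
  f$start <- (f$start - k) %% n
  f$end <- f$start + (g$features$end - g$features$start)
  g2$features <- f[order(f$start), ]
  ord2 <- extract_gene_order(g2)
  expect_true(orders_equal(ord, ord2, markers = TRUE))
})

test_that("token-line serialization round-trips", {
  ao <- ancestral_order()
  line <- format_gene_order(ao)
  expect_match(line, "^trnI -trnQ trnM ND2 ")
  expect_true(orders_equal(parse_gene_order(line), ao, markers = TRUE))
})

test_that("comparison reports the trnA/trnR translocation", {
  g <- generate_mitogenome(tdrl_swap_config(seed = 121))$genome
  ord <- extract_gene_order(g)
  rep <- compare_orders(ord, ancestral_order())
  expect_false(rep$identical)
  expect_length(rep$inverted, 0L)
  expect_true(all(rep$translocated$gene %in% c("trnA", "trnR")))
  expect_gte(nrow(rep$translocated), 1L)
  expect_equal(rep$affected_cluster, "ARNS1EF")
  expect_false(rep$transloc_heuristic)
})

test_that("comparison reports the inverted translocated trnI", {
  g <- generate_mitogenome(split_cr_config(seed = 122))$genome
  ord <- extract_gene_order(g)
  expect_match(format_gene_order(ord), "-trnI CR2 -trnQ trnM")
  expect_match(format_gene_order(ord), "-rrnS CR1$")
  rep <- compare_orders(ord, ancestral_order())
  expect_equal(rep$inverted, "trnI")
  expect_equal(rep$translocated$gene, "trnI")
  expect_equal(rep$affected_cluster, "IQM")
})

test_that("identical orders yield an empty report", {
  rep <- compare_orders(ancestral_order(), ancestral_order())
  expect_true(rep$identical)
  expect_equal(rep$breakpoints, 0L)
  expect_length(rep$inverted, 0L)
  expect_equal(nrow(rep$translocated), 0L)
})

test_that("breakpoint distance matches the adjacency-set oracle", {
  ao <- ancestral_order()
  expect_equal(breakpoint_distance(ao, ao), 0L)
  set.seed(7)
  for (i in 1:100) {
    a <- random_signed_order(8)
    b <- gene_order(sample(a$symbols),
                    a$signs[sample(seq_along(a$signs))])
    # same gene set, signs permuted independently of symbols: rebuild so
    # each symbol keeps one sign per order
    b <- gene_order(sample(a$symbols), sample(c(-1L, 1L), 8, replace = TRUE))
    expect_equal(breakpoint_distance(a, b), oracle_breakpoints(a, b))
    expect_equal(breakpoint_distance(a, b), breakpoint_distance(b, a))
  }
  # trnA/trnR swap distance agrees with the oracle
  g <- generate_mitogenome(tdrl_swap_config(seed = 123))$genome
  ord <- extract_gene_order(g)
  expect_equal(breakpoint_distance(ord, ao), oracle_breakpoints(ord, ao))
  expect_error(breakpoint_distance(ao, random_signed_order(5)),
               "gene-set mismatch")
})
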