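test_that("exact repeats are reported with full identity", {
  r <- find_tandem_repeats(strrep("ACGT", 25), min_unit = 4)
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit_length, 4L)
  expect_equal(r$copies_int, 25L)
  expect_equal(r$identity, 100)
  expect_equal(r$start, 0L)
  expect_equal(r$end, 100L)
})

test_that("the primitive period is preferred over its multiples", {
  set.seed(41)
  unit <- paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE,
                       prob = c(.4, .15, .1, .35)), collapse = "")
  s <- paste0(strrep("GATTACA", 10), strrep(unit, 12),
              strrep("TACCAGA", 10))
  r <- find_tandem_repeats(s, min_unit = 20)
  expect_equal(r$unit_length[which.max(r$copies)], 70L)
  expect_equal(r$copies_int[r$unit_length == 70L], 12L)
})

test_that("detection is deterministic", {
  g <- generate_mitogenome(split_cr_config(seed = 140))$genome
  cr <- g$features[g$features$name == "CR2", ]
  s <- feature_seq(g, cr)
  expect_identical(find_tandem_repeats(s), find_tandem_repeats(s))
})

test_that("planted arrays are recovered within tolerance", {
  set.seed(42)
  hits <- 0L; n_trials <- 40L
  for (i in seq_len(n_trials)) {
    unit_len <- sample(20:200, 1L)
    copies <- sample(3:12, 1L)
    cfg <- generator_config(
      seed = 3000L + i,
      cr_spec = list(CR = list(
        spacers = c(300L, 300L),
        arrays = list(list(unit_length = unit_len, copies = copies,
                           divergence = 0.05)))))
    g <- generate_mitogenome(cfg)
    cr <- g$genome$features[g$genome$features$name == "CR", ]
    r <- find_tandem_repeats(feature_seq(g$genome, cr))
    if (any(abs(r$unit_length - unit_len) <= 1L &
            abs(r$copies_int - copies) <= 1L)) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("uniform random sequence yields no arrays", {
  set.seed(43)
  fp <- 0L
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
    if (nrow(find_tandem_repeats(s)) > 0L) fp <- fp + 1L
  }
  expect_lte(fp, 1L)
})

test_that("parameter bounds are enforced", {
  expect_error(find_tandem_repeats("ACGTACGT", min_unit = 1), "bounds")
  expect_error(find_tandem_repeats("ACGTACGT", min_copies = 1), "bounds")
  expect_error(find_tandem_repeats("ACGTAC", min_unit = 8), "shorter")
})

test_that("schematic tiles the control region exactly", {
  # no repeats: a single unique segment per CR
  g0 <- generate_mitogenome(generator_config(seed = 141))$genome
  sch0 <- cr_schematic(g0, min_unit = 20)
  cr0 <- g0$features[g0$features$name == "CR", ]
  expect_equal(sch0$start[1], cr0$start)
  expect_equal(sch0$end[nrow(sch0)], cr0$end)
  # segments tile without overlap
  by_seg <- split(sch0[sch0$segment != "embedded", ],
                  sch0$segment[sch0$segment != "embedded"])
  for (seg in by_seg) {
    expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
  }
  # split CR with embedded trnI and the planted CR2 array
  g1 <- generate_mitogenome(split_cr_config(seed = 142))$genome
  sch1 <- cr_schematic(g1, min_unit = 20)
  expect_true(any(sch1$kind == "embedded_gene" & sch1$label == "trnI"))
  arr <- sch1[sch1$kind == "repeat_array", ]
  expect_equal(arr$segment, "CR2")
  expect_equal(arr$unit_length, 109L)
  expect_equal(arr$copies_int, 5L)
  txt <- format_cr_schematic(sch1)
  expect_match(txt, "CR2\\[5 x 109 bp\\]")
  # arrays never exceed their CR span
  cr2 <- g1$features[g1$features$name == "CR2", ]
  expect_true(all(arr$start >= cr2$start & arr$end <= cr2$end))
})
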