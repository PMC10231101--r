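test_that("apply_tdrl reproduces the duplication-loss semantics", {
  ord <- gene_order(c("trnA", "trnR"))
  # duplicate trnA-trnR, lose first trnA and second trnR -> trnR-trnA
  ev <- tdrl_event(c(1L, 3L), c(trnA = "second", trnR = "first"))
  expect_equal(apply_tdrl(ord, ev)$symbols, c("trnR", "trnA"))
  # identity retentions leave the order unchanged
  o5 <- gene_order(paste0("g", 1:5))
  ev_first <- tdrl_event(c(2L, 5L),
                         stats::setNames(rep("first", 3), paste0("g", 2:4)))
  ev_second <- tdrl_event(c(2L, 5L),
                          stats::setNames(rep("second", 3), paste0("g", 2:4)))
  expect_equal(apply_tdrl(o5, ev_first)$symbols, o5$symbols)
  expect_equal(apply_tdrl(o5, ev_second)$symbols, o5$symbols)
  # retention must cover every windowed gene
  expect_error(apply_tdrl(o5, tdrl_event(c(1L, 3L), c(g1 = "first"))),
               "retention missing")
  # signs never change
  os <- gene_order(paste0("g", 1:4), c(1L, -1L, 1L, -1L))
  ev2 <- tdrl_event(c(1L, 5L),
                    stats::setNames(sample(c("first", "second"), 4, TRUE),
                                    paste0("g", 1:4)))
  res <- apply_tdrl(os, ev2)
  expect_equal(res$signs[match(os$symbols, res$symbols)], os$signs)
})

test_that("a CR marker retained in both copies models a split CR", {
  ord <- gene_order(c("trnV", "rrnS", "CR", "trnQ"))
  # duplicate the CR-trnQ block; keep trnQ's first copy and both CR copies:
  # the gene ends up embedded between the two CR remnants
  ev <- tdrl_event(c(3L, 5L), c(trnQ = "first", CR = "both"))
  res <- apply_tdrl(ord, ev)
  expect_equal(res$symbols, c("trnV", "rrnS", "CR1", "trnQ", "CR2"))
})

test_that("tdrl_search finds the single-event trnA/trnR scenario", {
  ao <- ancestral_order()
  obs <- extract_gene_order(
    generate_mitogenome(tdrl_swap_config(seed = 130))$genome)
  ts <- tdrl_search(ao, obs)
  expect_true(ts$feasible)
  expect_equal(ts$n_events, 1L)
  ev <- ts$scenarios[[1]]$events[[1]]
  expect_equal(unname(ev$retention[c("trnA", "trnR")]),
               c("second", "first"))
  expect_setequal(names(ev$retention), c("trnA", "trnR"))
})

test_that("source equal to target yields one empty scenario", {
  ao <- ancestral_order()
  ts <- tdrl_search(ao, ao)
  expect_true(ts$feasible)
  expect_equal(ts$n_events, 0L)
  expect_length(ts$scenarios, 1L)
  expect_length(ts$scenarios[[1]]$events, 0L)
})

test_that("any sign flip makes TDRL infeasible", {
  ao <- ancestral_order()
  flipped <- ao
  i <- match("trnI", flipped$symbols)
  flipped$signs[i] <- -flipped$signs[i]
  ts <- tdrl_search(ao, flipped)
  expect_false(ts$feasible)
  expect_equal(ts$reason, "sign_change")
  expect_equal(ts$flipped, "trnI")
})

test_that("oracle enumerations match closed-form tiny cases", {
  o2 <- gene_order(c("A", "B"))
  expect_setequal(tdrl_reachable_oracle(o2, 1L), c("A B", "B A"))
  expect_equal(tdrl_reachable_oracle(o2, 0L), "A B")
  expect_error(tdrl_reachable_oracle(gene_order(LETTERS[1:8]), 1L),
               "at most 7")
})

test_that("search feasibility agrees with the oracle on 4-gene orders", {
  src <- gene_order(LETTERS[1:4])
  r1 <- tdrl_reachable_oracle(src, 1L)
  r2 <- tdrl_reachable_oracle(src, 2L)
  for (p in all_perms(LETTERS[1:4])) {
    tgt <- gene_order(p)
    key <- format_gene_order(tgt)
    ts <- tdrl_search(src, tgt, max_events = 2L)
    oracle_min <- if (key == "A B C D") 0L else if (key %in% r1) 1L
                  else if (key %in% r2) 2L else NA_integer_
    if (is.na(oracle_min)) {
      expect_false(ts$feasible)
    } else {
      expect_true(ts$feasible)
      expect_equal(ts$n_events, oracle_min)
    }
  }
})

test_that("returned scenarios re-apply to their targets", {
  set.seed(31)
  for (i in 1:60) {
    src <- random_signed_order(6)
    tgt <- src
    for (k in seq_len(sample(1:2, 1))) tgt <- apply_tdrl(tgt,
                                                 random_tdrl_event(tgt))
    ts <- tdrl_search(src, tgt, max_events = 2L)
    if (!ts$feasible) next          # 3+-event targets exceed the budget
    for (sc in ts$scenarios) {
      cur <- src
      for (ev in sc$events) cur <- apply_tdrl(cur, ev)
      expect_true(orders_equal(cur, tgt))
    }
  }
})

test_that("mechanism classification follows the decision rule", {
  ao <- ancestral_order()
  # identical
  rep0 <- compare_orders(ao, ao)
  expect_equal(classify_mechanism(rep0, ao, ao)$label, "none")
  # TDRL with the canonical duplication narrative
  obs <- extract_gene_order(
    generate_mitogenome(tdrl_swap_config(seed = 131))$genome)
  rep1 <- compare_orders(obs, ao)
  mc1 <- classify_mechanism(rep1, ao, obs)
  expect_equal(mc1$label, "TDRL")
  expect_gte(length(mc1$scenarios), 1L)
  expect_match(mc1$narrative[1], "trnA-trnR was duplicated")
  # inversion + translocation
  obs2 <- extract_gene_order(
    generate_mitogenome(split_cr_config(seed = 132))$genome)
  rep2 <- compare_orders(obs2, ao)
  mc2 <- classify_mechanism(rep2, ao, obs2)
  expect_equal(mc2$label, "recombination_inversion_translocation")
  expect_match(mc2$narrative[1], "trnI was inverted, then translocated")
  # inversion in place
  inv <- ao
  inv$signs[match("trnM", inv$symbols)] <- -1L
  rep3 <- compare_orders(inv, ao)
  mc3 <- classify_mechanism(rep3, ao, inv)
  expect_equal(mc3$label, "recombination_inversion")
})
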