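# shared fixtures and independent oracles for the test suite

# generator config planting the trnA/trnR TDRL swap rearrangement
tdrl_swap_config <- function(seed = 2) {
  generator_config(
    seed = seed,
    events = list(list(type = "tdrl", window = c("trnA", "trnR"),
                       retention = c(trnA = "second", trnR = "first"))))
}

# generator config emulating the split-CR arrangement with an inverted,
# translocated trnI and a 5 x 109 bp repeat array in CR2
split_cr_config <- function(seed = 3) {
  generator_config(
    seed = seed,
    events = list(list(type = "inversion", gene = "trnI")),
    split_cr = list(embedded = "trnI"),
    cr_spec = list(
      CR1 = list(spacers = c(980L), arrays = list()),
      CR2 = list(spacers = c(150L, 167L),
                 arrays = list(list(unit_length = 109L, copies = 5L,
                                    divergence = 0.02)))))
}

# all permutations of a vector (tiny n only)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# independent breakpoint oracle: undirected signed adjacency sets built
# with a representation unrelated to the package's implementation
oracle_breakpoints <- function(a, b) {
  adj_set <- function(ord) {
    keep <- !(ord$symbols %in% c("CR", "CR1", "CR2", "NCR"))
    sym <- ord$symbols[keep]; sgn <- ord$signs[keep]
    n <- length(sym)
    sapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      x <- sprintf("%+d%s", sgn[i], sym[i])
      y <- sprintf("%+d%s", sgn[j], sym[j])
      xr <- sprintf("%+d%s", -sgn[j], sym[j])
      yr <- sprintf("%+d%s", -sgn[i], sym[i])
      fwd <- paste(x, y); rev <- paste(xr, yr)
      min(fwd, rev)                       # canonical undirected form
    })
  }
  sa <- adj_set(a); sb <- adj_set(b)
  sum(!(sa %in% sb))
}

# random signed order over n placeholder genes
random_signed_order <- function(n, with_signs = TRUE) {
  sym <- sample(paste0("g", seq_len(n)))
  sgn <- if (with_signs) sample(c(-1L, 1L), n, replace = TRUE)
         else rep(1L, n)
  gene_order(sym, sgn)
}

# random TDRL event applicable to an order of length n
random_tdrl_event <- function(ord) {
  n <- length(ord$symbols)
  i <- sample.int(n - 1L, 1L)
  cand <- (i + 1L):n
  j <- cand[sample.int(length(cand), 1L)]
  genes <- ord$symbols[i:j]
  ret <- sample(c("first", "second"), length(genes), replace = TRUE)
  tdrl_event(c(i, j + 1L), stats::setNames(ret, genes))
}
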