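#' Tandem duplication/random loss (TDRL) events
#'
#' A TDRL event duplicates a contiguous window of the linearized gene order
#' in tandem and then deletes one copy of each duplicated gene.  The genes
#' retained from the first copy keep their relative order, followed by the
#' genes retained from the second copy; gene orientation (sign) can never
#' change.  Control-region markers may sit inside a window; they do not
#' count toward retention constraints and may keep both copies (modelling a
#' split control region as a duplication remnant).
#'
#' @param window integer c(i, j): 1-based half-open index span on the
#'   linearized order, length at least 2.
#' @param retention named character vector: for every gene in the window,
#'   \code{"first"} or \code{"second"}; markers may additionally use
#'   \code{"both"} (the default for markers).
#' @return object of class \code{tdrl_event}.
#' @export
tdrl_event <- function(window, retention) {
  stopifnot(length(window) == 2L, window[2L] - window[1L] >= 2L,
            all(retention %in% c("first", "second", "both")))
  structure(list(window = as.integer(window), retention = retention),
            class = "tdrl_event")
}

#' @export
print.tdrl_event <- function(x, ...) {
  cat(sprintf("TDRL window [%d,%d): %s\n", x$window[1L], x$window[2L],
              paste(names(x$retention), x$retention, sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Apply a TDRL event to a signed gene order
#'
#' Deterministic duplication-then-loss: the window is duplicated in tandem
#' and the non-retained copy of each gene deleted.  Signs are preserved.
#' A control-region marker retained \code{"both"} keeps both copies; when
#' the marker is named CR the copies are renamed CR1 and CR2.
#'
#' @param order a [gene_order()].
#' @param event a [tdrl_event()]; every gene in the window must appear in
#'   \code{event$retention}.
#' @return the rearranged [gene_order()].
#' @export
apply_tdrl <- function(order, event) {
  sym <- order$symbols; sgn <- order$signs
  i <- event$window[1L]; j <- event$window[2L]
  if (i < 1L || j > length(sym) + 1L || j - i < 2L)
    stop("window [", i, ",", j, ") out of bounds")
  win <- i:(j - 1L)
  wsym <- sym[win]; wsgn <- sgn[win]
  is_marker <- wsym %in% CONTROL_SYMBOLS
  ret <- event$retention
  miss <- setdiff(wsym[!is_marker], names(ret))
  if (length(miss))
    stop("retention missing window gene(s): ", paste(miss, collapse = ", "))
  r <- vapply(seq_along(wsym), function(k) {
    if (wsym[k] %in% names(ret)) unname(ret[[wsym[k]]])
    else "both"                                     # marker default
  }, "")
  if (any(r == "both" & !is_marker))
    stop("'both' retention is only allowed for control markers")
  keep1 <- r %in% c("first", "both")
  keep2 <- r %in% c("second", "both")
  s1 <- wsym[keep1]; g1 <- wsgn[keep1]
  s2 <- wsym[keep2]; g2 <- wsgn[keep2]
  ## a CR kept in both copies becomes a split control region
  if (any(wsym == "CR" & r == "both")) {
    s1[s1 == "CR"] <- "CR1"
    s2[s2 == "CR"] <- "CR2"
  }
  new_sym <- c(sym[seq_len(i - 1L)], s1, s2,
               if (j <= length(sym)) sym[j:length(sym)])
  new_sgn <- c(sgn[seq_len(i - 1L)], g1, g2,
               if (j <= length(sym)) sgn[j:length(sym)])
  gene_order(new_sym, new_sgn)
}

## --- one-step reachability --------------------------------------------------
## Characterization used by the search: applying one TDRL with window W to
## x yields y iff x and y agree outside W and, writing q[m] for the position
## in x's window of the gene at y's window position m, q splits into two
## increasing runs (the first-copy survivors then the second-copy
## survivors).  Restricted to the minimal differing span, the split is
## unique and the event canonical (first window gene retained from the
## second copy, last from the first).

one_step_event <- function(xs, ys) {
  d <- which(xs != ys)
  if (length(d) == 0L) return(NULL)            # identity: no event needed
  a <- d[1L]; b <- d[length(d)]
  q <- match(ys[a:b], xs[a:b])
  if (anyNA(q)) return(NA)                     # window contents differ
  desc <- which(diff(q) < 0L)
  if (length(desc) != 1L) return(NA)
  k <- desc[1L]
  L <- b - a + 1L
  ret <- character(L)
  ret[q[seq_len(k)]] <- "first"
  ret[q[(k + 1L):L]] <- "second"
  tdrl_event(c(a, b + 1L), stats::setNames(ret, xs[a:b]))
}

scenario_new <- function(events, orders) {
  structure(list(events = events, orders = orders), class = "tdrl_scenario")
}

#' @export
print.tdrl_scenario <- function(x, ...) {
  cat(length(x$events), "event(s):\n")
  for (e in x$events) print(e)
  invisible(x)
}

## all distinct one-event successors of symbol vector xs (signs ride along),
## windows restricted to [lo, hi] (1-based inclusive span)
tdrl_successors <- function(xs, lo, hi) {
  out <- new.env(parent = emptyenv())
  n <- hi - lo + 1L
  if (n < 2L) return(list())
  for (i in lo:(hi - 1L)) {
    for (j in (i + 1L):hi) {
      L <- j - i + 1L
      win <- xs[i:j]
      for (mask in 1:(2L^L - 2L)) {          # skip all-first / all-second
        bits <- bitwAnd(mask, 2L^(seq_len(L) - 1L)) > 0L
        res <- c(xs[seq_len(i - 1L)], win[!bits], win[bits],
                 if (j < length(xs)) xs[(j + 1L):length(xs)])
        key <- paste(res, collapse = " ")
        if (is.null(out[[key]]) && !identical(res, xs)) out[[key]] <- res
      }
    }
  }
  as.list(out)
}

#' Search for minimal TDRL scenarios between two signed gene orders
#'
#' Finds all scenarios of minimal event count (up to \code{max_events})
#' that transform \code{source} into \code{target} by tandem
#' duplication/random loss.  Returns infeasible immediately when any gene's
#' sign differs -- TDRL cannot generate inversions -- or when no scenario
#' exists within the budget.  The search is localized to the smallest
#' contiguous span containing all differences between the linearized
#' orders; scenarios are deduplicated by their intermediate orders, each
#' step represented by its canonical minimal-window event.  Control-region
#' markers are ignored by the search.
#'
#' @param source,target [gene_order()] objects over the same gene set.
#' @param max_events scenario length budget (default 2, maximum 3).
#' @return list of class \code{tdrl_search_result}: feasible (logical),
#'   reason (when infeasible), n_events, scenarios (list of scenarios, each
#'   with \code{events} and \code{orders}).
#' @export
tdrl_search <- function(source, target, max_events = 2L) {
  stopifnot(max_events >= 0L, max_events <= 3L)
  gs <- order_genes(canonical_rotation(source))
  gt <- order_genes(canonical_rotation(target))
  if (!setequal(gs$symbols, gt$symbols))
    stop("gene-set mismatch: ",
         paste(c(setdiff(gs$symbols, gt$symbols),
                 setdiff(gt$symbols, gs$symbols)), collapse = ", "))
  if (any(gs$signs != gt$signs[match(gs$symbols, gt$symbols)])) {
    flipped <- gs$symbols[gs$signs != gt$signs[match(gs$symbols,
                                                     gt$symbols)]]
    return(structure(list(feasible = FALSE, reason = "sign_change",
                          flipped = flipped, n_events = NA_integer_,
                          scenarios = list()),
                     class = "tdrl_search_result"))
  }
  xs <- gs$symbols; ys <- gt$symbols
  sgn_map <- stats::setNames(gs$signs, gs$symbols)

  if (identical(xs, ys))
    return(structure(list(feasible = TRUE, reason = NULL, n_events = 0L,
                          scenarios = list(scenario_new(list(), list(xs)))),
                     class = "tdrl_search_result"))

  d <- which(xs != ys)
  lo <- d[1L]; hi <- d[length(d)]

  ## exact enumeration of all scenarios of exactly `k` events, localized
  enumerate_exact <- function(x, k) {
    if (k == 0L) {
      if (identical(x, ys)) return(list(scenario_new(list(), list(x))))
      return(list())
    }
    if (k == 1L) {
      ev <- one_step_event(x, ys)
      if (is.null(ev) || !is.list(ev)) return(list())
      if (!verify_step(x, sgn_map, ev, ys)) return(list())
      return(list(scenario_new(list(ev), list(x, ys))))
    }
    succ <- tdrl_successors(x, lo, hi)
    out <- list()
    for (im in succ) {
      tails <- enumerate_exact(im, k - 1L)
      if (length(tails) == 0L) next
      ev1 <- one_step_event(x, im)
      if (is.null(ev1) || !is.list(ev1) ||
          !verify_step(x, sgn_map, ev1, im)) next
      for (tl in tails) {
        out[[length(out) + 1L]] <- scenario_new(
          c(list(ev1), tl$events), c(list(x), tl$orders))
      }
    }
    out
  }

  for (k in 1:max_events) {
    sc <- enumerate_exact(xs, k)
    if (length(sc)) {
      sc <- dedupe_scenarios(sc)
      sc <- sc[order(vapply(sc, function(s) s$events[[1L]]$window[1L], 0L),
                     vapply(sc, function(s) diff(s$events[[1L]]$window), 0L),
                     vapply(sc, scenario_key, ""))]
      return(structure(list(feasible = TRUE, reason = NULL, n_events = k,
                            scenarios = sc),
                       class = "tdrl_search_result"))
    }
  }
  structure(list(feasible = FALSE, reason = "no_scenario_within_budget",
                 n_events = NA_integer_, scenarios = list()),
            class = "tdrl_search_result")
}

## soundness check: re-apply the event through apply_tdrl (the independent
## application path) and compare with the expected order
verify_step <- function(xs, sgn_map, ev, expected) {
  o <- gene_order(xs, unname(sgn_map[xs]))
  res <- apply_tdrl(o, ev)
  orders_equal(res, gene_order(expected, unname(sgn_map[expected])))
}

scenario_key <- function(s) {
  paste(vapply(s$orders, paste, "", collapse = " "), collapse = " -> ")
}

dedupe_scenarios <- function(scenarios) {
  keys <- vapply(scenarios, scenario_key, "")
  scenarios[!duplicated(keys)]
}

#' @export
print.tdrl_search_result <- function(x, ...) {
  if (!x$feasible) {
    cat("infeasible:", x$reason, "\n")
  } else {
    cat(length(x$scenarios), "minimal scenario(s) of", x$n_events,
        "event(s)\n")
  }
  invisible(x)
}

#' Exhaustive TDRL reachability oracle
#'
#' Literal enumeration of every (window, retention) composition up to
#' \code{depth} events, used as an independent verification oracle for
#' [tdrl_search()].  Hard-limited to orders of at most 7 genes and depth at
#' most 2.
#'
#' @param order a [gene_order()] (markers dropped).
#' @param depth 0, 1 or 2.
#' @return character vector: the set of order strings (as
#'   [format_gene_order()], markers excluded) reachable in at most
#'   \code{depth} events, including the source.
#' @export
tdrl_reachable_oracle <- function(order, depth) {
  g <- order_genes(canonical_rotation(order))
  n <- length(g$symbols)
  if (n > 7L) stop("oracle limited to orders of at most 7 genes")
  if (depth > 2L) stop("oracle limited to depth at most 2")
  fmt <- function(sym) paste(ifelse(
    g$signs[match(sym, g$symbols)] < 0, paste0("-", sym), sym),
    collapse = " ")
  seen <- new.env(parent = emptyenv())
  seen[[fmt(g$symbols)]] <- TRUE
  frontier <- list(g$symbols)
  if (depth >= 1L) for (lev in seq_len(depth)) {
    nxt <- list()
    for (xs in frontier) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        L <- j - i + 1L
        win <- xs[i:j]
        for (mask in 0:(2L^L - 1L)) {
          bits <- bitwAnd(mask, 2L^(seq_len(L) - 1L)) > 0L
          ## literal tandem duplication then loss:
          ## copy-1 survivors (bit FALSE), then copy-2 survivors (bit TRUE)
          res <- c(xs[seq_len(i - 1L)], win[!bits], win[bits],
                   if (j < n) xs[(j + 1L):n])
          key <- fmt(res)
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            nxt[[length(nxt) + 1L]] <- res
          }
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  sort(ls(seen))
}

## --- mechanism classification ----------------------------------------------

#' Classify the rearrangement mechanism between two gene orders
#'
#' Decision rule: identical orders need no mechanism; orders differing
#' without any inversion that a minimal TDRL scenario can reach are
#' labelled TDRL (all minimal scenarios attached); a sign-flipped gene that
#' also moved is labelled recombination with inversion plus translocation;
#' a sign flip in place is recombination with inversion; anything else is
#' unexplained.  The narrative renders the inferred events as an ordered,
#' human-readable story.
#'
#' @param report a [compare_orders()] result for (observed, reference).
#' @param source the reference [gene_order()] (scenarios run from here).
#' @param target the observed [gene_order()].
#' @param max_events TDRL search budget (default 2).
#' @return list of class \code{mechanism_call}: label (one of none, TDRL,
#'   recombination_inversion, recombination_inversion_translocation,
#'   unexplained), narrative (character vector), scenarios, report.
#' @export
classify_mechanism <- function(report, source, target, max_events = 2L) {
  inv <- report$inverted
  tr <- report$translocated$gene
  label <- NULL; scenarios <- list(); narrative <- character()

  if (report$identical) {
    label <- "none"
    narrative <- "gene order identical to the reference"
  } else if (length(inv) == 0L) {
    ts <- tdrl_search(source, target, max_events = max_events)
    if (ts$feasible) {
      label <- "TDRL"
      scenarios <- ts$scenarios
      narrative <- tdrl_narrative(ts$scenarios[[1L]])
    } else {
      label <- "unexplained"
      narrative <- paste("no TDRL scenario within", max_events,
                         "events and no inversion observed")
    }
  } else if (length(tr) > 0L && all(inv %in% tr)) {
    label <- "recombination_inversion_translocation"
    narrative <- vapply(inv, function(g) {
      ctx <- report$translocated[report$translocated$gene == g, ]
      dest <- if (nrow(ctx) && grepl("CR", ctx$obs_context))
        "between control-region segments" else
        paste("to context", ctx$obs_context)
      paste0(g, " was inverted, then translocated ", dest)
    }, "")
  } else if (length(tr) == 0L) {
    label <- "recombination_inversion"
    narrative <- paste(paste(inv, collapse = ", "), "inverted in place")
  } else {
    label <- "unexplained"
    narrative <- "mixed inversion and translocation pattern"
  }
  structure(list(label = label, narrative = narrative,
                 scenarios = scenarios, report = report),
            class = "mechanism_call")
}

## Fig-style story for one scenario
tdrl_narrative <- function(scenario) {
  if (length(scenario$events) == 0L) return("no events required")
  vapply(seq_along(scenario$events), function(k) {
    ev <- scenario$events[[k]]
    w <- names(ev$retention)
    lost_first <- w[ev$retention == "second"]
    lost_second <- w[ev$retention == "first"]
    sprintf("%s was duplicated to %s; subsequently the first %s and the second %s were lost",
            paste(w, collapse = "-"),
            paste(c(w, w), collapse = "-"),
            paste(lost_first, collapse = ", "),
            paste(lost_second, collapse = ", "))
  }, "")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("mechanism:", x$label, "\n")
  for (s in x$narrative) cat(" -", s, "\n")
  invisible(x)
}
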