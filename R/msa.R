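# Minimal Sets Algorithm: for one target variable, every pair of observed
# transitions with different target outputs yields a "difference set" (the
# variables whose input states differ); any functional explanation of the
# target must read at least one variable of every difference set. The family
# of all subset-minimal hitting sets of the difference-set collection is the
# complete space of minimal regulator sets for the target.

# Incremental (Berge-style) minimal hitting set enumeration.
# sets: list of non-empty integer vectors. Returns list of sorted integer
# vectors forming an antichain; list(integer(0)) when sets is empty.
.minimal_hitting_sets <- function(sets) {
  fam <- list(integer(0))
  for (D in sets) {
    hit <- vapply(fam, function(H) any(D %in% H), logical(1))
    kept <- fam[hit]
    grown <- list()
    for (H in fam[!hit])
      for (v in D)
        grown[[length(grown) + 1L]] <- sort(c(H, v))
    cand <- c(kept, unique(grown))
    # drop candidates that contain another candidate
    keep <- rep(TRUE, length(cand))
    for (a in seq_along(cand)) {
      if (!keep[a]) next
      for (b in seq_along(cand)) {
        if (a == b || !keep[b]) next
        if (length(cand[[b]]) <= length(cand[[a]]) &&
            all(cand[[b]] %in% cand[[a]]) &&
            length(cand[[b]]) < length(cand[[a]])) {
          keep[a] <- FALSE
          break
        }
      }
    }
    fam <- cand[keep]
  }
  .order_sets(fam)
}

# canonical order: by size, then lexicographically by variable indices
.order_sets <- function(sets) {
  if (!length(sets)) return(sets)
  keys <- vapply(sets, function(s)
    paste(sprintf("%05d", c(length(s), s)), collapse = ","), character(1))
  sets[order(keys)]
}

#' Minimal regulator sets for one target
#'
#' Computes, from observed state transitions, the complete antichain of
#' subset-minimal variable sets that can explain the target's output: for
#' every pair of transitions with different target outputs the set of
#' variables whose inputs differ (the *difference set*) is formed, and the
#' family of all minimal hitting sets of these difference sets is returned.
#' A target whose output never changes needs no regulators and yields the
#' family `{ {} }`.
#'
#' Two transitions with identical input vectors but different target outputs
#' are functionally inconsistent (possible after discretization). By default
#' this is an error naming the colliding transitions; with `lenient = TRUE`
#' the later transition of each colliding pair is dropped with a warning.
#'
#' Each set receives two scores. The *evidence* score measures how
#' surprising the set's consistency with the data is under a
#' random-function null: a set whose input projection partitions the `u`
#' unique transitions into `m` classes was consistent with probability
#' `q^-(u - m)` by chance, so `u - m` (larger = stronger) is reported.
#' The *frequency* score is the product of the members' frequencies across
#' the family (the fraction of minimal sets containing the variable),
#' normalized to sum to one over the family — a reconstruction of a
#' published model-scoring scheme, replaceable via [select_model()]'s
#' `scorer`.
#'
#' @param ts A `transition_set` from [extract_transitions()].
#' @param target Probe name or index of the target variable.
#' @param lenient Drop later inconsistent transitions instead of erroring.
#' @return A `minimal_set_family`: list with `target`, `variables`, `sets`
#'   (list of integer index vectors), `scores`, `frequencies`.
#' @export
minimal_sets <- function(ts, target, lenient = FALSE) {
  stopifnot(inherits(ts, "transition_set"))
  vars <- colnames(ts$inputs)
  if (is.character(target)) {
    ti <- match(target, vars)
    if (is.na(ti)) stop("unknown target probe: ", target)
  } else ti <- as.integer(target)
  X <- ts$inputs
  y <- ts$outputs[, ti]
  keep <- rep(TRUE, nrow(X))
  diff_sets <- list()
  repeat {
    idx <- which(keep)
    bad <- NULL
    diff_sets <- list()
    for (a_pos in seq_along(idx)) {
      for (b_pos in seq_along(idx)) {
        if (b_pos <= a_pos) next
        a <- idx[a_pos]; b <- idx[b_pos]
        if (y[a] == y[b]) next
        D <- which(X[a, ] != X[b, ])
        if (!length(D)) {
          bad <- c(a, b)
          break
        }
        diff_sets[[length(diff_sets) + 1L]] <- D
      }
      if (!is.null(bad)) break
    }
    if (is.null(bad)) break
    msg <- sprintf(
      "inconsistent transitions for target %s: identical inputs at %s and %s give outputs %d and %d",
      vars[ti], rownames(X)[bad[1]], rownames(X)[bad[2]], y[bad[1]], y[bad[2]])
    if (!lenient) stop(msg)
    warning(msg, "; dropping the later transition")
    keep[bad[2]] <- FALSE
  }
  diff_sets <- unique(diff_sets)
  fam <- .minimal_hitting_sets(diff_sets)
  scores <- .score_family(fam)
  # evidence score: every candidate set is consistent with the data by
  # construction; a set whose input projection collapses the u unique
  # transitions into m classes had null probability q^-(u - m) of being
  # consistent under a random update table, so u - m measures how surprising
  # (hence how credible) the set's consistency is
  ux <- unique(X[keep, , drop = FALSE])
  u <- nrow(ux)
  evidence <- vapply(fam, function(s) {
    if (!length(s)) return(0)
    u - nrow(unique(ux[, s, drop = FALSE]))
  }, numeric(1))
  structure(list(target = vars[ti], variables = vars, sets = fam,
                 scores = scores$set_scores,
                 evidence = evidence,
                 frequencies = scores$frequencies),
            class = "minimal_set_family")
}

# frequency of each variable over the family; set score = product of member
# frequencies, normalized across the family (empty product = 1)
.score_family <- function(fam, n_vars = NULL) {
  if (!length(fam)) return(list(set_scores = numeric(), frequencies = numeric()))
  vars <- sort(unique(unlist(fam)))
  freq <- vapply(vars, function(v)
    mean(vapply(fam, function(s) v %in% s, logical(1))), numeric(1))
  names(freq) <- as.character(vars)
  raw <- vapply(fam, function(s)
    prod(freq[as.character(s)]), numeric(1)) # empty product = 1
  list(set_scores = raw / sum(raw), frequencies = freq)
}

#' @export
print.minimal_set_family <- function(x, ...) {
  cat(sprintf("<minimal_set_family> target %s: %d minimal set(s)\n",
              x$target, length(x$sets)))
  for (i in seq_len(min(length(x$sets), 10L))) {
    s <- x$sets[[i]]
    cat(sprintf("  {%s} score %.3f\n",
                paste(x$variables[s], collapse = ", "), x$scores[i]))
  }
  invisible(x)
}

#' Select one minimal set per target into a directed adjacency
#'
#' Applies the no-crosstalk filter and the scoring rule to each target's
#' minimal-set family and assembles the chosen sets into a probe-level
#' directed adjacency (`msa` matrix, entries 0/1; entry (target, j) = 1 for
#' every member j of the chosen set).
#'
#' The no-crosstalk filter discards candidate sets that contain an ectoderm
#' probe for a mesoderm-module target or vice versa — unless *all* of a
#' target's candidates violate it, in which case the unfiltered family is
#' kept with a warning (the constraint is applied wherever possible). Among
#' the surviving sets the one with the strongest consistency evidence is
#' chosen (see [minimal_sets()]), with ties broken by the frequency score,
#' then smaller size, then lexicographic variable order.
#'
#' @param families List of `minimal_set_family`, one per probe, in probe
#'   order (names ignored; each family carries its target).
#' @param probe_modules Named character vector probe -> module label;
#'   required for `crosstalk = "prefer-none"`, ignored otherwise.
#' @param crosstalk `"prefer-none"` (default) applies the filter;
#'   `"ignore"` skips it.
#' @param scorer Function `(sets)` returning a numeric score per set, used
#'   on the surviving sets; defaults to the frequency-product score.
#' @return List with `network` (probe-level `gene_network`, entries 0/1),
#'   `chosen` (named list of chosen sets as probe-name vectors), and
#'   `discarded` (named list of sets removed by the filter).
#' @export
select_model <- function(families, probe_modules = NULL,
                         crosstalk = c("prefer-none", "ignore"),
                         scorer = NULL) {
  crosstalk <- match.arg(crosstalk)
  if (!length(families)) stop("empty family list")
  vars <- families[[1]]$variables
  n <- length(vars)
  adj <- matrix(0L, n, n, dimnames = list(vars, vars))
  chosen <- discarded <- setNames(vector("list", 0L), character())
  for (fam in families) {
    if (!length(fam$sets))
      stop("empty minimal-set family for target ", fam$target)
    sets <- fam$sets
    evidence <- fam$evidence %||% rep(0, length(sets))
    dropped <- list()
    if (crosstalk == "prefer-none" && !is.null(probe_modules)) {
      tmod <- probe_modules[[fam$target]]
      opp <- switch(tmod, ectoderm = "mesoderm", mesoderm = "ectoderm", NA)
      if (!is.na(opp)) {
        viol <- vapply(sets, function(s)
          any(probe_modules[vars[s]] == opp), logical(1))
        if (all(viol)) {
          if (length(sets) > 0L && any(viol))
            warning(sprintf(
              "all candidate sets for target %s violate no-crosstalk; keeping them",
              fam$target))
        } else {
          dropped <- sets[viol]
          sets <- sets[!viol]
          evidence <- evidence[!viol]
        }
      }
    }
    scores <- if (is.null(scorer)) .score_family(sets)$set_scores
              else scorer(sets)
    sizes <- vapply(sets, length, integer(1))
    lex <- vapply(sets, function(s)
      paste(sprintf("%05d", s), collapse = ","), character(1))
    best <- order(-evidence, -scores, sizes, lex)[1]
    pick <- sets[[best]]
    adj[fam$target, vars[pick]] <- 1L
    chosen[[fam$target]] <- vars[pick]
    discarded[[fam$target]] <- lapply(dropped, function(s) vars[s])
  }
  list(network = new_gene_network(adj), chosen = chosen,
       discarded = discarded)
}
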