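# Independent oracles, deliberately implemented with different algorithms
# than the package (hand-rolled BFS, exhaustive subset enumeration, naive
# double loops) so that agreement is meaningful.

# BFS shortest-path average over ordered reachable pairs of distinct nodes.
# Undirected (-1) cells are traversable both ways; NA cells are non-edges.
oracle_apl <- function(adj) {
  n <- nrow(adj)
  nbr <- lapply(seq_len(n), function(j) {
    out <- c(which(!is.na(adj[, j]) & adj[, j] == 1L),   # j -> targets
             which(!is.na(adj[, j]) & adj[, j] == -1L))  # undirected
    setdiff(unique(out), j)
  })
  total <- 0; count <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbr[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    reached <- which(!is.na(dist) & seq_len(n) != s)
    total <- total + sum(dist[reached])
    count <- count + length(reached)
  }
  if (count == 0) NA_real_ else total / count
}

# brute-force motif counts over directed cells
oracle_motifs <- function(adj) {
  n <- nrow(adj)
  d <- function(from, to) !is.na(adj[to, from]) && adj[to, from] == 1L &&
    from != to
  two <- 0; ffl <- 0; fbl <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d(i, j) && d(j, i)) two <- two + 1
  }
  if (n >= 3) {
    trips <- expand.grid(a = seq_len(n), b = seq_len(n), c = seq_len(n))
    trips <- trips[trips$a != trips$b & trips$b != trips$c &
                     trips$a != trips$c, ]
    for (k in seq_len(nrow(trips))) {
      a <- trips$a[k]; b <- trips$b[k]; cc <- trips$c[k]
      if (d(a, b) && d(b, cc) && d(a, cc)) ffl <- ffl + 1
      if (a < b && a < cc && d(a, b) && d(b, cc) && d(cc, a)) fbl <- fbl + 1
    }
  }
  c(two_cycles = two, feedforward = ffl, feedback = fbl)
}

# exhaustive minimal hitting sets: enumerate all 2^n subsets, keep those
# hitting every difference set, then keep the subset-minimal ones
oracle_hitting_sets <- function(diff_sets, n_vars) {
  if (!length(diff_sets)) return(list(integer(0)))
  subsets <- lapply(0:(2^n_vars - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(n_vars) - 1)) > 0))
  hits <- Filter(function(s) all(vapply(diff_sets, function(D)
    any(D %in% s), logical(1))), subsets)
  minimal <- Filter(function(s) !any(vapply(hits, function(h)
    length(h) < length(s) && all(h %in% s), logical(1))), hits)
  minimal[order(vapply(minimal, function(s)
    paste(sprintf("%05d", c(length(s), s)), collapse = ","), character(1)))]
}

# naive per-cell confusion loop over all ordered off-diagonal pairs
oracle_confusion <- function(m_adj, g_adj) {
  counts <- c(TP = 0, TN = 0, HR = 0, FP = 0, FN = 0)
  n <- nrow(m_adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m <- m_adj[i, j]; g <- g_adj[i, j]
    if (is.na(m) || is.na(g)) next
    cls <- if (m == 1 && (g == 1 || g == -1)) "TP"
      else if (m == 1 && g == 0) "FP"
      else if (m == 0 && g == 0) "TN"
      else if (m == 0 && (g == 1 || g == -1)) "FN"
      else if (m == -1 && g == 1) "HR"
      else if (m == -1 && g == -1) "TP"
      else "FP" # m == -1, g == 0
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# random mixed-graph adjacency with symmetric -1 entries and NA cells
random_mixed_adj <- function(n, p_dir = 0.15, p_und = 0.1, p_abs = 0.3,
                             nodes = sprintf("n%02d", seq_len(n))) {
  adj <- matrix(NA_integer_, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!is.na(adj[i, j])) next
    r <- runif(1)
    if (r < p_und) {
      adj[i, j] <- adj[j, i] <- -1L
    } else if (r < p_und + p_dir) {
      adj[i, j] <- 1L
    } else if (r < p_und + p_dir + p_abs) {
      adj[i, j] <- 0L
    }
  }
  # directed cells may have overwritten half an undirected pair; repair
  bad <- which(!is.na(adj) & adj == -1L & !(t(adj) == -1L & !is.na(t(adj))),
               arr.ind = TRUE)
  if (nrow(bad)) adj[bad] <- 1L
  diag(adj) <- 0L
  adj
}

# small module map cycling through the five standard labels
cycle_modules <- function(nodes) {
  labs <- c("initiation", "ectoderm", "mesoderm", "mixed", "other")
  stats::setNames(rep(labs, length.out = length(nodes)), nodes)
}

# drop undirected edges from a network, keeping directed structure
directed_part <- function(net) {
  a <- adjacency(net)
  a[!is.na(a) & a == -1L] <- 0L
  new_gene_network(a, modules = network_modules(net))
}

# a 15-gene gold-standard-style fixture with the study's module layout and
# at least one positive and one negative pair in every feature domain
study_fixture <- function() {
  genes <- c("pal-1", "tbx-8", "tbx-9",
             "elt-1", "elt-3", "lin-26", "nhr-25",
             "hlh-1", "hnd-1", "unc-120",
             "nob-1", "scrt-1", "vab-7",
             "cwn-1", "mab-21")
  modules <- stats::setNames(
    rep(c("initiation", "ectoderm", "mesoderm", "mixed", "other"),
        c(3, 4, 3, 3, 2)), genes)
  edges <- data.frame(
    target = c("elt-1", "hlh-1", "hnd-1", "unc-120", "tbx-8",
               "elt-3", "lin-26", "hlh-1", "unc-120", "nob-1",
               "vab-7", "cwn-1", "mab-21"),
    source = c("pal-1", "pal-1", "pal-1", "pal-1", "pal-1",
               "elt-1", "nhr-25", "hnd-1", "vab-7", "lin-26",
               "nob-1", "nob-1", "scrt-1"),
    value = 1)
  und <- data.frame(target = c("tbx-9", "elt-3"),
                    source = c("tbx-8", "lin-26"), value = -1)
  zero <- data.frame(
    target = c("pal-1", "nhr-25", "elt-1", "hlh-1", "hnd-1",
               "tbx-9", "mab-21", "scrt-1"),
    source = c("elt-1", "elt-1", "lin-26", "unc-120", "hlh-1",
               "pal-1", "pal-1", "nob-1"),
    value = 0)
  make_network(genes, rbind(edges, und, zero), modules = modules)
}
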