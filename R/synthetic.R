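# Synthetic ground truth: a random directed network with module labels plus
# a random q-state update table per node over its parents — a finite
# dynamical system whose trajectories emulate developmental time-course
# expression data, and whose edges are known exactly so that inference and
# assessment can be validated end to end.

.default_module_sizes <- function(n) {
  # proportional to the 15-gene study composition
  # (3 initiation, 4 ectoderm, 3 mesoderm, 3 mixed, 2 other)
  w <- c(initiation = 3, ectoderm = 4, mesoderm = 3, mixed = 3, other = 2)
  raw <- w / sum(w) * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  sizes[sizes > 0]
}

#' Generate a ground-truth regulatory network
#'
#' Draws a random directed network: each ordered off-diagonal pair is an
#' edge with probability `density`, module labels are assigned from
#' `module_sizes`, and each node receives a random `q`-state update table
#' over its parents (so the network defines a finite dynamical system).
#' With `no_crosstalk = TRUE`, edges between the ectoderm and mesoderm
#' modules are never drawn, matching the biological constraint that the two
#' tissue programs do not regulate each other directly.
#'
#' @param n Number of genes (>= 2).
#' @param module_sizes Named integer vector of module sizes summing to `n`;
#'   defaults to the study's proportions (initiation 3 : ectoderm 4 :
#'   mesoderm 3 : mixed 3 : other 2, scaled to `n`).
#' @param density Edge probability in (0, 1); default 0.15.
#' @param q Number of dynamic states; default 3.
#' @param no_crosstalk Forbid ectoderm <-> mesoderm edges.
#' @param max_parents Safety cap on parent-set size (update tables have
#'   `q^k` rows).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A `ground_truth`: list with `network` (directed `gene_network`
#'   with fully known cells: 1 = edge, 0 = non-edge), `update` (per-node
#'   state tables), `modules`, `q`, `seed`.
#' @export
generate_network <- function(n, module_sizes = NULL, density = 0.15,
                             q = 3L, no_crosstalk = FALSE,
                             max_parents = 10L, seed = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(module_sizes)) module_sizes <- .default_module_sizes(n)
  if (sum(module_sizes) != n)
    stop(sprintf("module sizes sum to %d, not n = %d",
                 sum(module_sizes), n))
  genes <- sprintf("g%02d", seq_len(n))
  modules <- setNames(rep(names(module_sizes), module_sizes), genes)
  adj <- matrix(0L, n, n, dimnames = list(genes, genes))
  draw <- matrix(runif(n * n) < density, n, n)
  diag(draw) <- FALSE
  if (no_crosstalk) {
    ect <- modules == "ectoderm"
    mes <- modules == "mesoderm"
    draw[outer(ect, mes, "&") | outer(mes, ect, "&")] <- FALSE
  }
  adj[draw] <- 1L
  q <- as.integer(q)
  update <- lapply(seq_len(n), function(i) {
    parents <- which(adj[i, ] == 1L)
    if (length(parents) > max_parents)
      stop(sprintf(
        "node %s has %d parents (> max_parents = %d); lower the density",
        genes[i], length(parents), max_parents))
    list(parents = parents,
         table = sample(0:(q - 1L), q^length(parents), replace = TRUE))
  })
  names(update) <- genes
  structure(list(network = new_gene_network(adj, modules = modules),
                 update = update, modules = modules, q = q, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d genes, %d edges, q = %d\n",
              length(x$update),
              sum(adjacency(x$network) == 1L, na.rm = TRUE), x$q))
  invisible(x)
}

# advance one synchronous step of the finite dynamical system
.step_states <- function(gt, state) {
  q <- gt$q
  vapply(gt$update, function(u) {
    k <- length(u$parents)
    idx <- if (k == 0L) 1L
           else sum(state[u$parents] * q^(seq_len(k) - 1L)) + 1L
    u$table[idx]
  }, integer(1))
}

#' Simulate expression time courses from a ground truth
#'
#' Runs `n_series` independent trajectories of the finite dynamical system
#' from random initial states, for `T` time points each, and maps discrete
#' states to real abundances affinely (`abundance = state * spacing`) with
#' additive Gaussian noise. At `noise_sd = 0` the affine map makes
#' equal-frequency discretization an exact inverse for every probe that
#' visits all `q` states. A node with an empty parent set is constant from
#' the second time point of every series onward.
#'
#' @param gt A `ground_truth`.
#' @param T Time points per series (>= 2); default 10.
#' @param n_series Number of independent series; default 2 (the study
#'   profiled two genotypes over the same developmental window).
#' @param noise_sd Standard deviation of the additive measurement noise.
#' @param spacing Abundance difference between consecutive states.
#' @param seed Optional integer seed.
#' @return An [expression_timecourse()] with an extra field `states`
#'   (the integer state matrix, for validation against the truth).
#' @export
simulate_timecourse <- function(gt, T = 10L, n_series = 2L, noise_sd = 0,
                                spacing = 1, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (T < 2) stop("T must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  genes <- names(gt$update)
  n <- length(genes)
  states <- matrix(0L, n, T * n_series,
                   dimnames = list(genes, NULL))
  col <- 0L
  for (s in seq_len(n_series)) {
    st <- sample(0:(gt$q - 1L), n, replace = TRUE)
    for (t in seq_len(T)) {
      col <- col + 1L
      states[, col] <- st
      st <- .step_states(gt, st)
    }
  }
  colnames(states) <- sprintf("s%d_t%d", rep(seq_len(n_series), each = T),
                              rep(seq_len(T), n_series))
  values <- states * spacing +
    matrix(rnorm(length(states), sd = noise_sd), n)
  dimnames(values) <- dimnames(states)
  tc <- expression_timecourse(values,
                              series = rep(seq_len(n_series), each = T))
  tc$states <- states
  tc
}

#' Generate a synthetic evidence table from a ground truth
#'
#' Emulates a curated gene-interaction evidence table: every true edge
#' receives a record satisfying one randomly chosen directed-call clause of
#' [classify_evidence()] (significant + large fold change, significant +
#' one-hybrid hit, two or more directional genetic reports, or significant
#' + a single genetic report), and every non-edge an all-zero record
#' (explicit non-interaction). With probability `flip_rate` a record is
#' corrupted into the unknown region of the rule space (sub-threshold
#' significance with a non-zero fold change), so at `flip_rate = 0` the
#' gold-standard builder reproduces the truth exactly.
#'
#' @param gt A `ground_truth`.
#' @param flip_rate Corruption probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Evidence data frame (`target`, `source`, `sig`, `mag`, `y1h`,
#'   `gen`) with one row per ordered off-diagonal pair.
#' @export
generate_evidence <- function(gt, flip_rate = 0, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (flip_rate < 0 || flip_rate >= 1) stop("flip_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  adj <- adjacency(gt$network)
  genes <- rownames(adj)
  pairs <- expand.grid(target = genes, source = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target != pairs$source, ]
  m <- nrow(pairs)
  rec <- data.frame(pairs, sig = 0, mag = 0, y1h = 0L, gen = 0L,
                    stringsAsFactors = FALSE)
  is_edge <- adj[cbind(pairs$target, pairs$source)] == 1L
  for (k in which(is_edge)) {
    clause <- sample.int(4L, 1L)
    if (clause == 1L) {
      rec$sig[k] <- runif(1, 2, 4); rec$mag[k] <- runif(1, 2, 5)
    } else if (clause == 2L) {
      rec$sig[k] <- runif(1, 2, 4); rec$y1h[k] <- 1L
    } else if (clause == 3L) {
      rec$gen[k] <- sample(2:3, 1L)
    } else {
      rec$sig[k] <- runif(1, 2, 4); rec$gen[k] <- sample(c(-1L, 1L), 1L)
    }
  }
  flip <- runif(m) < flip_rate
  if (any(flip)) {
    rec$sig[flip] <- runif(sum(flip), 0.1, 1.9)
    rec$mag[flip] <- runif(sum(flip), 2.5, 5)
    rec$y1h[flip] <- 0L
    rec$gen[flip] <- 0L
  }
  rownames(rec) <- NULL
  rec
}

#' Split genes into multiple probes
#'
#' Emulates multi-probe microarray genes by duplicating selected genes'
#' rows into several probes with optional Gaussian jitter, updating the
#' probe map accordingly (gene count unchanged, probe count increased).
#' At `jitter_sd = 0` the duplicated probes are identical, so their
#' covariance equals their variance — the situation the covariance
#' coupling of the pipeline is designed to preserve.
#'
#' @param tc An [expression_timecourse()] whose probes are one per gene.
#' @param genes Genes to split.
#' @param copies Number of probes per split gene (default 2), recycled.
#' @param jitter_sd Standard deviation of the per-probe jitter.
#' @param seed Optional integer seed.
#' @return A new `expression_timecourse` with probes named
#'   `<gene>.p1, <gene>.p2, ...` for split genes.
#' @export
probe_split <- function(tc, genes, copies = 2L, jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(tc, "expression_timecourse"))
  if (!is.null(seed)) set.seed(seed)
  gene_of <- setNames(tc$map$gene, tc$map$probe)
  miss <- setdiff(genes, gene_of[rownames(tc$values)])
  if (length(miss)) stop("gene(s) not in time course: ",
                         paste(miss, collapse = ", "))
  copies <- rep_len(as.integer(copies), length(genes))
  rows <- list(); probes <- character(); owners <- character()
  for (p in rownames(tc$values)) {
    g <- gene_of[[p]]
    k <- match(g, genes)
    if (is.na(k)) {
      rows[[length(rows) + 1L]] <- tc$values[p, ]
      probes <- c(probes, p); owners <- c(owners, g)
    } else {
      for (cpy in seq_len(copies[k])) {
        rows[[length(rows) + 1L]] <- tc$values[p, ] +
          rnorm(ncol(tc$values), sd = jitter_sd)
        probes <- c(probes, sprintf("%s.p%d", g, cpy))
        owners <- c(owners, g)
      }
    }
  }
  values <- do.call(rbind, rows)
  rownames(values) <- probes
  expression_timecourse(values, series = tc$series,
                        map = probe_map(probes, owners))
}
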