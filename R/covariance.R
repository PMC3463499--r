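#' Covariance adjacency of a time course
#'
#' Computes the probe x probe sample variance-covariance matrix (n-1
#' divisor) over all time points pooled across series, thresholds it at the
#' median of the *entire* matrix (diagonal included), and marks every cell
#' at or above the threshold as an undirected interaction (`-1`); cells
#' below it become `0`. The median threshold couples the probe sets of
#' multi-probe genes, whose probes covary most strongly, while halving the
#' candidate pair space. Covariance carries no directional information, so
#' the result contains no `+1` entries.
#'
#' @param tc An [expression_timecourse()].
#' @param absolute Threshold `|cov|` against the median of `|cov|` instead
#'   of the signed values. Default `FALSE` (signed, as the raw matrix is
#'   summarized by its median).
#' @return A symmetric probe-level `gene_network` with entries in `-1, 0`;
#'   the threshold used is attached as attribute `"threshold"`.
#' @export
covariance_adjacency <- function(tc, absolute = FALSE) {
  stopifnot(inherits(tc, "expression_timecourse"))
  if (ncol(tc$values) < 2L) stop("need at least 2 time points")
  C <- cov(t(tc$values))
  M <- if (absolute) abs(C) else C
  thr <- median(M)
  adj <- matrix(0L, nrow(C), ncol(C), dimnames = dimnames(C))
  adj[M >= thr] <- -1L
  net <- new_gene_network(adj)
  attr(net, "threshold") <- thr
  net
}

# shared undirected rule of both combiners: i != j, covarying, and no MSA
# directed edge in either direction
.cov_undirected <- function(msa, cov) {
  und <- cov == -1L & msa == 0L & t(msa) == 0L
  diag(und) <- FALSE
  und
}

.check_same_probes <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("MSA and COV adjacencies cover different probe universes")
}

#' Combine MSA and COV adjacencies into a gene-level model
#'
#' The two pipeline orders combine the directed probe-level `msa` adjacency
#' (entries 0/1) and the undirected probe-level `cov` adjacency (entries
#' 0/-1) cell by cell, then collapse probes to genes by the unanimity rule
#' of [collapse_probes()].
#'
#' `combine_msa_cov()` (order MSA-COV) keeps every MSA directed edge and
#' adds an undirected edge for covarying pairs with no directed edge in
#' either direction:
#' * `+1` if `msa(i,j) = 1`;
#' * `-1` if `i != j`, `cov(i,j) = -1`, `msa(i,j) = 0` and `msa(j,i) = 0`;
#' * `0` otherwise.
#'
#' `combine_cov_msa()` (order COV-MSA) lets covariance decide which pairs
#' interact and MSA orient them, so a directed edge additionally requires
#' covariation:
#' * `+1` if `cov(i,j) = -1` and `msa(i,j) = 1`;
#' * `-1` as above;
#' * `0` otherwise (including covarying pairs oriented only in reverse).
#'
#' Undirected self-loops are discarded in both orders (self-regulation
#' cannot be established from covariance).
#'
#' @param msa Probe-level directed `gene_network` (entries 0/1), e.g. from
#'   [select_model()].
#' @param cov Probe-level undirected `gene_network` (entries 0/-1) from
#'   [covariance_adjacency()].
#' @param map A [probe_map()] covering all probes.
#' @param modules Optional gene-to-module map for the collapsed result.
#' @return Gene-level `gene_network`.
#' @export
combine_msa_cov <- function(msa, cov, map, modules = NULL) {
  A_msa <- adjacency(msa)
  A_cov <- adjacency(cov)
  .check_same_probes(A_msa, A_cov)
  P <- matrix(0L, nrow(A_msa), ncol(A_msa), dimnames = dimnames(A_msa))
  P[A_msa == 1L] <- 1L
  P[.cov_undirected(A_msa, A_cov)] <- -1L
  collapse_probes(new_gene_network(P), map, modules = modules)
}

#' @rdname combine_msa_cov
#' @export
combine_cov_msa <- function(cov, msa, map, modules = NULL) {
  A_msa <- adjacency(msa)
  A_cov <- adjacency(cov)
  .check_same_probes(A_msa, A_cov)
  P <- matrix(0L, nrow(A_msa), ncol(A_msa), dimnames = dimnames(A_msa))
  P[A_cov == -1L & A_msa == 1L] <- 1L
  P[.cov_undirected(A_msa, A_cov)] <- -1L
  collapse_probes(new_gene_network(P), map, modules = modules)
}
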