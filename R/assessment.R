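#' Feature subnetwork pair domains
#'
#' Builds the six ordered-pair domains over which a model is assessed
#' against a gold standard: `Overall` (every ordered off-diagonal pair),
#' `P` (pairs whose source is the designated master regulator), and for
#' each of the ectoderm and mesoderm modules a strict (`"s"`, both
#' endpoints inside the module) and a wide (`"w"`, at least one endpoint
#' inside the module) subnetwork. The diagonal is excluded everywhere.
#'
#' @param nodes Character vector of node identifiers.
#' @param modules Named character vector node -> module covering all nodes.
#' @param master Master-regulator node (source of the `P` domain).
#' @return Named list of data frames (`target`, `source`):
#'   `Overall`, `P`, `E(s)`, `E(w)`, `M(s)`, `M(w)`.
#' @export
feature_domains <- function(nodes, modules, master) {
  nodes <- as.character(nodes)
  if (!master %in% nodes)
    stop("master regulator ", master, " is not a network node")
  miss <- setdiff(nodes, names(modules))
  if (length(miss))
    stop("modules missing for node(s): ", paste(miss, collapse = ", "))
  all_pairs <- expand.grid(target = nodes, source = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$target != all_pairs$source, ]
  in_mod <- function(g, mod) modules[g] == mod
  sub <- function(cond) {
    d <- all_pairs[cond, , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  ect_t <- in_mod(all_pairs$target, "ectoderm")
  ect_s <- in_mod(all_pairs$source, "ectoderm")
  mes_t <- in_mod(all_pairs$target, "mesoderm")
  mes_s <- in_mod(all_pairs$source, "mesoderm")
  list(
    "Overall" = sub(rep(TRUE, nrow(all_pairs))),
    "P" = sub(all_pairs$source == master),
    "E(s)" = sub(ect_t & ect_s),
    "E(w)" = sub(ect_t | ect_s),
    "M(s)" = sub(mes_t & mes_s),
    "M(w)" = sub(mes_t | mes_s))
}

# classify one scoreable (model, gold) cell pair into TP/TN/HR/FP/FN under
# the residual-combination policy
.classify_cell <- function(m, g, und_und, und_abs) {
  if (m == 1L) {
    if (g == 1L || g == -1L) "TP" else "FP"
  } else if (m == 0L) {
    if (g == 0L) "TN" else "FN"
  } else { # m == -1
    if (g == 1L) "HR"
    else if (g == -1L) und_und
    else und_abs
  }
}

#' Half-right-aware confusion counts
#'
#' Scores a model against a gold standard over a domain of ordered pairs.
#' Per pair: `TP` when the model's directed edge matches a gold directed or
#' undirected edge; `TN` when both agree on a non-interaction; `HR`
#' ("half-right") when the model offers an undirected edge where the gold
#' standard has a directed one; `FP` when the model asserts an edge the gold
#' standard excludes; `FN` when the model misses a gold edge. Pairs with an
#' unknown cell in *either* matrix are excluded — only actual predictions
#' against actual knowledge are counted. The two combinations the scheme
#' leaves open default to: model `-1` vs gold `-1` = `TP` (both assert the
#' interaction, neither orients it) and model `-1` vs gold `0` = `FP`.
#'
#' In `pair_mode = "unordered"` each unordered pair is counted once: both
#' ordered cells are classified and merged with precedence
#' `TP > HR > FP > FN > TN`.
#'
#' @param model,gold `gene_network`s over the same node universe.
#' @param domain Data frame of ordered pairs (`target`, `source`), e.g. an
#'   element of [feature_domains()]; default all off-diagonal pairs.
#' @param und_und Class of (model `-1`, gold `-1`): `"TP"` (default) or
#'   `"HR"`.
#' @param und_abs Class of (model `-1`, gold `0`): `"FP"` (default) or
#'   `"TN"`.
#' @param pair_mode `"ordered"` (default) or `"unordered"`.
#' @return A `confusion_summary`: list with `TP`, `TN`, `HR`, `FP`, `FN`,
#'   `n_scoreable`, `n_pairs`.
#' @export
confusion_counts <- function(model, gold, domain = NULL,
                             und_und = c("TP", "HR"),
                             und_abs = c("FP", "TN"),
                             pair_mode = c("ordered", "unordered")) {
  und_und <- match.arg(und_und)
  und_abs <- match.arg(und_abs)
  pair_mode <- match.arg(pair_mode)
  A_m <- adjacency(model)
  A_g <- adjacency(gold)
  if (!identical(rownames(A_m), rownames(A_g))) {
    if (!setequal(rownames(A_m), rownames(A_g)))
      stop("model and gold standard cover different node universes")
    A_m <- A_m[rownames(A_g), rownames(A_g)] # same set, align the order
  }
  nodes <- rownames(A_m)
  if (is.null(domain)) {
    domain <- expand.grid(target = nodes, source = nodes,
                          stringsAsFactors = FALSE)
    domain <- domain[domain$target != domain$source, ]
  }
  counts <- c(TP = 0, TN = 0, HR = 0, FP = 0, FN = 0)
  prec <- c("TP", "HR", "FP", "FN", "TN")
  if (pair_mode == "ordered") {
    n_pairs <- nrow(domain)
    for (k in seq_len(nrow(domain))) {
      m <- A_m[domain$target[k], domain$source[k]]
      g <- A_g[domain$target[k], domain$source[k]]
      if (is.na(m) || is.na(g)) next
      cls <- .classify_cell(m, g, und_und, und_abs)
      counts[cls] <- counts[cls] + 1
    }
  } else {
    key <- paste(pmin(domain$target, domain$source),
                 pmax(domain$target, domain$source))
    domain <- domain[!duplicated(key), , drop = FALSE]
    n_pairs <- nrow(domain)
    for (k in seq_len(nrow(domain))) {
      i <- domain$target[k]; j <- domain$source[k]
      cls <- character()
      for (cell in list(c(i, j), c(j, i))) {
        m <- A_m[cell[1], cell[2]]
        g <- A_g[cell[1], cell[2]]
        if (!is.na(m) && !is.na(g))
          cls <- c(cls, .classify_cell(m, g, und_und, und_abs))
      }
      if (!length(cls)) next
      cls <- prec[min(match(cls, prec))]
      counts[cls] <- counts[cls] + 1
    }
  }
  structure(c(as.list(counts),
              list(n_scoreable = sum(counts), n_pairs = n_pairs)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "<confusion_summary> TP %g, TN %g, HR %g, FP %g, FN %g (%g of %g pairs scoreable)\n",
    x$TP, x$TN, x$HR, x$FP, x$FN, x$n_scoreable, x$n_pairs))
  invisible(x)
}

#' Classifier point from confusion counts
#'
#' Computes the half-right-weighted rates: recall
#' `TPR = (TP + 0.5 HR) / (TP + 0.5 HR + FN + 0.5 HR)`, precision
#' `PPV = (TP + 0.5 HR) / (TP + 0.5 HR + FP)`, and `FPR = FP / (FP + TN)`.
#' A half-right prediction contributes half a true positive to both the
#' numerator and the miss term. Zero denominators yield `NA` (undefined is a
#' value, not an error).
#'
#' @param cs A `confusion_summary`.
#' @return List with `tpr`, `ppv`, `fpr` (each a number or `NA`).
#' @export
classifier_point <- function(cs) {
  h <- 0.5 * cs$HR
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(tpr = rate(cs$TP + h, cs$TP + h + cs$FN + h),
       ppv = rate(cs$TP + h, cs$TP + h + cs$FP),
       fpr = rate(cs$FP, cs$FP + cs$TN))
}

#' Signed distances from the random-guess diagonals
#'
#' `roc_distance()` is the signed Euclidean distance of the point
#' `(FPR, TPR)` from the ROC diagonal `y = x`:
#' `sqrt(2) * (TPR - FPR) / 2`, negative below the diagonal.
#' `pr_distance()` is the signed distance of `(recall, precision)` from the
#' PR anti-diagonal `y = 1 - x`: `sqrt(2) * (recall - 1 + precision) / 2`,
#' negative below it. Both lie in `[-sqrt(2)/2, sqrt(2)/2]`; the best
#' possible single point (perfect classifier corner) is at distance
#' `sqrt(2)/2`, about 0.7. `NA` inputs propagate.
#'
#' @param fpr,tpr,recall,precision Rates in `[0, 1]` (or `NA`).
#' @return Signed distance (or `NA`).
#' @export
roc_distance <- function(fpr, tpr) sqrt(2) * (tpr - fpr) / 2

#' @rdname roc_distance
#' @export
pr_distance <- function(recall, precision) sqrt(2) * (recall - 1 + precision) / 2

#' Assess a model network against a gold standard
#'
#' Runs the half-right-aware confusion counting over the six feature
#' domains of [feature_domains()], derives the PR and ROC points of each,
#' and summarizes the model by its *total distance*: the sum of the signed
#' PR and ROC distances over all six features (12 signed terms; maximum
#' `12 * sqrt(2)/2`, about 8.49). Undefined rates contribute 0 to the total
#' and are flagged. Prediction counts are reported over the `Overall`
#' domain: `predictions = TP + TN + HR + FP` (pairs where the model commits
#' to something the gold standard can judge) and
#' `correct = TP + TN + 0.5 HR`.
#'
#' @param model,gold `gene_network`s over the same node universe.
#' @param modules Named character vector node -> module (defaults to the
#'   gold standard's module map).
#' @param master Master-regulator node for the `P` domain.
#' @inheritParams confusion_counts
#' @return An `assessment_report`: list with `features` (data frame of
#'   counts, rates and distances per domain), `predictions`, `correct`,
#'   `pct_correct`, `total_distance`, `undefined` (feature/rate flags), and
#'   the policy settings used.
#' @export
assess_model <- function(model, gold, modules = NULL, master,
                         und_und = c("TP", "HR"), und_abs = c("FP", "TN"),
                         pair_mode = c("ordered", "unordered")) {
  und_und <- match.arg(und_und)
  und_abs <- match.arg(und_abs)
  pair_mode <- match.arg(pair_mode)
  if (is.null(modules)) modules <- network_modules(gold)
  if (is.null(modules))
    stop("modules must be given (or carried by the gold standard)")
  nodes <- network_nodes(gold)
  domains <- feature_domains(nodes, modules, master)
  rows <- list()
  undefined <- character()
  for (feat in names(domains)) {
    cs <- confusion_counts(model, gold, domains[[feat]],
                           und_und = und_und, und_abs = und_abs,
                           pair_mode = pair_mode)
    pt <- classifier_point(cs)
    prd <- pr_distance(pt$tpr, pt$ppv)
    rocd <- roc_distance(pt$fpr, pt$tpr)
    if (is.na(prd) || is.na(rocd))
      undefined <- c(undefined, feat)
    rows[[feat]] <- data.frame(
      feature = feat, TP = cs$TP, TN = cs$TN, HR = cs$HR, FP = cs$FP,
      FN = cs$FN, n_scoreable = cs$n_scoreable, tpr = pt$tpr, ppv = pt$ppv,
      fpr = pt$fpr, pr_distance = prd, roc_distance = rocd,
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  ov <- features[features$feature == "Overall", ]
  total <- sum(features$pr_distance, na.rm = TRUE) +
    sum(features$roc_distance, na.rm = TRUE)
  predictions <- ov$TP + ov$TN + ov$HR + ov$FP
  correct <- ov$TP + ov$TN + 0.5 * ov$HR
  structure(list(
    features = features,
    predictions = predictions,
    correct = correct,
    pct_correct = if (predictions > 0) 100 * correct / predictions
                  else NA_real_,
    total_distance = total,
    undefined = undefined,
    policy = list(und_und = und_und, und_abs = und_abs,
                  pair_mode = pair_mode, master = master)),
    class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<assessment_report> %g predictions, %g correct (%.0f%%); total distance %.2f\n",
    x$predictions, x$correct, x$pct_correct, x$total_distance))
  f <- x$features
  f[, c("tpr", "ppv", "fpr", "pr_distance", "roc_distance")] <-
    round(f[, c("tpr", "ppv", "fpr", "pr_distance", "roc_distance")], digits)
  print(f, row.names = FALSE)
  if (length(x$undefined))
    cat("  undefined rates (contributing 0):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Write an assessment report as JSON
#'
#' @param report An `assessment_report`.
#' @param path Output path.
#' @export
write_assessment_report <- function(report, path) {
  stopifnot(inherits(report, "assessment_report"))
  out <- unclass(report)
  out$schema <- "msanet/assessment-report/1"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
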