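test_that("confusion cells classify per the half-right scheme", {
  cell <- function(m, g) {
    nodes <- c("i", "j")
    mk <- function(v) {
      a <- matrix(NA_integer_, 2, 2, dimnames = list(nodes, nodes))
      if (v == -1L) a["i", "j"] <- a["j", "i"] <- v else a["i", "j"] <- v
      new_gene_network(a)
    }
    cs <- confusion_counts(mk(m), mk(g),
                           domain = data.frame(target = "i", source = "j"))
    names(which(unlist(cs[c("TP", "TN", "HR", "FP", "FN")]) == 1))
  }
  expect_identical(cell(1L, 1L), "TP")
  expect_identical(cell(1L, -1L), "TP")   # directed vs undirected gold
  expect_identical(cell(1L, 0L), "FP")
  expect_identical(cell(0L, 0L), "TN")
  expect_identical(cell(0L, 1L), "FN")
  expect_identical(cell(0L, -1L), "FN")
  expect_identical(cell(-1L, 1L), "HR")
  expect_identical(cell(-1L, -1L), "TP")  # residual default
  expect_identical(cell(-1L, 0L), "FP")   # residual default
})

test_that("unknown pairs are excluded and counts conserve the domain", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    m_adj <- random_mixed_adj(n)
    g_adj <- random_mixed_adj(n)
    cs <- confusion_counts(new_gene_network(m_adj), new_gene_network(g_adj))
    o <- oracle_confusion(m_adj, g_adj)
    expect_equal(unlist(cs[c("TP", "TN", "HR", "FP", "FN")]),
                 o, ignore_attr = TRUE)
    scoreable <- sum(!is.na(m_adj) & !is.na(g_adj)) - n # minus diagonal
    expect_equal(cs$n_scoreable, scoreable)
  }
  expect_error(
    confusion_counts(
      new_gene_network(random_mixed_adj(3)),
      new_gene_network(random_mixed_adj(3, nodes = c("x", "y", "z")))),
    "universe")
})

test_that("classifier points follow the half-right-weighted formulas", {
  cs <- structure(list(TP = 4, TN = 10, HR = 2, FP = 1, FN = 3,
                       n_scoreable = 20, n_pairs = 20),
                  class = "confusion_summary")
  pt <- classifier_point(cs)
  expect_equal(pt$tpr, 5 / 9)
  expect_equal(pt$ppv, 5 / 6)
  expect_equal(pt$fpr, 1 / 11)
  # HR = 0 reduces to the standard formulas
  cs$HR <- 0
  pt <- classifier_point(cs)
  expect_equal(pt$tpr, 4 / 7)
  expect_equal(pt$ppv, 4 / 5)
  # zero denominators yield NA, not an error
  cs0 <- structure(list(TP = 0, TN = 5, HR = 0, FP = 0, FN = 0,
                        n_scoreable = 5, n_pairs = 5),
                   class = "confusion_summary")
  pt <- classifier_point(cs0)
  expect_true(is.na(pt$ppv))
  expect_true(is.na(pt$tpr))
  expect_equal(pt$fpr, 0)
})

test_that("signed distances hit the documented extremes and signs", {
  expect_equal(roc_distance(0, 1), sqrt(2) / 2)
  expect_equal(round(roc_distance(0, 1), 1), 0.7)
  expect_equal(roc_distance(0.3, 0.3), 0)
  expect_equal(roc_distance(1, 0), -sqrt(2) / 2)
  expect_equal(pr_distance(1, 1), sqrt(2) / 2)
  expect_equal(pr_distance(0.25, 0.75), 0)
  expect_equal(pr_distance(0, 0), -sqrt(2) / 2)
  expect_true(is.na(roc_distance(NA_real_, 1)))
  # bounds over the unit square
  g <- expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1))
  expect_true(all(abs(roc_distance(g$x, g$y)) <= sqrt(2) / 2 + 1e-12))
  expect_true(all(abs(pr_distance(g$x, g$y)) <= sqrt(2) / 2 + 1e-12))
})

test_that("feature domains have the right pair counts", {
  net <- study_fixture()
  doms <- feature_domains(network_nodes(net), network_modules(net), "pal-1")
  expect_equal(nrow(doms[["Overall"]]), 15 * 14)
  expect_equal(nrow(doms[["P"]]), 14)
  expect_equal(nrow(doms[["E(s)"]]), 4 * 3)
  expect_equal(nrow(doms[["E(w)"]]), 15 * 14 - 11 * 10)
  expect_equal(nrow(doms[["M(s)"]]), 3 * 2)
  expect_equal(nrow(doms[["M(w)"]]), 15 * 14 - 12 * 11)
  expect_true(all(doms[["P"]]$source == "pal-1"))
  expect_error(feature_domains(network_nodes(net), network_modules(net),
                               "nope"), "not a network node")
})

test_that("self-assessment of a rich gold standard attains the maximum", {
  gold <- study_fixture()
  rep <- assess_model(gold, gold, master = "pal-1")
  expect_equal(rep$total_distance, 12 * sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(round(rep$total_distance, 2), 8.49)
  expect_true(all(rep$features$tpr == 1))
  expect_true(all(rep$features$ppv == 1))
  expect_true(all(rep$features$fpr == 0))
  expect_length(rep$undefined, 0)
})

test_that("a model on both random-guess diagonals has zero total distance", {
  # gold: i,j,k targets of s with one positive and one negative per domain;
  # simplest construction: model with tpr = fpr and precision = 1 - recall
  # per feature is hard to arrange globally, so build the degenerate case:
  # an all-unknown model makes no predictions -> every rate undefined ->
  # every distance contributes 0
  gold <- study_fixture()
  blank <- make_network(network_nodes(gold), modules = network_modules(gold))
  rep <- assess_model(blank, gold, master = "pal-1")
  expect_equal(rep$total_distance, 0)
  expect_equal(rep$predictions, 0)
  expect_length(rep$undefined, 6)
})

test_that("total distance and prediction counts compose per the report contract", {
  set.seed(41)
  gold <- study_fixture()
  nodes <- network_nodes(gold)
  model <- new_gene_network(random_mixed_adj(15, nodes = nodes),
                            modules = network_modules(gold))
  rep <- assess_model(model, gold, master = "pal-1")
  f <- rep$features
  ov <- f[f$feature == "Overall", ]
  expect_equal(rep$predictions, ov$TP + ov$TN + ov$HR + ov$FP)
  expect_equal(rep$correct, ov$TP + ov$TN + 0.5 * ov$HR)
  d <- ifelse(is.na(f$pr_distance), 0, f$pr_distance) +
    ifelse(is.na(f$roc_distance), 0, f$roc_distance)
  expect_equal(rep$total_distance, sum(d))
  expect_true(abs(rep$total_distance) <= 6 * sqrt(2))
  expect_true(all(f$tpr >= 0 & f$tpr <= 1, na.rm = TRUE))
  expect_true(all(f$fpr >= 0 & f$fpr <= 1, na.rm = TRUE))
  # report serializes to JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_assessment_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$total_distance, rep$total_distance)
})

test_that("residual-combination policies and pair mode are configurable", {
  nodes <- c("i", "j")
  mk <- function(v) {
    a <- matrix(NA_integer_, 2, 2, dimnames = list(nodes, nodes))
    a["i", "j"] <- a["j", "i"] <- v
    new_gene_network(a)
  }
  und <- mk(-1L)
  gz <- mk(0L)
  cs <- confusion_counts(und, gz, und_abs = "TN")
  expect_equal(cs$TN, 2)
  cs <- confusion_counts(und, mk(-1L), und_und = "HR")
  expect_equal(cs$HR, 2)
  # unordered mode counts each unordered pair once
  cs <- confusion_counts(und, mk(-1L), pair_mode = "unordered")
  expect_equal(cs$TP, 1)
  expect_equal(cs$n_scoreable, 1)
})
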