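test_that("discretization matches its quantile and identity contracts", {
  tcm <- function(x) expression_timecourse(matrix(x, 1,
                                                  dimnames = list("p", NULL)))
  expect_warning(d <- discretize(tcm(c(5, 5, 5, 5)), q = 7), "fewer")
  expect_equal(unname(d$values[1, ]), c(0, 0, 0, 0))
  d <- discretize(tcm(c(10, 20, 30, 40, 50, 60, 70)), q = 7)
  expect_equal(unname(d$values[1, ]), 0:6)
  d <- discretize(tcm(c(1, 9, 2, 8, 3, 7, 4, 6)), q = 2)
  expect_equal(unname(d$values[1, ]), c(0, 1, 0, 1, 0, 1, 0, 1))
  # equal-width differs from equal-frequency on skewed data
  x <- c(0, 1, 2, 3, 100, 101, 102, 103, 104, 105)
  ef <- discretize(tcm(x), q = 2)$values[1, ]
  ew <- discretize(tcm(x), q = 2, method = "equal-width")$values[1, ]
  expect_equal(unname(ef), c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  expect_equal(unname(ew), c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
  # agglomerative single-link splits at the largest gap
  ag <- discretize(tcm(x), q = 2, method = "agglomerative")$values[1, ]
  expect_equal(unname(ag), c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
  expect_error(discretize(tcm(1:4), q = 1), "at least 2")
})

test_that("transitions respect series boundaries", {
  vals <- matrix(seq_len(40), nrow = 2,
                 dimnames = list(c("p1", "p2"), NULL))
  tc <- expression_timecourse(vals, series = rep(1:2, each = 10))
  ts <- extract_transitions(suppressWarnings(discretize(tc, q = 7)))
  expect_equal(nrow(ts$inputs), 18) # two series of 10 -> 2 x 9
  one <- expression_timecourse(vals[, 1:10, drop = FALSE])
  ts1 <- extract_transitions(suppressWarnings(discretize(one, q = 7)))
  expect_equal(nrow(ts1$inputs), 9)
  # length-2 series: single transition (state(t0), state(t1))
  two <- expression_timecourse(vals[, 1:2, drop = FALSE])
  ts2 <- extract_transitions(suppressWarnings(discretize(two, q = 7)))
  expect_equal(nrow(ts2$inputs), 1)
  expect_error(expression_timecourse(vals, series = c(rep(1, 19), 2)),
               "at least 2")
})

make_ts <- function(inputs, outputs, q = 2L) {
  colnames(inputs) <- colnames(outputs) <- paste0("x", seq_len(ncol(inputs)))
  rownames(inputs) <- rownames(outputs) <- paste0("s1_t", seq_len(nrow(inputs)))
  structure(list(inputs = inputs, outputs = outputs, q = q),
            class = "transition_set")
}

test_that("minimal sets match hand-worked difference-set examples", {
  # difference sets {x2}, {x1,x2} -> family {{x2}}
  ts <- make_ts(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                cbind(c(0, 1, 1), 0, 0))
  fam <- minimal_sets(ts, "x1")
  expect_identical(fam$sets, list(2L))
  # difference sets {x1,x2}, {x1} -> family {{x1}}
  ts <- make_ts(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                cbind(c(0, 0, 1), 0, 0))
  fam <- minimal_sets(ts, "x1")
  expect_identical(fam$sets, list(1L))
  # constant output -> the empty family
  ts <- make_ts(rbind(c(0, 0), c(1, 0), c(0, 1)), cbind(c(1, 1, 1), 0))
  fam <- minimal_sets(ts, "x1")
  expect_identical(fam$sets, list(integer(0)))
  expect_equal(fam$scores, 1)
})

test_that("inconsistent transitions error by default and drop leniently", {
  ts <- make_ts(rbind(c(0, 0), c(0, 0), c(1, 0)), cbind(c(0, 1, 1), 0))
  expect_error(minimal_sets(ts, "x1"), "inconsistent")
  expect_warning(fam <- minimal_sets(ts, "x1", lenient = TRUE), "dropping")
  expect_identical(fam$sets, list(1L))
})

test_that("minimal-set families equal exhaustive enumeration on random systems", {
  set.seed(71)
  for (rep in 1:60) {
    n_vars <- sample(2:8, 1)
    n_trans <- sample(3:10, 1)
    inputs <- matrix(sample(0:1, n_vars * n_trans, TRUE), n_trans)
    outputs <- matrix(0L, n_trans, n_vars)
    # outputs as a function of the full input (always consistent)
    key <- apply(inputs, 1, paste, collapse = "")
    outputs[, 1] <- as.integer(as.integer(factor(key)) %% 2)
    ts <- make_ts(inputs, outputs)
    fam <- minimal_sets(ts, "x1")
    # oracle difference sets by direct double loop
    diff_sets <- list()
    for (a in seq_len(n_trans - 1)) for (b in (a + 1):n_trans) {
      if (outputs[a, 1] != outputs[b, 1])
        diff_sets[[length(diff_sets) + 1L]] <- which(inputs[a, ] != inputs[b, ])
    }
    expect_identical(fam$sets, oracle_hitting_sets(unique(diff_sets), n_vars))
    # antichain: no member contains another
    for (i in seq_along(fam$sets)) for (j in seq_along(fam$sets)) {
      if (i != j)
        expect_false(all(fam$sets[[i]] %in% fam$sets[[j]]))
    }
    expect_equal(sum(fam$scores), 1)
  }
})

test_that("select_model prefers crosstalk-free sets wherever possible", {
  fam <- function(target, sets, vars) {
    structure(list(target = target, variables = vars, sets = sets,
                   scores = rep(1 / length(sets), length(sets)),
                   evidence = rep(1, length(sets))),
              class = "minimal_set_family")
  }
  vars <- c("e1", "m1", "m2")
  mods <- c(e1 = "ectoderm", m1 = "mesoderm", m2 = "mesoderm")
  # mesodermal target: the ectodermal candidate is discarded
  sel <- select_model(list(fam("m2", list(1L, 2L), vars),
                           fam("e1", list(integer(0)), vars),
                           fam("m1", list(integer(0)), vars)),
                      probe_modules = mods)
  expect_identical(adjacency(sel$network)["m2", "m1"], 1L)
  expect_identical(adjacency(sel$network)["m2", "e1"], 0L)
  # all candidates violate: retained with a warning
  expect_warning(
    sel <- select_model(list(fam("m2", list(1L), vars),
                             fam("e1", list(integer(0)), vars),
                             fam("m1", list(integer(0)), vars)),
                        probe_modules = mods),
    "wherever possible|keeping them")
  expect_identical(adjacency(sel$network)["m2", "e1"], 1L)
  expect_error(select_model(list(fam("m1", list(), vars))), "empty")
})

test_that("covariance adjacency reproduces the hand-computed example", {
  tc <- expression_timecourse(rbind(p1 = c(1, 2, 3, 4), p2 = c(2, 4, 6, 8),
                                    p3 = c(4, 3, 2, 1)))
  net <- covariance_adjacency(tc)
  expect_equal(attr(net, "threshold"), 5 / 3)
  adj <- adjacency(net)
  # only off-diagonal undirected pair: p1-p2
  expect_identical(adj["p1", "p2"], -1L)
  expect_identical(adj["p2", "p1"], -1L)
  expect_identical(adj["p1", "p3"], 0L)
  expect_identical(adj["p2", "p3"], 0L)
  # ties at the median are included (>= comparison): p1 and p3 variances
  expect_identical(adj["p1", "p1"], -1L)
  expect_identical(adj["p3", "p3"], -1L)
  # identical probes covary maximally
  tc2 <- expression_timecourse(rbind(a = c(1, 5, 2, 7), b = c(1, 5, 2, 7),
                                     c = c(3, 3, 3.5, 3)))
  expect_identical(adjacency(covariance_adjacency(tc2))["a", "b"], -1L)
  # symmetry on random data
  set.seed(17)
  tc3 <- expression_timecourse(
    matrix(rnorm(60), 6, dimnames = list(paste0("p", 1:6), NULL)))
  a <- adjacency(covariance_adjacency(tc3))
  expect_identical(a, t(a))
})

test_that("the combiners implement their cell rules and collapse probes", {
  probes <- c("a", "b")
  pm <- probe_map(probes, probes)
  msa <- matrix(0L, 2, 2, dimnames = list(probes, probes))
  cov0 <- matrix(0L, 2, 2, dimnames = list(probes, probes))
  # msa edge kept in MSA-COV even without covariance support
  msa1 <- msa; msa1["b", "a"] <- 1L
  out <- combine_msa_cov(new_gene_network(msa1), new_gene_network(cov0), pm)
  expect_identical(adjacency(out)["b", "a"], 1L)
  # ... but vetoed in COV-MSA
  out <- combine_cov_msa(new_gene_network(cov0), new_gene_network(msa1), pm)
  expect_identical(adjacency(out)["b", "a"], 0L)
  # covarying pair with no directed edge either way -> undirected
  cov1 <- cov0; cov1["a", "b"] <- cov1["b", "a"] <- -1L
  out <- combine_msa_cov(new_gene_network(msa), new_gene_network(cov1), pm)
  expect_identical(adjacency(out)["a", "b"], -1L)
  expect_identical(adjacency(out)["b", "a"], -1L)
  # covarying pair oriented one way only -> 0 in COV-MSA
  out <- combine_cov_msa(new_gene_network(cov1), new_gene_network(msa1), pm)
  expect_identical(adjacency(out)["b", "a"], 1L) # cov & msa agree
  expect_identical(adjacency(out)["a", "b"], 0L) # reverse: oriented away
  # undirected self-loops discarded
  covd <- cov0; diag(covd) <- -1L
  out <- combine_msa_cov(new_gene_network(msa), new_gene_network(covd), pm)
  expect_true(all(diag(adjacency(out)) == 0L))
  expect_error(
    combine_msa_cov(new_gene_network(msa),
                    new_gene_network(matrix(0L, 1, 1,
                                            dimnames = list("a", "a"))), pm),
    "universe")
})

test_that("multi-probe collapse requires unanimity across the probe block", {
  probes <- c("a1", "a2", "b")
  pm <- probe_map(probes, c("A", "A", "B"))
  msa <- matrix(0L, 3, 3, dimnames = list(probes, probes))
  cov0 <- matrix(0L, 3, 3, dimnames = list(probes, probes))
  msa["b", "a1"] <- 1L
  out <- combine_msa_cov(new_gene_network(msa), new_gene_network(cov0), pm)
  expect_identical(adjacency(out)["B", "A"], 0L) # a2 probe dissents
  msa["b", "a2"] <- 1L
  out <- combine_msa_cov(new_gene_network(msa), new_gene_network(cov0), pm)
  expect_identical(adjacency(out)["B", "A"], 1L)
})

test_that("the pipeline is deterministic and COV-MSA directed edges nest in MSA-COV's", {
  set.seed(3)
  for (s in c(11, 22, 33)) {
    gt <- generate_network(8, density = 0.2, q = 3, seed = s)
    tc <- simulate_timecourse(gt, T = 12, n_series = 2, noise_sd = 0,
                              seed = s + 500)
    r1 <- suppressWarnings(run_pipeline(tc, q = 3, order = "msa-cov",
                                        modules = gt$modules))
    r1b <- suppressWarnings(run_pipeline(tc, q = 3, order = "msa-cov",
                                         modules = gt$modules))
    expect_identical(adjacency(r1$network), adjacency(r1b$network))
    r2 <- suppressWarnings(run_pipeline(tc, q = 3, order = "cov-msa",
                                        modules = gt$modules))
    d1 <- adjacency(r1$network) == 1L
    d2 <- adjacency(r2$network) == 1L
    expect_true(all(!d2 | d1)) # COV-MSA adds a conjunct, never an edge
    # provenance records the stages
    expect_named(r1$provenance,
                 c("order", "q", "method", "crosstalk", "absolute", "seed",
                   "n_probes", "n_transitions", "cov_threshold", "families",
                   "chosen", "discarded"))
  }
})

test_that("on noise-free data every chosen family contains true-parent subsets", {
  set.seed(12)
  for (s in c(5, 6)) {
    gt <- generate_network(8, density = 0.2, q = 3, seed = s)
    tc <- simulate_timecourse(gt, T = 15, n_series = 2, noise_sd = 0,
                              seed = s + 900)
    dtc <- suppressWarnings(discretize(tc, q = 3))
    ts <- extract_transitions(dtc)
    for (g in colnames(ts$inputs)) {
      fam <- minimal_sets(ts, g)
      parents <- names(gt$update[[g]]$parents)
      sets <- lapply(fam$sets, function(x) fam$variables[x])
      expect_true(any(vapply(sets, function(x) all(x %in% parents),
                             logical(1))),
                  info = sprintf("seed %d target %s", s, g))
    }
  }
})
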