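test_that("confusion cells follow the domain mapping", {
  cc <- confusion(c("neutral", "pathogenic"), c("neutral", "pathogenic"))
  expect_equal(unclass(cc), c(true_neutral = 1L, false_neutral = 0L,
                              false_pathogenic = 0L, true_pathogenic = 1L))
  cc2 <- confusion(c("pathogenic", "neutral"), c("neutral", "pathogenic"))
  expect_equal(unclass(cc2), c(true_neutral = 0L, false_neutral = 1L,
                               false_pathogenic = 1L, true_pathogenic = 0L))
  expect_error(confusion("neutral", c("neutral", "pathogenic")), "length")
})

test_that("confusion counts equal a brute-force tally on random inputs", {
  pred <- random_labels(200, seed = 61)
  lab <- random_labels(200, seed = 62)
  cc <- confusion(pred, lab)
  tally <- c(0L, 0L, 0L, 0L)
  for (i in 1:200) {
    cell <- if (pred[i] == "neutral" && lab[i] == "neutral") 1L
            else if (pred[i] == "neutral") 2L
            else if (lab[i] == "neutral") 3L else 4L
    tally[cell] <- tally[cell] + 1L
  }
  expect_equal(unname(unclass(cc)), tally)
})

test_that("metrics reproduce the arithmetic identities and NA on empty classes", {
  m <- metrics(confusion_counts(90, 10, 10, 90))
  expect_equal(m[["accuracy"]], 0.90)
  m2 <- metrics(confusion_counts(0, 0, 0, 10))
  expect_equal(m2[["accuracy"]], 1)
  expect_true(is.na(m2[["rate_N_given_0"]]) && is.na(m2[["rate_P_given_0"]]))
  m3 <- metrics(confusion_counts(91, 8, 9, 92))
  expect_equal(m3[["rate_N_given_0"]], 91 / 100)
  expect_equal(m3[["rate_P_given_1"]], 92 / 100)
  expect_equal(m3[["paper_formula_sensitivity"]], 91 / 99)
  expect_equal(m3[["paper_formula_type2"]], 9 / 101)
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("class-conditional rate pairs sum to one on random counts", {
  local_rng(71, {
    for (i in 1:50) {
      cc <- confusion_counts(sample(0:40, 1), sample(0:40, 1),
                             sample(0:40, 1), sample(1:40, 1))
      m <- metrics(cc)
      tn <- cc[["true_neutral"]]; fp <- cc[["false_pathogenic"]]
      fn <- cc[["false_neutral"]]; tp <- cc[["true_pathogenic"]]
      if (tn + fp > 0)
        expect_equal(m[["rate_N_given_0"]] + m[["rate_P_given_0"]], 1)
      if (fn + tp > 0)
        expect_equal(m[["rate_N_given_1"]] + m[["rate_P_given_1"]], 1)
      expect_equal(m[["accuracy"]], (tn + tp) / sum(unclass(cc)))
    }
  })
})

test_that("k-fold CV partitions each class with fold sizes differing by at most one", {
  fv <- random_features(230, c("SPP", "ExAC", "NDamage", "COMMON"), seed = 81)
  labels <- c(rep("neutral", 107), rep("pathogenic", 123))
  cv <- kfold_cv(fv, labels, k = 10, classifier = proposed_topology(),
                 seed = 99)
  folds <- attr(cv, "folds")
  expect_equal(sort(unique(folds)), 1:10)
  for (cl in c("neutral", "pathogenic")) {
    sizes <- table(folds[labels == cl])
    expect_length(sizes, 10L)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  cv2 <- kfold_cv(fv, labels, k = 10, classifier = proposed_topology(),
                  seed = 99)
  expect_identical(cv$mean, cv2$mean)
  expect_identical(attr(cv2, "folds"), folds)
  expect_error(kfold_cv(fv, c(rep("neutral", 5), rep("pathogenic", 225)),
                        k = 10, classifier = proposed_topology()),
               "at least k")
})

test_that("equal-fold CV of a fixed topology averages to the whole-set accuracy", {
  fv <- random_features(200, c("SPP", "ExAC", "NDamage", "COMMON"), seed = 82)
  labels <- c(rep("neutral", 100), rep("pathogenic", 100))
  top <- proposed_topology()
  cv <- kfold_cv(fv, labels, k = 10, classifier = top, seed = 7)
  full_acc <- metrics(confusion(classify_batch(fv, top)$label,
                                labels))[["accuracy"]]
  expect_equal(unname(cv$mean["accuracy"]), full_acc, tolerance = 1e-12)
})

test_that("CV with a builder classifier re-builds the chain per fold", {
  cfg <- preset_generator_config("ordered_separability", n_variants = 2000,
                                 seed = 15)
  v <- generate_variants(cfg)
  fv <- discretize_variants(v)
  builder <- function(features, labels)
    build_greedy(features, labels,
                 allowed_roots = c("SPP", "NDamage"))$topology
  cv <- kfold_cv(fv, v$label, k = 5, classifier = builder, seed = 3)
  expect_equal(cv$replicates, 5L)
  expect_true(all(cv$mean[c("accuracy")] > 0.8))
})

test_that("Monte Carlo with fraction one is the exact point estimate with zero spread", {
  fv <- random_features(150, c("SPP", "ExAC", "NDamage", "COMMON"), seed = 91)
  labels <- random_labels(150, seed = 92)
  top <- proposed_topology()
  mc <- monte_carlo(fv, labels, top, fraction = 1, replicates = 20, seed = 5)
  point <- metrics(confusion(classify_batch(fv, top)$label, labels))
  expect_equal(unname(mc$sd["accuracy"]), 0)
  expect_equal(mc$mean, unclass(point)[names(mc$mean)])
  mc2 <- monte_carlo(fv, labels, top, fraction = 1, replicates = 20, seed = 5)
  expect_identical(mc$mean, mc2$mean)
  expect_error(monte_carlo(fv[1, , drop = FALSE], labels[1], top,
                           fraction = 0.1), "zero")
  # bootstrap mode draws with replacement and still summarizes
  mb <- monte_carlo(fv, labels, top, fraction = 0.5, replicates = 10,
                    seed = 6, replace = TRUE)
  expect_equal(mb$replicates, 10L)
})

test_that("phi equals the Pearson correlation of the indicators", {
  x <- c(1, 1, 0, 0, 1, 0, 1, 0)
  expect_equal(phi_coefficient(x, x), 1)
  tab <- c(rep(1, 5), rep(1, 5), rep(0, 5), rep(0, 5))
  tab_y <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5))
  expect_equal(phi_coefficient(tab, tab_y), 0)
  local_rng(101, {
    for (i in 1:30) {
      a <- stats::rbinom(60, 1, stats::runif(1, 0.2, 0.8))
      b <- stats::rbinom(60, 1, stats::runif(1, 0.2, 0.8))
      if (length(unique(a)) < 2 || length(unique(b)) < 2) next
      expect_equal(phi_coefficient(a, b), stats::cor(a, b), tolerance = 1e-12)
      expect_equal(phi_coefficient(a, b), phi_coefficient(b, a))
      expect_equal(phi_coefficient(1 - a, 1 - b), phi_coefficient(a, b))
    }
  })
  deg <- phi_coefficient(c(1, 1, 1), c(0, 1, 0))
  expect_true(is.na(deg))
  expect_true(attr(deg, "degenerate"))
  expect_error(phi_coefficient(c(0, 2), c(0, 1)), "binary")
})

test_that("pairwise class-conditional tables normalize to 100 and match a tally", {
  fv <- random_features(500, c("SPP", "ExAC"), seed = 111)
  labels <- random_labels(500, seed = 112)
  pd <- pairwise_distribution(fv, labels, c("SPP", "ExAC"))
  for (cl in c("neutral", "pathogenic")) {
    expect_equal(sum(pd[[cl]]), 100)
    sel <- labels == cl
    for (i in 0:1) for (j in 0:1) {
      want <- 100 * sum(fv$SPP[sel] == i & fv$ExAC[sel] == j) / sum(sel)
      expect_equal(pd[[cl]][as.character(i), as.character(j)], want)
    }
  }
  # degenerate inputs
  fv0 <- data.frame(SPP = c(0, 0), ExAC = c(0, 0))
  pd0 <- pairwise_distribution(fv0, c("neutral", "neutral"), c("SPP", "ExAC"))
  expect_equal(pd0$neutral["0", "0"], 100)
  expect_true(all(is.na(pd0$pathogenic)))
})

test_that("level reports equal single-feature metrics at depth one and ignore inert levels", {
  fv <- random_features(400, c("SPP", "ExAC", "NDamage", "COMMON"), seed = 121)
  labels <- random_labels(400, seed = 122)
  top <- proposed_topology()
  rep4 <- level_report(fv, labels, top)
  m1 <- metrics(confusion(ifelse(fv$SPP == 1, "pathogenic", "neutral"),
                          labels))
  expect_equal(rep4$accuracy[1], 100 * m1[["accuracy"]])
  expect_equal(rep4$fpr[1], 100 * m1[["rate_P_given_0"]])
  expect_equal(rep4$fnr[1], 100 * m1[["rate_N_given_1"]])
  # constant-1 second level changes nothing
  fv2 <- fv; fv2$ExAC <- 1L
  rep2 <- level_report(fv2, labels, chain_topology(c("SPP", "ExAC")))
  expect_equal(rep2[2, c("accuracy", "fpr", "fnr")],
               rep2[1, c("accuracy", "fpr", "fnr")], ignore_attr = TRUE)
  # monotone refinement
  expect_true(all(diff(rep4$fpr) <= 0))
  expect_true(all(diff(rep4$fnr) >= 0))
})
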