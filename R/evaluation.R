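# Confusion-based evaluation: the four cell counts, the derived rates,
# stratified k-fold cross-validation, Monte Carlo subsampling, phi
# correlations, pairwise feature-distribution tables and per-level reports.

#' Confusion counts
#'
#' Tallies predictions against labels using the domain cell names: a neutral
#' prediction on a neutral variant is a True Neutral; a neutral prediction on
#' a pathogenic variant a False Neutral; a pathogenic prediction on a neutral
#' variant a False Pathogenic; a pathogenic prediction on a pathogenic variant
#' a True Pathogenic.
#'
#' @param predictions,labels Equal-length character vectors over
#'   `{"neutral","pathogenic"}`.
#' @return Named integer vector of class `"confusion_counts"`:
#'   `true_neutral`, `false_neutral`, `false_pathogenic`, `true_pathogenic`.
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0L)
    stop("predictions and labels must have equal, non-zero length")
  .check_labels(labels)
  .check_labels(predictions)
  pn <- predictions == "neutral"
  ln <- labels == "neutral"
  structure(c(true_neutral = sum(pn & ln),
              false_neutral = sum(pn & !ln),
              false_pathogenic = sum(!pn & ln),
              true_pathogenic = sum(!pn & !ln)),
            class = "confusion_counts")
}

#' Build confusion counts directly from the four cells
#'
#' @param true_neutral,false_neutral,false_pathogenic,true_pathogenic
#'   Non-negative integer cell counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(true_neutral, false_neutral, false_pathogenic,
                             true_pathogenic) {
  cells <- c(true_neutral = true_neutral, false_neutral = false_neutral,
             false_pathogenic = false_pathogenic,
             true_pathogenic = true_pathogenic)
  if (any(cells < 0)) stop("confusion counts must be non-negative")
  structure(as.integer(cells), names = names(cells),
            class = "confusion_counts")
}

#' Derived metrics from confusion counts
#'
#' Computes accuracy and the class-conditional rates that structure the
#' benchmark tables: within true-neutral variants the fraction predicted
#' neutral (`rate_N_given_0`) vs. pathogenic (`rate_P_given_0`), and within
#' true-pathogenic variants predicted neutral (`rate_N_given_1`) vs.
#' pathogenic (`rate_P_given_1`); each pair sums to 1 whenever its class is
#' populated. The `paper_formula_*` entries additionally report the verbatim
#' prediction-conditioned formulas (sensitivity = TN/(TN+FN),
#' Type I = FN/(TN+FN), specificity = TP/(TP+FP), Type II = FP/(TP+FP)),
#' which normalize within the predicted class instead. Ratios with a zero
#' denominator are `NA`, never zero.
#'
#' @param cc A [confusion()] result (or named vector with the four cells).
#' @return Named numeric vector of class `"metrics_report"`.
#' @export
metrics <- function(cc) {
  tn <- as.numeric(cc[["true_neutral"]]); fn <- as.numeric(cc[["false_neutral"]])
  fp <- as.numeric(cc[["false_pathogenic"]]); tp <- as.numeric(cc[["true_pathogenic"]])
  total <- tn + fn + fp + tp
  if (total == 0) stop("metrics: empty confusion counts")
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  structure(c(
    accuracy = (tn + tp) / total,
    rate_N_given_0 = rat(tn, tn + fp),
    rate_P_given_0 = rat(fp, tn + fp),
    rate_N_given_1 = rat(fn, fn + tp),
    rate_P_given_1 = rat(tp, fn + tp),
    paper_formula_sensitivity = rat(tn, tn + fn),
    paper_formula_type1 = rat(fn, tn + fn),
    paper_formula_specificity = rat(tp, tp + fp),
    paper_formula_type2 = rat(fp, tp + fp)
  ), class = "metrics_report")
}

# Classifier argument: a fixed chain_topology, or a builder
# function(features, labels) -> chain_topology.
.resolve_classifier <- function(classifier, features, labels) {
  if (inherits(classifier, "chain_topology")) return(classifier)
  if (is.function(classifier)) {
    top <- classifier(features, labels)
    if (!inherits(top, "chain_topology"))
      stop("builder classifier must return a chain_topology")
    return(top)
  }
  stop("classifier must be a chain_topology or a builder function")
}

.summary_stats <- function(metric_mat, sd_type) {
  # metric_mat: replicates x metrics
  m <- colMeans(metric_mat, na.rm = TRUE)
  n_eff <- colSums(!is.na(metric_mat))
  centered <- sweep(metric_mat, 2, m)
  ss <- colSums(centered^2, na.rm = TRUE)
  s <- if (sd_type == "population") sqrt(ss / pmax(n_eff, 1))
       else sqrt(ss / pmax(n_eff - 1, 1))
  list(mean = m, sd = s)
}

.resampling_summary <- function(metric_mat, sd_type, replicates, fraction,
                                seed, kind) {
  st <- .summary_stats(metric_mat, sd_type)
  structure(list(mean = st$mean, sd = st$sd, replicates = replicates,
                 fraction = fraction, seed = seed, kind = kind,
                 sd_type = sd_type, per_replicate = metric_mat),
            class = "resampling_summary")
}

#' @export
print.resampling_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s summary over %d replicates (seed %s)\n", x$kind,
              x$replicates, format(x$seed)))
  tab <- data.frame(mean = round(x$mean, digits), sd = round(x$sd, digits))
  print(tab)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Neutral and pathogenic variants are each split into `k` folds by a seeded
#' permutation (per-class fold sizes differ by at most one); iteration `i`
#' tests on the union of the i-th neutral and i-th pathogenic folds. With a
#' builder classifier the chain is re-built on the remaining folds each
#' iteration; with a fixed topology only evaluation varies.
#'
#' @param features,labels Labeled 0/1 feature data.
#' @param k Number of folds (default 10); each class must have >= `k` members.
#' @param classifier A [chain_topology()] or a builder
#'   `function(features, labels)` returning one.
#' @param seed Integer seed driving the fold assignment.
#' @param sd_type `"population"` (denominator n, default) or `"sample"`.
#' @return A `resampling_summary`: per-metric mean and standard deviation
#'   over the `k` test folds.
#' @export
kfold_cv <- function(features, labels, k = 10L, classifier, seed = 1L,
                     sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  .check_labels(labels)
  classes <- c("neutral", "pathogenic")
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  if (any(vapply(idx_by_class, length, integer(1)) < k))
    stop("each class needs at least k members for ", k, "-fold CV")
  fold_of <- integer(length(labels))
  local_rng(seed, {
    for (ix in idx_by_class) {
      shuffled <- sample(ix)
      fold_of[shuffled] <- rep_len(seq_len(k), length(ix))
    }
  })
  metric_names <- names(metrics(structure(c(true_neutral = 1, false_neutral = 0,
                                            false_pathogenic = 0,
                                            true_pathogenic = 1), class = "confusion_counts")))
  mat <- matrix(NA_real_, nrow = k, ncol = length(metric_names),
                dimnames = list(NULL, metric_names))
  for (i in seq_len(k)) {
    test <- fold_of == i
    top <- .resolve_classifier(classifier, features[!test, , drop = FALSE],
                               labels[!test])
    pred <- classify_batch(features[test, , drop = FALSE], top)$label
    mat[i, ] <- metrics(confusion(pred, labels[test]))
  }
  out <- .resampling_summary(mat, sd_type, replicates = k, fraction = NA_real_,
                             seed = seed, kind = sprintf("%d-fold CV", k))
  attr(out, "folds") <- fold_of
  out
}

#' Monte Carlo subsampling evaluation
#'
#' In each replicate, a uniform random sample of `round(fraction * n)`
#' variants is drawn (without replacement by default, within the replicate),
#' classified with the fixed topology, and the metrics computed; the summary
#' reports the per-metric mean and standard deviation over replicates.
#' Sampling is unstratified.
#'
#' @inheritParams kfold_cv
#' @param classifier A fixed [chain_topology()] (the chain is trained once,
#'   upstream).
#' @param fraction Sample fraction in (0, 1], default 0.3.
#' @param replicates Number of replicates, default 1000.
#' @param replace Bootstrap mode: sample with replacement (default `FALSE`).
#' @return A `resampling_summary`.
#' @export
monte_carlo <- function(features, labels, classifier, fraction = 0.3,
                        replicates = 1000L, seed = 1L, replace = FALSE,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(fraction > 0, fraction <= 1, replicates >= 1)
  .check_labels(labels)
  n <- length(labels)
  m <- round(fraction * n)
  if (m < 1L) stop("monte_carlo: sample size is zero")
  top <- if (inherits(classifier, "chain_topology")) classifier
         else .resolve_classifier(classifier, features, labels)
  pred <- classify_batch(features, top)$label  # fixed chain: classify once
  metric_names <- names(metrics(confusion(c("neutral", "pathogenic"),
                                          c("neutral", "pathogenic"))))
  mat <- matrix(NA_real_, nrow = replicates, ncol = length(metric_names),
                dimnames = list(NULL, metric_names))
  local_rng(seed, {
    for (r in seq_len(replicates)) {
      take <- sample.int(n, m, replace = replace)
      mat[r, ] <- metrics(confusion(pred[take], labels[take]))
    }
  })
  .resampling_summary(mat, sd_type, replicates = replicates,
                      fraction = fraction, seed = seed, kind = "Monte Carlo")
}

#' Phi coefficient of two binary variables
#'
#' Computed from the 2x2 contingency table as
#' `(n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`; algebraically equal to the
#' Pearson correlation of the two 0/1 indicator sequences. Degenerate tables
#' (any zero margin) return `NA` with attribute `degenerate = TRUE`.
#'
#' @param x,y Equal-length 0/1 vectors (logicals accepted).
#' @return Numeric in \[-1, 1\], or `NA` for degenerate margins.
#' @export
phi_coefficient <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y) || length(x) == 0L)
    stop("phi_coefficient: x and y must have equal, non-zero length")
  if (!all(x %in% c(0L, 1L)) || !all(y %in% c(0L, 1L)))
    stop("phi_coefficient: inputs must be binary 0/1")
  n11 <- as.numeric(sum(x == 1L & y == 1L))
  n10 <- as.numeric(sum(x == 1L & y == 0L))
  n01 <- as.numeric(sum(x == 0L & y == 1L))
  n00 <- as.numeric(sum(x == 0L & y == 0L))
  margins <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  if (any(margins == 0))
    return(structure(NA_real_, degenerate = TRUE))
  (n11 * n00 - n10 * n01) / sqrt(prod(margins))
}

#' Pairwise class-conditional feature distribution
#'
#' For each true class separately, the percentage of variants falling in each
#' of the four value combinations of a feature pair (0-0, 0-1, 1-0, 1-1); the
#' four cells of a populated class sum to 100. This is the pairwise
#' complementarity layout: an off-diagonal cell is the share of variants one
#' feature classifies correctly and the other does not.
#'
#' @param features 0/1 feature data.frame containing both pair members.
#' @param labels Class labels.
#' @param pair Character vector of two feature names.
#' @return List with one 2x2 percentage matrix per class (`neutral`,
#'   `pathogenic`), dimnames `0`/`1` (first feature on rows); all-`NA` matrix
#'   for an empty class.
#' @export
pairwise_distribution <- function(features, labels, pair) {
  stopifnot(length(pair) == 2L, all(pair %in% colnames(features)))
  .check_labels(labels)
  one_class <- function(cl) {
    sel <- labels == cl
    m <- matrix(NA_real_, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
    if (!any(sel)) return(m)
    f1 <- factor(features[[pair[1]]][sel], levels = c(0, 1))
    f2 <- factor(features[[pair[2]]][sel], levels = c(0, 1))
    100 * table(f1, f2, dnn = NULL) / sum(sel)
  }
  list(neutral = one_class("neutral"), pathogenic = one_class("pathogenic"))
}

#' Per-level report for a chain topology
#'
#' Classifies with every prefix of the chain (length 1, 2, ...) and reports,
#' per level, the accuracy, the false-pathogenic rate among true neutrals
#' (FPR) and the false-neutral rate among true pathogenics (FNR), all in
#' percent.
#'
#' @inheritParams pairwise_distribution
#' @param topology A [chain_topology()].
#' @return data.frame with columns `level`, `feature`, `accuracy`, `fpr`,
#'   `fnr` (percent).
#' @export
level_report <- function(features, labels, topology) {
  stopifnot(inherits(topology, "chain_topology"))
  .check_labels(labels)
  L <- length(topology$levels)
  out <- data.frame(level = seq_len(L), feature = topology$levels,
                    accuracy = NA_real_, fpr = NA_real_, fnr = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    pred <- classify_batch(features,
                           chain_topology(topology$levels[seq_len(l)]))$label
    m <- metrics(confusion(pred, labels))
    out$accuracy[l] <- 100 * m[["accuracy"]]
    out$fpr[l] <- 100 * m[["rate_P_given_0"]]
    out$fnr[l] <- 100 * m[["rate_N_given_1"]]
  }
  out
}
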