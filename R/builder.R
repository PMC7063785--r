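# Greedy level-wise induction of a chain topology, plus the exhaustive-search
# oracle used to check it.

#' Accuracy of a chain over a labeled feature matrix
#'
#' @param features 0/1 feature data.frame.
#' @param labels Character vector over `{"neutral","pathogenic"}`.
#' @param levels Character vector of chain levels.
#' @return Fraction of variants whose chain classification equals the label.
#' @export
chain_accuracy <- function(features, labels, levels) {
  pred <- classify_batch(features, chain_topology(levels))$label
  mean(pred == labels)
}

.check_labels <- function(labels) {
  if (!all(labels %in% c("neutral", "pathogenic")))
    stop("labels must be 'neutral' or 'pathogenic'")
}

#' Greedy chain induction
#'
#' Builds a chain level by level. The root is the accuracy-maximizing feature
#' among `allowed_roots`; at every later level each remaining candidate is
#' appended provisionally, the whole-dataset accuracy of the provisional
#' chain is computed, and the maximizer is kept if it strictly improves on
#' the current chain. Construction stops on no strict improvement, on
#' reaching `max_depth`, or on exhausting the candidates. Ties are broken by
#' lexicographic feature name. Scoring uses the validation set when given,
#' otherwise the training set. Deterministic.
#'
#' @param features,labels Training data: 0/1 feature data.frame and class
#'   labels (`"neutral"`/`"pathogenic"`), equal lengths > 0.
#' @param candidates Feature names eligible for the chain.
#' @param allowed_roots Subset of `candidates` permitted at level 1.
#' @param max_depth Maximum chain length, default 4.
#' @param val_features,val_labels Optional validation set used for level
#'   scoring instead of the training set.
#' @return List with `topology` (a [chain_topology()]) and `trace` (class
#'   `"build_trace"`): per level the chosen feature, its accuracy, and the
#'   full candidate-accuracy table (whole-dataset accuracy plus accuracy
#'   restricted to the variants surviving the previous levels), and the
#'   `stopping_reason` (`"no_improvement"`, `"max_depth"`, or
#'   `"features_exhausted"`).
#' @export
build_greedy <- function(features, labels,
                         candidates = colnames(features),
                         allowed_roots = candidates,
                         max_depth = 4L,
                         val_features = NULL, val_labels = NULL) {
  stopifnot(nrow(features) == length(labels), nrow(features) > 0,
            length(candidates) > 0, all(allowed_roots %in% candidates))
  .check_labels(labels)
  score_f <- if (is.null(val_features)) features else val_features
  score_l <- if (is.null(val_features)) labels else val_labels
  if (!is.null(val_features)) .check_labels(score_l)

  chain <- character(0)
  trace_levels <- list()
  current_acc <- -Inf  # level 1 is always taken: a chain needs >= 1 level
  stopping <- "features_exhausted"
  repeat {
    if (length(chain) >= max_depth) { stopping <- "max_depth"; break }
    pool <- if (length(chain) == 0L) sort(allowed_roots)
            else sort(setdiff(candidates, chain))
    if (length(pool) == 0L) { stopping <- "features_exhausted"; break }
    alive <- if (length(chain) == 0L) rep(TRUE, length(score_l))
             else classify_batch(score_f, chain_topology(chain))$label == "pathogenic"
    cand_tab <- data.frame(feature = pool,
                           accuracy = NA_real_,
                           survivor_accuracy = NA_real_,
                           stringsAsFactors = FALSE)
    for (i in seq_along(pool)) {
      prov <- c(chain, pool[i])
      pred <- classify_batch(score_f, chain_topology(prov))$label
      cand_tab$accuracy[i] <- mean(pred == score_l)
      cand_tab$survivor_accuracy[i] <-
        if (any(alive)) mean(pred[alive] == score_l[alive]) else NA_real_
    }
    best <- which.max(cand_tab$accuracy)  # pool sorted: first max = lex tie-break
    if (length(chain) > 0L && cand_tab$accuracy[best] <= current_acc) {
      stopping <- "no_improvement"; break
    }
    chain <- c(chain, pool[best])
    current_acc <- cand_tab$accuracy[best]
    trace_levels[[length(chain)]] <- list(feature = pool[best],
                                          accuracy = current_acc,
                                          candidates = cand_tab)
  }
  trace <- structure(list(levels = trace_levels, stopping_reason = stopping),
                     class = "build_trace")
  list(topology = chain_topology(chain), trace = trace)
}

#' @export
print.build_trace <- function(x, ...) {
  for (k in seq_along(x$levels))
    cat(sprintf("level %d: %s (accuracy %.4f)\n", k, x$levels[[k]]$feature,
                x$levels[[k]]$accuracy))
  cat("stopping reason:", x$stopping_reason, "\n")
  invisible(x)
}

# Number of root-restricted ordered selections of lengths 1..depth.
.n_chains <- function(n_cand, n_roots, depth) {
  total <- 0
  for (l in seq_len(min(depth, n_cand))) {
    rest <- 1
    if (l > 1) for (j in seq_len(l - 1)) rest <- rest * (n_cand - j)
    total <- total + n_roots * rest
  }
  total
}

#' Exhaustive best chain (oracle for the greedy builder)
#'
#' Enumerates every root-restricted chain of length 1 up to `depth` and
#' returns the best under a deterministic ranking that mirrors the greedy
#' builder's level-wise maximization: (1) highest final accuracy, compared as
#' exact correct-classification counts; (2) highest prefix accuracy, level by
#' level; (3) shorter chain; (4) lexicographic level names. The prefix
#' tie-break matters because all full-length chains over the same feature set
#' produce identical final labels (the chain is a conjunction), so final
#' accuracy alone cannot rank the permutations.
#'
#' @inheritParams build_greedy
#' @param depth Maximum chain length; the enumeration is refused above 5,000
#'   chains (at most 6 features at full depth).
#' @return The best [chain_topology()].
#' @export
exhaustive_best <- function(features, labels,
                            candidates = colnames(features),
                            allowed_roots = candidates,
                            depth = length(candidates)) {
  stopifnot(nrow(features) == length(labels), nrow(features) > 0,
            length(candidates) > 0, all(allowed_roots %in% candidates))
  .check_labels(labels)
  if (.n_chains(length(candidates), length(allowed_roots), depth) > 5000)
    stop("exhaustive_best: search space too large (> 5000 chains)")

  n <- length(labels)
  best_chain <- NULL
  best_counts <- NULL  # integer correct-counts per prefix level
  # enumerate depth-first in lexicographic order, lengths interleaved so that
  # a prefix is visited before its extensions (=> shorter wins full ties)
  recurse <- function(chain) {
    counts <- integer(length(chain))
    for (l in seq_along(chain)) {
      pred <- classify_batch(features, chain_topology(chain[seq_len(l)]))$label
      counts[l] <- sum(pred == labels)
    }
    if (.chain_beats(counts, best_counts)) {
      best_chain <<- chain
      best_counts <<- counts
    }
    if (length(chain) < depth)
      for (f in sort(setdiff(candidates, chain))) recurse(c(chain, f))
  }
  for (root in sort(allowed_roots)) recurse(root)
  chain_topology(best_chain)
}

# TRUE iff prefix correct-counts `a` rank strictly above incumbent `b`:
# final count, then level-by-level prefix counts, else keep incumbent
# (enumeration order already prefers shorter, then lexicographic).
.chain_beats <- function(a, b) {
  if (is.null(b)) return(TRUE)
  fa <- a[length(a)]; fb <- b[length(b)]
  if (fa != fb) return(fa > fb)
  for (l in seq_len(min(length(a), length(b)))) {
    if (a[l] != b[l]) return(a[l] > b[l])
  }
  FALSE
}
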