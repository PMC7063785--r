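# Linear filter-chain trees: every level either exits a variant as Neutral
# (terminal) or passes it to the next level; surviving all levels means
# Pathogenic.

#' Chain topology
#'
#' An ordered list of feature names defining a linear filter-chain decision
#' tree. The default name is the hyphenated level order, e.g.
#' `"SPP-ExAC-NDamage-COMMON"`.
#'
#' @param levels Character vector of unique feature names, length >= 1.
#' @param name Optional topology name.
#' @return An object of class `"chain_topology"`.
#' @export
chain_topology <- function(levels, name = NULL) {
  levels <- as.character(levels)
  if (length(levels) < 1L) stop("a chain topology needs at least one level")
  if (anyDuplicated(levels)) stop("chain levels must be unique")
  structure(list(name = if (is.null(name)) paste(levels, collapse = "-")
                        else name,
                 levels = levels),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat("Chain topology", x$name, "\n")
  cat("  levels:", paste(seq_along(x$levels), x$levels, sep = ":",
                         collapse = " -> "), "-> pathogenic\n")
  invisible(x)
}

.check_features_cover <- function(features, topology) {
  miss <- setdiff(topology$levels, colnames(features))
  if (length(miss))
    stop("feature matrix lacks topology feature(s): ",
         paste(miss, collapse = ", "))
}

#' Classify a batch of feature vectors with a chain topology
#'
#' Walks the levels in order: the first level whose feature value is 0 exits
#' the variant as neutral at that level (final — later levels never revisit
#' it); a variant with value 1 at every level is pathogenic with exit level
#' `length(levels) + 1`.
#'
#' @param features 0/1 feature data.frame/matrix covering the topology's
#'   features (e.g. from [discretize_variants()]).
#' @param topology A [chain_topology()].
#' @return data.frame with columns `label` (`"neutral"`/`"pathogenic"`) and
#'   `exit_level` (1-based), in input order, plus attribute `survivors`: the
#'   count of variants still pathogenic after each level.
#' @export
classify_batch <- function(features, topology) {
  stopifnot(inherits(topology, "chain_topology"))
  if (is.matrix(features)) features <- as.data.frame(features)
  .check_features_cover(features, topology)
  n <- nrow(features)
  L <- length(topology$levels)
  exit <- rep.int(L + 1L, n)
  alive <- rep.int(TRUE, n)
  survivors <- stats::setNames(integer(L), topology$levels)
  for (k in seq_len(L)) {
    v <- features[[topology$levels[k]]]
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
      stop("feature '", topology$levels[k], "' is not strictly binary")
    drop <- alive & v == 0L
    exit[drop] <- k
    alive <- alive & v == 1L
    survivors[k] <- sum(alive)
  }
  out <- data.frame(
    label = ifelse(exit == L + 1L, "pathogenic", "neutral"),
    exit_level = exit, stringsAsFactors = FALSE)
  attr(out, "survivors") <- survivors
  out
}

#' Classify a single feature vector
#'
#' @param fv Named 0/1 vector (or single-row data.frame) covering the
#'   topology's features.
#' @inheritParams classify_batch
#' @return List with `label` and `exit_level`.
#' @export
classify <- function(fv, topology) {
  if (is.data.frame(fv)) {
    stopifnot(nrow(fv) == 1L)
    row <- fv
  } else {
    row <- as.data.frame(as.list(fv), optional = TRUE)
  }
  res <- classify_batch(row, topology)
  list(label = res$label[1L], exit_level = res$exit_level[1L])
}

#' Enumerate root-restricted chain topologies
#'
#' All permutations of the given features whose first level is in
#' `allowed_roots`, in deterministic lexicographic order of the level
#' sequences. With four features and two allowed roots this yields twelve
#' topologies.
#'
#' @param features Character vector of feature names.
#' @param allowed_roots Subset of `features` permitted at the root.
#' @return List of [chain_topology()] objects.
#' @export
enumerate_topologies <- function(features, allowed_roots = features) {
  features <- as.character(features)
  allowed_roots <- as.character(allowed_roots)
  if (length(allowed_roots) == 0L)
    stop("allowed_roots must name at least one feature")
  if (!all(allowed_roots %in% features))
    stop("allowed_roots must be a subset of features")
  perms <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (v in sort(x)) out <- c(out, lapply(perms(setdiff(x, v)),
                                            function(p) c(v, p)))
    out
  }
  out <- list()
  for (root in sort(allowed_roots))
    out <- c(out, lapply(perms(setdiff(features, root)),
                         function(p) chain_topology(c(root, p))))
  # lexicographic order of the full level sequence
  keys <- vapply(out, function(t) paste(t$levels, collapse = "\r"), character(1))
  out[order(keys, method = "radix")]
}

#' Read / write a topology as JSON
#'
#' Schema: `{"name": str, "levels": [feature, ...]}`.
#'
#' @param path JSON file.
#' @return [read_topology()] returns a [chain_topology()];
#'   [write_topology()] returns `path` invisibly.
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chain_topology(obj$levels, name = obj$name)
}

#' @rdname read_topology
#' @param topology A [chain_topology()].
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "chain_topology"))
  jsonlite::write_json(list(name = topology$name, levels = topology$levels),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
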