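# Binary discretization: every classifying variable becomes a 0/1 flag with
# 1 = pathogenic-leaning, 0 = neutral-leaning.

.AUX_FEATURES <- c("interpro_domain", "transition_transversion",
                   "charged_uncharged", "hydrophobic_hydrophilic",
                   "essential_nonessential", "initial_exon", "ppi")

#' Standard biochemical amino-acid partitions
#'
#' Charged residues and hydrophobic residues (single-letter codes), used by
#' the biochemical-change features. Both sets are configurable arguments of
#' [discretize_auxiliary()] and [feature_registry()].
#'
#' @name aa_sets
#' @export
charged_aa <- function() c("D", "E", "K", "R", "H")

#' @rdname aa_sets
#' @export
hydrophobic_aa <- function() c("A", "V", "L", "I", "M", "F", "W", "C")

#' Feature registry
#'
#' Names the features to discretize and carries their parameters: the allele
#' frequency thresholds of the ExAC and COMMON levels, the damage-call cutoff
#' of NDamage, the damage-predictor roster, and the amino-acid class sets for
#' the biochemical features.
#'
#' @param features Feature names; any of `SPP`, `ExAC`, `NDamage`, `COMMON`
#'   and the auxiliary features (`interpro_domain`, `transition_transversion`,
#'   `charged_uncharged`, `hydrophobic_hydrophilic`, `essential_nonessential`,
#'   `initial_exon`, `ppi`).
#' @param exac_threshold,common_threshold Allele-frequency thresholds in
#'   (0, 1); frequencies at or below the threshold (or missing) are
#'   pathogenic-leaning. Default 1e-4.
#' @param ndamage_cutoff Pathogenic-call count (of the roster, default 9
#'   predictors) at or above which NDamage is pathogenic-leaning. Default 5.
#' @param damage_predictors Damage-predictor roster (<= 9 names).
#' @param charged_set,hydrophobic_set Amino-acid class sets.
#' @return A list of class `"treespp_registry"`.
#' @export
feature_registry <- function(features = c("SPP", "ExAC", "NDamage", "COMMON"),
                             exac_threshold = 1e-4,
                             common_threshold = 1e-4,
                             ndamage_cutoff = 5L,
                             damage_predictors = default_damage_predictors(),
                             charged_set = charged_aa(),
                             hydrophobic_set = hydrophobic_aa()) {
  known <- c("SPP", "ExAC", "NDamage", "COMMON", .AUX_FEATURES)
  if (anyDuplicated(features)) stop("feature names must be unique")
  unknown <- setdiff(features, known)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  stopifnot(exac_threshold > 0, exac_threshold < 1,
            common_threshold > 0, common_threshold < 1,
            ndamage_cutoff >= 1, ndamage_cutoff <= 9,
            length(damage_predictors) <= 9)
  structure(list(features = features,
                 exac_threshold = exac_threshold,
                 common_threshold = common_threshold,
                 ndamage_cutoff = as.integer(ndamage_cutoff),
                 damage_predictors = damage_predictors,
                 charged_set = charged_set,
                 hydrophobic_set = hydrophobic_set),
            class = "treespp_registry")
}

#' SPP consensus feature
#'
#' Neutral (0) only when SIFT, PolyPhen and PROVEAN all call neutral;
#' pathogenic-leaning (1) when at least one calls pathogenic. All three calls
#' must be present — variants with missing consensus calls are excluded
#' upstream by [filter_training_set()].
#'
#' @param variants Annotated variant data.frame.
#' @return Integer 0/1 vector.
#' @export
discretize_spp <- function(variants) {
  calls <- cbind(variants$sift_call, variants$polyphen_call,
                 variants$provean_call)
  if (anyNA(calls))
    stop("discretize_spp: missing SIFT/PolyPhen/PROVEAN call(s); ",
         "apply filter_training_set() first")
  as.integer(rowSums(calls == "pathogenic") > 0L)
}

# Shared frequency rule: neutral-leaning (0) only for a present frequency
# strictly above the threshold; at-or-below, or absent, is pathogenic-leaning.
.discretize_af <- function(af, threshold) {
  as.integer(!(!is.na(af) & af > threshold))
}

#' ExAC allele-frequency feature
#'
#' Neutral (0) iff the ExAC allele frequency is present and exceeds the
#' threshold; pathogenic-leaning (1) for rare (at or below threshold) or
#' uncatalogued/missing frequencies. A frequency exactly at the threshold
#' falls on the pathogenic side.
#'
#' @inheritParams discretize_spp
#' @param threshold Frequency threshold in (0, 1), default 1e-4.
#' @return Integer 0/1 vector.
#' @export
discretize_exac <- function(variants, threshold = 1e-4) {
  stopifnot(threshold > 0, threshold < 1)
  .discretize_af(variants$exac_af, threshold)
}

#' 1000 Genomes COMMON frequency feature
#'
#' Same rule as [discretize_exac()] over the COMMON allele frequency.
#'
#' @inheritParams discretize_exac
#' @return Integer 0/1 vector.
#' @export
discretize_common <- function(variants, threshold = 1e-4) {
  stopifnot(threshold > 0, threshold < 1)
  .discretize_af(variants$common_af, threshold)
}

#' NDamage damage-call count feature
#'
#' Counts the damage predictors calling the variant pathogenic (missing calls
#' count as not-pathogenic) and returns 1 iff the count reaches the cutoff.
#'
#' @inheritParams discretize_spp
#' @param cutoff Integer in 1..9, default 5.
#' @param predictors Damage-predictor roster; calls are read from the
#'   corresponding `damage.<name>` columns (absent columns count as missing).
#' @return Integer 0/1 vector.
#' @export
discretize_ndamage <- function(variants, cutoff = 5L,
                               predictors = default_damage_predictors()) {
  stopifnot(cutoff >= 1, cutoff <= 9, length(predictors) <= 9)
  cols <- paste0("damage.", predictors)
  cols <- cols[cols %in% names(variants)]
  count <- integer(nrow(variants))
  for (col in cols) {
    x <- variants[[col]]
    count <- count + as.integer(!is.na(x) & x == "pathogenic")
  }
  as.integer(count >= cutoff)
}

#' Auxiliary binary features
#'
#' The screened features beyond the four tree variables.
#' `transition_transversion` is 1 for transversions (purine <-> pyrimidine)
#' and 0 for transitions; `charged_uncharged` (`hydrophobic_hydrophilic`) is 1
#' iff the amino-acid change crosses the charged (hydrophobic) set, i.e.
#' exactly one of the two residues is in the set; `interpro_domain`,
#' `essential_nonessential`, `initial_exon` and `ppi` pass through the
#' corresponding `aux.*` annotation flags. Missing required fields yield 0
#' (neutral-leaning) and are reported as imputed in the provenance of
#' [discretize_variants()].
#'
#' @inheritParams discretize_spp
#' @param feature One auxiliary feature name.
#' @param charged_set,hydrophobic_set Amino-acid class sets.
#' @return Integer 0/1 vector.
#' @export
discretize_auxiliary <- function(variants, feature,
                                 charged_set = charged_aa(),
                                 hydrophobic_set = hydrophobic_aa()) {
  if (!feature %in% .AUX_FEATURES)
    stop("unknown auxiliary feature: ", feature)
  n <- nrow(variants)
  if (feature == "transition_transversion") {
    purine <- c("A", "G")
    ok <- !is.na(variants$ref) & !is.na(variants$alt) &
      variants$ref %in% c("A", "C", "G", "T") &
      variants$alt %in% c("A", "C", "G", "T")
    transition <- ok & ((variants$ref %in% purine) == (variants$alt %in% purine))
    return(as.integer(ok & !transition))
  }
  if (feature %in% c("charged_uncharged", "hydrophobic_hydrophilic")) {
    set <- if (feature == "charged_uncharged") charged_set else hydrophobic_set
    ok <- !is.na(variants$ref_aa) & !is.na(variants$alt_aa)
    crosses <- ok & xor(variants$ref_aa %in% set, variants$alt_aa %in% set)
    return(as.integer(crosses))
  }
  col <- paste0("aux.", feature)
  if (!col %in% names(variants)) return(integer(n))
  flag <- variants[[col]]
  as.integer(!is.na(flag) & flag == 1L)
}

# Which rows of a feature had their raw annotation missing (hence imputed).
.feature_imputed <- function(variants, feature) {
  n <- nrow(variants)
  switch(feature,
    SPP = rep(FALSE, n),
    ExAC = is.na(variants$exac_af),
    COMMON = is.na(variants$common_af),
    NDamage = rep(FALSE, n),  # missing calls lower the count by design
    transition_transversion = is.na(variants$ref) | is.na(variants$alt) |
      !(variants$ref %in% c("A", "C", "G", "T")) |
      !(variants$alt %in% c("A", "C", "G", "T")),
    charged_uncharged = is.na(variants$ref_aa) | is.na(variants$alt_aa),
    hydrophobic_hydrophilic = is.na(variants$ref_aa) | is.na(variants$alt_aa),
    {
      col <- paste0("aux.", feature)
      if (col %in% names(variants)) is.na(variants[[col]]) else rep(TRUE, n)
    })
}

#' Discretize variants into a binary feature matrix
#'
#' Applies every registered discretizer and returns one 0/1 column per
#' feature (1 = pathogenic-leaning). The `provenance` attribute is a parallel
#' character matrix marking each value `"observed"` or `"imputed_missing"`
#' (an absent annotation filled by the feature's missing-value rule).
#'
#' @param variants Annotated variant data.frame.
#' @param registry A [feature_registry()].
#' @return Integer data.frame, rows as `variants`, one column per registry
#'   feature, with attribute `provenance`.
#' @export
discretize_variants <- function(variants, registry = feature_registry()) {
  stopifnot(inherits(registry, "treespp_registry"))
  n <- nrow(variants)
  values <- list()
  prov <- matrix("observed", nrow = n, ncol = length(registry$features),
                 dimnames = list(NULL, registry$features))
  for (f in registry$features) {
    values[[f]] <- switch(f,
      SPP = discretize_spp(variants),
      ExAC = discretize_exac(variants, registry$exac_threshold),
      NDamage = discretize_ndamage(variants, registry$ndamage_cutoff,
                                   registry$damage_predictors),
      COMMON = discretize_common(variants, registry$common_threshold),
      discretize_auxiliary(variants, f, registry$charged_set,
                           registry$hydrophobic_set))
    prov[.feature_imputed(variants, f), f] <- "imputed_missing"
  }
  out <- as.data.frame(values, optional = TRUE)
  if (n == 0L) out <- as.data.frame(stats::setNames(
    rep(list(integer(0)), length(registry$features)), registry$features))
  attr(out, "provenance") <- prov
  out
}
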