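#' @keywords internal
"_PACKAGE"

# Column layout of an annotated-variant table. Predictor calls are stored
# normalized ("neutral"/"pathogenic"/NA); damage-predictor calls live in
# "damage.<name>" columns, auxiliary binary flags in "aux.<name>" columns.

.CALL_LEVELS <- c("neutral", "pathogenic")
.LABEL_LEVELS <- c("neutral", "pathogenic", "unlabeled")
.CONSEQUENCE_LEVELS <- c("non_synonymous", "synonymous", "other")

#' Default damage-predictor roster
#'
#' Names of the nine damage predictors whose calls feed the NDamage count.
#' The roster is configurable everywhere it is consumed; these defaults follow
#' common dbNSFP predictor columns.
#'
#' @return Character vector of nine predictor names.
#' @export
default_damage_predictors <- function() {
  c("MutationTaster", "MutationAssessor", "FATHMM", "LRT", "MetaLR",
    "M_CAP", "PrimateAI", "DANN", "VEST4")
}

#' Field map: annotation roles to table columns / VCF INFO keys
#'
#' Connects the roles the classifier needs (the three consensus predictors,
#' allele frequencies, damage predictors, clinical significance, ...) to the
#' column names of a TSV or the INFO keys of a VCF. Per-predictor call
#' encodings are part of the map because annotation pipelines differ; the
#' defaults follow dbNSFP conventions (SIFT "D"/"T", PolyPhen "D"/"P"/"B" with
#' "possibly damaging" counted as pathogenic, PROVEAN "D"/"N").
#'
#' @param dialect `"tsv"` or `"vcf"`; only the default chrom/pos/ref/alt
#'   bindings differ (fixed VCF columns vs. named TSV columns).
#' @param damage_predictors Character vector (up to nine) of damage-predictor
#'   names; each predictor `P` is read from column/key `damage.P`.
#' @param aux_features Character vector of auxiliary flag names; each read
#'   from column/key `aux.<name>`.
#' @return A list with one entry per role, class `"treespp_field_map"`.
#' @export
default_field_map <- function(dialect = c("tsv", "vcf"),
                              damage_predictors = default_damage_predictors(),
                              aux_features = c("interpro_domain", "essential_nonessential",
                                               "initial_exon", "ppi")) {
  dialect <- match.arg(dialect)
  fm <- list(
    chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
    consequence = "consequence",
    sift = "SIFT", polyphen = "Polyphen", provean = "PROVEAN",
    exac_af = "ExAC_AF", common_af = "COMMON_AF",
    clnsig = "CLNSIG",
    ref_aa = "ref_aa", alt_aa = "alt_aa",
    damage = stats::setNames(paste0("damage.", damage_predictors), damage_predictors),
    aux = if (length(aux_features))
      stats::setNames(paste0("aux.", aux_features), aux_features) else character(0),
    call_codes = list(
      sift     = list(pathogenic = "D", neutral = "T"),
      polyphen = list(pathogenic = c("D", "P"), neutral = "B"),
      provean  = list(pathogenic = "D", neutral = "N"),
      damage   = list(pathogenic = "D", neutral = c("T", "N", "B"))
    )
  )
  fm$dialect <- dialect
  class(fm) <- "treespp_field_map"
  fm
}

#' ClinVar clinical-significance label policy
#'
#' Maps raw CLNSIG strings to neutral / pathogenic / unlabeled. Numeric codes
#' are authoritative: 2 and 3 are neutral, 4 and 5 pathogenic. Textual
#' synonyms (modern ClinVar VCFs) are translated to codes first. Multi-valued
#' fields (separated by `,`, `|` or `/`) must map homogeneously to one class;
#' any mixture, or any token outside the policy, yields `unlabeled`.
#'
#' @param neutral_codes,pathogenic_codes Character code sets; must be disjoint.
#' @param text_synonyms Named character vector, raw term -> code. Matching is
#'   case-insensitive with spaces treated as underscores.
#' @return A list of class `"treespp_label_policy"`.
#' @export
default_label_policy <- function(neutral_codes = c("2", "3"),
                                 pathogenic_codes = c("4", "5"),
                                 text_synonyms = c(
                                   "benign" = "2",
                                   "likely_benign" = "3",
                                   "likely_pathogenic" = "4",
                                   "pathogenic" = "5"
                                 )) {
  if (length(intersect(neutral_codes, pathogenic_codes)) > 0L)
    stop("label policy: neutral and pathogenic code sets must be disjoint")
  structure(list(neutral_codes = as.character(neutral_codes),
                 pathogenic_codes = as.character(pathogenic_codes),
                 text_synonyms = text_synonyms),
            class = "treespp_label_policy")
}

#' Harmonize ClinVar significance strings
#'
#' Total function: every input gets one of `"neutral"`, `"pathogenic"`,
#' `"unlabeled"`. `NA`, empty strings, unknown tokens, and fields mixing codes
#' from both sides all map to `unlabeled`.
#'
#' @param clnsig_raw Character vector of raw CLNSIG values.
#' @param policy A label policy, see [default_label_policy()].
#' @return Character vector over `{"neutral","pathogenic","unlabeled"}`.
#' @export
#' @examples
#' parse_label(c("2", "5", "0", "2|5", "Benign/Likely_benign"))
parse_label <- function(clnsig_raw, policy = default_label_policy()) {
  stopifnot(inherits(policy, "treespp_label_policy"))
  syn <- policy$text_synonyms
  names(syn) <- tolower(gsub(" ", "_", names(syn)))
  one <- function(x) {
    if (is.na(x) || !nzchar(x)) return("unlabeled")
    tokens <- strsplit(x, "[,|/]")[[1]]
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) return("unlabeled")
    key <- tolower(gsub(" ", "_", tokens))
    codes <- ifelse(key %in% names(syn), unname(syn[key]), tokens)
    cls <- ifelse(codes %in% policy$neutral_codes, "neutral",
           ifelse(codes %in% policy$pathogenic_codes, "pathogenic", "unlabeled"))
    u <- unique(cls)
    if (length(u) == 1L && u != "unlabeled") u else "unlabeled"
  }
  vapply(as.character(clnsig_raw), one, character(1), USE.NAMES = FALSE)
}

# Normalize raw predictor call strings to "neutral"/"pathogenic"/NA.
# Already-normalized values pass through; anything else is missing.
.normalize_call <- function(x, codes) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c(codes$pathogenic, "pathogenic")] <- "pathogenic"
  out[x %in% c(codes$neutral, "neutral")] <- "neutral"
  out
}

.damage_cols <- function(variants) {
  grep("^damage\\.", names(variants), value = TRUE)
}

.aux_cols <- function(variants) {
  grep("^aux\\.", names(variants), value = TRUE)
}

# Assemble the canonical annotated-variant data.frame from a raw named list
# of per-role character/numeric vectors (already mapped from file columns).
.build_variants <- function(raw, field_map, label_policy, n) {
  num <- function(x) suppressWarnings(as.numeric(x))
  get <- function(role, default = rep(NA_character_, n)) {
    if (!is.null(raw[[role]])) raw[[role]] else default
  }
  out <- data.frame(
    chrom = as.character(get("chrom")),
    pos = suppressWarnings(as.integer(get("pos"))),
    ref = as.character(get("ref")),
    alt = as.character(get("alt")),
    consequence = {
      cq <- as.character(get("consequence"))
      ifelse(cq %in% .CONSEQUENCE_LEVELS, cq,
             ifelse(is.na(cq), NA_character_, "other"))
    },
    sift_call = .normalize_call(get("sift"), field_map$call_codes$sift),
    polyphen_call = .normalize_call(get("polyphen"), field_map$call_codes$polyphen),
    provean_call = .normalize_call(get("provean"), field_map$call_codes$provean),
    exac_af = num(get("exac_af")),
    common_af = num(get("common_af")),
    clnsig_raw = as.character(get("clnsig")),
    ref_aa = as.character(get("ref_aa")),
    alt_aa = as.character(get("alt_aa")),
    stringsAsFactors = FALSE
  )
  for (p in names(field_map$damage))
    out[[paste0("damage.", p)]] <-
      .normalize_call(get(paste0("damage_", p)), field_map$call_codes$damage)
  for (a in names(field_map$aux)) {
    v <- suppressWarnings(as.integer(get(paste0("aux_", a))))
    v[!v %in% c(0L, 1L)] <- NA_integer_
    out[[paste0("aux.", a)]] <- v
  }
  bad_af <- function(x) !is.na(x) & (x < 0 | x > 1)
  if (any(bad_af(out$exac_af)) || any(bad_af(out$common_af)))
    stop("allele frequencies outside [0, 1]")
  out$label <- parse_label(out$clnsig_raw, label_policy)
  out
}

#' Read an annotated variant table
#'
#' Reads a flat TSV (header row, one named column per annotation) or a VCF 4.x
#' with per-variant INFO annotations, and returns the canonical annotated
#' variant data.frame consumed by the rest of the package. Unmapped or
#' unparseable annotation values become missing (`NA`), never fabricated.
#' Multi-allelic VCF records are split into one row per alternate allele;
#' comma-separated INFO values with one entry per allele are index-matched,
#' scalar values are recycled.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param field_map Role-to-column (or role-to-INFO-key) map; see
#'   [default_field_map()].
#' @param label_policy Passed to [parse_label()].
#' @return A data.frame with one row per variant (per alt allele for VCF) in
#'   input order: coordinates, normalized predictor calls, `damage.*` call
#'   columns, `exac_af`/`common_af`, `aux.*` flags, amino acids, `clnsig_raw`
#'   and the harmonized `label`.
#' @export
read_annotated_table <- function(path, dialect = c("tsv", "vcf"),
                                 field_map = default_field_map(dialect),
                                 label_policy = default_label_policy()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  required <- c("sift", "polyphen", "provean", "clnsig")
  if (!all(required %in% names(field_map)))
    stop("field_map lacks required roles: ",
         paste(setdiff(required, names(field_map)), collapse = ", "))
  if (dialect == "tsv") .read_tsv(path, field_map, label_policy)
  else .read_vcf(path, field_map, label_policy)
}

.read_tsv <- function(path, field_map, label_policy) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("", ".", "NA")),
    error = function(e) stop("malformed TSV header/body in ", path, ": ",
                             conditionMessage(e)))
  required_cols <- c(sift = field_map$sift, polyphen = field_map$polyphen,
                     provean = field_map$provean, clnsig = field_map$clnsig)
  missing_roles <- names(required_cols)[!required_cols %in% names(tab)]
  if (length(missing_roles))
    stop("mapped columns absent from TSV for roles: ",
         paste(missing_roles, collapse = ", "))
  raw <- list()
  scalar_roles <- c("chrom", "pos", "ref", "alt", "consequence", "sift",
                    "polyphen", "provean", "exac_af", "common_af", "clnsig",
                    "ref_aa", "alt_aa")
  for (role in scalar_roles) {
    col <- field_map[[role]]
    if (!is.null(col) && col %in% names(tab)) raw[[role]] <- tab[[col]]
  }
  for (p in names(field_map$damage)) {
    col <- field_map$damage[[p]]
    if (col %in% names(tab)) raw[[paste0("damage_", p)]] <- tab[[col]]
  }
  for (a in names(field_map$aux)) {
    col <- field_map$aux[[a]]
    if (col %in% names(tab)) raw[[paste0("aux_", a)]] <- tab[[col]]
  }
  .build_variants(raw, field_map, label_policy, n = nrow(tab))
}

.read_vcf <- function(path, field_map, label_policy) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF in ", path, ": ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  n_alt <- vapply(alt_list, length, integer(1))
  n_alt[n_alt == 0L] <- 1L
  alt_list[lengths(alt_list) == 0L] <- list(NA_character_)
  rec_idx <- rep(seq_len(n_rec), n_alt)         # expanded record index
  allele_idx <- unlist(lapply(n_alt, seq_len))  # 1-based alt index per row

  info_field <- function(key) {
    if (is.na(key) || !nzchar(key)) return(rep(NA_character_, length(rec_idx)))
    vals <- if (n_rec > 0) vcfR::extract.info(vcf, element = key)
            else character(0)
    if (is.null(vals)) vals <- rep(NA_character_, n_rec)
    per_rec <- strsplit(ifelse(is.na(vals), NA_character_, as.character(vals)),
                        ",", fixed = TRUE)
    out <- character(length(rec_idx))
    for (i in seq_along(rec_idx)) {
      v <- per_rec[[rec_idx[i]]]
      out[i] <- if (is.null(v) || all(is.na(v))) NA_character_
                else if (length(v) == n_alt[rec_idx[i]]) v[allele_idx[i]]
                else v[1L]
    }
    out
  }

  raw <- list(
    chrom = fix[rec_idx, "CHROM"],
    pos = fix[rec_idx, "POS"],
    ref = fix[rec_idx, "REF"],
    alt = unlist(alt_list)
  )
  for (role in c("consequence", "sift", "polyphen", "provean", "exac_af",
                 "common_af", "clnsig", "ref_aa", "alt_aa"))
    raw[[role]] <- info_field(field_map[[role]])
  for (p in names(field_map$damage))
    raw[[paste0("damage_", p)]] <- info_field(field_map$damage[[p]])
  for (a in names(field_map$aux))
    raw[[paste0("aux_", a)]] <- info_field(field_map$aux[[a]])
  .build_variants(raw, field_map, label_policy, n = length(rec_idx))
}

#' Apply the training-set filters
#'
#' Retains exactly the variants that are (1) non-synonymous, (2) carry
#' non-missing calls from all of SIFT, PolyPhen and PROVEAN, and (3) have a
#' harmonized label of neutral or pathogenic. Criteria are applied
#' sequentially, so each removed variant is counted once, under the first
#' criterion it fails.
#'
#' @param variants Annotated variant data.frame.
#' @return The retained subset, in input order, with attribute `removed`: a
#'   named integer vector (`not_non_synonymous`, `missing_spp_call`,
#'   `unlabeled`). Idempotent.
#' @export
filter_training_set <- function(variants) {
  keep1 <- !is.na(variants$consequence) & variants$consequence == "non_synonymous"
  keep2 <- keep1 & !is.na(variants$sift_call) & !is.na(variants$polyphen_call) &
    !is.na(variants$provean_call)
  keep3 <- keep2 & variants$label %in% c("neutral", "pathogenic")
  removed <- c(not_non_synonymous = sum(!keep1),
               missing_spp_call = sum(keep1 & !keep2),
               unlabeled = sum(keep2 & !keep3))
  out <- variants[keep3, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Write annotated variants as TSV
#'
#' Writes the canonical column layout (readable back with
#' [read_annotated_table()] and the default field map). Missing values are
#' written as empty fields.
#'
#' @param variants Annotated variant data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotated_tsv <- function(variants, path) {
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    consequence = variants$consequence,
                    SIFT = variants$sift_call,
                    Polyphen = variants$polyphen_call,
                    PROVEAN = variants$provean_call,
                    ExAC_AF = variants$exac_af,
                    COMMON_AF = variants$common_af,
                    CLNSIG = variants$clnsig_raw,
                    ref_aa = variants$ref_aa, alt_aa = variants$alt_aa,
                    label = variants$label,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(.damage_cols(variants), .aux_cols(variants)))
    out[[col]] <- variants[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
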