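# Fixtures built in code: tiny annotated-variant frames and random feature
# matrices used across the test files.

# One canonical variant row with overridable annotations. `damage` is the
# number of pathogenic damage calls (rest neutral), or a length-9 character
# vector of raw calls.
variant_row <- function(sift = "pathogenic", polyphen = "neutral",
                        provean = "neutral", exac_af = NA_real_,
                        common_af = NA_real_, damage = 0L,
                        consequence = "non_synonymous", clnsig = "5",
                        chrom = "1", pos = 100L, ref = "A", alt = "G",
                        ref_aa = "A", alt_aa = "V",
                        interpro = NA_integer_) {
  row <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    consequence = consequence,
                    sift_call = sift, polyphen_call = polyphen,
                    provean_call = provean,
                    exac_af = exac_af, common_af = common_af,
                    clnsig_raw = clnsig, ref_aa = ref_aa, alt_aa = alt_aa,
                    stringsAsFactors = FALSE)
  preds <- default_damage_predictors()
  calls <- if (is.character(damage)) damage
           else c(rep("pathogenic", damage), rep("neutral", 9L - damage))
  for (j in seq_along(preds)) row[[paste0("damage.", preds[j])]] <- calls[j]
  row[["aux.interpro_domain"]] <- interpro
  row$label <- parse_label(row$clnsig_raw)
  row
}

variants_from_rows <- function(...) do.call(rbind, list(...))

# Random 0/1 feature data.frame with the given column names.
random_features <- function(n, names, p = rep(0.5, length(names)), seed = 1) {
  local_rng(seed, {
    out <- lapply(seq_along(names),
                  function(j) stats::rbinom(n, 1L, p[j]))
    names(out) <- names
    as.data.frame(out, optional = TRUE)
  })
}

random_labels <- function(n, p_path = 0.5, seed = 1) {
  local_rng(seed, ifelse(stats::runif(n) < p_path, "pathogenic", "neutral"))
}

proposed_topology <- function() {
  chain_topology(c("SPP", "ExAC", "NDamage", "COMMON"))
}
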