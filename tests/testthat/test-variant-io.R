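test_that("clinical-significance labels harmonize by code, synonym and conflict rule", {
  expect_equal(parse_label(c("2", "3", "4", "5")),
               c("neutral", "neutral", "pathogenic", "pathogenic"))
  expect_equal(parse_label(c("0", "1", "6", "", NA)),
               rep("unlabeled", 5))
  expect_equal(parse_label(c("Benign", "Likely_benign", "Likely pathogenic",
                             "Pathogenic", "Benign/Likely_benign")),
               c("neutral", "neutral", "pathogenic", "pathogenic", "neutral"))
  expect_equal(parse_label(c("2|5", "5,3", "2|0")), rep("unlabeled", 3))
  expect_equal(parse_label(c("2|2", "4,5")), c("neutral", "pathogenic"))
})

test_that("every two-code combination follows the homogeneity rule", {
  policy <- default_label_policy()
  codes <- as.character(0:7)
  side <- function(code) {
    if (code %in% policy$neutral_codes) "neutral"
    else if (code %in% policy$pathogenic_codes) "pathogenic"
    else "unlabeled"
  }
  for (a in codes) for (b in codes) {
    s <- c(side(a), side(b))
    want <- if (length(unique(s)) == 1L && s[1] != "unlabeled") s[1]
            else "unlabeled"
    expect_identical(parse_label(paste(a, b, sep = "|")), want,
                     label = paste0("combo ", a, "|", b))
  }
})

test_that("disjointness of label code sets is enforced", {
  expect_error(default_label_policy(neutral_codes = c("2", "4")),
               "disjoint")
})

test_that("TSV rows map onto annotated variants, with missing fields as NA", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tconsequence\tSIFT\tPolyphen\tPROVEAN\tExAC_AF\tCOMMON_AF\tCLNSIG",
    "1\t100\tA\tG\tnon_synonymous\tD\tP\tD\t0.00002\t\t5",
    "2\t200\tC\tT\tsynonymous\tT\tB\tN\t\t0.3\t2"), tf)
  v <- read_annotated_table(tf, "tsv")
  expect_equal(nrow(v), 2L)
  expect_equal(v$sift_call, c("pathogenic", "neutral"))
  expect_equal(v$polyphen_call, c("pathogenic", "neutral"))
  expect_equal(v$provean_call, c("pathogenic", "neutral"))
  expect_equal(v$exac_af, c(2e-5, NA))
  expect_equal(v$common_af, c(NA, 0.3))
  expect_equal(v$label, c("pathogenic", "neutral"))
  expect_true(all(is.na(v$`damage.MutationTaster`)))
})

test_that("an empty TSV with a valid header yields an empty variant set", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt\tSIFT\tPolyphen\tPROVEAN\tCLNSIG", tf)
  v <- read_annotated_table(tf, "tsv")
  expect_equal(nrow(v), 0L)
})

test_that("a mapped column absent from the table names the missing role", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tSIFT\tPolyphen\tCLNSIG", "1\tD\tB\t5"), tf)
  expect_error(read_annotated_table(tf, "tsv"), "provean")
  expect_error(read_annotated_table("no/such/file.tsv", "tsv"), "exist")
})

test_that("VCF records parse, split multi-allelic sites, and default missing INFO", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SIFT,Number=A,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tG,T\t.\tPASS\tSIFT=D,T;Polyphen=B;PROVEAN=D;CLNSIG=5",
    "2\t200\t.\tC\tT\t.\tPASS\tSIFT=D;Polyphen=D;PROVEAN=D;CLNSIG=2;consequence=non_synonymous"),
    tf)
  v <- read_annotated_table(tf, "vcf")
  expect_equal(nrow(v), 3L)                      # 2 alts + 1
  expect_equal(v$alt, c("G", "T", "T"))
  expect_equal(v$sift_call, c("pathogenic", "neutral", "pathogenic"))
  expect_equal(v$polyphen_call, c("neutral", "neutral", "pathogenic"))
  expect_true(all(is.na(v$exac_af)))             # key absent -> missing
  expect_equal(v$label, c("pathogenic", "pathogenic", "neutral"))
  expect_equal(v$consequence, c(NA, NA, "non_synonymous"))
})

test_that("training-set filters apply sequentially with per-criterion counts", {
  v <- variants_from_rows(
    variant_row(),                                        # retained
    variant_row(consequence = "synonymous"),              # criterion 1
    variant_row(provean = NA_character_),                 # criterion 2
    variant_row(clnsig = "0"),                            # criterion 3
    variant_row(sift = "neutral", polyphen = "neutral",
                provean = "neutral", clnsig = "2"))       # retained
  tr <- filter_training_set(v)
  expect_equal(nrow(tr), 2L)
  expect_equal(attr(tr, "removed"),
               c(not_non_synonymous = 1L, missing_spp_call = 1L,
                 unlabeled = 1L))
  expect_equal(sum(attr(tr, "removed")) + nrow(tr), nrow(v))
  expect_equal(tr$pos, v$pos[c(1, 5)])                    # order preserved
  # idempotence
  tr2 <- filter_training_set(tr)
  expect_equal(nrow(tr2), nrow(tr))
  expect_equal(unname(attr(tr2, "removed")), c(0L, 0L, 0L))
})

test_that("TSV and VCF round trips preserve downstream feature vectors", {
  cfg <- preset_generator_config("clinvar_like", n_variants = 300, seed = 5)
  v <- filter_training_set(generate_variants(cfg))
  fv <- discretize_variants(v)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_tsv(v, tsv)
  v_tsv <- read_annotated_table(tsv, "tsv")
  expect_equal(discretize_variants(v_tsv), fv, ignore_attr = TRUE)
  expect_equal(v_tsv$label, v$label)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(v, vcf)
  v_vcf <- read_annotated_table(vcf, "vcf")
  expect_equal(discretize_variants(v_vcf), fv, ignore_attr = TRUE)
  expect_equal(v_vcf$label, v$label)
})
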