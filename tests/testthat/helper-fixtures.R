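# Shared fixtures and independent oracles for the test suite.

# --- pedigrees ---------------------------------------------------------------

family_template <- function() {
  read_ped(system.file("extdata", "family5_synthetic.ped",
                       package = "varfunnel"))
}

# Founder couple + children with the given roles (children genotyped).
small_pedigree <- function(child_roles,
                           founder_roles = c("unknown", "unknown"),
                           founder_sampled = c(TRUE, TRUE)) {
  n <- length(child_roles)
  kids <- paste0("C", seq_len(n))
  pedigree(
    id = c("F1", "F2", kids),
    father = c(NA, NA, rep("F1", n)),
    mother = c(NA, NA, rep("F2", n)),
    sex = c("male", "female", rep("unknown", n)),
    role = c(founder_roles, child_roles),
    sample_available = c(founder_sampled, rep(TRUE, n)),
    name = "TINY"
  )
}

# Published segregation pattern of the candidate variant in the family
# fixture: het in the four sequenced cases and one benign-nodule member,
# wild-type in two benign-nodule members and the genotyped control.
pot1_genotypes <- function() {
  c(`I-1` = 0, `II-2` = 1, `II-3` = 1, `II-4` = 0, `II-5` = 1,
    `II-6` = 1, `II-7` = 0, `II-8` = 1)
}

# --- independent segregation oracle ------------------------------------------

# Literal per-member constraint enumeration, written independently of
# classify_segregation: walk the members one by one and apply the dominant
# rule directly.
oracle_segregation <- function(dosages, ped) {
  verdicts <- logical(0)
  informative <- FALSE
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    d <- if (id %in% names(dosages)) dosages[[id]] else NA
    if (ped$role[i] == "case") {
      if (!is.na(d)) {
        informative <- TRUE
        verdicts <- c(verdicts, d >= 1)
      }
    } else if (ped$role[i] == "control") {
      if (!is.na(d)) verdicts <- c(verdicts, d == 0)
    }
  }
  if (!informative) return(NA) # uninformative
  all(verdicts)
}

# --- independent ACMG oracle -------------------------------------------------

# Direct transcription of the 2015 combining standard as explicit logical
# tests over strength counts (independent of the packaged JSON table).
oracle_acmg <- function(codes) {
  codes <- unique(codes)
  pvs <- sum(grepl("^PVS", codes))
  ps <- sum(grepl("^PS", codes))
  pm <- sum(grepl("^PM", codes))
  pp <- sum(grepl("^PP", codes))
  ba <- sum(grepl("^BA", codes))
  bs <- sum(grepl("^BS", codes))
  bp <- sum(grepl("^BP", codes))
  path <- (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) ||
                          pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  lp <- (pvs >= 1 && pm >= 1) || (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) || pm >= 3 || (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  ben <- ba >= 1 || bs >= 2
  lb <- (bs >= 1 && bp >= 1) || bp >= 2
  if ((path || lp) && (ben || lb)) return("VUS")
  if (path) return("Pathogenic")
  if (lp) return("Likely pathogenic")
  if (ben) return("Benign")
  if (lb) return("Likely benign")
  "VUS"
}

# --- variant rows ------------------------------------------------------------

# A single-variant table over `ped` that passes every default gate; override
# any field with ...
make_variant <- function(ped, ..., id = "v1") {
  members <- ped$id[ped$sample_available]
  row <- list(id = id, chrom = "1", pos = 1000L, ref = "A", alt = "G",
              qual = 100, filter_pass = TRUE, gene = "GENE1",
              consequence = "missense",
              maf_1kg = NA_real_, maf_exac_nontcga = NA_real_,
              cadd_phred = 25, gerp = 4, phastcons = 0.9, phylop = 5)
  for (p in predictor_tools()) row[[p]] <- "D"
  for (s in members) {
    role <- ped$role[ped$id == s]
    row[[paste0("gt_", s)]] <- if (role == "case") 1L else 0L
    row[[paste0("dp_", s)]] <- 30L
  }
  override <- list(...)
  for (nm in names(override)) row[[nm]] <- override[[nm]]
  variant_table(as.data.frame(row, check.names = FALSE,
                              stringsAsFactors = FALSE), ped)
}

# Bind single-variant tables into one table.
bind_variants <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("variant_table", "data.frame")
  out
}

# --- toy VCF -----------------------------------------------------------------

# Hand-written multi-sample VCF exercising multi-allelic splitting, missing
# annotations, half-calls and record-level DP fallback.
toy_vcf_lines <- function(samples) {
  gt9 <- function(...) paste(..., sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=MAF_1KG,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=MAF_EXAC_NONTCGA,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=CADD_PHRED,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=GERP,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=PHASTCONS,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=PHYLOP,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"record depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FILTER=<ID=FAIL,Description=\"f\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  n <- length(samples)
  gts <- function(v) paste(v, collapse = "\t")
  rec1 <- gt9("1", "100", "rs1", "A", "G", "50", "PASS",
              "GENE=G1;CSQ_CLASS=missense;CADD_PHRED=12.5;SIFT=D",
              "GT:DP", gts(c("0/1:20", rep("0/0:22", n - 1))))
  rec2 <- gt9("2", "200", "rs2", "C", "A,T", "80", "PASS",
              "GENE=G2;CSQ_CLASS=synonymous",
              "GT:DP", gts(c("1/2:15", "./1:10", rep("0/0:30", n - 2))))
  rec3 <- gt9("3", "300", "rs3", "T", "C", "30", "FAIL",
              "GENE=G3;CSQ_CLASS=missense;MAF_1KG=0.25;DP=18",
              "GT", gts(c("1/1", rep("0/0", n - 1))))
  c(header, rec1, rec2, rec3)
}
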