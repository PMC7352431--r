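# Annotated multi-sample variant tables.
#
# Internal representation: a plain data.frame (class "variant_table") with
# one row per bi-allelic alternate allele and columns
#   id, chrom, pos, ref, alt, qual, filter_pass, gene, consequence,
#   maf_1kg, maf_exac_nontcga, cadd_phred, gerp, phastcons, phylop,
#   <10 predictor columns, values "D"/"T"/NA>,
#   gt_<member> (dosage 0/1/2/NA), dp_<member> (read depth).
# Two on-disk dialects are supported: a flat TSV mirroring these columns
# ("." = missing) and VCF 4.x with the equivalent INFO/FORMAT keys.

vt_fixed_cols <- function() {
  c("id", "chrom", "pos", "ref", "alt", "qual", "filter_pass",
    "gene", "consequence",
    "maf_1kg", "maf_exac_nontcga", "cadd_phred", "gerp", "phastcons",
    "phylop", predictor_tools())
}

vt_num_cols <- function() {
  c("qual", "maf_1kg", "maf_exac_nontcga", "cadd_phred", "gerp",
    "phastcons", "phylop")
}

# VCF INFO keys for the annotation columns, in column order.
vt_info_keys <- function() {
  keys <- c(gene = "GENE", consequence = "CSQ_CLASS",
            maf_1kg = "MAF_1KG", maf_exac_nontcga = "MAF_EXAC_NONTCGA",
            cadd_phred = "CADD_PHRED", gerp = "GERP",
            phastcons = "PHASTCONS", phylop = "PHYLOP")
  pred <- toupper(predictor_tools())
  names(pred) <- predictor_tools()
  c(keys, pred)
}

#' Members represented in a variant table
#'
#' @param vt A `variant_table`.
#' @return Character vector of member ids with `gt_` columns.
#' @export
vt_members <- function(vt) {
  sub("^gt_", "", grep("^gt_", names(vt), value = TRUE))
}

#' Extract the dosage matrix of a variant table
#'
#' @param vt A `variant_table`.
#' @return Integer matrix, rows = variants, columns named by member id.
#' @export
vt_dosage <- function(vt) {
  members <- vt_members(vt)
  m <- as.matrix(as.data.frame(vt[paste0("gt_", members)]))
  storage.mode(m) <- "integer"
  colnames(m) <- members
  rownames(m) <- vt$id
  m
}

vt_depth <- function(vt) {
  members <- vt_members(vt)
  cols <- paste0("dp_", members)
  cols <- cols[cols %in% names(vt)]
  if (!length(cols)) {
    m <- matrix(NA_integer_, nrow(vt), length(members),
                dimnames = list(vt$id, members))
    return(m)
  }
  m <- as.matrix(as.data.frame(vt[cols]))
  storage.mode(m) <- "integer"
  colnames(m) <- sub("^dp_", "", cols)
  rownames(m) <- vt$id
  m
}

#' Validate and class a variant table
#'
#' @param df Data.frame carrying the variant-table columns.
#' @param ped Optional [pedigree()]; when given, genotype columns must match
#'   pedigree member ids and unmatched sample columns are an error.
#' @return The validated `variant_table`.
#' @export
variant_table <- function(df, ped = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(vt_fixed_cols(), names(df))
  if (length(missing_cols)) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  members <- sub("^gt_", "", grep("^gt_", names(df), value = TRUE))
  if (!length(members)) stop("variant table has no gt_<member> columns")
  if (!is.null(ped)) {
    unmatched <- setdiff(members, ped$id)
    if (length(unmatched)) {
      stop("sample columns do not match pedigree member ids: ",
           paste(unmatched, collapse = ", "))
    }
  }
  df$pos <- as.integer(df$pos)
  if (any(!is.na(df$pos) & df$pos < 1L)) stop("pos must be >= 1")
  for (cc in vt_num_cols()) df[[cc]] <- as.numeric(df[[cc]])
  rng_bad <- function(x) !is.na(x) & (x < 0 | x > 1)
  if (any(rng_bad(df$maf_1kg)) || any(rng_bad(df$maf_exac_nontcga))) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (any(rng_bad(df$phastcons))) stop("phastcons must lie in [0, 1]")
  df$filter_pass <- as.logical(df$filter_pass)
  bad_csq <- !is.na(df$consequence) &
    !(df$consequence %in% consequence_classes())
  if (any(bad_csq)) {
    stop("unknown consequence class: ",
         paste(unique(df$consequence[bad_csq]), collapse = ", "))
  }
  for (p in predictor_tools()) {
    v <- toupper(substr(as.character(df[[p]]), 1, 1))
    v[v %in% c(".", "")] <- NA_character_
    if (any(!is.na(v) & !(v %in% c("D", "T")))) {
      stop("predictor calls must be D, T or missing (column ", p, ")")
    }
    df[[p]] <- v
  }
  for (mcol in paste0("gt_", members)) {
    g <- suppressWarnings(as.integer(df[[mcol]]))
    if (any(!is.na(g) & !(g %in% 0:2))) {
      stop("genotype dosages must be 0, 1, 2 or missing (column ", mcol, ")")
    }
    df[[mcol]] <- g
  }
  for (dcol in paste0("dp_", members)) {
    if (!dcol %in% names(df)) df[[dcol]] <- NA_integer_
    df[[dcol]] <- as.integer(df[[dcol]])
  }
  df <- df[c(vt_fixed_cols(), paste0("gt_", members), paste0("dp_", members))]
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read an annotated multi-sample variant table
#'
#' @param path Path to a variant file.
#' @param ped A [pedigree()]; sample columns must map onto member ids.
#' @param dialect `"tsv"`, `"vcf"`, or `"auto"` (by file extension).
#' @return A `variant_table` with one row per bi-allelic alternate allele;
#'   multi-allelic VCF records are split with per-alternate annotations.
#' @export
read_variant_table <- function(path, ped, dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  switch(dialect,
         tsv = read_variant_tsv(path, ped),
         vcf = read_variant_vcf(path, ped))
}

read_variant_tsv <- function(path, ped) {
  hdr <- names(data.table::fread(path, sep = "\t", nrows = 0L,
                                 header = TRUE, check.names = FALSE))
  gt_cols <- grep("^gt_", hdr, value = TRUE)
  dp_cols <- grep("^dp_", hdr, value = TRUE)
  classes <- list(
    character = c("id", "chrom", "ref", "alt", "gene", "consequence",
                  predictor_tools(), gt_cols),
    integer = c("pos", dp_cols),
    numeric = vt_num_cols(),
    logical = "filter_pass"
  )
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".",
                          colClasses = classes, check.names = FALSE,
                          data.table = FALSE)
  for (mcol in gt_cols) {
    g <- dt[[mcol]]
    bad <- which(!is.na(g) & !(g %in% c("0", "1", "2")))
    if (length(bad)) {
      stop(sprintf("malformed genotype '%s' in column %s, line %d",
                   g[bad[1]], mcol, bad[1] + 1L))
    }
  }
  variant_table(dt, ped)
}

#' Write a variant table as flat TSV
#'
#' Numeric values are written with 17 significant digits so a read
#' round-trips bit-identically; missing values are `"."`.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_tsv <- function(vt, path) {
  members <- vt_members(vt)
  out <- data.frame(row.names = seq_len(nrow(vt)), check.names = FALSE)
  for (cc in names(vt)) {
    out[[cc]] <- if (cc %in% vt_num_cols()) {
      fmt_num(vt[[cc]])
    } else if (cc == "pos" || grepl("^(gt|dp)_", cc)) {
      fmt_int(vt[[cc]])
    } else if (cc == "filter_pass") {
      ifelse(is.na(vt[[cc]]), ".", ifelse(vt[[cc]], "TRUE", "FALSE"))
    } else {
      fmt_chr(vt[[cc]])
    }
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = ".",
                     col.names = TRUE)
  invisible(path)
}

# ---- VCF dialect -----------------------------------------------------------

# Dosage of alt allele index `a` from a GT string; any "." allele makes the
# call missing (half-calls are treated conservatively as missing).
gt_to_dosage <- function(gt, a) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  toks <- strsplit(gt, "[/|]")[[1]]
  if (any(toks == ".")) return(NA_integer_)
  if (!all(grepl("^[0-9]+$", toks))) {
    stop("malformed genotype: ", gt)
  }
  sum(toks == as.character(a))
}

info_value <- function(field, i, a) {
  if (is.null(field)) return(NA)
  v <- if (methods::is(field, "List") || is.list(field)) {
    field[[i]]
  } else {
    field[i]
  }
  if (!length(v)) return(NA)
  out <- if (length(v) >= a) v[a] else v[1]
  if (is.character(out) && (is.na(out) || out == ".")) return(NA_character_)
  out
}

read_variant_vcf <- function(path, ped) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  qual <- VariantAnnotation::qual(vcf)
  filt <- VariantAnnotation::filt(vcf)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  samples <- colnames(gt)
  unmatched <- setdiff(samples, ped$id)
  if (length(unmatched)) {
    stop("sample columns do not match pedigree member ids: ",
         paste(unmatched, collapse = ", "))
  }
  rec_dp <- if ("DP" %in% names(info)) info$DP else NULL

  keys <- vt_info_keys()
  rows <- list()
  ids <- rownames(gt) %||% paste0(chrom, ":", pos)
  for (i in seq_along(chrom)) {
    alts <- as.character(altL[[i]])
    for (a in seq_along(alts)) {
      row <- list(
        id = if (length(alts) > 1L) paste0(ids[i], "_", a) else ids[i],
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[a],
        qual = as.numeric(qual[i]),
        filter_pass = is.na(filt[i]) || filt[i] %in% c("PASS", ".")
      )
      for (col in names(keys)) {
        val <- info_value(info[[keys[[col]]]], i, a)
        row[[col]] <- if (col %in% c("gene", "consequence",
                                     predictor_tools())) {
          as.character(val)
        } else {
          as.numeric(val)
        }
      }
      for (s in samples) {
        row[[paste0("gt_", s)]] <- gt_to_dosage(gt[i, s], a)
        d <- if (!is.null(dp)) as.integer(dp[i, s]) else NA_integer_
        if (is.na(d) && !is.null(rec_dp)) d <- as.integer(rec_dp[i])
        row[[paste0("dp_", s)]] <- d
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  variant_table(df, ped)
}

#' Write a variant table as VCF 4.2
#'
#' Each row becomes one bi-allelic record; annotations are emitted as the
#' INFO keys `GENE`, `CSQ_CLASS`, `MAF_1KG`, `MAF_EXAC_NONTCGA`,
#' `CADD_PHRED`, `GERP`, `PHASTCONS`, `PHYLOP` plus one upper-case key per
#' predictor; genotypes as `GT` and per-sample depth as `DP`.
#'
#' @param vt A `variant_table`.
#' @param path Output path (plain-text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(vt, path) {
  members <- vt_members(vt)
  keys <- vt_info_keys()
  info_types <- ifelse(names(keys) %in% vt_num_cols() |
                         names(keys) %in% c("maf_1kg", "maf_exac_nontcga",
                                            "cadd_phred", "gerp",
                                            "phastcons", "phylop"),
                       "Float", "String")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varfunnel",
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            unname(keys), info_types, names(keys)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FILTER=<ID=FAIL,Description=\"Failed caller internal filters\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", members), collapse = "\t")
  )
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  recs <- vapply(seq_len(nrow(vt)), function(i) {
    info <- character()
    for (col in names(keys)) {
      v <- vt[[col]][i]
      if (is.na(v)) next
      vs <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      info <- c(info, paste0(keys[[col]], "=", vs))
    }
    fmt <- vapply(members, function(s) {
      g <- vt[[paste0("gt_", s)]][i]
      d <- vt[[paste0("dp_", s)]][i]
      paste0(if (is.na(g)) "./." else gt_str[[as.character(g)]],
             ":", if (is.na(d)) "." else d)
    }, character(1))
    paste(c(vt$chrom[i], vt$pos[i], fmt_chr(vt$id[i]), vt$ref[i], vt$alt[i],
            if (is.na(vt$qual[i])) "." else sprintf("%.17g", vt$qual[i]),
            if (isTRUE(vt$filter_pass[i])) "PASS" else "FAIL",
            if (length(info)) paste(info, collapse = ";") else ".",
            "GT:DP", fmt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
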