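# Gene-level intolerance ranking. Intolerance evidence ranks candidates; it
# never removes them (scores are "not cut-offs for selection").

INTOL_PCT_COLS <- c("esp6500_pct", "exac_pct", "local_pct")

#' Read a gene-intolerance reference table
#'
#' Tab-separated with columns `gene`, `esp6500_pct`, `exac_pct`, `local_pct`
#' (intolerance percentiles in [0, 100]; lower = more intolerant in the raw
#' rankings, but this table stores "intolerance percentile" where higher
#' means more intolerant), `pli` (loss-of-function intolerance in [0, 1])
#' and `mis_z` (missense constraint Z-score). `"."` denotes missing.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of `gene_intolerance` records.
#' @export
read_intolerance_table <- function(path) {
  if (!file.exists(path)) stop("intolerance table not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".",
                          data.table = FALSE)
  need <- c("gene", INTOL_PCT_COLS, "pli", "mis_z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("intolerance table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in INTOL_PCT_COLS) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] > 100))) {
      stop("intolerance percentiles must lie in [0, 100]: ", cc)
    }
  }
  df$pli <- as.numeric(df$pli)
  if (any(!is.na(df$pli) & (df$pli < 0 | df$pli > 1))) {
    stop("pLI must lie in [0, 1]")
  }
  df$mis_z <- as.numeric(df$mis_z)
  df[c("gene", INTOL_PCT_COLS, "pli", "mis_z")]
}

#' Class-specific gene score for a variant
#'
#' Returns the gene's pLI for truncating consequences (nonsense, frameshift,
#' splice), the missense Z-score for missense variants, and a neutral 0 when
#' the relevant score is missing or the consequence has no class score.
#'
#' @param consequence Consequence class of the variant.
#' @param record One row of an intolerance table (list or data.frame row),
#'   or `NULL` for a gene absent from the reference.
#' @return A single numeric score.
#' @export
variant_class_score <- function(consequence, record) {
  if (is.null(record) || (is.data.frame(record) && nrow(record) == 0L)) {
    return(0)
  }
  pli <- record$pli
  mis_z <- record$mis_z
  if (isTRUE(consequence %in% c("nonsense", "frameshift", "splice"))) {
    if (length(pli) && !is.na(pli)) return(as.numeric(pli))
  } else if (isTRUE(consequence == "missense")) {
    if (length(mis_z) && !is.na(mis_z)) return(as.numeric(mis_z))
  }
  0
}

#' Rank candidate variants by gene intolerance evidence
#'
#' Computes, per candidate, `rank_score = mean(available intolerance
#' percentiles)/100 + normalized class score`, where the class score is pLI
#' for truncating variants and `pnorm(mis_z)` for missense variants (0 when
#' missing; the pnorm maps the unbounded Z onto [0, 1]). Genes with all
#' percentiles missing receive the neutral 0.5. No candidate is ever
#' dropped; ties are broken by (chrom, pos).
#'
#' @param candidates A `variant_table`-like data.frame of candidates.
#' @param records Intolerance table from [read_intolerance_table()].
#' @return `candidates`, re-ordered by decreasing `rank_score`, with added
#'   `rank_score` and `rank` columns.
#' @export
composite_rank <- function(candidates, records) {
  n <- nrow(candidates)
  if (!n) {
    candidates$rank_score <- numeric(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  idx <- match(candidates$gene, records$gene)
  pct <- as.matrix(records[idx, INTOL_PCT_COLS, drop = FALSE])
  mean_pct <- rowMeans(pct, na.rm = TRUE)
  mean_pct[is.nan(mean_pct)] <- 50
  class_norm <- vapply(seq_len(n), function(i) {
    rec <- if (is.na(idx[i])) NULL else records[idx[i], , drop = FALSE]
    raw <- variant_class_score(candidates$consequence[i], rec)
    csq <- candidates$consequence[i]
    if (isTRUE(csq == "missense")) {
      has <- !is.null(rec) && length(rec$mis_z) && !is.na(rec$mis_z)
      if (has) stats::pnorm(raw) else 0
    } else if (isTRUE(csq %in% c("nonsense", "frameshift", "splice"))) {
      raw
    } else {
      0
    }
  }, numeric(1))
  candidates$rank_score <- mean_pct / 100 + class_norm
  ord <- order(-candidates$rank_score, candidates$chrom, candidates$pos)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}
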