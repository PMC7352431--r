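# The prioritization funnel: quality -> rarity -> segregation -> CADD ->
# conservation -> consensus deleteriousness vote, with a lenient rescue path
# for known cancer genes (rescue bypasses the CADD/conservation/vote stages,
# never quality, rarity or segregation).

#' Filter cascade configuration
#'
#' Boundary semantics follow the published thresholds literally: strict `>`
#' for QUAL, coverage, CADD, GERP and PhastCons; inclusive `>=` for PhyloP
#' and for the consensus fraction ("at least 60%"); the MAF gate removes
#' variants strictly above `maf_max`, so a frequency of exactly 0.1% is
#' retained.
#'
#' @param qual_min Caller QUAL must exceed this (default 20).
#' @param depth_min Minimum read depth (strict `>`, default 5) over genotyped
#'   members.
#' @param maf_max Maximum population MAF (default 0.001); variants above it
#'   in any available source are removed, missing sources count as rare.
#' @param cadd_min Scaled PHRED-like CADD threshold (strict `>`, default 10).
#' @param gerp_min GERP threshold (strict `>`, default 2).
#' @param phastcons_min PhastCons threshold (strict `>`, default 0.3).
#' @param phylop_min PhyloP threshold (inclusive `>=`, default 3).
#' @param consensus_fraction Fraction of available predictor calls that must
#'   be deleterious (inclusive, default 0.6).
#' @param min_predictor_calls Minimum number of non-missing predictor calls
#'   for the vote to be evaluable (default 5); fewer available calls fail the
#'   vote unless the variant is rescued.
#' @param cadd_missing_fails Whether a missing CADD score fails the CADD
#'   stage (default TRUE; CADD is the primary deleteriousness gate).
#' @param vote_consequences Consequence classes eligible for the vote stage;
#'   variants outside the set (synonymous/other by default) fail it.
#' @param rescue_genes Character vector of gene symbols handled leniently
#'   with regard to the CADD, conservation and vote stages.
#' @param stage_order Order in which stages are applied.
#' @return A `filter_config` list.
#' @export
filter_config <- function(qual_min = 20,
                          depth_min = 5,
                          maf_max = 0.001,
                          cadd_min = 10,
                          gerp_min = 2,
                          phastcons_min = 0.3,
                          phylop_min = 3,
                          consensus_fraction = 0.6,
                          min_predictor_calls = 5L,
                          cadd_missing_fails = TRUE,
                          vote_consequences = coding_altering(),
                          rescue_genes = character(),
                          stage_order = c("quality", "rarity", "segregation",
                                          "cadd", "conservation", "vote")) {
  thr <- c(qual_min, depth_min, maf_max, cadd_min, gerp_min,
           phastcons_min, phylop_min)
  if (any(!is.finite(thr))) stop("all thresholds must be finite")
  if (consensus_fraction <= 0 || consensus_fraction > 1) {
    stop("consensus_fraction must lie in (0, 1]")
  }
  stages <- c("quality", "rarity", "segregation", "cadd", "conservation",
              "vote")
  if (!setequal(stage_order, stages)) {
    stop("stage_order must be a permutation of: ",
         paste(stages, collapse = ", "))
  }
  structure(
    list(qual_min = qual_min, depth_min = depth_min, maf_max = maf_max,
         cadd_min = cadd_min, gerp_min = gerp_min,
         phastcons_min = phastcons_min, phylop_min = phylop_min,
         consensus_fraction = consensus_fraction,
         min_predictor_calls = as.integer(min_predictor_calls),
         cadd_missing_fails = isTRUE(cadd_missing_fails),
         vote_consequences = vote_consequences,
         rescue_genes = as.character(rescue_genes),
         stage_order = stage_order),
    class = "filter_config"
  )
}

#' Read a filter configuration from JSON
#'
#' The JSON object mirrors [filter_config()] field for field; absent fields
#' take their defaults.
#'
#' @param path Path to a JSON file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(filter_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(filter_config, vals)
}

#' Caller quality gate
#'
#' Passes when QUAL strictly exceeds `qual_min`, the minimum read depth over
#' genotyped members (non-missing genotype and depth) strictly exceeds
#' `depth_min`, and the variant passed all caller internal filters. Variants
#' with no usable depth fail.
#'
#' @param vt A `variant_table`.
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per variant.
#' @export
quality_filter <- function(vt, cfg = filter_config()) {
  dos <- vt_dosage(vt)
  dep <- vt_depth(vt)
  dep[is.na(dos)] <- NA_integer_
  n_used <- rowSums(!is.na(dep))
  min_dep <- suppressWarnings(
    apply(dep, 1L, function(x) min(x, na.rm = TRUE)))
  depth_ok <- n_used > 0L & is.finite(min_dep) & min_dep > cfg$depth_min
  !is.na(vt$qual) & vt$qual > cfg$qual_min &
    depth_ok & !is.na(vt$filter_pass) & vt$filter_pass
}

#' Population rarity gate
#'
#' Passes when every available MAF source is at or below `maf_max`; missing
#' sources are treated as rare (novel variants survive).
#'
#' @inheritParams quality_filter
#' @return Logical vector.
#' @export
rarity_filter <- function(vt, cfg = filter_config()) {
  ok1 <- is.na(vt$maf_1kg) | vt$maf_1kg <= cfg$maf_max
  ok2 <- is.na(vt$maf_exac_nontcga) | vt$maf_exac_nontcga <= cfg$maf_max
  ok1 & ok2
}

#' CADD deleteriousness gate
#'
#' Passes when the scaled PHRED-like CADD score strictly exceeds `cadd_min`;
#' by default a missing score fails (rescued variants bypass this stage).
#'
#' @inheritParams quality_filter
#' @return Logical vector.
#' @export
cadd_filter <- function(vt, cfg = filter_config()) {
  present <- !is.na(vt$cadd_phred)
  pass <- present & vt$cadd_phred > cfg$cadd_min
  if (!cfg$cadd_missing_fails) pass <- pass | !present
  pass
}

#' Evolutionary conservation gate
#'
#' Passes when GERP > `gerp_min`, PhastCons > `phastcons_min` and
#' PhyloP >= `phylop_min`, skipping individually missing scores (they are
#' corroborating evidence, not a hard conjunction), but requiring at least
#' one score to be present.
#'
#' @inheritParams quality_filter
#' @return Logical vector.
#' @export
conservation_filter <- function(vt, cfg = filter_config()) {
  g_ok <- is.na(vt$gerp) | vt$gerp > cfg$gerp_min
  c_ok <- is.na(vt$phastcons) | vt$phastcons > cfg$phastcons_min
  p_ok <- is.na(vt$phylop) | vt$phylop >= cfg$phylop_min
  any_present <- !is.na(vt$gerp) | !is.na(vt$phastcons) | !is.na(vt$phylop)
  g_ok & c_ok & p_ok & any_present
}

# Normalize a single set of predictor calls to the canonical named vector.
as_predictor_calls <- function(calls) {
  tools <- predictor_tools()
  if (is.list(calls)) calls <- unlist(calls)
  calls <- stats::setNames(as.character(calls), names(calls))
  if (is.null(names(calls)) || !all(nzchar(names(calls)))) {
    if (length(calls) != length(tools)) {
      stop("unnamed predictor calls must have length ", length(tools))
    }
    names(calls) <- tools
  }
  if (!setequal(names(calls), tools)) {
    stop("predictor calls must be named by the 10 tools: ",
         paste(tools, collapse = ", "))
  }
  v <- toupper(substr(calls[tools], 1, 1))
  v[v %in% c(".", "", "NA")] <- NA_character_
  if (any(!is.na(v) & !(v %in% c("D", "T")))) {
    stop("predictor calls must be deleterious (D), tolerated (T) or missing")
  }
  stats::setNames(v, tools)
}

#' Consensus deleteriousness vote
#'
#' A variant passes when at least `consensus_fraction` of its available
#' (non-missing) predictor calls are deleterious and at least
#' `min_predictor_calls` calls are available. Missing calls shrink the
#' denominator rather than counting against the variant.
#'
#' @param calls Named character vector over the 10 predictor tools with
#'   values `"D"`, `"T"` or `NA` (a bare length-10 vector is accepted).
#' @param cfg A [filter_config()].
#' @return List with `pass`, `n_deleterious`, `n_available`.
#' @export
deleteriousness_vote <- function(calls, cfg = filter_config()) {
  v <- as_predictor_calls(calls)
  n_avail <- sum(!is.na(v))
  n_del <- sum(v == "D", na.rm = TRUE)
  pass <- n_avail >= cfg$min_predictor_calls && n_avail > 0L &&
    n_del >= cfg$consensus_fraction * n_avail - 1e-9
  list(pass = pass, n_deleterious = n_del, n_available = n_avail)
}

# Vectorized vote stage: consequence eligibility plus consensus vote.
vote_filter <- function(vt, cfg = filter_config()) {
  calls <- as.matrix(as.data.frame(vt[predictor_tools()]))
  n_avail <- rowSums(!is.na(calls))
  n_del <- rowSums(calls == "D", na.rm = TRUE)
  eligible <- !is.na(vt$consequence) &
    vt$consequence %in% cfg$vote_consequences
  eligible & n_avail >= cfg$min_predictor_calls &
    n_del >= cfg$consensus_fraction * n_avail - 1e-9
}

#' Known cancer-gene rescue check
#'
#' A variant is rescue-eligible when its gene is on the rescue list and its
#' consequence is coding-altering. Rescued variants bypass the CADD,
#' conservation and vote stages but never the quality, rarity or segregation
#' stages.
#'
#' @inheritParams quality_filter
#' @return Logical vector.
#' @export
rescue_check <- function(vt, cfg = filter_config()) {
  !is.na(vt$gene) & vt$gene %in% cfg$rescue_genes &
    !is.na(vt$consequence) & vt$consequence %in% coding_altering()
}

segregation_filter <- function(vt, ped, cfg = filter_config()) {
  segregation_pass_matrix(vt_dosage(vt), ped)
}

LENIENT_STAGES <- c("cadd", "conservation", "vote")

#' Run the full prioritization cascade
#'
#' Applies the configured stages in order, recording a per-variant decision
#' trail (`pass` / `fail` / `rescued` / `not-applicable`) and per-stage
#' surviving counts. Rescue-eligible variants (see [rescue_check()]) are
#' marked `rescued` at the lenient stages and survive them. Candidates are
#' ordered by [composite_rank()] when an intolerance table is supplied,
#' otherwise by (chrom, pos).
#'
#' @param variants A `variant_table` (or coercible data.frame).
#' @param ped A [pedigree()] with at least one case.
#' @param cfg A [filter_config()].
#' @param intolerance Optional gene-intolerance table
#'   (see [read_intolerance_table()]).
#' @return A `funnel_report`: list with `stages` (per-stage counts), `trail`
#'   (decision trail data.frame), `candidates` (surviving variants with a
#'   `rescued` flag and rank columns) and `n_input`.
#' @export
run_cascade <- function(variants, ped, cfg = filter_config(),
                        intolerance = NULL) {
  vt <- if (inherits(variants, "variant_table")) {
    variant_table(variants, ped)
  } else {
    variant_table(as.data.frame(variants), ped)
  }
  if (!any(ped$role == "case")) {
    stop("pedigree has no case member; segregation filtering is undefined")
  }
  n <- nrow(vt)
  stages <- cfg$stage_order
  alive <- rep(TRUE, n)
  rescued <- rescue_check(vt, cfg)
  trail <- matrix("not-applicable", nrow = n, ncol = length(stages),
                  dimnames = list(NULL, stages))
  stage_df <- data.frame(stage = stages, n_input = NA_integer_,
                         n_surviving = NA_integer_,
                         n_rescued = NA_integer_,
                         stringsAsFactors = FALSE)
  for (k in seq_along(stages)) {
    s <- stages[k]
    stage_df$n_input[k] <- sum(alive)
    res <- if (n == 0L) {
      logical(0)
    } else {
      switch(s,
             quality = quality_filter(vt, cfg),
             rarity = rarity_filter(vt, cfg),
             segregation = segregation_filter(vt, ped, cfg),
             cadd = cadd_filter(vt, cfg),
             conservation = conservation_filter(vt, cfg),
             vote = vote_filter(vt, cfg))
    }
    if (s %in% LENIENT_STAGES) {
      idx_r <- alive & rescued
      idx_n <- alive & !rescued
      trail[idx_r, s] <- "rescued"
      trail[idx_n, s] <- ifelse(res[idx_n], "pass", "fail")
      alive <- alive & (res | rescued)
    } else {
      trail[alive, s] <- ifelse(res[alive], "pass", "fail")
      alive <- alive & res
    }
    stage_df$n_surviving[k] <- sum(alive)
    stage_df$n_rescued[k] <- if (s %in% LENIENT_STAGES) {
      sum(alive & rescued & !res)
    } else {
      0L
    }
  }
  cand <- vt[alive, , drop = FALSE]
  cand$rescued <- rescued[alive]
  if (!is.null(intolerance) && nrow(cand)) {
    cand <- composite_rank(cand, intolerance)
  } else if (nrow(cand)) {
    ord <- order(cand$chrom, cand$pos)
    cand <- cand[ord, , drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
  } else {
    cand$rank <- integer(0)
  }
  rownames(cand) <- NULL
  trail_df <- data.frame(id = vt$id, as.data.frame(trail),
                         stringsAsFactors = FALSE, check.names = FALSE)
  structure(
    list(stages = stage_df, trail = trail_df, candidates = cand,
         n_input = n, config = cfg),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("Variant prioritization funnel: %d variants in\n", x$n_input))
  for (k in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-13s %6d -> %6d%s\n",
                x$stages$stage[k], x$stages$n_input[k],
                x$stages$n_surviving[k],
                if (x$stages$n_rescued[k] > 0)
                  sprintf("  (%d rescued)", x$stages$n_rescued[k]) else ""))
  }
  cat(sprintf("Final candidates: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates)) {
    cols <- intersect(c("rank", "id", "chrom", "pos", "ref", "alt", "gene",
                        "consequence", "cadd_phred", "rescued", "rank_score"),
                      names(x$candidates))
    print.data.frame(x$candidates[cols], row.names = FALSE)
  }
  invisible(x)
}
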