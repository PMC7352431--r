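# Quantification of the wet-lab readouts: qPCR relative telomere length
# (T/S = 2^-dCt against an albumin single-copy control, RTL against a
# reference DNA pool) and ChIP telomere dot-blot enrichment, plus the
# two-sample comparison used for group contrasts.

#' Construct a qPCR measurement
#'
#' @param sample Sample id.
#' @param ct_telomere,ct_albumin Replicate Ct values (cycles) for the
#'   telomere and single-copy (albumin) targets: a numeric vector for a
#'   single run, or a list of numeric vectors with one element per run.
#' @return A `qpcr_measurement` list with `sample`, `ct_telomere`,
#'   `ct_albumin` (lists of per-run replicate vectors) and `n_runs`.
#' @export
qpcr_measurement <- function(sample, ct_telomere, ct_albumin) {
  as_runs <- function(x, what) {
    if (!is.list(x)) x <- list(x)
    x <- lapply(x, as.numeric)
    vals <- unlist(x)
    if (any(!is.na(vals) & (vals <= 0 | !is.finite(vals)))) {
      stop("Ct values must be positive and finite (", what, ")")
    }
    x
  }
  tel <- as_runs(ct_telomere, "telomere")
  alb <- as_runs(ct_albumin, "albumin")
  if (length(tel) != length(alb)) {
    stop("telomere and albumin targets must cover the same runs")
  }
  structure(list(sample = as.character(sample), ct_telomere = tel,
                 ct_albumin = alb, n_runs = length(tel)),
            class = "qpcr_measurement")
}

#' Telomere/single-copy (T/S) ratio
#'
#' Computes `2^-(mean Ct_telomere - mean Ct_albumin)`. Replicate Cts are
#' averaged within each run, a per-run T/S is formed, and run-level T/S
#' values are averaged across runs (`aggregate = "runs_mean"`); with
#' `aggregate = "pooled"` all replicates are pooled before a single 2^-dCt.
#' No amplification-efficiency correction is applied.
#'
#' @param m A [qpcr_measurement()].
#' @param aggregate Replicate aggregation scheme.
#' @return A single numeric T/S value.
#' @export
ts_ratio <- function(m, aggregate = c("runs_mean", "pooled")) {
  stopifnot(inherits(m, "qpcr_measurement"))
  aggregate <- match.arg(aggregate)
  all_tel <- unlist(m$ct_telomere)
  all_alb <- unlist(m$ct_albumin)
  if (all(is.na(all_tel))) stop("all telomere Ct replicates are missing")
  if (all(is.na(all_alb))) stop("all albumin Ct replicates are missing")
  if (aggregate == "pooled") {
    return(2^-(mean(all_tel, na.rm = TRUE) - mean(all_alb, na.rm = TRUE)))
  }
  per_run <- vapply(seq_len(m$n_runs), function(r) {
    mt <- mean(m$ct_telomere[[r]], na.rm = TRUE)
    ma <- mean(m$ct_albumin[[r]], na.rm = TRUE)
    2^-(mt - ma)
  }, numeric(1))
  mean(per_run[is.finite(per_run)])
}

#' Relative telomere length
#'
#' RTL is a sample's T/S divided by the T/S of the reference DNA sample
#' (e.g. genomic DNA pooled from healthy individuals).
#'
#' @param sample_ts Sample T/S value.
#' @param reference_ts Reference T/S value; must be strictly positive.
#' @return `sample_ts / reference_ts`.
#' @export
relative_tl <- function(sample_ts, reference_ts) {
  if (any(is.na(reference_ts)) || any(reference_ts <= 0)) {
    stop("reference T/S must be positive")
  }
  sample_ts / reference_ts
}

#' Read a long-format Ct table
#'
#' Tab-separated with columns `sample`, `run`, `target` (`telomere` or
#' `albumin`), `replicate`, `ct`; `"."` = missing.
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_ct_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".",
                          data.table = FALSE)
  need <- c("sample", "run", "target", "replicate", "ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("Ct table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- !df$target %in% c("telomere", "albumin")
  if (any(bad)) {
    stop("target must be 'telomere' or 'albumin'; found: ",
         paste(unique(df$target[bad]), collapse = ", "))
  }
  df$ct <- as.numeric(df$ct)
  df
}

#' Per-sample T/S and RTL from a long Ct table
#'
#' @param ct_table Data.frame as returned by [read_ct_table()].
#' @param reference Sample id of the reference DNA; its RTL is exactly 1.
#' @param aggregate Passed to [ts_ratio()].
#' @return Data.frame with columns `sample`, `ts`, `rtl`.
#' @export
compute_rtl <- function(ct_table, reference,
                        aggregate = c("runs_mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  samples <- unique(ct_table$sample)
  if (!reference %in% samples) {
    stop("reference sample not present: ", reference)
  }
  ts <- vapply(samples, function(s) {
    sub <- ct_table[ct_table$sample == s, , drop = FALSE]
    runs <- sort(unique(sub$run))
    tel <- lapply(runs, function(r) {
      sub$ct[sub$run == r & sub$target == "telomere"]
    })
    alb <- lapply(runs, function(r) {
      sub$ct[sub$run == r & sub$target == "albumin"]
    })
    ts_ratio(qpcr_measurement(s, tel, alb), aggregate = aggregate)
  }, numeric(1))
  data.frame(sample = samples, ts = unname(ts),
             rtl = unname(relative_tl(ts, ts[[reference]])),
             stringsAsFactors = FALSE)
}

#' ChIP dot-blot fold enrichment
#'
#' The immunoprecipitated telomeric signal is normalized to the *total*
#' input telomeric DNA: the measured input signal is first scaled up by the
#' fraction of chromatin it represents, giving
#' `chip_signal / (input_signal / input_fraction)`.
#'
#' @param chip_signal Densitometry signal of the ChIP lane (>= 0).
#' @param input_signal Densitometry signal of the input lane (> 0).
#' @param input_fraction Fraction of total chromatin loaded as input, in
#'   (0, 1] (e.g. 0.1 for a 10% input).
#' @return Numeric fold enrichment (vectorized).
#' @export
chip_enrichment <- function(chip_signal, input_signal, input_fraction = 1) {
  if (any(is.na(input_signal)) || any(input_signal <= 0)) {
    stop("input signal must be positive")
  }
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    stop("input_fraction must lie in (0, 1]")
  }
  if (any(!is.na(chip_signal) & chip_signal < 0)) {
    stop("chip signal must be non-negative")
  }
  chip_signal / (input_signal / input_fraction)
}

#' Two-tailed equal-variance t-test between RTL groups
#'
#' Classical two-sample Student t-test (pooled variance, two-sided), as used
#' for comparing relative telomere length between genotype groups.
#'
#' @param group_a,group_b Numeric vectors of RTL values, each of length
#'   >= 2.
#' @return List with `t`, `df`, `p_value`.
#' @export
compare_rtl_groups <- function(group_a, group_b) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  pooled <- sum((group_a - mean(group_a))^2) +
    sum((group_b - mean(group_b))^2)
  if (pooled == 0) {
    stop("degenerate comparison: zero pooled variance")
  }
  res <- stats::t.test(group_a, group_b, var.equal = TRUE,
                       alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
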