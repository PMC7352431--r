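# Closed-form expectations under the synthetic generator. These are derived
# analytically from the configured distributions -- independently of the
# generator's sampling code and of the cascade predicates -- so they serve
# as an oracle for calibration tests.

#' Hardy-Weinberg genotype probabilities
#'
#' @param af Alternate allele frequency.
#' @return Numeric vector `c(P(dosage 0), P(1), P(2))`.
#' @export
hwe_probs <- function(af) {
  c((1 - af)^2, 2 * af * (1 - af), af^2)
}

# P(child dosage = 0,1,2 | parental dosages gf, gm) under Mendelian
# transmission (each parent passes an alternate allele w.p. dosage/2).
child_dosage_probs <- function(gf, gm) {
  pf <- gf / 2
  pm <- gm / 2
  c((1 - pf) * (1 - pm),
    pf * (1 - pm) + (1 - pf) * pm,
    pf * pm)
}

#' Closed-form dominant segregation pass probability
#'
#' Probability that a variant whose genotypes are drawn independently of
#' phenotype (founders at Hardy-Weinberg equilibrium for frequency `af`,
#' children by Mendelian transmission) passes the dominant segregation
#' filter: every genotyped case carries >= 1 alternate allele and every
#' genotyped control carries none. Obtained by summing over the nine founder
#' genotype combinations; children are conditionally independent given the
#' founders. Supports the founder-couple template (every non-founder has the
#' two founders as parents).
#'
#' @param ped A founder-couple [pedigree()].
#' @param af Alternate allele frequency.
#' @return A probability.
#' @export
segregation_pass_prob <- function(ped, af) {
  founders <- ped$id[is.na(ped$father)]
  if (length(founders) != 2L) {
    stop("closed form requires exactly two founders")
  }
  kids <- ped$id[!is.na(ped$father)]
  if (!all(ped$father[match(kids, ped$id)] %in% founders &
           ped$mother[match(kids, ped$id)] %in% founders)) {
    stop("closed form requires all children to share the founder couple")
  }
  constrained <- function(id) {
    ped$sample_available[ped$id == id] &&
      ped$role[ped$id == id] %in% c("case", "control")
  }
  hw <- hwe_probs(af)
  p <- 0
  for (gf in 0:2) {
    for (gm in 0:2) {
      w <- hw[gf + 1] * hw[gm + 1]
      q <- 1
      for (fid in founders) {
        if (!constrained(fid)) next
        g <- if (fid == founders[1]) gf else gm
        q <- q * if (ped$role[ped$id == fid] == "case") {
          as.numeric(g >= 1)
        } else {
          as.numeric(g == 0)
        }
      }
      tp <- child_dosage_probs(gf, gm)
      for (kid in kids) {
        if (!constrained(kid)) next
        q <- q * if (ped$role[ped$id == kid] == "case") {
          tp[2] + tp[3]
        } else {
          tp[1]
        }
      }
      p <- p + w * q
    }
  }
  p
}

# P(consensus vote passes | latent deleteriousness d) with per-tool
# missingness m and deleterious-call probability theta: the number of
# available calls is Binomial(10, 1 - m); given n available, deleterious
# calls are Binomial(n, theta) and the vote passes when
# n >= min_calls and k >= ceil(frac * n).
vote_pass_prob <- function(theta, miss, frac, min_calls) {
  total <- length(predictor_tools())
  p <- 0
  for (n in seq_len(total)) {
    if (n < min_calls) next
    kmin <- ceiling(frac * n - 1e-9)
    p_n <- stats::dbinom(n, total, 1 - miss)
    p <- p + p_n * (1 - stats::pbinom(kmin - 1, n, theta))
  }
  p
}

#' Closed-form survivor probability for a background variant
#'
#' Probability that one background variant drawn under `simcfg` survives the
#' default cascade under `cfg`, computed analytically:
#' quality (log-normal QUAL above the gate, Poisson depths above the gate
#' for all genotyped members, caller pass), rarity jointly with segregation
#' over the discrete frequency spectrum (a common variant survives the
#' rarity gate only when both MAF sources are unobserved), consequence
#' eligibility, and the CADD/conservation/vote gates mixed over the latent
#' deleteriousness indicator (they are dependent through it). Assumes the
#' default stage set with an empty rescue list.
#'
#' @param simcfg A [sim_config()].
#' @param ped The pedigree the variants are generated on.
#' @param cfg A [filter_config()].
#' @return A probability.
#' @export
expected_survivor_prob <- function(simcfg, ped, cfg = filter_config()) {
  if (length(cfg$rescue_genes)) {
    stop("closed form assumes an empty rescue list")
  }
  n_members <- sum(ped$sample_available)
  p_quality <- (1 - stats::plnorm(cfg$qual_min, simcfg$qual_meanlog,
                                  simcfg$qual_sdlog)) *
    simcfg$caller_pass_prob *
    (1 - stats::ppois(cfg$depth_min, simcfg$depth_lambda))^n_members

  p_maf_blind <- prod(simcfg$maf_missing)
  p_rare_seg <- sum(vapply(seq_along(simcfg$af_values), function(k) {
    af <- simcfg$af_values[k]
    r <- if (af <= cfg$maf_max) 1 else p_maf_blind
    simcfg$af_weights[k] * r * segregation_pass_prob(ped, af)
  }, numeric(1)))

  p_class <- sum(simcfg$consequence_probs[
    names(simcfg$consequence_probs) %in% cfg$vote_consequences])

  p_annot <- 0
  for (d in c(FALSE, TRUE)) {
    pd <- if (d) simcfg$p_deleterious else 1 - simcfg$p_deleterious
    mu_c <- if (d) simcfg$cadd$mean1 else simcfg$cadd$mean0
    sd_c <- if (d) simcfg$cadd$sd1 else simcfg$cadd$sd0
    p_cadd <- (1 - simcfg$cadd$missing) *
      (1 - stats::pnorm(cfg$cadd_min, mu_c, sd_c))
    if (!cfg$cadd_missing_fails) p_cadd <- p_cadd + simcfg$cadd$missing

    mu_g <- if (d) simcfg$gerp$mean1 else simcfg$gerp$mean0
    sd_g <- if (d) simcfg$gerp$sd1 else simcfg$gerp$sd0
    p_g <- 1 - stats::pnorm(cfg$gerp_min, mu_g, sd_g)
    a_p <- if (d) simcfg$phastcons$shape1_1 else simcfg$phastcons$shape1_0
    b_p <- if (d) simcfg$phastcons$shape2_1 else simcfg$phastcons$shape2_0
    p_c <- 1 - stats::pbeta(cfg$phastcons_min, a_p, b_p)
    mu_p <- if (d) simcfg$phylop$mean1 else simcfg$phylop$mean0
    sd_p <- if (d) simcfg$phylop$sd1 else simcfg$phylop$sd0
    p_p <- 1 - stats::pnorm(cfg$phylop_min, mu_p, sd_p)
    m <- c(simcfg$gerp$missing, simcfg$phastcons$missing,
           simcfg$phylop$missing)
    p_cons <- prod(m + (1 - m) * c(p_g, p_c, p_p)) - prod(m)

    theta <- if (d) simcfg$predictor$p_del_true else simcfg$predictor$p_del_null
    p_vote <- vote_pass_prob(theta, simcfg$predictor$missing,
                             cfg$consensus_fraction,
                             cfg$min_predictor_calls)
    p_annot <- p_annot + pd * p_cadd * p_cons * p_vote
  }
  p_quality * p_rare_seg * p_class * p_annot
}

#' Expected background survivor count per dataset
#'
#' @inheritParams expected_survivor_prob
#' @return `n_background * expected_survivor_prob(...)`.
#' @export
expected_background_survivors <- function(simcfg, ped,
                                          cfg = filter_config()) {
  simcfg$n_background * expected_survivor_prob(simcfg, ped, cfg)
}
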