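# Synthetic pedigree / variant generator. Emulates a two-generation cancer
# family (founder couple + nine children with mixed phenotype roles), a
# planted heterozygous dominant causal variant inherited from one founder,
# and background variants whose genotypes follow Hardy-Weinberg + Mendelian
# transmission independently of phenotype, with annotation scores drawn from
# configurable distributions tied to a latent per-variant deleteriousness
# indicator.
#
# Reproducibility: every variant is drawn from its own deterministic
# substream keyed by (seed, index), so enlarging n_background never changes
# earlier variants, and identical configurations give byte-identical output
# files.

#' Simulation configuration
#'
#' Defaults state the simulated world: a family mirroring the studied
#' two-generation pedigree (4 genotyped cases, 3 potential carriers with
#' benign nodules, 2 genotyped controls; the causal allele enters through
#' the untyped deceased father), 1000 background variants per dataset, a
#' discretized allele-frequency spectrum weighted toward rare sites, and a
#' latent deleteriousness indicator (prior 0.05) that jointly shifts CADD,
#' conservation scores and the ten predictor calls.
#'
#' @param seed Integer master seed (< 2^31).
#' @param n_background Number of background variants.
#' @param af_values,af_weights Discrete allele-frequency spectrum the true
#'   population frequency is drawn from.
#' @param maf_missing Named probabilities that each MAF source is
#'   unobserved.
#' @param qual_meanlog,qual_sdlog Log-normal caller QUAL distribution.
#' @param depth_lambda Poisson mean per-member read depth.
#' @param caller_pass_prob Probability a variant passes caller internal
#'   filters.
#' @param p_deleterious Prior of the latent deleteriousness indicator.
#' @param cadd,gerp,phylop Lists with `mean0`, `sd0` (latent-benign),
#'   `mean1`, `sd1` (latent-deleterious) and `missing` for the normal score
#'   distributions.
#' @param phastcons List with beta shapes `shape1_0`, `shape2_0`,
#'   `shape1_1`, `shape2_1` and `missing`.
#' @param predictor List with `p_del_true`, `p_del_null` (per-tool
#'   deleterious-call probability given the latent indicator) and `missing`.
#' @param consequence_probs Named probabilities over consequence classes.
#' @param n_children Number of second-generation members.
#' @param role_assignment Optional named character vector of roles for the
#'   children (names `II-1`...); defaults to the packaged family template
#'   when `n_children == 9`, otherwise roles cycle case/carrier/control.
#' @param sample_unavailable Ids without a genotypable sample (default the
#'   deceased father `I-2` and one unsequenced case `II-9`).
#' @param causal_gene Gene symbol carried by the planted variant.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_background = 1000L,
                       af_values = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2,
                                     1e-1, 3e-1),
                       af_weights = c(0.20, 0.15, 0.10, 0.10, 0.10, 0.15,
                                      0.10, 0.10),
                       maf_missing = c(maf_1kg = 0.10,
                                       maf_exac_nontcga = 0.10),
                       qual_meanlog = log(60), qual_sdlog = 0.8,
                       depth_lambda = 30,
                       caller_pass_prob = 0.98,
                       p_deleterious = 0.05,
                       cadd = list(mean0 = 5, sd0 = 4, mean1 = 22, sd1 = 5,
                                   missing = 0.05),
                       gerp = list(mean0 = 0, sd0 = 2, mean1 = 4, sd1 = 1.5,
                                   missing = 0.10),
                       phastcons = list(shape1_0 = 0.5, shape2_0 = 2,
                                        shape1_1 = 4, shape2_1 = 1,
                                        missing = 0.10),
                       phylop = list(mean0 = 0.5, sd0 = 1.5, mean1 = 5,
                                     sd1 = 2, missing = 0.10),
                       predictor = list(p_del_true = 0.90, p_del_null = 0.15,
                                        missing = 0.15),
                       consequence_probs = c(synonymous = 0.30,
                                             missense = 0.55,
                                             nonsense = 0.02, splice = 0.03,
                                             frameshift = 0.02,
                                             inframe_indel = 0.02,
                                             other = 0.06),
                       n_children = 9L,
                       role_assignment = NULL,
                       sample_unavailable = c("I-2", "II-9"),
                       causal_gene = "POT1") {
  stopifnot(length(af_values) == length(af_weights),
            all(af_weights >= 0), sum(af_weights) > 0,
            all(af_values > 0 & af_values < 1),
            n_background >= 0, n_children >= 0)
  af_weights <- af_weights / sum(af_weights)
  probs <- c(maf_missing, caller_pass_prob, p_deleterious,
             cadd$missing, gerp$missing, phastcons$missing, phylop$missing,
             predictor$p_del_true, predictor$p_del_null, predictor$missing,
             consequence_probs)
  stopifnot(all(probs >= 0 & probs <= 1))
  stopifnot(abs(sum(consequence_probs) - 1) < 1e-8,
            setequal(names(consequence_probs), consequence_classes()))
  structure(
    list(seed = as.integer(seed), n_background = as.integer(n_background),
         af_values = af_values, af_weights = af_weights,
         maf_missing = maf_missing,
         qual_meanlog = qual_meanlog, qual_sdlog = qual_sdlog,
         depth_lambda = depth_lambda, caller_pass_prob = caller_pass_prob,
         p_deleterious = p_deleterious,
         cadd = cadd, gerp = gerp, phastcons = phastcons, phylop = phylop,
         predictor = predictor,
         consequence_probs = consequence_probs[consequence_classes()],
         n_children = as.integer(n_children),
         role_assignment = role_assignment,
         sample_unavailable = sample_unavailable,
         causal_gene = causal_gene),
    class = "sim_config"
  )
}

default_child_roles <- function() {
  c(`II-1` = "control", `II-2` = "case", `II-3` = "case",
    `II-4` = "carrier", `II-5` = "case", `II-6` = "carrier",
    `II-7` = "control", `II-8` = "case", `II-9` = "case")
}

#' Simulate the family pedigree
#'
#' The default template mirrors the studied family: a founder couple
#' (mother with benign nodules and a genotypable sample; deceased, untyped
#' father) and nine children, of whom four are genotyped cases, two are
#' genotyped carriers, two are genotyped controls, and one case lacks a
#' sample — 11 members, 9 genotypable.
#'
#' @param cfg A [sim_config()].
#' @return A [pedigree()].
#' @export
simulate_family <- function(cfg = sim_config()) {
  n <- cfg$n_children
  kids <- if (n > 0) paste0("II-", seq_len(n)) else character()
  roles <- cfg$role_assignment
  if (is.null(roles)) {
    roles <- if (n == 9L) {
      default_child_roles()
    } else {
      stats::setNames(rep(c("case", "carrier", "control"), length.out = n),
                      kids)
    }
  }
  if (!all(kids %in% names(roles))) {
    stop("role_assignment must name every child: ",
         paste(setdiff(kids, names(roles)), collapse = ", "))
  }
  ids <- c("I-1", "I-2", kids)
  pedigree(
    id = ids,
    father = c(NA, NA, rep("I-2", n)),
    mother = c(NA, NA, rep("I-1", n)),
    sex = c("female", "male",
            rep(c("female", "male"), length.out = n)),
    role = c("carrier", "unknown", unname(roles[kids])),
    sample_available = !(ids %in% cfg$sample_unavailable),
    name = "SIMFAM"
  )
}

empty_variant_row <- function(members) {
  row <- list(id = NA_character_, chrom = NA_character_, pos = NA_integer_,
              ref = NA_character_, alt = NA_character_, qual = NA_real_,
              filter_pass = NA, gene = NA_character_,
              consequence = NA_character_,
              maf_1kg = NA_real_, maf_exac_nontcga = NA_real_,
              cadd_phred = NA_real_, gerp = NA_real_, phastcons = NA_real_,
              phylop = NA_real_)
  for (p in predictor_tools()) row[[p]] <- NA_character_
  for (s in members) row[[paste0("gt_", s)]] <- NA_integer_
  for (s in members) row[[paste0("dp_", s)]] <- NA_integer_
  row
}

#' Plant the causal variant
#'
#' Constructs a heterozygous dominant variant carried by the untyped father
#' founder and transmitted so that every genotyped case is heterozygous and
#' every genotyped control is wild-type; carrier-role children receive the
#' allele with Mendelian probability 1/2. Annotation values are drawn above
#' every cascade gate (novel in both MAF sources, QUAL/depth above the
#' quality gate, CADD/conservation above threshold, at least 60% of ten
#' available predictor calls deleterious), so the variant survives the
#' default cascade by construction.
#'
#' @param ped Pedigree from [simulate_family()].
#' @param cfg A [sim_config()].
#' @return A one-row `variant_table`.
#' @export
plant_causal_variant <- function(ped, cfg = sim_config()) {
  founders <- ped$id[is.na(ped$father)]
  if (length(founders) != 2L) stop("template requires exactly two founders")
  carrier_founder <- founders[2]
  other_founder <- founders[1]
  f_role <- ped$role[ped$id == carrier_founder]
  f_sampled <- ped$sample_available[ped$id == carrier_founder]
  if (f_role == "control" && f_sampled) {
    stop("role constraints unsatisfiable: the transmitting founder is a genotyped control")
  }
  o_role <- ped$role[ped$id == other_founder]
  if (o_role == "case") {
    stop("role constraints unsatisfiable: the non-carrier founder is a case")
  }
  members <- ped$id[ped$sample_available]
  with_seed(substream_seed(cfg$seed, 0L), {
    row <- empty_variant_row(members)
    row$id <- "planted"
    row$chrom <- "7"
    row$pos <- sample.int(1e8L, 1L)
    row$ref <- "G"
    row$alt <- "T"
    row$qual <- round(stats::rlnorm(1, log(200), 0.3), 2)
    row$filter_pass <- TRUE
    row$gene <- cfg$causal_gene
    row$consequence <- "missense"
    row$maf_1kg <- NA_real_
    row$maf_exac_nontcga <- NA_real_
    row$cadd_phred <- max(15, stats::rnorm(1, cfg$cadd$mean1, cfg$cadd$sd1))
    row$gerp <- max(2.5, stats::rnorm(1, cfg$gerp$mean1, cfg$gerp$sd1))
    row$phastcons <- max(0.5, stats::rbeta(1, cfg$phastcons$shape1_1,
                                           cfg$phastcons$shape2_1))
    row$phylop <- max(3.5, stats::rnorm(1, cfg$phylop$mean1, cfg$phylop$sd1))
    calls <- ifelse(stats::runif(10) < cfg$predictor$p_del_true, "D", "T")
    need <- ceiling(0.6 * 10)
    short <- need - sum(calls == "D")
    if (short > 0) calls[which(calls == "T")[seq_len(short)]] <- "D"
    for (k in seq_along(predictor_tools())) {
      row[[predictor_tools()[k]]] <- calls[k]
    }
    dose <- stats::setNames(rep(NA_integer_, length(members)), members)
    for (s in members) {
      role <- ped$role[ped$id == s]
      is_child <- !is.na(ped$father[ped$id == s])
      dose[s] <- if (s == carrier_founder) {
        1L
      } else if (!is_child) {
        0L # the non-transmitting founder is wild-type
      } else if (role == "case") {
        1L
      } else if (role == "control") {
        0L
      } else {
        stats::rbinom(1, 1, 0.5) # Mendelian coin from the het father
      }
      row[[paste0("gt_", s)]] <- dose[[s]]
      row[[paste0("dp_", s)]] <- 20L + stats::rpois(1, cfg$depth_lambda)
    }
    variant_table(as.data.frame(row, check.names = FALSE,
                                stringsAsFactors = FALSE), ped)
  })
}

#' Simulate background variants
#'
#' Genotypes are independent of phenotype: founder genotypes follow
#' Hardy-Weinberg at a frequency drawn from the configured spectrum and
#' children follow Mendelian transmission from the founders. Annotation
#' scores are drawn from the configured distributions conditioned on a
#' latent deleteriousness indicator; the ten predictor calls are
#' conditionally independent given that indicator. MAF sources report the
#' true frequency when observed. Each variant uses its own deterministic
#' substream, so variant i is identical regardless of `n_background`.
#'
#' @param ped Pedigree from [simulate_family()].
#' @param cfg A [sim_config()].
#' @return A `variant_table` with `cfg$n_background` rows.
#' @export
simulate_background <- function(ped, cfg = sim_config()) {
  n <- cfg$n_background
  members <- ped$id[ped$sample_available]
  founders <- ped$id[is.na(ped$father)]
  kids <- ped$id[!is.na(ped$father)]
  n_kids <- length(kids)
  template <- empty_variant_row(members)
  cols <- lapply(template, function(v) rep(v, length.out = max(n, 0L)))
  if (n == 0L) {
    df <- as.data.frame(
      lapply(template, function(v) v[0]),
      check.names = FALSE, stringsAsFactors = FALSE)
    return(variant_table(df, ped))
  }
  tools <- predictor_tools()
  csq <- names(cfg$consequence_probs)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    with_seed(substream_seed(cfg$seed, i), {
      af <- sample(cfg$af_values, 1L, prob = cfg$af_weights)
      g_founder <- stats::rbinom(2L, 2L, af) # HWE founder dosages
      gt <- stats::setNames(integer(2 + n_kids), c(founders, kids))
      gt[founders] <- g_founder
      if (n_kids > 0) {
        gt[kids] <- stats::rbinom(n_kids, 1L, g_founder[1] / 2) +
          stats::rbinom(n_kids, 1L, g_founder[2] / 2)
      }
      miss <- stats::runif(2) < cfg$maf_missing
      qual <- stats::rlnorm(1, cfg$qual_meanlog, cfg$qual_sdlog)
      depth <- stats::rpois(length(members), cfg$depth_lambda)
      pass <- stats::runif(1) < cfg$caller_pass_prob
      d <- stats::runif(1) < cfg$p_deleterious
      cadd_v <- if (d) stats::rnorm(1, cfg$cadd$mean1, cfg$cadd$sd1) else
        stats::rnorm(1, cfg$cadd$mean0, cfg$cadd$sd0)
      gerp_v <- if (d) stats::rnorm(1, cfg$gerp$mean1, cfg$gerp$sd1) else
        stats::rnorm(1, cfg$gerp$mean0, cfg$gerp$sd0)
      pc_v <- if (d) stats::rbeta(1, cfg$phastcons$shape1_1,
                                  cfg$phastcons$shape2_1) else
        stats::rbeta(1, cfg$phastcons$shape1_0, cfg$phastcons$shape2_0)
      pp_v <- if (d) stats::rnorm(1, cfg$phylop$mean1, cfg$phylop$sd1) else
        stats::rnorm(1, cfg$phylop$mean0, cfg$phylop$sd0)
      score_miss <- stats::runif(4) < c(cfg$cadd$missing, cfg$gerp$missing,
                                        cfg$phastcons$missing,
                                        cfg$phylop$missing)
      theta <- if (d) cfg$predictor$p_del_true else cfg$predictor$p_del_null
      call_miss <- stats::runif(10) < cfg$predictor$missing
      call_del <- stats::runif(10) < theta
      calls <- ifelse(call_miss, NA_character_,
                      ifelse(call_del, "D", "T"))
      conseq <- sample(csq, 1L, prob = cfg$consequence_probs)
      chrom <- as.character(sample.int(22L, 1L))
      pos <- sample.int(1e8L, 1L)
      ra <- sample(bases, 2L)
      gene <- sprintf("SYNGENE%04d", sample.int(2000L, 1L))

      cols$id[i] <- sprintf("bg%06d", i)
      cols$chrom[i] <- chrom
      cols$pos[i] <- pos
      cols$ref[i] <- ra[1]
      cols$alt[i] <- ra[2]
      cols$qual[i] <- qual
      cols$filter_pass[i] <- pass
      cols$gene[i] <- gene
      cols$consequence[i] <- conseq
      cols$maf_1kg[i] <- if (miss[1]) NA_real_ else af
      cols$maf_exac_nontcga[i] <- if (miss[2]) NA_real_ else af
      cols$cadd_phred[i] <- if (score_miss[1]) NA_real_ else cadd_v
      cols$gerp[i] <- if (score_miss[2]) NA_real_ else gerp_v
      cols$phastcons[i] <- if (score_miss[3]) NA_real_ else pc_v
      cols$phylop[i] <- if (score_miss[4]) NA_real_ else pp_v
      for (k in seq_along(tools)) cols[[tools[k]]][i] <- calls[k]
      for (s in members) cols[[paste0("gt_", s)]][i] <- gt[[s]]
      for (k in seq_along(members)) {
        cols[[paste0("dp_", members[k])]][i] <- depth[k]
      }
    })
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  variant_table(df, ped)
}

#' Simulate a complete study
#'
#' Generates the pedigree, the background variants and the planted causal
#' variant (appended as the last row, id `"planted"`). When `dir` is given,
#' writes `family.ped`, `variants.tsv`, optionally `variants.vcf`, and a
#' deterministic `sim_manifest.json` (configuration + canonical hash).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @param write_vcf Also emit the VCF dialect.
#' @return List with `pedigree`, `variants`, `config` and (when written)
#'   `dir`.
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL,
                           write_vcf = FALSE) {
  ped <- simulate_family(cfg)
  bg <- simulate_background(ped, cfg)
  planted <- plant_causal_variant(ped, cfg)
  vt <- rbind(bg, planted)
  class(vt) <- c("variant_table", "data.frame")
  out <- list(pedigree = ped, variants = vt, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_ped(ped, file.path(dir, "family.ped"))
    write_variant_tsv(vt, file.path(dir, "variants.tsv"))
    if (write_vcf) write_variant_vcf(vt, file.path(dir, "variants.vcf"))
    manifest <- list(tool = "varfunnel::simulate_study",
                     version = as.character(utils::packageVersion("varfunnel")),
                     config = canonicalize(unclass(cfg)),
                     config_hash = config_hash(cfg))
    jsonlite::write_json(manifest, file.path(dir, "sim_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$dir <- dir
  }
  out
}
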