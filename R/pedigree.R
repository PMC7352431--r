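# Pedigree representation, phenotype roles, and co-segregation logic.
#
# A pedigree is a data.frame (class "pedigree_fam") with one row per member:
#   id, father, mother (NA for founders), sex, role, sample_available,
#   generation (computed). Roles drive the segregation filter:
#   case    -- must carry the allele (dominant model),
#   control -- must not carry,
#   carrier -- intermediate phenotype, unconstrained either way,
#   unknown -- unconstrained.

PED_ROLES <- c("case", "carrier", "control", "unknown")
PED_SEXES <- c("male", "female", "unknown")

#' Construct a pedigree
#'
#' @param id Character vector of unique member labels (e.g. `"II-2"`).
#' @param father,mother Parent ids; both `NA` (or `"0"`) for founders. A
#'   member has either zero or two known parents.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param role Phenotype role: `"case"`, `"carrier"` (intermediate phenotype,
#'   unconstrained), `"control"` or `"unknown"`.
#' @param sample_available Logical; whether a genotypable sample exists.
#' @param name Family name.
#' @return A `pedigree_fam` data.frame with a computed `generation` column
#'   (founders are generation 1; every child's generation exceeds its
#'   parents').
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", role = "unknown",
                     sample_available = TRUE, name = "FAM") {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    father = rep_len(as.character(father), n),
    mother = rep_len(as.character(mother), n),
    sex = rep_len(as.character(sex), n),
    role = rep_len(as.character(role), n),
    sample_available = rep_len(as.logical(sample_available), n),
    stringsAsFactors = FALSE
  )
  df$father[df$father %in% c("0", "")] <- NA_character_
  df$mother[df$mother %in% c("0", "")] <- NA_character_

  if (anyDuplicated(df$id)) {
    stop("duplicate member ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (!all(df$sex %in% PED_SEXES)) {
    stop("sex must be one of: ", paste(PED_SEXES, collapse = ", "))
  }
  if (!all(df$role %in% PED_ROLES)) {
    stop("role must be one of: ", paste(PED_ROLES, collapse = ", "))
  }
  half <- xor(is.na(df$father), is.na(df$mother))
  if (any(half)) {
    stop("members must have zero or two known parents: ",
         paste(df$id[half], collapse = ", "))
  }
  known <- c(stats::na.omit(df$father), stats::na.omit(df$mother))
  if (!all(known %in% df$id)) {
    stop("parent ids not in pedigree: ",
         paste(setdiff(known, df$id), collapse = ", "))
  }

  df$generation <- compute_generations(df)
  attr(df, "family") <- name
  class(df) <- c("pedigree_fam", "data.frame")
  df
}

# Founders are generation 1; children get max(parent generations) + 1.
# Failure to resolve all members indicates a cycle.
compute_generations <- function(df) {
  gen <- ifelse(is.na(df$father) & is.na(df$mother), 1L, NA_integer_)
  names(gen) <- df$id
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      gf <- gen[df$father[i]]
      gm <- gen[df$mother[i]]
      if (!is.na(gf) && !is.na(gm)) {
        gen[i] <- max(gf, gm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) {
      stop("pedigree contains a relationship cycle involving: ",
           paste(df$id[is.na(gen)], collapse = ", "))
    }
  }
  unname(gen)
}

#' @export
print.pedigree_fam <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d members (%d genotypable)\n",
              attr(x, "family") %||% "FAM", nrow(x), sum(x$sample_available)))
  tab <- table(factor(x$role, levels = PED_ROLES))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read a pedigree from an extended PED file
#'
#' Expects tab- or whitespace-separated text with the six classic PED
#' columns (family, id, father, mother, sex, phenotype) extended by a 7th
#' `role` column (`case`/`carrier`/`control`/`unknown`) and an optional 8th
#' 0/1 `sample` column marking whether a genotypable sample exists (assumed
#' 1 when absent). `"0"` denotes an unknown parent; sex is coded 1 = male,
#' 2 = female, 0 = unknown. Lines starting with `#` are ignored.
#'
#' @param path Path to the PED file.
#' @return A [pedigree()] object.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty PED file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  ncols <- lengths(fields)
  if (any(ncols < 7L)) {
    stop("PED line(s) with fewer than 7 columns: line ",
         paste(which(ncols < 7L), collapse = ", "))
  }
  m <- do.call(rbind, lapply(fields, function(f) {
    length(f) <- 8L
    f
  }))
  fam <- m[, 1]
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[m[, 5]]
  sex[is.na(sex)] <- "unknown"
  samp <- ifelse(is.na(m[, 8]), TRUE, m[, 8] != "0")
  pedigree(
    id = m[, 2], father = m[, 3], mother = m[, 4],
    sex = unname(sex), role = m[, 7], sample_available = samp,
    name = fam[1]
  )
}

#' Write a pedigree to an extended PED file
#'
#' Inverse of [read_ped()]; always writes the 8-column dialect.
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree_fam"))
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  phen <- ifelse(ped$role == "case", "2",
                 ifelse(ped$role == "control", "1", "0"))
  lines <- paste(attr(ped, "family") %||% "FAM", ped$id,
                 ifelse(is.na(ped$father), "0", ped$father),
                 ifelse(is.na(ped$mother), "0", ped$mother),
                 sexcode, phen, ped$role,
                 ifelse(ped$sample_available, "1", "0"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Coerce to a genotype vector
#'
#' A genotype vector maps member ids to alternate-allele dosages 0, 1, 2 or
#' `NA` (missing). Members absent from the vector are treated as missing.
#'
#' @param gv Named numeric/integer vector of dosages.
#' @param ped Pedigree the members must belong to.
#' @return Named integer vector over all pedigree ids (absent members `NA`).
#' @export
as_genotype_vector <- function(gv, ped) {
  stopifnot(inherits(ped, "pedigree_fam"))
  if (is.null(names(gv)) && length(gv)) {
    stop("genotype vector must be named by member id")
  }
  bad <- setdiff(names(gv), ped$id)
  if (length(bad)) {
    stop("genotype vector has ids not in the pedigree: ",
         paste(bad, collapse = ", "))
  }
  vals <- suppressWarnings(as.integer(gv))
  if (any(!is.na(vals) & !(vals %in% 0:2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  out <- rep(NA_integer_, nrow(ped))
  names(out) <- ped$id
  out[names(gv)] <- vals
  out
}

#' Classify pedigree co-segregation of a variant
#'
#' Under the autosomal dominant model a variant segregates with disease when
#' every case with a non-missing genotype carries at least one alternate
#' allele and every control with a non-missing genotype carries none.
#' Carrier-role (intermediate phenotype) and unknown-role members impose no
#' constraint; missing genotypes impose no constraint but are counted.
#'
#' @param gv Genotype vector (see [as_genotype_vector()]).
#' @param ped A [pedigree()] containing at least one case.
#' @param model Inheritance model; only `"dominant"` is implemented.
#' @return A `segregation_decision` list: `pass`, `n_case_carriers`,
#'   `n_control_carriers`, `n_missing` (missing genotypes among
#'   constraint-bearing case/control members).
#' @export
classify_segregation <- function(gv, ped, model = "dominant") {
  model <- match.arg(model, "dominant")
  dos <- as_genotype_vector(gv, ped)
  role <- ped$role
  is_case <- role == "case"
  is_ctrl <- role == "control"
  if (!any(is_case)) stop("pedigree has no case member")
  case_d <- dos[is_case]
  ctrl_d <- dos[is_ctrl]
  if (all(is.na(case_d))) {
    stop("uninformative variant: no case with a non-missing genotype")
  }
  pass <- all(case_d[!is.na(case_d)] >= 1L) &&
    (!length(ctrl_d) || all(ctrl_d[!is.na(ctrl_d)] == 0L))
  structure(
    list(
      pass = pass,
      n_case_carriers = sum(case_d >= 1L, na.rm = TRUE),
      n_control_carriers = sum(ctrl_d >= 1L, na.rm = TRUE),
      n_missing = sum(is.na(case_d)) + sum(is.na(ctrl_d))
    ),
    class = "segregation_decision"
  )
}

#' @export
print.segregation_decision <- function(x, ...) {
  cat(sprintf(
    "Segregation: %s (case carriers: %d, control carriers: %d, missing: %d)\n",
    if (x$pass) "PASS" else "FAIL",
    x$n_case_carriers, x$n_control_carriers, x$n_missing))
  invisible(x)
}

# Vectorized dominant-model segregation over a dosage matrix
# (rows = variants, columns named by member id). Uninformative variants
# (no genotyped case) are FALSE rather than an error, for use inside the
# cascade. Returns a logical vector.
segregation_pass_matrix <- function(dosage, ped) {
  stopifnot(is.matrix(dosage))
  case_ids <- intersect(colnames(dosage), ped$id[ped$role == "case"])
  ctrl_ids <- intersect(colnames(dosage), ped$id[ped$role == "control"])
  if (!length(case_ids)) return(rep(FALSE, nrow(dosage)))
  cd <- dosage[, case_ids, drop = FALSE]
  informative <- rowSums(!is.na(cd)) >= 1L
  cases_ok <- rowSums(cd < 1L, na.rm = TRUE) == 0L
  if (length(ctrl_ids)) {
    kd <- dosage[, ctrl_ids, drop = FALSE]
    ctrls_ok <- rowSums(kd >= 1L, na.rm = TRUE) == 0L
  } else {
    ctrls_ok <- rep(TRUE, nrow(dosage))
  }
  informative & cases_ok & ctrls_ok
}

# Dosages a child can have given parental dosages (NULL when unconstrained).
mendel_possible <- function(gf, gm) {
  alleles <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  unique(as.vector(outer(alleles[[gf + 1L]], alleles[[gm + 1L]], `+`)))
}

#' List Mendelian-inheritance violations
#'
#' Checks every parent-offspring trio in which all three genotypes are
#' non-missing; a trio violates Mendelian transmission when the child's
#' dosage cannot arise from any combination of parental gametes. Trios with
#' any missing genotype are unconstrained (an untyped parent can always be
#' assigned a compatible genotype).
#'
#' @param gv Genotype vector.
#' @param ped A [pedigree()].
#' @return A data.frame of violations with columns `child`, `father`,
#'   `mother`, `child_dosage`, `father_dosage`, `mother_dosage`; zero rows
#'   when the variant is Mendelian-consistent.
#' @export
mendelian_consistency <- function(gv, ped) {
  dos <- as_genotype_vector(gv, ped)
  out <- list()
  for (i in seq_len(nrow(ped))) {
    f <- ped$father[i]
    m <- ped$mother[i]
    if (is.na(f) || is.na(m)) next
    dc <- dos[ped$id[i]]
    df_ <- dos[f]
    dm <- dos[m]
    if (is.na(dc) || is.na(df_) || is.na(dm)) next
    if (!(dc %in% mendel_possible(df_, dm))) {
      out[[length(out) + 1L]] <- data.frame(
        child = ped$id[i], father = f, mother = m,
        child_dosage = dc, father_dosage = df_, mother_dosage = dm,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(child = character(), father = character(), mother = character(),
               child_dosage = integer(), father_dosage = integer(),
               mother_dosage = integer(), stringsAsFactors = FALSE)
  }
}
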