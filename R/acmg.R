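# Generic ACMG/AMP 2015 evidence combiner. The combining table ships as a
# structured-text fixture (inst/extdata/acmg_combining_rules.json) mapping
# evidence-strength counts to the five classification tiers.

ACMG_CLASSES <- c("Benign", "Likely benign", "VUS", "Likely pathogenic",
                  "Pathogenic")

#' Valid ACMG evidence codes
#'
#' @return Character vector of the 28 recognized codes (PVS1, PS1-PS4,
#'   PM1-PM6, PP1-PP5, BA1, BS1-BS4, BP1-BP7).
#' @export
acmg_codes <- function() {
  c("PVS1",
    paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

acmg_strength <- function(codes) {
  sub("[0-9]+$", "", codes)
}

#' Load the ACMG combining rule table
#'
#' @param path Path to a combining-rules JSON file; defaults to the table
#'   packaged with varfunnel (ACMG/AMP 2015 standard combinations).
#' @return A named list of combination requirement lists per class.
#' @export
acmg_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "acmg_combining_rules.json",
                        package = "varfunnel", mustWork = TRUE)
  }
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(is.list(rules$combinations))
  rules
}

#' Combine ACMG evidence codes into a five-tier classification
#'
#' Counts codes by strength category (PVS, PS, PM, PP, BA, BS, BP) and
#' matches them against the packaged combining table. When both a
#' pathogenic-side and a benign-side combination are met the evidence is
#' contradictory and the call is `"VUS"`; with no combination met the call
#' is also `"VUS"`.
#'
#' @param codes Character vector of evidence codes (set semantics;
#'   duplicates collapse). Unknown codes are an error.
#' @param rules Combining table from [acmg_rules()].
#' @return One of `"Pathogenic"`, `"Likely pathogenic"`, `"VUS"`,
#'   `"Likely benign"`, `"Benign"`.
#' @export
combine_evidence <- function(codes, rules = acmg_rules()) {
  codes <- unique(as.character(codes))
  codes <- codes[nzchar(codes)]
  unknown <- setdiff(codes, acmg_codes())
  if (length(unknown)) {
    stop("unknown ACMG evidence code(s): ", paste(unknown, collapse = ", "))
  }
  counts <- table(factor(acmg_strength(codes),
                         levels = c("PVS", "PS", "PM", "PP",
                                    "BA", "BS", "BP")))
  met <- function(class) {
    combos <- rules$combinations[[class]]
    if (is.null(combos)) return(FALSE)
    any(vapply(combos, function(req) {
      all(vapply(names(req), function(strength) {
        counts[[strength]] >= req[[strength]]
      }, logical(1)))
    }, logical(1)))
  }
  path_side <- met("Pathogenic") || met("Likely pathogenic")
  benign_side <- met("Benign") || met("Likely benign")
  if (path_side && benign_side) return("VUS")
  if (met("Pathogenic")) return("Pathogenic")
  if (met("Likely pathogenic")) return("Likely pathogenic")
  if (met("Benign")) return("Benign")
  if (met("Likely benign")) return("Likely benign")
  "VUS"
}
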