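# Shared constants and small internal helpers.

#' Names of the ten deleteriousness predictors
#'
#' Column names used for the per-variant categorical predictor calls
#' (dbNSFP-style). Calls take the values `"D"` (deleterious), `"T"`
#' (tolerated) or `NA` (no call).
#'
#' @return Character vector of length 10.
#' @export
predictor_tools <- function() {
  c("sift", "polyphen2_hdiv", "polyphen2_hvar", "lrt",
    "mutation_taster", "mutation_assessor", "fathmm",
    "metasvm", "metalr", "provean")
}

#' Recognized consequence classes
#'
#' @return Character vector of the consequence labels a variant table may
#'   carry.
#' @export
consequence_classes <- function() {
  c("synonymous", "missense", "nonsense", "splice",
    "frameshift", "inframe_indel", "other")
}

# Consequences considered protein/coding-altering (eligible for gene rescue
# and, by default, for the consensus vote stage).
coding_altering <- function() {
  setdiff(consequence_classes(), c("synonymous", "other"))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-item substream seed (Lehmer-style mixing, kept < 2^31 so
# it is always a valid R integer seed). Item i's stream does not depend on
# how many items are drawn in total.
substream_seed <- function(seed, i) {
  s <- as.double(abs(as.integer(seed)) %% 2147483647L)
  as.integer((s * 48271 + as.double(i) * 7919 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format numbers for text output so a read round-trips bit-identically:
# 17 significant digits uniquely identify a double.
fmt_num <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}

fmt_int <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%d", as.integer(x[ok]))
  out
}

fmt_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "."
  x
}

# Recursively sort list names so that semantically equal configurations
# serialize identically regardless of key order.
canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    x <- lapply(x, canonicalize)
  }
  x
}

#' Stable hash of a configuration object
#'
#' Serializes the object to canonical JSON (keys sorted recursively) and
#' returns its MD5 digest, so the hash is invariant under key reordering.
#'
#' @param x A list-like configuration object.
#' @return A character MD5 digest.
#' @export
config_hash <- function(x) {
  x <- canonicalize(unclass(x))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}
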