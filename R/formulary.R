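## Formulary: canonical molecule -> (drug_class, drug_group) catalogue with
## available tablet strengths. Every downstream stage classifies dispensings
## through it; unknown molecules are a hard error, never silently dropped.

.parse_strengths <- function(s) {
  lapply(strsplit(as.character(s), ";", fixed = TRUE), function(x) {
    v <- suppressWarnings(as.numeric(trimws(x)))
    v
  })
}

#' Read a formulary catalogue from CSV
#'
#' The CSV must have columns `molecule`, `drug_class`, `drug_group` and
#' `strengths` (semicolon-separated available tablet strengths in mg, in
#' strictly increasing order). Molecules are matched case-insensitively
#' after trimming whitespace, and must be unique.
#'
#' Recognised `drug_class` values are the antidepressant classes in
#' [AD_CLASSES] plus `antipsychotic` and `mood_stabiliser`; `drug_group`
#' must be consistent with the class (antidepressant classes belong to the
#' `antidepressant` group, and the antipsychotic / mood-stabiliser classes
#' to their same-named groups). Mood stabilisers (lithium and friends) can
#' be loaded and classified, but are never counted as antidepressants by
#' any downstream rule.
#'
#' @param path Path to the formulary CSV.
#' @return A `formulary` object (a validated data frame with a
#'   `strengths_mg` list column).
#' @seealso [default_formulary()], [classify()]
#' @export
read_formulary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule", "drug_class", "drug_group", "strengths")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("formulary CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  molecule <- trimws(df$molecule)
  key <- tolower(molecule)
  if (anyDuplicated(key)) {
    dup <- unique(molecule[duplicated(key)])
    stop("duplicate molecule(s) in formulary: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_cl <- setdiff(unique(df$drug_class), .ALL_CLASSES)
  if (length(bad_cl)) {
    stop("unknown drug_class label(s): ", paste(bad_cl, collapse = ", "),
         call. = FALSE)
  }
  bad_gr <- setdiff(unique(df$drug_group), .DRUG_GROUPS)
  if (length(bad_gr)) {
    stop("unknown drug_group label(s): ", paste(bad_gr, collapse = ", "),
         call. = FALSE)
  }
  want_group <- ifelse(df$drug_class %in% AD_CLASSES, "antidepressant",
                       df$drug_class)
  if (any(want_group != df$drug_group)) {
    off <- molecule[want_group != df$drug_group]
    stop("drug_class/drug_group mismatch for: ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  str_mg <- .parse_strengths(df$strengths)
  ok <- vapply(str_mg, function(v) {
    length(v) > 0L && !anyNA(v) && all(v > 0) && all(diff(v) > 0)
  }, logical(1L))
  if (!all(ok)) {
    stop("strengths must be positive and strictly increasing for: ",
         paste(molecule[!ok], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(molecule = molecule, molecule_key = key,
                    drug_class = df$drug_class, drug_group = df$drug_group,
                    stringsAsFactors = FALSE)
  out$strengths_mg <- str_mg
  class(out) <- c("formulary", "data.frame")
  out
}

#' Illustrative default formulary
#'
#' Ships with the package for examples and simulation. It covers the
#' antidepressant classes marketed in Australia (one row per molecule, with
#' representative tablet strengths), a small set of antipsychotics and the
#' common mood stabilisers. It is an illustrative catalogue, not an
#' authoritative national formulary: in particular the antipsychotic list
#' is a stand-in and real analyses should load their own catalogue with
#' [read_formulary()].
#'
#' @return A `formulary` object.
#' @export
default_formulary <- function() {
  read_formulary(system.file("extdata", "formulary.csv", package = "rxlines",
                             mustWork = TRUE))
}

#' Classify molecules against a formulary
#'
#' Deterministic, case-insensitive lookup of `drug_class` and `drug_group`.
#' Any molecule absent from the formulary raises an error naming the
#' unclassified molecules; dispensings are never silently dropped.
#'
#' @param molecule Character vector of molecule names.
#' @param formulary A `formulary` object.
#' @return A data frame with columns `molecule`, `drug_class`, `drug_group`
#'   (one row per input element, in order).
#' @export
classify <- function(molecule, formulary) {
  stopifnot(inherits(formulary, "formulary"))
  key <- tolower(trimws(as.character(molecule)))
  idx <- match(key, formulary$molecule_key)
  if (anyNA(idx)) {
    unk <- unique(molecule[is.na(idx)])
    stop("unclassified molecule(s), not in formulary: ",
         paste(unk, collapse = ", "), call. = FALSE)
  }
  data.frame(molecule = as.character(molecule),
             drug_class = formulary$drug_class[idx],
             drug_group = formulary$drug_group[idx],
             stringsAsFactors = FALSE)
}

## Strength ladder lookup used by the simulator.
.strengths_of <- function(formulary, molecule) {
  idx <- match(tolower(trimws(molecule)), formulary$molecule_key)
  formulary$strengths_mg[[idx]]
}

#' @export
print.formulary <- function(x, ...) {
  cat("<formulary> ", nrow(x), " molecules: ",
      sum(x$drug_group == "antidepressant"), " antidepressant, ",
      sum(x$drug_group == "antipsychotic"), " antipsychotic, ",
      sum(x$drug_group == "mood_stabiliser"), " mood stabiliser\n", sep = "")
  tab <- table(x$drug_class[x$drug_group == "antidepressant"])
  cat("  antidepressant classes:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}
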