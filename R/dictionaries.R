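#' Normalize a drug name for dictionary lookup
#'
#' Trim, upper-case, collapse internal whitespace, and strip trailing
#' dose tokens ("20MG", "10 MG", "0.5 ML", "40MG TABLET"). The same
#' normalization is applied when the dictionary is built and when a name
#' is looked up, so matching is exact-after-normalization; there is no
#' fuzzy matching (a false exposure is worse than a missed one here).
#'
#' @param x character vector of verbatim drug names.
#' @return normalized names.
#' @examples
#' normalize_drug_name("  Atorvastatin Calcium 20MG ") # "ATORVASTATIN CALCIUM"
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  dose_token <- "([0-9]+(\\.[0-9]+)?[[:space:]]*(MG|MCG|G|ML|IU)|TABLET(S)?|CAPSULE(S)?)"
  repeat {
    x2 <- sub(paste0("[[:space:]]+", dose_token, "$"), "", x)
    if (identical(x2, x)) break
    x <- x2
  }
  trimws(x)
}

#' Read a drug dictionary (name to ATC code)
#'
#' Two-column TSV with header `name`, `atc_code`. Names are normalized with
#' [normalize_drug_name()] at build time.
#'
#' @param path TSV path; defaults to the dictionary bundled with the
#'   package (generic names plus common brand synonyms).
#' @return a `drug_dictionary` object (named character vector of ATC codes).
#' @export
read_drug_dictionary <- function(path = default_dictionary_path()) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character", showProgress = FALSE)
  stopifnot(all(c("name", "atc_code") %in% names(d)))
  if (nrow(d) == 0L) stop("drug dictionary is empty: ", path)
  entries <- setNames(d$atc_code, normalize_drug_name(d$name))
  structure(entries, class = "drug_dictionary")
}

#' @rdname read_drug_dictionary
#' @export
default_dictionary_path <- function() {
  system.file("extdata", "atc_dictionary.tsv", package = "faersignal",
              mustWork = TRUE)
}

#' Resolve a verbatim drug name to an ATC code
#'
#' @param drug_name character vector of verbatim names.
#' @param dictionary a [read_drug_dictionary()] object.
#' @return character vector of ATC codes, NA where the name is not in the
#'   dictionary.
#' @examples
#' dict <- read_drug_dictionary()
#' resolve_drug("ATORVASTATIN CALCIUM 20MG", dict) # "C10AA05"
#' resolve_drug("IBUPROFEN", dict)                 # "M01AE01"
#' @export
resolve_drug <- function(drug_name, dictionary) {
  stopifnot(inherits(dictionary, "drug_dictionary"), length(dictionary) > 0)
  ## normalize each distinct verbatim name once; drug columns repeat heavily
  u <- unique(drug_name)
  res <- unname(unclass(dictionary)[normalize_drug_name(u)])
  as.character(res[match(drug_name, u)])
}

#' Read a PT-to-SOC mapping table
#'
#' Four-column TSV: `pt_code`, `pt_name`, `soc_code`, `soc_name`. Each PT
#' maps to exactly one SOC (primary-SOC convention; multi-axial linkage is
#' out of scope). The bundled file is a constructed stand-in for the
#' licensed MedDRA dictionary — adequate for synthetic data and for wiring
#' a real MedDRA export in the same format.
#'
#' @param path TSV path; defaults to the bundled synthetic map.
#' @return a `meddra_map` data.frame.
#' @export
read_meddra_map <- function(path = default_meddra_path()) {
  m <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = c("pt_name", "soc_name"),
                                           integer = c("pt_code", "soc_code")),
                         showProgress = FALSE)
  stopifnot(all(c("pt_code", "pt_name", "soc_code", "soc_name") %in% names(m)))
  if (anyDuplicated(m$pt_code)) {
    stop("PT->SOC map violates the primary-SOC convention: duplicated pt_code")
  }
  m <- as.data.frame(m)
  class(m) <- c("meddra_map", class(m))
  m
}

#' @rdname read_meddra_map
#' @export
default_meddra_path <- function() {
  system.file("extdata", "meddra_pt_soc_synthetic.tsv",
              package = "faersignal", mustWork = TRUE)
}

## internal: pt name (case-insensitive) -> pt_code lookup
pt_code_from_name <- function(pt_name, map) {
  idx <- match(toupper(trimws(pt_name)), toupper(map$pt_name))
  map$pt_code[idx]
}
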