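## The public FAERS ASCII dialect: "$"-delimited, no quoting, one header row.
## Column order is header-driven; extra columns are carried along untouched.

.faers_schemas <- list(
  DEMO = list(
    required = c("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod"),
    integer = c("primaryid", "caseid"),
    numeric = "age"
  ),
  DRUG = list(
    required = c("primaryid", "drug_seq", "role_cod", "drugname"),
    integer = c("primaryid", "drug_seq"),
    numeric = character()
  ),
  REAC = list(
    required = c("primaryid", "pt"),
    integer = "primaryid",
    numeric = character()
  ),
  THER = list(
    required = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
    integer = c("primaryid", "dsg_drug_seq"),
    numeric = character()
  ),
  OUTC = list(
    required = c("primaryid", "outc_cod"),
    integer = "primaryid",
    numeric = character()
  ),
  ## schema stubs: readable, never analyzed
  RPSR = list(required = c("primaryid", "rpsr_cod"), integer = "primaryid",
              numeric = character()),
  INDI = list(required = c("primaryid", "indi_pt"), integer = "primaryid",
              numeric = character())
)

#' Table kinds understood by the FAERS readers
#' @return character vector of table kinds.
#' @export
faers_table_kinds <- function() names(.faers_schemas)

coerce_faers_types <- function(dt, kind) {
  sch <- .faers_schemas[[kind]]
  for (col in intersect(sch$integer, names(dt))) {
    ## lenient: unparseable ids/counts become NA, never an error
    suppressWarnings(data.table::set(dt, j = col,
                                     value = as.integer(dt[[col]])))
  }
  for (col in intersect(sch$numeric, names(dt))) {
    suppressWarnings(data.table::set(dt, j = col,
                                     value = as.numeric(dt[[col]])))
  }
  ## optional integer columns present in our normalized dialect
  if (kind == "REAC" && "pt_cod" %in% names(dt)) {
    suppressWarnings(data.table::set(dt, j = "pt_cod",
                                     value = as.integer(dt$pt_cod)))
  }
  dt
}

#' Read one FAERS-style "$"-delimited ASCII table
#'
#' The first line must be a "$"-delimited header; matching is
#' case-insensitive and order-independent. Numeric fields that do not parse
#' become NA (spontaneous-report extracts are dirty by nature and a single
#' malformed age must not abort a quarter). An empty file yields an empty
#' table of the right shape.
#'
#' @param path file path.
#' @param kind one of [faers_table_kinds()] ("DEMO", "DRUG", "REAC", "THER",
#'   "OUTC", plus the "RPSR"/"INDI" stubs).
#' @return data.frame with lower-case column names and typed key columns.
#' @export
read_faers_table <- function(path, kind) {
  kind <- toupper(kind)
  stopifnot(kind %in% names(.faers_schemas))
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- .faers_schemas[[kind]]

  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    out <- data.table::as.data.table(
      setNames(rep(list(character()), length(sch$required)), sch$required))
    return(as.data.frame(coerce_faers_types(out, kind)))
  }
  header <- tolower(trimws(strsplit(first, "$", fixed = TRUE)[[1]]))
  missing_cols <- setdiff(sch$required, header)
  if (length(missing_cols)) {
    stop("schema error in ", kind, " table '", path,
         "': missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- data.table::fread(path, sep = "$", quote = "", header = TRUE,
                          colClasses = "character", fill = TRUE,
                          na.strings = NULL, showProgress = FALSE)
  data.table::setnames(dt, tolower(names(dt)))
  dt <- coerce_faers_types(dt, kind)
  as.data.frame(dt)
}

#' Write a table in the FAERS ASCII dialect
#'
#' "$"-delimited, no quoting, header row from the column names. NA is
#' written as the empty string so [read_faers_table()] round-trips.
#'
#' @param x data.frame.
#' @param path output path.
#' @param kind table kind (checked against the schema's required columns).
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, kind) {
  kind <- toupper(kind)
  stopifnot(kind %in% names(.faers_schemas))
  missing_cols <- setdiff(.faers_schemas[[kind]]$required, tolower(names(x)))
  if (length(missing_cols)) {
    stop("cannot write ", kind, " table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data.table::fwrite(x, path, sep = "$", quote = FALSE, na = "",
                     col.names = TRUE)
  invisible(path)
}
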