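#' Table schemas used by the pipeline
#'
#' @format list mapping schema name to required column names and types.
#' @keywords internal
table_schemas <- function() {
  list(
    incidence = list(cols = c(sex = "character", cohort = "numeric",
                              age_low = "numeric", age_high = "numeric",
                              cases = "numeric", person_years = "numeric"),
                     key = c("sex", "cohort", "age_low")),
    census = list(cols = c(year = "numeric", sex = "character",
                           age = "numeric", person_years = "numeric"),
                  key = c("year", "sex", "age")),
    gerd = list(cols = c(sex = "character", age = "numeric",
                         prevalence = "numeric"),
                key = c("sex", "age")),
    screening = list(cols = c(age = "numeric", sex = "character",
                              gerd = "logical", be_found = "logical"),
                     key = NULL),
    histories = list(cols = c(id = "numeric", be_onset_age = "numeric",
                              be_length = "numeric", n_stem_cells = "numeric",
                              oac_detection_age = "numeric",
                              n_events = "numeric"),
                     key = "id")
  )
}

#' Read and validate a pipeline table from CSV
#'
#' Validates the required columns, their types and the schema's key
#' uniqueness and value invariants, naming the offending column or rows in
#' any error.
#'
#' @param path CSV file path (comma-separated, header row, UTF-8).
#' @param schema one of `"incidence"`, `"census"`, `"gerd"`, `"screening"`,
#'   `"histories"`.
#' @param strict if `TRUE`, unknown columns are rejected.
#' @return validated data frame.
#' @export
read_table <- function(path, schema, strict = FALSE) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas))
    stop("unknown schema '", schema, "'; valid: ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path, call. = FALSE)
  sch <- schemas[[schema]]
  missing <- setdiff(names(sch$cols), names(df))
  if (length(missing) > 0)
    stop("schema '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (strict) {
    extra <- setdiff(names(df), names(sch$cols))
    if (length(extra) > 0)
      stop("schema '", schema, "': unknown column(s) ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  for (col in names(sch$cols)) {
    want <- sch$cols[[col]]
    v <- df[[col]]
    if (want == "numeric" && !is.numeric(v))
      stop("schema '", schema, "': column '", col, "' must be numeric",
           call. = FALSE)
    if (want == "logical" && !is.logical(v)) {
      if (all(v %in% c("TRUE", "FALSE", 0, 1))) df[[col]] <- as.logical(v)
      else stop("schema '", schema, "': column '", col, "' must be logical",
                call. = FALSE)
    }
    if (want == "numeric" && anyNA(v))
      stop("schema '", schema, "': non-numeric or missing cell in column '",
           col, "' (rows ", paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           ")", call. = FALSE)
  }
  if (!is.null(sch$key)) {
    dup <- duplicated(df[, sch$key, drop = FALSE])
    if (any(dup))
      stop("schema '", schema, "': duplicate key (",
           paste(sch$key, collapse = ","), ") at rows ",
           paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  if (schema == "incidence") validate_incidence(df)
  if (schema == "census") validate_census(df)
  if (schema == "gerd" && any(df$prevalence < 0 | df$prevalence > 1))
    stop("gerd table: prevalence outside [0, 1]", call. = FALSE)
  df
}

#' Write a pipeline table to CSV
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_incidence <- function(df) {
  req <- c("sex", "cohort", "age_low", "age_high", "cases", "person_years")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("incidence table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$age_low >= df$age_high))
    stop("incidence table: age_low must be below age_high", call. = FALSE)
  if (any(df$cases < 0) || any(df$person_years <= 0))
    stop("incidence table: cases must be >= 0 and person_years > 0", call. = FALSE)
  if (any(df$cases / df$person_years >= 1))
    stop("incidence table: implied rate >= 1 case per person-year", call. = FALSE)
  key <- paste(df$sex, df$cohort, df$age_low)
  if (anyDuplicated(key))
    stop("incidence table: duplicate (sex, cohort, age bin) at rows ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  invisible(df)
}

validate_census <- function(df) {
  req <- c("year", "sex", "age", "person_years")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("census table: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$person_years < 0))
    stop("census table: person_years must be >= 0", call. = FALSE)
  key <- paste(df$year, df$sex, df$age)
  if (anyDuplicated(key))
    stop("census table: duplicate (year, sex, age) at rows ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Serialize a hazard curve to CSV
#'
#' Columns: `age`, `hazard`, `survival`, `be_prevalence_cancer_free`,
#' `incidence_per_100k`, `sex`, `cohort`, `subgroup`.
#'
#' @param curve a `hazard_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hazard_curve <- function(curve, path) {
  stopifnot(inherits(curve, "hazard_curve"))
  write_table(as.data.frame(curve), path)
}
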