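# Plain-text cohort I/O: header `subject_id,group,<marker1>,...`, comma- or
# tab-delimited, group as literal label strings.

#' Read a cohort table from CSV/TSV
#'
#' Expects a header `subject_id,group,<markers...>`; the delimiter is
#' taken from the file extension (`.tsv`/`.tab` = tab, otherwise comma)
#' unless given. Marker order is preserved from the header. Validation
#' failures (missing columns, non-numeric or missing concentrations,
#' unknown group values, duplicate subject ids) are reported with the
#' offending row/column named.
#'
#' @param path file path.
#' @param coding a [classCoding()]; the group column must only contain
#'   its two labels.
#' @param sep field delimiter, or `NULL` to infer from the extension.
#' @param ageColumn optional name of a numeric per-subject covariate
#'   column (e.g. `"age"`) to read into `colData` rather than the marker
#'   block.
#' @return a [BiomarkerCohort-class].
#' @export
readCohort <- function(path, coding = classCoding(), sep = NULL,
                       ageColumn = NULL) {
    if (!file.exists(path)) stop("cannot read cohort file: ", path)
    if (is.null(sep))
        sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t"
               else ","
    df <- read.csv(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
    required <- c("subject_id", "group")
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    markerCols <- setdiff(colnames(df), c(required, ageColumn))
    if (!length(markerCols)) stop("no marker columns found")
    if (anyDuplicated(df$subject_id))
        stop("duplicate subject id(s): ",
             paste(unique(df$subject_id[duplicated(df$subject_id)]),
                   collapse = ", "))
    bad <- setdiff(unique(df$group), c(coding$positive, coding$negative))
    if (length(bad))
        stop("unknown group value(s): ", paste(bad, collapse = ", "))
    X <- matrix(NA_real_, nrow(df), length(markerCols),
                dimnames = list(NULL, markerCols))
    for (j in seq_along(markerCols)) {
        raw <- df[[markerCols[j]]]
        v <- suppressWarnings(as.numeric(raw))
        if (anyNA(v)) {
            row <- which(is.na(v))[1L]
            stop("non-numeric or missing value '", raw[row],
                 "' in column '", markerCols[j], "', row ", row)
        }
        X[, j] <- v
    }
    cohort <- BiomarkerCohort(X, df$group, subjectIds = df$subject_id)
    if (!is.null(ageColumn)) {
        age <- suppressWarnings(as.numeric(df[[ageColumn]]))
        if (anyNA(age))
            stop("missing or non-numeric value in column '", ageColumn, "'")
        SummarizedExperiment::colData(cohort)[[ageColumn]] <- age
    }
    validObject(cohort)
    cohort
}

#' Write a cohort table as CSV/TSV
#'
#' Header `subject_id,group,<marker1>,...`; groups written as their
#' literal labels. The written file round-trips through [readCohort()].
#'
#' @param cohort a [BiomarkerCohort-class].
#' @param path file path; a `.tsv`/`.tab` extension switches to tabs.
#' @param digits significant digits written (default 17, lossless for
#'   doubles).
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, digits = 17) {
    stopifnot(is(cohort, "BiomarkerCohort"))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t"
           else ","
    X <- cohortMatrix(cohort)
    df <- data.frame(subject_id = colnames(cohort),
                     group = groupLabels(cohort),
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (mk in colnames(X))
        df[[mk]] <- sprintf(paste0("%.", digits, "g"), X[, mk])
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}
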