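#' @include AllGenerics.R
NULL

## ----------------------------------------------------------------------
## TumorCohort construction and accessors
## ----------------------------------------------------------------------

#' Construct a TumorCohort
#'
#' Combines a validated expression matrix (genes x patients, log2 units)
#' with a canonical clinical table into a
#' [SummarizedExperiment::SummarizedExperiment]-derived container. Every
#' clinical `patient_id` must appear among the expression columns and
#' vice versa; the clinical rows are reordered to the expression column
#' order.
#'
#' @param expression numeric matrix, genes in rows, patients in columns,
#'   with unique dimnames; see [validateExpression()].
#' @param clinical data.frame with columns `patient_id`, `er_status`,
#'   `treatment`, `survival_time` (years), `outcome`, and optionally
#'   `age_at_diagnosis`, `tumor_size`.
#' @param indexGene gene symbol whose distribution is deconvolved
#'   (default `"NAT1"`).
#' @return a [TumorCohort-class].
#' @examples
#' cfg <- syntheticConfig(nPatients = 120, nCorrGenesLow = 5,
#'                        nCorrGenesHigh = 5, nNullGenes = 10, seed = 1)
#' coh <- generateCohort(cfg)
#' indexGene(coh)
#' @export
TumorCohort <- function(expression, clinical, indexGene = "NAT1") {
    expression <- validateExpression(expression)
    clinical <- validateClinical(clinical)
    if (!setequal(clinical$patient_id, colnames(expression)))
        stop("clinical patient_ids and expression patient_ids differ")
    clinical <- clinical[match(colnames(expression), clinical$patient_id), ,
                         drop = FALSE]
    rownames(clinical) <- clinical$patient_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = expression),
        colData = S4Vectors::DataFrame(clinical))
    new("TumorCohort", se, indexGene = indexGene)
}

#' @rdname TumorCohort-class
#' @export
setMethod("indexGene", "TumorCohort", function(object) object@indexGene)

#' @rdname TumorCohort-class
#' @export
setMethod("indexValues", "TumorCohort", function(object)
    SummarizedExperiment::assay(object, "log2expr")[indexGene(object), ])

#' @rdname TumorCohort-class
#' @export
setMethod("clinicalData", "TumorCohort", function(object)
    as.data.frame(SummarizedExperiment::colData(object)))

#' @rdname TumorCohort-class
#' @export
exprMatrix <- function(x) SummarizedExperiment::assay(x, "log2expr")

setMethod("show", "TumorCohort", function(object) {
    callNextMethod()
    cat("indexGene:", object@indexGene, "\n")
})

## ----------------------------------------------------------------------
## Validation helpers
## ----------------------------------------------------------------------

#' Validate an expression matrix
#'
#' Checks the invariants of the genes-by-patients log2 matrix: numeric,
#' all finite, unique row (gene) and column (patient) identifiers.
#'
#' @param m numeric matrix with dimnames.
#' @return the matrix, invisibly unchanged, for piping into
#'   [TumorCohort()].
#' @export
validateExpression <- function(m) {
    if (!is.matrix(m) || !is.numeric(m))
        stop("expression must be a numeric matrix")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("expression matrix needs gene rownames and patient colnames")
    dup <- rownames(m)[duplicated(rownames(m))]
    if (length(dup))
        stop("duplicated gene identifier(s): ", paste(unique(dup), collapse = ", "))
    dup <- colnames(m)[duplicated(colnames(m))]
    if (length(dup))
        stop("duplicated patient identifier(s): ",
             paste(unique(dup), collapse = ", "))
    if (anyNA(m) || any(!is.finite(m)))
        stop("expression matrix contains non-finite values")
    m
}

validateClinical <- function(cl) {
    cl <- as.data.frame(cl)
    miss <- setdiff(REQUIRED_CLINICAL, colnames(cl))
    if (length(miss))
        stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(cl$patient_id))
        stop("duplicated patient_id in clinical table")
    if (any(is.na(cl$survival_time)) || any(cl$survival_time < 0))
        stop("survival_time must be non-negative")
    for (col in c("er_status", "treatment", "outcome")) {
        lev <- switch(col, er_status = ER_LEVELS, treatment = TREATMENT_LEVELS,
                      outcome = OUTCOME_LEVELS)
        bad <- setdiff(unique(as.character(cl[[col]])), lev)
        if (length(bad))
            stop(col, " outside closed vocabulary: ", paste(bad, collapse = ", "))
        cl[[col]] <- as.character(cl[[col]])
    }
    if (!"age_at_diagnosis" %in% colnames(cl)) cl$age_at_diagnosis <- NA_real_
    if (!"tumor_size" %in% colnames(cl)) cl$tumor_size <- NA_real_
    cl
}

## ----------------------------------------------------------------------
## Readers / writers
## ----------------------------------------------------------------------

#' Read a log2 expression matrix from tab-separated text
#'
#' First column (or row, depending on `orientation`) holds identifiers;
#' the body must be numeric. Non-numeric cells and duplicated
#' identifiers are rejected with an informative error.
#'
#' @param path TSV file, one header row, first column of identifiers.
#' @param orientation `"genes_in_rows"` (default) or
#'   `"patients_in_rows"` (matrix is transposed after reading).
#' @return validated numeric matrix, genes in rows.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path,
                           orientation = c("genes_in_rows",
                                           "patients_in_rows")) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression table needs id column plus data")
    ids <- as.character(df[[1L]])
    body <- df[, -1L, drop = FALSE]
    for (j in seq_along(body)) {
        if (!is.numeric(body[[j]])) {
            bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
            stop(sprintf("non-numeric cell at row '%s', column '%s'",
                         ids[bad], colnames(body)[j]))
        }
    }
    m <- as.matrix(body)
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (orientation == "patients_in_rows") m <- t(m)
    validateExpression(m)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are serialised with `%.17g` so that a read/write round trip
#' reproduces the doubles exactly.
#'
#' @param m genes-by-patients numeric matrix.
#' @param path output file.
#' @param idColumn header for the identifier column.
#' @export
writeExpression <- function(m, path, idColumn = "gene_id") {
    validateExpression(m)
    txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    lines <- c(paste(c(idColumn, colnames(m)), collapse = "\t"),
               paste(rownames(m), txt, sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Column/category mapping for clinical tables
#'
#' Describes how a source clinical table maps onto the canonical fields:
#' which columns hold which variables, the survival-time unit, and how
#' source category codes translate into the closed vocabularies.
#' Treatment can be given either directly (a `treatment` column already
#' in canonical codes) or derived from two boolean columns (hormone
#' therapy, chemotherapy): neither -> `none`, hormone only ->
#' `hormone_only`, chemo only -> `chemo_only`, both -> `other`.
#'
#' @param columns named character vector mapping canonical names
#'   (`patient_id`, `er_status`, `survival_time`, `outcome`, optionally
#'   `treatment` or `hormone`/`chemo`, `age_at_diagnosis`, `tumor_size`)
#'   to source column names.
#' @param timeUnit `"years"` or `"months"` (months are divided by 12).
#' @param outcomeCodes,erCodes named character vectors translating
#'   source codes to canonical levels; codes absent from the map become
#'   `"unknown"` with a warning.
#' @param booleanTrue values counted as TRUE in boolean treatment
#'   columns.
#' @return a list usable as the `mapping` argument of [readClinical()].
#' @export
clinicalMapping <- function(columns = c(patient_id = "patient_id",
                                        er_status = "er_status",
                                        treatment = "treatment",
                                        survival_time = "survival_time",
                                        outcome = "outcome",
                                        age_at_diagnosis = "age_at_diagnosis",
                                        tumor_size = "tumor_size"),
                            timeUnit = c("years", "months"),
                            outcomeCodes = setNames(OUTCOME_LEVELS,
                                                    OUTCOME_LEVELS),
                            erCodes = setNames(ER_LEVELS, ER_LEVELS),
                            booleanTrue = c("1", "TRUE", "YES", "yes")) {
    list(columns = columns, timeUnit = match.arg(timeUnit),
         outcomeCodes = outcomeCodes, erCodes = erCodes,
         booleanTrue = booleanTrue)
}

#' Read a clinical table from tab-separated text
#'
#' Applies a [clinicalMapping()] to translate source columns and codes
#' into the canonical patient record: survival time in years, closed
#' vocabularies for ER status, treatment arm and outcome. Category
#' codes absent from the mapping yield `"unknown"` (ER/outcome) or
#' `"other"` (treatment) with a warning; negative survival times are an
#' error.
#'
#' @param path TSV file with a header of named columns.
#' @param mapping a [clinicalMapping()].
#' @return data.frame of canonical patient records.
#' @export
readClinical <- function(path, mapping = clinicalMapping()) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    cols <- mapping$columns
    need <- c("patient_id", "survival_time", "outcome")
    for (f in need)
        if (!cols[[f]] %in% colnames(df))
            stop("source table lacks column '", cols[[f]], "' for ", f)
    out <- data.frame(patient_id = as.character(df[[cols[["patient_id"]]]]),
                      stringsAsFactors = FALSE)

    st <- as.numeric(df[[cols[["survival_time"]]]])
    if (anyNA(st)) stop("non-numeric survival_time")
    if (mapping$timeUnit == "months") st <- st / 12
    if (any(st < 0)) stop("negative survival_time")
    out$survival_time <- st

    mapCodes <- function(x, codes, default, what) {
        x <- as.character(x)
        known <- x %in% names(codes)
        if (!all(known))
            warning(sprintf("%s code(s) not in mapping, set to '%s': %s",
                            what, default,
                            paste(unique(x[!known]), collapse = ", ")))
        ifelse(known, unname(codes[x]), default)
    }
    out$outcome <- mapCodes(df[[cols[["outcome"]]]], mapping$outcomeCodes,
                            "unknown", "outcome")
    if ("er_status" %in% names(cols) && cols[["er_status"]] %in% colnames(df))
        out$er_status <- mapCodes(df[[cols[["er_status"]]]], mapping$erCodes,
                                  "unknown", "er_status")
    else out$er_status <- "unknown"

    if ("treatment" %in% names(cols) && cols[["treatment"]] %in% colnames(df)) {
        tr <- as.character(df[[cols[["treatment"]]]])
        known <- tr %in% TREATMENT_LEVELS
        if (!all(known))
            warning("treatment code(s) not in vocabulary, set to 'other': ",
                    paste(unique(tr[!known]), collapse = ", "))
        out$treatment <- ifelse(known, tr, "other")
    } else if (all(c("hormone", "chemo") %in% names(cols)) &&
               all(cols[c("hormone", "chemo")] %in% colnames(df))) {
        h <- as.character(df[[cols[["hormone"]]]]) %in% mapping$booleanTrue
        c2 <- as.character(df[[cols[["chemo"]]]]) %in% mapping$booleanTrue
        out$treatment <- ifelse(!h & !c2, "none",
                         ifelse(h & !c2, "hormone_only",
                         ifelse(!h & c2, "chemo_only", "other")))
    } else out$treatment <- "other"

    for (f in c("age_at_diagnosis", "tumor_size"))
        out[[f]] <- if (f %in% names(cols) && cols[[f]] %in% colnames(df))
            as.numeric(df[[cols[[f]]]]) else NA_real_
    validateClinical(out)
}

#' Write a canonical clinical table as tab-separated text
#'
#' @param clinical canonical clinical data.frame.
#' @param path output file.
#' @export
writeClinical <- function(clinical, path) {
    clinical <- validateClinical(clinical)
    utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Element-wise log2 transform of raw intensities
#'
#' @param raw numeric vector or matrix of strictly positive intensities.
#' @return base-2 logarithms, same shape.
#' @export
log2Transform <- function(raw) {
    if (any(!is.finite(raw)) || any(raw <= 0))
        stop("log2Transform requires strictly positive finite intensities")
    log2(raw)
}
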