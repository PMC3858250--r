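#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Column-data contract shared by the cohort class and the readers.
.CLINICAL_FACTORS <- c("node_positive", "dfi_lt_12mo", "cea_gt_200",
                       "multiple_tumors", "size_gt_5cm")
.OUTCOME_COLS <- c("dss_time", "dss_event",
                   "lrfs_time", "lrfs_event", "lrfs_type")

#' MRSExperiment: an annotated expression cohort
#'
#' An `MRSExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] and holds a genes x
#' samples log-scale expression matrix (assay `"exprs"`) together with
#' the per-sample annotation the molecular-risk-score pipeline needs:
#' the five binary clinical-risk-score factors and two censored
#' endpoints, disease-specific survival (DSS) and liver-recurrence-free
#' survival (LRFS).  LRFS additionally carries an event-type code
#' (0 censored, 1 liver recurrence, 2 cancer death without liver
#' recurrence, the competing event).
#'
#' Required `colData` columns: `node_positive`, `dfi_lt_12mo`,
#' `cea_gt_200`, `multiple_tumors`, `size_gt_5cm` (logical, no missing
#' values), `dss_time`, `dss_event`, `lrfs_time`, `lrfs_event`,
#' `lrfs_type`.  Times are months and must be positive; `lrfs_event`
#' must equal `as.integer(lrfs_type == 1)`.
#'
#' For synthetic cohorts, `metadata(x)$truth` records the planted
#' prognostic genes and the coefficients used in hazard generation, and
#' `metadata(x)$config` the generating [simulationConfig()].
#'
#' @seealso [simulateCohort()], [dssOutcomes()], [clinicalFactors()]
#' @export
setClass("MRSExperiment", contains = "SummarizedExperiment")

.validMRSExperiment <- function(object) {
    msg <- character()
    if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- colData(object)
    missing_cols <- setdiff(c(.CLINICAL_FACTORS, .OUTCOME_COLS), colnames(cd))
    if (length(missing_cols))
        return(paste("missing colData columns:",
                     paste(missing_cols, collapse = ", ")))
    for (f in .CLINICAL_FACTORS) {
        v <- cd[[f]]
        if (!is.logical(v) || anyNA(v))
            msg <- c(msg, sprintf("factor '%s' must be logical with no NA", f))
    }
    for (tcol in c("dss_time", "lrfs_time")) {
        v <- cd[[tcol]]
        if (!is.numeric(v) || anyNA(v) || any(v <= 0))
            msg <- c(msg, sprintf("'%s' must be positive with no NA", tcol))
    }
    if (!all(cd$dss_event %in% c(0L, 1L)))
        msg <- c(msg, "'dss_event' must be 0/1")
    if (!all(cd$lrfs_type %in% c(0L, 1L, 2L)))
        msg <- c(msg, "'lrfs_type' must be 0/1/2")
    if (!identical(as.integer(cd$lrfs_event),
                   as.integer(cd$lrfs_type == 1L)))
        msg <- c(msg, "'lrfs_event' must equal (lrfs_type == 1)")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (length(msg)) msg else TRUE
}
setValidity("MRSExperiment", .validMRSExperiment)

#' Construct an MRSExperiment
#'
#' @param exprs genes x samples numeric matrix with unique row and
#'   column names (log-scale expression).
#' @param clinical data.frame with `sample_id` and the five logical CRS
#'   factor columns.
#' @param dss,lrfs outcome data.frames with columns `sample_id`,
#'   `time`, `event` and (for `lrfs`) `event_type`.
#' @param truth optional list describing planted signal
#'   (`genes`, `beta`).
#' @param config optional generating configuration.
#' @return an [MRSExperiment-class] object.
#' @export
MRSExperiment <- function(exprs, clinical, dss, lrfs,
                          truth = list(), config = list()) {
    stopifnot(is.matrix(exprs), is.numeric(exprs))
    ids <- colnames(exprs)
    if (is.null(ids)) stop("expression matrix must carry sample ids")
    clinical <- .alignById(clinical, ids, "clinical")
    dss <- .alignById(dss, ids, "dss outcomes")
    lrfs <- .alignById(lrfs, ids, "lrfs outcomes")
    if (is.null(lrfs$event_type))
        stop("lrfs outcomes must carry an 'event_type' column")
    cd <- DataFrame(row.names = ids)
    for (f in .CLINICAL_FACTORS) cd[[f]] <- as.logical(clinical[[f]])
    cd$dss_time <- as.numeric(dss$time)
    cd$dss_event <- as.integer(dss$event)
    cd$lrfs_time <- as.numeric(lrfs$time)
    cd$lrfs_type <- as.integer(lrfs$event_type)
    cd$lrfs_event <- as.integer(cd$lrfs_type == 1L)
    se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
    obj <- new("MRSExperiment", se)
    S4Vectors::metadata(obj)$truth <- truth
    S4Vectors::metadata(obj)$config <- config
    obj
}

.alignById <- function(df, ids, what) {
    df <- as.data.frame(df)
    if (is.null(df$sample_id))
        stop(sprintf("%s table must have a 'sample_id' column", what))
    if (anyDuplicated(df$sample_id))
        stop(sprintf("duplicated sample ids in %s", what))
    miss <- setdiff(ids, df$sample_id)
    if (length(miss))
        stop(sprintf("%s missing for samples: %s", what,
                     paste(utils::head(miss, 5), collapse = ", ")))
    df[match(ids, df$sample_id), , drop = FALSE]
}

#' QuantileReference: a frozen quantile-normalization target
#'
#' Stores the sorted per-rank means computed from a training matrix by
#' [quantileNormalize()] so that new samples can be mapped onto the
#' identical distribution by [applyReference()] without re-estimation.
#'
#' @slot reference non-decreasing numeric vector, one value per gene
#'   rank.
#' @slot samples sample identifiers the reference was computed from.
#' @export
setClass("QuantileReference",
         representation(reference = "numeric", samples = "character"))

setValidity("QuantileReference", function(object) {
    r <- object@reference
    if (length(r) < 1L) return("empty reference")
    if (anyNA(r)) return("reference contains NA")
    if (is.unsorted(r)) return("reference must be non-decreasing")
    TRUE
})

#' SignatureModel: a frozen molecular risk score
#'
#' Everything needed to score new samples: the selected genes, their
#' training centers and scales, the per-gene weights (first principal
#' component loadings or standardized Cox coefficients), the
#' orientation sign that makes higher scores mean higher hazard on the
#' training data, and the training-median threshold that dichotomizes
#' the score into high/low risk.  Nothing is re-estimated at scoring
#' time.
#'
#' @slot endpoint `"dss"` or `"lrfs"`.
#' @slot genes selected gene identifiers.
#' @slot center,scale per-gene training mean and standard deviation.
#' @slot weights per-gene weights, same order as `genes`.
#' @slot weightMode `"pc1"` or `"coef"`.
#' @slot orientation `+1` or `-1`.
#' @slot threshold training-median MRS; scores strictly above it are
#'   high risk, ties go low.
#' @slot alpha the p-value cutoff that selected the genes.
#' @slot cv cross-validation metadata from [cvSelectThreshold()]
#'   (possibly empty).
#' @export
setClass("SignatureModel",
         representation(endpoint = "character", genes = "character",
                        center = "numeric", scale = "numeric",
                        weights = "numeric", weightMode = "character",
                        orientation = "numeric", threshold = "numeric",
                        alpha = "numeric", cv = "list"))

setValidity("SignatureModel", function(object) {
    msg <- character()
    k <- length(object@genes)
    if (k < 1L) msg <- c(msg, "at least one selected gene is required")
    if (length(object@weights) != k ||
        length(object@center) != k || length(object@scale) != k)
        msg <- c(msg, "genes, center, scale and weights must be co-ordered")
    if (!object@weightMode %in% c("pc1", "coef"))
        msg <- c(msg, "weightMode must be 'pc1' or 'coef'")
    if (!object@orientation %in% c(-1, 1))
        msg <- c(msg, "orientation must be +1 or -1")
    if (!object@endpoint %in% c("dss", "lrfs"))
        msg <- c(msg, "endpoint must be 'dss' or 'lrfs'")
    if (any(object@scale <= 0)) msg <- c(msg, "scales must be positive")
    if (length(msg)) msg else TRUE
})

#' ValidationReport: the frozen-model validation summary
#'
#' Aggregates, for one endpoint and one scored cohort, the
#' Kaplan-Meier curves by risk group, log-rank tests, concordance
#' indices of the continuous MRS and of the CRS, multivariate Cox
#' hazard ratios for the two dichotomized scores, 3-year survival per
#' group, and the combined CRS+MRS three-group stratification.
#'
#' @slot endpoint `"dss"` or `"lrfs"`.
#' @slot cohort label of the cohort the report describes.
#' @slot km tidy data.frame of KM curves
#'   (`group`, `time`, `n_risk`, `n_event`, `survival`).
#' @slot logrank list of log-rank results (`mrs`, `combined`), each
#'   with `chisq`, `df`, `p`.
#' @slot concordance named numeric (`mrs`, `crs`).
#' @slot cox data.frame of multivariate hazard ratios
#'   (`term`, `hr`, `lo95`, `hi95`, `p`).
#' @slot surv3yr data.frame of 3-year survival by group.
#' @slot scores per-sample data.frame
#'   (`sample_id`, `mrs`, `mrs_group`, `crs`, `crs_group`,
#'   `combined_group`).
#' @export
setClass("ValidationReport",
         representation(endpoint = "character", cohort = "character",
                        km = "data.frame", logrank = "list",
                        concordance = "numeric", cox = "data.frame",
                        surv3yr = "data.frame", scores = "data.frame"))
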