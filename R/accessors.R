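#' Accessors for MRSExperiment and SignatureModel
#'
#' `exprsMatrix()` returns the expression assay; `clinicalFactors()`
#' the five logical CRS factors; `dssOutcomes()` / `lrfsOutcomes()`
#' the per-sample outcome tables (`sample_id`, `time`, `event`,
#' `event_type`); `truthGenes()` the planted prognostic genes of a
#' synthetic cohort (empty for real data).
#'
#' @param x an [MRSExperiment-class].
#' @return see individual descriptions.
#' @name mrs-accessors
#' @aliases exprsMatrix clinicalFactors dssOutcomes lrfsOutcomes truthGenes
NULL

#' @rdname mrs-accessors
#' @export
exprsMatrix <- function(x) assay(x, "exprs")

#' @rdname mrs-accessors
#' @export
clinicalFactors <- function(x) {
    cd <- colData(x)
    out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
    for (f in .CLINICAL_FACTORS) out[[f]] <- cd[[f]]
    out
}

#' @rdname mrs-accessors
#' @export
dssOutcomes <- function(x) {
    cd <- colData(x)
    data.frame(sample_id = colnames(x), time = cd$dss_time,
               event = cd$dss_event,
               event_type = cd$dss_event, stringsAsFactors = FALSE)
}

#' @rdname mrs-accessors
#' @export
lrfsOutcomes <- function(x) {
    cd <- colData(x)
    data.frame(sample_id = colnames(x), time = cd$lrfs_time,
               event = cd$lrfs_event, event_type = cd$lrfs_type,
               stringsAsFactors = FALSE)
}

#' Outcomes for a named endpoint
#'
#' @param x an [MRSExperiment-class].
#' @param endpoint `"dss"` or `"lrfs"`.
#' @return outcome data.frame as in [dssOutcomes()].
#' @export
endpointOutcomes <- function(x, endpoint = c("dss", "lrfs")) {
    endpoint <- match.arg(endpoint)
    if (endpoint == "dss") dssOutcomes(x) else lrfsOutcomes(x)
}

#' @rdname mrs-accessors
#' @export
truthGenes <- function(x) {
    tr <- S4Vectors::metadata(x)$truth
    if (is.null(tr)) list(genes = character(), beta = numeric()) else tr
}

#' @rdname mrs-accessors
#' @param object object to display.
#' @export
setMethod("show", "MRSExperiment", function(object) {
    cat(sprintf("MRSExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    cd <- colData(object)
    cat(sprintf("  DSS events: %d/%d; LRFS events: %d/%d (competing: %d)\n",
                sum(cd$dss_event), ncol(object),
                sum(cd$lrfs_event), ncol(object),
                sum(cd$lrfs_type == 2L)))
    tr <- truthGenes(object)
    if (length(tr$genes))
        cat(sprintf("  planted prognostic genes: %d\n", length(tr$genes)))
    invisible(NULL)
})

#' Genes, weights and threshold of a frozen signature
#'
#' @param model a [SignatureModel-class].
#' @return `signatureGenes()` the selected gene ids;
#'   `signatureWeights()` a named numeric vector of oriented weights;
#'   `mrsThreshold()` the frozen training-median threshold.
#' @name signature-accessors
NULL

#' @rdname signature-accessors
#' @export
signatureGenes <- function(model) model@genes

#' @rdname signature-accessors
#' @export
signatureWeights <- function(model) {
    stats::setNames(model@orientation * model@weights, model@genes)
}

#' @rdname signature-accessors
#' @export
mrsThreshold <- function(model) model@threshold

setMethod("show", "SignatureModel", function(object) {
    cat(sprintf("SignatureModel (%s, weight mode '%s')\n",
                object@endpoint, object@weightMode))
    cat(sprintf("  %d genes selected at p < %g\n",
                length(object@genes), object@alpha))
    cat(sprintf("  orientation %+d, MRS threshold %.4f\n",
                as.integer(object@orientation), object@threshold))
    invisible(NULL)
})

setMethod("show", "QuantileReference", function(object) {
    cat(sprintf("QuantileReference: %d ranks from %d samples\n",
                length(object@reference), length(object@samples)))
    invisible(NULL)
})

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf("ValidationReport (%s, %s cohort)\n",
                object@endpoint, object@cohort))
    cat(sprintf("  concordance: MRS %.3f, CRS %.3f\n",
                object@concordance[["mrs"]], object@concordance[["crs"]]))
    lr <- object@logrank$mrs
    cat(sprintf("  log-rank high vs low MRS: chi2 = %.2f, p = %.3g\n",
                lr$chisq, lr$p))
    if (nrow(object@surv3yr)) {
        cat("  3-year survival by combined CRS+MRS group:\n")
        cmb <- object@surv3yr[object@surv3yr$stratification == "combined", ]
        for (i in seq_len(nrow(cmb)))
            cat(sprintf("    %-12s %.0f%%\n", cmb$group[i],
                        100 * cmb$survival[i]))
    }
    invisible(NULL)
})
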