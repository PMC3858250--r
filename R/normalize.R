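#' Log2-transform an expression matrix
#'
#' @param matrix genes x samples numeric matrix of raw intensities.
#' @param offset small positive constant added before taking logs
#'   (default 1); use 0 only when all intensities are strictly
#'   positive.
#' @return elementwise `log2(matrix + offset)`, dimnames preserved.
#' @export
log2Transform <- function(matrix, offset = 1) {
    stopifnot(is.matrix(matrix), is.numeric(matrix))
    bad <- which(matrix + offset <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        g <- rownames(matrix)[bad[1L, 1L]]
        s <- colnames(matrix)[bad[1L, 2L]]
        stop(sprintf(
            "non-positive value after offset at gene '%s', sample '%s'",
            if (is.null(g)) bad[1L, 1L] else g,
            if (is.null(s)) bad[1L, 2L] else s))
    }
    log2(matrix + offset)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference
#' distribution, defined as the across-sample mean of the per-sample
#' sorted values; within-sample rank order is preserved and tied raw
#' values receive the mean of the reference values their ranks span.
#' The reference is returned as a [QuantileReference-class] so that
#' future samples can be mapped onto it by [applyReference()] without
#' re-estimation.
#'
#' @param matrix genes x samples numeric matrix, at least two samples,
#'   no missing values.
#' @return list with `matrix` (normalized, same dimnames) and
#'   `reference` (a [QuantileReference-class]).
#' @export
quantileNormalize <- function(matrix) {
    stopifnot(is.matrix(matrix), is.numeric(matrix))
    if (ncol(matrix) < 2L)
        stop("quantile normalization needs at least two samples")
    if (anyNA(matrix)) stop("missing values are not allowed")
    sorted <- apply(matrix, 2L, sort)
    ref <- as.numeric(rowMeans(sorted))
    norm <- apply(matrix, 2L, .mapToReference, ref = ref)
    dimnames(norm) <- dimnames(matrix)
    list(matrix = norm,
         reference = new("QuantileReference", reference = ref,
                         samples = colnames(matrix) %||% character()))
}

#' Map samples onto a frozen quantile reference
#'
#' Rank-maps each column of `matrix` onto the stored reference
#' distribution, exactly as [quantileNormalize()] would have done had
#' the sample been part of the reference cohort.  A single test sample
#' is permitted.
#'
#' @param matrix genes x samples numeric matrix; gene count must equal
#'   the reference length.
#' @param ref a [QuantileReference-class].
#' @return normalized matrix, dimnames preserved.
#' @export
applyReference <- function(matrix, ref) {
    stopifnot(is(ref, "QuantileReference"))
    if (is.vector(matrix)) matrix <- as.matrix(matrix)
    if (nrow(matrix) != length(ref@reference))
        stop(sprintf("gene count (%d) does not match reference length (%d)",
                     nrow(matrix), length(ref@reference)))
    if (anyNA(matrix)) stop("missing values are not allowed")
    norm <- apply(matrix, 2L, .mapToReference, ref = ref@reference)
    norm <- matrix(norm, nrow = nrow(matrix))
    dimnames(norm) <- dimnames(matrix)
    norm
}

## Replace values by reference quantiles at their ranks; a run of tied
## values receives the mean of the reference entries its ranks span.
.mapToReference <- function(x, ref) {
    y <- numeric(length(x))
    y[order(x)] <- ref
    if (anyDuplicated(x)) y <- stats::ave(y, match(x, x), FUN = mean)
    y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess a raw cohort: log2 then quantile normalization
#'
#' Convenience wrapper reproducing the standard microarray
#' preprocessing on an [MRSExperiment-class] whose assay holds raw
#' intensities.  With `split` supplied, training samples are
#' normalized jointly and test samples are mapped onto the frozen
#' training reference; otherwise all samples are normalized jointly.
#'
#' @param cohort an [MRSExperiment-class] with raw intensities.
#' @param offset log2 offset, see [log2Transform()].
#' @param split optional [splitCohort()] result for frozen-reference
#'   normalization of the test samples.
#' @return the cohort with its `exprs` assay replaced by normalized
#'   values; the reference is stored in `metadata(x)$quantile_reference`.
#' @export
normalizeCohort <- function(cohort, offset = 1, split = NULL) {
    X <- log2Transform(exprsMatrix(cohort), offset = offset)
    if (is.null(split)) {
        qn <- quantileNormalize(X)
        out <- qn$matrix
        ref <- qn$reference
    } else {
        qn <- quantileNormalize(X[, split$train_ids, drop = FALSE])
        ref <- qn$reference
        out <- X
        out[, split$train_ids] <- qn$matrix
        out[, split$test_ids] <-
            applyReference(X[, split$test_ids, drop = FALSE], ref)
    }
    SummarizedExperiment::assay(cohort, "exprs") <- out
    S4Vectors::metadata(cohort)$quantile_reference <- ref
    cohort
}
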