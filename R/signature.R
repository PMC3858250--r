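#' Rank screened genes by standardized coefficient magnitude
#'
#' Orders a [screenGenes()] result by decreasing `|z|` (the
#' standardized Cox coefficient), breaking exact ties
#' lexicographically by gene id so the ranking is deterministic.
#' Degenerate genes sort last.
#'
#' @param results a [screenGenes()] result.
#' @return the same data.frame, reordered.
#' @export
rankGenes <- function(results) {
    if (!nrow(results)) stop("empty screening result")
    key <- abs(results$z)
    key[results$degenerate] <- -Inf
    results[order(-key, results$gene_id), , drop = FALSE]
}

#' Choose the screening threshold by cross-validation
#'
#' For each candidate p-value cutoff, genes are re-screened within
#' each cross-validation training fold, the first principal component
#' of the selected genes is fitted on the fold-training samples, the
#' held-out samples are scored with that frozen direction, and the Cox
#' score statistic (squared score z) of the held-out risk score is
#' recorded.  The cutoff maximizing the mean statistic across folds is
#' chosen; ties break toward the stricter cutoff.  Folds are seeded
#' and stratified by event status; a fold whose training part has no
#' events is re-drawn (up to `retries`), then an error is raised.
#'
#' @param train_matrix genes x samples matrix (training cohort).
#' @param outcome outcome data.frame for the same samples.
#' @param grid candidate p-value cutoffs (default
#'   `10^-(seq(2, 4, 0.5))`).
#' @param folds number of folds K (default 5).
#' @param weight_mode `"pc1"` or `"coef"`, the score used in
#'   evaluation (default `"pc1"`).
#' @param seed fold-assignment seed.
#' @param retries redraw attempts for degenerate folds.
#' @return list with `cutpoint` (chosen alpha) and `cv` metadata
#'   (`grid`, `folds`, `fold_assignment`, `stat` per fold x candidate,
#'   `mean_stat`).
#' @export
cvSelectThreshold <- function(train_matrix, outcome,
                              grid = 10^-(seq(2, 4, by = 0.5)),
                              folds = 5L,
                              weight_mode = c("pc1", "coef"),
                              seed = 1L, retries = 20L) {
    weight_mode <- match.arg(weight_mode)
    if (is(train_matrix, "MRSExperiment"))
        train_matrix <- exprsMatrix(train_matrix)
    if (!length(grid)) stop("empty candidate grid")
    if (folds < 2L) stop("need at least 2 folds")
    grid <- sort(grid)   # ascending: strictest first
    ids <- colnames(train_matrix)
    outcome <- outcome[match(ids, outcome$sample_id), , drop = FALSE]
    cs <- .asCauseSpecific(outcome)

    set.seed(seed %% .Machine$integer.max)
    assign_folds <- function() {
        f <- integer(length(ids))
        for (s in unique(cs$event)) {
            idx <- which(cs$event == s)
            f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
        f
    }
    fold <- assign_folds()
    ok <- function(f) all(vapply(seq_len(folds), function(k)
        sum(cs$event[f != k]) >= 2L, logical(1L)))
    tries <- 0L
    while (!ok(fold)) {
        tries <- tries + 1L
        if (tries > retries)
            stop("could not draw folds with events in every training part")
        fold <- assign_folds()
    }

    stat <- matrix(NA_real_, folds, length(grid),
                   dimnames = list(NULL, signif(grid, 3)))
    for (k in seq_len(folds)) {
        tr <- fold != k; te <- !tr
        scr <- screenGenes(train_matrix[, tr, drop = FALSE],
                           outcome[tr, , drop = FALSE],
                           alpha = max(grid))
        for (j in seq_along(grid)) {
            sel <- scr$gene_id[!scr$degenerate & scr$p < grid[j]]
            if (!length(sel)) { stat[k, j] <- 0; next }
            mdl <- .fitDirection(train_matrix[sel, tr, drop = FALSE],
                                 scr[match(sel, scr$gene_id), ],
                                 weight_mode)
            sc <- .applyDirection(mdl,
                                  train_matrix[sel, te, drop = FALSE])
            if (stats::sd(sc) == 0 || sum(cs$event[te]) < 1L) {
                stat[k, j] <- 0
            } else {
                z <- .coxScoreZ(sc, cs$time[te], cs$event[te])
                stat[k, j] <- z^2
            }
        }
    }
    mean_stat <- colMeans(stat)
    best <- which.max(mean_stat)    # first max = strictest cutoff on ties
    list(cutpoint = grid[best],
         cv = list(grid = grid, folds = folds, fold_assignment = fold,
                   seed = seed, stat = stat, mean_stat = mean_stat,
                   chosen = grid[best]))
}

## Center/scale a selected submatrix and compute the weight vector.
.fitDirection <- function(sub, scr, weight_mode) {
    ctr <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    Z <- (sub - ctr) / sdv
    w <- if (weight_mode == "pc1") {
        sv <- svd(Z, nu = 1L, nv = 0L)
        sv$u[, 1L]
    } else {
        scr$z
    }
    list(center = ctr, scale = sdv, weights = w)
}

.applyDirection <- function(mdl, sub) {
    Z <- (sub - mdl$center) / mdl$scale
    as.numeric(crossprod(Z, mdl$weights))
}

#' Fit a frozen molecular risk score on training data
#'
#' Screens the training matrix at `cutpoint`, centers and scales the
#' selected genes with training statistics, computes per-gene weights
#' (first principal-component loadings of the standardized
#' genes x samples submatrix, or the standardized Cox coefficients),
#' orients the score so that higher values mean higher hazard on the
#' training data, and freezes the training-median threshold.
#'
#' @param train_matrix genes x samples matrix or
#'   [MRSExperiment-class] (training cohort).
#' @param outcome outcome data.frame for the training samples.
#' @param cutpoint p-value cutoff selecting the signature genes
#'   (e.g. from [cvSelectThreshold()]).
#' @param weight_mode `"pc1"` (default) or `"coef"`.
#' @param endpoint endpoint label stored in the model.
#' @param cv optional cross-validation metadata to store.
#' @return a [SignatureModel-class].
#' @export
fitSignature <- function(train_matrix, outcome, cutpoint = 0.001,
                         weight_mode = c("pc1", "coef"),
                         endpoint = c("dss", "lrfs"), cv = list()) {
    weight_mode <- match.arg(weight_mode)
    endpoint <- match.arg(endpoint)
    if (is(train_matrix, "MRSExperiment"))
        train_matrix <- exprsMatrix(train_matrix)
    ids <- colnames(train_matrix)
    outcome <- outcome[match(ids, outcome$sample_id), , drop = FALSE]
    scr <- screenGenes(train_matrix, outcome, alpha = cutpoint)
    sel <- scr$gene_id[scr$selected]
    if (!length(sel))
        stop("no genes selected at p < ", cutpoint,
             "; increase the cutpoint")
    mdl <- .fitDirection(train_matrix[sel, , drop = FALSE],
                         scr[match(sel, scr$gene_id), ], weight_mode)
    score <- .applyDirection(mdl, train_matrix[sel, , drop = FALSE])
    cs <- .asCauseSpecific(outcome)
    bfit <- .coxEngine(matrix(score, nrow = 1L), cs$time, cs$event)
    orientation <- if (bfit$beta[1L] < 0) -1 else 1
    mrs <- orientation * score
    new("SignatureModel", endpoint = endpoint, genes = sel,
        center = setNames(mdl$center, sel),
        scale = setNames(mdl$scale, sel),
        weights = setNames(mdl$weights, sel),
        weightMode = weight_mode, orientation = orientation,
        threshold = median(mrs), alpha = cutpoint, cv = cv)
}

#' Score samples with a frozen signature
#'
#' Computes `mrs = orientation * sum_g w_g (x_g - center_g)/scale_g`
#' for every sample and dichotomizes at the frozen training-median
#' threshold: scores strictly above the threshold are `"high"` risk,
#' ties go `"low"`.  Nothing is re-estimated, so scoring depends only
#' on the model and the expression values.
#'
#' @param model a [SignatureModel-class].
#' @param matrix genes x samples matrix or [MRSExperiment-class]
#'   containing every model gene.
#' @return data.frame `sample_id`, `mrs`, `group` (`"high"`/`"low"`).
#' @export
computeMRS <- function(model, matrix) {
    stopifnot(is(model, "SignatureModel"))
    if (is(matrix, "MRSExperiment")) matrix <- exprsMatrix(matrix)
    miss <- setdiff(model@genes, rownames(matrix))
    if (length(miss))
        stop("matrix is missing model genes: ",
             paste(miss, collapse = ", "))
    sub <- matrix[model@genes, , drop = FALSE]
    Z <- (sub - model@center) / model@scale
    mrs <- model@orientation * as.numeric(crossprod(Z, model@weights))
    data.frame(sample_id = colnames(matrix), mrs = mrs,
               group = ifelse(mrs > model@threshold, "high", "low"),
               stringsAsFactors = FALSE)
}
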