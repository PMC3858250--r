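#' @importFrom survival Surv coxph coxph.control finegray survfit survdiff
#' @importFrom stats pnorm pchisq median sd setNames cor quantile
NULL

## ---------------------------------------------------------------------
## Vectorised Newton-Raphson for univariate Cox models, Efron ties.
##
## Fits, for every row of X simultaneously, the single-covariate Cox
## partial likelihood.  Risk-set and tied-death sums are expressed as
## matrix products with fixed 0/1 indicator matrices so the per-gene
## work is dense linear algebra.  Used by screenGenes() across
## thousands of genes and by coxUnivariate() for a single covariate.
## ---------------------------------------------------------------------
.coxEngine <- function(X, time, event, tol = 1e-10, maxit = 30L,
                       iterate = TRUE) {
    G <- nrow(X); n <- ncol(X)
    stopifnot(length(time) == n, length(event) == n)
    if (sum(event) < 1L) stop("no events in outcome")
    ord <- order(time)
    to <- time[ord]; eo <- event[ord]
    Xo <- X[, ord, drop = FALSE]
    ev_times <- unique(to[eo == 1L])
    K <- length(ev_times)
    A <- outer(to, ev_times, `>=`) * 1
    D <- (outer(to, ev_times, `==`) & eo == 1L) * 1
    d <- colSums(D)
    maxd <- max(d)
    XD <- Xo %*% D
    x_event_sum <- rowSums(XD)

    rowsd <- sqrt(pmax(0, rowMeans(Xo^2) - rowMeans(Xo)^2))
    degen <- rowsd == 0
    beta <- numeric(G)
    converged <- rep(TRUE, G)

    derivs <- function(beta) {
        W <- exp(sweep(Xo, 1L, beta, `*`))
        WX <- W * Xo; WXX <- WX * Xo
        S0 <- W %*% A; S1 <- WX %*% A; S2 <- WXX %*% A
        s0d <- W %*% D; s1d <- WX %*% D; s2d <- WXX %*% D
        U <- x_event_sum
        I <- numeric(G)
        for (l in seq_len(maxd) - 1L) {
            cols <- which(d > l)
            f <- l / d[cols]
            fm <- rep(f, each = G)
            S0l <- S0[, cols, drop = FALSE] - fm * s0d[, cols, drop = FALSE]
            S1l <- S1[, cols, drop = FALSE] - fm * s1d[, cols, drop = FALSE]
            S2l <- S2[, cols, drop = FALSE] - fm * s2d[, cols, drop = FALSE]
            r1 <- S1l / S0l
            U <- U - rowSums(r1)
            I <- I + rowSums(S2l / S0l - r1 * r1)
        }
        list(U = U, I = I)
    }

    dv <- derivs(beta)
    if (iterate) {
        for (it in seq_len(maxit)) {
            active <- !degen & abs(dv$U) > tol & dv$I > 0
            if (!any(active)) break
            step <- numeric(G)
            step[active] <- dv$U[active] / dv$I[active]
            step <- pmin(pmax(step, -2), 2)   # damp early overshoot
            beta <- beta + step
            dv <- derivs(beta)
        }
        converged <- degen | (abs(dv$U) <= tol * 100 & abs(beta) < 15)
    }
    se <- ifelse(degen | dv$I <= 0, Inf, 1 / sqrt(dv$I))
    z <- ifelse(is.finite(se), beta / se, 0)
    p <- ifelse(degen, 1, 2 * pnorm(-abs(z)))
    list(beta = ifelse(degen, 0, beta), se = se, z = z, p = p,
         degenerate = degen, converged = converged,
         score_z = {        # score test at the supplied beta (0 if !iterate)
             if (!iterate) ifelse(degen | dv$I <= 0, 0,
                                  dv$U / sqrt(dv$I)) else NULL
         })
}

.asCauseSpecific <- function(outcome) {
    ev <- if (!is.null(outcome$event_type))
        as.integer(outcome$event_type == 1L) else as.integer(outcome$event)
    list(time = as.numeric(outcome$time), event = ev)
}

#' Univariate Cox regression of survival on one covariate
#'
#' Maximizes the Efron-corrected Cox partial likelihood by
#' Newton-Raphson; the standard error comes from the observed
#' information and the p-value from the two-sided Wald test.
#' Competing events (`event_type == 2`) are treated as censoring, the
#' cause-specific convention.  A constant covariate returns the
#' degenerate convention `beta = 0`, `se = Inf`, `p = 1`.
#'
#' @param x numeric covariate vector, one value per sample.
#' @param outcome data.frame with `time`, `event` and optionally
#'   `event_type`.
#' @param gene_id label carried into the result.
#' @return one-row data.frame: `gene_id`, `beta`, `se`, `z`, `p`,
#'   `analysis`, `degenerate`, `converged`.
#' @examples
#' oc <- data.frame(time = 1:6, event = 1L)
#' coxUnivariate(c(1, 1, 1, 0, 0, 0), oc)
#' @export
coxUnivariate <- function(x, outcome, gene_id = "x") {
    stopifnot(is.numeric(x))
    if (anyNA(x)) stop("covariate contains missing values")
    cs <- .asCauseSpecific(outcome)
    if (length(x) != length(cs$time))
        stop("covariate and outcome lengths differ")
    fit <- .coxEngine(matrix(x, nrow = 1L), cs$time, cs$event)
    data.frame(gene_id = gene_id, beta = fit$beta, se = fit$se,
               z = fit$z, p = fit$p, analysis = "cox",
               degenerate = fit$degenerate, converged = fit$converged,
               stringsAsFactors = FALSE)
}

#' Univariate Fine-Gray subdistribution-hazard regression
#'
#' Fits the subdistribution hazard model for the endpoint event
#' (`event_type == 1`) in the presence of the competing event
#' (`event_type == 2`), via the inverse-probability-of-censoring
#' weighted data expansion of [survival::finegray()] followed by a
#' weighted Cox fit with robust (sandwich) standard errors.  Without
#' competing events the model coincides with cause-specific Cox
#' regression.
#'
#' @inheritParams coxUnivariate
#' @return one-row data.frame as [coxUnivariate()], with
#'   `analysis = "finegray"`.
#' @export
finegrayUnivariate <- function(x, outcome, gene_id = "x") {
    if (is.null(outcome$event_type))
        stop("finegray analysis requires an 'event_type' column")
    if (!any(outcome$event_type == 1L))
        stop("no endpoint events (event_type == 1) present")
    if (length(x) != nrow(outcome))
        stop("covariate and outcome lengths differ")
    fg <- .finegrayExpand(outcome)
    dat <- fg
    dat$x <- x[fg$.row]
    fit <- coxph(Surv(fgstart, fgstop, fgstatus) ~ x, data = dat,
                 weights = fgwt, id = .row, robust = TRUE,
                 control = coxph.control(eps = 1e-11, iter.max = 50,
                                         timefix = FALSE))
    beta <- unname(stats::coef(fit))
    se <- sqrt(diag(fit$var))[1L]
    z <- beta / se
    data.frame(gene_id = gene_id, beta = beta, se = se, z = z,
               p = 2 * pnorm(-abs(z)), analysis = "finegray",
               degenerate = FALSE, converged = TRUE,
               stringsAsFactors = FALSE)
}

## The IPCW expansion depends only on the outcome, so screening many
## genes reuses one expansion (.row maps expanded rows to samples).
.finegrayExpand <- function(outcome) {
    status <- factor(outcome$event_type, levels = c(0L, 1L, 2L),
                     labels = c("censored", "endpoint", "competing"))
    df <- data.frame(time = as.numeric(outcome$time), status = status,
                     .row = seq_len(nrow(outcome)))
    survival::finegray(Surv(time, status) ~ ., data = df,
                       etype = "endpoint")
}

#' Screen every gene for univariate survival association
#'
#' Fits a univariate model per gene (cause-specific Cox by default, or
#' Fine-Gray subdistribution regression) and selects genes with Wald
#' `p < alpha`.  Each gene is standardized to mean 0, SD 1 across the
#' supplied samples before fitting, so the reported coefficient is a
#' per-SD log hazard ratio and the z statistics are comparable across
#' genes.  Zero-variance genes are flagged degenerate, never selected.
#'
#' @param matrix genes x samples expression matrix, or an
#'   [MRSExperiment-class].
#' @param outcome outcome data.frame (`sample_id`, `time`, `event`,
#'   `event_type`) covering the matrix samples.
#' @param alpha significance cutoff (default 0.001).
#' @param analysis `"cox"` or `"finegray"`.
#' @param standardize standardize each gene before fitting
#'   (default TRUE).
#' @return data.frame with one row per gene: `gene_id`, `beta`, `se`,
#'   `z`, `p`, `analysis`, `degenerate`, `selected`.
#' @export
screenGenes <- function(matrix, outcome, alpha = 0.001,
                        analysis = c("cox", "finegray"),
                        standardize = TRUE) {
    analysis <- match.arg(analysis)
    if (is(matrix, "MRSExperiment")) matrix <- exprsMatrix(matrix)
    stopifnot(is.matrix(matrix))
    if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
    ids <- colnames(matrix)
    if (!is.null(outcome$sample_id)) {
        common <- intersect(ids, outcome$sample_id)
        if (!length(common))
            stop("no overlapping samples between matrix and outcomes")
        matrix <- matrix[, common, drop = FALSE]
        outcome <- outcome[match(common, outcome$sample_id), , drop = FALSE]
    } else if (nrow(outcome) != ncol(matrix)) {
        stop("no sample ids and outcome length differs from sample count")
    }
    X <- matrix
    ctr <- rowMeans(X)
    sdv <- sqrt(pmax(0, rowMeans(X^2) - ctr^2)) * sqrt(ncol(X) / (ncol(X) - 1))
    degen <- sdv == 0
    if (standardize) {
        X <- (X - ctr) / ifelse(degen, 1, sdv)
    }
    if (analysis == "cox") {
        cs <- .asCauseSpecific(outcome)
        fit <- .coxEngine(X, cs$time, cs$event)
        res <- data.frame(gene_id = rownames(matrix), beta = fit$beta,
                          se = fit$se, z = fit$z, p = fit$p,
                          analysis = "cox",
                          degenerate = fit$degenerate | degen,
                          stringsAsFactors = FALSE)
    } else {
        fg <- .finegrayExpand(outcome)
        rows <- lapply(seq_len(nrow(X)), function(g) {
            if (degen[g])
                return(data.frame(gene_id = rownames(matrix)[g], beta = 0,
                                  se = Inf, z = 0, p = 1,
                                  analysis = "finegray", degenerate = TRUE,
                                  stringsAsFactors = FALSE))
            r <- finegrayUnivariate(X[g, ], outcome,
                                    gene_id = rownames(matrix)[g])
            r$converged <- NULL
            r
        })
        res <- do.call(rbind, rows)
    }
    res$selected <- !res$degenerate & res$p < alpha
    rownames(res) <- NULL
    res
}

#' Gene ids selected by a screening run
#' @param results a [screenGenes()] result.
#' @return character vector of selected gene ids.
#' @export
selectedGenes <- function(results) results$gene_id[results$selected]

#' Compare two per-gene p-value sets
#'
#' The diagnostic behind the competing-risks sensitivity check:
#' correlates the per-gene p-values of two screening analyses (for
#' example cause-specific Cox vs Fine-Gray) over their shared gene
#' universe.
#'
#' @param results_a,results_b [screenGenes()] results over the same
#'   genes.
#' @return list with `correlation` (Pearson, on the p-value scale) and
#'   `table` (gene_id, p_a, p_b) for plotting.
#' @export
comparePvalueSets <- function(results_a, results_b) {
    m <- merge(results_a[, c("gene_id", "p")],
               results_b[, c("gene_id", "p")],
               by = "gene_id", suffixes = c("_a", "_b"))
    if (nrow(m) < 3L)
        stop("need at least 3 shared genes to compare p-value sets")
    list(correlation = cor(m$p_a, m$p_b),
         table = m[order(m$gene_id), ])
}

## Cox score test (z at beta = 0) of one covariate; used by
## cross-validation to evaluate held-out risk scores.
.coxScoreZ <- function(x, time, event) {
    fit <- .coxEngine(matrix(x, nrow = 1L), time, event, iterate = FALSE)
    fit$score_z[1L]
}
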