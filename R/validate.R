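#' Clinical risk score from the five adverse factors
#'
#' One point each for node-positive primary, disease-free interval
#' under 12 months, preoperative CEA above 200 ng/ml, more than one
#' hepatic tumor, and largest tumor above 5 cm; a sum of 3 or more is
#' high risk.
#'
#' @param clinical data.frame with `sample_id` and the five logical
#'   factor columns, no missing values.
#' @return data.frame `sample_id`, `crs` (0-5), `crs_group`
#'   (`"high"` if `crs >= 3`, else `"low"`).
#' @export
computeCRS <- function(clinical) {
    miss <- setdiff(.CLINICAL_FACTORS, colnames(clinical))
    if (length(miss))
        stop("missing clinical factors: ", paste(miss, collapse = ", "))
    fac <- as.matrix(clinical[.CLINICAL_FACTORS])
    if (anyNA(fac))
        stop("input error: missing values in clinical factors")
    score <- as.integer(rowSums(fac))
    data.frame(sample_id = clinical$sample_id, crs = score,
               crs_group = ifelse(score >= 3L, "high", "low"),
               stringsAsFactors = FALSE)
}

#' Random 2:1 train/test split
#'
#' Uniformly random partition with a 2:1 train:test ratio, rounding
#' toward the training set, reproducible from the seed.
#'
#' @param sample_ids character vector, at least 3 samples.
#' @param seed integer seed.
#' @return list of class `"CohortSplit"`: `train_ids`, `test_ids`,
#'   `seed`.
#' @export
splitCohort <- function(sample_ids, seed = 1L) {
    n <- length(sample_ids)
    if (n < 3L) stop("need at least 3 samples to split 2:1")
    if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
    set.seed(seed %% .Machine$integer.max)
    n_test <- floor(n / 3)
    test <- sort(sample(sample_ids, n_test))
    structure(list(train_ids = setdiff(sample_ids, test),
                   test_ids = test, seed = as.integer(seed)),
              class = "CohortSplit")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param outcomes outcome data.frame with `time` and `event`
#'   (competing `event_type == 2` is treated as censoring).
#' @return data.frame of class `"KMCurve"` with one row per distinct
#'   event time: `time`, `n_risk`, `n_event`, `survival`; attribute
#'   `max_followup` is the largest observed time.
#' @export
kmEstimate <- function(outcomes) {
    cs <- .asCauseSpecific(outcomes)
    if (!length(cs$time)) stop("empty outcome set")
    fit <- survfit(Surv(cs$time, cs$event) ~ 1)
    keep <- fit$n.event > 0
    out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                      n_event = fit$n.event[keep],
                      survival = fit$surv[keep])
    attr(out, "max_followup") <- max(cs$time)
    class(out) <- c("KMCurve", "data.frame")
    out
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation; `S(0) = 1`.  Beyond the
#' last follow-up time the last value is returned with attribute
#' `extrapolated = TRUE`.
#'
#' @param curve a [kmEstimate()] result.
#' @param t non-negative time (months).
#' @return survival probability (attribute `extrapolated` if `t`
#'   exceeds follow-up).
#' @export
survivalAt <- function(curve, t) {
    stopifnot(t >= 0)
    s <- c(1, curve$survival)[findInterval(t, curve$time) + 1L]
    mf <- attr(curve, "max_followup")
    if (!is.null(mf) && t > mf) attr(s, "extrapolated") <- TRUE
    s
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank chi-square on `k - 1` degrees of
#' freedom comparing the survival distributions of two or more groups.
#'
#' @param outcomes outcome data.frame (`time`, `event`; competing
#'   events censored).
#' @param group vector of group labels aligned with `outcomes`.
#' @return list `chisq`, `df`, `p`.
#' @export
logrankTest <- function(outcomes, group) {
    cs <- .asCauseSpecific(outcomes)
    group <- as.factor(as.character(group))
    if (nlevels(group) < 2L)
        stop("log-rank test needs at least two groups")
    if (sum(cs$event) < 1L) stop("no events")
    sd <- survdiff(Surv(cs$time, cs$event) ~ group)
    df <- nlevels(group) - 1L
    list(chisq = unname(sd$chisq), df = df,
         p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Among permissible pairs (the shorter observed time is an event;
#' pairs with tied times and both events are excluded; with tied times
#' and exactly one event, the event is taken as the earlier failure),
#' the fraction in which the higher risk score belongs to the earlier
#' failure, counting score ties 1/2.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param outcomes outcome data.frame aligned with `scores`
#'   (competing events censored).
#' @return concordance in `[0, 1]`.
#' @export
concordanceIndex <- function(scores, outcomes) {
    cs <- .asCauseSpecific(outcomes)
    n <- length(scores)
    stopifnot(n == length(cs$time))
    if (anyNA(scores)) stop("missing scores")
    t <- cs$time; e <- cs$event
    ## pair (i, j) permissible with i the failure:
    ##   t_i < t_j and e_i = 1, or t_i = t_j and e_i = 1, e_j = 0
    Tl <- outer(t, t, `<`); Te <- outer(t, t, `==`)
    Ei <- matrix(e == 1L, n, n)
    Ej <- t(Ei)
    perm <- (Tl & Ei) | (Te & Ei & !Ej)
    if (!any(perm)) stop("no permissible pairs")
    Sg <- outer(scores, scores, `>`); Se <- outer(scores, scores, `==`)
    conc <- sum(perm & Sg) + 0.5 * sum(perm & Se)
    conc / sum(perm)
}

#' Multivariate Cox regression with Wald intervals
#'
#' Efron-tie Cox model over the supplied covariates; hazard ratios
#' with normal-approximation 95% confidence intervals and Wald
#' p-values.  Collinear covariates raise an error naming the aliased
#' columns.
#'
#' @param covariates data.frame of numeric/logical covariates (one
#'   column per term), rows aligned with `outcomes`.
#' @param outcomes outcome data.frame (competing events censored).
#' @return data.frame `term`, `beta`, `se`, `hr`, `lo95`, `hi95`, `p`.
#' @export
coxMultivariate <- function(covariates, outcomes) {
    cs <- .asCauseSpecific(outcomes)
    M <- as.matrix(data.frame(lapply(covariates, as.numeric)))
    if (nrow(M) != length(cs$time))
        stop("covariates and outcomes are not aligned")
    qx <- qr(cbind(1, M))
    if (qx$rank < ncol(M) + 1L) {
        aliased <- colnames(M)[qx$pivot[seq_len(ncol(M) + 1L) > qx$rank] - 1L]
        aliased <- aliased[!is.na(aliased)]
        stop("collinear covariates: ",
             paste(aliased, collapse = ", "))
    }
    fit <- coxph(Surv(cs$time, cs$event) ~ M,
                 control = coxph.control(eps = 1e-11, iter.max = 50))
    beta <- unname(stats::coef(fit))
    se <- sqrt(diag(fit$var))
    data.frame(term = colnames(M), beta = beta, se = se,
               hr = exp(beta), lo95 = exp(beta - 1.96 * se),
               hi95 = exp(beta + 1.96 * se),
               p = 2 * pnorm(-abs(beta / se)),
               stringsAsFactors = FALSE)
}

#' Combine clinical and molecular risk classes into three groups
#'
#' Both scores high gives `"high"`, both low gives `"low"`, any
#' disagreement gives `"intermediate"`.
#'
#' @param crs_class,mrs_class vectors of `"high"`/`"low"` labels.
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
combineRiskGroups <- function(crs_class, mrs_class) {
    ok <- function(x) all(x %in% c("high", "low")) && !anyNA(x)
    if (length(crs_class) != length(mrs_class))
        stop("class vectors differ in length")
    if (!ok(crs_class) || !ok(mrs_class))
        stop("risk classes must be 'high' or 'low' with no missing values")
    out <- ifelse(crs_class == "high" & mrs_class == "high", "high",
                  ifelse(crs_class == "low" & mrs_class == "low", "low",
                         "intermediate"))
    factor(out, levels = c("low", "intermediate", "high"))
}

#' Build the validation report for a scored cohort
#'
#' Assembles, for one endpoint and one cohort, the Kaplan-Meier curves
#' and log-rank test for the frozen high/low MRS groups, concordance
#' indices of the continuous MRS and of the CRS, a multivariate Cox
#' model with the dichotomized CRS and MRS, 3-year survival per group,
#' and the combined CRS+MRS three-group stratification with its
#' log-rank test.
#'
#' @param scores [computeMRS()] result for the cohort.
#' @param crs [computeCRS()] result for the cohort.
#' @param outcomes outcome data.frame for the cohort.
#' @param endpoint `"dss"` or `"lrfs"`.
#' @param cohort label (e.g. `"test"`).
#' @return a [ValidationReport-class].
#' @export
buildReport <- function(scores, crs, outcomes,
                        endpoint = c("dss", "lrfs"), cohort = "test") {
    endpoint <- match.arg(endpoint)
    ids <- scores$sample_id
    if (is.null(ids)) stop("scores must carry sample ids")
    crs <- crs[match(ids, crs$sample_id), , drop = FALSE]
    outcomes <- outcomes[match(ids, outcomes$sample_id), , drop = FALSE]
    if (anyNA(crs$crs) || anyNA(outcomes$time))
        stop("scores, CRS and outcomes do not cover the same samples")
    combined <- combineRiskGroups(crs$crs_group, scores$group)

    km_all <- list()
    s3 <- list()
    addKM <- function(label, group) {
        for (g in unique(as.character(group))) {
            oc <- outcomes[group == g, , drop = FALSE]
            if (!nrow(oc)) next
            cv <- kmEstimate(oc)
            if (nrow(cv))
                km_all[[length(km_all) + 1L]] <<-
                    cbind(stratification = label, group = g,
                          as.data.frame(cv))
            s3[[length(s3) + 1L]] <<-
                data.frame(stratification = label, group = g,
                           survival = as.numeric(survivalAt(cv, 36)),
                           stringsAsFactors = FALSE)
        }
    }
    addKM("mrs", scores$group)
    addKM("combined", as.character(combined))

    lr_mrs <- if (length(unique(scores$group)) >= 2L)
        logrankTest(outcomes, scores$group)
    else list(chisq = NA_real_, df = NA_integer_, p = NA_real_)
    lr_comb <- if (nlevels(droplevels(combined)) >= 2L)
        logrankTest(outcomes, droplevels(combined))
    else list(chisq = NA_real_, df = NA_integer_, p = NA_real_)

    conc <- c(mrs = concordanceIndex(scores$mrs, outcomes),
              crs = concordanceIndex(crs$crs, outcomes))

    cov <- data.frame(crs_high = crs$crs_group == "high",
                      mrs_high = scores$group == "high")
    cox <- tryCatch(coxMultivariate(cov, outcomes),
                    error = function(e)
                        data.frame(term = character(), beta = numeric(),
                                   se = numeric(), hr = numeric(),
                                   lo95 = numeric(), hi95 = numeric(),
                                   p = numeric()))

    per_sample <- data.frame(sample_id = ids, mrs = scores$mrs,
                             mrs_group = scores$group, crs = crs$crs,
                             crs_group = crs$crs_group,
                             combined_group = as.character(combined),
                             stringsAsFactors = FALSE)
    new("ValidationReport", endpoint = endpoint, cohort = cohort,
        km = do.call(rbind, km_all), logrank = list(mrs = lr_mrs,
                                                    combined = lr_comb),
        concordance = conc, cox = cox,
        surv3yr = do.call(rbind, s3), scores = per_sample)
}

#' Serialize a validation report to a plain list
#'
#' @param report a [ValidationReport-class].
#' @return nested list suitable for JSON serialization.
#' @export
reportToList <- function(report) {
    list(endpoint = report@endpoint, cohort = report@cohort,
         concordance = as.list(report@concordance),
         logrank = report@logrank,
         cox = report@cox, surv3yr = report@surv3yr,
         km = report@km, scores = report@scores)
}
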