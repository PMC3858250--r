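test_that("the clinical risk score sums adverse factors with the >=3
           high-risk boundary", {
    crs <- computeCRS(clinical_with_counts(c(5, 0, 3, 2)))
    expect_equal(crs$crs, c(5L, 0L, 3L, 2L))
    expect_equal(crs$crs_group, c("high", "low", "high", "low"))
    bad <- clinical_with_counts(c(1, 2))
    bad$cea_gt_200 <- NULL
    expect_error(computeCRS(bad), "cea_gt_200")
    bad2 <- clinical_with_counts(c(1, 2))
    bad2$node_positive[1] <- NA
    expect_error(computeCRS(bad2), "missing")
})

test_that("the cohort split honors the 2:1 ratio, reproducibility and
           uniformity", {
    ids <- sprintf("p%03d", 1:96)
    sp <- splitCohort(ids, seed = 5)
    expect_length(sp$train_ids, 64)
    expect_length(sp$test_ids, 32)
    expect_setequal(c(sp$train_ids, sp$test_ids), ids)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_identical(splitCohort(ids, seed = 5), sp)
    expect_error(splitCohort(ids[1:2]), "3")

    counts <- integer(length(ids)); names(counts) <- ids
    nrep <- 4000
    for (s in seq_len(nrep))
        counts[splitCohort(ids, seed = s)$test_ids] <-
            counts[splitCohort(ids, seed = s)$test_ids] + 1L
    expect_true(all(abs(counts / nrep - 1 / 3) < 0.03))
})

test_that("the product-limit estimator matches hand computation and
           reduces to the empirical survival function", {
    allc <- data.frame(time = c(2, 4, 7), event = 0L)
    expect_equal(kmEstimate(allc)$survival, numeric(0))
    expect_equal(survivalAt(kmEstimate(allc), 5), 1)

    hand <- data.frame(time = c(1, 2, 3), event = c(0L, 1L, 1L))
    cv <- kmEstimate(hand)
    expect_equal(survivalAt(cv, 2), 0.5, tolerance = 1e-10)
    expect_equal(survivalAt(cv, 2.5), 0.5, tolerance = 1e-10)
    expect_equal(survivalAt(cv, 3), 0, tolerance = 1e-10)
    expect_equal(survivalAt(cv, 0), 1)

    set.seed(2)
    t <- sort(rexp(30)); noc <- data.frame(time = t, event = 1L)
    cv2 <- kmEstimate(noc)
    expect_equal(cv2$survival, 1 - seq_len(30) / 30)

    far <- survivalAt(cv, 99)
    expect_true(isTRUE(attr(far, "extrapolated")))
})

test_that("the log-rank test matches hand O-E/V arithmetic, is
           symmetric in labels, and vanishes for identical groups", {
    oc <- data.frame(time = c(1, 3, 5, 2, 4, 6),
                     event = c(1, 1, 1, 1, 1, 0))
    grp <- rep(c("A", "B"), each = 3)
    res <- logrankTest(oc, grp)
    expect_equal(res$chisq, oracle_logrank(oc$time, oc$event, grp),
                 tolerance = 1e-10)
    expect_equal(logrankTest(oc, ifelse(grp == "A", "B", "A"))$chisq,
                 res$chisq, tolerance = 1e-12)

    dup <- rbind(oc, oc)
    expect_equal(logrankTest(dup, rep(c("A", "B"), each = 6))$chisq, 0)
    expect_error(logrankTest(oc, rep("A", 6)), "two groups")
})

test_that("log-rank type-I error is nominal under the null", {
    set.seed(7)
    rej <- 0; nsim <- 400
    for (i in 1:nsim) {
        oc <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.7))
        if (logrankTest(oc, rep(c("A", "B"), 30))$p < 0.05)
            rej <- rej + 1
    }
    ci <- qbinom(c(0.005, 0.995), nsim, 0.05)
    expect_gte(rej, ci[1])
    expect_lte(rej, ci[2])
})

test_that("concordance hits its exact extremes and the reversal
           property", {
    n <- 20
    set.seed(3)
    t <- sort(rexp(n))
    oc <- data.frame(time = t, event = 1L)
    expect_equal(concordanceIndex(-t, oc), 1)
    expect_equal(concordanceIndex(t, oc), 0)
    s <- rnorm(n)
    expect_equal(concordanceIndex(s, oc),
                 1 - concordanceIndex(-s, oc), tolerance = 1e-12)
    expect_error(concordanceIndex(rep(1, 3),
                                  data.frame(time = c(1, 1, 1),
                                             event = c(1L, 1L, 1L))),
                 "permissible")
})

test_that("multivariate Cox reduces to the univariate fit, recovers
           planted effects, and names collinear covariates", {
    oc <- random_outcome(50, seed = 21)
    x <- rbinom(50, 1, 0.5)
    uni <- coxUnivariate(x, oc)
    multi <- coxMultivariate(data.frame(x = x), oc)
    expect_equal(multi$beta, uni$beta, tolerance = 1e-10)
    expect_true(multi$lo95 <= multi$hr && multi$hr <= multi$hi95)

    expect_error(coxMultivariate(data.frame(a = x, b = x), oc),
                 "collinear.*b")

    set.seed(22)
    n <- 500
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.4)
    tt <- rexp(n, 0.05 * exp(0.7 * a + 0.4 * b))
    cc <- rexp(n, 0.03)
    oc2 <- data.frame(time = pmin(tt, cc),
                      event = as.integer(tt <= cc))
    fit <- coxMultivariate(data.frame(a = a, b = b), oc2)
    expect_lt(abs(fit$beta[1] - 0.7), 3 * fit$se[1])
    expect_lt(abs(fit$beta[2] - 0.4), 3 * fit$se[2])
})

test_that("combined risk groups follow the three-way rule and
           partition any cohort", {
    expect_equal(as.character(combineRiskGroups("high", "high")),
                 "high")
    expect_equal(as.character(combineRiskGroups("low", "low")), "low")
    expect_equal(as.character(combineRiskGroups("high", "low")),
                 "intermediate")
    expect_equal(as.character(combineRiskGroups("low", "high")),
                 "intermediate")
    set.seed(4)
    crs <- sample(c("high", "low"), 50, TRUE)
    mrs <- sample(c("high", "low"), 50, TRUE)
    cmb <- combineRiskGroups(crs, mrs)
    expect_false(anyNA(cmb))
    expect_equal(length(cmb), 50)
    expect_error(combineRiskGroups(c("high", NA), c("low", "low")),
                 "missing")
})

test_that("the validation report is deterministic and traceable to its
           components", {
    cfg <- simulationConfig(n_samples = 100, n_genes = 200,
                            effect_size = 0.6, seed = 31)
    coh <- simulateCohort(cfg)
    oc <- dssOutcomes(coh)
    m <- fitSignature(exprsMatrix(coh), oc, cutpoint = 0.001)
    sc <- computeMRS(m, exprsMatrix(coh))
    crs <- computeCRS(clinicalFactors(coh))
    r1 <- buildReport(sc, crs, oc, endpoint = "dss", cohort = "train")
    r2 <- buildReport(sc, crs, oc, endpoint = "dss", cohort = "train")
    expect_identical(reportToList(r1), reportToList(r2))
    expect_equal(unname(r1@concordance["mrs"]),
                 concordanceIndex(sc$mrs, oc))
    expect_equal(r1@logrank$mrs$p, logrankTest(oc, sc$group)$p)
    km_high <- r1@km[r1@km$stratification == "mrs" &
                     r1@km$group == "high", ]
    direct <- kmEstimate(oc[sc$group == "high", ])
    expect_equal(km_high$survival, direct$survival)
    expect_error(buildReport(sc[1:10, ], crs[11:20, ], oc), "cover")
})
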