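test_that("genes rank by |z| with a lexicographic tie-break and the
           ranking survives covariate rescaling", {
    res <- data.frame(gene_id = c("gene1", "gene2", "gene3"),
                      beta = c(1, -2, 0.3), se = 1,
                      z = c(2.1, -3.5, 0.4), p = c(0.03, 0.001, 0.7),
                      analysis = "cox", degenerate = FALSE,
                      selected = TRUE)
    expect_identical(rankGenes(res)$gene_id,
                     c("gene2", "gene1", "gene3"))
    tie <- res; tie$z <- c(-2, 2, 2)
    expect_identical(rankGenes(tie)$gene_id,
                     c("gene1", "gene2", "gene3"))

    oc <- random_outcome(40, seed = 3)
    X <- random_matrix(15, 40, seed = 3)
    r1 <- rankGenes(screenGenes(X, oc, standardize = FALSE))
    r2 <- rankGenes(screenGenes(X * 7, oc, standardize = FALSE))
    expect_identical(r1$gene_id, r2$gene_id)
})

test_that("cross-validation returns a lone candidate, is reproducible,
           and prefers signal-bearing cutpoints over a null cohort's", {
    cfg <- simulationConfig(n_samples = 120, n_genes = 300, seed = 41)
    coh <- simulateCohort(cfg)
    oc <- dssOutcomes(coh)
    one <- cvSelectThreshold(exprsMatrix(coh), oc, grid = 0.001,
                             seed = 2)
    expect_equal(one$cutpoint, 0.001)

    a <- cvSelectThreshold(exprsMatrix(coh), oc, seed = 7)
    b <- cvSelectThreshold(exprsMatrix(coh), oc, seed = 7)
    expect_identical(a, b)

    hits <- 0; margin <- 0
    for (s in 1:5) {
        sig_cfg <- simulationConfig(n_samples = 120, n_genes = 300,
                                    effect_size = 0.7, seed = 100 + s)
        nul_cfg <- simulationConfig(n_samples = 120, n_genes = 300,
                                    effect_size = 0, clinical_effect = 0,
                                    seed = 100 + s)
        sig <- simulateCohort(sig_cfg); nul <- simulateCohort(nul_cfg)
        cv_sig <- cvSelectThreshold(exprsMatrix(sig), dssOutcomes(sig),
                                    seed = s)
        cv_nul <- cvSelectThreshold(exprsMatrix(nul), dssOutcomes(nul),
                                    seed = s)
        if (max(cv_sig$cv$mean_stat) > max(cv_nul$cv$mean_stat))
            margin <- margin + 1
        sel <- selectedGenes(screenGenes(exprsMatrix(sig),
                                         dssOutcomes(sig),
                                         alpha = cv_sig$cutpoint))
        if (length(intersect(sel, truthGenes(sig)$genes)) >=
            length(truthGenes(sig)$genes) / 2)
            hits <- hits + 1
    }
    expect_gte(margin, 4)
    expect_gte(hits, 4)
})

test_that("a rank-one selected submatrix yields scores aligned with the
           latent direction", {
    set.seed(50)
    n <- 60
    v <- rnorm(n)
    loading <- runif(10, 0.5, 2) * sample(c(-1, 1), 10, TRUE)
    X <- outer(loading, v)
    rownames(X) <- paste0("g", sprintf("%02d", 1:10))
    colnames(X) <- paste0("s", sprintf("%02d", 1:n))
    oc <- data.frame(sample_id = colnames(X),
                     time = rexp(n, 0.05 * exp(v)),
                     event = 1L)
    model <- fitSignature(X, oc, cutpoint = 1, weight_mode = "pc1")
    sc <- computeMRS(model, X)
    expect_gt(abs(cor(sc$mrs, v)), 0.999)
})

test_that("training MRS always has a positive Cox coefficient and the
           two weight modes estimate the same direction", {
    cors <- numeric(5)
    for (s in 1:5) {
        cfg <- simulationConfig(n_samples = 120, n_genes = 300,
                                effect_size = 0.6, seed = 200 + s)
        coh <- simulateCohort(cfg)
        oc <- dssOutcomes(coh)
        for (wm in c("pc1", "coef")) {
            m <- fitSignature(exprsMatrix(coh), oc, cutpoint = 0.001,
                              weight_mode = wm)
            sc <- computeMRS(m, exprsMatrix(coh))
            expect_gt(coxUnivariate(sc$mrs, oc)$beta, 0)
            if (wm == "pc1") pc1 <- sc$mrs else cf <- sc$mrs
        }
        cors[s] <- cor(pc1, cf)
    }
    expect_gte(sum(cors >= 0.8), 4)
})

test_that("the frozen median split gives exactly n/2 high and low on
           even-sized training data with distinct scores", {
    cfg <- simulationConfig(n_samples = 100, n_genes = 200,
                            effect_size = 0.7, seed = 61)
    coh <- simulateCohort(cfg)
    m <- fitSignature(exprsMatrix(coh), dssOutcomes(coh),
                      cutpoint = 0.001)
    sc <- computeMRS(m, exprsMatrix(coh))
    expect_equal(unname(table(sc$group)["high"]), 50)
    expect_equal(unname(table(sc$group)["low"]), 50)

    ## with odd n the median is a realized score; that sample ties the
    ## threshold and must go low
    cfg1 <- simulationConfig(n_samples = 101, n_genes = 200,
                             effect_size = 0.7, seed = 62)
    coh1 <- simulateCohort(cfg1)
    m1 <- fitSignature(exprsMatrix(coh1), dssOutcomes(coh1),
                       cutpoint = 0.001)
    sc1 <- computeMRS(m1, exprsMatrix(coh1))
    expect_identical(unique(sc1$group[sc1$mrs == mrsThreshold(m1)]),
                     "low")
    expect_equal(unname(table(sc1$group)["low"]), 51)
})

test_that("scoring is a frozen pure function of the model and matrix", {
    cfg <- simulationConfig(n_samples = 90, n_genes = 150,
                            effect_size = 0.6, seed = 71)
    coh <- simulateCohort(cfg)
    m <- fitSignature(exprsMatrix(coh), dssOutcomes(coh),
                      cutpoint = 0.001)
    X <- exprsMatrix(coh)
    expect_identical(computeMRS(m, X), computeMRS(m, X))
    ## samples sitting exactly at the per-gene centers score zero
    ctr <- matrix(m@center, ncol = 1,
                  dimnames = list(m@genes, "ctr"))
    expect_equal(computeMRS(m, ctr)$mrs, 0)
    expect_error(computeMRS(m, X[-match(m@genes[1], rownames(X)), ]),
                 m@genes[1])
})

test_that("a one-gene signature is that gene's standardized expression
           up to sign", {
    set.seed(81)
    n <- 80
    X <- random_matrix(5, n, seed = 81)
    oc <- data.frame(sample_id = colnames(X),
                     time = rexp(n, 0.05 * exp(0.9 * X[1, ])),
                     event = 1L)
    scr <- screenGenes(X, oc)
    cut <- sort(scr$p)[1] * 1.0001    # admit exactly the top gene
    m <- fitSignature(X, oc, cutpoint = cut)
    expect_length(signatureGenes(m), 1L)
    g <- signatureGenes(m)
    z <- (X[g, ] - mean(X[g, ])) / sd(X[g, ])
    sc <- computeMRS(m, X)
    expect_equal(abs(cor(sc$mrs, z)), 1, tolerance = 1e-12)
})

test_that("errors demand a workable cutpoint and complete gene sets", {
    oc <- random_outcome(30, seed = 91)
    X <- random_matrix(10, 30, seed = 91)
    expect_error(fitSignature(X, cbind(oc, event_type = oc$event),
                              cutpoint = 1e-12), "cutpoint")
})

test_that("signature JSON round-trips to identical scores", {
    cfg <- simulationConfig(n_samples = 80, n_genes = 120,
                            effect_size = 0.7, seed = 99)
    coh <- simulateCohort(cfg)
    m <- fitSignature(exprsMatrix(coh), dssOutcomes(coh),
                      cutpoint = 0.001)
    path <- tempfile(fileext = ".json")
    writeSignature(m, path)
    m2 <- readSignature(path)
    expect_identical(computeMRS(m, exprsMatrix(coh)),
                     computeMRS(m2, exprsMatrix(coh)))
})
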