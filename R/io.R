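#' @importFrom data.table fread fwrite
#' @importFrom jsonlite write_json read_json toJSON fromJSON
NULL

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene
#' identifiers and whose header row holds sample identifiers.
#' Duplicate identifiers, blank or non-numeric cells are rejected with
#' their coordinates.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames, sample colnames.
#' @export
readExpression <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1L),
                            data.table = FALSE, na.strings = NULL)
    if (ncol(dt) < 2L) stop("malformed expression file: no sample columns")
    gene_ids <- dt[[1L]]
    dup <- gene_ids[duplicated(gene_ids)]
    if (length(dup))
        stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
    samples <- colnames(dt)[-1L]
    if (anyDuplicated(samples))
        stop("duplicated sample id(s) in header")
    vals <- dt[, -1L, drop = FALSE]
    X <- matrix(NA_real_, nrow(dt), length(samples),
                dimnames = list(gene_ids, samples))
    for (j in seq_along(samples)) {
        col <- vals[[j]]
        if (is.character(col)) {
            num <- suppressWarnings(as.numeric(col))
            bad <- which(is.na(num))
            if (length(bad))
                stop(sprintf(
                    "non-numeric or blank cell at row %d (gene '%s'), column '%s'",
                    bad[1L] + 1L, gene_ids[bad[1L]], samples[j]))
            col <- num
        }
        if (anyNA(col))
            stop(sprintf("missing value at gene '%s', column '%s'",
                         gene_ids[which(is.na(col))[1L]], samples[j]))
        X[, j] <- col
    }
    if (nrow(X) > 2L && ncol(X) > 2L && nrow(X) < ncol(X))
        stop("more samples than genes: input looks transposed; ",
             "supply genes in rows")
    X
}

#' Write an expression matrix as TSV
#' @param matrix genes x samples numeric matrix.
#' @param path output path.
#' @export
writeExpression <- function(matrix, path) {
    df <- data.frame(gene_id = rownames(matrix), matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t")
    invisible(path)
}

#' Read clinical factors and survival outcomes from CSV
#'
#' The clinical CSV must contain `sample_id` and the five CRS factor
#' columns (logical or 0/1, no missing values, mirroring the study's
#' exclusion of incomplete CRS data); the outcome CSV must contain
#' `sample_id`, `time_months`, `event` and `event_type`.  When
#' `expression_ids` is given, rows are aligned to it and samples
#' missing from either side are reported in the `exclusions`
#' attribute.
#'
#' @param clinical_path,outcome_path file paths.
#' @param expression_ids optional sample ids to align to.
#' @return list `clinical`, `outcomes`; attribute `exclusions`.
#' @export
readClinicalOutcomes <- function(clinical_path, outcome_path,
                                 expression_ids = NULL) {
    clin <- data.table::fread(clinical_path, data.table = FALSE)
    if (!"sample_id" %in% colnames(clin))
        stop("clinical file lacks a 'sample_id' column")
    miss <- setdiff(.CLINICAL_FACTORS, colnames(clin))
    if (length(miss))
        stop("clinical file missing CRS factor(s): ",
             paste(miss, collapse = ", "))
    for (f in .CLINICAL_FACTORS) {
        v <- clin[[f]]
        if (is.numeric(v) && all(v %in% c(0, 1))) v <- v == 1
        if (!is.logical(v) || anyNA(v))
            stop(sprintf("factor '%s' must be complete logical/0-1", f))
        clin[[f]] <- v
    }
    oc <- data.table::fread(outcome_path, data.table = FALSE)
    need <- c("sample_id", "time_months", "event")
    miss <- setdiff(need, colnames(oc))
    if (length(miss))
        stop("outcome file missing column(s): ",
             paste(miss, collapse = ", "))
    if (any(!is.finite(oc$time_months)) || any(oc$time_months <= 0))
        stop("validation error: times must be positive months")
    if (is.null(oc$event_type)) oc$event_type <- as.integer(oc$event)
    outcomes <- data.frame(sample_id = oc$sample_id,
                           time = as.numeric(oc$time_months),
                           event = as.integer(oc$event),
                           event_type = as.integer(oc$event_type),
                           stringsAsFactors = FALSE)
    excl <- list()
    if (!is.null(expression_ids)) {
        excl$clinical_only <- setdiff(clin$sample_id, expression_ids)
        excl$outcome_only <- setdiff(outcomes$sample_id, expression_ids)
        excl$expression_only <- setdiff(expression_ids,
                                        intersect(clin$sample_id,
                                                  outcomes$sample_id))
        keep <- intersect(expression_ids,
                          intersect(clin$sample_id, outcomes$sample_id))
        clin <- clin[match(keep, clin$sample_id), , drop = FALSE]
        outcomes <- outcomes[match(keep, outcomes$sample_id), ,
                             drop = FALSE]
    }
    structure(list(clinical = clin, outcomes = outcomes),
              exclusions = excl)
}

#' Write and read a frozen signature model as JSON
#'
#' Versioned schema (`schema = "survMRS/signature/v1"`) carrying the
#' genes, centers, scales, weights, orientation, weight mode and the
#' frozen threshold.
#'
#' @param model a [SignatureModel-class].
#' @param path file path.
#' @return `writeSignature` the path, invisibly; `readSignature` the
#'   model.
#' @export
writeSignature <- function(model, path) {
    obj <- list(schema = "survMRS/signature/v1",
                endpoint = model@endpoint, genes = model@genes,
                center = unname(model@center),
                scale = unname(model@scale),
                weights = unname(model@weights),
                weight_mode = model@weightMode,
                orientation = model@orientation,
                threshold = model@threshold, alpha = model@alpha)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$schema, "survMRS/signature/v1"))
        stop("unrecognized signature schema")
    new("SignatureModel", endpoint = obj$endpoint,
        genes = obj$genes,
        center = setNames(obj$center, obj$genes),
        scale = setNames(obj$scale, obj$genes),
        weights = setNames(obj$weights, obj$genes),
        weightMode = obj$weight_mode, orientation = obj$orientation,
        threshold = obj$threshold, alpha = obj$alpha, cv = list())
}

#' Write a synthetic cohort to plain-text files
#'
#' Expression TSV, clinical CSV, per-endpoint outcome CSVs
#' (`sample_id`, `time_months`, `event`, `event_type`) and the planted
#' truth as JSON.
#'
#' @param cohort an [MRSExperiment-class].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
               clinical = file.path(dir, "clinical.csv"),
               dss = file.path(dir, "outcomes_dss.csv"),
               lrfs = file.path(dir, "outcomes_lrfs.csv"),
               truth = file.path(dir, "truth.json"))
    writeExpression(exprsMatrix(cohort), paths["expression"])
    data.table::fwrite(clinicalFactors(cohort), paths["clinical"])
    for (ep in c("dss", "lrfs")) {
        oc <- endpointOutcomes(cohort, ep)
        data.table::fwrite(data.frame(sample_id = oc$sample_id,
                                      time_months = oc$time,
                                      event = oc$event,
                                      event_type = oc$event_type),
                           paths[ep])
    }
    jsonlite::write_json(truthGenes(cohort), paths["truth"],
                         auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

#' Run the whole molecular-risk-score pipeline
#'
#' Orchestrates simulate (or load) -> normalize -> split -> screen ->
#' train -> score -> validate, writing every stage artifact plus a
#' manifest (configuration, seeds and a configuration hash) into
#' `outdir`.  The frozen model derived from the training samples is
#' applied unchanged to the test samples.
#'
#' @param config list (or path to a YAML/JSON file) with optional
#'   entries: `simulation` (arguments to [simulationConfig()]), or
#'   `paths` (`expression`, `clinical`, `outcomes_dss`,
#'   `outcomes_lrfs`) for file input; `endpoint` (`"dss"` default);
#'   `weight_mode` (`"pc1"`); `alpha_grid`; `cv_folds` (5);
#'   `split_seed`, `cv_seed`; `normalize` (`"none"` default,
#'   `"joint"`, or `"frozen"`); `log2_offset` (1).
#' @param outdir output directory.
#' @return list with `model`, `report_train`, `report_test`, `split`,
#'   `screen`, and `paths` of written artifacts.
#' @export
runPipeline <- function(config = list(), outdir = tempfile("mrs_run_")) {
    if (is.character(config)) {
        config <- if (grepl("\\.ya?ml$", config))
            yaml::read_yaml(config)
        else jsonlite::read_json(config, simplifyVector = TRUE)
    }
    defaults <- list(endpoint = "dss", weight_mode = "pc1",
                     alpha_grid = 10^-(seq(2, 4, by = 0.5)),
                     cv_folds = 5L, split_seed = 1L, cv_seed = 1L,
                     normalize = "none", log2_offset = 1)
    config <- utils::modifyList(defaults, config)
    if (!config$endpoint %in% c("dss", "lrfs"))
        stop("config error: endpoint must be 'dss' or 'lrfs'")
    if (any(config$alpha_grid <= 0) || any(config$alpha_grid > 1))
        stop("config error: alpha_grid values must be in (0, 1]")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

    if (!is.null(config$paths)) {
        X <- readExpression(config$paths$expression)
        co <- readClinicalOutcomes(config$paths$clinical,
                                   config$paths$outcomes_dss,
                                   colnames(X))
        co2 <- readClinicalOutcomes(config$paths$clinical,
                                    config$paths$outcomes_lrfs,
                                    colnames(X))
        keep <- co$outcomes$sample_id
        cohort <- MRSExperiment(X[, keep, drop = FALSE], co$clinical,
                                co$outcomes, co2$outcomes)
    } else {
        simcfg <- do.call(simulationConfig,
                          as.list(config$simulation %||% list()))
        cohort <- simulateCohort(simcfg)
        config$simulation <- unclass(simcfg)
    }

    split <- splitCohort(colnames(cohort), seed = config$split_seed)
    if (config$normalize == "joint") {
        cohort <- normalizeCohort(cohort, offset = config$log2_offset)
    } else if (config$normalize == "frozen") {
        cohort <- normalizeCohort(cohort, offset = config$log2_offset,
                                  split = split)
    }
    train <- cohort[, split$train_ids]
    test <- cohort[, split$test_ids]
    oc_train <- endpointOutcomes(train, config$endpoint)
    oc_test <- endpointOutcomes(test, config$endpoint)

    cvres <- cvSelectThreshold(exprsMatrix(train), oc_train,
                               grid = config$alpha_grid,
                               folds = config$cv_folds,
                               weight_mode = config$weight_mode,
                               seed = config$cv_seed)
    model <- fitSignature(exprsMatrix(train), oc_train,
                          cutpoint = cvres$cutpoint,
                          weight_mode = config$weight_mode,
                          endpoint = config$endpoint, cv = cvres$cv)
    scr <- screenGenes(exprsMatrix(train), oc_train,
                       alpha = model@alpha)

    crs_all <- computeCRS(clinicalFactors(cohort))
    sc_train <- computeMRS(model, train)
    sc_test <- computeMRS(model, test)
    rep_train <- buildReport(sc_train,
                             crs_all[match(split$train_ids,
                                           crs_all$sample_id), ],
                             oc_train, endpoint = config$endpoint,
                             cohort = "train")
    rep_test <- buildReport(sc_test,
                            crs_all[match(split$test_ids,
                                          crs_all$sample_id), ],
                            oc_test, endpoint = config$endpoint,
                            cohort = "test")

    paths <- c(model = file.path(outdir, "signature.json"),
               screen = file.path(outdir, "screening.tsv"),
               scores_train = file.path(outdir, "scores_train.csv"),
               scores_test = file.path(outdir, "scores_test.csv"),
               report_train = file.path(outdir, "report_train.json"),
               report_test = file.path(outdir, "report_test.json"),
               split = file.path(outdir, "split.json"),
               manifest = file.path(outdir, "manifest.json"))
    writeSignature(model, paths["model"])
    data.table::fwrite(scr, paths["screen"], sep = "\t")
    data.table::fwrite(sc_train, paths["scores_train"])
    data.table::fwrite(sc_test, paths["scores_test"])
    jsonlite::write_json(reportToList(rep_train), paths["report_train"],
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(reportToList(rep_test), paths["report_test"],
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(unclass(split), paths["split"],
                         auto_unbox = TRUE)
    manifest <- list(package = "survMRS",
                     version = tryCatch(
                         as.character(utils::packageVersion("survMRS")),
                         error = function(e) "dev"),
                     config = config, config_hash = rlang::hash(config))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         force = TRUE)
    list(model = model, report_train = rep_train,
         report_test = rep_test, split = split, screen = scr,
         cv = cvres, paths = paths, cohort = cohort)
}
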