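## Independent oracles and tiny fixture builders used across the test
## suite.  The oracles are deliberately written as direct, loop-based
## transcriptions of the definitions, sharing no code with the package
## implementations they check.

## Efron-corrected Cox partial log-likelihood for one covariate,
## evaluated by explicit loops over event times.
oracle_cox_loglik <- function(beta, x, time, event) {
    ll <- 0
    for (tk in sort(unique(time[event == 1]))) {
        deaths <- which(time == tk & event == 1)
        risk <- which(time >= tk)
        d <- length(deaths)
        wd <- exp(beta * x[deaths])
        wr <- exp(beta * x[risk])
        ll <- ll + sum(beta * x[deaths])
        for (l in seq_len(d) - 1)
            ll <- ll - log(sum(wr) - (l / d) * sum(wd))
    }
    ll
}

## Grid maximizer of the Efron partial likelihood over [-5, 5]; the
## likelihood is evaluated for the whole beta grid at once from the
## same per-event-time sums the scalar version loops over.
oracle_cox_grid <- function(x, time, event, step = 1e-4) {
    grid <- seq(-5, 5, by = step)
    E <- exp(outer(grid, x))
    ll <- numeric(length(grid))
    for (tk in sort(unique(time[event == 1]))) {
        deaths <- which(time == tk & event == 1)
        risk <- which(time >= tk)
        d <- length(deaths)
        ll <- ll + grid * sum(x[deaths])
        Sr <- rowSums(E[, risk, drop = FALSE])
        Sd <- rowSums(E[, deaths, drop = FALSE])
        for (l in seq_len(d) - 1)
            ll <- ll - log(Sr - (l / d) * Sd)
    }
    grid[which.max(ll)]
}

## Harrell's c by exhaustive double loop, straight from the pair
## conventions: permissible if the shorter time is an event (ties in
## time with both events excluded; tied time, one event counts the
## event as earlier); score ties count 1/2.
oracle_concordance <- function(scores, time, event) {
    num <- 0; den <- 0
    n <- length(scores)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        permissible <- (time[i] < time[j] && event[i] == 1) ||
            (time[i] == time[j] && event[i] == 1 && event[j] == 0)
        if (!permissible) next
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
    }
    num / den
}

## Log-rank observed-minus-expected arithmetic for two groups, by
## explicit loops over event times.
oracle_logrank <- function(time, event, group) {
    gl <- sort(unique(group))
    stopifnot(length(gl) == 2)
    OE <- 0; V <- 0
    for (tk in sort(unique(time[event == 1]))) {
        at_risk <- time >= tk
        n <- sum(at_risk)
        n1 <- sum(at_risk & group == gl[1])
        d <- sum(event == 1 & time == tk)
        d1 <- sum(event == 1 & time == tk & group == gl[1])
        OE <- OE + d1 - d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    OE^2 / V
}

## Small right-censored outcome table with continuous (tie-free) times.
random_outcome <- function(n, event_frac = 0.7, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    data.frame(sample_id = sprintf("s%03d", seq_len(n)),
               time = round(rexp(n, 0.1), 6) + 0.01,
               event = rbinom(n, 1, event_frac),
               stringsAsFactors = FALSE)
}

## Tiny expression matrix with named dimensions.
random_matrix <- function(G, n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(rnorm(G * n), G, n,
           dimnames = list(sprintf("g%03d", seq_len(G)),
                           sprintf("s%03d", seq_len(n))))
}

## A clinical table with chosen factor counts per sample.
clinical_with_counts <- function(counts) {
    n <- length(counts)
    out <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    factors <- c("node_positive", "dfi_lt_12mo", "cea_gt_200",
                 "multiple_tumors", "size_gt_5cm")
    for (j in seq_along(factors))
        out[[factors[j]]] <- counts >= j
    out
}
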