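# Cox proportional-hazards screening and Kaplan-Meier reporting, built on
# the survival package (Efron tie handling throughout).

#' Fit a Cox proportional-hazards model
#'
#' Wraps [survival::coxph()] (Efron ties) and returns per-covariate
#' coefficients, standard errors, Wald z / p, hazard ratios with 95%
#' confidence intervals, and the log partial likelihood. Monotone-likelihood
#' (perfect separation) and other non-convergence is surfaced as an error
#' with the offending covariates named; collinear fits can be ridge-
#' stabilized via `ridge`.
#'
#' @param time,event survival times (> 0) and 0/1 event indicators.
#' @param X numeric covariate matrix (subjects x covariates) or vector.
#' @param ridge optional ridge penalty (theta) for stabilizing collinear
#'   candidate sets; 0 = none.
#' @return A `cox_fit`: data.frame `coefficients` (`beta`, `se`, `z`, `p`,
#'   `HR`, `ciLow`, `ciHigh`), `loglik`, `n`, `nevent`, `ridged`.
#' @export
coxFit <- function(time, event, X, ridge = 0) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < 1) stop("no events: Cox fit is undefined")
  vv <- apply(X, 2, sd)
  if (any(vv < 1e-12))
    stop("zero-variance covariate(s): ",
         paste(colnames(X)[vv < 1e-12], collapse = ", "))
  df <- data.frame(time = time, event = event)
  df <- cbind(df, as.data.frame(X))
  rhs <- paste(sprintf("`%s`", colnames(X)), collapse = " + ")
  if (ridge > 0)
    rhs <- sprintf("ridge(%s, theta = %g)",
                   paste(sprintf("`%s`", colnames(X)), collapse = ", "), ridge)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        stop("Cox fit did not converge (possible monotone likelihood / ",
             "perfect separation): ", conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(
        survival::coxph(fml, data = df, ties = "efron",
                        control = survival::coxph.control(iter.max = 50)))
    })
  sm <- summary(fit)
  co <- sm$coefficients
  beta <- co[, "coef"]
  se <- co[, grep("^se", colnames(co))[1]]
  structure(list(
    coefficients = data.frame(
      covariate = colnames(X)[seq_along(beta)],
      beta = as.numeric(beta), se = as.numeric(se),
      z = as.numeric(beta / se),
      p = as.numeric(2 * pnorm(-abs(beta / se))),
      HR = exp(as.numeric(beta)),
      ciLow = exp(as.numeric(beta - 1.96 * se)),
      ciHigh = exp(as.numeric(beta + 1.96 * se)),
      stringsAsFactors = FALSE),
    loglik = fit$loglik[length(fit$loglik)],
    n = fit$n, nevent = fit$nevent, ridged = ridge > 0),
    class = "cox_fit")
}

#' Univariate Cox screening of all features
#'
#' Fits a one-covariate Cox model per feature and flags features with Wald
#' p < alpha. Features whose fit fails (degenerate risk sets, perfect
#' separation) are reported in `failed` rather than silently dropped.
#'
#' @param table complete [RadiomicsFeatureTable-class] or subjects x features
#'   matrix.
#' @param time,event survival record (taken from the table's clinical data
#'   when omitted).
#' @param alpha significance level.
#' @return list with `results` (feature, beta, HR, p), `significant`
#'   (feature names with p < alpha) and `failed` (feature -> error message).
#' @export
screenUnivariate <- function(table, time = NULL, event = NULL, alpha = 0.05) {
  X <- if (is(table, "RadiomicsFeatureTable")) featureMatrix(table) else table
  if (anyNA(X)) stop("feature table must be complete (impute first)")
  if (is.null(time)) {
    cd <- clinicalData(table)
    time <- cd$survival_days; event <- cd$event
  }
  rows <- list(); failed <- character(0)
  for (f in colnames(X)) {
    ft <- tryCatch(coxFit(time, event, X[, f, drop = FALSE]),
                   error = function(e) conditionMessage(e))
    if (is.character(ft)) { failed[f] <- ft; next }
    co <- ft$coefficients
    rows[[f]] <- data.frame(feature = f, beta = co$beta, HR = co$HR,
                            p = co$p, stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), beta = numeric(0), HR = numeric(0),
               p = numeric(0))
  rownames(results) <- NULL
  list(results = results,
       significant = results$feature[results$p < alpha],
       failed = failed, alpha = alpha)
}

#' Multivariate refinement of univariate candidates
#'
#' Joint Cox fit of all univariately significant features; per-covariate Wald
#' p-values identify the features that stay significant. An empty candidate
#' set returns an empty fit (no error); a collinear set is refit with a small
#' ridge penalty and flagged.
#'
#' @param candidates character vector of feature names.
#' @param table,time,event as in [screenUnivariate()].
#' @return A `cox_fit`, or a list with `coefficients = NULL` when
#'   `candidates` is empty.
#' @export
multivariateRefine <- function(candidates, table, time = NULL, event = NULL) {
  if (length(candidates) == 0)
    return(structure(list(coefficients = NULL, loglik = NA_real_,
                          n = 0L, nevent = 0L, ridged = FALSE),
                     class = "cox_fit"))
  X <- if (is(table, "RadiomicsFeatureTable")) featureMatrix(table) else table
  if (is.null(time)) {
    cd <- clinicalData(table)
    time <- cd$survival_days; event <- cd$event
  }
  Xc <- X[, candidates, drop = FALSE]
  tryCatch(coxFit(time, event, Xc),
           error = function(e) {
             ft <- coxFit(time, event, Xc, ridge = 0.1)
             ft$note <- paste("ridge-stabilized:", conditionMessage(e))
             ft
           })
}

#' Third-quartile dichotomization
#'
#' Threshold = the third quartile (linear-interpolation quantile, R type 7);
#' the high-risk group is the values *strictly greater* than the threshold.
#'
#' @param values numeric vector (>= 4 values, not all identical).
#' @return list with `threshold`, `high` (logical vector), `nHigh`, `nLow`.
#' @export
dichotomizeQ3 <- function(values) {
  if (length(values) < 4) stop("need >= 4 values to dichotomize at Q3")
  if (max(values) - min(values) < 1e-300)
    stop("degenerate split: all values identical")
  thr <- quantile(values, 0.75, names = FALSE, type = 7)
  high <- values > thr
  if (!any(high) || all(high)) stop("degenerate split at the third quartile")
  list(threshold = thr, high = high, nHigh = sum(high), nLow = sum(!high))
}

#' Kaplan-Meier medians, log-rank test and hazard ratio for two groups
#'
#' Median survival per group (earliest time with survival <= 0.5; `NA` when
#' not reached), the log-rank (Mantel-Cox) chi-square and p via
#' [survival::survdiff()], and the hazard ratio with 95% CI from a
#' one-covariate Cox fit on group membership (second level vs first).
#'
#' @param time,event survival record.
#' @param group two-level factor or logical (e.g. the Q3 `high` indicator).
#' @return list with `medians`, `chisq`, `p`, `HR`, `ciLow`, `ciHigh`,
#'   `kmTable` (time, at-risk, survival per group).
#' @export
kmLogrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("need exactly 2 groups")
  ev <- tapply(event, group, sum)
  if (any(ev < 1)) stop("each group must contain >= 1 event")
  df <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  med <- summary(sf)$table[, "median"]
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- unname(sd0$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  cf <- tryCatch(coxFit(time, event, as.numeric(group == levels(group)[2])),
                 error = function(e) NULL)
  co <- if (is.null(cf)) {
    # complete separation of the curves: the Cox HR estimate is unbounded
    data.frame(HR = NA_real_, ciLow = NA_real_, ciHigh = NA_real_)
  } else cf$coefficients
  km <- summary(sf)
  kmTable <- data.frame(group = sub("^group=", "", as.character(km$strata)),
                        time = km$time, atRisk = km$n.risk,
                        survival = km$surv)
  list(medians = setNames(as.numeric(med), levels(group)),
       chisq = chisq, p = p,
       HR = co$HR, ciLow = co$ciLow, ciHigh = co$ciHigh,
       kmTable = kmTable)
}

#' Full survival-prognostication stage
#'
#' Univariate Cox screen at `alpha`, multivariate refinement of the
#' survivors, selection of the multivariate-significant feature with the
#' smallest p as the prognosticator, Q3 dichotomization and Kaplan-Meier /
#' log-rank comparison with HR and 95% CI.
#'
#' @param table complete [RadiomicsFeatureTable-class].
#' @param alpha significance level.
#' @return list with `univariate`, `multivariate`, `prognosticator`,
#'   `threshold`, `km` (or `NULL` when no feature survives screening).
#' @export
survivalStage <- function(table, alpha = 0.05) {
  cd <- clinicalData(table)
  uni <- screenUnivariate(table, alpha = alpha)
  multi <- multivariateRefine(uni$significant, table)
  prog <- NULL; thr <- NULL; km <- NULL
  if (!is.null(multi$coefficients) && nrow(multi$coefficients) > 0) {
    co <- multi$coefficients
    sig <- co[co$p < alpha, , drop = FALSE]
    pick <- if (nrow(sig) > 0) sig$covariate[which.min(sig$p)] else
      co$covariate[which.min(co$p)]
    prog <- pick
    X <- featureMatrix(table)
    dq <- tryCatch(dichotomizeQ3(X[, pick]), error = function(e) NULL)
    if (!is.null(dq)) {
      thr <- dq$threshold
      km <- tryCatch(
        kmLogrank(cd$survival_days, cd$event,
                  factor(ifelse(dq$high, "high", "low"),
                         levels = c("low", "high"))),
        error = function(e) NULL)
    }
  }
  list(univariate = uni, multivariate = multi, prognosticator = prog,
       threshold = thr, km = km)
}
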