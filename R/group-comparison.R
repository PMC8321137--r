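# Subgroup comparison: Kruskal-Wallis omnibus + Dunn's multiple-comparisons
# test per feature, and a cohort-level tally of how many subgroups each
# feature separates.

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction, p from chi-square with g-1 df
#' (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `H` and `p`.
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("a group has 0 observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn's multiple-comparisons test
#'
#' Pairwise z statistics from differences of mean pooled ranks with
#' tie-corrected variance
#' \deqn{\sigma^2_{ab} = \left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac1{n_a}+\frac1{n_b}\right)}
#' and two-sided p-values, Bonferroni-adjusted over the number of pairs
#' (capped at 1). Adjustment can be disabled.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each nonempty).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p.adj`.
#' @export
dunnPairwise <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stop("need >= 2 groups")
  ni <- vapply(groups, length, integer(1))
  if (any(ni == 0)) stop("a group has 0 observations")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  gidx <- rep(seq_along(groups), ni)
  meanRank <- tapply(r, gidx, mean)
  ties <- table(x)
  tieTerm <- sum(ties^3 - ties)
  v0 <- N * (N + 1) / 12 - tieTerm / (12 * (N - 1))
  pairs <- combn(seq_along(groups), 2)
  m <- ncol(pairs)
  res <- data.frame(group1 = names(groups)[pairs[1, ]],
                    group2 = names(groups)[pairs[2, ]],
                    z = numeric(m), p = numeric(m), p.adj = numeric(m),
                    stringsAsFactors = FALSE)
  for (c0 in seq_len(m)) {
    a <- pairs[1, c0]; b <- pairs[2, c0]
    se <- sqrt(v0 * (1 / ni[a] + 1 / ni[b]))
    z <- if (se < 1e-300) 0 else (meanRank[[a]] - meanRank[[b]]) / se
    p <- 2 * pnorm(-abs(z))
    res$z[c0] <- z
    res$p[c0] <- p
    res$p.adj[c0] <- if (adjust == "bonferroni") min(p * m, 1) else p
  }
  res
}

# size of the largest set of groups that are pairwise separated at alpha
.largestClique <- function(sepMat) {
  g <- nrow(sepMat)
  best <- 1L
  for (size in g:2) {
    combs <- combn(g, size)
    for (c0 in seq_len(ncol(combs))) {
      s <- combs[, c0]
      if (all(sepMat[s, s][upper.tri(diag(size))])) return(size)
    }
  }
  best
}

#' Compare every feature across the four molecular subgroups
#'
#' Runs Kruskal-Wallis and Dunn's test per feature at significance level
#' `alpha`, and assigns each feature a discriminability level: the size of
#' the largest set of subgroups that are all pairwise separated (adjusted
#' p < alpha). The summary counts features discriminating 3 and 4 groups.
#' Bonferroni adjustment is applied within a feature's 6 pairwise
#' comparisons; no correction is applied across features.
#'
#' @param table a complete [RadiomicsFeatureTable-class] or subjects x
#'   features matrix.
#' @param labels subgroup labels (taken from the table's clinical data when
#'   omitted).
#' @param alpha significance level (default 0.05).
#' @param adjust passed to [dunnPairwise()].
#' @return list with `results` (per-feature data.frame: `feature`, `H`,
#'   `p.kw`, `level`, plus pairwise adjusted p-values), `pairwise` (long
#'   data.frame of all pairwise tests), and `summary`
#'   (`level3_count`, `level4_count`, feature name lists).
#' @export
compareAllFeatures <- function(table, labels = NULL, alpha = 0.05,
                               adjust = "bonferroni") {
  X <- if (is(table, "RadiomicsFeatureTable")) featureMatrix(table) else table
  if (is.null(labels)) {
    if (!is(table, "RadiomicsFeatureTable"))
      stop("labels required for a plain matrix")
    labels <- clinicalData(table)$subgroup
  }
  if (anyNA(X)) stop("feature table must be complete (impute first)")
  labels <- factor(labels, levels = intersect(SUBGROUPS, unique(labels)))
  if (nlevels(labels) < 2) stop("need >= 2 subgroups")
  feats <- colnames(X)
  pairRows <- list(); rows <- list()
  for (f in feats) {
    groups <- split(X[, f], labels)
    kw <- kruskalWallis(groups)
    dn <- dunnPairwise(groups, adjust = adjust)
    sep <- matrix(FALSE, nlevels(labels), nlevels(labels))
    gi <- match(dn$group1, levels(labels)); gj <- match(dn$group2, levels(labels))
    sep[cbind(gi, gj)] <- dn$p.adj < alpha
    sep <- sep | t(sep)
    lvl <- .largestClique(sep)
    rows[[f]] <- data.frame(feature = f, H = kw$H, p.kw = kw$p,
                            level = lvl, stringsAsFactors = FALSE)
    dn$feature <- f
    pairRows[[f]] <- dn
  }
  results <- do.call(rbind, rows); rownames(results) <- NULL
  pairwise <- do.call(rbind, pairRows); rownames(pairwise) <- NULL
  list(results = results,
       pairwise = pairwise,
       summary = list(
         alpha = alpha, adjust = adjust,
         level3_count = sum(results$level == 3),
         level4_count = sum(results$level == 4),
         level3_features = results$feature[results$level == 3],
         level4_features = results$feature[results$level == 4]))
}
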