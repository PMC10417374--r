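#' Relative expression by the 2^-ddCt method
#'
#' Computes the fold change of a target transcript in a sample relative
#' to a calibrator, each normalized to a reference gene:
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator)` and fold change
#' `2^-ddCt`. Vectorised over samples.
#'
#' @param ct_target_s,ct_ref_s Target and reference Ct in the sample.
#' @param ct_target_c,ct_ref_c Target and reference Ct in the calibrator.
#' @return Numeric fold change(s), strictly positive;
#'   `ddCt = -log2(fold)`.
#' @export
#' @examples
#' ddct_fold_change(25, 20, 24, 21)  # ddCt = 2 -> 0.25
ddct_fold_change <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  cts <- cbind(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c)
  2^(-ddct)
}

#' Split a cohort into young and old age groups at the median
#'
#' @param ages Ages in weeks (>= 2 values).
#' @return Factor with levels `young`, `old` (`young` = strictly below
#'   the cohort median) and attribute `median_age`.
#' @export
assign_age_groups <- function(ages) {
  if (length(ages) < 2L) stop("need at least 2 ages")
  med <- stats::median(ages, na.rm = TRUE)
  if (all(ages == ages[1L], na.rm = TRUE))
    warning("all ages equal; every individual assigned to 'old' (>= median rule)")
  lab <- factor(ifelse(ages < med, "young", "old"), levels = c("young", "old"))
  attr(lab, "median_age") <- med
  lab
}

# one-sample Kolmogorov-Smirnov test against a normal with the sample's
# mean and SD; `lilliefors = TRUE` calibrates the p-value by Monte Carlo
# to account for the estimated parameters
ks_normal <- function(x, lilliefors = FALSE, nsim = 1000L) {
  x <- x[is.finite(x)]
  m <- mean(x); s <- stats::sd(x)
  if (s <= 0) stop("constant input")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", m, s))
  p <- kt$p.value
  if (lilliefors) {
    n <- length(x)
    d0 <- kt$statistic
    dsim <- vapply(seq_len(nsim), function(i) {
      z <- stats::rnorm(n)
      suppressWarnings(stats::ks.test(z, "pnorm", mean(z), stats::sd(z))$statistic)
    }, 1)
    p <- (sum(dsim >= d0) + 1) / (nsim + 1)
  }
  list(statistic = unname(kt$statistic), p = p)
}

#' Normality-gated correlation
#'
#' Correlates two variables with Pearson's coefficient when a
#' Kolmogorov-Smirnov test finds both compatible with a normal
#' distribution (at `alpha`), and with Spearman's rank coefficient
#' otherwise. Pairwise-complete observations are used.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alpha Normality-gate level (default 0.05).
#' @param lilliefors Use a Monte Carlo Lilliefors-corrected KS p-value.
#' @return List: `method` (`"pearson"` or `"spearman"`), `estimate`, `p`,
#'   `n`, and the two gate p-values.
#' @export
correlate_with_phenotype <- function(x, y, alpha = 0.05, lilliefors = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need >= 5 paired non-missing values")
  if (stats::sd(x) <= 0 || stats::sd(y) <= 0)
    stop("undefined correlation: constant vector")
  kx <- ks_normal(x, lilliefors); ky <- ks_normal(y, lilliefors)
  method <- if (kx$p > alpha && ky$p > alpha) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(method = method, estimate = unname(ct$estimate), p = ct$p.value,
       n = length(x), ks_p_x = kx$p, ks_p_y = ky$p)
}

#' Normality-gated two-group comparison
#'
#' Applies a two-sided t-test when both groups pass the KS normality
#' gate, and a Mann-Whitney U (Wilcoxon rank-sum) test otherwise.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping of the same length.
#' @param alpha Normality-gate level.
#' @param lilliefors See [correlate_with_phenotype()].
#' @return List: `test` (`"t"` or `"mann-whitney"`), `statistic`, `p`,
#'   group sizes.
#' @export
compare_groups <- function(values, labels, alpha = 0.05, lilliefors = FALSE) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- droplevels(factor(labels[ok]))
  if (nlevels(labels) != 2L) stop("need exactly two non-empty groups")
  g <- split(values, labels)
  if (any(lengths(g) < 3L)) stop("both groups need >= 3 values")
  normal <- vapply(g, function(v)
    stats::sd(v) > 0 && ks_normal(v, lilliefors)$p > alpha, TRUE)
  if (all(normal)) {
    tt <- stats::t.test(g[[1L]], g[[2L]])
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         n1 = length(g[[1L]]), n2 = length(g[[2L]]))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g[[1L]], g[[2L]], exact = FALSE))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value, n1 = length(g[[1L]]), n2 = length(g[[2L]]))
  }
}

#' Select intermediate molecular phenotypes associated with a pathophenotype
#'
#' Two-stage screen: every molecule univariately associated with the
#' phenotype at p < `alpha_entry` (normality-gated correlation,
#' pairwise-complete) enters a multiple linear regression (listwise
#' complete); collinear candidates are pruned by highest variance
#' inflation factor (VIF) first until all VIFs fall below `vif_max`. No
#' multiple-testing correction is applied at this exploratory stage.
#'
#' @param panel Individuals x molecules numeric matrix (named columns).
#' @param phenotype Numeric per-individual phenotype.
#' @param alpha_entry Univariate entry threshold (default 0.05).
#' @param vif_max VIF pruning threshold (default 10).
#' @param log_transform Log-transform panel levels before screening
#'   (default `FALSE`).
#' @param lilliefors See [correlate_with_phenotype()].
#' @return List: `selected` data frame (`molecule`, `estimate`, `p`,
#'   univariate `cor`, `cor_method`), ordered by multiple-regression p;
#'   `candidates`; `dropped_vif`; and the fitted `lm` object (or `NULL`
#'   when no candidate passes).
#' @export
select_imps <- function(panel, phenotype, alpha_entry = 0.05, vif_max = 10,
                        log_transform = FALSE, lilliefors = FALSE) {
  panel <- as.matrix(panel)
  if (is.null(colnames(panel))) stop("panel columns must be named")
  if (ncol(panel) < 1L) stop("need >= 1 candidate molecule")
  if (log_transform) panel <- log(panel)
  uni <- lapply(colnames(panel), function(m) {
    res <- try(correlate_with_phenotype(panel[, m], phenotype,
                                        lilliefors = lilliefors),
               silent = TRUE)
    if (inherits(res, "try-error")) list(estimate = NA, p = NA, method = NA)
    else res
  })
  names(uni) <- colnames(panel)
  cand <- colnames(panel)[vapply(uni, function(u)
    is.finite(u$p) && u$p < alpha_entry, TRUE)]
  if (!length(cand))
    return(list(selected = data.frame(molecule = character(),
                                      estimate = numeric(), p = numeric(),
                                      cor = numeric(), cor_method = character(),
                                      stringsAsFactors = FALSE),
                candidates = character(), dropped_vif = character(),
                model = NULL))
  dropped <- character(0)
  repeat {
    dat <- data.frame(.y = phenotype, panel[, cand, drop = FALSE],
                      check.names = FALSE)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fit <- stats::lm(.y ~ ., data = dat)
    if (length(cand) < 2L) break
    v <- .vif(dat[, cand, drop = FALSE])
    if (all(v < vif_max, na.rm = TRUE)) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    cand <- setdiff(cand, worst)
  }
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1L]
  # lm backtick-quotes non-syntactic names; strip for matching
  terms <- gsub("^`|`$", "", terms)
  sel <- data.frame(molecule = terms, estimate = sm[-1L, 1L], p = sm[-1L, 4L],
                    cor = vapply(terms, function(m) uni[[m]]$estimate, 1),
                    cor_method = vapply(terms, function(m) uni[[m]]$method, ""),
                    stringsAsFactors = FALSE)
  sel <- sel[order(sel$p), ]
  rownames(sel) <- NULL
  list(selected = sel, candidates = cand, dropped_vif = dropped, model = fit)
}

# variance inflation factors from the correlation structure of a
# complete-case predictor matrix
.vif <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2, 1e-12)
  }, 1, USE.NAMES = FALSE) -> v
  stats::setNames(v, colnames(X))
}

#' PCA of molecule levels with a median-split phenotype overlay
#'
#' Centers and unit-scales the variables, computes principal components,
#' and labels individuals `high`/`low` by whether the phenotype exceeds
#' its median (ties at the median go to `low`). Zero-variance variables
#' are dropped with a warning.
#'
#' @param x Individuals x variables numeric matrix (>= 2 variables,
#'   >= 4 individuals after NA removal).
#' @param phenotype Numeric per-individual phenotype used for the split.
#' @return List: `scores`, `loadings`, `sdev`, `labels` (factor
#'   high/low), `dropped` (zero-variance variables).
#' @export
pca_classify <- function(x, phenotype) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 variables")
  ok <- stats::complete.cases(x) & is.finite(phenotype)
  x <- x[ok, , drop = FALSE]
  phenotype <- phenotype[ok]
  if (nrow(x) < 4L) stop("need >= 4 complete individuals")
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds <= 0]
  if (length(dropped)) {
    warning("dropping zero-variance variable(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 variables left after dropping")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  med <- stats::median(phenotype)
  labels <- factor(ifelse(phenotype > med, "high", "low"),
                   levels = c("low", "high"))
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       labels = labels, dropped = dropped)
}
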