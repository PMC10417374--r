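#' Assemble a patient cohort for candidate-SNV analysis
#'
#' @param geno Individuals x SNVs dosage matrix coded 0/1/2 (count of the
#'   minor/alternate allele), `NA` allowed; columns must be named.
#' @param r2 Optional per-SNV imputation quality in `[0, 1]`.
#' @param outcome Optional binary CDA outcome (0/1).
#' @param baseline,followup Optional cardiac-function index (LVEF or
#'   LVFS, %) at baseline and follow-up; `followup` may be a matrix with
#'   one column per time point.
#' @param cohort Cohort tag, e.g. `"pediatric"`, `"breast"`, `"cmr"`.
#' @return A `human_cohort` object.
#' @export
human_cohort <- function(geno, r2 = NULL, outcome = NULL,
                         baseline = NULL, followup = NULL,
                         cohort = "generic") {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) stop("SNV columns must be named")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(r2)) {
    if (length(r2) != ncol(geno)) stop("one R2 value per SNV required")
    if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("R2 must lie in [0, 1]")
    names(r2) <- colnames(geno)
  }
  if (!is.null(outcome) && !all(outcome %in% c(0, 1, NA)))
    stop("outcome must be binary 0/1")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("pt", seq_len(nrow(geno)))
  structure(list(geno = geno, r2 = r2, outcome = outcome,
                 baseline = baseline, followup = followup, cohort = cohort),
            class = "human_cohort")
}

#' @export
print.human_cohort <- function(x, ...) {
  cat(sprintf("Human cohort '%s': %d individuals, %d SNVs\n",
              x$cohort, nrow(x$geno), ncol(x$geno)))
  if (!is.null(x$outcome))
    cat(sprintf("  CDA cases: %d / %d\n", sum(x$outcome == 1, na.rm = TRUE),
                sum(!is.na(x$outcome))))
  invisible(x)
}

#' Remove poorly imputed SNVs
#'
#' Drops every SNV whose imputation quality is strictly below `r2_min`
#' (the boundary value is kept).
#'
#' @param cohort A [human_cohort()] with `r2` present.
#' @param r2_min Threshold (default 0.7).
#' @return The filtered cohort; the number removed is reported via
#'   `message()` and stored in attribute `n_removed`.
#' @export
filter_by_imputation <- function(cohort, r2_min = 0.7) {
  stopifnot(inherits(cohort, "human_cohort"))
  if (is.null(cohort$r2)) stop("cohort carries no imputation R2 values")
  keep <- cohort$r2 >= r2_min
  message(sum(!keep), " SNV(s) removed with imputation R2 < ", r2_min)
  cohort$geno <- cohort$geno[, keep, drop = FALSE]
  cohort$r2 <- cohort$r2[keep]
  attr(cohort, "n_removed") <- sum(!keep)
  cohort
}

#' Label cardiotoxicity cases from cardiac-function decline
#'
#' A patient is a case when the cardiac-function index (LVEF or LVFS, %)
#' drops by `drop_threshold` absolute percentage points or more between
#' baseline and any provided follow-up time point.
#'
#' @param baseline Baseline index per patient.
#' @param followup Follow-up index; vector or matrix (one column per time
#'   point). Patients with no finite follow-up get `NA` (excluded,
#'   logged).
#' @param drop_threshold Case threshold in percentage points (default 5;
#'   the boundary drop is a case).
#' @return Integer vector 0/1/`NA`.
#' @export
label_cda_cases <- function(baseline, followup, drop_threshold = 5) {
  followup <- as.matrix(followup)
  if (nrow(followup) != length(baseline))
    stop("baseline and followup must cover the same patients")
  drops <- baseline - followup
  max_drop <- apply(drops, 1L, function(d)
    if (all(!is.finite(d))) NA_real_ else max(d, na.rm = TRUE))
  out <- ifelse(is.na(max_drop) | !is.finite(baseline), NA_integer_,
                as.integer(max_drop >= drop_threshold))
  if (anyNA(out))
    message(sum(is.na(out)), " patient(s) excluded for missing follow-up")
  out
}

#' Encode a biallelic SNV under a genetic model
#'
#' @param dosages Vector of 0/1/2 dosages (`NA` allowed).
#' @param model One of `"codominant"` (two indicators: het and
#'   homozygote-alternate), `"dominant"` (dosage >= 1), `"recessive"`
#'   (dosage == 2), `"overdominant"` (dosage == 1), `"log-additive"`
#'   (dosage as numeric trend).
#' @return Numeric matrix with one or (codominant) two named columns.
#' @export
encode_genetic_model <- function(dosages,
                                 model = c("codominant", "dominant",
                                           "recessive", "overdominant",
                                           "log-additive")) {
  model <- match.arg(model)
  if (!all(dosages %in% c(0, 1, 2, NA)))
    stop("dosages must be coded 0/1/2 (NA allowed)")
  switch(model,
    codominant = cbind(het = as.numeric(dosages == 1),
                       hom_alt = as.numeric(dosages == 2)),
    dominant = cbind(dominant = as.numeric(dosages >= 1)),
    recessive = cbind(recessive = as.numeric(dosages == 2)),
    overdominant = cbind(overdominant = as.numeric(dosages == 1)),
    `log-additive` = cbind(log_additive = as.numeric(dosages)))
}

#' Single-SNV case/control association under a genetic model
#'
#' Logistic regression of the binary CDA outcome on the encoded SNV;
#' the p-value is the likelihood-ratio test against the intercept-only
#' model and odds ratios are `exp(coefficient)` (one per design column
#' for the codominant model). Complete (quasi-)separation is flagged and
#' the reported odds ratio then comes from a lightly ridge-penalized
#' refit.
#'
#' @param cohort A [human_cohort()] with `outcome` set, or a dosage
#'   matrix (then pass `outcome`).
#' @param snv SNV name or column index.
#' @param model Genetic model (see [encode_genetic_model()]).
#' @param outcome Binary outcome when `cohort` is a bare matrix.
#' @return Data frame (one row per design column): `snv`, `model`,
#'   `term`, `or`, `p` (model-level LRT p), `separated`.
#' @export
associate_snv <- function(cohort, snv, model = "log-additive",
                          outcome = NULL) {
  if (inherits(cohort, "human_cohort")) {
    geno <- cohort$geno
    outcome <- cohort$outcome
  } else geno <- as.matrix(cohort)
  if (is.null(outcome)) stop("outcome required")
  x <- geno[, snv]
  ok <- !is.na(x) & !is.na(outcome)
  x <- x[ok]; y <- outcome[ok]
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  X <- encode_genetic_model(x, model)
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("encoded column constant for SNV ", snv, " under model ", model)
  fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
  p <- stats::pchisq(fit$null.deviance - fit$deviance, df = ncol(X),
                     lower.tail = FALSE)
  beta <- stats::coef(fit)[-1L]
  separated <- !fit$converged || any(abs(beta) > 15, na.rm = TRUE)
  if (separated) {
    # small-ridge fallback keeps the odds ratio finite; LRT p retained
    rf <- glmnet::glmnet(cbind(X, 0), y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    beta <- as.numeric(rf$beta)[seq_len(ncol(X))]
  }
  data.frame(snv = if (is.character(snv)) snv else colnames(geno)[snv],
             model = model, term = colnames(X), or = exp(unname(beta)),
             p = p, separated = separated, stringsAsFactors = FALSE)
}

#' Pick the best-supported genetic model for a SNV
#'
#' Fits all five genetic models and flags the one with the lowest AIC
#' (an operational choice; the selection itself is exploratory).
#'
#' @inheritParams associate_snv
#' @return Data frame `model`, `aic`, `p`, `chosen`.
#' @export
best_genetic_model <- function(cohort, snv, outcome = NULL) {
  models <- c("codominant", "dominant", "recessive", "overdominant",
              "log-additive")
  if (inherits(cohort, "human_cohort")) {
    geno <- cohort$geno; outcome <- cohort$outcome
  } else geno <- as.matrix(cohort)
  x <- geno[, snv]
  ok <- !is.na(x) & !is.na(outcome)
  x <- x[ok]; y <- outcome[ok]
  rows <- lapply(models, function(m) {
    X <- encode_genetic_model(x, m)
    if (any(apply(X, 2L, stats::sd) == 0))
      return(data.frame(model = m, aic = NA_real_, p = NA_real_))
    fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
    data.frame(model = m, aic = stats::AIC(fit),
               p = stats::pchisq(fit$null.deviance - fit$deviance,
                                 df = ncol(X), lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$chosen <- !is.na(out$aic) & out$aic == min(out$aic, na.rm = TRUE)
  out
}

# vectorised Rao score test of logistic association (log-additive
# encoding) for every SNV column at once; intercept-only null
.logistic_score_p <- function(X, y) {
  ybar <- mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  U <- drop(crossprod(Xc, y - ybar))
  V <- ybar * (1 - ybar) * colSums(Xc^2)
  chi <- ifelse(V > 1e-12, U^2 / V, 0)
  stats::pchisq(chi, df = 1L, lower.tail = FALSE)
}

# stratified index split: `frac` of each outcome class
.stratified_split <- function(y, frac) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  s1 <- sample(idx1, max(1L, round(frac * length(idx1))))
  s0 <- sample(idx0, max(1L, round(frac * length(idx0))))
  sort(c(s1, s0))
}

#' Bootstrap SNV pre-selection for the risk score
#'
#' Repeatedly splits the training cohort into an 80% evaluation and a 20%
#' validation portion (stratified by outcome). A SNV scores a hit in an
#' iteration when its log-additive logistic association has p < `alpha`
#' in both portions; SNVs with at least `min_hits` hits across `n_iter`
#' iterations become risk-score candidates. Fully reproducible given
#' `seed`.
#'
#' @param geno Training dosage matrix (0/1/2; `NA`s are mean-imputed
#'   within SNV for this step).
#' @param outcome Binary training outcome.
#' @param n_iter Number of bootstrap iterations (default 100).
#' @param eval_frac Evaluation-portion fraction (default 0.8).
#' @param min_hits Minimum hits for selection (default 5).
#' @param alpha Per-portion significance level (default 0.05).
#' @param seed Integer seed (required).
#' @return Data frame `snv`, `hits` (only SNVs with
#'   `hits >= min_hits`), with attribute `all_hits` (named vector over
#'   all SNVs).
#' @export
bootstrap_select_snvs <- function(geno, outcome, n_iter = 100L,
                                  eval_frac = 0.8, min_hits = 5L,
                                  alpha = 0.05, seed) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (missing(seed)) stop("seed is required for reproducibility")
  geno <- .mean_impute(as.matrix(geno))
  y <- outcome
  ok <- !is.na(y)
  geno <- geno[ok, , drop = FALSE]; y <- y[ok]
  if (min(table(y)) < 20L)
    warning("fewer than 20 individuals in an outcome class; selection may be unstable")
  hits <- stats::setNames(integer(ncol(geno)), colnames(geno))
  .with_seed(seed, {
    for (it in seq_len(n_iter)) {
      ev <- .stratified_split(y, eval_frac)
      va <- setdiff(seq_along(y), ev)
      p_ev <- .logistic_score_p(geno[ev, , drop = FALSE], y[ev])
      p_va <- .logistic_score_p(geno[va, , drop = FALSE], y[va])
      hits <- hits + as.integer(p_ev < alpha & p_va < alpha)
    }
  })
  sel <- hits[hits >= min_hits]
  out <- data.frame(snv = names(sel), hits = unname(sel),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hits, out$snv), ]
  rownames(out) <- NULL
  attr(out, "all_hits") <- hits
  out
}

.mean_impute <- function(X) {
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(X, na.rm = TRUE)
    X[nas] <- mu[nas[, 2L]]
  }
  X
}

# run expr with a local RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Fit the LASSO risk-score model
#'
#' L1-penalized logistic regression of the CDA outcome on the candidate
#' SNVs (log-additive coding, missing dosages mean-imputed). The penalty
#' strength is chosen by stratified 10-fold cross-validation minimizing
#' the binomial deviance (`lambda_rule = "1se"` applies the one-standard-
#' error rule instead). The probability cutoff is then set on the
#' training data by the maximum Youden index.
#'
#' @param geno Training dosage matrix.
#' @param outcome Binary training outcome.
#' @param candidates Candidate SNV names (from
#'   [bootstrap_select_snvs()]).
#' @param seed Integer seed for fold assignment.
#' @param nfolds CV folds (default 10).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param hit_counts Optional named hit counts stored with the model.
#' @return A `risk_score_model`: selected SNVs and coefficients,
#'   `intercept`, `lambda`, `cutoff`, `youden`, training `metrics`,
#'   flags.
#' @export
fit_lasso_risk_model <- function(geno, outcome, candidates, seed,
                                 nfolds = 10L, lambda_rule = c("min", "1se"),
                                 hit_counts = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (!length(candidates)) stop("need >= 1 candidate SNV")
  if (missing(seed)) stop("seed is required for reproducibility")
  missing_cols <- setdiff(candidates, colnames(geno))
  if (length(missing_cols))
    stop("candidate SNV(s) absent from genotypes: ",
         paste(missing_cols, collapse = ", "))
  ok <- !is.na(outcome)
  X <- .mean_impute(as.matrix(geno[ok, candidates, drop = FALSE]))
  y <- outcome[ok]
  single <- length(candidates) == 1L
  fit <- .with_seed(seed, {
    if (single) {
      # glmnet needs >= 2 columns; fall back to an unpenalized fit
      g <- stats::glm(y ~ X, family = stats::binomial())
      list(a0 = stats::coef(g)[1L],
           beta = stats::setNames(stats::coef(g)[2L], candidates),
           lambda = 0)
    } else {
      foldid <- integer(length(y))
      for (cl in unique(y)) {
        idx <- which(y == cl)
        foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
      }
      cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                              type.measure = "deviance", foldid = foldid)
      lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
      co <- stats::coef(cv, s = lam)
      beta <- stats::setNames(as.numeric(co)[-1L], rownames(co)[-1L])
      list(a0 = as.numeric(co)[1L], beta = beta, lambda = lam, cv = cv)
    }
  })
  nz <- fit$beta[fit$beta != 0]
  intercept_only <- length(nz) == 0L
  scores <- .risk_scores(fit$a0, nz, X)
  yj <- if (intercept_only) list(cutoff = 0.5, J = 0, roc = NULL)
        else optimize_cutoff_youden(scores, y)
  model <- structure(list(
    snvs = names(nz), coef = nz, intercept = unname(fit$a0),
    lambda = fit$lambda, lambda_rule = lambda_rule, cutoff = yj$cutoff,
    youden = yj$J, hit_counts = hit_counts,
    intercept_only = intercept_only, single_candidate = single,
    seed = seed,
    train_metrics = .classification_metrics(scores, y, yj$cutoff)),
    class = "risk_score_model")
  model
}

.risk_scores <- function(a0, beta, X) {
  lp <- rep(a0, nrow(X))
  if (length(beta)) lp <- lp + drop(X[, names(beta), drop = FALSE] %*% beta)
  stats::plogis(lp)
}

.auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.classification_metrics <- function(scores, y, cutoff) {
  pred <- as.integer(scores >= cutoff)
  c(auc = .auc_rank(scores, y),
    sensitivity = if (sum(y == 1)) mean(pred[y == 1] == 1) else NA_real_,
    specificity = if (sum(y == 0)) mean(pred[y == 0] == 0) else NA_real_)
}

#' @export
print.risk_score_model <- function(x, ...) {
  cat("Penalized SNV risk-score model\n")
  cat(sprintf("  lambda = %.5g (%s rule), cutoff = %.3f (Youden J = %.3f)\n",
              x$lambda, x$lambda_rule, x$cutoff, x$youden))
  cat(sprintf("  %d SNV(s) with nonzero coefficients%s\n", length(x$snvs),
              if (x$intercept_only) " [intercept-only]" else ""))
  m <- x$train_metrics
  cat(sprintf("  training: AUC %.3f, sens %.3f, spec %.3f\n",
              m["auc"], m["sensitivity"], m["specificity"]))
  invisible(x)
}

#' Youden-optimal probability cutoff
#'
#' Sweeps every observed score as a threshold (classification rule:
#' `score >= cutoff` is a predicted case), computes sensitivity and
#' specificity, and returns the cutoff maximizing Youden's
#' `J = sensitivity + specificity - 1`; on ties the smallest such
#' threshold is reported.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1).
#' @return List: `cutoff`, `J`, and the full `roc` data frame
#'   (`threshold`, `sensitivity`, `specificity`, `J`).
#' @export
optimize_cutoff_youden <- function(scores, labels) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) sum(scores >= t & labels == 1) / n1, 1)
  spec <- vapply(th, function(t) sum(scores < t & labels == 0) / n0, 1)
  J <- sens + spec - 1
  best <- which(J == max(J))[1L]   # thresholds sorted: first max = smallest
  list(cutoff = th[best], J = J[best],
       roc = data.frame(threshold = th, sensitivity = sens,
                        specificity = spec, J = J))
}

#' Evaluate a risk-score model on a held-out cohort
#'
#' @param model A `risk_score_model`.
#' @param geno Test dosage matrix containing all model SNVs.
#' @param outcome Binary test outcome.
#' @return Named vector `auc`, `sensitivity`, `specificity` (at the
#'   trained cutoff).
#' @export
evaluate_on_test <- function(model, geno, outcome) {
  stopifnot(inherits(model, "risk_score_model"))
  missing_cols <- setdiff(model$snvs, colnames(geno))
  if (length(missing_cols))
    stop("test cohort lacks model SNV(s): ",
         paste(missing_cols, collapse = ", "))
  ok <- !is.na(outcome)
  X <- .mean_impute(as.matrix(geno[ok, , drop = FALSE]))
  scores <- .risk_scores(model$intercept, model$coef, X)
  .classification_metrics(scores, outcome[ok], model$cutoff)
}

#' Risk probabilities from a fitted model
#'
#' @param model A `risk_score_model`.
#' @param geno Dosage matrix containing the model SNVs.
#' @return Per-individual predicted probability of CDA.
#' @export
predict_risk <- function(model, geno) {
  X <- .mean_impute(as.matrix(geno))
  .risk_scores(model$intercept, model$coef, X)
}

#' Read a dosage matrix from a VCF file
#'
#' Minimal GT-field reader for candidate-gene panels: biallelic sites
#' become 0/1/2 alternate-allele dosages; multi-allelic sites are skipped
#' with a warning; missing genotypes (`./.`) become `NA`. Imputation R2
#' is taken from the INFO `R2=` key when present.
#'
#' @param path Path to an uncompressed VCF.
#' @return A [human_cohort()] (outcome unset).
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1L], "#CHROM"))
    stop("not a VCF: missing #CHROM header")
  hdr <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  samples <- hdr[-(1:9)]
  if (!length(samples)) stop("VCF contains no sample columns")
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- character(0); dos <- list(); r2 <- numeric(0)
  for (f in rows) {
    if (grepl(",", f[5L], fixed = TRUE)) {
      warning("skipping multi-allelic site ", f[3L])
      next
    }
    gt_i <- match("GT", strsplit(f[9L], ":", fixed = TRUE)[[1L]])
    if (is.na(gt_i)) stop("no GT field at site ", f[3L])
    gts <- vapply(f[-(1:9)], function(s)
      strsplit(s, ":", fixed = TRUE)[[1L]][gt_i], "", USE.NAMES = FALSE)
    alleles <- strsplit(gts, "[/|]")
    d <- vapply(alleles, function(a) {
      if (any(a == ".")) NA_real_ else sum(a == "1")
    }, 1)
    id <- if (f[3L] == ".") paste0(f[1L], ":", f[2L]) else f[3L]
    ids <- c(ids, id)
    dos[[length(dos) + 1L]] <- d
    m <- regmatches(f[8L], regexpr("(?:^|;)R2=([0-9.eE+-]+)", f[8L]))
    r2 <- c(r2, if (length(m)) as.numeric(sub(".*R2=", "", m)) else NA_real_)
  }
  geno <- do.call(cbind, dos)
  colnames(geno) <- ids
  rownames(geno) <- samples
  human_cohort(geno, r2 = if (all(is.na(r2))) NULL else r2)
}
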