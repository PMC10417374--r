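#' Specify a multi-QTL model
#'
#' @param chr Chromosome label per locus.
#' @param pos Grid position (cM) per locus.
#' @param interactions Optional list of integer pairs indexing `chr`/`pos`
#'   entries whose product enters the model (default none; the additive
#'   models used for basal-vs-extended comparisons carry no interactions).
#' @return A `qtl_model_spec` object.
#' @export
qtl_model_spec <- function(chr = character(), pos = numeric(),
                           interactions = list()) {
  chr <- as.character(chr)
  pos <- as.numeric(pos)
  if (length(chr) != length(pos)) stop("chr and pos must have equal length")
  if (anyDuplicated(paste(chr, pos))) stop("model loci must be distinct")
  for (ia in interactions) {
    if (length(ia) != 2L || any(ia < 1L) || any(ia > length(chr)))
      stop("interactions must be pairs of indices into the locus list")
  }
  structure(list(chr = chr, pos = pos, interactions = interactions),
            class = "qtl_model_spec")
}

#' @export
print.qtl_model_spec <- function(x, ...) {
  if (!length(x$chr)) cat("QTL model: null (intercept only)\n")
  else cat("QTL model:", paste(sprintf("%s@%g", x$chr, x$pos), collapse = " + "),
           if (length(x$interactions))
             paste0(" + ", length(x$interactions), " interaction(s)") else "",
           "\n", sep = "")
  invisible(x)
}

# design matrix (without intercept) for a model spec; names the columns
.model_design <- function(probs, spec) {
  k <- length(spec$chr)
  if (!k) return(matrix(numeric(0), nrow = nrow(probs[[1L]]$p_het), ncol = 0L))
  cols <- lapply(seq_len(k), function(i)
    .find_locus(probs, spec$chr[i], spec$pos[i]))
  X <- do.call(cbind, lapply(cols, `[[`, "p_het"))
  colnames(X) <- vapply(cols, function(l) sprintf("%s@%g", l$chr, l$pos), "")
  for (ia in spec$interactions) {
    X <- cbind(X, X[, ia[1L]] * X[, ia[2L]])
    colnames(X)[ncol(X)] <- paste(colnames(X)[ia[1L]], colnames(X)[ia[2L]],
                                  sep = ":")
  }
  X
}

#' Fit a multi-QTL fixed model by Haley-Knott regression
#'
#' Regresses the phenotype on the heterozygote probabilities at the model
#' loci (plus products for any interaction terms). The model LOD is
#' `(n/2) * log10(RSS0/RSS1)` against the intercept-only null, and the
#' percent phenotypic variance explained follows the identity
#' `%var = 100 * (1 - 10^(-2 * LOD / n))`. A drop-one-term analysis (see
#' [drop_one_analysis()]) is attached when the model has at least one
#' term.
#'
#' @param probs A `genoprob_grid`.
#' @param phenotype Per-individual phenotype; `NA`s dropped listwise.
#' @param spec A [qtl_model_spec()].
#' @return A `qtl_model_fit`: list with `spec`, `lod`, `pct_var`, `n`,
#'   `rss0`, `rss1`, `coef`, and `drop_one` table.
#' @export
fit_qtl_model <- function(probs, phenotype, spec) {
  stopifnot(inherits(probs, "genoprob_grid"), inherits(spec, "qtl_model_spec"))
  if (length(phenotype) != nrow(probs[[1L]]$p_het))
    stop("phenotype length (", length(phenotype),
         ") does not match individuals in grid (",
         nrow(probs[[1L]]$p_het), ")")
  X <- .model_design(probs, spec)
  keep <- which(is.finite(phenotype))
  y <- phenotype[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n < p + 5L) stop("need n >= number of model terms + 5 (n = ", n, ")")
  if (stats::var(y) <= 0) stop("degenerate input: phenotype is constant")
  rss0 <- sum((y - mean(y))^2)
  if (p == 0L) {
    fit <- list(spec = spec, lod = 0, pct_var = 0, n = n,
                rss0 = rss0, rss1 = rss0,
                coef = c(`(Intercept)` = mean(y)), drop_one = NULL)
    class(fit) <- "qtl_model_fit"
    return(fit)
  }
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    aliased <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("collinear model design; offending term(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- qr.resid(qrD, y)
  rss1 <- sum(res^2)
  lod <- (n / 2) * log10(rss0 / max(rss1, rss0 * 1e-12))
  fit <- list(spec = spec, lod = lod,
              pct_var = 100 * (1 - 10^(-2 * lod / n)),
              n = n, rss0 = rss0, rss1 = rss1,
              coef = stats::setNames(drop(qr.coef(qrD, y)), colnames(D)),
              drop_one = NULL)
  class(fit) <- "qtl_model_fit"
  fit$drop_one <- drop_one_analysis(probs, phenotype, spec, .full = fit)
  fit
}

#' @export
print.qtl_model_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  LOD = %.3f, %%var = %.2f, n = %d\n", x$lod, x$pct_var, x$n))
  if (!is.null(x$drop_one)) {
    cat("  drop-one analysis:\n")
    print(x$drop_one, row.names = FALSE)
  }
  invisible(x)
}

#' Drop-one-term analysis of a multi-QTL model
#'
#' Each term (locus or interaction) is removed in turn and the model
#' refitted; dropping a locus also drops every interaction that involves
#' it. The table reports the LOD attributable to the term (full minus
#' reduced model LOD) and an F-test p-value comparing the two fits; a
#' term is flagged `retained` when p < `alpha` (the inclusion rule for
#' extended genetic models).
#'
#' @inheritParams fit_qtl_model
#' @param alpha Retention threshold (default 0.05).
#' @param .full Internal: precomputed full fit.
#' @return Data frame `term`, `type`, `df`, `lod_drop`, `F`, `p`,
#'   `retained`.
#' @export
drop_one_analysis <- function(probs, phenotype, spec, alpha = 0.05,
                              .full = NULL) {
  stopifnot(inherits(spec, "qtl_model_spec"))
  k <- length(spec$chr)
  n_ia <- length(spec$interactions)
  if (k + n_ia == 0L) stop("drop-one analysis needs a model with >= 1 term")
  full <- if (is.null(.full)) {
    f <- spec; f2 <- fit_qtl_model(probs, phenotype, spec); f2
  } else .full
  # avoid recursion: reduced fits are computed without their own drop-one
  reduced_fit <- function(spec_r) {
    X <- .model_design(probs, spec_r)
    keep <- which(is.finite(phenotype))
    y <- phenotype[keep]
    X <- X[keep, , drop = FALSE]
    n <- length(y)
    if (ncol(X) == 0L) return(list(rss = sum((y - mean(y))^2), p = 1L))
    D <- cbind(1, X)
    qrD <- qr(D)
    list(rss = sum(qr.resid(qrD, y)^2), p = ncol(D))
  }
  p_full <- 1L + k + n_ia
  rows <- list()
  term_specs <- c(
    lapply(seq_len(k), function(i) {
      keep_ia <- Filter(function(ia) !(i %in% ia), spec$interactions)
      keep_ia <- lapply(keep_ia, function(ia) ifelse(ia > i, ia - 1L, ia))
      list(term = sprintf("%s@%g", spec$chr[i], spec$pos[i]), type = "locus",
           spec = qtl_model_spec(spec$chr[-i], spec$pos[-i], keep_ia),
           df = 1L + sum(vapply(spec$interactions,
                                function(ia) i %in% ia, TRUE)))
    }),
    lapply(seq_len(n_ia), function(j) {
      ia <- spec$interactions[[j]]
      list(term = sprintf("%s@%g:%s@%g", spec$chr[ia[1L]], spec$pos[ia[1L]],
                          spec$chr[ia[2L]], spec$pos[ia[2L]]),
           type = "interaction",
           spec = qtl_model_spec(spec$chr, spec$pos, spec$interactions[-j]),
           df = 1L)
    }))
  n <- full$n
  for (ts in term_specs) {
    red <- reduced_fit(ts$spec)
    lod_r <- (n / 2) * log10(full$rss0 / max(red$rss, full$rss0 * 1e-12))
    df1 <- ts$df
    df2 <- n - p_full
    dRSS <- red$rss - full$rss1
    # a removal that leaves RSS numerically unchanged carries no evidence
    Fstat <- if (dRSS <= 1e-10 * full$rss0) 0
             else (dRSS / df1) / (full$rss1 / df2)
    pval <- max(stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                .Machine$double.xmin)
    rows[[length(rows) + 1L]] <- data.frame(
      term = ts$term, type = ts$type, df = df1,
      lod_drop = max(full$lod - lod_r, 0), F = Fstat, p = pval,
      retained = pval < alpha, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare a basal QTL model against extended models
#'
#' Mirrors the basal-versus-extended genetic-model comparison used to ask
#' whether loci linked to intermediate molecular phenotypes (ipQTLs)
#' explain additional pathophenotype variance beyond the directly linked
#' locus (cdaQTL). An extended model is reported as an improvement only
#' when every term it adds over the basal model passes the drop-one
#' p < `alpha` rule.
#'
#' @param basal A `qtl_model_fit` (typically the single-cdaQTL model).
#' @param extended A `qtl_model_fit` or list of them, fitted on the same
#'   phenotype and individuals.
#' @param alpha Drop-one retention threshold (default 0.05).
#' @return Data frame `model`, `components`, `lod`, `pct_var`,
#'   `delta_pct_var`, `max_added_p`, `improved`.
#' @export
compare_models <- function(basal, extended, alpha = 0.05) {
  stopifnot(inherits(basal, "qtl_model_fit"))
  if (inherits(extended, "qtl_model_fit")) extended <- list(extended)
  ids <- names(extended)
  if (is.null(ids)) ids <- paste("model", seq_along(extended))
  comp <- function(fit) paste(sprintf("%s@%g", fit$spec$chr, fit$spec$pos),
                              collapse = " + ")
  rows <- list(data.frame(
    model = "basal", components = comp(basal), lod = basal$lod,
    pct_var = basal$pct_var, delta_pct_var = 0, max_added_p = NA_real_,
    improved = NA, stringsAsFactors = FALSE))
  basal_terms <- sprintf("%s@%g", basal$spec$chr, basal$spec$pos)
  for (i in seq_along(extended)) {
    fit <- extended[[i]]
    stopifnot(inherits(fit, "qtl_model_fit"))
    if (fit$n != basal$n)
      stop("mismatched n across fits: ", fit$n, " vs ", basal$n)
    added <- setdiff(fit$drop_one$term, basal_terms)
    added_p <- fit$drop_one$p[fit$drop_one$term %in% added]
    rows[[length(rows) + 1L]] <- data.frame(
      model = ids[i], components = comp(fit), lod = fit$lod,
      pct_var = fit$pct_var, delta_pct_var = fit$pct_var - basal$pct_var,
      max_added_p = if (length(added_p)) max(added_p) else NA_real_,
      improved = length(added_p) > 0 && all(added_p < alpha),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
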