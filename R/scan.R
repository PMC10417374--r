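#' Genome scans for a quantitative trait in a backcross
#'
#' `scan_em()` performs interval mapping with the expectation-maximization
#' algorithm: at every grid position the phenotype is modelled as a
#' two-component normal mixture (genotype-class means, common SD) whose
#' per-individual mixing weights are the HMM genotype probabilities; the
#' LOD score is the base-10 log likelihood ratio against a single-normal
#' null. `scan_hk()` is the Haley-Knott approximation: the phenotype is
#' regressed on the heterozygote probability at each position and
#' `LOD = (n/2) * log10(RSS0/RSS1)`. The two agree exactly at fully typed
#' markers.
#'
#' @param probs A `genoprob_grid` from [calc_genotype_probs()].
#' @param phenotype Numeric per-individual phenotype; `NA`s dropped.
#' @param trait Trait label stored in the result.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param maxit Maximum EM iterations per position.
#'
#' @return A `scan_result`: data frame with `chr`, `pos`, `loc`, `lod`,
#'   plus attributes `trait`, `method`, `n_used` and (for EM) a
#'   `converged` logical vector.
#' @export
scan_em <- function(probs, phenotype, trait = "trait",
                    tol = 1e-4, maxit = 4000L) {
  keep <- .scan_check(probs, phenotype)
  y <- phenotype[keep]
  n <- length(y)
  ybar <- mean(y)
  rss0 <- sum((y - ybar)^2)
  sig0 <- sqrt(rss0 / n)
  ll0 <- -n / 2 * (log(2 * pi * sig0^2) + 1)
  gp <- grid_positions(probs)
  P <- .phet_matrix(probs)[keep, , drop = FALSE]
  lod <- numeric(ncol(P))
  conv <- logical(ncol(P))
  for (j in seq_len(ncol(P))) {
    fit <- .em_mixture(y, P[, j], tol = tol, maxit = maxit)
    lod[j] <- (fit$ll - ll0) / log(10)
    conv[j] <- fit$converged
  }
  if (any(lod < -1e-8))
    warning("negative LOD beyond tolerance at ", sum(lod < -1e-8), " position(s)")
  lod <- pmax(lod, 0)
  .scan_result(gp, lod, trait, "em", n, converged = conv)
}

# one-position EM: fixed per-individual prior pi = P(het), free means,
# common sigma; returns maximized mixture log-likelihood
.em_mixture <- function(y, pi1, tol = 1e-4, maxit = 4000L) {
  n <- length(y)
  w <- pi1
  sw <- sum(w); swc <- n - sw
  if (sw < 1e-10 || swc < 1e-10) {
    # monomorphic position: mixture collapses onto the null
    m <- mean(y); s2 <- sum((y - m)^2) / n
    return(list(ll = -n / 2 * (log(2 * pi * s2) + 1), converged = TRUE))
  }
  mu1 <- sum(w * y) / sw
  mu0 <- sum((1 - w) * y) / swc
  s2 <- sum(w * (y - mu1)^2 + (1 - w) * (y - mu0)^2) / n
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    s2 <- max(s2, 1e-12)
    d0 <- stats::dnorm(y, mu0, sqrt(s2))
    d1 <- stats::dnorm(y, mu1, sqrt(s2))
    mix <- pmax((1 - pi1) * d0 + pi1 * d1, 1e-300)
    ll <- sum(log(mix))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    w <- pi1 * d1 / mix
    sw <- sum(w); swc <- n - sw
    if (sw < 1e-10 || swc < 1e-10) break
    mu1 <- sum(w * y) / sw
    mu0 <- sum((1 - w) * y) / swc
    s2 <- sum(w * (y - mu1)^2 + (1 - w) * (y - mu0)^2) / n
  }
  list(ll = ll_old, converged = converged)
}

#' @rdname scan_em
#' @export
scan_hk <- function(probs, phenotype, trait = "trait") {
  keep <- .scan_check(probs, phenotype)
  y <- phenotype[keep]
  n <- length(y)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  gp <- grid_positions(probs)
  P <- .phet_matrix(probs)[keep, , drop = FALSE]
  Pc <- sweep(P, 2L, colMeans(P))
  sxx <- colSums(Pc^2)
  sxy <- drop(crossprod(Pc, yc))
  r2 <- ifelse(sxx > 1e-12, sxy^2 / (sxx * rss0), 0)
  capped <- r2 > 1 - 1e-12
  r2 <- pmin(r2, 1 - 1e-12)
  lod <- -(n / 2) * log10(1 - r2)
  out <- .scan_result(gp, lod, trait, "hk", n)
  attr(out, "capped") <- capped
  out
}

.scan_check <- function(probs, phenotype) {
  stopifnot(inherits(probs, "genoprob_grid"))
  n_ind <- nrow(probs[[1L]]$p_het)
  if (length(phenotype) != n_ind)
    stop("phenotype length (", length(phenotype),
         ") does not match individuals in grid (", n_ind, ")")
  keep <- which(is.finite(phenotype))
  if (length(keep) < 10L)
    stop("need >= 10 non-missing phenotype values, got ", length(keep))
  if (stats::var(phenotype[keep]) <= 0)
    stop("degenerate input: phenotype is constant")
  keep
}

.scan_result <- function(gp, lod, trait, method, n_used, converged = NULL) {
  out <- data.frame(chr = gp$chr, pos = gp$pos, loc = gp$loc, lod = lod,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "trait") <- trait
  attr(out, "method") <- method
  attr(out, "n_used") <- n_used
  if (!is.null(converged)) attr(out, "converged") <- converged
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Genome scan (%s) for '%s': %d positions, n = %d, max LOD = %.3f\n",
              attr(x, "method"), attr(x, "trait"), nrow(x), attr(x, "n_used"),
              max(x$lod)))
  invisible(x)
}

#' Classify QTL peaks from a genome scan
#'
#' Reports one peak per chromosome-local maximum of the LOD curve above
#' the suggestive threshold: significant when LOD > 3, suggestive when
#' 1.5 <= LOD < 3 (half-open band). On a plateau of equal maxima the
#' leftmost (lowest cM) position is reported. Secondary maxima on a
#' chromosome are kept only when separated from every retained peak by a
#' LOD valley at least 1.5 below the smaller of the two peaks. Each peak
#' carries a 1.5-LOD support interval (contiguous positions within 1.5
#' LOD of the peak).
#'
#' @param scan A `scan_result`.
#' @param significant LOD threshold for the significant class (default 3).
#' @param suggestive Lower LOD bound for the suggestive class (default 1.5).
#' @param condition Condition tag (trait, therapy arm, age group, heart
#'   zone) stored with each peak; defaults to the scan's trait.
#' @param drop LOD drop defining both the support interval and the
#'   valley rule (default 1.5).
#' @return A `qtl_peaks` data frame: `chr`, `pos`, `lod`, `class`,
#'   `ci_lo`, `ci_hi`, `condition`, `trait`, `method`. May have zero rows.
#' @export
classify_peaks <- function(scan, significant = 3.0, suggestive = 1.5,
                           condition = attr(scan, "trait"), drop = 1.5) {
  stopifnot(inherits(scan, "scan_result"), nrow(scan) > 0L)
  rows <- list()
  for (cc in unique(scan$chr)) {
    s <- scan[scan$chr == cc, ]
    lod <- s$lod
    K <- length(lod)
    cand <- which(
      (seq_len(K) == 1L | lod > c(-Inf, lod[-K])) &
      (seq_len(K) == K | lod >= c(lod[-1L], -Inf)))
    cand <- cand[lod[cand] >= suggestive]
    if (!length(cand)) next
    cand <- cand[order(-lod[cand], s$pos[cand])]
    kept <- integer(0)
    for (k in cand) {
      ok <- TRUE
      for (q in kept) {
        span <- seq(min(k, q), max(k, q))
        if (min(lod[span]) > min(lod[k], lod[q]) - drop) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, k)
    }
    for (k in sort(kept)) {
      # contiguous run around the peak within `drop` LOD of its height
      lo <- k; while (lo > 1L && lod[lo - 1L] >= lod[k] - drop) lo <- lo - 1L
      hi <- k; while (hi < K && lod[hi + 1L] >= lod[k] - drop) hi <- hi + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chr = cc, pos = s$pos[k], lod = lod[k],
        class = if (lod[k] > significant) "significant" else "suggestive",
        ci_lo = s$pos[lo], ci_hi = s$pos[hi],
        condition = condition, trait = attr(scan, "trait"),
        method = attr(scan, "method"), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chr = character(), pos = numeric(), lod = numeric(),
               class = character(), ci_lo = numeric(), ci_hi = numeric(),
               condition = character(), trait = character(),
               method = character(), stringsAsFactors = FALSE)
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

#' Consolidate condition-specific QTL peaks into a registry
#'
#' Peaks on the same chromosome whose 1.5-LOD support intervals overlap
#' (transitively) are merged into one registry entry listing all member
#' conditions; entries are numbered sequentially in chromosome order.
#'
#' @param peaks A `qtl_peaks` data frame (peaks may come from many scans;
#'   `rbind` them first).
#' @return Data frame with `qtl` (sequential id), `chr`, `ci_lo`,
#'   `ci_hi`, `peak_pos` (position of the strongest member), `max_lod`,
#'   `n_peaks`, `conditions` (collapsed with `;`).
#' @export
consolidate_qtls <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (!nrow(peaks))
    return(data.frame(qtl = integer(), chr = character(), ci_lo = numeric(),
                      ci_hi = numeric(), peak_pos = numeric(),
                      max_lod = numeric(), n_peaks = integer(),
                      conditions = character(), stringsAsFactors = FALSE))
  entries <- list()
  for (cc in unique(peaks$chr)) {
    p <- peaks[peaks$chr == cc, ]
    p <- p[order(p$ci_lo, p$ci_hi), ]
    cur <- p[1L, , drop = FALSE]
    lo <- cur$ci_lo; hi <- cur$ci_hi
    members <- list(cur)
    flush <- function(lo, hi, members) {
      m <- do.call(rbind, members)
      best <- which.max(m$lod)
      data.frame(chr = cc, ci_lo = lo, ci_hi = hi,
                 peak_pos = m$pos[best], max_lod = m$lod[best],
                 n_peaks = nrow(m),
                 conditions = paste(unique(m$condition), collapse = ";"),
                 stringsAsFactors = FALSE)
    }
    if (nrow(p) > 1L) for (i in 2:nrow(p)) {
      if (p$ci_lo[i] <= hi) {   # overlap (closed intervals)
        hi <- max(hi, p$ci_hi[i])
        members[[length(members) + 1L]] <- p[i, , drop = FALSE]
      } else {
        entries[[length(entries) + 1L]] <- flush(lo, hi, members)
        lo <- p$ci_lo[i]; hi <- p$ci_hi[i]
        members <- list(p[i, , drop = FALSE])
      }
    }
    entries[[length(entries) + 1L]] <- flush(lo, hi, members)
  }
  out <- do.call(rbind, entries)
  out <- cbind(qtl = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Export a genome scan as a tidy table
#'
#' @param scan A `scan_result`.
#' @param stratum Optional stratum tag column.
#' @return Tidy data frame `chr, pos, lod, trait, method, stratum`.
#' @export
tidy_scan <- function(scan, stratum = NA_character_) {
  data.frame(chr = scan$chr, pos = scan$pos, lod = scan$lod,
             trait = attr(scan, "trait"), method = attr(scan, "method"),
             stratum = stratum, stringsAsFactors = FALSE)
}
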