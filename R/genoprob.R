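#' Conditional genotype probabilities on a pseudomarker grid
#'
#' Computes, for every individual and every position on a grid of true
#' markers plus pseudomarkers, the posterior probability of carrying the
#' heterozygous genotype, given the observed marker genotypes. The hidden
#' state along each chromosome is a two-state Markov chain (recurrent
#' homozygote / heterozygote, stationary prior 1/2 each, as in a
#' backcross); transition probability between adjacent grid positions is
#' the recombination fraction of their distance; an observed genotype
#' matches the hidden state with probability `1 - error_prob` and
#' mismatches with `error_prob`; missing observations are uninformative.
#' Posteriors are computed by the forward-backward algorithm.
#'
#' The grid on each chromosome is the union of the true marker positions
#' and a regular lattice from the first to the last marker at `step` cM,
#' so marker positions are always present and pseudomarker insertion never
#' changes the posterior at a marker.
#'
#' @param cross A [backcross()] object (or a [genetic_map()] together
#'   with `geno`).
#' @param geno Genotype matrix when `cross` is a bare map.
#' @param step Pseudomarker spacing in cM (default 2.5). `Inf` gives a
#'   markers-only grid.
#' @param error_prob Genotyping error probability (default 0.001),
#'   applied symmetrically to both states; must lie in `[0, 0.5)`.
#' @param map_function Passed to [map_to_recomb()].
#'
#' @return A `genoprob_grid` object: per chromosome a list with `pos`
#'   (grid positions, cM), `loc` (marker name or `c<chr>.loc<pos>` for
#'   pseudomarkers), `is_marker`, and `p_het` (individuals x positions
#'   matrix of heterozygote posterior probabilities).
#' @export
calc_genotype_probs <- function(cross, geno = NULL, step = 2.5,
                                error_prob = 0.001,
                                map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (inherits(cross, "backcross")) {
    map <- cross$map
    geno <- cross$geno
  } else {
    map <- cross
    if (is.null(geno)) stop("geno required when cross is a bare map")
    geno <- backcross(map, geno)$geno
  }
  if (!is.finite(step) && !identical(step, Inf)) stop("step must be positive")
  if (is.finite(step) && step <= 0) stop("step must be positive")
  if (error_prob < 0 || error_prob >= 0.5)
    stop("error_prob must lie in [0, 0.5)")
  chromosomes <- attr(map, "chromosomes")
  n_ind <- nrow(geno)
  res <- vector("list", length(chromosomes))
  names(res) <- chromosomes
  for (cc in chromosomes) {
    sel <- which(map$chr == cc)
    if (!length(sel)) stop("chromosome ", cc, " has no markers")
    mpos <- map$pos_cM[sel]
    if (any(!is.finite(mpos))) stop("non-finite marker positions on chromosome ", cc)
    grid <- if (is.finite(step) && max(mpos) > min(mpos)) {
      sort(unique(c(mpos, seq(min(mpos), max(mpos), by = step))))
    } else sort(unique(mpos))
    # map each grid position to a marker index (0 = pseudomarker)
    midx <- match(grid, mpos)           # first marker at that position
    loc <- ifelse(is.na(midx),
                  sprintf("c%s.loc%g", cc, grid),
                  map$marker[sel][midx])
    obs <- .grid_observations(geno[, sel, drop = FALSE], mpos, grid, error_prob)
    p_het <- .forward_backward_phet(obs, grid, error_prob, map_function)
    rownames(p_het) <- rownames(geno)
    res[[cc]] <- list(chr = cc, pos = grid, loc = loc,
                      is_marker = !is.na(midx), p_het = p_het)
  }
  structure(res, class = "genoprob_grid", step = step,
            error_prob = error_prob, map_function = map_function,
            individuals = rownames(geno))
}

# Collapse coincident markers onto grid positions as per-state emission
# likelihoods (n x K x 2 array): several markers at one position multiply.
.grid_observations <- function(geno_chr, mpos, grid, error_prob) {
  n <- nrow(geno_chr)
  K <- length(grid)
  e <- array(1, dim = c(n, K, 2L))
  for (j in seq_along(mpos)) {
    k <- match(mpos[j], grid)
    o <- geno_chr[, j]
    hom_lik <- ifelse(is.na(o), 1, ifelse(o == 0L, 1 - error_prob, error_prob))
    het_lik <- ifelse(is.na(o), 1, ifelse(o == 1L, 1 - error_prob, error_prob))
    e[, k, 1L] <- e[, k, 1L] * hom_lik
    e[, k, 2L] <- e[, k, 2L] * het_lik
  }
  e
}

# Scaled forward-backward for the 2-state backcross chain, vectorised
# over individuals. Returns n x K matrix of P(het | observations).
.forward_backward_phet <- function(emis, grid, error_prob, map_function) {
  n <- dim(emis)[1L]
  K <- dim(emis)[2L]
  r <- if (K > 1L) map_to_recomb(diff(grid), map_function) else numeric(0)
  a1 <- matrix(0, n, K)  # forward, state hom
  a2 <- matrix(0, n, K)  # forward, state het
  a1[, 1L] <- 0.5 * emis[, 1L, 1L]
  a2[, 1L] <- 0.5 * emis[, 1L, 2L]
  sc <- a1[, 1L] + a2[, 1L]
  a1[, 1L] <- a1[, 1L] / sc; a2[, 1L] <- a2[, 1L] / sc
  for (k in seq_len(K - 1L)) {
    rr <- r[k]
    f1 <- a1[, k] * (1 - rr) + a2[, k] * rr
    f2 <- a1[, k] * rr + a2[, k] * (1 - rr)
    f1 <- f1 * emis[, k + 1L, 1L]
    f2 <- f2 * emis[, k + 1L, 2L]
    sc <- f1 + f2
    a1[, k + 1L] <- f1 / sc
    a2[, k + 1L] <- f2 / sc
  }
  b1 <- rep(1, n); b2 <- rep(1, n)
  post <- matrix(0, n, K)
  post[, K] <- a2[, K] / (a1[, K] + a2[, K])
  for (k in rev(seq_len(K - 1L))) {
    rr <- r[k]
    g1 <- b1 * emis[, k + 1L, 1L]
    g2 <- b2 * emis[, k + 1L, 2L]
    b1 <- g1 * (1 - rr) + g2 * rr
    b2 <- g1 * rr + g2 * (1 - rr)
    sc <- b1 + b2
    b1 <- b1 / sc; b2 <- b2 / sc
    num <- a2[, k] * b2
    post[, k] <- num / (a1[, k] * b1 + num)
  }
  post
}

#' @export
print.genoprob_grid <- function(x, ...) {
  K <- sum(vapply(x, function(ch) length(ch$pos), 1L))
  cat("Genotype probability grid:", length(x), "chromosome(s),",
      K, "positions,", nrow(x[[1L]]$p_het), "individuals\n")
  cat("  step:", attr(x, "step"), "cM; error_prob:", attr(x, "error_prob"),
      "; map function:", attr(x, "map_function"), "\n")
  invisible(x)
}

#' Grid positions of a genotype probability object
#'
#' @param probs A `genoprob_grid`.
#' @return Data frame with `chr`, `pos`, `loc`, `is_marker`.
#' @export
grid_positions <- function(probs) {
  stopifnot(inherits(probs, "genoprob_grid"))
  do.call(rbind, lapply(probs, function(ch)
    data.frame(chr = ch$chr, pos = ch$pos, loc = ch$loc,
               is_marker = ch$is_marker, stringsAsFactors = FALSE)))
}

# n x (total grid positions) matrix of p_het, chromosomes concatenated
.phet_matrix <- function(probs) {
  do.call(cbind, lapply(probs, function(ch) ch$p_het))
}

#' Restrict a genotype probability grid to a subset of individuals
#'
#' @param probs A `genoprob_grid`.
#' @param idx Row indices or individual names.
#' @return A `genoprob_grid` for the subset.
#' @export
subset_genoprob <- function(probs, idx) {
  stopifnot(inherits(probs, "genoprob_grid"))
  out <- lapply(probs, function(ch) {
    ch$p_het <- ch$p_het[idx, , drop = FALSE]
    ch
  })
  attributes(out) <- attributes(probs)
  attr(out, "individuals") <- rownames(out[[1L]]$p_het)
  out
}

# locate the grid column nearest to (chr, pos); exact matches preferred
.find_locus <- function(probs, chr, pos, tol = 1e-6) {
  chr <- as.character(chr)
  if (!chr %in% names(probs)) stop("chromosome ", chr, " not in grid")
  ch <- probs[[chr]]
  k <- which.min(abs(ch$pos - pos))
  if (abs(ch$pos[k] - pos) > tol && abs(ch$pos[k] - pos) > attr(probs, "step"))
    warning(sprintf("position %s@%g matched to grid position %g", chr, pos, ch$pos[k]))
  list(chr = chr, k = k, pos = ch$pos[k], loc = ch$loc[k],
       p_het = ch$p_het[, k])
}
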