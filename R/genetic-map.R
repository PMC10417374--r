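#' Construct a genetic map
#'
#' A genetic map is the coordinate system for all linkage analysis: an
#' ordered set of chromosomes, each carrying uniquely named markers at
#' non-decreasing centimorgan (cM) positions.
#'
#' @param chr Chromosome label for each marker (character or coercible).
#'   Chromosome order is the order of first appearance.
#' @param marker Marker names; must be globally unique.
#' @param pos_cM Marker positions in centimorgan; non-negative, finite,
#'   non-decreasing within each chromosome.
#'
#' @return A `genetic_map` object: a data frame with columns `chr`,
#'   `marker`, `pos_cM` and a `chromosomes` attribute giving chromosome
#'   order.
#' @export
#' @examples
#' gm <- genetic_map(chr = c(1, 1, 2), marker = c("m1", "m2", "m3"),
#'                   pos_cM = c(0, 10, 0))
genetic_map <- function(chr, marker, pos_cM) {
  chr <- as.character(chr)
  marker <- as.character(marker)
  pos_cM <- as.numeric(pos_cM)
  if (length(chr) != length(marker) || length(chr) != length(pos_cM))
    stop("chr, marker and pos_cM must have equal length")
  if (length(marker) == 0L) stop("a genetic map needs at least one marker")
  if (anyDuplicated(marker)) stop("marker names must be globally unique")
  if (any(!is.finite(pos_cM))) stop("marker positions must be finite")
  if (any(pos_cM < 0)) stop("marker positions must be non-negative")
  chromosomes <- unique(chr)
  for (cc in chromosomes) {
    p <- pos_cM[chr == cc]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", cc)
  }
  out <- data.frame(chr = chr, marker = marker, pos_cM = pos_cM,
                    stringsAsFactors = FALSE)
  attr(out, "chromosomes") <- chromosomes
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  chromosomes <- attr(x, "chromosomes")
  cat("Genetic map:", length(chromosomes), "chromosome(s),",
      nrow(x), "markers\n")
  for (cc in chromosomes) {
    p <- x$pos_cM[x$chr == cc]
    cat(sprintf("  chr %s: %d markers, %.1f-%.1f cM\n",
                cc, length(p), min(p), max(p)))
  }
  invisible(x)
}

#' Map distance to recombination fraction
#'
#' Converts an inter-locus distance in centimorgan to a recombination
#' fraction. The default is Haldane's function (no crossover
#' interference), `r = (1 - exp(-2d/100)) / 2`; Kosambi's function,
#' `r = tanh(2d/100) / 2`, is available as an option.
#'
#' @param d Distance(s) in cM; must be non-negative.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
#' @examples
#' map_to_recomb(10)   # ~0.0906
map_to_recomb <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  M <- d / 100
  switch(map_function,
         haldane = (1 - exp(-2 * M)) / 2,
         kosambi = tanh(2 * M) / 2)
}

# genotype codes used throughout: 0 = recurrent homozygote (FVB/FVB),
# 1 = heterozygote (FVB/C57), NA = missing
GENO_LETTERS <- c(`0` = "A", `1` = "H")

#' Bundle a genetic map with backcross genotypes
#'
#' @param map A [genetic_map()].
#' @param geno Integer matrix, individuals x markers, values 0
#'   (recurrent homozygote), 1 (heterozygote) or `NA`; columns in map
#'   marker order.
#' @return A `backcross` object (list with `map` and `geno`).
#' @export
backcross <- function(map, geno) {
  stopifnot(inherits(map, "genetic_map"))
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map))
    stop("geno must have one column per map marker")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("genotype codes must be 0, 1 or NA")
  storage.mode(geno) <- "integer"
  colnames(geno) <- map$marker
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  structure(list(map = map, geno = geno), class = "backcross")
}

#' @export
print.backcross <- function(x, ...) {
  cat("Backcross cohort:", nrow(x$geno), "individuals\n")
  print(x$map)
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Read a cross file
#'
#' File dialect: CSV where row 1 holds marker names, row 2 chromosome
#' labels, row 3 cM positions, and each later row one individual's
#' genotypes coded `A` (recurrent homozygote), `H` (heterozygote) or `-`
#' (missing). [write_cross_csv()] writes the same dialect and the pair
#' round-trips bit-exactly.
#'
#' @param path Path to the CSV file.
#' @return A [backcross()] object.
#' @export
read_cross_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("cross file needs marker, chromosome and position rows")
  cells <- strsplit(lines, ",", fixed = TRUE)
  markers <- cells[[1L]]
  chrs <- cells[[2L]]
  pos <- as.numeric(cells[[3L]])
  map <- genetic_map(chrs, markers, pos)
  ind <- cells[-(1:3)]
  geno <- matrix(NA_integer_, nrow = length(ind), ncol = length(markers))
  for (i in seq_along(ind)) {
    g <- ind[[i]]
    if (length(g) != length(markers))
      stop("individual row ", i, " has ", length(g), " fields, expected ",
           length(markers))
    bad <- !g %in% c("A", "H", "-")
    if (any(bad)) stop("unknown genotype letter(s): ",
                       paste(unique(g[bad]), collapse = ", "))
    geno[i, ] <- ifelse(g == "A", 0L, ifelse(g == "H", 1L, NA_integer_))
  }
  backcross(map, geno)
}

#' Write a cross file
#'
#' @param cross A [backcross()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname read_cross_csv
#' @export
write_cross_csv <- function(cross, path) {
  stopifnot(inherits(cross, "backcross"))
  map <- cross$map
  g <- matrix("-", nrow = nrow(cross$geno), ncol = ncol(cross$geno))
  g[!is.na(cross$geno) & cross$geno == 0L] <- "A"
  g[!is.na(cross$geno) & cross$geno == 1L] <- "H"
  lines <- c(paste(map$marker, collapse = ","),
             paste(map$chr, collapse = ","),
             paste(as.character(map$pos_cM), collapse = ","),
             apply(g, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
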