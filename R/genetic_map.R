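#' Construct a genetic map
#'
#' A genetic map holds chromosome lengths in centiMorgans and base pairs,
#' plus optional anchor loci that pin particular physical positions to map
#' positions. Conversion between bp and cM is by monotone linear
#' interpolation through the anchors (the chromosome ends `(0, 0)` and
#' `(length_bp, length_cM)` are always implicit anchors).
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`,
#'   `length_cM`, and logical `is_z` flagging the sex chromosome.
#' @param loci optional data.frame of anchor loci with columns `chrom`,
#'   `pos_bp`, `pos_cM` (and optionally `locus` names). Within each
#'   chromosome `pos_cM` must be non-decreasing in `pos_bp`.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(chromosomes, loci = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_bp", "length_cM") %in% names(chromosomes)))
  if (is.null(chromosomes$is_z)) chromosomes$is_z <- FALSE
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cM <= 0))
    stop("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome ids")
  if (!is.null(loci)) {
    stopifnot(all(c("chrom", "pos_bp", "pos_cM") %in% names(loci)))
    if (!all(loci$chrom %in% chromosomes$chrom))
      stop("anchor locus on unknown chromosome")
    for (ch in unique(loci$chrom)) {
      l <- loci[loci$chrom == ch, ]
      l <- l[order(l$pos_bp), ]
      if (is.unsorted(l$pos_cM)) stop("pos_cM must be non-decreasing in pos_bp")
      len <- chromosomes[chromosomes$chrom == ch, ]
      if (any(l$pos_bp < 0 | l$pos_bp > len$length_bp) ||
          any(l$pos_cM < 0 | l$pos_cM > len$length_cM))
        stop("anchor locus outside chromosome")
    }
  }
  structure(list(chromosomes = chromosomes, loci = loci), class = "genetic_map")
}

#' Default genome for simulation
#'
#' 20 autosomes plus one Z chromosome, each 50 cM long; physical length
#' defaults to 15 Mb per chromosome (0.3 Mb per cM). Chromosome 18 carries
#' two named anchor loci: the behavioural QTL peak at 0 cM and the linked
#' red-band colour-pattern locus (`optix`) at 1.2 cM, the marker used to
#' select carriers in the backcross design.
#'
#' @param n_autosomes number of autosomes.
#' @param length_cM genetic length per chromosome (cM).
#' @param length_bp physical length per chromosome (bp).
#' @return a `genetic_map`.
#' @export
default_genetic_map <- function(n_autosomes = 20, length_cM = 50,
                                length_bp = 15e6) {
  chroms <- data.frame(
    chrom = c(paste0("chr", seq_len(n_autosomes)), "chrZ"),
    length_bp = length_bp, length_cM = length_cM,
    is_z = c(rep(FALSE, n_autosomes), TRUE),
    stringsAsFactors = FALSE
  )
  bp_per_cM <- length_bp / length_cM
  loci <- NULL
  if (n_autosomes >= 18) {
    loci <- data.frame(
      chrom = "chr18",
      pos_bp = c(1, round(1.2 * bp_per_cM)),
      pos_cM = c(0, 1.2),
      locus = c("qtl_peak", "optix"),
      stringsAsFactors = FALSE
    )
  }
  genetic_map(chroms, loci)
}

map_anchor_points <- function(map, chrom) {
  row <- map$chromosomes[map$chromosomes$chrom == chrom, ]
  if (nrow(row) != 1) stop("unknown chromosome: ", chrom)
  bp <- c(0, row$length_bp)
  cM <- c(0, row$length_cM)
  if (!is.null(map$loci)) {
    l <- map$loci[map$loci$chrom == chrom, ]
    if (nrow(l)) {
      bp <- c(bp, l$pos_bp)
      cM <- c(cM, l$pos_cM)
    }
  }
  o <- order(bp)
  list(bp = bp[o], cM = cM[o])
}

#' Convert physical to map position (and back)
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome id.
#' @param pos_bp,pos_cM positions to convert.
#' @return numeric vector of converted positions.
#' @export
bp_to_cM <- function(map, chrom, pos_bp) {
  a <- map_anchor_points(map, chrom)
  approx(a$bp, a$cM, xout = pos_bp, rule = 2, ties = "ordered")$y
}

#' @rdname bp_to_cM
#' @export
cM_to_bp <- function(map, chrom, pos_cM) {
  a <- map_anchor_points(map, chrom)
  approx(a$cM, a$bp, xout = pos_cM, rule = 2, ties = "ordered")$y
}

map_chrom_ids <- function(map) map$chromosomes$chrom

map_chrom_length_bp <- function(map, chrom) {
  map$chromosomes$length_bp[match(chrom, map$chromosomes$chrom)]
}

map_chrom_length_cM <- function(map, chrom) {
  map$chromosomes$length_cM[match(chrom, map$chromosomes$chrom)]
}

map_z_chrom <- function(map) {
  z <- map$chromosomes$chrom[map$chromosomes$is_z]
  if (length(z)) z else NA_character_
}
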