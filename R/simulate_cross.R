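# Forward simulation of hybrid genomes: tract-based haplotypes, Haldane
# (no-interference) meiosis, and backcross pedigrees with selection at a
# marker locus. Ancestry codes: 1 = "mel" (species A), 2 = "cyd" (species B).

SPECIES_CODES <- c(mel = 1L, cyd = 2L)

new_haplotype <- function(map, anc) {
  h <- lapply(map_chrom_ids(map), function(ch)
    list(ends = map_chrom_length_bp(map, ch), anc = anc))
  names(h) <- map_chrom_ids(map)
  h
}

#' Construct founder genomes
#'
#' `pure_genome()` returns a genome with both haplotypes from one species;
#' `f1_genome()` returns a first-generation hybrid, heterozygous
#' (one mel and one cyd haplotype) along every chromosome.
#'
#' @param map a [genetic_map].
#' @param species `"mel"` or `"cyd"`.
#' @return an object of class `hybrid_genome`: two haplotypes, each a
#'   per-chromosome list of ancestry tracts (`ends` in bp, 0-based
#'   half-open tiling; `anc` ancestry codes).
#' @export
pure_genome <- function(map, species = c("cyd", "mel")) {
  species <- match.arg(species)
  anc <- SPECIES_CODES[[species]]
  structure(list(h1 = new_haplotype(map, anc), h2 = new_haplotype(map, anc),
                 chroms = map_chrom_ids(map)),
            class = "hybrid_genome")
}

#' @rdname pure_genome
#' @export
f1_genome <- function(map) {
  structure(list(h1 = new_haplotype(map, SPECIES_CODES[["mel"]]),
                 h2 = new_haplotype(map, SPECIES_CODES[["cyd"]]),
                 chroms = map_chrom_ids(map)),
            class = "hybrid_genome")
}

# ancestry of a haploid tract list at positions (bp, 0-based)
tract_anc_at <- function(tr, pos) {
  tr$anc[findInterval(pos, tr$ends) + 1L]
}

#' Ancestry genotype at genomic positions
#'
#' @param genome a `hybrid_genome`.
#' @param chrom chromosome id (single).
#' @param pos numeric vector of positions (bp).
#' @return integer matrix with two rows (one per haplotype), entries
#'   1 (mel) or 2 (cyd).
#' @export
genotype_at <- function(genome, chrom, pos) {
  rbind(h1 = tract_anc_at(genome$h1[[chrom]], pos),
        h2 = tract_anc_at(genome$h2[[chrom]], pos))
}

# slice a tract list to [from, to), coordinates shifted to keep absolute bp
tract_slice <- function(tr, from, to) {
  if (to <= from) return(list(ends = numeric(0), anc = integer(0)))
  i1 <- findInterval(from, tr$ends) + 1L
  i2 <- findInterval(to - 1e-9, tr$ends) + 1L
  ends <- tr$ends[i1:i2]
  ends[length(ends)] <- to
  list(ends = ends, anc = tr$anc[i1:i2])
}

tract_concat <- function(pieces) {
  ends <- unlist(lapply(pieces, `[[`, "ends"), use.names = FALSE)
  anc <- unlist(lapply(pieces, `[[`, "anc"), use.names = FALSE)
  if (length(anc) > 1) {  # merge adjacent tracts of equal ancestry
    keep <- c(anc[-length(anc)] != anc[-1], TRUE)
    ends <- ends[keep]; anc <- anc[keep]
  }
  list(ends = ends, anc = anc)
}

#' Simulate one meiosis (Haldane model)
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' chromosome's genetic length in Morgans; crossover positions are uniform
#' on the cM scale (no interference); the starting haplotype is chosen at
#' random. Returns the transmitted gamete as a haploid tract list.
#'
#' @param parent a `hybrid_genome`.
#' @param map a [genetic_map].
#' @param seed optional integer seed.
#' @return named per-chromosome list of tracts (`ends`, `anc`).
#' @export
simulate_meiosis <- function(parent, map, seed = NULL) {
  if (!inherits(map, "genetic_map") || nrow(map$chromosomes) == 0)
    stop("empty or invalid genetic map")
  if (!is.null(seed)) set.seed(seed)
  gam <- lapply(map_chrom_ids(map), function(ch) {
    L_bp <- map_chrom_length_bp(map, ch)
    L_cM <- map_chrom_length_cM(map, ch)
    n_xo <- rpois(1, L_cM / 100)
    phase <- sample.int(2L, 1L)
    h <- list(parent$h1[[ch]], parent$h2[[ch]])
    if (n_xo == 0) return(h[[phase]])
    cuts_bp <- sort(cM_to_bp(map, ch, runif(n_xo, 0, L_cM)))
    bounds <- c(0, cuts_bp, L_bp)
    pieces <- vector("list", length(bounds) - 1L)
    for (k in seq_along(pieces)) {
      pieces[[k]] <- tract_slice(h[[phase]], bounds[k], bounds[k + 1L])
      phase <- 3L - phase
    }
    tract_concat(pieces)
  })
  names(gam) <- map_chrom_ids(map)
  gam
}

combine_gametes <- function(g1, g2, chroms) {
  structure(list(h1 = g1, h2 = g2, chroms = chroms), class = "hybrid_genome")
}

#' Specify a backcross pedigree
#'
#' The cross starts from an F1 between the two species and is backcrossed
#' to the recurrent parent for `n_bc` generations; at each generation only
#' offspring with the required genotype at the selected marker are kept
#' (in the motivating design, carriers of the dominant red-band allele,
#' i.e. heterozygous at the colour-pattern locus on chromosome 18).
#'
#' The default of four backcross meioses reflects the expectation that the
#' resulting genome is 1/16 heterozygous away from the selected chromosome;
#' see the methods vignette for the relationship between generation
#' counting and this expectation.
#'
#' @param n_bc number of backcross meioses from the F1 (>= 0).
#' @param recurrent recurrent parent species (`"cyd"` or `"mel"`).
#' @param marker list with `chrom` and `pos_bp` of the selected marker, or
#'   `NULL` for no selection.
#' @param required_genotype required marker genotype, `"het"` or `"hom"`.
#' @param max_retries retries per generation before declaring selection
#'   impossible.
#' @return an object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(n_bc = 4, recurrent = "cyd",
                          marker = list(chrom = "chr18", pos_bp = 360000),
                          required_genotype = "het", max_retries = 1000) {
  stopifnot(n_bc >= 0)
  structure(list(n_bc = n_bc, recurrent = match.arg(recurrent, c("cyd", "mel")),
                 marker = marker, required_genotype = required_genotype,
                 max_retries = max_retries),
            class = "pedigree_spec")
}

marker_ok <- function(genome, marker, required) {
  if (is.null(marker)) return(TRUE)
  g <- genotype_at(genome, marker$chrom, marker$pos_bp)
  het <- g[1] != g[2]
  if (required == "het") het else !het
}

#' Simulate a cohort of backcross hybrid genomes
#'
#' Each requested genome is an independent realisation of the pedigree:
#' starting from the F1, `n_bc` successive backcross meioses to the
#' recurrent parent, retaining at each generation only offspring with the
#' required genotype at the selected marker.
#'
#' @param spec a [pedigree_spec].
#' @param map a [genetic_map].
#' @param n number of genomes to simulate.
#' @param seed optional integer seed.
#' @return list of `hybrid_genome` objects (true ancestry tracts).
#' @export
simulate_pedigree <- function(spec, map, n = 1, seed = NULL) {
  stopifnot(inherits(spec, "pedigree_spec"))
  if (!is.null(spec$marker) &&
      !(spec$marker$chrom %in% map_chrom_ids(map)))
    stop("selected marker chromosome not in map")
  if (!is.null(seed)) set.seed(seed)
  chroms <- map_chrom_ids(map)
  rec_anc <- SPECIES_CODES[[spec$recurrent]]
  rec_hap <- new_haplotype(map, rec_anc)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- f1_genome(map)
    if (spec$n_bc > 0) {
      for (gen in seq_len(spec$n_bc)) {
        ok <- FALSE
        for (try in seq_len(spec$max_retries)) {
          cand <- combine_gametes(simulate_meiosis(g, map), rec_hap, chroms)
          if (marker_ok(cand, spec$marker, spec$required_genotype)) {
            g <- cand; ok <- TRUE; break
          }
        }
        if (!ok) stop("selection at marker impossible after ",
                      spec$max_retries, " retries (generation ", gen, ")")
      }
    }
    out[[i]] <- g
  }
  out
}

#' Heterozygous genome fraction from ancestry tracts
#'
#' Base-pair-weighted fraction of the genome at which the two haplotypes
#' carry different species ancestries, optionally excluding a chromosome
#' (e.g. the one under selection in the cross).
#'
#' @param genome a `hybrid_genome`.
#' @param exclude_chrom chromosome ids to exclude (default none).
#' @return numeric scalar in `[0, 1]`.
#' @export
het_fraction <- function(genome, exclude_chrom = NULL) {
  chroms <- setdiff(genome$chroms, exclude_chrom)
  if (!length(chroms)) stop("no chromosomes left after exclusion")
  tot <- 0; het <- 0
  for (ch in chroms) {
    t1 <- genome$h1[[ch]]; t2 <- genome$h2[[ch]]
    ends <- sort(unique(c(t1$ends, t2$ends)))
    starts <- c(0, ends[-length(ends)])
    w <- ends - starts
    mids <- (starts + ends) / 2
    diffanc <- tract_anc_at(t1, mids) != tract_anc_at(t2, mids)
    tot <- tot + sum(w)
    het <- het + sum(w[diffanc])
  }
  het / tot
}
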