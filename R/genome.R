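#' Generate a toy genome with planted RSS heptamers
#'
#' Background sequence is i.i.d. uniform ACGT.  Canonical heptamers
#' (CACAGTG) and degenerate cryptic heptamers drawn from the consensus
#' CAC(A/C)(C/G)(A/T)(G/C) are planted at recorded offsets and orientations;
#' no two plantings fall within 50 bp of each other and none within 30 bp of
#' a chromosome end.  A forward-orientation planting writes the heptamer
#' itself at the offset; a reverse-orientation planting writes its reverse
#' complement (so the heptamer reads 5'->3' on the minus strand).
#'
#' @param config A [sim_config()].  `config$seed` seeds the generator, so a
#'   fixed config yields byte-identical genomes.
#' @return A `toy_genome`: list with `chromosomes` (named character vector)
#'   and `planted_rss` (data.frame chrom, offset, orientation, heptamer,
#'   is_canonical, used).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  lens <- config$chromosome_lengths
  chroms <- vapply(lens, function(L) rand_dna(L), character(1))
  names(chroms) <- names(lens)

  n_total <- config$n_canonical_rss + config$n_cryptic_rss
  # allocate plantings to chromosomes proportionally to length
  alloc <- as.vector(table(factor(
    sample(names(lens), n_total, replace = TRUE, prob = lens / sum(lens)),
    levels = names(lens))))
  names(alloc) <- names(lens)

  rss <- list()
  is_canon <- c(rep(TRUE, config$n_canonical_rss),
                rep(FALSE, config$n_cryptic_rss))
  is_canon <- sample(is_canon)  # interleave classes across chromosomes
  k <- 0L
  for (chrom in names(lens)) {
    n_here <- alloc[[chrom]]
    if (n_here == 0) next
    offs <- plant_positions(lens[[chrom]], n_here, min_gap = 50L,
                            edge = as.integer(min(1050, max(50, lens[[chrom]] %/% 8))))
    for (o in offs) {
      k <- k + 1L
      canonical <- is_canon[k]
      hep <- if (canonical) "CACAGTG" else random_cryptic_heptamer()
      ori <- sample(c("+", "-"), 1)
      written <- if (ori == "+") hep else revcomp(hep)
      substr0(chroms[[chrom]], o) <- written
      rss[[k]] <- data.frame(chrom = chrom, offset = o, orientation = ori,
                             heptamer = hep, is_canonical = canonical,
                             stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, rss)
  if (is.null(planted)) {
    planted <- data.frame(chrom = character(0), offset = integer(0),
                          orientation = character(0),
                          heptamer = character(0),
                          is_canonical = logical(0))
  }
  planted <- planted[order(planted$chrom, planted$offset), , drop = FALSE]
  rownames(planted) <- NULL
  planted$used <- logical(nrow(planted))
  structure(list(chromosomes = chroms, planted_rss = planted),
            class = "toy_genome")
}

# Cryptic heptamers follow the degenerate consensus CAC(A/C)(C/G)(A/T)(G/C).
random_cryptic_heptamer <- function() {
  paste0("CAC",
         sample(c("A", "C"), 1), sample(c("C", "G"), 1),
         sample(c("A", "T"), 1), sample(c("G", "C"), 1))
}

# Draw n positions in [edge, L - edge - 7] with pairwise gaps >= min_gap.
plant_positions <- function(L, n, min_gap = 50L, edge = 1050L) {
  lo <- edge
  hi <- L - edge - 7L
  if (hi <= lo) stop("chromosome too short for requested plantings")
  offs <- integer(0)
  tries <- 0L
  while (length(offs) < n) {
    cand <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    if (!length(offs) || min(abs(offs - cand)) >= min_gap) {
      offs <- c(offs, cand)
    }
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop("could not place ", n, " plantings with min gap ", min_gap)
    }
  }
  sort(offs)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$chromosomes), "chromosome(s), total",
      sum(nchar(x$chromosomes)), "bp\n")
  cat("  planted RSS heptamers:", nrow(x$planted_rss),
      sprintf("(%d canonical, %d cryptic)\n",
              sum(x$planted_rss$is_canonical),
              sum(!x$planted_rss$is_canonical)))
  invisible(x)
}

# Sequence accessors, 0-based half-open -------------------------------------

genome_seq <- function(genome, chrom, start, end) {
  substr0(genome$chromosomes[[chrom]], start, end)
}

genome_edit <- function(genome, chrom, start, value) {
  substr0(genome$chromosomes[[chrom]], start) <- value
  genome
}

#' Write a toy genome to FASTA
#'
#' @param genome A `toy_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a genome FASTA into the toy-genome container
#'
#' @param path FASTA path.
#' @return A `toy_genome` (with an empty planting registry).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  chroms <- as.character(x)
  names(chroms) <- sub("\\s.*$", "", names(x))
  structure(list(chromosomes = chroms,
                 planted_rss = data.frame(chrom = character(0),
                                          offset = integer(0),
                                          orientation = character(0),
                                          heptamer = character(0),
                                          is_canonical = logical(0),
                                          used = logical(0))),
            class = "toy_genome")
}
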