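#' Generate a random reference genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC fraction. Used as a
#' stand-in for real reference genomes when forward-simulating metagenomic
#' mixtures.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc_fraction target GC content, strictly between 0 and 1.
#' @param seed optional integer seed; the same `(length, gc_fraction, seed)`
#'   always yields the same sequence.
#' @param id,taxon_id identifiers attached to the genome.
#' @return an object of class `genome_spec` with fields `id`, `taxon_id`,
#'   `length`, `gc_fraction` (target) and `sequence`.
#' @examples
#' g <- generate_genome(2000, 0.5, seed = 1)
#' nchar(g$sequence)
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                            id = "genome1", taxon_id = id) {
  if (!is.numeric(length) || length(length) != 1L || length < 1000)
    stop("'length' must be a single integer >= 1000", call. = FALSE)
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stop("'gc_fraction' must lie strictly between 0 and 1", call. = FALSE)
  set_seed_if(seed)
  seq <- random_dna(as.integer(length), gc_fraction)
  genome_spec(id = id, taxon_id = taxon_id, sequence = seq,
              gc_fraction = gc_fraction)
}

#' Construct a genome specification from an explicit sequence
#'
#' @param id,taxon_id identifiers.
#' @param sequence DNA string over A/C/G/T.
#' @param gc_fraction target GC used at generation time; defaults to the
#'   empirical GC of `sequence`.
#' @return a `genome_spec` object.
#' @export
genome_spec <- function(id, taxon_id = id, sequence, gc_fraction = NULL) {
  if (grepl("[^ACGT]", sequence))
    stop("genome sequence may only contain A, C, G, T", call. = FALSE)
  if (is.null(gc_fraction)) {
    tab <- table(strsplit(sequence, "", fixed = TRUE)[[1L]])
    gc_fraction <- sum(tab[c("C", "G")], na.rm = TRUE) / nchar(sequence)
  }
  structure(
    list(id = id, taxon_id = taxon_id, length = nchar(sequence),
         gc_fraction = gc_fraction, sequence = sequence),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %s (taxon %s): %d bp, GC target %.3f\n",
              x$id, x$taxon_id, x$length, x$gc_fraction))
  invisible(x)
}

#' Evolve a derived strain by random substitutions
#'
#' Introduces independent per-site substitutions (no indels) at a fixed
#' divergence, producing a strain genome at a known distance from its
#' ancestor. Supports divergent-reference scenarios in which damage signals
#' are partially masked by biological sequence variation.
#'
#' @param genome a `genome_spec`.
#' @param divergence per-site substitution probability in `[0, 0.25)`.
#' @param seed optional integer seed.
#' @param id,taxon_id identifiers for the derived strain.
#' @return a `genome_spec` of equal length.
#' @export
evolve_strain <- function(genome, divergence, seed = NULL,
                          id = paste0(genome$id, "_d"), taxon_id = id) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 0.25)
    stop("'divergence' must lie in [0, 0.25)", call. = FALSE)
  set_seed_if(seed)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(chars)) < divergence
  if (any(hit)) {
    base_idx <- match(chars[hit], DNA_BASES)
    # shift by 1..3 modulo 4: uniform over the three other bases
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    chars[hit] <- DNA_BASES[((base_idx - 1L + shift) %% 4L) + 1L]
  }
  genome_spec(id = id, taxon_id = taxon_id,
              sequence = paste(chars, collapse = ""),
              gc_fraction = genome$gc_fraction)
}
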