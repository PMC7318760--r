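#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Deterministic child seed for a pipeline stage; keeps all seeds < 2^31 - 1.
derive_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483647L) * 48271 %% 2147483647 + salt) %% 2147483647L
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' Reverse complement of plain character DNA sequences
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences into per-base vectors with molecule bookkeeping.
explode_seqs <- function(seqs) {
  ch <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(ch)
  list(
    chars = unlist(ch, use.names = FALSE),
    mol   = rep.int(seq_along(seqs), lens),
    len   = rep.int(lens, lens),
    pos0  = sequence(lens) - 1L,
    lens  = lens
  )
}

# Inverse of explode_seqs: rebuild one string per molecule.
implode_seqs <- function(chars, mol, n_mol) {
  groups <- split(chars, factor(mol, levels = seq_len(n_mol)))
  unname(vapply(groups, paste, character(1L), collapse = ""))
}

# Rebuild only the molecules whose bases changed; untouched molecules keep
# their original string (substantial speed-up at low substitution rates).
rebuild_changed <- function(orig, chars, mol, hit) {
  out <- orig
  changed <- unique(mol[hit])
  if (length(changed) == 0L) return(out)
  sel <- mol %in% changed
  out[changed] <- implode_seqs(chars[sel], match(mol[sel], changed),
                               length(changed))
  out
}

# Random DNA string with a given GC fraction.
random_dna <- function(n, gc_fraction = 0.5) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2, (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}
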