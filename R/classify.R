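# Minimal k-mer classifier standing in for a BlastN-mode aligner: the binning
# contract (per-genome match scores -> score margin -> LCA) is what the
# downstream enrichment analysis consumes.

.canonical_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0L))
  km <- substring(sequence, 1:(n - k + 1L), k:n)
  # k-mer i reverse-complemented is a forward k-mer of the reverse complement
  rc_seq <- revcomp(sequence)
  starts <- (n - k + 1L):1L
  km_rc <- substring(rc_seq, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", km)
  pmin(km, km_rc)[keep]
}

#' Build a canonical k-mer index over a reference genome set
#'
#' @param genomes list of `genome_spec` objects (or a named character vector
#'   of sequences).
#' @param k odd k-mer size between 11 and 31 (default 21).
#' @return an object of class `kmer_index` mapping each canonical k-mer
#'   (lexicographic minimum of the k-mer and its reverse complement) to the
#'   set of genomes containing it.
#' @export
kmer_index <- function(genomes, k = 21) {
  if (k %% 2L != 1L || k < 11 || k > 31)
    stop("'k' must be odd and within [11, 31]", call. = FALSE)
  if (is.character(genomes)) {
    ids <- names(genomes)
    taxa <- ids
    seqs <- unname(genomes)
  } else {
    ids <- vapply(genomes, `[[`, character(1L), "id")
    taxa <- vapply(genomes, `[[`, character(1L), "taxon_id")
    seqs <- vapply(genomes, `[[`, character(1L), "sequence")
  }
  if (is.null(ids) || anyDuplicated(ids))
    stop("genomes must carry unique ids", call. = FALSE)
  kml <- lapply(seqs, function(s) unique(.canonical_kmers(s, k)))
  kmer <- unlist(kml, use.names = FALSE)
  gidx <- rep.int(seq_along(seqs), lengths(kml))
  env <- list2env(split(gidx, kmer), hash = TRUE,
                  size = max(length(kmer), 1L))
  structure(list(k = as.integer(k), env = env, genome_ids = ids,
                 taxon_ids = stats::setNames(taxa, ids)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d genomes, %d distinct canonical k-mers\n",
              x$k, length(x$genome_ids), length(ls(x$env))))
  invisible(x)
}

#' Score one read against the index
#'
#' The score of a genome is the number of the read's k-mers present in that
#' genome; canonical k-mers make the score strand-symmetric.
#'
#' @param read a DNA string.
#' @param index a `kmer_index`.
#' @return named integer vector (genomes with score > 0); empty for reads
#'   shorter than `k` or with no matches.
#' @export
score_read <- function(read, index) {
  stopifnot(inherits(index, "kmer_index"))
  km <- .canonical_kmers(read, index$k)
  sc <- integer(length(index$genome_ids))
  for (x in km) {
    g <- get0(x, envir = index$env, inherits = FALSE)
    if (!is.null(g)) sc[g] <- sc[g] + 1L
  }
  pos <- sc > 0L
  stats::setNames(sc[pos], index$genome_ids[pos])
}

#' Assign one read's scores to a taxonomy node by the LCA rule
#'
#' Candidate genomes are those scoring at least `max_score * (1 - margin)`
#' and at least `min_score`; ties always widen the candidate set. The read is
#' assigned to the lowest common ancestor of the candidates' taxa, or left
#' unclassified when no genome qualifies.
#'
#' @param scores named scores from [score_read()].
#' @param tree a `taxonomy_tree`.
#' @param genome_taxa named character vector mapping genome id to taxon id
#'   (defaults to the index's mapping when assigning via [classify_reads()]).
#' @param min_score minimum qualifying score (default 5).
#' @param margin relative score margin (default 0.1).
#' @return a node id, or `NA_character_` for unclassified.
#' @export
assign_lca <- function(scores, tree, genome_taxa, min_score = 5, margin = 0.1) {
  if (length(scores) == 0L) return(NA_character_)
  thr <- max(max(scores) * (1 - margin), min_score)
  cand <- names(scores)[scores >= thr]
  if (length(cand) == 0L) return(NA_character_)
  taxa <- genome_taxa[cand]
  if (anyNA(taxa)) stop("genome without a taxon mapping: ",
                        paste(cand[is.na(taxa)], collapse = ", "), call. = FALSE)
  lca(tree, unique(taxa))
}

#' Classify a set of reads
#'
#' @param reads character vector of read sequences, optionally named with
#'   read ids.
#' @param index a `kmer_index`.
#' @param tree a `taxonomy_tree` containing every indexed taxon.
#' @param min_score,margin see [assign_lca()].
#' @return data frame of class `classification_result` with columns
#'   `read_id`, `best_score`, `n_candidates`, `taxon` (`NA` = unclassified).
#' @export
classify_reads <- function(reads, index, tree, min_score = 5, margin = 0.1) {
  stopifnot(inherits(index, "kmer_index"), inherits(tree, "taxonomy_tree"))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  out <- data.frame(read_id = ids, best_score = 0L, n_candidates = 0L,
                    taxon = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    sc <- score_read(reads[[i]], index)
    if (length(sc) == 0L) next
    out$best_score[i] <- max(sc)
    thr <- max(max(sc) * (1 - margin), min_score)
    out$n_candidates[i] <- sum(sc >= thr)
    out$taxon[i] <- assign_lca(sc, tree, index$taxon_ids, min_score, margin)
  }
  class(out) <- c("classification_result", "data.frame")
  out
}

#' Per-node direct and cumulative read counts
#'
#' The cumulative count of a node is its direct count plus the cumulative
#' counts of all its children, so the root's cumulative count equals the
#' number of classified reads.
#'
#' @param assignments a `classification_result` (or any data frame with a
#'   `taxon` column; `NA` = unclassified).
#' @param tree a `taxonomy_tree`.
#' @return data frame (`node`, `rank`, `name`, `direct`, `cumulative`) sorted
#'   by decreasing cumulative count.
#' @export
summarize_assignments <- function(assignments, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxa <- assignments$taxon[!is.na(assignments$taxon)]
  ids <- tree$nodes$id
  direct <- stats::setNames(rep(0L, length(ids)), ids)
  if (length(taxa) > 0L) {
    tab <- table(taxa)
    direct[names(tab)] <- as.integer(tab)
  }
  cumulative <- direct
  parent_of <- stats::setNames(tree$nodes$parent, ids)
  for (id in ids[order(tree$depth[ids], decreasing = TRUE)]) {
    p <- parent_of[[id]]
    if (!is.na(p)) cumulative[[p]] <- cumulative[[p]] + cumulative[[id]]
  }
  out <- data.frame(node = ids, rank = tree$nodes$rank, name = tree$nodes$name,
                    direct = unname(direct[ids]),
                    cumulative = unname(cumulative[ids]),
                    stringsAsFactors = FALSE)
  out[order(-out$cumulative, out$node), , drop = FALSE]
}
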