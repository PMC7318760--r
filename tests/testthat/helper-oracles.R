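# Independent brute-force oracles used to check the package's fast paths.

# LCA by full ancestor-set intersection on a raw node table.
bf_ancestors <- function(nodes, id) {
  parent <- setNames(nodes$parent, nodes$id)
  path <- id
  while (!is.na(parent[[path[length(path)]]]) &&
         parent[[path[length(path)]]] != path[length(path)])
    path <- c(path, parent[[path[length(path)]]])
  path
}

bf_lca <- function(nodes, ids) {
  common <- Reduce(intersect, lapply(ids, bf_ancestors, nodes = nodes))
  depths <- vapply(common, function(x) length(bf_ancestors(nodes, x)), integer(1L))
  common[which.max(depths)]
}

# Random rooted tree as a node table: node i's parent is a uniformly chosen
# earlier node, which guarantees acyclicity.
random_tree <- function(n) {
  ids <- sprintf("n%02d", seq_len(n))
  parent <- c(ids[1L], ids[pmax(1L, vapply(2:n, function(i)
    sample.int(i - 1L, 1L), integer(1L)))])
  data.frame(id = ids, parent = parent,
             rank = "clade", name = ids, stringsAsFactors = FALSE)
}

# Exact conditional C->T frequency by enumeration over all deamination
# outcomes of each molecule (feasible for molecules with few Cs).
bf_conditional_freq <- function(seqs, model, position,
                                release = 1, retention = 1) {
  num <- den <- 0
  for (s in seqs) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    len <- length(chars)
    if (len <= position || chars[position + 1L] != "C") next
    cpos <- which(chars == "C") - 1L
    d5 <- cpos; d3 <- len - 1L - cpos
    d <- if (model$symmetric_ends) pmin(d5, d3) else d5
    p <- model$p_base + (model$p_term - model$p_base) * exp(-d / model$decay_len)
    m <- length(cpos)
    for (subset in 0:(2^m - 1L)) {
      deam <- as.logical(bitwAnd(subset, 2^(seq_len(m) - 1L)))
      prob <- prod(ifelse(deam, p, 1 - p))
      has_u <- any(deam)
      p_enr <- if (has_u) release else (1 - retention)
      hit_at_pos <- any(deam & cpos == position)
      num <- num + prob * p_enr * hit_at_pos
      den <- den + prob * p_enr
    }
  }
  num / den
}

# Per-base reference coverage (marks every covered base).
bf_reference_coverage <- function(blocks, reference_length) {
  covered <- logical(reference_length)
  for (i in seq_len(nrow(blocks))) {
    if (blocks$ref_end[i] > blocks$ref_start[i])
      covered[(blocks$ref_start[i] + 1L):blocks$ref_end[i]] <- TRUE
  }
  sum(covered) / reference_length
}

# Shared small fixtures -------------------------------------------------

# three species at ~5% pairwise divergence under a two-genus taxonomy
three_taxon_fixture <- function(seed = 101, genome_length = 30000) {
  anc <- generate_genome(genome_length, 0.5, seed = seed, id = "anc")
  list(
    genomes = list(
      evolve_strain(anc, 0.025, seed = seed + 1L, id = "spA", taxon_id = "spA"),
      evolve_strain(anc, 0.025, seed = seed + 2L, id = "spB", taxon_id = "spB"),
      evolve_strain(anc, 0.025, seed = seed + 3L, id = "spC", taxon_id = "spC")),
    tree = build_taxonomy(data.frame(
      id = c("root", "g1", "g2", "spA", "spB", "spC"),
      parent = c("root", "root", "root", "g1", "g1", "g2"),
      rank = c("root", "genus", "genus", "species", "species", "species"),
      name = c("root", "g1", "g2", "spA", "spB", "spC"))))
}

# assigned taxon equals the truth or one of its ancestors
assigned_correct <- function(assigned, truth, tree) {
  mapply(function(a, t) !is.na(a) && a %in% ancestors(tree, t), assigned, truth)
}
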