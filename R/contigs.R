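# Disambiguating two co-assembled relatives: length-filter contigs, align
# them to both candidate reference genomes, call contigs unique to one
# reference, and summarise reference coverage and k-mer coverage modes.

#' Length-filter contigs
#'
#' @param contigs data frame with at least `id` and `sequence` (and usually
#'   `coverage`).
#' @param min_length inclusive minimum contig length in bp (default 2000;
#'   boundary values pass).
#' @return the retained rows.
#' @export
filter_contigs <- function(contigs, min_length = 2000) {
  stopifnot(is.data.frame(contigs), min_length >= 1)
  contigs[nchar(contigs$sequence) >= min_length, , drop = FALSE]
}

# exact-position k-mer index of one reference (forward strand)
.ref_kmer_positions <- function(reference, k) {
  n <- nchar(reference)
  km <- substring(reference, 1:(n - k + 1L), k:n)
  split(seq_len(n - k + 1L) - 1L, km)   # 0-based positions
}

# anchors for one query orientation: data.frame(qpos, rpos), 0-based
.anchors <- function(query, ref_index, k) {
  n <- nchar(query)
  if (n < k) return(data.frame(qpos = integer(0L), rpos = integer(0L)))
  km <- substring(query, 1:(n - k + 1L), k:n)
  hits <- ref_index[km]
  found <- !vapply(hits, is.null, logical(1L))
  if (!any(found)) return(data.frame(qpos = integer(0L), rpos = integer(0L)))
  qpos <- rep.int(which(found) - 1L, lengths(hits[found]))
  data.frame(qpos = qpos, rpos = unlist(hits[found], use.names = FALSE))
}

#' Align contigs to a reference by k-mer anchor chaining
#'
#' Seeds exact k-mer anchors, groups them by alignment diagonal (within a
#' small band, adequate for substitution-only divergence up to ~10%), chains
#' collinear anchors with a fixed gap tolerance, and stitches each chain into
#' an ungapped block whose identity is measured base-by-base. Only blocks
#' spanning at least `min_block` on the contig are emitted. Externally
#' produced coordinate tables with the same columns can substitute for this
#' aligner anywhere downstream.
#'
#' @param contigs data frame with `id` and `sequence`.
#' @param reference reference sequence (string) or a `genome_spec`.
#' @param ref_id reference identifier in the output.
#' @param min_block minimum contig span of an emitted block (default 1000).
#' @param k anchor k-mer size (default 15).
#' @param band diagonal band width for grouping anchors (default 30).
#' @param max_gap maximum along-contig gap between chained anchors (default
#'   200).
#' @return data frame of class `alignment_blocks`: `contig_id`, `ref_id`,
#'   `contig_start`, `contig_end`, `ref_start`, `ref_end` (0-based half-open,
#'   contig coordinates in the contig's own orientation), `strand`,
#'   `identity`.
#' @export
align_contigs <- function(contigs, reference, ref_id = "ref",
                          min_block = 1000, k = 15, band = 30, max_gap = 200) {
  stopifnot(is.data.frame(contigs), min_block >= 1)
  if (inherits(reference, "genome_spec")) {
    ref_id <- reference$id
    reference <- reference$sequence
  }
  if (nchar(reference) < k)
    stop("reference shorter than the anchor k-mer size", call. = FALSE)
  ref_index <- .ref_kmer_positions(reference, k)
  refc <- strsplit(reference, "", fixed = TRUE)[[1L]]
  out <- list()
  for (ci in seq_len(nrow(contigs))) {
    cseq <- contigs$sequence[ci]
    clen <- nchar(cseq)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") cseq else revcomp(cseq)
      an <- .anchors(q, ref_index, k)
      if (nrow(an) == 0L) next
      an$diag <- an$rpos - an$qpos
      an <- an[order(an$diag, an$qpos), , drop = FALSE]
      grp <- cumsum(c(1L, diff(an$diag) > band))
      for (g in split(an, grp)) {
        g <- g[order(g$qpos), , drop = FALSE]
        sub <- cumsum(c(1L, diff(g$qpos) > max_gap))
        for (h in split(g, sub)) {
          qs <- min(h$qpos); qe <- max(h$qpos) + k
          if (qe - qs < min_block) next
          d <- stats::median(h$diag)
          rs <- qs + d; re <- qe + d
          if (rs < 0L || re > nchar(reference)) next
          qchars <- strsplit(substr(q, qs + 1L, qe), "", fixed = TRUE)[[1L]]
          ident <- mean(qchars == refc[(rs + 1L):re])
          cs <- if (strand == "+") qs else clen - qe
          ce <- if (strand == "+") qe else clen - qs
          out[[length(out) + 1L]] <- data.frame(
            contig_id = contigs$id[ci], ref_id = ref_id,
            contig_start = cs, contig_end = ce,
            ref_start = rs, ref_end = re,
            strand = strand, identity = ident, stringsAsFactors = FALSE)
        }
      }
    }
  }
  blocks <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(contig_id = character(0L), ref_id = character(0L),
               contig_start = integer(0L), contig_end = integer(0L),
               ref_start = integer(0L), ref_end = integer(0L),
               strand = character(0L), identity = numeric(0L),
               stringsAsFactors = FALSE)
  class(blocks) <- c("alignment_blocks", "data.frame")
  blocks
}

#' Classify contigs by uniqueness to one of two references
#'
#' The qualifying aligned span of a contig per reference is the summed
#' contig span of its blocks (or the largest single block in `"single"`
#' mode). A contig is `unique_A`/`unique_B` when its span on that reference
#' reaches `min_unique_span` and it has no qualifying block at all on the
#' other; `shared` when both references have blocks; `unaligned` when
#' neither does; and `sub_threshold` when it aligns to only one reference
#' but below the unique-span rule.
#'
#' @param blocks_a,blocks_b `alignment_blocks` against references A and B
#'   (already filtered to blocks of at least the minimum block length).
#' @param contig_ids ids of all contigs under classification (so unaligned
#'   contigs are reported too).
#' @param min_unique_span minimum summed span for a unique call (default
#'   10000).
#' @param mode `"sum"` (default) or `"single"` (strict single-block rule).
#' @return data frame of class `contig_classification`: `contig_id`,
#'   `span_a`, `span_b`, `label`.
#' @export
classify_contigs <- function(blocks_a, blocks_b, contig_ids,
                             min_unique_span = 10000, mode = c("sum", "single")) {
  mode <- match.arg(mode)
  span_of <- function(blocks) {
    if (nrow(blocks) == 0L)
      return(stats::setNames(numeric(0L), character(0L)))
    sp <- blocks$contig_end - blocks$contig_start
    if (mode == "sum") tapply(sp, blocks$contig_id, sum)
    else tapply(sp, blocks$contig_id, max)
  }
  sa <- span_of(blocks_a)
  sb <- span_of(blocks_b)
  span_a <- ifelse(contig_ids %in% names(sa), sa[contig_ids], 0)
  span_b <- ifelse(contig_ids %in% names(sb), sb[contig_ids], 0)
  label <- ifelse(span_a > 0 & span_b > 0, "shared",
           ifelse(span_a >= min_unique_span & span_b == 0, "unique_A",
           ifelse(span_b >= min_unique_span & span_a == 0, "unique_B",
           ifelse(span_a == 0 & span_b == 0, "unaligned", "sub_threshold"))))
  out <- data.frame(contig_id = contig_ids, span_a = unname(span_a),
                    span_b = unname(span_b), label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("contig_classification", "data.frame")
  out
}

#' Fraction of a reference covered by alignment blocks
#'
#' Union length of the merged reference intervals divided by the reference
#' length.
#'
#' @param blocks `alignment_blocks` on a single reference.
#' @param reference_length reference length in bp.
#' @return a real in `[0, 1]`.
#' @export
reference_coverage <- function(blocks, reference_length) {
  if (nrow(blocks) == 0L) return(0)
  if (any(blocks$ref_start < 0L) || any(blocks$ref_end > reference_length))
    stop("alignment block outside the reference", call. = FALSE)
  ir <- IRanges::IRanges(start = blocks$ref_start + 1L, end = blocks$ref_end)
  sum(IRanges::width(IRanges::reduce(ir))) / reference_length
}

#' Per-label histograms of contig k-mer coverage
#'
#' @param classification a `contig_classification`.
#' @param contigs data frame with `id` and `coverage` (assembler-reported
#'   k-mer coverage; contigs with missing coverage are excluded with a
#'   warning).
#' @param breaks histogram break points passed to [hist()] (default 20
#'   equal-width bins over the observed range).
#' @return data frame `label`, `bin_low`, `bin_high`, `count`; counts sum to
#'   the number of classified contigs with coverage metadata.
#' @export
coverage_histogram <- function(classification, contigs, breaks = 20) {
  stopifnot(is.data.frame(classification), is.data.frame(contigs))
  cov <- stats::setNames(contigs$coverage, contigs$id)[classification$contig_id]
  if (anyNA(cov)) {
    warning(sum(is.na(cov)), " contig(s) lack coverage metadata and are excluded",
            call. = FALSE)
  }
  keep <- !is.na(cov)
  cov <- cov[keep]
  lab <- classification$label[keep]
  if (length(cov) == 0L)
    return(data.frame(label = character(0L), bin_low = numeric(0L),
                      bin_high = numeric(0L), count = integer(0L)))
  h0 <- graphics::hist(cov, breaks = breaks, plot = FALSE)
  br <- h0$breaks
  out <- list()
  for (l in sort(unique(lab))) {
    cnt <- graphics::hist(cov[lab == l], breaks = br, plot = FALSE)$counts
    out[[l]] <- data.frame(label = l, bin_low = br[-length(br)],
                           bin_high = br[-1L], count = cnt,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read contigs from FASTA, parsing assembler coverage tokens
#'
#' Coverage is taken from SPAdes-style `_cov_<x>` header tokens, or from a
#' sidecar TSV (`id`, `coverage`).
#'
#' @param path contigs FASTA.
#' @param coverage_tsv optional sidecar TSV overriding header tokens.
#' @return data frame `id`, `sequence`, `coverage` (`NA` when unavailable).
#' @export
read_contigs <- function(path, coverage_tsv = NULL) {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  cov <- suppressWarnings(
    as.numeric(sub(".*_cov_([0-9.]+).*", "\\1", ids,
                   perl = TRUE)))
  cov[!grepl("_cov_", ids)] <- NA_real_
  df <- data.frame(id = ids, sequence = as.character(dss), coverage = cov,
                   stringsAsFactors = FALSE)
  if (!is.null(coverage_tsv)) {
    sc <- utils::read.delim(coverage_tsv)
    df$coverage <- sc$coverage[match(df$id, sc$id)]
  }
  df
}

#' Simulate a pair of references sharing an identical region, plus contigs
#'
#' Builds reference A = unique-A segment + shared segment and reference
#' B = shared segment + unique-B segment, then cuts contigs from the
#' unique-A, unique-B and shared regions or draws them as random sequence,
#' with lengths straddling the length- and unique-span thresholds and k-mer
#' coverage values drawn from two lognormal modes (emulating two organisms
#' co-assembled at different abundances).
#'
#' @param n_contigs total contigs (default 200).
#' @param unique_length length of each reference's unique segment (default
#'   60000).
#' @param shared_length length of the shared segment (default 15000).
#' @param divergence substitution divergence of each contig from its source
#'   region (default 0.01).
#' @param cov_meanlog two-mode lognormal meanlog for A- and B-derived contig
#'   coverage (default `c(log(30), log(8))`).
#' @param seed master seed.
#' @return list with `ref_a`, `ref_b` (`genome_spec`), and `contigs` (data
#'   frame `id`, `sequence`, `coverage`, `true_label` in
#'   `unique_A`/`unique_B`/`shared`/`unaligned`/`sub_threshold`/`filtered`).
#' @export
simulate_contig_set <- function(n_contigs = 200, unique_length = 60000,
                                shared_length = 15000, divergence = 0.01,
                                cov_meanlog = c(log(30), log(8)), seed = NULL) {
  ua <- generate_genome(unique_length, 0.5, seed = derive_seed(seed, 21L), id = "uA")
  ub <- generate_genome(unique_length, 0.5, seed = derive_seed(seed, 22L), id = "uB")
  sh <- generate_genome(shared_length, 0.5, seed = derive_seed(seed, 23L), id = "sh")
  ref_a <- genome_spec("refA", "taxonA", paste0(ua$sequence, sh$sequence))
  ref_b <- genome_spec("refB", "taxonB", paste0(sh$sequence, ub$sequence))
  set_seed_if(derive_seed(seed, 24L))
  # class layout: unique above span, unique below span (sub_threshold),
  # shared, unaligned, and a few below the 2 kb length filter
  classes <- sample(rep(c("unique_A", "unique_B", "shared", "unaligned",
                          "sub_threshold", "filtered"),
                        times = round(n_contigs * c(0.25, 0.25, 0.2, 0.15, 0.1, 0.05))))
  classes <- classes[seq_len(min(n_contigs, length(classes)))]
  while (length(classes) < n_contigs) classes <- c(classes, "shared")
  n <- length(classes)
  len <- integer(n); src <- character(n)
  for (i in seq_len(n)) {
    len[i] <- switch(classes[i],
      unique_A = , unique_B = sample(10500:12500, 1L),
      shared = sample(2500:6000, 1L),
      unaligned = sample(2500:8000, 1L),
      sub_threshold = sample(3000:6000, 1L),
      filtered = sample(500:1999, 1L))
    src[i] <- switch(classes[i],
      unique_A = "A", unique_B = "B", shared = "S",
      sub_threshold = sample(c("A", "B"), 1L),
      unaligned = "R", filtered = sample(c("A", "B", "S"), 1L))
  }
  seqs <- character(n); covs <- numeric(n)
  for (i in seq_len(n)) {
    if (src[i] == "R") {
      seqs[i] <- random_dna(len[i], 0.5)
      covs[i] <- stats::rlnorm(1L, log(15), 0.4)
      next
    }
    region <- switch(src[i], A = ua$sequence, B = ub$sequence, S = sh$sequence)
    start <- sample.int(nchar(region) - len[i] + 1L, 1L)
    s <- substr(region, start, start + len[i] - 1L)
    if (divergence > 0) {
      g <- genome_spec("tmp", sequence = s)
      s <- evolve_strain(g, divergence)$sequence
    }
    if (stats::runif(1L) < 0.5) s <- revcomp(s)
    seqs[i] <- s
    covs[i] <- stats::rlnorm(1L, if (src[i] == "B") cov_meanlog[2L] else cov_meanlog[1L], 0.25)
  }
  contigs <- data.frame(
    id = sprintf("contig%04d_cov_%0.2f", seq_len(n), covs),
    sequence = seqs, coverage = covs, true_label = classes,
    stringsAsFactors = FALSE)
  list(ref_a = ref_a, ref_b = ref_b, contigs = contigs)
}
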