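# Strain comparison at ascertained SNPs: haploid consensus genotyping of
# historical samples, SNP ascertainment in modern strains with a
# missing-to-reference merge policy, pairwise SNP identity, and PCA.

#' Haploid consensus genotype calls from a pileup
#'
#' Majority-rule consensus: the most frequent base is called when depth
#' reaches `min_depth` and the base's fraction reaches `majority_fraction`;
#' exact ties and everything else are missing.
#'
#' @param pileup data frame with columns `A`, `C`, `G`, `T` (per-site base
#'   counts from a sample's alignments).
#' @param min_depth minimum total depth (default 3).
#' @param majority_fraction minimum fraction of the leading base, in
#'   `(0.5, 1]` (default 0.7).
#' @return character vector of calls (`NA` = missing), one per pileup row.
#' @export
call_haploid_genotypes <- function(pileup, min_depth = 3, majority_fraction = 0.7) {
  stopifnot(is.data.frame(pileup), all(DNA_BASES %in% names(pileup)))
  if (min_depth < 1) stop("'min_depth' must be >= 1", call. = FALSE)
  if (majority_fraction <= 0.5 || majority_fraction > 1)
    stop("'majority_fraction' must lie in (0.5, 1]", call. = FALSE)
  m <- as.matrix(pileup[, DNA_BASES])
  depth <- rowSums(m)
  top <- max.col(m, ties.method = "first")
  top_count <- m[cbind(seq_len(nrow(m)), top)]
  tied <- rowSums(m == top_count) > 1L
  ok <- depth >= min_depth & !tied & top_count / pmax(depth, 1L) >= majority_fraction
  ifelse(ok, DNA_BASES[top], NA_character_)
}

#' Simulate a base-count pileup from a known sample sequence
#'
#' Per-site depths are Poisson and each sequenced base is mis-read to one of
#' the other three with probability `error_rate`; supports end-to-end testing
#' of the genotyping stage with known truth.
#'
#' @param sequence the sample's true sequence at the pileup sites.
#' @param mean_depth Poisson mean depth (default 10).
#' @param error_rate per-base error (default 0.005).
#' @param seed optional seed.
#' @return data frame with columns `A`, `C`, `G`, `T`.
#' @export
simulate_pileup <- function(sequence, mean_depth = 10, error_rate = 0.005,
                            seed = NULL) {
  set_seed_if(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  depth <- stats::rpois(n, mean_depth)
  out <- matrix(0L, n, 4L, dimnames = list(NULL, DNA_BASES))
  true_idx <- match(chars, DNA_BASES)
  for (i in seq_len(n)) {
    if (depth[i] == 0L) next
    err <- stats::rbinom(1L, depth[i], error_rate)
    out[i, true_idx[i]] <- depth[i] - err
    if (err > 0L) {
      wrong <- sample.int(3L, err, replace = TRUE)
      wrong_idx <- ((true_idx[i] - 1L + wrong) %% 4L) + 1L
      for (wi in wrong_idx) out[i, wi] <- out[i, wi] + 1L
    }
  }
  as.data.frame(out)
}

#' Derive per-sample allele calls at candidate sites from strain sequences
#'
#' Compares each strain sequence to the reference and returns the allele
#' matrix at every position where at least one strain differs.
#'
#' @param sequences named character vector of strain sequences, all the same
#'   length as `reference`.
#' @param reference reference sequence.
#' @return list with `positions` (1-based), `ref` (reference alleles) and
#'   `calls` (samples x sites character matrix).
#' @export
genotypes_from_sequences <- function(sequences, reference) {
  lens <- nchar(sequences)
  if (any(lens != nchar(reference)))
    stop("all sequences must match the reference length (substitutions only)",
         call. = FALSE)
  refc <- strsplit(reference, "", fixed = TRUE)[[1L]]
  mats <- vapply(sequences, function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                 character(nchar(reference)))
  diff_any <- rowSums(mats != refc) > 0L
  pos <- which(diff_any)
  list(positions = pos, ref = refc[pos],
       calls = t(mats[pos, , drop = FALSE]))
}

#' Ascertain biallelic SNPs from modern strain genotypes
#'
#' Applies the missing-to-reference merge policy (uncalled modern genotypes
#' are assumed to be reference calls), then keeps sites that segregate among
#' the modern samples with strictly two alleles (counting the reference
#' allele).
#'
#' @param calls samples x sites character matrix of modern-strain alleles
#'   (`NA` = missing); column order matches `ref`.
#' @param ref reference allele per site.
#' @param positions optional site positions (1-based) carried into the
#'   output.
#' @param missing_policy only `"ref"` is supported (the merge policy above).
#' @return an object of class `genotype_matrix`: `sites` (data frame with
#'   `position`, `ref`, `alt`) and `calls` (samples x ascertained-sites
#'   matrix, no missing values).
#' @export
ascertain_snps <- function(calls, ref, positions = seq_along(ref),
                           missing_policy = "ref") {
  stopifnot(is.matrix(calls), ncol(calls) == length(ref))
  if (nrow(calls) < 2L)
    stop("SNP ascertainment needs at least 2 modern samples", call. = FALSE)
  missing_policy <- match.arg(missing_policy)
  for (j in seq_len(ncol(calls))) calls[is.na(calls[, j]), j] <- ref[j]
  keep <- logical(ncol(calls))
  alt <- character(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    alleles <- unique(c(ref[j], calls[, j]))
    if (length(alleles) == 2L && any(calls[, j] != ref[j])) {
      keep[j] <- TRUE
      alt[j] <- setdiff(alleles, ref[j])
    }
  }
  structure(
    list(sites = data.frame(position = positions[keep], ref = ref[keep],
                            alt = alt[keep], stringsAsFactors = FALSE),
         calls = calls[, keep, drop = FALSE]),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d biallelic sites\n",
              nrow(x$calls), nrow(x$sites)))
  invisible(x)
}

#' Keep only sites with full information in all historical samples
#'
#' Appends the historical calls to the ascertained matrix and drops every
#' site at which any historical sample is missing, so the retained sites are
#' segregating in modern material and covered by read data in all historical
#' samples.
#'
#' @param gm a `genotype_matrix` of modern samples (from [ascertain_snps()]).
#' @param historical_calls samples x sites matrix of historical calls
#'   (`NA` = missing), with columns matching `gm$sites`.
#' @return a `genotype_matrix` whose `calls` stack modern then historical
#'   samples; zero retained sites trigger a warning.
#' @export
full_information_filter <- function(gm, historical_calls) {
  stopifnot(inherits(gm, "genotype_matrix"), is.matrix(historical_calls),
            ncol(historical_calls) == nrow(gm$sites))
  keep <- colSums(is.na(historical_calls)) == 0L
  if (!any(keep))
    warning("no site has full information across all historical samples",
            call. = FALSE)
  structure(
    list(sites = gm$sites[keep, , drop = FALSE],
         calls = rbind(gm$calls[, keep, drop = FALSE],
                       historical_calls[, keep, drop = FALSE])),
    class = "genotype_matrix"
  )
}

#' Pairwise SNP identity
#'
#' Fraction of ascertained sites at which two call vectors carry the same
#' allele.
#'
#' @param calls_a,calls_b equal-length character vectors over the same site
#'   set.
#' @return a real in `[0, 1]`.
#' @export
snp_identity <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b))
    stop("call vectors differ in length", call. = FALSE)
  if (length(calls_a) == 0L) stop("no sites to compare", call. = FALSE)
  mean(calls_a == calls_b)
}

#' All pairwise SNP identities of a genotype matrix
#'
#' @param gm a `genotype_matrix` (no missing calls).
#' @return symmetric samples x samples matrix with unit diagonal.
#' @export
snp_identity_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$calls)
  out <- matrix(1, n, n, dimnames = list(rownames(gm$calls), rownames(gm$calls)))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <- snp_identity(gm$calls[i, ], gm$calls[j, ])
  }
  out
}

#' Principal component analysis of a biallelic genotype matrix
#'
#' Sites are encoded 0 (reference allele) / 1 (alternative allele), columns
#' are centered and not scaled, and the eigendecomposition of the sample
#' covariance gives component coordinates and variance shares.
#'
#' @param gm a `genotype_matrix` with no missing calls.
#' @param n_components number of components to report (default 2, capped at
#'   the matrix rank).
#' @return an object of class `snp_pca`: `scores` (samples x components),
#'   `var_explained` (percentages) and `sdev`.
#' @export
snp_pca <- function(gm, n_components = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  enc <- matrix(0, nrow(gm$calls), ncol(gm$calls),
                dimnames = dimnames(gm$calls))
  for (j in seq_len(ncol(enc)))
    enc[, j] <- as.numeric(gm$calls[, j] == gm$sites$alt[j])
  if (all(apply(enc, 2L, function(v) length(unique(v)) == 1L)))
    stop("genotype matrix has no variance; PCA undefined", call. = FALSE)
  pc <- stats::prcomp(enc, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  var_share <- pc$sdev^2 / sum(pc$sdev^2) * 100
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 var_explained = var_share[seq_len(k)],
                 sdev = pc$sdev),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat(sprintf("<snp_pca> %d samples; PC1 %.1f%%, PC2 %s of variance\n",
              nrow(x$scores), x$var_explained[1L],
              if (length(x$var_explained) > 1L)
                sprintf("%.1f%%", x$var_explained[2L]) else "-"))
  invisible(x)
}

#' Read a minimal VCF-like genotype table
#'
#' Strict parser for the package's interchange format: a headered TSV with
#' columns `CHROM`, `POS` (1-based), `REF`, `ALT` and one column per sample
#' holding `0` (ref), `1` (alt) or `.` (missing).
#'
#' @param path file path.
#' @return list with `sites` (CHROM/POS/REF/ALT data frame) and `calls`
#'   (samples x sites character matrix of alleles, `NA` = missing).
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns CHROM, POS, REF, ALT, <samples>",
         call. = FALSE)
  samples <- setdiff(names(df), need)
  if (length(samples) == 0L) stop("no sample columns found", call. = FALSE)
  calls <- matrix(NA_character_, length(samples), nrow(df),
                  dimnames = list(samples, NULL))
  for (s in samples) {
    gt <- df[[s]]
    if (!all(gt %in% c("0", "1", ".")))
      stop("sample column '", s, "' contains values other than 0/1/.",
           call. = FALSE)
    calls[s, ] <- ifelse(gt == ".", NA_character_,
                         ifelse(gt == "0", df$REF, df$ALT))
  }
  list(sites = data.frame(CHROM = df$CHROM, POS = as.integer(df$POS),
                          REF = df$REF, ALT = df$ALT, stringsAsFactors = FALSE),
       calls = calls)
}

#' Simulate a two-cluster strain panel with historical samples
#'
#' Generates a reference genome, two diverged cluster ancestors, modern
#' strains within each cluster, and historical strains drawn from cluster 1.
#' Emulates strain-level population structure in which historical isolates
#' belong to one modern clade.
#'
#' @param genome_length reference length (default 20000).
#' @param n_modern modern strains per cluster (default 4).
#' @param n_historical historical strains, all from cluster 1 (default 2).
#' @param between_divergence cluster-ancestor divergence from the reference
#'   (default 0.02).
#' @param within_divergence strain divergence from its cluster ancestor
#'   (default 0.002).
#' @param seed master seed.
#' @return list with `reference` (string), `modern` (named vector of
#'   sequences), `historical` (named vector), `cluster` (named cluster id per
#'   modern strain).
#' @export
simulate_strain_panel <- function(genome_length = 20000, n_modern = 4,
                                  n_historical = 2,
                                  between_divergence = 0.02,
                                  within_divergence = 0.002, seed = NULL) {
  ref <- generate_genome(genome_length, 0.5, seed = derive_seed(seed, 11L),
                         id = "ref")
  anc1 <- evolve_strain(ref, between_divergence, seed = derive_seed(seed, 12L))
  anc2 <- evolve_strain(ref, between_divergence, seed = derive_seed(seed, 13L))
  modern <- character(0L); cluster <- character(0L)
  for (cl in 1:2) {
    anc <- if (cl == 1L) anc1 else anc2
    for (i in seq_len(n_modern)) {
      g <- evolve_strain(anc, within_divergence,
                         seed = derive_seed(seed, 100L * cl + i))
      nm <- sprintf("modern_c%d_%d", cl, i)
      modern[nm] <- g$sequence
      cluster[nm] <- paste0("cluster", cl)
    }
  }
  historical <- character(0L)
  for (i in seq_len(n_historical)) {
    g <- evolve_strain(anc1, within_divergence, seed = derive_seed(seed, 900L + i))
    historical[sprintf("historical_%d", i)] <- g$sequence
  }
  list(reference = ref$sequence, modern = modern, historical = historical,
       cluster = cluster)
}
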