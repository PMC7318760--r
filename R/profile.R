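#' Build an alignment table
#'
#' Gap-free aligned base pairs (read vs reference) in read orientation, the
#' unit consumed by [accumulate_profile()]. Reverse-strand alignments must be
#' reverse-complemented (both strings) before construction so positions count
#' from the sequenced 5' end; [read_alignments_sam()] and
#' [truth_alignments()] do this for you.
#'
#' @param read_id,ref_id identifiers.
#' @param read,ref equal-length strings over A/C/G/T/N (indels projected out).
#' @param strand `"+"` or `"-"` (informational).
#' @return a data frame of class `alignment_table`.
#' @export
alignment_table <- function(read_id, ref_id, read, ref, strand = "+") {
  if (any(nchar(read) != nchar(ref)))
    stop("paired read/reference strings must have equal length", call. = FALSE)
  if (any(grepl("[^ACGTN]", read)) || any(grepl("[^ACGTN]", ref)))
    stop("alignment strings may only contain A, C, G, T, N", call. = FALSE)
  structure(
    data.frame(read_id = read_id, ref_id = ref_id, read = read, ref = ref,
               strand = strand, stringsAsFactors = FALSE),
    class = c("alignment_table", "data.frame")
  )
}

#' Truth alignments of a simulated library
#'
#' Pairs each observed read with the reference bases it was sampled from
#' (the pre-damage fragment sequence in read orientation), i.e. a perfect,
#' mapper-free alignment.
#'
#' @param lib a `fractioned_library`, or its `molecules` data frame.
#' @param fraction optionally restrict to `"enriched"` or `"depleted"`.
#' @return an `alignment_table`.
#' @export
truth_alignments <- function(lib, fraction = NULL) {
  m <- if (inherits(lib, "fractioned_library")) lib$molecules else lib
  if (!is.null(fraction)) m <- m[m$fraction %in% fraction, , drop = FALSE]
  obs <- if (!is.null(m$seq_observed)) m$seq_observed else m$seq_damaged
  alignment_table(m$read_id, m$genome_id, obs, m$seq_original, m$strand)
}

# expand a CIGAR string into (op, len) pairs
.parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Read alignments from a SAM/BAM file
#'
#' Loads mapped records via Rsamtools, reconstructs the aligned reference
#' bases from the reference FASTA using each record's CIGAR (match columns
#' kept; insertions, deletions and clips projected out), and
#' reverse-complements reverse-strand records so that all pairs are in read
#' orientation.
#'
#' @param path SAM or BAM file.
#' @param reference named character vector of reference sequences, or a
#'   FASTA path readable by `Biostrings::readDNAStringSet`.
#' @param min_mapq minimum mapping quality (records below are dropped;
#'   `NA` MAPQ is kept).
#' @return an `alignment_table`.
#' @export
read_alignments_sam <- function(path, reference, min_mapq = 0) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM alignments", call. = FALSE)
  if (length(reference) == 1L && file.exists(reference)) {
    dss <- Biostrings::readDNAStringSet(reference)
    reference <- stats::setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- is.na(rec$mapq) | rec$mapq >= min_mapq
  n <- sum(keep)
  out_read <- out_ref <- out_id <- out_rn <- out_st <- character(n)
  j <- 0L
  for (i in which(keep)) {
    cg <- .parse_cigar(rec$cigar[i])
    qseq <- as.character(rec$seq[i])
    rname <- as.character(rec$rname[i])
    rseq <- reference[[rname]]
    qpos <- 1L; rpos <- rec$pos[i]
    qparts <- rparts <- character(0L)
    for (t in seq_along(cg$op)) {
      op <- cg$op[t]; len <- cg$len[t]
      if (op %in% c("M", "=", "X")) {
        qparts <- c(qparts, substr(qseq, qpos, qpos + len - 1L))
        rparts <- c(rparts, substr(rseq, rpos, rpos + len - 1L))
        qpos <- qpos + len; rpos <- rpos + len
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      } # H, P consume nothing
    }
    rd <- paste(qparts, collapse = ""); rf <- paste(rparts, collapse = "")
    strand <- if (bitwAnd(rec$flag[i], 16L) > 0L) "-" else "+"
    if (strand == "-") { rd <- revcomp(rd); rf <- revcomp(rf) }
    j <- j + 1L
    out_id[j] <- rec$qname[i]; out_rn[j] <- rname
    out_read[j] <- rd; out_ref[j] <- rf; out_st[j] <- strand
  }
  alignment_table(out_id, out_rn, out_read, out_ref, out_st)
}

#' Accumulate a position-specific substitution profile
#'
#' Counts, for each read position from the 5' end and from the 3' end, all
#' 16 ordered reference/read base pairs (the 12 off-diagonal cells are the
#' substitution types) together with opportunity counts (occurrences of each
#' reference base). N bases are excluded from both counts and opportunities.
#'
#' @param alignments an `alignment_table` (read orientation).
#' @param n_positions number of terminal positions to profile (default 25).
#' @return an object of class `substitution_profile`: list with `n_positions`,
#'   `n_alignments`, and for each end (`p5`, `p3`) a `counts` array of
#'   dimension `n_positions x 4(ref) x 4(read)` plus an `opportunities`
#'   matrix `n_positions x 4`.
#' @export
accumulate_profile <- function(alignments, n_positions = 25) {
  stopifnot(is.data.frame(alignments), n_positions >= 1)
  if (nrow(alignments) == 0L) stop("no alignments to profile", call. = FALSE)
  if (any(nchar(alignments$read) != nchar(alignments$ref)))
    stop("length-mismatched alignment pair", call. = FALSE)
  n_positions <- as.integer(n_positions)
  L <- nchar(alignments$read)
  mk <- function() list(
    counts = array(0L, dim = c(n_positions, 4L, 4L),
                   dimnames = list(NULL, DNA_BASES, DNA_BASES)),
    opportunities = matrix(0L, n_positions, 4L, dimnames = list(NULL, DNA_BASES)))
  p5 <- mk(); p3 <- mk()
  for (i in seq_len(n_positions)) {
    keep <- L >= i
    if (!any(keep)) break
    rf5 <- substr(alignments$ref[keep], i, i)
    rd5 <- substr(alignments$read[keep], i, i)
    ok <- rf5 %in% DNA_BASES & rd5 %in% DNA_BASES
    tab <- table(factor(rf5[ok], DNA_BASES), factor(rd5[ok], DNA_BASES))
    p5$counts[i, , ] <- p5$counts[i, , ] + tab
    p5$opportunities[i, ] <- p5$opportunities[i, ] + rowSums(tab)
    j <- L[keep] - i + 1L
    rf3 <- substr(alignments$ref[keep], j, j)
    rd3 <- substr(alignments$read[keep], j, j)
    ok <- rf3 %in% DNA_BASES & rd3 %in% DNA_BASES
    tab <- table(factor(rf3[ok], DNA_BASES), factor(rd3[ok], DNA_BASES))
    p3$counts[i, , ] <- p3$counts[i, , ] + tab
    p3$opportunities[i, ] <- p3$opportunities[i, ] + rowSums(tab)
  }
  structure(list(n_positions = n_positions, n_alignments = nrow(alignments),
                 p5 = p5, p3 = p3),
            class = "substitution_profile")
}

#' Element-wise sum of substitution profiles
#'
#' The profile of concatenated alignment sets equals the sum of their
#' profiles.
#'
#' @param ... `substitution_profile` objects with equal `n_positions`.
#' @return a `substitution_profile`.
#' @export
merge_profiles <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && !inherits(ps[[1L]], "substitution_profile")) ps <- ps[[1L]]
  stopifnot(length(ps) >= 1L,
            all(vapply(ps, inherits, logical(1L), "substitution_profile")))
  np <- unique(vapply(ps, `[[`, integer(1L), "n_positions"))
  if (length(np) != 1L) stop("profiles differ in n_positions", call. = FALSE)
  out <- ps[[1L]]
  for (p in ps[-1L]) {
    for (end in c("p5", "p3")) {
      out[[end]]$counts <- out[[end]]$counts + p[[end]]$counts
      out[[end]]$opportunities <- out[[end]]$opportunities + p[[end]]$opportunities
    }
    out$n_alignments <- out$n_alignments + p$n_alignments
  }
  out
}

#' @export
print.substitution_profile <- function(x, ...) {
  f <- ct_frequencies(x, "5p")
  cat(sprintf("<substitution_profile> %d alignments, %d positions; 5' C->T at pos 0: %s\n",
              x$n_alignments, x$n_positions,
              if (is.na(f[1L])) "NA" else sprintf("%.4f", f[1L])))
  invisible(x)
}

#' C->T substitution frequencies by position
#'
#' @param profile a `substitution_profile`.
#' @param end `"5p"` or `"3p"` (positions counted from that end, in read
#'   orientation).
#' @return numeric vector of length `n_positions`: counts(C->T)/opportunities(C);
#'   positions with zero C opportunities are `NA`, never 0.
#' @export
ct_frequencies <- function(profile, end = c("5p", "3p")) {
  stopifnot(inherits(profile, "substitution_profile"))
  end <- match.arg(end)
  e <- profile[[if (end == "5p") "p5" else "p3"]]
  opp <- unname(e$opportunities[, "C"])
  unname(ifelse(opp > 0L, e$counts[, "C", "T"] / opp, NA_real_))
}

#' Long-format table of all 12 substitution types
#'
#' @param profile a `substitution_profile`.
#' @return data frame with columns `end`, `position` (0-based), `ref`, `read`,
#'   `count`, `opportunities`, `frequency` (`NA` where undefined).
#' @export
substitution_table <- function(profile) {
  stopifnot(inherits(profile, "substitution_profile"))
  rows <- list()
  for (end in c("5p", "3p")) {
    e <- profile[[if (end == "5p") "p5" else "p3"]]
    for (rf in DNA_BASES) for (rd in setdiff(DNA_BASES, rf)) {
      opp <- e$opportunities[, rf]
      rows[[length(rows) + 1L]] <- data.frame(
        end = end, position = seq_len(profile$n_positions) - 1L,
        ref = rf, read = rd, count = e$counts[, rf, rd],
        opportunities = opp,
        frequency = ifelse(opp > 0L, e$counts[, rf, rd] / opp, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a 5' C->T frequency table
#'
#' Two-column table (`pos` 1-based, `5pC>T`), the shape of mapDamage's
#' `5pCtoT_freq.txt`. Undefined frequencies are written as `NA`.
#'
#' @param profile a `substitution_profile`.
#' @param path output file.
#' @param end which end to tabulate.
#' @export
write_ct_table <- function(profile, path, end = "5p") {
  f <- ct_frequencies(profile, end)
  df <- data.frame(pos = seq_along(f), freq = f)
  names(df)[2L] <- if (end == "5p") "5pC>T" else "3pC>T"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the exponential decay model to positional C->T frequencies
#'
#' Weighted least squares of
#' `p(i) = p_base + (p_term - p_base) * exp(-i / decay_len)` with weights
#' proportional to opportunity counts, within the parameter domains
#' (`p_term >= p_base`, both in `[0,1]`, `decay_len > 0`). Constant inputs are
#' degenerate: `p_term = p_base` and `decay_len` unidentifiable (`NA`).
#'
#' @param frequencies C->T frequencies by 0-based position (`NA` allowed).
#' @param opportunities C opportunity counts by position (weights).
#' @param n_boot number of bootstrap refits (binomial resampling of counts)
#'   for parameter standard errors; 0 skips the bootstrap.
#' @param seed optional seed for the bootstrap.
#' @return an object of class `decay_fit`: `p_term`, `p_base`, `decay_len`,
#'   `rss`, `se` (named, `NA` without bootstrap), `degenerate`.
#' @export
fit_decay_model <- function(frequencies, opportunities, n_boot = 0, seed = NULL) {
  ok <- !is.na(frequencies) & opportunities > 0
  if (sum(ok) < 4L)
    stop("need at least 4 defined positions to fit the decay model", call. = FALSE)
  i <- which(ok) - 1L
  f <- frequencies[ok]
  w <- opportunities[ok]
  if (diff(range(f)) < 1e-9) {
    return(structure(list(p_term = mean(f), p_base = mean(f), decay_len = NA_real_,
                          rss = 0, se = c(p_term = NA, p_base = NA, decay_len = NA),
                          degenerate = TRUE),
                     class = "decay_fit"))
  }
  fit1 <- function(fv, wv) {
    df <- data.frame(i = i, f = fv)
    # parameterize p_term = p_base + delta so p_term >= p_base is structural
    m <- minpack.lm::nlsLM(
      f ~ pb + delta * exp(-i / dl), data = df,
      start = list(pb = max(min(fv), 1e-4), delta = max(max(fv) - min(fv), 1e-4),
                   dl = 3),
      lower = c(pb = 0, delta = 0, dl = 1e-3),
      upper = c(pb = 1, delta = 1, dl = 1e4),
      weights = wv,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    c(p_term = unname(cf["pb"] + cf["delta"]), p_base = unname(cf["pb"]),
      decay_len = unname(cf["dl"]), rss = sum(stats::residuals(m)^2 * wv))
  }
  est <- tryCatch(fit1(f, w), error = function(e)
    stop("decay model fit failed: ", conditionMessage(e), call. = FALSE))
  se <- c(p_term = NA_real_, p_base = NA_real_, decay_len = NA_real_)
  if (n_boot > 0L) {
    set_seed_if(seed)
    boots <- matrix(NA_real_, n_boot, 3L)
    for (b in seq_len(n_boot)) {
      fb <- stats::rbinom(length(f), size = round(w), prob = pmin(pmax(f, 0), 1)) / round(w)
      bb <- tryCatch(fit1(fb, w), error = function(e) rep(NA_real_, 4L))
      boots[b, ] <- bb[1:3]
    }
    se <- apply(boots, 2L, stats::sd, na.rm = TRUE)
    names(se) <- c("p_term", "p_base", "decay_len")
  }
  structure(list(p_term = est[["p_term"]], p_base = est[["p_base"]],
                 decay_len = est[["decay_len"]], rss = est[["rss"]],
                 se = se, degenerate = FALSE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> p_term=%.4g p_base=%.4g decay_len=%s%s\n",
              x$p_term, x$p_base,
              if (is.na(x$decay_len)) "NA (unidentifiable)" else sprintf("%.4g", x$decay_len),
              if (x$degenerate) " [degenerate: constant frequencies]" else ""))
  invisible(x)
}

#' Fold amplification of the C->T frequency between two profiles
#'
#' Ratio of C->T frequencies (selected over unselected) at one read position;
#' the fraction-level readout of how strongly uracil selection magnifies the
#' terminal damage signal.
#'
#' @param profile_selected,profile_unselected `substitution_profile`s.
#' @param position 0-based read position (default 0).
#' @param end `"5p"` or `"3p"`.
#' @return a single numeric fold.
#' @export
amplification_fold <- function(profile_selected, profile_unselected,
                               position = 0, end = "5p") {
  fs <- ct_frequencies(profile_selected, end)[position + 1L]
  fu <- ct_frequencies(profile_unselected, end)[position + 1L]
  if (is.na(fs) || is.na(fu))
    stop("C->T frequency undefined at position ", position, call. = FALSE)
  if (fu == 0)
    stop("amplification fold undefined: unselected frequency is 0 at position ",
         position, call. = FALSE)
  fs / fu
}
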