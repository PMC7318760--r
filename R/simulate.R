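#' Position-dependent cytosine deamination model
#'
#' Post-mortem deamination converts cytosine to uracil, which is read as
#' thymine during sequencing. The per-site probability decays exponentially
#' with distance `i` from a molecule end:
#' `p(i) = p_base + (p_term - p_base) * exp(-i / decay_len)`.
#'
#' @param p_term deamination probability at the terminal base.
#' @param p_base interior plateau probability; must not exceed `p_term`.
#' @param decay_len exponential decay scale in bases (> 0).
#' @param symmetric_ends if `TRUE` (single-stranded library chemistry) C->T
#'   applies at both ends, with the smaller of the two end distances driving
#'   the probability. Ignored when `double_stranded = TRUE`.
#' @param double_stranded if `TRUE`, model a double-stranded library end
#'   pattern instead: C->T governed by 5' distance, G->A by 3' distance.
#' @return an object of class `damage_model`.
#' @examples
#' dm <- damage_model(p_term = 0.4, p_base = 0.01, decay_len = 3)
#' damage_prob(dm, 0:5)
#' @export
damage_model <- function(p_term = 0.3, p_base = 0.01, decay_len = 3,
                         symmetric_ends = TRUE, double_stranded = FALSE) {
  assert_prob(p_term, "p_term")
  assert_prob(p_base, "p_base")
  if (p_term < p_base) stop("'p_term' must be >= 'p_base'", call. = FALSE)
  if (!is.numeric(decay_len) || decay_len <= 0)
    stop("'decay_len' must be a positive number of bases", call. = FALSE)
  structure(
    list(p_term = p_term, p_base = p_base, decay_len = decay_len,
         symmetric_ends = isTRUE(symmetric_ends),
         double_stranded = isTRUE(double_stranded)),
    class = "damage_model"
  )
}

#' Per-site deamination probability at a distance from a molecule end
#'
#' @param model a `damage_model`.
#' @param dist non-negative distances (in bases) from the relevant end.
#' @return numeric vector of probabilities in `[p_base, p_term]`.
#' @export
damage_prob <- function(model, dist) {
  stopifnot(inherits(model, "damage_model"))
  model$p_base + (model$p_term - model$p_base) * exp(-dist / model$decay_len)
}

#' @export
print.damage_model <- function(x, ...) {
  cat(sprintf("<damage_model> p_term=%.3g p_base=%.3g decay_len=%.3g (%s)\n",
              x$p_term, x$p_base, x$decay_len,
              if (x$double_stranded) "double-stranded ends"
              else if (x$symmetric_ends) "symmetric ssDNA ends" else "5' end only"))
  invisible(x)
}

#' Uracil-selection fractionation model
#'
#' During uracil selection, library molecules are immobilised on beads:
#' molecules without uracils remain attached (U-depleted fraction) while
#' uracil-containing molecules are released into solution (U-enriched
#' fraction). Efficiencies below 1 model imperfect physical partitioning.
#'
#' @param release_efficiency probability that a uracil-containing molecule is
#'   released into the enriched fraction.
#' @param retention_efficiency probability that a uracil-free molecule stays
#'   in the depleted fraction.
#' @return an object of class `fractionation_model`.
#' @export
fractionation_model <- function(release_efficiency = 1, retention_efficiency = 1) {
  assert_prob(release_efficiency, "release_efficiency")
  assert_prob(retention_efficiency, "retention_efficiency")
  structure(list(release_efficiency = release_efficiency,
                 retention_efficiency = retention_efficiency),
            class = "fractionation_model")
}

#' Multi-taxon mixture specification
#'
#' @param ... one or more components built with [mix_component()].
#' @return an object of class `taxon_mix`.
#' @export
taxon_mix <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) && !inherits(comps[[1L]], "mix_component"))
    comps <- comps[[1L]]
  if (length(comps) == 0L) stop("a taxon_mix needs at least one component", call. = FALSE)
  if (!all(vapply(comps, inherits, logical(1L), "mix_component")))
    stop("all components must be built with mix_component()", call. = FALSE)
  w <- vapply(comps, `[[`, numeric(1L), "weight")
  if (any(w < 0) || sum(w) <= 0)
    stop("abundance weights must be non-negative and normalizable", call. = FALSE)
  structure(comps, class = "taxon_mix")
}

#' One taxon of a mixture
#'
#' @param genome a `genome_spec`.
#' @param weight non-negative abundance weight.
#' @param damage a `damage_model`; modern contaminants get
#'   `damage_model(0, 0)` (no deamination).
#' @return an object of class `mix_component`.
#' @export
mix_component <- function(genome, weight = 1,
                          damage = damage_model(p_term = 0, p_base = 0)) {
  stopifnot(inherits(genome, "genome_spec"), inherits(damage, "damage_model"))
  if (!is.numeric(weight) || weight < 0)
    stop("'weight' must be non-negative", call. = FALSE)
  structure(list(genome = genome, weight = weight, damage = damage),
            class = "mix_component")
}

#' Sample DNA fragments from a taxon mixture
#'
#' Draws molecules with taxa proportional to abundance weights, uniform start
#' coordinates, equiprobable strands, and lognormal lengths truncated at a
#' minimum. Coordinates are 0-based half-open on the source genome; sequences
#' are reported 5'->3' as sequenced.
#'
#' @param mix a `taxon_mix`.
#' @param n_molecules number of molecules (>= 1).
#' @param length_meanlog,length_sdlog lognormal parameters for fragment length.
#' @param min_length minimum molecule length in bp (default 30, the usual
#'   mapping cutoff for short ancient reads).
#' @param seed optional integer seed.
#' @return a data frame of pre-damage molecules with columns `read_id`,
#'   `taxon_id`, `genome_id`, `start`, `end`, `strand`, `seq_original`.
#' @export
sample_fragments <- function(mix, n_molecules,
                             length_meanlog = log(45), length_sdlog = 0.35,
                             min_length = 30, seed = NULL) {
  stopifnot(inherits(mix, "taxon_mix"))
  if (!is.numeric(n_molecules) || n_molecules < 1)
    stop("'n_molecules' must be >= 1", call. = FALSE)
  glens <- vapply(mix, function(cc) cc$genome$length, numeric(1L))
  if (min_length > max(glens))
    stop("'min_length' exceeds every genome length in the mix", call. = FALSE)
  set_seed_if(seed)
  n_molecules <- as.integer(n_molecules)
  w <- vapply(mix, `[[`, numeric(1L), "weight")
  comp <- sample.int(length(mix), n_molecules, replace = TRUE, prob = w / sum(w))
  glen <- glens[comp]
  # truncated lognormal lengths, also capped at the source genome length
  len <- pmin(round(stats::rlnorm(n_molecules, length_meanlog, length_sdlog)), glen)
  bad <- which(len < min_length)
  while (length(bad) > 0L) {
    len[bad] <- pmin(round(stats::rlnorm(length(bad), length_meanlog, length_sdlog)),
                     glen[bad])
    bad <- bad[len[bad] < min_length]
  }
  len <- as.integer(len)
  start <- as.integer(floor(stats::runif(n_molecules) * (glen - len + 1)))
  strand <- sample(c("+", "-"), n_molecules, replace = TRUE)
  seqs <- character(n_molecules)
  for (ci in seq_along(mix)) {
    rows <- which(comp == ci)
    if (length(rows) == 0L) next
    s <- substring(mix[[ci]]$genome$sequence, start[rows] + 1L, start[rows] + len[rows])
    minus <- strand[rows] == "-"
    if (any(minus)) s[minus] <- revcomp(s[minus])
    seqs[rows] <- s
  }
  data.frame(
    read_id = sprintf("read%07d", seq_len(n_molecules)),
    taxon_id = vapply(mix, function(cc) cc$genome$taxon_id, character(1L))[comp],
    genome_id = vapply(mix, function(cc) cc$genome$id, character(1L))[comp],
    start = start, end = start + len, strand = strand,
    seq_original = seqs,
    stringsAsFactors = FALSE
  )
}

#' Apply the deamination model to molecules
#'
#' Each cytosine is deaminated independently with the position-dependent
#' probability of the model; deaminated cytosines are read as thymines. The
#' set of deaminated offsets (0-based, read orientation) is recorded as the
#' truth mask and is never altered by downstream sequencing error.
#'
#' @param molecules data frame from [sample_fragments()] (or rows thereof).
#' @param model a `damage_model`.
#' @param seed optional integer seed.
#' @return the molecules with added columns `mask` (list of integer offsets),
#'   `n_deaminated` and `seq_damaged`.
#' @export
apply_deamination <- function(molecules, model, seed = NULL) {
  stopifnot(is.data.frame(molecules), inherits(model, "damage_model"))
  set_seed_if(seed)
  n <- nrow(molecules)
  ex <- explode_seqs(molecules$seq_original)
  dist5 <- ex$pos0
  dist3 <- ex$len - 1L - ex$pos0
  chars <- ex$chars
  if (model$double_stranded) {
    pC <- damage_prob(model, dist5)
    pG <- damage_prob(model, dist3)
    hitC <- chars == "C" & stats::runif(length(chars)) < pC
    hitG <- chars == "G" & stats::runif(length(chars)) < pG
    chars[hitC] <- "T"
    chars[hitG] <- "A"
    hit <- hitC | hitG
  } else {
    d <- if (model$symmetric_ends) pmin(dist5, dist3) else dist5
    p <- damage_prob(model, d)
    hit <- chars == "C" & stats::runif(length(chars)) < p
    chars[hit] <- "T"
  }
  mask <- split(ex$pos0[hit], factor(ex$mol[hit], levels = seq_len(n)))
  molecules$mask <- unname(mask)
  molecules$n_deaminated <- lengths(mask)
  molecules$seq_damaged <- rebuild_changed(molecules$seq_original, chars, ex$mol, hit)
  molecules
}

#' Partition molecules into U-enriched and U-depleted fractions
#'
#' A molecule carrying at least one deaminated site (a uracil) is released
#' into the enriched fraction with probability `release_efficiency`;
#' a uracil-free molecule stays in the depleted fraction with probability
#' `retention_efficiency`. Every molecule ends up in exactly one fraction.
#'
#' @param molecules data frame with an `n_deaminated` column (see
#'   [apply_deamination()]).
#' @param fractionation a `fractionation_model`.
#' @param seed optional integer seed.
#' @return the molecules with an added `fraction` column
#'   (`"enriched"`/`"depleted"`).
#' @export
partition_library <- function(molecules, fractionation = fractionation_model(),
                              seed = NULL) {
  stopifnot(is.data.frame(molecules), inherits(fractionation, "fractionation_model"))
  if (is.null(molecules$n_deaminated))
    stop("molecules must carry a deamination mask; run apply_deamination() first",
         call. = FALSE)
  set_seed_if(seed)
  has_u <- molecules$n_deaminated > 0L
  u <- stats::runif(nrow(molecules))
  enriched <- ifelse(has_u, u < fractionation$release_efficiency,
                     u >= fractionation$retention_efficiency)
  molecules$fraction <- ifelse(enriched, "enriched", "depleted")
  molecules
}

#' Add uniform sequencing error
#'
#' Each base of the damaged sequence is substituted, independently with
#' probability `error_rate`, by one of the three other bases uniformly.
#' Applied after deamination; the truth mask is left untouched, so the
#' depleted fraction of a simulation retains a small C->T error floor as in
#' real libraries.
#'
#' @param molecules data frame with `seq_damaged`.
#' @param error_rate per-base substitution probability in `[0, 0.1)`.
#' @param seed optional integer seed.
#' @return the molecules with an added/updated `seq_observed` column.
#' @export
add_sequencing_error <- function(molecules, error_rate = 0.001, seed = NULL) {
  stopifnot(is.data.frame(molecules))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.1)
    stop("'error_rate' must lie in [0, 0.1)", call. = FALSE)
  src <- if (!is.null(molecules$seq_damaged)) molecules$seq_damaged else molecules$seq_original
  if (error_rate == 0) {
    molecules$seq_observed <- src
    return(molecules)
  }
  set_seed_if(seed)
  ex <- explode_seqs(src)
  chars <- ex$chars
  hit <- stats::runif(length(chars)) < error_rate
  if (any(hit)) {
    base_idx <- match(chars[hit], DNA_BASES)
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    chars[hit] <- DNA_BASES[((base_idx - 1L + shift) %% 4L) + 1L]
  }
  molecules$seq_observed <- rebuild_changed(src, chars, ex$mol, hit)
  molecules
}

#' Simulation configuration
#'
#' @param mix a `taxon_mix`.
#' @param n_molecules total number of molecules to simulate.
#' @param fractionation a `fractionation_model`.
#' @param error_rate per-base sequencing error rate.
#' @param length_meanlog,length_sdlog,min_length fragment length distribution
#'   (lognormal, truncated at `min_length`).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(mix, n_molecules = 10000,
                       fractionation = fractionation_model(),
                       error_rate = 0.001,
                       length_meanlog = log(45), length_sdlog = 0.35,
                       min_length = 30) {
  stopifnot(inherits(mix, "taxon_mix"), inherits(fractionation, "fractionation_model"))
  structure(list(mix = mix, n_molecules = as.integer(n_molecules),
                 fractionation = fractionation, error_rate = error_rate,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 min_length = as.integer(min_length)),
            class = "sim_config")
}

#' Simulate a fractionated sequencing library in memory
#'
#' Composes fragment sampling, per-taxon deamination, uracil-based
#' partitioning and sequencing error. One master seed drives the whole
#' simulation through deterministically derived per-stage child seeds.
#'
#' @param config a `sim_config`.
#' @param seed integer master seed (optional but recommended).
#' @return an object of class `fractioned_library`: a list with `molecules`
#'   (data frame including truth columns), `config` and `seed`.
#' @export
simulate_library <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mol <- sample_fragments(config$mix, config$n_molecules,
                          config$length_meanlog, config$length_sdlog,
                          config$min_length, seed = derive_seed(seed, 1L))
  taxa <- vapply(config$mix, function(cc) cc$genome$taxon_id, character(1L))
  mol$mask <- vector("list", nrow(mol))
  mol$n_deaminated <- 0L
  mol$seq_damaged <- mol$seq_original
  for (ci in seq_along(config$mix)) {
    rows <- which(mol$taxon_id == taxa[ci])
    if (length(rows) == 0L) next
    sub <- apply_deamination(mol[rows, , drop = FALSE], config$mix[[ci]]$damage,
                             seed = derive_seed(seed, 100L + ci))
    mol$mask[rows] <- sub$mask
    mol$n_deaminated[rows] <- sub$n_deaminated
    mol$seq_damaged[rows] <- sub$seq_damaged
  }
  mol <- partition_library(mol, config$fractionation, seed = derive_seed(seed, 2L))
  mol <- add_sequencing_error(mol, config$error_rate, seed = derive_seed(seed, 3L))
  structure(list(molecules = mol, config = config, seed = seed),
            class = "fractioned_library")
}

#' @export
print.fractioned_library <- function(x, ...) {
  tab <- table(x$molecules$fraction)
  cat(sprintf("<fractioned_library> %d molecules (%d enriched / %d depleted), %d taxa\n",
              nrow(x$molecules),
              if ("enriched" %in% names(tab)) tab[["enriched"]] else 0L,
              if ("depleted" %in% names(tab)) tab[["depleted"]] else 0L,
              length(unique(x$molecules$taxon_id))))
  invisible(x)
}

#' Truth table of a simulated library
#'
#' @param lib a `fractioned_library`.
#' @return data frame with one record per molecule: `read_id`, `taxon_id`,
#'   `genome_id`, `start`, `end`, `strand`, `n_deaminated`, `mask` (comma
#'   separated 0-based offsets) and `fraction`.
#' @export
truth_table <- function(lib) {
  stopifnot(inherits(lib, "fractioned_library"))
  m <- lib$molecules
  data.frame(
    read_id = m$read_id, taxon_id = m$taxon_id, genome_id = m$genome_id,
    start = m$start, end = m$end, strand = m$strand,
    n_deaminated = m$n_deaminated,
    mask = vapply(m$mask, function(v) paste(v, collapse = ","), character(1L)),
    fraction = m$fraction,
    stringsAsFactors = FALSE
  )
}

#' Simulate a sample and write per-fraction read files plus ground truth
#'
#' Writes one FASTA/FASTQ file per fraction, a headered TSV truth table and a
#' flat `key=value` echo of the configuration. Read headers duplicate the
#' truth labels after a reserved `|` delimiter.
#'
#' @param config a `sim_config`.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param format `"fasta"` or `"fastq"` (constant quality "I").
#' @return (invisibly) the `fractioned_library`, with an attribute `files`
#'   naming the written paths.
#' @export
simulate_sample <- function(config, seed = NULL, out_dir, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  lib <- simulate_library(config, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- lib$molecules
  files <- character(0L)
  for (frac in c("enriched", "depleted")) {
    rows <- m[m$fraction == frac, , drop = FALSE]
    ids <- sprintf("%s|taxon=%s|ndeam=%d|frac=%s",
                   rows$read_id, rows$taxon_id, rows$n_deaminated, frac)
    path <- file.path(out_dir, sprintf("%s.%s", frac, format))
    dss <- Biostrings::DNAStringSet(rows$seq_observed)
    names(dss) <- ids
    if (format == "fasta") {
      Biostrings::writeXStringSet(dss, path, format = "fasta", width = 1000L)
    } else {
      qual <- Biostrings::BStringSet(strrep("I", nchar(rows$seq_observed)))
      Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
    }
    files <- c(files, path)
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth_table(lib), truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.txt")
  dm <- function(cc) sprintf("%s:%g,%g,%g", cc$genome$taxon_id,
                             cc$damage$p_term, cc$damage$p_base, cc$damage$decay_len)
  lines <- c(
    sprintf("n_molecules=%d", config$n_molecules),
    sprintf("error_rate=%g", config$error_rate),
    sprintf("length_meanlog=%g", config$length_meanlog),
    sprintf("length_sdlog=%g", config$length_sdlog),
    sprintf("min_length=%d", config$min_length),
    sprintf("release_efficiency=%g", config$fractionation$release_efficiency),
    sprintf("retention_efficiency=%g", config$fractionation$retention_efficiency),
    sprintf("taxa=%s", paste(vapply(config$mix, dm, character(1L)), collapse = ";")),
    sprintf("seed=%s", if (is.null(seed)) "NA" else as.character(seed)),
    sprintf("format=%s", format)
  )
  writeLines(lines, cfg_path)
  attr(lib, "files") <- c(files, truth_path, cfg_path)
  invisible(lib)
}
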