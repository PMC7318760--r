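# Analytic oracle for damage frequencies conditional on fraction membership.
#
# For a molecule whose C-bearing sites {i_j} have per-site deamination
# probabilities p(i_j), the probability of carrying at least one uracil is
# P_U = 1 - prod_j (1 - p(i_j)). Under fractionation efficiencies r (release)
# and s (retention), membership probabilities are
#   P(enriched) = P_U * r + (1 - P_U) * (1 - s)
#   P(depleted) = P_U * (1 - r) + (1 - P_U) * s
# and a deamination at site i (which implies a uracil) co-occurs with the
# enriched fraction with probability p(i) * r. The observed C->T frequency at
# read position i within a fraction is the ratio of these, aggregated over
# molecules weighted by their membership probability.

# per-base uracil-event probabilities for one molecule (read orientation)
.site_event_probs <- function(chars, len, model) {
  pos0 <- seq_len(len) - 1L
  d5 <- pos0
  d3 <- len - 1L - pos0
  ev <- numeric(len)
  if (model$double_stranded) {
    ev[chars == "C"] <- damage_prob(model, d5[chars == "C"])
    ev[chars == "G"] <- damage_prob(model, d3[chars == "G"])
  } else {
    d <- if (model$symmetric_ends) pmin(d5, d3) else d5
    ev[chars == "C"] <- damage_prob(model, d[chars == "C"])
  }
  ev
}

#' Expected conditional C->T frequency per fraction (exact)
#'
#' Computes, without simulation, the expected C->T substitution frequency at
#' given read positions among molecules of the U-enriched fraction, the
#' U-depleted fraction, or the unselected library, for an exact molecule set
#' (with its actual cytosine placements) or for a fragment-length
#' distribution with i.i.d. base composition. This is the independent oracle
#' against which Monte-Carlo damage profiles are checked, and the analytic
#' route to the fold-amplification that uracil selection produces.
#'
#' @param model a [damage_model()].
#' @param molecules data frame with a `seq_original` column (e.g. from
#'   [sample_fragments()]); exactly one of `molecules` and `length_dist` must
#'   be given.
#' @param length_dist data frame with columns `length` and `prob`
#'   (a fragment-length distribution to integrate over).
#' @param gc_fraction base composition used with `length_dist`
#'   (P(C) = P(G) = `gc_fraction`/2).
#' @param positions 0-based read positions (distance from the 5' end).
#' @param fraction which library to evaluate: `"enriched"`, `"depleted"` or
#'   `"unselected"`.
#' @param fractionation a [fractionation_model()].
#' @return numeric vector of expected frequencies, one per position; `NA`
#'   (with a warning) where the fraction has zero expected membership among
#'   molecules carrying a C at that position, e.g. for an undamaged model.
#' @examples
#' dm <- damage_model(p_term = 0.3, p_base = 0.1, decay_len = 1e9)
#' mol <- data.frame(seq_original = "CCAA")
#' # not run through the decay: explicit two-site enumeration gives 0.3/0.37
#' @export
expected_conditional_damage <- function(model, molecules = NULL,
                                        length_dist = NULL, gc_fraction = 0.5,
                                        positions = 0:9,
                                        fraction = c("enriched", "depleted", "unselected"),
                                        fractionation = fractionation_model()) {
  stopifnot(inherits(model, "damage_model"),
            inherits(fractionation, "fractionation_model"))
  fraction <- match.arg(fraction)
  if (is.null(molecules) == is.null(length_dist))
    stop("give exactly one of 'molecules' or 'length_dist'", call. = FALSE)
  r <- fractionation$release_efficiency
  s <- fractionation$retention_efficiency

  if (!is.null(molecules)) {
    seqs <- molecules$seq_original
    lens <- nchar(seqs)
    if (any(positions >= max(lens)))
      stop("a requested position lies beyond every molecule length", call. = FALSE)
    charl <- strsplit(seqs, "", fixed = TRUE)
    evl <- mapply(.site_event_probs, charl, lens,
                  MoreArgs = list(model = model), SIMPLIFY = FALSE)
    pu <- vapply(evl, function(e) 1 - prod(1 - e), numeric(1L))
    out <- numeric(length(positions))
    for (k in seq_along(positions)) {
      i <- positions[k]
      hasC <- lens > i & vapply(charl, function(ch) ch[i + 1L] == "C", logical(1L))
      if (!any(hasC)) { out[k] <- NA_real_; next }
      p_i <- vapply(evl[hasC], function(e) e[i + 1L], numeric(1L))
      out[k] <- switch(fraction,
        enriched   = .safe_ratio(sum(p_i * r),
                                 sum(pu[hasC] * r + (1 - pu[hasC]) * (1 - s))),
        depleted   = .safe_ratio(sum(p_i * (1 - r)),
                                 sum(pu[hasC] * (1 - r) + (1 - pu[hasC]) * s)),
        unselected = mean(p_i)
      )
    }
    return(out)
  }

  # length-distribution route: i.i.d. composition, P(C) = P(G) = gc/2
  stopifnot(is.data.frame(length_dist), all(c("length", "prob") %in% names(length_dist)))
  qc <- gc_fraction / 2
  L <- as.integer(length_dist$length)
  w <- length_dist$prob / sum(length_dist$prob)
  if (any(positions >= max(L)))
    stop("a requested position lies beyond every molecule length", call. = FALSE)
  out <- numeric(length(positions))
  for (k in seq_along(positions)) {
    i <- positions[k]
    keep <- which(L > i)
    num <- den <- 0
    for (j in keep) {
      len <- L[j]
      pos0 <- seq_len(len) - 1L
      d5 <- pos0; d3 <- len - 1L - pos0
      if (model$double_stranded) {
        e <- qc * damage_prob(model, d5) + qc * damage_prob(model, d3)
        p_i <- damage_prob(model, i)
      } else {
        d <- if (model$symmetric_ends) pmin(d5, d3) else d5
        e <- qc * damage_prob(model, d)
        p_i <- damage_prob(model, if (model$symmetric_ends) min(i, len - 1L - i) else i)
      }
      # condition on an actual C at position i
      pu_i <- 1 - (1 - p_i) * prod(1 - e[-(i + 1L)])
      num <- num + w[j] * switch(fraction,
        enriched = p_i * r, depleted = p_i * (1 - r), unselected = p_i)
      den <- den + w[j] * switch(fraction,
        enriched = pu_i * r + (1 - pu_i) * (1 - s),
        depleted = pu_i * (1 - r) + (1 - pu_i) * s,
        unselected = 1)
    }
    out[k] <- .safe_ratio(num, den)
  }
  out
}

.safe_ratio <- function(num, den) {
  if (den <= 0) {
    warning("conditional frequency undefined: fraction has zero expected membership",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Analytic fold-amplification of terminal damage by uracil selection
#'
#' Ratio of the expected C->T frequency at a read position in the U-enriched
#' fraction over the unselected library. Selection conditions on the molecule
#' carrying at least one uracil, so low-damage libraries are amplified most:
#' the fold approaches `1 / P(any uracil)` and shrinks towards 1 as damage
#' grows.
#'
#' @inheritParams expected_conditional_damage
#' @param position a single 0-based read position (default 0, the terminal
#'   base).
#' @return a single numeric fold; `NA` (with a warning) when undefined, e.g.
#'   for a fully undamaged model.
#' @export
conditional_fold <- function(model, molecules = NULL, length_dist = NULL,
                             gc_fraction = 0.5, position = 0,
                             fractionation = fractionation_model()) {
  enr <- expected_conditional_damage(model, molecules, length_dist, gc_fraction,
                                     positions = position, fraction = "enriched",
                                     fractionation = fractionation)
  uns <- expected_conditional_damage(model, molecules, length_dist, gc_fraction,
                                     positions = position, fraction = "unselected",
                                     fractionation = fractionation)
  if (is.na(enr) || is.na(uns) || uns == 0) {
    warning("amplification fold undefined for this model/molecule set", call. = FALSE)
    return(NA_real_)
  }
  enr / uns
}
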