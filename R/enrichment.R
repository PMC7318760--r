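#' Per-taxon relative enrichment between library fractions
#'
#' Normalizes each taxon's assigned-read count by the total assigned reads of
#' its fraction and reports the log2 ratio of the U-enriched over the
#' U-depleted proportion. Confidence intervals come from Jeffreys posterior
#' draws on each proportion (`Beta(x + 1/2, n - x + 1/2)`) propagated to the
#' log-ratio; when either taxon count is zero, a pseudocount of 0.5 is added
#' to both taxon counts (and 1 to each fraction total) for the point
#' estimate, keeping non-zero ratios exact.
#'
#' @param counts data frame with columns `taxon`, `enriched`, `depleted`
#'   (non-negative integer read counts per fraction).
#' @param total_enriched,total_depleted total assigned reads per fraction;
#'   default the column sums (appropriate when `counts` covers disjoint taxa
#'   such as the direct counts of phyla).
#' @param alpha two-sided CI level (default 0.05 for 95% intervals).
#' @param n_draws Monte-Carlo draws for the CI (default 1000).
#' @param pseudocount added to zero cells (default 0.5).
#' @param raw_counts if `TRUE`, skip the per-fraction normalization and use
#'   raw read counts (figure-parity mode for fractions of equal depth).
#' @return data frame of class `enrichment_result`: `taxon`, `prop_enriched`,
#'   `prop_depleted`, `log2_ratio`, `ci_lower`, `ci_upper`.
#' @examples
#' counts <- data.frame(taxon = c("a", "b"), enriched = c(200, 800),
#'                      depleted = c(100, 900))
#' relative_enrichment(counts, total_enriched = 1000, total_depleted = 1000)
#' @export
relative_enrichment <- function(counts, total_enriched = sum(counts$enriched),
                                total_depleted = sum(counts$depleted),
                                alpha = 0.05, n_draws = 1000,
                                pseudocount = 0.5, raw_counts = FALSE) {
  stopifnot(is.data.frame(counts),
            all(c("taxon", "enriched", "depleted") %in% names(counts)))
  if (total_enriched <= 0 || total_depleted <= 0)
    stop("both fraction totals must be > 0", call. = FALSE)
  if (any(counts$enriched > total_enriched) || any(counts$depleted > total_depleted))
    stop("taxon counts exceed fraction totals", call. = FALSE)
  ne <- if (raw_counts) 1 else total_enriched
  nd <- if (raw_counts) 1 else total_depleted
  xe <- counts$enriched
  xd <- counts$depleted
  zero <- xe == 0 | xd == 0
  pe <- ifelse(zero, (xe + pseudocount) / (ne + 2 * pseudocount), xe / ne)
  pd <- ifelse(zero, (xd + pseudocount) / (nd + 2 * pseudocount), xd / nd)
  ratio <- log2(pe / pd)
  lo <- hi <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    de <- stats::rbeta(n_draws, xe[i] + 0.5, total_enriched - xe[i] + 0.5)
    dd <- stats::rbeta(n_draws, xd[i] + 0.5, total_depleted - xd[i] + 0.5)
    if (raw_counts) { de <- de * total_enriched; dd <- dd * total_depleted }
    r <- log2(de / dd)
    q <- stats::quantile(r, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo[i] <- q[1L]; hi[i] <- q[2L]
  }
  out <- data.frame(taxon = counts$taxon,
                    prop_enriched = xe / total_enriched,
                    prop_depleted = xd / total_depleted,
                    log2_ratio = ratio, ci_lower = lo, ci_upper = hi,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Label taxa as ancient-like or recent-like
#'
#' A taxon is `ancient-like` when the lower CI bound of its log2 enrichment
#' ratio exceeds `threshold`, `recent-like` when the upper bound lies below
#' `-threshold`, and `ambiguous` otherwise.
#'
#' @param results an `enrichment_result` (CIs already computed at the desired
#'   alpha).
#' @param threshold log2-ratio magnitude a CI must clear (default 0.5).
#' @return the results with an added `label` column.
#' @export
classify_taxa <- function(results, threshold = 0.5) {
  stopifnot(inherits(results, "enrichment_result") ||
              all(c("ci_lower", "ci_upper") %in% names(results)))
  results$label <- ifelse(results$ci_lower > threshold, "ancient-like",
                   ifelse(results$ci_upper < -threshold, "recent-like",
                          "ambiguous"))
  results
}

#' Build fraction counts from two per-node summaries
#'
#' Joins the per-node count tables of the two fractions (see
#' [summarize_assignments()]) on node id, using cumulative counts.
#'
#' @param enriched_summary,depleted_summary data frames from
#'   [summarize_assignments()].
#' @param nodes optionally restrict to these node ids (e.g. the phyla of
#'   interest); defaults to all nodes present in either summary.
#' @return data frame with `taxon`, `enriched`, `depleted`.
#' @export
fraction_counts <- function(enriched_summary, depleted_summary, nodes = NULL) {
  if (is.null(nodes))
    nodes <- union(enriched_summary$node, depleted_summary$node)
  ge <- stats::setNames(enriched_summary$cumulative, enriched_summary$node)
  gd <- stats::setNames(depleted_summary$cumulative, depleted_summary$node)
  data.frame(taxon = nodes,
             enriched = ifelse(nodes %in% names(ge), ge[nodes], 0L),
             depleted = ifelse(nodes %in% names(gd), gd[nodes], 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
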