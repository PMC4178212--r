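#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' drawing `n` active reactions from a universe of `N` of which `K` belong to
#' the pathway, the chance of an overlap at least as large as the observed
#' `k`. Computed as a log-domain sum of `exp(lchoose(K,i) + lchoose(N-K,n-i)
#' - lchoose(N,n))` terms accumulated from the largest term for numerical
#' stability.
#'
#' @param N Universe size (integer).
#' @param K Pathway size within the universe.
#' @param n Number of active reactions drawn.
#' @param k Observed overlap.
#' @return `p_raw`, a probability in \[0, 1\].
#' @examples
#' hypergeometric_test(100, 10, 20, 8)
#' @export
hypergeometric_test <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L, length(k) == 1L)
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n); k <- as.integer(k)
  if (K > N || n > N || k > min(K, n) || any(c(N, K, n, k) < 0L)) {
    stop(sprintf("inconsistent counts: N=%d, K=%d, n=%d, k=%d", N, K, n, k),
         call. = FALSE)
  }
  if (k == 0L) return(1)
  i <- k:min(K, n)
  logt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logt)
  p <- exp(m) * sum(exp(logt - m))
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th order statistic by
#' `m / i`, enforces monotonicity from the largest rank down (cumulative
#' minimum), caps at 1, and returns the adjusted values in the input order.
#' Under this adjustment, declaring `p_adjusted <= alpha` controls the false
#' discovery rate at `alpha`.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.02, 0.8))
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Read a pathway membership table (TSV: pathway, reaction id)
#' @param path Path to a two-column tab-separated file, one
#'   pathway/reaction pair per line, with header `pathway`, `reaction`.
#' @return Data frame with columns `pathway`, `reaction`.
#' @export
read_pathway_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "reaction") %in% names(d)))
  d
}

#' @keywords internal
pathway_map_from_model <- function(model) {
  rx <- model$reactions
  keep <- nzchar(rx$pathway)
  data.frame(pathway = rx$pathway[keep], reaction = rx$id[keep],
             stringsAsFactors = FALSE)
}

#' Pathway over-representation among predicted-active reactions
#'
#' Tests each pathway for enrichment within the set of reactions classified
#' `active` (verdicts `undetermined` are read strictly and excluded). The
#' default universe is every reaction that belongs to at least one pathway
#' (pathway-less reactions, e.g. exchanges, can contribute to no pathway and
#' would only dilute the test); `universe = "all"` uses every classified
#' reaction instead. Raw p-values come from [hypergeometric_test()] and are
#' adjusted across all tested pathways with [bh_adjust()].
#'
#' @param calls `activity_calls` from [classify_activity()] (any data frame
#'   with `reaction` and `verdict` columns works).
#' @param pathway_map Data frame (`pathway`, `reaction`) or a
#'   [metabolic_model()] whose pathway labels are used.
#' @param alpha Significance threshold on the adjusted p-value (default 0.05).
#' @param universe `"annotated"` (default) or `"all"`.
#' @return Data frame sorted by `p_adjusted` (ties by `p_raw`, then pathway
#'   name): `pathway`, `N`, `K`, `n`, `k`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
enrich_pathways <- function(calls, pathway_map, alpha = 0.05,
                            universe = c("annotated", "all")) {
  universe <- match.arg(universe)
  stopifnot(all(c("reaction", "verdict") %in% names(calls)),
            alpha > 0, alpha < 1)
  if (inherits(pathway_map, "metabolic_model")) {
    pathway_map <- pathway_map_from_model(pathway_map)
  }
  stopifnot(all(c("pathway", "reaction") %in% names(pathway_map)))
  extra <- setdiff(pathway_map$reaction, calls$reaction)
  if (length(extra) > 0L) {
    stop(sprintf("pathway map references unclassified reactions: %s",
                 paste(utils::head(extra, 5L), collapse = ", ")), call. = FALSE)
  }
  univ <- if (universe == "annotated") unique(pathway_map$reaction) else calls$reaction
  active <- intersect(calls$reaction[calls$verdict == "active"], univ)
  N <- length(univ)
  n <- length(active)
  if (n == 0L) message("fluxcue: empty active set; all enrichment p-values are 1")
  pathways <- sort(unique(pathway_map$pathway))
  res <- do.call(rbind, lapply(pathways, function(pw) {
    members <- intersect(pathway_map$reaction[pathway_map$pathway == pw], univ)
    K <- length(members)
    k <- length(intersect(members, active))
    data.frame(pathway = pw, N = N, K = K, n = n, k = k,
               p_raw = hypergeometric_test(N, K, n, k),
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- bh_adjust(res$p_raw)
  res$significant <- res$p_adjusted <= alpha
  res[order(res$p_adjusted, res$p_raw, res$pathway), , drop = FALSE]
}

#' Cross-condition enrichment contrast
#'
#' Labels each pathway by where it reached significance: `"A_only"`,
#' `"B_only"`, `"both"`, or `"neither"`. Both inputs must cover the same
#' pathway set (same map, same alpha).
#'
#' @param results_a,results_b Outputs of [enrich_pathways()] for the two
#'   conditions.
#' @return Data frame: `pathway`, `significant_a`, `significant_b`, `status`.
#' @export
contrast_enrichment <- function(results_a, results_b) {
  if (!setequal(results_a$pathway, results_b$pathway)) {
    stop("contrast_enrichment: pathway sets differ between conditions", call. = FALSE)
  }
  b <- results_b[match(results_a$pathway, results_b$pathway), ]
  status <- ifelse(results_a$significant & b$significant, "both",
                   ifelse(results_a$significant, "A_only",
                          ifelse(b$significant, "B_only", "neither")))
  out <- data.frame(pathway = results_a$pathway,
                    significant_a = results_a$significant,
                    significant_b = b$significant,
                    status = status, stringsAsFactors = FALSE)
  out[order(out$pathway), , drop = FALSE]
}
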