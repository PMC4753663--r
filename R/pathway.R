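# Metabolite-set over-representation analysis (one-sided Fisher's exact /
# hypergeometric test, log-space) and pathway-topology impact (normalized
# out-degree centrality of the hit compounds).

#' Map query metabolites onto a pathway library's compound universe
#'
#' Case-insensitive exact match of query ids against the union of the
#' library's compound ids; duplicates collapse to one entry and unmapped
#' metabolites are returned, never silently dropped.
#'
#' @param query Character vector of metabolite/compound ids.
#' @param library A `pathway_library`.
#' @return List with `mapped` (canonical library ids) and `unmapped`
#'   (original query strings).
#' @export
map_compounds <- function(query, library) {
  stopifnot(inherits(library, "pathway_library"))
  ferm_assert(length(library$pathways) > 0, "empty pathway library")
  universe <- unique(unlist(lapply(library$pathways, `[[`, "compounds")))
  idx <- match(toupper(unique(query)), toupper(universe))
  list(mapped = universe[idx[!is.na(idx)]],
       unmapped = unique(query)[is.na(idx)])
}

#' One-sided over-representation p-value (Fisher's exact test)
#'
#' Upper-tail hypergeometric probability of observing `x` or more pathway
#' members in a query of size `n` drawn from a background of `N` compounds
#' of which `K` belong to the pathway:
#' `p = sum_{k = x}^{min(n, K)} C(K, k) C(N-K, n-k) / C(N, n)`,
#' accumulated in log-space for numerical stability.
#'
#' @param x Observed hits (0 <= x <= min(n, K)).
#' @param n Query size; `K` pathway size; `N` background size.
#' @param K,N See above.
#' @return p-value in (0, 1].
#' @export
ora_fisher <- function(x, n, K, N) {
  ferm_assert(all(c(x, n, K, N) >= 0) && n <= N && K <= N,
              "inconsistent counts: need n <= N and K <= N")
  ferm_assert(x <= min(n, K), "inconsistent counts: x > min(n, K)")
  ferm_assert(x >= max(0, n + K - N),
              "inconsistent counts: x below the minimum attainable overlap")
  ks <- seq.int(x, min(n, K))
  lt <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  min(exp(log_sum_exp(lt)), 1)
}

#' Pathway-topology impact of a hit set
#'
#' `impact = sum_{i in hits} c_i / sum_{i in pathway} c_i`, with `c_i` the
#' out-degree of compound `i` in the pathway's directed reaction graph
#' (alternative: relative betweenness). Compounds in the membership set but
#' absent from the edge list have centrality 0; a pathway whose total
#' centrality is 0 gets impact 0.
#'
#' @param pathway A single pathway entry (list with `compounds`, `edges`)
#'   or a `pathway_library` element.
#' @param hits Character vector of hit compound ids (subset of the
#'   pathway's compounds).
#' @param centrality `"out_degree"` (default) or `"betweenness"`.
#' @return Impact fraction in \\[0, 1\\].
#' @export
pathway_impact <- function(pathway, hits,
                           centrality = c("out_degree", "betweenness")) {
  centrality <- match.arg(centrality)
  compounds <- pathway$compounds
  ferm_assert(all(hits %in% compounds), "hits outside the pathway compounds")
  g <- igraph::graph_from_data_frame(pathway$edges, directed = TRUE,
                                     vertices = data.frame(name = compounds))
  cent <- switch(centrality,
                 out_degree = igraph::degree(g, mode = "out"),
                 betweenness = igraph::betweenness(g, directed = TRUE))
  total <- sum(cent)
  if (total == 0) return(0)
  sum(cent[hits]) / total
}

#' Over-representation + topology analysis of one metabolite set
#'
#' For every pathway sharing at least one compound with the query, computes
#' the hypergeometric enrichment p-value ([ora_fisher()]), `-log(p)` in the
#' configured base, the topology impact ([pathway_impact()]) and a
#' Benjamini-Hochberg FDR column (informational; the filter uses the raw
#' p, matching the `-log10(p) > 1`, i.e. `p < 0.1`, convention). Results
#' are sorted by p ascending, ties broken by impact descending then id.
#'
#' @param members Character vector: the metabolite set (one classification
#'   type, typically).
#' @param library A `pathway_library`.
#' @param background Character vector: the compound universe `N` (default:
#'   every compound in the library; conventionally the set of metabolites
#'   actually measured).
#' @param neglog_base Base of the `-log(p)` filter statistic (default 10).
#' @param neglog_threshold Filter cut on `-log(p)` (default 1).
#' @param centrality Passed to [pathway_impact()].
#' @return Data frame of class `pathway_enrichment` with one row per hit
#'   pathway: `pathway`, `name`, `x`, `n`, `K`, `N`, `p`, `neg_log_p`,
#'   `fdr`, `impact`, `passes_filter`; the surviving
#'   (pathway, metabolite) incidences are attached as
#'   `attr(, "incidence")`.
#' @export
enrich_type <- function(members, library, background = NULL,
                        neglog_base = 10, neglog_threshold = 1,
                        centrality = "out_degree") {
  stopifnot(inherits(library, "pathway_library"))
  ferm_assert(length(library$pathways) > 0, "empty pathway library")
  if (is.null(background)) {
    background <- unique(unlist(lapply(library$pathways, `[[`, "compounds")))
  }
  members <- unique(members)
  ferm_assert(all(members %in% background),
              "background must contain every (mapped) query member")
  N <- length(unique(background))
  n <- length(members)

  empty <- data.frame(pathway = character(0), name = character(0),
                      x = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), neg_log_p = numeric(0),
                      fdr = numeric(0), impact = numeric(0),
                      passes_filter = logical(0), stringsAsFactors = FALSE)
  if (n == 0) {
    warning("empty mapped query: no enrichment computed")
    attr(empty, "incidence") <- data.frame(pathway = character(0),
                                           metabolite = character(0))
    class(empty) <- c("pathway_enrichment", "data.frame")
    return(empty)
  }

  rows <- list(); hits_by_pw <- list()
  for (p_entry in library$pathways) {
    pw_compounds <- intersect(p_entry$compounds, background)
    K <- length(pw_compounds)
    hit <- intersect(members, pw_compounds)
    x <- length(hit)
    if (x == 0) next
    pval <- ora_fisher(x, n, K, N)
    rows[[p_entry$id]] <- data.frame(
      pathway = p_entry$id, name = p_entry$description,
      x = x, n = n, K = K, N = N, p = pval,
      neg_log_p = -log(pval, base = neglog_base),
      impact = pathway_impact(p_entry, hit, centrality),
      stringsAsFactors = FALSE)
    hits_by_pw[[p_entry$id]] <- hit
  }
  if (!length(rows)) {
    attr(empty, "incidence") <- data.frame(pathway = character(0),
                                           metabolite = character(0))
    class(empty) <- c("pathway_enrichment", "data.frame")
    return(empty)
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$passes_filter <- res$neg_log_p > neglog_threshold
  res <- res[order(res$p, -res$impact, res$pathway), ]
  rownames(res) <- NULL
  res <- res[, c("pathway", "name", "x", "n", "K", "N", "p", "neg_log_p",
                 "fdr", "impact", "passes_filter")]

  surv <- res$pathway[res$passes_filter]
  incidence <- if (length(surv)) {
    do.call(rbind, lapply(surv, function(id) {
      data.frame(pathway = id, metabolite = hits_by_pw[[id]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(pathway = character(0), metabolite = character(0),
               stringsAsFactors = FALSE)
  }
  attr(res, "incidence") <- incidence
  class(res) <- c("pathway_enrichment", "data.frame")
  res
}
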