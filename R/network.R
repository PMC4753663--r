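# Bipartite metabolite-pathway network assembly and ratio trajectories.

#' Assemble the bipartite metabolite-pathway network
#'
#' Merges the surviving (pathway, metabolite) incidences of one or more
#' enrichment results into a single bipartite graph. Metabolite nodes carry
#' their classification `type_code`; pathway nodes carry the best (smallest)
#' `p`, its `neg_log_p` and the `impact` from the enrichment rows. Nodes
#' are deduplicated across types; each metabolite keeps its single type
#' code.
#'
#' @param enrichments A `pathway_enrichment` or list of them (e.g. one per
#'   metabolite type).
#' @param typed Typed-metabolite table from [classify_metabolites()].
#' @return An [igraph] graph with vertex attributes `kind`
#'   ("metabolite"/"pathway"), `type` (logical bipartite marker: TRUE for
#'   pathway nodes), `type_code`, `p`, `neg_log_p`, `impact`.
#' @export
build_network <- function(enrichments, typed) {
  if (inherits(enrichments, "pathway_enrichment")) {
    enrichments <- list(enrichments)
  }
  inc <- do.call(rbind, lapply(enrichments, attr, "incidence"))
  res <- do.call(rbind, lapply(enrichments, function(e) {
    as.data.frame(e)[, c("pathway", "p", "neg_log_p", "impact")]
  }))
  if (is.null(inc) || nrow(inc) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  unknown <- setdiff(inc$metabolite, typed$metabolite)
  ferm_assert(length(unknown) == 0,
              sprintf("incidence references untyped metabolite(s): %s",
                      paste(unknown, collapse = ", ")))
  inc <- unique(inc)

  met_nodes <- unique(inc$metabolite)
  pw_nodes <- unique(inc$pathway)
  # per-pathway summary: smallest p across the contributing type queries
  res <- res[res$pathway %in% pw_nodes, , drop = FALSE]
  res <- res[order(res$p), ]
  res <- res[!duplicated(res$pathway), ]
  res <- res[match(pw_nodes, res$pathway), ]

  vertices <- data.frame(
    name = c(met_nodes, pw_nodes),
    kind = c(rep("metabolite", length(met_nodes)),
             rep("pathway", length(pw_nodes))),
    type = c(rep(FALSE, length(met_nodes)), rep(TRUE, length(pw_nodes))),
    type_code = c(typed$type_code[match(met_nodes, typed$metabolite)],
                  rep(NA_character_, length(pw_nodes))),
    p = c(rep(NA_real_, length(met_nodes)), res$p),
    neg_log_p = c(rep(NA_real_, length(met_nodes)), res$neg_log_p),
    impact = c(rep(NA_real_, length(met_nodes)), res$impact),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    data.frame(from = inc$metabolite, to = inc$pathway),
    directed = FALSE, vertices = vertices)
}

#' Write / read the network as GraphML and an edge-list TSV
#'
#' @param graph Graph from [build_network()].
#' @param graphml,edges_tsv Output paths (either may be `NULL` to skip).
#' @return Paths invisibly.
#' @export
write_network <- function(graph, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml)) igraph::write_graph(graph, graphml,
                                             format = "graphml")
  if (!is.null(edges_tsv)) {
    e <- igraph::as_data_frame(graph, what = "edges")
    names(e)[1:2] <- c("metabolite", "pathway")
    write_tsv_table(e, edges_tsv)
  }
  invisible(c(graphml = graphml, edges_tsv = edges_tsv))
}

#' Ratio trajectories of closely related metabolite pairs
#'
#' For each (numerator, denominator) pair, computes per sampling time the
#' ratio of replicate-mean relative abundances. Display values follow the
#' conventional rounding: integers for ratios >= 10, three decimals below.
#' A zero denominator mean yields `NA` with a diagnostic warning.
#'
#' @param a_r Relative-abundance table ([relative_abundance()] output).
#' @param pairs Data frame with columns `numerator`, `denominator`
#'   (metabolite column names).
#' @return Data frame: `numerator`, `denominator`, `time_h`, `ratio`,
#'   `display`.
#' @export
ratio_trajectories <- function(a_r, pairs) {
  ferm_assert(all(c("numerator", "denominator") %in% names(pairs)),
              "pairs needs numerator and denominator columns")
  missing <- setdiff(unique(c(pairs$numerator, pairs$denominator)),
                     names(a_r))
  ferm_assert(length(missing) == 0,
              sprintf("metabolite(s) absent from the table: %s",
                      paste(missing, collapse = ", ")))
  times <- sort(unique(a_r$time_h))
  mean_at <- function(col) {
    vapply(times, function(tt) mean(a_r[[col]][a_r$time_h == tt]),
           numeric(1))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    num <- mean_at(pairs$numerator[i])
    den <- mean_at(pairs$denominator[i])
    r <- ifelse(den > 0, num / den, NA_real_)
    if (anyNA(r)) {
      warning(sprintf("zero denominator mean for %s at t = %s h",
                      pairs$denominator[i],
                      paste(times[is.na(r)], collapse = ", ")))
    }
    data.frame(numerator = pairs$numerator[i],
               denominator = pairs$denominator[i],
               time_h = times, ratio = r,
               display = ifelse(is.na(r), NA_character_,
                                ifelse(r >= 10, sprintf("%.0f", r),
                                       sprintf("%.3f", r))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
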