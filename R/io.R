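# GMT (named compound sets) and SIF (directed edge lists) readers/writers.
# Both are plain line-oriented text formats; the SIF "relation" field is used
# to tag each edge with its pathway id so one file serializes a whole library.

#' Write / read a pathway library as GMT + SIF
#'
#' A pathway library couples, per pathway, a compound membership set with a
#' directed graph on those compounds (reaction adjacency). Membership is
#' serialized as GMT (`id <TAB> description <TAB> member...`), edges as SIF
#' (`source <TAB> pathway-id <TAB> target`). The pair round-trips losslessly
#' up to set/edge-set equality.
#'
#' @param library A `pathway_library` object (see [make_pathway_library()]).
#' @param gmt,sif File paths.
#' @return `write_pathway_library` returns the paths invisibly;
#'   `read_pathway_library` returns a `pathway_library`.
#' @export
write_pathway_library <- function(library, gmt, sif) {
  stopifnot(inherits(library, "pathway_library"))
  gmt_lines <- vapply(library$pathways, function(p) {
    paste(c(p$id, p$description, p$compounds), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, gmt)
  edges <- do.call(rbind, lapply(library$pathways, function(p) {
    if (nrow(p$edges) == 0L) return(NULL)
    data.frame(from = p$edges$from, relation = p$id, to = p$edges$to,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    writeLines(character(0), sif)
  } else {
    utils::write.table(edges, sif, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(gmt = gmt, sif = sif))
}

#' @rdname write_pathway_library
#' @export
read_pathway_library <- function(gmt, sif) {
  lines <- readLines(gmt)
  lines <- lines[nzchar(lines)]
  ferm_assert(length(lines) > 0, "empty GMT file")
  sif_lines <- readLines(sif)
  sif_lines <- sif_lines[nzchar(sif_lines)]
  edges_all <- if (length(sif_lines)) {
    parts <- strsplit(sif_lines, "\t", fixed = TRUE)
    ferm_assert(all(lengths(parts) == 3L), "SIF lines must have 3 fields")
    data.frame(from = vapply(parts, `[`, "", 1L),
               relation = vapply(parts, `[`, "", 2L),
               to = vapply(parts, `[`, "", 3L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), relation = character(0),
               to = character(0), stringsAsFactors = FALSE)
  }
  pathways <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    ferm_assert(length(f) >= 3L, "GMT lines need id, description, >=1 member")
    id <- f[[1]]
    e <- edges_all[edges_all$relation == id, c("from", "to"), drop = FALSE]
    rownames(e) <- NULL
    list(id = id, description = f[[2]], compounds = unique(f[-(1:2)]),
         edges = e)
  })
  names(pathways) <- vapply(pathways, `[[`, "", "id")
  ferm_assert(!anyDuplicated(names(pathways)), "duplicate pathway ids in GMT")
  new_pathway_library(pathways)
}

new_pathway_library <- function(pathways) {
  for (p in pathways) {
    nodes <- unique(c(p$edges$from, p$edges$to))
    ferm_assert(all(nodes %in% p$compounds),
                sprintf("pathway %s: graph nodes outside compound set", p$id))
  }
  structure(list(pathways = pathways), class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  sizes <- vapply(x$pathways, function(p) length(p$compounds), integer(1))
  cat(sprintf("pathway_library: %d pathways, sizes %d-%d\n",
              length(x$pathways), min(sizes), max(sizes)))
  invisible(x)
}
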