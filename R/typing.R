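# Nine-type metabolite classification from per-response VIP and coefficient
# values. VIP has priority over the coefficient: the coefficient sign is
# consulted only for a response whose VIP exceeds the threshold. Labels and
# the two-character network codes (growth slot first, butanol slot second;
# "*" = not significant):
#
#   A  VIPb<=1          VIPg<=1            "**"
#   B  VIPb>1,Coeffb<0  VIPg<=1            "*-"
#   C  VIPb>1,Coeffb>0  VIPg<=1            "*+"
#   D  VIPb>1,Coeffb<0  VIPg>1,Coeffg>0    "+-"
#   E  VIPb<=1          VIPg>1,Coeffg>0    "+*"
#   F  VIPb<=1          VIPg>1,Coeffg<0    "-*"
#   G  VIPb>1,Coeffb>0  VIPg>1,Coeffg<0    "-+"
#   H  VIPb>1,Coeffb>0  VIPg>1,Coeffg>0    "++"
#   I  VIPb>1,Coeffb<0  VIPg>1,Coeffg<0    "--"

TYPE_CODES <- c(A = "**", B = "*-", C = "*+", D = "+-", E = "+*",
                F = "-*", G = "-+", H = "++", I = "--")

#' Classify metabolites into the nine VIP/coefficient types
#'
#' Each metabolite carries a VIP and an autoscaled PLS coefficient for the
#' butanol-production response (`VIPb`, `Coeffb`) and for the growth
#' response (`VIPg`, `Coeffg`). A response is significant when its VIP
#' strictly exceeds `vip_threshold` (a VIP exactly equal to the threshold
#' counts as not significant). The sign of the coefficient is read only for
#' significant responses, giving the nine mutually exclusive, jointly
#' exhaustive types listed above.
#'
#' Boundary handling: a coefficient exactly 0 on a significant response
#' cannot be signed by the rule table; it inherits the sign of the other
#' response's coefficient (positive if that is also 0) and the record is
#' flagged `ambiguous`. Non-finite scores yield `type_label = NA`
#' (`unclassified`), reported via a warning, never silently dropped.
#'
#' @param scores Data frame with columns `metabolite`, `VIPb`, `Coeffb`,
#'   `VIPg`, `Coeffg` (extra columns are carried through).
#' @param vip_threshold Significance cut on VIP (default 1.0).
#' @return The input with `type_label`, `type_code`, `ambiguous`,
#'   `unclassified` columns appended.
#' @export
classify_metabolites <- function(scores, vip_threshold = 1.0) {
  need <- c("metabolite", "VIPb", "Coeffb", "VIPg", "Coeffg")
  ferm_assert(all(need %in% names(scores)),
              paste("scores needs columns:", paste(need, collapse = ", ")))
  n <- nrow(scores)
  label <- character(n)
  ambiguous <- logical(n)
  unclassified <- logical(n)
  for (i in seq_len(n)) {
    v <- scores[i, c("VIPb", "Coeffb", "VIPg", "Coeffg")]
    if (!all(is.finite(as.numeric(v)))) {
      label[i] <- NA_character_
      unclassified[i] <- TRUE
      next
    }
    sig_b <- scores$VIPb[i] > vip_threshold
    sig_g <- scores$VIPg[i] > vip_threshold
    signed <- function(x, other) {
      if (x > 0) "+" else if (x < 0) "-" else {
        ambiguous[i] <<- TRUE
        if (other > 0 || other == 0) "+" else "-"
      }
    }
    sb <- if (sig_b) signed(scores$Coeffb[i], scores$Coeffg[i]) else "*"
    sg <- if (sig_g) signed(scores$Coeffg[i], scores$Coeffb[i]) else "*"
    label[i] <- switch(paste0(sg, sb),
                       "**" = "A", "*-" = "B", "*+" = "C", "+-" = "D",
                       "+*" = "E", "-*" = "F", "-+" = "G", "++" = "H",
                       "--" = "I")
  }
  if (any(unclassified)) {
    warning(sprintf("unclassified (non-finite scores): %s",
                    paste(scores$metabolite[unclassified], collapse = ", ")))
  }
  out <- scores
  out$type_label <- label
  out$type_code <- ifelse(is.na(label), NA_character_, TYPE_CODES[label])
  out$ambiguous <- ambiguous
  out$unclassified <- unclassified
  out
}

#' Network code for a type label
#'
#' Maps a type label A..I to its two-character code (growth slot then
#' butanol slot; `*` = VIP below threshold, otherwise the coefficient
#' sign), e.g. `A -> "**"`, `D -> "+-"`, `H -> "++"`.
#'
#' @param type_label Character vector of labels in `A`..`I`.
#' @return Character vector of codes.
#' @export
type_code <- function(type_label) {
  ferm_assert(all(type_label %in% names(TYPE_CODES)),
              sprintf("unknown type label(s): %s",
                      paste(setdiff(type_label, names(TYPE_CODES)),
                            collapse = ", ")))
  unname(TYPE_CODES[type_label])
}
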