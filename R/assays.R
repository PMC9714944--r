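#' RCCX assay identifiers
#'
#' The seven duplex qPCR assays covering the genetic elements of the RCCX
#' copy number variation: the two C4 paralogs, the two CYP21 paralogs, the
#' HERV-K(C4) deletion and insertion alleles, and the RCCX segment
#' breakpoint ("BP"). Each assay co-amplifies the RPPH1 internal reference
#' gene on a second channel.
#'
#' @return Character vector of the seven assay identifiers.
#' @export
rccx_assays <- function() {
  c("C4A", "C4B", "CYP21A1P", "CYP21A2", "HERV_del", "HERV_ins", "BP")
}

#' Paralogous assay pairs of the RCCX region
#'
#' Groups the allele-specific assays into the three paralog pairs whose
#' integer GCNs must sum to the total RCCX segment count. The breakpoint
#' assay is not part of a pair; its GCN equals total segments minus 2.
#'
#' @return Named list of length 3, each a character vector of two assay ids.
#' @export
rccx_pairs <- function() {
  list(
    C4    = c("C4A", "C4B"),
    CYP21 = c("CYP21A1P", "CYP21A2"),
    HERV  = c("HERV_del", "HERV_ins")
  )
}

#' Assay configuration
#'
#' Holds per-assay calibration offsets (cycles, applied in Cq space), the
#' ambiguity half-width on the measured-GCN axis, and the reference gene
#' name. The misclassification boundary is `1 - ambiguity_halfwidth` by
#' construction: a measured GCN farther than the half-width from every
#' integer is ambiguous, and one within the half-width of a wrong integer
#' is misclassified.
#'
#' @param offsets Named numeric vector of calibration offsets in cycles,
#'   one per assay; missing assays default to 0.
#' @param ambiguity_halfwidth Half-width of the unambiguous window around
#'   each integer GCN, in GCN units. Default 0.3 (boundary inclusive).
#' @param reference_gene Name of the internal reference gene.
#' @return Object of class `rccx_assay_config`.
#' @export
assay_config <- function(offsets = NULL, ambiguity_halfwidth = 0.3,
                         reference_gene = "RPPH1") {
  stopifnot(is.numeric(ambiguity_halfwidth), length(ambiguity_halfwidth) == 1,
            ambiguity_halfwidth > 0, ambiguity_halfwidth < 0.5)
  full <- setNames(numeric(length(rccx_assays())), rccx_assays())
  if (!is.null(offsets)) {
    if (is.null(names(offsets)) || !all(names(offsets) %in% rccx_assays()))
      stop("`offsets` must be named by assay id: ",
           paste(rccx_assays(), collapse = ", "))
    full[names(offsets)] <- offsets
  }
  structure(
    list(offsets = full,
         ambiguity_halfwidth = ambiguity_halfwidth,
         misclass_boundary = 1 - ambiguity_halfwidth,
         reference_gene = reference_gene),
    class = "rccx_assay_config")
}

#' @export
print.rccx_assay_config <- function(x, ...) {
  cat("RCCX assay configuration\n")
  cat("  reference gene:", x$reference_gene, "\n")
  cat("  ambiguity half-width:", x$ambiguity_halfwidth,
      "(misclassification boundary", x$misclass_boundary, ")\n")
  cat("  offsets (cycles):\n")
  print(round(x$offsets, 4))
  invisible(x)
}

# internal: validate an assay id vector against the known set
check_assay_ids <- function(ids) {
  bad <- setdiff(unique(as.character(ids)), rccx_assays())
  if (length(bad))
    stop("unknown assay id(s): ", paste(bad, collapse = ", "),
         "; known assays: ", paste(rccx_assays(), collapse = ", "))
  invisible(TRUE)
}
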