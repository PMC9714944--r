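#' Construct an RCCX haplotype
#'
#' An RCCX haplotype is an ordered run of 1-4 tandem segments on one
#' chromosome; every segment carries one C4 gene (C4A or C4B), one CYP21
#' gene (the CYP21A2 functional gene or the CYP21A1P pseudogene) and either
#' the insertion or the deletion allele of the HERV-K(C4) retrovirus in C4
#' intron 9. The breakpoint count of a haplotype is its segment count
#' minus 1.
#'
#' @param c4 Character vector, one element per segment, values "A" or "B".
#' @param cyp21 Character vector, values "A1P" or "A2".
#' @param herv Character vector, values "insertion" or "deletion".
#' @return Object of class `rccx_haplotype`: a data.frame with one row per
#'   segment and columns `c4`, `cyp21`, `herv`.
#' @examples
#' bimodular <- rccx_haplotype(c("A", "B"), c("A1P", "A2"),
#'                             c("insertion", "deletion"))
#' @export
rccx_haplotype <- function(c4, cyp21, herv) {
  n <- length(c4)
  if (n < 1 || n > 4)
    stop("a haplotype has 1 to 4 segments, got ", n)
  if (length(cyp21) != n || length(herv) != n)
    stop("`c4`, `cyp21` and `herv` must have one element per segment")
  stopifnot(all(c4 %in% c("A", "B")),
            all(cyp21 %in% c("A1P", "A2")),
            all(herv %in% c("insertion", "deletion")))
  structure(data.frame(c4 = c4, cyp21 = cyp21, herv = herv,
                       stringsAsFactors = FALSE),
            class = c("rccx_haplotype", "data.frame"))
}

#' Diploid RCCX genotype from two haplotypes
#'
#' Derives the seven integer locus GCNs from an ordered pair of haplotypes.
#' By construction the four totals are equal: C4A + C4B, CYP21A1P +
#' CYP21A2, HERV deletion + insertion, and breakpoint count + 2 all equal
#' the total number of RCCX segments in the diploid genome.
#'
#' @param hap1,hap2 `rccx_haplotype` objects.
#' @return Object of class `rccx_genotype`: list with `hap1`, `hap2`,
#'   integer vector `gcn` named by assay id, and `total`.
#' @export
rccx_genotype <- function(hap1, hap2) {
  stopifnot(inherits(hap1, "rccx_haplotype"), inherits(hap2, "rccx_haplotype"))
  segs <- rbind(as.data.frame(hap1), as.data.frame(hap2))
  gcn <- c(
    C4A      = sum(segs$c4 == "A"),
    C4B      = sum(segs$c4 == "B"),
    CYP21A1P = sum(segs$cyp21 == "A1P"),
    CYP21A2  = sum(segs$cyp21 == "A2"),
    HERV_del = sum(segs$herv == "deletion"),
    HERV_ins = sum(segs$herv == "insertion"),
    BP       = (nrow(hap1) - 1L) + (nrow(hap2) - 1L)
  )
  g <- structure(list(hap1 = hap1, hap2 = hap2,
                      gcn = as.integer(gcn) |> setNames(names(gcn)),
                      total = nrow(segs)),
                 class = "rccx_genotype")
  stopifnot(genotype_consistent(g))
  g
}

#' @export
print.rccx_genotype <- function(x, ...) {
  cat("RCCX genotype: total", x$total, "segments (",
      nrow(x$hap1), "+", nrow(x$hap2), ")\n")
  print(x$gcn)
  invisible(x)
}

# internal: the four-way total equality every genotype must satisfy
genotype_consistent <- function(g) {
  gc <- g$gcn
  totals <- c(gc["C4A"] + gc["C4B"],
              gc["CYP21A1P"] + gc["CYP21A2"],
              gc["HERV_del"] + gc["HERV_ins"],
              gc["BP"] + 2L)
  all(totals == g$total) && all(gc >= 0L)
}

#' Default RCCX haplotype frequency table
#'
#' A stylised three-haplotype population model: monomodular (one segment),
#' bimodular (two segments) and trimodular (three segments) haplotypes at
#' frequencies 0.55 / 0.40 / 0.05, each carrying exactly one CYP21A2 on its
#' last segment. Diploid totals range 2-6 with a realistic skew toward
#' totals 3-4. The frequencies are a configurable modelling choice, not a
#' population estimate.
#'
#' @return Named list with elements `haplotypes` (list of
#'   `rccx_haplotype`) and `freqs` (numeric, summing to 1).
#' @export
default_haplotype_freqs <- function() {
  mono <- rccx_haplotype("B", "A2", "deletion")
  bi   <- rccx_haplotype(c("A", "B"), c("A1P", "A2"),
                         c("insertion", "deletion"))
  tri  <- rccx_haplotype(c("A", "A", "B"), c("A1P", "A1P", "A2"),
                         c("insertion", "insertion", "deletion"))
  list(haplotypes = list(mono = mono, bi = bi, tri = tri),
       freqs = c(mono = 0.55, bi = 0.40, tri = 0.05))
}

#' Draw a diploid genotype from a haplotype frequency map
#'
#' Samples two haplotypes independently from the supplied frequency table
#' and combines them. Uses the current R random number generator state.
#'
#' @param freqs List with `haplotypes` and `freqs` as returned by
#'   [default_haplotype_freqs()].
#' @return An `rccx_genotype`.
#' @export
sample_genotype <- function(freqs = default_haplotype_freqs()) {
  if (length(freqs$haplotypes) == 0)
    stop("empty haplotype frequency map")
  p <- freqs$freqs
  if (abs(sum(p) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (got ", sum(p), ")")
  idx <- sample.int(length(p), 2, replace = TRUE, prob = p)
  rccx_genotype(freqs$haplotypes[[idx[1]]], freqs$haplotypes[[idx[2]]])
}

#' Draw a cohort of genotypes
#'
#' @param n Number of diploid genotypes to draw.
#' @inheritParams sample_genotype
#' @return List of `rccx_genotype` of length `n`.
#' @export
sample_genotypes <- function(n, freqs = default_haplotype_freqs()) {
  stopifnot(n >= 1)
  replicate(n, sample_genotype(freqs), simplify = FALSE)
}

#' Ground-truth table for a list of genotypes
#'
#' @param genotypes List of `rccx_genotype`.
#' @param sample_ids Optional character vector of sample identifiers.
#' @return data.frame with `sample_id`, the seven integer GCN columns and
#'   `total`.
#' @export
genotype_truth <- function(genotypes, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_along(genotypes))
  gc <- t(vapply(genotypes, function(g) g$gcn, integer(7)))
  out <- data.frame(sample_id = sample_ids, gc,
                    total = vapply(genotypes, function(g) g$total, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
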