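#' Construct a transcript model
#'
#' A transcript model is the basic unit evaluated throughout the package: a
#' single transcript with its ordered exon structure on a genome.  Exons are
#' stored internally in 0-based half-open coordinates; GTF input/output
#' converts to and from the 1-based inclusive convention of that format.
#'
#' @param transcript_id Character scalar, unique identifier of the model.
#' @param gene_id Character scalar, identifier of the gene the model belongs to.
#' @param chrom Character scalar, chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix (`start`, `end`) of 0-based
#'   half-open exon intervals.  Rows need not be sorted; they are sorted on
#'   construction.  Exons must be pairwise non-overlapping and separated by
#'   at least one base.
#' @param source_label Character scalar naming the submission or pipeline the
#'   model came from.
#'
#' @return An object of class `transcript_model`.
#' @export
#' @examples
#' tx <- transcript_model("tx1", "g1", "chr1", "+",
#'                        cbind(c(99, 300), c(200, 400)))
#' junction_chain(tx)
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             source_label = "unknown") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            is.character(chrom), length(chrom) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L)
    stop("transcript ", transcript_id, " has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("transcript ", transcript_id, " has an exon with start >= end")
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gaps < 1))
      stop("transcript ", transcript_id,
           " has overlapping or abutting exons (exons must be separated by >= 1 base)")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 source_label = source_label),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s%s, %d exon(s), span %d-%d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$exons[1L, 1L], x$exons[nrow(x$exons), 2L]))
  invisible(x)
}

#' Junction (intron) chain of a transcript model
#'
#' The ordered list of intron intervals between consecutive exons.  The chain
#' is the identity under which transcript structures are compared across
#' submissions ("unique junction chain", UJC): two models share a UJC exactly
#' when chromosome, strand and every intron coordinate agree, regardless of
#' the positions of the outermost transcript ends.
#'
#' @param t A [transcript_model].
#' @return An object of class `junction_chain` with fields `chrom`, `strand`
#'   and `introns` (0-based half-open intervals; zero rows for a mono-exon
#'   model).
#' @export
junction_chain <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nrow(t$exons)
  if (n == 1L) {
    introns <- matrix(numeric(0), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  } else {
    introns <- cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
  }
  structure(list(chrom = t$chrom, strand = t$strand, introns = introns),
            class = "junction_chain")
}

#' @export
print.junction_chain <- function(x, ...) {
  cat(sprintf("<junction_chain> %s%s: %d intron(s)\n", x$chrom, x$strand,
              nrow(x$introns)))
  invisible(x)
}

# Canonical string key of a junction chain: chain identity used for indexing
# and set arithmetic.  Mono-exon chains get an empty intron block and are
# never entered into chain indices.
chain_key <- function(chain) {
  paste0(chain$chrom, "|", chain$strand, "|",
         paste(chain$introns[, 1L], chain$introns[, 2L],
               sep = "-", collapse = ";"))
}

# Keys of individual splice features
junction_keys <- function(chain) {
  if (nrow(chain$introns) == 0L) return(character(0))
  paste0(chain$chrom, "|", chain$strand, "|",
         chain$introns[, 1L], "-", chain$introns[, 2L])
}

# Donor = intron boundary at the transcript's 5' side of the intron
# (intron start on "+", intron end on "-"); acceptor is the other boundary.
donor_keys <- function(chain) {
  if (nrow(chain$introns) == 0L) return(character(0))
  pos <- if (chain$strand == "+") chain$introns[, 1L] else chain$introns[, 2L]
  paste0(chain$chrom, "|", chain$strand, "|", pos)
}

acceptor_keys <- function(chain) {
  if (nrow(chain$introns) == 0L) return(character(0))
  pos <- if (chain$strand == "+") chain$introns[, 2L] else chain$introns[, 1L]
  paste0(chain$chrom, "|", chain$strand, "|", pos)
}

# Biological 5' (TSS) and 3' (TTS) genomic end positions of a model.
# On "+" the TSS is the leftmost coordinate; on "-" the rightmost.
transcript_ends <- function(t) {
  lo <- unname(t$exons[1L, 1L])
  hi <- unname(t$exons[nrow(t$exons), 2L])
  if (t$strand == "+") c(tss = lo, tts = hi) else c(tss = hi, tts = lo)
}

# Genomic span [start, end) of a model
transcript_span <- function(t) {
  c(start = unname(t$exons[1L, 1L]), end = unname(t$exons[nrow(t$exons), 2L]))
}

# Do two half-open intervals overlap?
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Any exon of model a overlapping any exon of model b (same chrom assumed
# checked by the caller)
exonic_overlap <- function(a, b) {
  ea <- a$exons; eb <- b$exons
  for (i in seq_len(nrow(ea)))
    if (any(intervals_overlap(ea[i, 1L], ea[i, 2L], eb[, 1L], eb[, 2L])))
      return(TRUE)
  FALSE
}
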