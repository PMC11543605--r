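#' Bundle orthogonal support evidence
#'
#' Collects the optional external evidence used for end and junction
#' support: CAGE peaks (5' support), 3'-end sequencing / poly(A) peaks
#' (3' support), short-read junction counts and a genome for poly(A)
#' hexamer and splice-dinucleotide checks.  Every component is optional;
#' evidence-dependent clauses simply evaluate to `FALSE` (and are recorded
#' as unevaluable where the interface reports them) when their component is
#' absent.
#'
#' @param cage_peaks,tts_peaks Data frames with columns
#'   `chrom`, `start`, `end`, `strand` (0-based half-open; strand `"*"`
#'   matches both), e.g. from [read_bed_peaks()].
#' @param junction_counts Named numeric vector of short-read counts keyed
#'   `"chrom|strand|start-end"` (0-based half-open intron), e.g. from
#'   [read_junction_counts()].
#' @param genome A `Biostrings::DNAStringSet` named by chromosome, or a
#'   FASTA path.
#' @param polya_motifs Hexamers accepted as poly(A) signals.
#' @return An object of class `support_evidence`.
#' @export
support_evidence <- function(cage_peaks = NULL, tts_peaks = NULL,
                             junction_counts = NULL, genome = NULL,
                             polya_motifs = c("AATAAA", "ATTAAA")) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  for (pk in list(cage_peaks, tts_peaks)) {
    if (!is.null(pk)) {
      stopifnot(is.data.frame(pk),
                all(c("chrom", "start", "end", "strand") %in% names(pk)))
      if (any(pk$start >= pk$end)) stop("invalid peak interval (start >= end)")
    }
  }
  if (!is.null(junction_counts) && any(junction_counts < 0))
    stop("junction counts must be >= 0")
  structure(list(cage_peaks = cage_peaks, tts_peaks = tts_peaks,
                 junction_counts = junction_counts, genome = genome,
                 polya_motifs = polya_motifs),
            class = "support_evidence")
}

#' Read a BED6 peak file into the evidence peak format
#' @param path BED file path.
#' @return Data frame `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
read_bed_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a junction short-read support table
#'
#' Expects a TSV with columns `chrom start end strand count` where
#' `start`/`end` give the 0-based half-open intron interval.
#'
#' @param path TSV path.
#' @return Named numeric vector keyed `"chrom|strand|start-end"`.
#' @export
read_junction_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "count")
  if (!all(need %in% names(df)))
    stop("junction support table must have columns: ",
         paste(need, collapse = " "))
  stats::setNames(as.numeric(df$count),
                  paste0(df$chrom, "|", df$strand, "|", df$start, "-", df$end))
}

# min distance from a point to a set of half-open intervals (0 if inside)
point_interval_dist <- function(p, start, end) {
  if (length(start) == 0L) return(Inf)
  min(pmax(start - p, p - (end - 1L), 0))
}

# genomic coordinate of the terminal base at the 5' or 3' end
end_base <- function(t, which = c("tss", "tts")) {
  which <- match.arg(which)
  n <- nrow(t$exons)
  if (t$strand == "+") {
    if (which == "tss") t$exons[1L, 1L] else t$exons[n, 2L] - 1L
  } else {
    if (which == "tss") t$exons[n, 2L] - 1L else t$exons[1L, 1L]
  }
}

#' Reference end support and reference match
#'
#' Computes `ref_5p` / `ref_3p` (query end within `window` nt of the
#' nearest same-gene reference TSS / TTS, strand-aware) and
#' `reference_match` (FSM whose both ends lie within `window` nt of the
#' single matched reference's ends).  Also fills the signed end distances of
#' the call (positive = query end downstream of the matched reference end in
#' transcript orientation).
#'
#' @param call A `category_call` from [classify()].
#' @param query The classified [transcript_model].
#' @param catalog The [build_catalog()] result.
#' @param window Inclusive distance threshold in nt (default 50).
#' @return List with `ref_5p`, `ref_3p`, `reference_match`, `tss_distance`,
#'   `tts_distance`.
#' @export
match_reference <- function(call, query, catalog, window = 50) {
  qends <- transcript_ends(query)
  genes <- if (!is.na(call$matched_reference_id)) {
    unique(c(call$assoc_gene_ids,
             catalog$tx_table[call$matched_reference_id, "gene_id"]))
  } else call$assoc_gene_ids
  tt <- catalog$tx_table[catalog$tx_table$gene_id %in% genes, , drop = FALSE]
  ref_5p <- nrow(tt) > 0L && min(abs(tt$tss - qends["tss"])) <= window
  ref_3p <- nrow(tt) > 0L && min(abs(tt$tts - qends["tts"])) <= window

  tss_d <- tts_d <- NA_real_
  reference_match <- FALSE
  if (!is.na(call$matched_reference_id)) {
    r <- catalog$tx_table[call$matched_reference_id, ]
    sign <- if (query$strand == "+") 1 else -1
    tss_d <- sign * (qends["tss"] - r$tss)
    tts_d <- sign * (qends["tts"] - r$tts)
    reference_match <- call$category == "FSM" &&
      abs(qends["tss"] - r$tss) <= window && abs(qends["tts"] - r$tts) <= window
  }
  list(ref_5p = ref_5p, ref_3p = ref_3p, reference_match = reference_match,
       tss_distance = unname(tss_d), tts_distance = unname(tts_d))
}

#' Experimental end support (CAGE / 3' peaks / poly(A) motif)
#'
#' `cage_5p` is true when the query 5' end lies inside or within `window`
#' nt of a CAGE peak.  `polya_3p` is true when the 3' end lies within
#' `window` nt of a 3'-end peak, or when a poly(A) hexamer occurs within 50
#' bases upstream of the 3' end on the transcript strand (the motif clause
#' needs the genome).
#'
#' @param query A [transcript_model].
#' @param evidence A [support_evidence()] bundle.
#' @param window Inclusive distance threshold in nt.
#' @param check_motif `NULL` (auto: use the motif clause iff a genome is
#'   present), or logical; `TRUE` without a genome is a configuration error.
#' @return List `cage_5p`, `polya_3p` plus `cage_evaluable`,
#'   `polya_evaluable` recording which clauses could be evaluated.
#' @export
evidence_support <- function(query, evidence, window = 50, check_motif = NULL) {
  stopifnot(inherits(evidence, "support_evidence"))
  if (isTRUE(check_motif) && is.null(evidence$genome))
    stop("poly(A) motif check requested but no genome supplied")
  use_motif <- if (is.null(check_motif)) !is.null(evidence$genome) else check_motif

  p5 <- end_base(query, "tss")
  p3 <- end_base(query, "tts")

  peak_hit <- function(peaks, p) {
    if (is.null(peaks)) return(NA)
    sel <- peaks$chrom == query$chrom &
      (peaks$strand == "*" | peaks$strand == query$strand)
    point_interval_dist(p, peaks$start[sel], peaks$end[sel]) <= window
  }
  cage <- peak_hit(evidence$cage_peaks, p5)
  tts <- peak_hit(evidence$tts_peaks, p3)

  motif <- NA
  if (use_motif) {
    motif <- polya_motif_upstream(query, evidence$genome,
                                  motifs = evidence$polya_motifs)
  }
  list(cage_5p = isTRUE(cage),
       polya_3p = isTRUE(tts) || isTRUE(motif),
       cage_evaluable = !is.na(cage),
       polya_evaluable = !is.na(tts) || !is.na(motif))
}

# poly(A) hexamer within the 50 genomic bases upstream of (and including)
# the 3' terminal base, read on the transcript strand
polya_motif_upstream <- function(query, genome, motifs = c("AATAAA", "ATTAAA"),
                                 span = 50L) {
  if (!query$chrom %in% names(genome)) return(FALSE)
  seqlen <- Biostrings::width(genome[query$chrom])
  if (query$strand == "+") {
    e <- query$exons[nrow(query$exons), 2L]       # half-open end
    from <- max(1L, e - span + 1L); to <- min(seqlen, e)
    s <- Biostrings::subseq(genome[[query$chrom]], from, to)
  } else {
    s0 <- query$exons[1L, 1L]                      # 0-based start
    from <- s0 + 1L; to <- min(seqlen, s0 + span)
    s <- Biostrings::reverseComplement(
      Biostrings::subseq(genome[[query$chrom]], from, to))
  }
  txt <- as.character(s)
  any(vapply(motifs, function(m) grepl(m, txt, fixed = TRUE), logical(1)))
}

#' Supported reference / novel transcript model flags
#'
#' SRTM: an FSM/ISM transcript whose 5' end is within the window of a
#' reference TSS or has CAGE support, AND whose 3' end is within the window
#' of a reference TTS or has poly(A)/3'-end-sequencing support.  SNTM: the
#' same end condition for an NIC/NNC transcript, additionally requiring
#' short-read support (count >= 1) at every novel junction.
#'
#' @param call A `category_call`.
#' @param flags Combined end flags: a list providing `ref_5p`, `ref_3p`,
#'   `cage_5p`, `polya_3p` (missing members are treated as `FALSE`).
#' @param novel_junction_counts Numeric vector of short-read counts for the
#'   query's novel junctions (length 0 when there are none).
#' @return List `srtm`, `sntm` (each `NA` when the category gate does not
#'   apply).
#' @export
srtm_sntm <- function(call, flags, novel_junction_counts = numeric(0)) {
  g <- function(nm) isTRUE(flags[[nm]])
  end5 <- g("ref_5p") || g("cage_5p")
  end3 <- g("ref_3p") || g("polya_3p")
  srtm <- if (call$category %in% c("FSM", "ISM")) end5 && end3 else NA
  sntm <- if (call$category %in% c("NIC", "NNC")) {
    end5 && end3 && all(novel_junction_counts >= 1)
  } else NA
  list(srtm = srtm, sntm = sntm)
}

# counts for the query's novel junctions (keys absent from the catalog);
# junctions with no entry in the support table count 0
novel_junction_support <- function(query, catalog, evidence) {
  jk <- junction_keys(junction_chain(query))
  novel <- jk[!jk %in% catalog$junction_set]
  if (length(novel) == 0L) return(numeric(0))
  if (is.null(evidence$junction_counts)) return(rep(0, length(novel)))
  cnt <- evidence$junction_counts[novel]
  cnt[is.na(cnt)] <- 0
  unname(cnt)
}
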