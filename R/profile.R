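#' Splice dinucleotides of an intron
#'
#' Returns the donor-acceptor dinucleotide pair of an intron read on the
#' transcript strand (e.g. `"GT-AG"`).  Canonical pairs are GT-AG, GC-AG
#' and AT-AC.
#'
#' @param chrom,strand,start,end Intron location (0-based half-open).
#' @param genome Named `DNAStringSet`.
#' @return Character scalar like `"GT-AG"`, or `NA` if the chromosome is
#'   missing from the genome.
#' @export
splice_dinucleotides <- function(chrom, strand, start, end, genome) {
  if (!chrom %in% names(genome)) return(NA_character_)
  seq <- genome[[chrom]]
  left <- as.character(Biostrings::subseq(seq, start + 1L, start + 2L))
  right <- as.character(Biostrings::subseq(seq, end - 1L, end))
  if (strand == "+") {
    paste0(left, "-", right)
  } else {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    paste0(rc(right), "-", rc(left))
  }
}

CANONICAL_PAIRS <- c("GT-AG", "GC-AG", "AT-AC")

#' Junction-level profile of a submission
#'
#' Summarizes the distinct splice junctions of a set of transcript models
#' against the reference catalog and optional evidence: the fraction of
#' novel junctions, non-canonical junctions and non-canonical transcripts
#' (needs a genome), and the fraction of junctions / of transcripts fully
#' supported by short reads (needs a junction support table).  Fields whose
#' evidence is missing are reported `NA`, never zero.
#'
#' @param models List of [transcript_model] (the submission).
#' @param catalog A [build_catalog()] result.
#' @param evidence Optional [support_evidence()] (junction counts, genome).
#' @return One-row data frame: `n_transcripts`, `n_multiexon`,
#'   `n_junctions` (distinct), `pct_novel_junctions`,
#'   `pct_noncanonical_junctions`, `pct_noncanonical_transcripts`,
#'   `pct_junctions_supported`, `pct_transcripts_fully_supported`.
#' @export
junction_profile <- function(models, catalog, evidence = NULL) {
  chains <- lapply(models, junction_chain)
  jk_per_tx <- lapply(chains, junction_keys)
  multi <- vapply(jk_per_tx, length, integer(1)) > 0L
  all_keys <- unique(unlist(jk_per_tx, use.names = FALSE))
  nj <- length(all_keys)

  pct <- function(x, n) if (n > 0L) 100 * x / n else NA_real_

  pct_novel <- pct(sum(!all_keys %in% catalog$junction_set), nj)

  genome <- if (!is.null(evidence)) evidence$genome else NULL
  pct_noncan_j <- pct_noncan_tx <- NA_real_
  if (!is.null(genome) && nj > 0L) {
    parts <- strsplit(all_keys, "|", fixed = TRUE)
    dinuc <- vapply(parts, function(p) {
      se <- as.numeric(strsplit(p[3L], "-", fixed = TRUE)[[1L]])
      splice_dinucleotides(p[1L], p[2L], se[1L], se[2L], genome)
    }, character(1))
    noncan <- stats::setNames(!dinuc %in% CANONICAL_PAIRS, all_keys)
    pct_noncan_j <- pct(sum(noncan), nj)
    tx_noncan <- vapply(jk_per_tx[multi],
                        function(k) any(noncan[k]), logical(1))
    pct_noncan_tx <- pct(sum(tx_noncan), sum(multi))
  }

  counts <- if (!is.null(evidence)) evidence$junction_counts else NULL
  pct_supp_j <- pct_supp_tx <- NA_real_
  if (!is.null(counts) && nj > 0L) {
    supp <- stats::setNames(!is.na(counts[all_keys]) & counts[all_keys] >= 1,
                            all_keys)
    pct_supp_j <- pct(sum(supp), nj)
    tx_supp <- vapply(jk_per_tx[multi], function(k) all(supp[k]), logical(1))
    pct_supp_tx <- pct(sum(tx_supp), sum(multi))
  }

  data.frame(n_transcripts = length(models),
             n_multiexon = sum(multi),
             n_junctions = nj,
             pct_novel_junctions = pct_novel,
             pct_noncanonical_junctions = pct_noncan_j,
             pct_noncanonical_transcripts = pct_noncan_tx,
             pct_junctions_supported = pct_supp_j,
             pct_transcripts_fully_supported = pct_supp_tx)
}

#' Junction-chain length ratio
#'
#' For an ISM call, the fraction of the matched reference's junctions the
#' query retains (in (0,1)); for NIC/NNC, the junction count of the longest
#' same-locus reference divided by the query's junction count.  Undefined
#' (NA) for other categories or when an NIC/NNC locus has only mono-exon
#' references.
#'
#' @param call A `category_call`.
#' @param query The classified [transcript_model].
#' @param catalog The [build_catalog()] result.
#' @return Numeric scalar or `NA`.
#' @export
chain_length_ratios <- function(call, query, catalog) {
  nq <- nrow(query$exons) - 1L
  if (call$category == "ISM") {
    nr <- catalog$tx_table[call$matched_reference_id, "n_introns"]
    return(nq / nr)
  }
  if (call$category %in% c("NIC", "NNC")) {
    if (length(call$assoc_ref_ids) == 0L) return(NA_real_)
    nref <- catalog$tx_table[call$assoc_ref_ids, "n_introns"]
    if (all(nref == 0L)) return(NA_real_)
    return(max(nref) / nq)
  }
  NA_real_
}

#' Classify a whole submission into a SQANTI-style table
#'
#' Runs [classify()], [match_reference()], [evidence_support()] and
#' [srtm_sntm()] over every model of a submission and assembles the
#' per-transcript classification table.
#'
#' @param models List of [transcript_model] (the submission).
#' @param catalog A [build_catalog()] result.
#' @param evidence Optional [support_evidence()].
#' @param window End window in nt (default 50).
#' @return Data frame with one row per query: `query_id`, `category`,
#'   `other_subtype`, `matched_reference_id`, `tss_distance`,
#'   `tts_distance`, `nic_reason`, `ref_5p`, `ref_3p`, `cage_5p`,
#'   `polya_3p`, `reference_match`, `srtm`, `sntm`,
#'   `n_novel_junctions`, `all_novel_junctions_supported`,
#'   `chain_length_ratio`.
#' @export
classify_submission <- function(models, catalog, evidence = NULL, window = 50) {
  rows <- lapply(models, function(q) {
    call <- classify(q, catalog, window = window)
    mr <- match_reference(call, q, catalog, window = window)
    ev <- if (!is.null(evidence)) {
      evidence_support(q, evidence, window = window)
    } else list(cage_5p = FALSE, polya_3p = FALSE)
    flags <- c(mr[c("ref_5p", "ref_3p")], ev[c("cage_5p", "polya_3p")])
    njc <- novel_junction_support(q, catalog,
                                  evidence %||% support_evidence())
    ss <- srtm_sntm(call, flags, njc)
    data.frame(query_id = call$query_id,
               category = call$category,
               other_subtype = call$other_subtype,
               matched_reference_id = call$matched_reference_id,
               tss_distance = mr$tss_distance,
               tts_distance = mr$tts_distance,
               nic_reason = call$nic_reason,
               ref_5p = mr$ref_5p, ref_3p = mr$ref_3p,
               cage_5p = isTRUE(ev$cage_5p), polya_3p = isTRUE(ev$polya_3p),
               reference_match = mr$reference_match,
               srtm = if (is.na(ss$srtm)) NA else ss$srtm,
               sntm = if (is.na(ss$sntm)) NA else ss$sntm,
               n_novel_junctions = length(njc),
               all_novel_junctions_supported =
                 if (length(njc)) all(njc >= 1) else NA,
               chain_length_ratio = chain_length_ratios(call, q, catalog),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
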