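#' Classify a query transcript against a reference catalog
#'
#' Assigns one structural category per query by comparing its junction chain
#' and splice sites with the reference:
#' \describe{
#'   \item{FSM}{full splice match -- the query's complete intron chain equals
#'     a reference transcript's chain.}
#'   \item{ISM}{incomplete splice match -- the chain is a consecutive,
#'     proper sub-chain of a reference chain at the same locus (5'/3'
#'     truncation).}
#'   \item{NNC}{novel not in catalog -- at least one donor or acceptor site
#'     is not annotated (strand-aware exact coordinate).}
#'   \item{NIC}{novel in catalog -- all splice sites are annotated but the
#'     transcript is novel: a new combination of known junctions, a novel
#'     junction pairing known sites, or unannotated intron retention.}
#'   \item{other}{antisense, fusion, genic, intergenic or mono-exon-match,
#'     by overlap logic.}
#' }
#' Queries with no same-strand locus association are resolved to
#' antisense/intergenic before the novel-site test (an antisense query's
#' sites are never annotated on its own strand, so a blind site test would
#' absorb it into NNC).
#'
#' Mono-exon queries are delegated to [classify_mono_exon()].
#'
#' @param query A [transcript_model].
#' @param catalog A [build_catalog()] result.
#' @param window End window (nt) used only for the mono-exon rule.
#' @return An object of class `category_call`: `query_id`, `category`,
#'   `other_subtype`, `matched_reference_id`, `nic_reason`, plus the
#'   associated gene/locus bookkeeping used by downstream support scoring.
#'   `tss_distance`/`tts_distance` are filled by [match_reference()].
#' @export
classify <- function(query, catalog, window = 50) {
  stopifnot(inherits(query, "transcript_model"),
            inherits(catalog, "reference_catalog"))
  if (nrow(query$exons) == 1L)
    return(classify_mono_exon(query, catalog, window = window))

  qchain <- junction_chain(query)
  qkey <- chain_key(qchain)

  # FSM: exact chain identity
  if (!is.null(catalog$chain_index[[qkey]])) {
    matched <- best_end_match(query, catalog$chain_index[[qkey]], catalog)
    return(new_call(query, "FSM", matched_reference_id = matched,
                    assoc = assoc_refs(query, qchain, catalog)))
  }

  assoc <- assoc_refs(query, qchain, catalog)

  # ISM: consecutive proper sub-chain of an associated reference
  if (length(assoc$ids)) {
    hosts <- assoc$ids[vapply(assoc$ids, function(id) {
      rin <- catalog$chains[[id]]$introns
      is_consecutive_subchain(qchain$introns, rin)
    }, logical(1))]
    if (length(hosts)) {
      matched <- best_end_match(query, hosts, catalog)
      return(new_call(query, "ISM", matched_reference_id = matched,
                      assoc = assoc))
    }
  }

  # no same-strand association: antisense or intergenic
  if (length(assoc$ids) == 0L) {
    sub <- if (opposite_strand_overlap(query, catalog)) "antisense" else "intergenic"
    return(new_call(query, "other", other_subtype = sub, assoc = assoc))
  }

  # fusion: association spans >= 2 disjoint same-strand loci
  if (length(unique(catalog$locus_of[assoc$ids])) >= 2L)
    return(new_call(query, "other", other_subtype = "fusion", assoc = assoc))

  # NNC: any unannotated donor or acceptor
  novel_site <- any(!donor_keys(qchain) %in% catalog$donor_set) ||
    any(!acceptor_keys(qchain) %in% catalog$acceptor_set)
  if (novel_site)
    return(new_call(query, "NNC", assoc = assoc))

  # NIC: all sites known; pick the reason
  reason <- if (has_intron_retention(query, assoc$ids, catalog)) {
    "intron-retention"
  } else if (any(!junction_keys(qchain) %in% catalog$junction_set)) {
    "novel-junction-known-sites"
  } else {
    "junction-combination"
  }
  new_call(query, "NIC", nic_reason = reason, assoc = assoc)
}

#' Classify a mono-exon query
#'
#' Unspliced models carry no junction chain, so chain-based categories do
#' not apply; FSM is never assigned.  The rule used: a query matching a
#' mono-exon reference on the same strand with both ends within `window` nt
#' is `other/mono-exon-match`; otherwise same-strand span overlap gives
#' `other/genic`, opposite-strand-only overlap `other/antisense`, no overlap
#' `other/intergenic`.
#'
#' @inheritParams classify
#' @return A `category_call` with category `"other"`.
#' @export
classify_mono_exon <- function(query, catalog, window = 50) {
  stopifnot(nrow(query$exons) == 1L)
  tt <- catalog$tx_table
  qs <- query$exons[1L, 1L]; qe <- query$exons[1L, 2L]
  same <- tt$chrom == query$chrom & tt$strand == query$strand &
    intervals_overlap(tt$start, tt$end, qs, qe)
  qends <- transcript_ends(query)
  mono <- same & tt$n_introns == 0L &
    abs(tt$tss - qends["tss"]) <= window & abs(tt$tts - qends["tts"]) <= window
  assoc <- list(ids = tt$transcript_id[same],
                genes = unique(tt$gene_id[same]))
  if (any(mono)) {
    cand <- tt$transcript_id[mono]
    matched <- best_end_match(query, cand, catalog)
    return(new_call(query, "other", other_subtype = "mono-exon-match",
                    matched_reference_id = matched, assoc = assoc))
  }
  if (any(same))
    return(new_call(query, "other", other_subtype = "genic", assoc = assoc))
  sub <- if (opposite_strand_overlap(query, catalog)) "antisense" else "intergenic"
  new_call(query, "other", other_subtype = sub, assoc = assoc)
}

new_call <- function(query, category,
                     other_subtype = "none",
                     matched_reference_id = NA_character_,
                     nic_reason = "none",
                     assoc = list(ids = character(0), genes = character(0))) {
  structure(list(query_id = query$transcript_id,
                 category = category,
                 other_subtype = other_subtype,
                 matched_reference_id = matched_reference_id,
                 tss_distance = NA_real_,
                 tts_distance = NA_real_,
                 nic_reason = nic_reason,
                 assoc_ref_ids = assoc$ids,
                 assoc_gene_ids = assoc$genes),
            class = "category_call")
}

#' @export
print.category_call <- function(x, ...) {
  cat(sprintf("<category_call> %s: %s%s%s\n", x$query_id, x$category,
              if (x$other_subtype != "none") paste0("/", x$other_subtype) else "",
              if (!is.na(x$matched_reference_id))
                paste0(" -> ", x$matched_reference_id) else ""))
  invisible(x)
}

# Same-strand reference transcripts associated with the query: span overlap
# plus either exonic overlap or a shared splice site/junction.
assoc_refs <- function(query, qchain, catalog) {
  tt <- catalog$tx_table
  qs <- query$exons[1L, 1L]; qe <- query$exons[nrow(query$exons), 2L]
  cand <- tt$transcript_id[tt$chrom == query$chrom &
                             tt$strand == query$strand &
                             intervals_overlap(tt$start, tt$end, qs, qe)]
  if (length(cand) == 0L)
    return(list(ids = character(0), genes = character(0)))
  qj <- junction_keys(qchain)
  qsites <- c(donor_keys(qchain), acceptor_keys(qchain))
  keep <- vapply(cand, function(id) {
    ref <- catalog$transcripts[[id]]
    if (exonic_overlap(query, ref)) return(TRUE)
    rch <- catalog$chains[[id]]
    any(junction_keys(rch) %in% qj) ||
      any(c(donor_keys(rch), acceptor_keys(rch)) %in% qsites)
  }, logical(1))
  ids <- cand[keep]
  list(ids = ids, genes = unique(tt[ids, "gene_id"]))
}

opposite_strand_overlap <- function(query, catalog) {
  tt <- catalog$tx_table
  qs <- query$exons[1L, 1L]; qe <- query$exons[nrow(query$exons), 2L]
  opp <- tt$chrom == query$chrom & tt$strand != query$strand &
    intervals_overlap(tt$start, tt$end, qs, qe)
  for (id in tt$transcript_id[opp]) {
    ref <- catalog$transcripts[[id]]
    ea <- query$exons
    for (i in seq_len(nrow(ea)))
      if (any(intervals_overlap(ea[i, 1L], ea[i, 2L],
                                ref$exons[, 1L], ref$exons[, 2L])))
        return(TRUE)
  }
  FALSE
}

# Among candidate reference ids, the one minimizing |dTSS| + |dTTS|
# (deterministic tie-break by id order in the catalog table).
best_end_match <- function(query, cand_ids, catalog) {
  qends <- transcript_ends(query)
  tt <- catalog$tx_table[cand_ids, , drop = FALSE]
  cost <- abs(tt$tss - qends["tss"]) + abs(tt$tts - qends["tts"])
  cand_ids[which.min(cost)]
}

# qin a consecutive run strictly inside rin?
is_consecutive_subchain <- function(qin, rin) {
  nq <- nrow(qin); nr <- nrow(rin)
  if (nq == 0L || nq >= nr) return(FALSE)
  for (off in 0:(nr - nq)) {
    if (all(qin[, 1L] == rin[off + seq_len(nq), 1L]) &&
        all(qin[, 2L] == rin[off + seq_len(nq), 2L]))
      return(TRUE)
  }
  FALSE
}

# Any query exon fully containing an annotated intron of an associated
# reference, with both flanking splice sites strictly inside the exon.
has_intron_retention <- function(query, assoc_ids, catalog) {
  if (length(assoc_ids) == 0L) return(FALSE)
  ex <- query$exons
  for (id in assoc_ids) {
    rin <- catalog$chains[[id]]$introns
    if (nrow(rin) == 0L) next
    for (i in seq_len(nrow(ex))) {
      if (any(ex[i, 1L] < rin[, 1L] & rin[, 2L] < ex[i, 2L]))
        return(TRUE)
    }
  }
  FALSE
}
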