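#' Build an indexed reference catalog
#'
#' Indexes a set of reference transcript models for structural
#' classification and detection scoring: the junction-chain index (chain ->
#' reference ids, multi-exon transcripts only), the sets of annotated
#' introns, donors and acceptors (strand-aware exact genomic coordinates),
#' per-transcript 5'/3' end positions, and gene loci obtained by
#' single-linkage clustering of exonic overlap.
#'
#' @param models List of [transcript_model] objects (the reference
#'   annotation).  Duplicate transcript ids are an error.
#' @param pool_strands Passed to [group_loci()]; if `FALSE` (default) loci
#'   are clustered per strand.
#' @return An object of class `reference_catalog`.
#' @export
build_catalog <- function(models, pool_strands = FALSE) {
  stopifnot(length(models) >= 1L)
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id in reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids

  chains <- lapply(models, junction_chain)
  multi <- vapply(chains, function(ch) nrow(ch$introns) > 0L, logical(1))
  keys <- vapply(chains[multi], chain_key, character(1))
  chain_index <- split(names(chains[multi]), keys)

  junction_set <- unique(unlist(lapply(chains, junction_keys), use.names = FALSE))
  donor_set <- unique(unlist(lapply(chains, donor_keys), use.names = FALSE))
  acceptor_set <- unique(unlist(lapply(chains, acceptor_keys), use.names = FALSE))
  if (is.null(junction_set)) junction_set <- character(0)
  if (is.null(donor_set)) donor_set <- character(0)
  if (is.null(acceptor_set)) acceptor_set <- character(0)

  ends <- t(vapply(models, transcript_ends, c(tss = 0, tts = 0)))
  spans <- t(vapply(models, transcript_span, c(start = 0, end = 0)))
  tx_table <- data.frame(
    transcript_id = ids,
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    strand = vapply(models, `[[`, character(1), "strand"),
    start = spans[, 1L], end = spans[, 2L],
    tss = ends[, "tss"], tts = ends[, "tts"],
    n_introns = vapply(models, function(t) nrow(t$exons) - 1L, integer(1)),
    row.names = ids, stringsAsFactors = FALSE)

  loci <- group_loci(models, pool_strands = pool_strands)
  locus_of <- rep(NA_integer_, length(models))
  names(locus_of) <- ids
  for (k in seq_along(loci)) locus_of[loci[[k]]$members] <- k

  structure(list(transcripts = models,
                 chains = chains,
                 chain_index = chain_index,
                 junction_set = junction_set,
                 donor_set = donor_set,
                 acceptor_set = acceptor_set,
                 tx_table = tx_table,
                 loci = loci,
                 locus_of = locus_of),
            class = "reference_catalog")
}

#' @export
print.reference_catalog <- function(x, ...) {
  cat(sprintf(paste0("<reference_catalog> %d transcripts, %d distinct chains, ",
                     "%d junctions, %d loci\n"),
              length(x$transcripts), length(x$chain_index),
              length(x$junction_set), length(x$loci)))
  invisible(x)
}

#' Cluster transcript models into gene loci
#'
#' Single-linkage clustering by exonic overlap: two models belong to the
#' same locus when their exons overlap directly or through a chain of
#' pairwise-overlapping intermediates on the same chromosome (and strand,
#' unless `pool_strands`).  The result partitions the input.
#'
#' @param models List of [transcript_model] objects.
#' @param pool_strands If `TRUE`, cluster regardless of strand.
#' @return List of loci; each locus is a list with `chrom`, `strand`
#'   (`"*"` when pooled or mixed), `start`, `end` and `members`
#'   (transcript ids).
#' @export
group_loci <- function(models, pool_strands = FALSE) {
  n <- length(models)
  if (n == 0L) return(list())
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  chrom <- vapply(models, `[[`, character(1), "chrom")
  strand <- vapply(models, `[[`, character(1), "strand")
  grp_key <- if (pool_strands) chrom else paste0(chrom, strand)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }

  for (g in unique(grp_key)) {
    idx <- which(grp_key == g)
    if (length(idx) < 2L) next
    # sort by span start; link i to any later j whose span starts before the
    # running max end AND that shares exonic overlap
    starts <- vapply(models[idx], function(t) t$exons[1L, 1L], numeric(1))
    ord <- idx[order(starts)]
    for (a in seq_along(ord)) {
      for (b in seq_len(a - 1L)) {
        ta <- models[[ord[a]]]; tb <- models[[ord[b]]]
        if (intervals_overlap(ta$exons[1L, 1L], ta$exons[nrow(ta$exons), 2L],
                              tb$exons[1L, 1L], tb$exons[nrow(tb$exons), 2L]) &&
            exonic_overlap(ta, tb))
          union_(ord[a], ord[b])
      }
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), roots), function(idx) {
    mem <- models[idx]
    st <- unique(strand[idx])
    list(chrom = chrom[idx[1L]],
         strand = if (length(st) == 1L) st else "*",
         start = min(vapply(mem, function(t) t$exons[1L, 1L], numeric(1))),
         end = max(vapply(mem, function(t) t$exons[nrow(t$exons), 2L], numeric(1))),
         members = unname(ids[idx]))
  })
  names(out) <- NULL
  # deterministic order: by chrom, start
  out[order(vapply(out, `[[`, character(1), "chrom"),
            vapply(out, `[[`, numeric(1), "start"))]
}
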