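#' Read transcript models from a GTF file
#'
#' Parses `exon` features of a GENCODE-dialect GTF (attributes
#' `gene_id "X"; transcript_id "Y";`) into a list of [transcript_model]
#' objects.  GTF coordinates (1-based, inclusive) are converted to the
#' internal 0-based half-open convention.  Exon order in the file is
#' irrelevant; exons are sorted per transcript.
#'
#' @param path Path to a GTF file.
#' @param source_label Label recorded on every model (submission / pipeline
#'   name); defaults to the file name.
#' @return Named list of [transcript_model] objects (names = transcript ids),
#'   in order of first appearance in the file.
#' @export
read_gtf <- function(path, source_label = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (is.null(source_label))
    source_label <- tools::file_path_sans_ext(basename(path))
  first <- readLines(path, n = 100L)
  if (!any(nzchar(first) & !startsWith(first, "#")))
    return(structure(list(), names = character(0)))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("GTF parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  if (is.null(gr$transcript_id) || is.null(gr$gene_id) ||
      anyNA(gr$transcript_id) || anyNA(gr$gene_id))
    stop("GTF parse error in ", path,
         ": exon feature missing transcript_id or gene_id attribute")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),           # half-open
                   strand = as.character(GenomicRanges::strand(gr)),
                   transcript_id = gr$transcript_id,
                   gene_id = gr$gene_id,
                   stringsAsFactors = FALSE)
  ids <- unique(df$transcript_id)
  models <- vector("list", length(ids))
  names(models) <- ids
  for (id in ids) {
    sub <- df[df$transcript_id == id, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1L)
      stop("transcript ", id, " has exons on multiple chromosomes")
    if (length(unique(sub$strand)) > 1L)
      stop("transcript ", id, " has exons on both strands")
    if (!sub$strand[1L] %in% c("+", "-"))
      stop("transcript ", id, " has no usable strand ('", sub$strand[1L], "')")
    if (length(unique(sub$gene_id)) > 1L)
      stop("transcript ", id, " is assigned to multiple gene_ids")
    models[[id]] <- transcript_model(id, sub$gene_id[1L], sub$chrom[1L],
                                     sub$strand[1L],
                                     cbind(sub$start, sub$end),
                                     source_label = source_label)
  }
  models
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: models are written as `exon` features in input
#' order (exons ascending within each transcript), converting internal
#' 0-based half-open coordinates back to 1-based inclusive GTF coordinates.
#' `read_gtf(write_gtf(x))` reproduces `x`.
#'
#' @param models List of [transcript_model] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  if (length(models) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom <- unlist(lapply(models, function(t) rep(t$chrom, nrow(t$exons))))
  strand <- unlist(lapply(models, function(t) rep(t$strand, nrow(t$exons))))
  starts <- unlist(lapply(models, function(t) t$exons[, 1L] + 1L))
  ends <- unlist(lapply(models, function(t) t$exons[, 2L]))
  src <- unlist(lapply(models, function(t) rep(t$source_label, nrow(t$exons))))
  txid <- unlist(lapply(models, function(t) rep(t$transcript_id, nrow(t$exons))))
  gid <- unlist(lapply(models, function(t) rep(t$gene_id, nrow(t$exons))))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  gr$source <- src
  gr$type <- "exon"
  gr$gene_id <- gid
  gr$transcript_id <- txid
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write unique junction chains as a BED6 file
#'
#' One BED record per distinct junction chain among the supplied models:
#' the record spans from the first donor to the last acceptor of the chain
#' (mono-exon models are skipped, having no chain).  Useful for visualizing
#' the consolidated chain-level content of one or several submissions.
#'
#' @param models List of [transcript_model] objects.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_ujc_bed <- function(models, path) {
  chains <- lapply(models, junction_chain)
  chains <- chains[vapply(chains, function(ch) nrow(ch$introns) > 0L, logical(1))]
  if (length(chains) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  keys <- vapply(chains, chain_key, character(1))
  chains <- chains[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  lines <- vapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    paste(ch$chrom, ch$introns[1L, 1L], ch$introns[nrow(ch$introns), 2L],
          gsub("[|;]", "_", keys[i]), 0L, ch$strand, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
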