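#' Per-transcript feature table for stratified evaluation
#'
#' Derives the transcript features used to stratify quantification
#' performance: mature transcript length, exon count, the number of
#' isoforms of the transcript's gene and the gene's K-value (exon-isoform
#' condition number), plus the ground-truth abundance when supplied.
#'
#' @param models List of [transcript_model] (annotation of the evaluated
#'   transcripts).
#' @param truth Optional named ground-truth TPM vector.
#' @param k_mode Exon identity mode for [k_value()].
#' @return Data frame: `transcript_id`, `length`, `n_exons`, `n_isoforms`,
#'   `k_value`, and `truth_tpm` when `truth` is given.
#' @export
transcript_features <- function(models, truth = NULL,
                                k_mode = c("exact", "segments")) {
  k_mode <- match.arg(k_mode)
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  genes <- vapply(models, `[[`, character(1), "gene_id")
  by_gene <- split(models, genes)
  kv <- vapply(by_gene, function(iso) k_value(iso, mode = k_mode), numeric(1))
  n_iso <- vapply(by_gene, length, integer(1))
  df <- data.frame(
    transcript_id = ids,
    length = vapply(models, function(t) sum(t$exons[, 2L] - t$exons[, 1L]),
                    numeric(1)),
    n_exons = vapply(models, function(t) nrow(t$exons), integer(1)),
    n_isoforms = n_iso[genes],
    k_value = kv[genes],
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    df$truth_tpm <- unname(truth[ids])
    df$truth_tpm[is.na(df$truth_tpm)] <- 0
  }
  df
}

#' Feature-stratified quantification report
#'
#' Recomputes SCC, MRD and NRMSE within bins of a transcript feature
#' (ground-truth abundance, exon count, length, isoform count, K-value ...)
#' and adds a min-max normalized MRD across the bins of the report.
#' Bins in which a metric is undefined (e.g. no positive-truth transcript,
#' or fewer than two members) are reported as missing, never as zero.
#'
#' @param est Named estimated TPM vector.
#' @param truth Named ground-truth TPM vector.
#' @param feature Named numeric vector: feature value per transcript
#'   (names matching truth ids).
#' @param breaks Bin breakpoints passed to [cut()] (or a single integer
#'   for that many quantile-ish equal-width bins).
#' @return Data frame: `bin`, `n`, `SCC`, `MRD`, `NRMSE`, `MRD_norm`.
#' @export
stratified_report <- function(est, truth, feature, breaks) {
  stopifnot(!is.null(names(truth)))
  f <- feature[names(truth)]
  bins <- cut(f, breaks = breaks, include.lowest = TRUE)
  safe <- function(fun, ids) tryCatch(fun(est[ids], truth[ids]),
                                      error = function(e) NA_real_)
  rows <- lapply(levels(bins), function(b) {
    ids <- names(truth)[!is.na(bins) & bins == b]
    if (length(ids) == 0L)
      return(data.frame(bin = b, n = 0L, SCC = NA_real_, MRD = NA_real_,
                        NRMSE = NA_real_))
    data.frame(bin = b, n = length(ids),
               SCC = safe(scc, ids), MRD = safe(mrd, ids),
               NRMSE = safe(nrmse, ids))
  })
  out <- do.call(rbind, rows)
  rng <- range(out$MRD, na.rm = TRUE)
  out$MRD_norm <- if (all(is.na(out$MRD)) || diff(rng) == 0) NA_real_
                  else (out$MRD - rng[1L]) / diff(rng)
  rownames(out) <- NULL
  out
}
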