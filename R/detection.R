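#' Score a submission against a ground-truth transcript set
#'
#' Truth-side accounting over junction chains: a truth transcript is a TP
#' when at least one prediction matches its chain exactly AND has both ends
#' within `window` nt; a PTP ("partial" TP) when it is chain-matched but
#' never end-matched; an FN when no prediction matches its chain.  Mono-exon
#' truth transcripts (which carry no chain) are matched by same-strand
#' overlap with both ends within the window.  Prediction-side: precision is
#' the fraction of predictions that chain-and-end match some truth
#' transcript; an FP matches no truth chain.  Redundancy is the number of
#' chain-matching predictions per distinct matched truth transcript.
#'
#' @param predictions List of [transcript_model] (the submission).
#' @param truth A [build_catalog()] built from the ground-truth models, or a
#'   list of models (then a catalog is built internally).
#' @param window End window in nt (default 50).
#' @return An object of class `detection_result`: counts `tp`, `ptp`, `fn`,
#'   `fp`, and statistics `sensitivity`, `precision`, `f1`, `pdr`,
#'   `redundancy` (`NA` when no prediction matches), `inv_redundancy`.
#' @export
evaluate_detection <- function(predictions, truth, window = 50) {
  if (!inherits(truth, "reference_catalog")) truth <- build_catalog(truth)
  n_truth <- length(truth$transcripts)
  if (n_truth == 0L) stop("empty ground-truth set")

  truth_ids <- names(truth$transcripts)
  chain_of_truth <- vapply(truth$chains, chain_key, character(1))
  multi_truth <- vapply(truth$chains, function(ch) nrow(ch$introns) > 0L,
                        logical(1))

  # for each prediction: ids of chain-matched truth, and end-matched subset
  n_pred <- length(predictions)
  chainhit <- vector("list", n_pred)
  endhit <- vector("list", n_pred)
  for (k in seq_len(n_pred)) {
    p <- predictions[[k]]
    pch <- junction_chain(p)
    pends <- transcript_ends(p)
    if (nrow(pch$introns) > 0L) {
      hit <- truth$chain_index[[chain_key(pch)]]
      if (is.null(hit)) hit <- character(0)
    } else {
      tt <- truth$tx_table
      sel <- !multi_truth & tt$chrom == p$chrom & tt$strand == p$strand &
        intervals_overlap(tt$start, tt$end,
                          p$exons[1L, 1L], p$exons[1L, 2L])
      hit <- truth_ids[sel]
    }
    chainhit[[k]] <- hit
    if (length(hit)) {
      tt <- truth$tx_table[hit, , drop = FALSE]
      ok <- abs(tt$tss - pends["tss"]) <= window &
        abs(tt$tts - pends["tts"]) <= window
      endhit[[k]] <- hit[ok]
    } else endhit[[k]] <- character(0)
  }

  chain_matched_truth <- unique(unlist(chainhit, use.names = FALSE))
  end_matched_truth <- unique(unlist(endhit, use.names = FALSE))
  tp <- length(end_matched_truth)
  ptp <- length(setdiff(chain_matched_truth, end_matched_truth))
  fn <- n_truth - length(chain_matched_truth)
  pred_chain_match <- vapply(chainhit, function(h) length(h) > 0L, logical(1))
  pred_end_match <- vapply(endhit, function(h) length(h) > 0L, logical(1))
  fp <- sum(!pred_chain_match)

  sensitivity <- tp / n_truth
  pdr <- (tp + ptp) / n_truth
  precision <- if (n_pred > 0L) sum(pred_end_match) / n_pred else 0
  f1 <- if (sensitivity + precision > 0) {
    2 * sensitivity * precision / (sensitivity + precision)
  } else 0
  n_matching_pred <- sum(pred_chain_match)
  redundancy <- if (length(chain_matched_truth) > 0L) {
    n_matching_pred / length(chain_matched_truth)
  } else NA_real_

  structure(list(tp = tp, ptp = ptp, fn = fn, fp = fp,
                 n_truth = n_truth, n_predictions = n_pred,
                 sensitivity = sensitivity, precision = precision, f1 = f1,
                 pdr = pdr, redundancy = redundancy,
                 inv_redundancy = if (is.na(redundancy)) NA_real_
                                  else 1 / redundancy),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(paste0("<detection_result> TP=%d PTP=%d FN=%d FP=%d | ",
                     "Sen=%.3f Pre=%.3f F1=%.3f PDR=%.3f Red=%s\n"),
              x$tp, x$ptp, x$fn, x$fp, x$sensitivity, x$precision, x$f1,
              x$pdr, ifelse(is.na(x$redundancy), "NA",
                            sprintf("%.2f", x$redundancy))))
  invisible(x)
}

#' Long-read coverage fraction of a transcript model
#'
#' Fraction of the model's sequence length covered by one or more reads:
#' the merged length of the covering intervals divided by the model length.
#'
#' @param model_length Transcript length in nt.
#' @param covered Two-column matrix of half-open intervals in transcript
#'   coordinates `[0, model_length)`; may overlap.
#' @return Fraction in `[0, 1]`.
#' @export
lrc <- function(model_length, covered) {
  stopifnot(model_length > 0)
  if (is.null(covered) || length(covered) == 0L) return(0)
  covered <- matrix(as.numeric(covered), ncol = 2L)
  if (any(covered[, 1L] < 0) || any(covered[, 2L] > model_length) ||
      any(covered[, 1L] >= covered[, 2L]))
    stop("coverage intervals must satisfy 0 <= start < end <= model_length")
  covered <- covered[order(covered[, 1L]), , drop = FALSE]
  tot <- 0; cur_s <- covered[1L, 1L]; cur_e <- covered[1L, 2L]
  for (i in seq_len(nrow(covered))[-1L]) {
    if (covered[i, 1L] <= cur_e) {
      cur_e <- max(cur_e, covered[i, 2L])
    } else {
      tot <- tot + (cur_e - cur_s); cur_s <- covered[i, 1L]; cur_e <- covered[i, 2L]
    }
  }
  tot <- tot + (cur_e - cur_s)
  tot / model_length
}

# distinct multi-exon chain keys of a list of models
ujc_set <- function(models) {
  chains <- lapply(models, junction_chain)
  chains <- chains[vapply(chains, function(ch) nrow(ch$introns) > 0L,
                          logical(1))]
  unique(vapply(chains, chain_key, character(1)))
}

#' Pairwise agreement of unique junction chains across submissions
#'
#' Row-normalized asymmetric overlap: entry (r, c) is the fraction of row
#' submission r's distinct chains also reported by column submission c.
#'
#' @param submissions Named list; each element either a list of
#'   [transcript_model] or a character vector of chain keys.
#' @return An object of class `agreement_matrix`: the `overlap` matrix plus
#'   per-submission chain counts.  Rows of empty submissions are `NaN`.
#' @export
pairwise_ujc_overlap <- function(submissions) {
  stopifnot(length(submissions) >= 2L)
  if (is.null(names(submissions)))
    names(submissions) <- paste0("sub", seq_along(submissions))
  sets <- lapply(submissions, function(s)
    if (is.character(s)) unique(s) else ujc_set(s))
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (r in seq_len(n)) for (c in seq_len(n)) {
    m[r, c] <- if (length(sets[[r]]) == 0L) NaN else
      length(intersect(sets[[r]], sets[[c]])) / length(sets[[r]])
  }
  structure(list(overlap = m,
                 sizes = vapply(sets, length, integer(1))),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat("<agreement_matrix> row-normalized UJC overlap\n")
  print(round(x$overlap, 3))
  invisible(x)
}

#' Detection agreement histogram across submissions
#'
#' For every distinct junction chain in the union of the submissions,
#' counts how many submissions report it, stratified by the structural
#' category of one representative model of that chain against `catalog`.
#'
#' @param submissions Named list of model lists (>= 2).
#' @param catalog A [build_catalog()] reference for category stratification,
#'   or `NULL` to skip stratification.
#' @return Data frame `chain`, `n_detecting`, `category`.
#' @export
detection_agreement <- function(submissions, catalog = NULL) {
  stopifnot(length(submissions) >= 2L)
  per_sub <- lapply(submissions, ujc_set)
  all_keys <- unique(unlist(per_sub, use.names = FALSE))
  n_det <- vapply(all_keys, function(k)
    sum(vapply(per_sub, function(s) k %in% s, logical(1))), integer(1))
  cat_of <- rep(NA_character_, length(all_keys))
  if (!is.null(catalog)) {
    # one representative model per chain
    reps <- list()
    for (sub in submissions) {
      for (mdl in sub) {
        ch <- junction_chain(mdl)
        if (nrow(ch$introns) == 0L) next
        k <- chain_key(ch)
        if (is.null(reps[[k]])) reps[[k]] <- mdl
      }
    }
    cat_of <- vapply(all_keys, function(k)
      classify(reps[[k]], catalog)$category, character(1))
  }
  data.frame(chain = all_keys, n_detecting = n_det, category = cat_of,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Distribution of transcripts per locus
#'
#' Clusters the models into loci with [group_loci()] and tabulates locus
#' sizes.
#'
#' @param models List of [transcript_model].
#' @param pool_strands Passed to [group_loci()].
#' @return Data frame `n_transcripts`, `n_loci`.
#' @export
transcripts_per_locus <- function(models, pool_strands = FALSE) {
  loci <- group_loci(models, pool_strands = pool_strands)
  sizes <- vapply(loci, function(l) length(l$members), integer(1))
  tab <- table(sizes)
  data.frame(n_transcripts = as.integer(names(tab)),
             n_loci = as.integer(tab), row.names = NULL)
}
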