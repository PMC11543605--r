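# Challenge-2 style quantification evaluation statistics.  Ground-truth
# metrics (SCC, MRD, NRMSE, PET) take named abundance vectors in TPM;
# replicate metrics (IM/ACVC, CM/ACC) take a quant_matrix; RE takes a single
# abundance vector.  All logs are natural.

#' Spearman correlation between estimate and ground truth
#'
#' Rank correlation (average ranks on ties) over the ground-truth id set;
#' estimates for unreported ids count as 0.
#'
#' @param est Named numeric vector of estimated TPM.
#' @param truth Named numeric vector of ground-truth TPM.
#' @return Correlation in `[-1, 1]`, or `NA` when either vector is constant.
#' @export
scc <- function(est, truth) {
  a <- align_to_truth(est, truth)
  if (stats::sd(a$est) == 0 || stats::sd(a$truth) == 0) return(NA_real_)
  stats::cor(a$est, a$truth, method = "spearman")
}

#' Median relative difference
#'
#' Median of `|theta_i - thetahat_i| / theta_i` over transcripts with
#' positive ground truth (the relative difference is undefined at
#' `theta_i = 0`).
#'
#' @inheritParams scc
#' @return Non-negative scalar.
#' @export
mrd <- function(est, truth) {
  a <- align_to_truth(est, truth)
  pos <- a$truth > 0
  if (!any(pos)) stop("MRD undefined: no transcript has positive ground truth")
  stats::median(abs(a$truth[pos] - a$est[pos]) / a$truth[pos])
}

#' Normalized root mean square error
#'
#' RMSE between estimate and ground truth divided by the sample (n-1)
#' standard deviation of the ground truth; invariant under joint positive
#' scaling of both vectors.
#'
#' @inheritParams scc
#' @return Non-negative scalar.
#' @export
nrmse <- function(est, truth) {
  a <- align_to_truth(est, truth)
  if (length(a$truth) < 2L) stop("NRMSE needs at least 2 transcripts")
  s <- stats::sd(a$truth)
  if (s == 0) stop("NRMSE undefined: constant ground truth")
  sqrt(mean((a$truth - a$est)^2)) / s
}

#' Irreproducibility measure and CV curve
#'
#' For every transcript x group cell, the coefficient of variation of
#' `log(TPM + 1)` across replicates: `CV_ig = s_ig / u_ig` with
#' `u_ig` the replicate mean and `s_ig = sqrt(mean((x - u_ig)^2))` (the
#' printed replicate s.d., dividing by R).  `IM = sqrt(mean(CV_ig^2))` over
#' the cells where the CV is defined (`u_ig > 0`); all-zero cells are
#' excluded and counted.  The CV-versus-abundance curve is summarized by
#' ACVC, the trapezoidal area under bin-averaged CV against bin-averaged
#' `u_ig` over `bins` equal-frequency bins.
#'
#' @param q A [quant_matrix] with `R >= 2`.
#' @param bins Number of equal-frequency abundance bins for the curve.
#' @return List: `IM`, `ACVC`, `curve` (data frame `u`, `cv`, `n`),
#'   `n_excluded` (all-zero cells), `cv_table` (per-cell `u`, `cv`).
#' @export
irreproducibility <- function(q, bins = 50) {
  stopifnot(inherits(q, "quant_matrix"))
  if (q$R < 2L) stop("IM needs at least 2 replicates per group")
  lv <- log(q$values + 1)
  us <- cvs <- numeric(0)
  for (g in q$groups) {
    xg <- lv[, q$col_groups == g, drop = FALSE]
    u <- rowMeans(xg)
    s <- sqrt(rowMeans((xg - u)^2))
    us <- c(us, u); cvs <- c(cvs, ifelse(u > 0, s / u, NA_real_))
  }
  defined <- !is.na(cvs)
  n_excluded <- sum(!defined)
  im <- sqrt(mean(cvs[defined]^2))

  u_d <- us[defined]; cv_d <- cvs[defined]
  ord <- order(u_d)
  u_d <- u_d[ord]; cv_d <- cv_d[ord]
  nb <- min(bins, length(u_d))
  idx <- ceiling(seq_along(u_d) / (length(u_d) / nb))
  curve <- data.frame(u = tapply(u_d, idx, mean),
                      cv = tapply(cv_d, idx, mean),
                      n = as.integer(table(idx)), row.names = NULL)
  acvc <- if (nrow(curve) >= 2L) trapezoid(curve$u, curve$cv) else 0
  list(IM = im, ACVC = acvc, curve = curve, n_excluded = n_excluded,
       cv_table = data.frame(u = us, cv = cvs))
}

#' Consistency curve between replicate pairs
#'
#' For a threshold `alpha` on `log(TPM + 1)`, two replicates agree on a
#' transcript when both values fall below the threshold or both fall at or
#' above it.  `C(alpha)` is the agreement fraction over all transcript x
#' group x replicate-pair events; `C(0) = 1` since log abundances are
#' non-negative.  The scalar CM is `C` at `cm_alpha`, and ACC the
#' trapezoidal area of the curve over the grid.
#'
#' @param q A [quant_matrix] with `R >= 2`.
#' @param alpha_grid Thresholds for the curve (default 0..10 by 0.1).
#' @param cm_alpha Threshold at which the scalar CM is taken (default 1).
#' @return List: `CM`, `ACC`, `curve` (data frame `alpha`, `C`).
#' @export
consistency <- function(q, alpha_grid = seq(0, 10, by = 0.1), cm_alpha = 1) {
  stopifnot(inherits(q, "quant_matrix"))
  if (q$R < 2L) stop("consistency needs at least 2 replicates per group")
  lv <- log(q$values + 1)
  pairs <- utils::combn(q$R, 2L)
  c_at <- function(alpha) {
    agree <- 0L; total <- 0L
    for (g in q$groups) {
      xg <- lv[, q$col_groups == g, drop = FALSE]
      b <- xg >= alpha
      for (p in seq_len(ncol(pairs))) {
        agree <- agree + sum(b[, pairs[1L, p]] == b[, pairs[2L, p]])
        total <- total + nrow(b)
      }
    }
    agree / total
  }
  cvals <- vapply(alpha_grid, c_at, numeric(1))
  list(CM = c_at(cm_alpha),
       ACC = trapezoid(alpha_grid, cvals),
       curve = data.frame(alpha = alpha_grid, C = cvals))
}

#' Resolution entropy of an abundance profile
#'
#' Bins the estimates into `M` equal-width bins of width `max(est)/M`
#' (top edge inclusive, so the maximum is always counted) and returns the
#' Shannon entropy `-sum P_m ln P_m` of the bin occupancy over non-empty
#' bins.  0 when all transcripts share one value (everything lands in one
#' bin); `ln(M)` when the bins are uniformly occupied.  An all-zero profile
#' returns 0 by convention.
#'
#' @param est Numeric vector of estimated TPM.
#' @param M Number of bins (default 100).
#' @return Entropy in nats, in `[0, ln(M)]`.
#' @export
resolution_entropy <- function(est, M = 100) {
  stopifnot(M >= 1L, all(est >= 0))
  mx <- max(est)
  if (mx == 0) return(0)
  alpha <- mx / M
  idx <- floor(est / alpha)
  idx[idx >= M] <- M - 1L   # top edge inclusive
  p <- as.numeric(table(idx))
  p <- p / sum(p)
  max(0, -sum(p * log(p)))   # max() also normalizes IEEE -0 to 0
}

#' Percentage of expressed transcripts
#'
#' Percentage of a ground-truth transcript set quantified with TPM above
#' zero.
#'
#' @param est Named numeric vector of estimated TPM.
#' @param truly_expressed_ids Character vector of ground-truth ids.
#' @param threshold Expression threshold (default 0, i.e. TPM > 0).
#' @return Percentage in `[0, 100]`.
#' @export
pet <- function(est, truly_expressed_ids, threshold = 0) {
  stopifnot(length(truly_expressed_ids) > 0L)
  v <- est[truly_expressed_ids]
  v[is.na(v)] <- 0
  100 * sum(v > threshold) / length(truly_expressed_ids)
}

#' Exon-isoform binary matrix of a gene
#'
#' Rows are the gene's isoforms, columns its exons, entries 1 when the
#' isoform includes the exon.  Exon identity defaults to the distinct exact
#' `(start, end)` exon intervals across the isoforms; `mode = "segments"`
#' instead uses the disjoint genomic segments induced by all exon
#' boundaries (an isoform includes a segment when one of its exons covers
#' it).
#'
#' @param gene_isoforms List of [transcript_model] of one gene.
#' @param mode `"exact"` (default) or `"segments"`.
#' @return Binary matrix, isoform ids as rownames.
#' @export
exon_isoform_matrix <- function(gene_isoforms, mode = c("exact", "segments")) {
  mode <- match.arg(mode)
  stopifnot(length(gene_isoforms) >= 1L)
  ids <- vapply(gene_isoforms, `[[`, character(1), "transcript_id")
  if (mode == "exact") {
    keys <- lapply(gene_isoforms, function(t)
      paste0(t$exons[, 1L], "-", t$exons[, 2L]))
    all_keys <- unique(unlist(keys))
    A <- t(vapply(keys, function(k) as.numeric(all_keys %in% k),
                  numeric(length(all_keys))))
    if (length(all_keys) == 1L) A <- matrix(A, ncol = 1L)
    dimnames(A) <- list(ids, all_keys)
  } else {
    bp <- sort(unique(unlist(lapply(gene_isoforms, function(t)
      c(t$exons[, 1L], t$exons[, 2L])))))
    seg <- cbind(bp[-length(bp)], bp[-1L])
    covers <- function(t, s, e) any(t$exons[, 1L] <= s & e <= t$exons[, 2L])
    A <- t(vapply(gene_isoforms, function(t)
      vapply(seq_len(nrow(seg)), function(j)
        as.numeric(covers(t, seg[j, 1L], seg[j, 2L])), numeric(1)),
      numeric(nrow(seg))))
    if (nrow(seg) == 1L) A <- matrix(A, ncol = 1L)
    keep <- colSums(A) > 0
    A <- A[, keep, drop = FALSE]
    dimnames(A) <- list(ids, paste0(seg[keep, 1L], "-", seg[keep, 2L]))
  }
  A
}

#' K-value: condition number of the exon-isoform matrix
#'
#' The ratio of the largest to the smallest singular value of the gene's
#' exon-isoform binary matrix; higher values mean more entangled isoform
#' structure (harder quantification).  A rank-deficient matrix (e.g. two
#' isoforms with identical exon content) yields `Inf`.
#'
#' @param gene_isoforms List of [transcript_model] of one gene, or a
#'   pre-built binary matrix.
#' @param mode Exon identity mode, see [exon_isoform_matrix()].
#' @return Condition number `>= 1`, possibly `Inf`.
#' @export
k_value <- function(gene_isoforms, mode = c("exact", "segments")) {
  A <- if (is.matrix(gene_isoforms)) gene_isoforms
       else exon_isoform_matrix(gene_isoforms, mode = match.arg(mode))
  sv <- svd(A, nu = 0, nv = 0)$d
  if (min(sv) < 1e-12 * max(sv)) return(Inf)
  max(sv) / min(sv)
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}
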