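# Hand-built miniature reference used across classifier tests.
# Gene A (+, chr1): 5-exon skeleton plus an exon-3-skipping isoform.
# Gene B (+, chr1): two isoforms using alternative splice sites.
# Gene C (-, chr1): mono-exon gene.
# Gene D (-, chr1): 2-exon gene.
mini_reference <- function() {
  list(
    A1 = transcript_model("A1", "geneA", "chr1", "+",
                          cbind(c(100, 300, 500, 700, 900),
                                c(200, 400, 600, 800, 1000))),
    A2 = transcript_model("A2", "geneA", "chr1", "+",
                          cbind(c(100, 300, 700, 900),
                                c(200, 400, 800, 1000))),
    B1 = transcript_model("B1", "geneB", "chr1", "+",
                          cbind(c(5000, 5200, 5400),
                                c(5100, 5300, 5500))),
    B2 = transcript_model("B2", "geneB", "chr1", "+",
                          cbind(c(5000, 5220, 5430),
                                c(5120, 5320, 5500))),
    C1 = transcript_model("C1", "geneC", "chr1", "-",
                          cbind(7000, 7600)),
    D1 = transcript_model("D1", "geneD", "chr1", "-",
                          cbind(c(9000, 9400), c(9200, 9600))))
}

mini_catalog <- function() build_catalog(mini_reference())

tm <- function(id, exons, strand = "+", gene = "q", chrom = "chr1")
  transcript_model(id, gene, chrom, strand, exons)

# ---------------------------------------------------------------------------
# Independent step-by-step transcriptions of the printed metric formulas.
# These deliberately use plain loops / base definitions, not the package's
# code paths.

oracle_scc <- function(est, truth) {
  rg1 <- rank(truth); rg2 <- rank(est)
  n <- length(rg1)
  cv <- sum((rg1 - mean(rg1)) * (rg2 - mean(rg2))) / (n - 1)
  cv / (sd(rg1) * sd(rg2))
}

oracle_mrd <- function(est, truth) {
  keep <- truth > 0
  median(abs(truth[keep] - est[keep]) / truth[keep])
}

oracle_nrmse <- function(est, truth) {
  I <- length(truth)
  sqrt(sum((truth - est)^2) / I) / sd(truth)
}

# x: array I x G x R of TPM estimates
oracle_im <- function(x) {
  I <- dim(x)[1]; G <- dim(x)[2]; R <- dim(x)[3]
  cvs <- c()
  for (i in seq_len(I)) for (g in seq_len(G)) {
    lv <- log(x[i, g, ] + 1)
    u <- sum(lv) / R
    s <- sqrt(sum((lv - u)^2) / R)
    if (u > 0) cvs <- c(cvs, s / u)
  }
  sqrt(sum(cvs^2) / length(cvs))
}

oracle_c_alpha <- function(x, alpha) {
  I <- dim(x)[1]; G <- dim(x)[2]; R <- dim(x)[3]
  hits <- 0; total <- 0
  for (i in seq_len(I)) for (g in seq_len(G))
    for (r1 in seq_len(R - 1)) for (r2 in (r1 + 1):R) {
      a <- log(x[i, g, r1] + 1); b <- log(x[i, g, r2] + 1)
      hits <- hits + as.numeric((a < alpha && b < alpha) ||
                                  (a >= alpha && b >= alpha))
      total <- total + 1
    }
  hits / total
}

oracle_re <- function(v, M) {
  mx <- max(v)
  if (mx == 0) return(0)
  alpha <- mx / M
  n <- rep(0, M)
  for (val in v) {
    m <- floor(val / alpha)
    if (m >= M) m <- M - 1
    n[m + 1] <- n[m + 1] + 1
  }
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

oracle_pet <- function(est, truth_ids) {
  hit <- 0
  for (id in truth_ids) {
    v <- est[id]
    if (!is.na(v) && v > 0) hit <- hit + 1
  }
  100 * hit / length(truth_ids)
}

# condition number via eigenvalues of the Gram matrix
oracle_k <- function(A) {
  G <- if (nrow(A) <= ncol(A)) A %*% t(A) else t(A) %*% A
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  if (min(ev) < 1e-24 * max(ev)) return(Inf)
  sqrt(max(ev) / min(ev))
}

# quant_matrix -> I x G x R array for the oracles
qm_array <- function(q) {
  I <- nrow(q$values); G <- length(q$groups); R <- q$R
  x <- array(0, c(I, G, R))
  for (g in seq_len(G))
    x[, g, ] <- q$values[, q$col_groups == q$groups[g], drop = FALSE]
  x
}

# Brute-force structural classifier over tiny catalogs (category only; no
# fusion/subtype logic): enumerates every reference transcript directly.
oracle_classify <- function(query, reference) {
  qch <- junction_chain(query)
  eq_chain <- function(a, b) nrow(a$introns) == nrow(b$introns) &&
    a$chrom == b$chrom && a$strand == b$strand &&
    all(a$introns == b$introns)
  sub_chain <- function(a, b) {
    na <- nrow(a$introns); nb <- nrow(b$introns)
    if (na == 0 || na >= nb) return(FALSE)
    for (off in 0:(nb - na))
      if (all(a$introns == b$introns[off + seq_len(na), , drop = FALSE]))
        return(TRUE)
    FALSE
  }
  overl <- function(q, r) {
    if (q$chrom != r$chrom || q$strand != r$strand) return(FALSE)
    for (i in seq_len(nrow(q$exons)))
      for (j in seq_len(nrow(r$exons)))
        if (q$exons[i, 1] < r$exons[j, 2] && r$exons[j, 1] < q$exons[i, 2])
          return(TRUE)
    FALSE
  }
  for (r in reference)
    if (eq_chain(qch, junction_chain(r))) return("FSM")
  assoc <- Filter(function(r) overl(query, r), reference)
  for (r in assoc)
    if (sub_chain(qch, junction_chain(r))) return("ISM")
  if (length(assoc) == 0) return("other")
  donors <- acceptors <- character(0)
  for (r in reference) {
    rch <- junction_chain(r)
    if (nrow(rch$introns) == 0) next
    d <- if (r$strand == "+") rch$introns[, 1] else rch$introns[, 2]
    a <- if (r$strand == "+") rch$introns[, 2] else rch$introns[, 1]
    donors <- c(donors, paste(r$chrom, r$strand, d))
    acceptors <- c(acceptors, paste(r$chrom, r$strand, a))
  }
  qd <- if (query$strand == "+") qch$introns[, 1] else qch$introns[, 2]
  qa <- if (query$strand == "+") qch$introns[, 2] else qch$introns[, 1]
  if (any(!paste(query$chrom, query$strand, qd) %in% donors) ||
      any(!paste(query$chrom, query$strand, qa) %in% acceptors))
    return("NNC")
  "NIC"
}
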