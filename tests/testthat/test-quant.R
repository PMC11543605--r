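# Quantification statistics against independent formula transcriptions.

test_that("SCC follows the rank-covariance definition", {
  truth <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(scc(truth, truth), 1)
  expect_equal(scc(rev(unname(truth)) |> stats::setNames(names(truth)), truth), -1)
  est <- c(a = 1, b = 3, c = 2, d = 4)
  expect_equal(scc(est, truth), 0.8)
  expect_equal(scc(est, truth), oracle_scc(est[names(truth)], truth),
               tolerance = 1e-12)
  # invariant under strictly increasing transforms
  expect_equal(scc(exp(est), truth^3 + 1), scc(est, truth))
  # constant input is undefined
  expect_true(is.na(scc(c(a = 1, b = 1), c(a = 5, b = 5))))
  # unreported ids count as zero estimates
  expect_equal(scc(c(a = 1), c(a = 1, b = 2, c = 3)),
               oracle_scc(c(1, 0, 0), c(1, 2, 3)))
})

test_that("MRD is the median relative difference over expressed truth", {
  truth <- c(x = 10, y = 10)
  expect_equal(mrd(truth, truth), 0)
  expect_equal(mrd(c(x = 5, y = 20), truth), 0.75)
  expect_equal(mrd(c(z = 5), c(z = 4)), 0.25)
  expect_error(mrd(c(a = 1), c(a = 0)), "positive")
  est <- c(x = 3, y = 12)
  expect_equal(mrd(est, truth), oracle_mrd(est, truth), tolerance = 1e-12)
})

test_that("NRMSE is scale-invariant RMSE over the truth s.d.", {
  truth <- c(a = 0, b = 10)
  expect_equal(nrmse(truth, truth), 0)
  expect_equal(nrmse(c(a = 0, b = 0), truth), 1)
  t2 <- c(a = 3, b = 8, c = 1, d = 9)
  e2 <- c(a = 2, b = 9, c = 0, d = 12)
  expect_equal(nrmse(e2, t2), oracle_nrmse(e2, t2), tolerance = 1e-12)
  expect_equal(nrmse(7 * e2, 7 * t2), nrmse(e2, t2), tolerance = 1e-12)
  expect_error(nrmse(c(a = 1, b = 2), c(a = 5, b = 5)), "constant")
})

test_that("IM matches the printed replicate-CV formula", {
  # one transcript, one group, two replicates with log(TPM+1) = 1 and 3:
  # u = 2, s = sqrt(((1-2)^2 + (3-2)^2)/2) = 1, CV = 1/2, IM = 1/2
  v <- matrix(c(exp(1) - 1, exp(3) - 1), nrow = 1)
  q <- quant_matrix(v, c("g1", "g1"), c("r1", "r2"))
  expect_equal(irreproducibility(q)$IM, 0.5, tolerance = 1e-12)

  # identical replicates: nothing irreproducible
  v2 <- matrix(rep(c(5, 9, 0), 2), ncol = 2,
               dimnames = list(c("a", "b", "c"), NULL))
  q2 <- quant_matrix(v2, c("g1", "g1"), c("r1", "r2"))
  ir <- irreproducibility(q2)
  expect_equal(ir$IM, 0)
  expect_equal(ir$ACVC, 0)
  expect_equal(ir$n_excluded, 1L)  # the all-zero transcript

  # random instance against the loop oracle
  set.seed(8)
  v3 <- matrix(rexp(6 * 6, rate = 0.05), nrow = 6)
  q3 <- quant_matrix(v3, rep(c("g1", "g2"), each = 3), rep(1:3, 2))
  expect_equal(irreproducibility(q3)$IM, oracle_im(qm_array(q3)),
               tolerance = 1e-12)
  expect_error(irreproducibility(quant_matrix(v3[, 1, drop = FALSE],
                                              "g1", "r1")),
               "2 replicates")
})

test_that("consistency curves match the indicator definition", {
  # log values 0.5 and 1.5 disagree at alpha = 1
  v <- matrix(c(exp(0.5) - 1, exp(1.5) - 1), nrow = 1)
  q <- quant_matrix(v, c("g", "g"), c("r1", "r2"))
  cc <- consistency(q, alpha_grid = c(0, 1, 2))
  expect_equal(cc$CM, 0)
  expect_equal(cc$curve$C[cc$curve$alpha == 0], 1)   # all >= 0
  expect_equal(cc$curve$C[cc$curve$alpha == 2], 1)   # all below
  set.seed(12)
  v2 <- matrix(rexp(5 * 6, 0.1), nrow = 5)
  q2 <- quant_matrix(v2, rep(c("a", "b"), each = 3), rep(1:3, 2))
  for (alpha in c(0, 0.7, 2.3)) {
    expect_equal(consistency(q2, alpha_grid = c(0, alpha), cm_alpha = alpha)$CM,
                 oracle_c_alpha(qm_array(q2), alpha), tolerance = 1e-12)
  }
})

test_that("resolution entropy spans 0 to ln(M)", {
  expect_equal(resolution_entropy(rep(7.3, 50)), 0)
  expect_equal(resolution_entropy(rep(0, 10)), 0)
  # two equal-mass bins
  expect_equal(resolution_entropy(c(rep(1, 5), rep(100, 5)), M = 2), log(2))
  # uniformly filled bins reach the maximum
  M <- 100
  v <- (seq_len(M) - 0.5) * (10 / M)
  expect_equal(resolution_entropy(v, M = M), log(M))
  set.seed(3)
  v2 <- rexp(40, 0.2)
  expect_equal(resolution_entropy(v2, M = 25), oracle_re(v2, 25),
               tolerance = 1e-12)
})

test_that("PET counts expressed ground-truth transcripts", {
  est <- c(a = 1, b = 0, c = 2, d = 5)
  expect_equal(pet(est, c("a", "c", "d")), 100)
  expect_equal(pet(est, c("a", "b", "c", "d")), 75)
  expect_equal(pet(c(a = 0), c("a", "zz")), 0)
  expect_equal(pet(est, names(est)), oracle_pet(est, names(est)))
})

test_that("K-value is the exon-isoform condition number", {
  g <- list(tm("i1", cbind(c(0, 200), c(100, 300)), gene = "g"),
            tm("i2", cbind(200, 300), gene = "g"))
  A <- exon_isoform_matrix(g)
  expect_equal(unname(A), rbind(c(1, 1), c(0, 1)))
  # singular values of [[1,1],[0,1]]: sqrt((3 +/- sqrt(5))/2), whose ratio
  # is the squared golden ratio (3 + sqrt(5))/2
  expect_equal(k_value(g), (3 + sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(k_value(g), oracle_k(A), tolerance = 1e-12)

  single <- list(tm("i1", cbind(c(0, 200, 400), c(100, 300, 500)), gene = "g"))
  expect_equal(k_value(single), 1)

  dup <- c(g[1], list(tm("i3", cbind(c(0, 200), c(100, 300)), gene = "g")))
  expect_equal(k_value(dup[c(1, 2)]), Inf)

  # disjoint-segment construction differs when exon ends vary
  alt <- list(tm("i1", cbind(0, 300), gene = "g"),
              tm("i2", cbind(100, 300), gene = "g"))
  expect_equal(ncol(exon_isoform_matrix(alt, mode = "segments")), 2L)
  expect_equal(ncol(exon_isoform_matrix(alt, mode = "exact")), 2L)
  expect_equal(unname(exon_isoform_matrix(alt, mode = "segments")),
               rbind(c(1, 1), c(0, 1)))
})

test_that("mixing expectation is the renormalized weighted mean", {
  a <- c(t1 = 2e5, t2 = 8e5)
  b <- c(t1 = 6e5, t2 = 4e5)
  expect_equal(mixing_expected(a, b, 1), a)
  expect_equal(mixing_expected(a, b, 0), b)
  expect_equal(mixing_expected(a, b, 0.5), c(t1 = 4e5, t2 = 6e5))
  expect_equal(mixing_expected(a, a, 0.3), a)
  expect_error(mixing_expected(a, b, 1.2), "\\[0, 1\\]")

  ev <- evaluate_mixing(mixing_expected(a, b, 0.3), a, b, 0.3)
  expect_equal(ev$SCC, 1)
  expect_equal(ev$MRD, 0)
  expect_equal(ev$NRMSE, 0)
})

test_that("stratified reports recompute metrics per feature bin", {
  set.seed(5)
  ids <- sprintf("t%03d", 1:200)
  truth <- stats::setNames(rlnorm(200, 1, 1.5), ids)
  noise_lo <- exp(rnorm(200, 0, 0.1))
  est <- truth * noise_lo
  feature <- stats::setNames(truth, ids)

  one_bin <- stratified_report(est, truth, feature,
                               breaks = c(0, max(truth) + 1))
  expect_equal(one_bin$MRD[1], mrd(est, truth), tolerance = 1e-12)
  expect_equal(one_bin$SCC[1], scc(est, truth), tolerance = 1e-12)
  expect_equal(one_bin$n[1], 200L)

  # low-abundance transcripts get noisier estimates -> higher MRD there
  noisy <- truth
  lo <- truth <= 2
  noisy[lo] <- truth[lo] * exp(rnorm(sum(lo), 0, 1))
  noisy[!lo] <- truth[!lo] * exp(rnorm(sum(!lo), 0, 0.05))
  rep2 <- stratified_report(noisy, truth, feature, breaks = c(0, 2, Inf))
  expect_equal(sum(rep2$n), 200L)
  expect_gt(rep2$MRD[1], rep2$MRD[2])
  expect_equal(rep2$MRD_norm, c(1, 0))

  # transcript features derive from the annotation
  ref <- mini_reference()
  feats <- transcript_features(ref)
  expect_equal(feats$n_exons[feats$transcript_id == "A1"], 5L)
  expect_equal(feats$n_isoforms[feats$transcript_id == "B2"], 2L)
  expect_equal(feats$length[feats$transcript_id == "C1"], 600)
  expect_true(all(feats$k_value >= 1))
})

test_that("quant tables round-trip through long and wide TSV", {
  set.seed(6)
  v <- matrix(rexp(8, 0.1), nrow = 2,
              dimnames = list(c("tx1", "tx2"), NULL))
  q <- quant_matrix(v, rep(c("g1", "g2"), each = 2), rep(c("r1", "r2"), 2))
  wide <- tempfile(fileext = ".tsv")
  write_quant_tsv(q, wide)
  q2 <- read_quant_tsv(wide)
  expect_equal(q2$values, q$values)
  expect_equal(q2$R, 2L)

  long <- tempfile(fileext = ".tsv")
  df <- data.frame(transcript_id = rep(rownames(v), 4),
                   group = rep(rep(c("g1", "g2"), each = 2), each = 2),
                   replicate = rep(rep(c("r1", "r2"), 2), each = 2),
                   TPM = as.vector(v))
  utils::write.table(df, long, sep = "\t", quote = FALSE, row.names = FALSE)
  q3 <- read_quant_tsv(long)
  expect_equal(unname(q3$values), unname(q$values))

  tr <- tempfile(fileext = ".tsv")
  write_truth_tsv(c(tx1 = 5.5, tx2 = 0), tr)
  expect_equal(read_truth_tsv(tr), c(tx1 = 5.5, tx2 = 0))
})
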