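# Structural categories, end/junction support flags and submission tables.

test_that("chain identity and truncation give FSM and ISM", {
  cat <- mini_catalog()
  # exact chain of A1, jittered ends
  fsm <- tm("q_fsm", cbind(c(130, 300, 500, 700, 900),
                           c(200, 400, 600, 800, 1040)))
  call <- classify(fsm, cat)
  expect_equal(call$category, "FSM")
  expect_equal(call$matched_reference_id, "A1")

  # introns 2-3 of A1's 4-intron chain
  ism <- tm("q_ism", cbind(c(300, 500, 700), c(400, 600, 800)))
  call <- classify(ism, cat)
  expect_equal(call$category, "ISM")
  expect_equal(call$matched_reference_id, "A1")
  expect_equal(chain_length_ratios(call, ism, cat), 0.5)
})

test_that("FSM ties break to the reference with closest ends", {
  r1 <- tm("r1", cbind(c(0, 200), c(100, 300)), gene = "g")
  r2 <- tm("r2", cbind(c(40, 200), c(100, 260)), gene = "g")
  cat <- build_catalog(list(r1, r2))
  q <- tm("q", cbind(c(35, 200), c(100, 265)))
  expect_equal(classify(q, cat)$matched_reference_id, "r2")
})

test_that("NIC splits into combination, novel junction and intron retention", {
  cat <- mini_catalog()
  # intron 1 of B1 combined with intron 2 of B2: all junctions annotated
  combo <- tm("q_combo", cbind(c(5000, 5200, 5430), c(5100, 5320, 5500)))
  call <- classify(combo, cat)
  expect_equal(call$category, "NIC")
  expect_equal(call$nic_reason, "junction-combination")

  # skipping A1 exon 4: novel junction (600,900) between annotated sites
  novel <- tm("q_nj", cbind(c(100, 300, 500, 900), c(200, 400, 600, 1000)))
  call <- classify(novel, cat)
  expect_equal(call$category, "NIC")
  expect_equal(call$nic_reason, "novel-junction-known-sites")

  # exon (300,600) spans annotated intron (400,500) entirely
  ir <- tm("q_ir", cbind(c(100, 300, 700, 900), c(200, 600, 800, 1000)))
  call <- classify(ir, cat)
  expect_equal(call$category, "NIC")
  expect_equal(call$nic_reason, "intron-retention")
})

test_that("novel donors or acceptors give NNC; overlap logic gives other", {
  cat <- mini_catalog()
  # acceptor shifted 10 nt inside annotated exon 2
  nnc <- tm("q_nnc", cbind(c(100, 310, 500, 700, 900),
                           c(200, 400, 600, 800, 1000)))
  expect_equal(classify(nnc, cat)$category, "NNC")

  # antisense: spliced query on the opposite strand of gene A
  anti <- tm("q_anti", cbind(c(150, 350), c(250, 450)), strand = "-")
  call <- classify(anti, cat)
  expect_equal(call$category, "other")
  expect_equal(call$other_subtype, "antisense")

  # fusion: junctions bridging gene A and gene B loci
  fus <- tm("q_fus", cbind(c(900, 5000, 5200), c(1000, 5100, 5300)))
  call <- classify(fus, cat)
  expect_equal(call$other_subtype, "fusion")

  # intergenic multi-exon
  inter <- tm("q_int", cbind(c(20000, 20200), c(20100, 20300)))
  expect_equal(classify(inter, cat)$other_subtype, "intergenic")
})

test_that("mono-exon queries follow the end-window overlap rule", {
  cat <- mini_catalog()
  m1 <- tm("m1", cbind(7005, 7595), strand = "-")
  call <- classify(m1, cat)
  expect_equal(call$other_subtype, "mono-exon-match")
  expect_equal(call$matched_reference_id, "C1")

  # inside an intron of gene A, same strand
  m2 <- tm("m2", cbind(250, 290))
  expect_equal(classify(m2, cat)$other_subtype, "genic")

  # opposite strand of gene C
  m3 <- tm("m3", cbind(7005, 7595), strand = "+")
  expect_equal(classify(m3, cat)$other_subtype, "antisense")

  m4 <- tm("m4", cbind(15000, 15200))
  expect_equal(classify(m4, cat)$other_subtype, "intergenic")

  # ends off by > window lose the mono-exon match but stay genic
  m5 <- tm("m5", cbind(7100, 7500), strand = "-")
  expect_equal(classify(m5, cat)$other_subtype, "genic")
})

test_that("reference end windows are inclusive at 50 nt and FSM-gated", {
  cat <- mini_catalog()
  at50 <- tm("q50", cbind(c(150, 300, 500, 700, 900),
                          c(200, 400, 600, 800, 1050)))
  call <- classify(at50, cat)
  mr <- match_reference(call, at50, cat, window = 50)
  expect_true(mr$ref_5p && mr$ref_3p && mr$reference_match)
  expect_equal(mr$tss_distance, 50)
  expect_equal(mr$tts_distance, 50)

  off51 <- tm("q51", cbind(c(151, 300, 500, 700, 900),
                           c(200, 400, 600, 800, 1000)))
  mr <- match_reference(classify(off51, cat), off51, cat, window = 50)
  expect_false(mr$ref_5p)
  expect_false(mr$reference_match)
  expect_true(mr$ref_3p)

  # window monotonicity: growing the window never revokes a match
  mr_wide <- match_reference(classify(off51, cat), off51, cat, window = 51)
  expect_true(mr_wide$reference_match)

  # ISM never yields reference_match, whatever the window
  ism <- tm("q_ism", cbind(c(300, 500, 700), c(400, 600, 800)))
  mr <- match_reference(classify(ism, cat), ism, cat, window = 1e6)
  expect_false(mr$reference_match)
})

test_that("experimental end support uses peaks and poly(A) hexamers", {
  q <- tm("q", cbind(c(100, 300), c(200, 400)))
  cage <- data.frame(chrom = "chr1", start = 90, end = 120, strand = "+")
  ev <- support_evidence(cage_peaks = cage)
  s <- evidence_support(q, ev)
  expect_true(s$cage_5p)
  expect_false(s$polya_3p)
  expect_false(s$polya_evaluable)

  # no evidence at all: flags false, nothing evaluable
  s0 <- evidence_support(q, support_evidence())
  expect_false(s0$cage_5p || s0$polya_3p)
  expect_false(s0$cage_evaluable || s0$polya_evaluable)

  # AATAAA 20 nt upstream of the 3' end on the + strand
  seq <- paste(rep("C", 500), collapse = "")
  substr(seq, 375, 380) <- "AATAAA"   # 0-based 374..380; 3' end at 400
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chr1"
  s <- evidence_support(q, support_evidence(genome = genome))
  expect_true(s$polya_3p)
  # motif on the wrong strand does not count
  qm <- tm("qm", cbind(c(100, 300), c(200, 400)), strand = "-")
  s <- evidence_support(qm, support_evidence(genome = genome))
  expect_false(s$polya_3p)

  expect_error(evidence_support(q, support_evidence(), check_motif = TRUE),
               "no genome")
})

test_that("SRTM and SNTM compose end support with novel-junction coverage", {
  cat <- mini_catalog()
  fsm <- tm("f", cbind(c(100, 300, 500, 700, 900),
                       c(200, 400, 600, 800, 1000)))
  call <- classify(fsm, cat)
  mr <- match_reference(call, fsm, cat)
  ss <- srtm_sntm(call, list(ref_5p = mr$ref_5p, polya_3p = TRUE))
  expect_true(ss$srtm)
  expect_true(is.na(ss$sntm))

  nnc <- tm("n", cbind(c(100, 310, 500, 700, 900),
                       c(200, 400, 600, 800, 1000)))
  call <- classify(nnc, cat)
  # supported ends but one novel junction with zero coverage
  ss <- srtm_sntm(call, list(cage_5p = TRUE, ref_3p = TRUE),
                  novel_junction_counts = c(0))
  expect_false(ss$sntm)
  ss <- srtm_sntm(call, list(cage_5p = TRUE, ref_3p = TRUE),
                  novel_junction_counts = c(3))
  expect_true(ss$sntm)
  expect_true(is.na(ss$srtm))
})

test_that("junction profiles report novelty, support and canonicity", {
  cat <- mini_catalog()
  # submission = reference subset: no novel junctions
  prof <- junction_profile(mini_reference()[c("A1", "B1")], cat)
  expect_equal(prof$pct_novel_junctions, 0)
  expect_true(is.na(prof$pct_noncanonical_junctions))  # no genome given
  expect_true(is.na(prof$pct_junctions_supported))     # no counts given

  # 4 junctions of A1, 3 supported
  a1 <- mini_reference()["A1"]
  keys <- paste0("chr1|+|", c("200-300", "400-500", "600-700", "800-900"))
  counts <- stats::setNames(c(5, 2, 1, 0), keys)
  prof <- junction_profile(a1, cat, support_evidence(junction_counts = counts))
  expect_equal(prof$pct_junctions_supported, 75)
  expect_equal(prof$pct_transcripts_fully_supported, 0)

  # constructed genome: intron (200,300) is CT-AC, (400,500) is GT-AG
  seq <- strsplit(paste(rep("A", 1200), collapse = ""), "")[[1]]
  seq[201:202] <- c("C", "T"); seq[299:300] <- c("A", "C")
  seq[401:402] <- c("G", "T"); seq[499:500] <- c("A", "G")
  seq[601:602] <- c("G", "T"); seq[699:700] <- c("A", "G")
  seq[801:802] <- c("G", "T"); seq[899:900] <- c("A", "G")
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- "chr1"
  expect_equal(splice_dinucleotides("chr1", "+", 200, 300, genome), "CT-AC")
  prof <- junction_profile(a1, cat, support_evidence(genome = genome))
  expect_equal(prof$pct_noncanonical_junctions, 25)
  expect_equal(prof$pct_noncanonical_transcripts, 100)
})

test_that("chain-length ratio covers the NIC/NNC side", {
  cat <- mini_catalog()
  nnc6 <- tm("q6", cbind(c(100, 310, 500, 700, 900, 1100, 1300),
                         c(200, 400, 600, 800, 1000, 1200, 1400)))
  call <- classify(nnc6, cat)
  expect_equal(call$category, "NNC")
  expect_equal(chain_length_ratios(call, nnc6, cat), 4 / 6)
  # FSM has no defined ratio
  fsm <- tm("f", cbind(c(100, 300, 500, 700, 900),
                       c(200, 400, 600, 800, 1000)))
  expect_true(is.na(chain_length_ratios(classify(fsm, cat), fsm, cat)))
})

test_that("classification satisfies closure, partition and jitter invariance", {
  cfg <- sim_config(seed = 21, n_models = 120)
  ann <- gen_annotation(cfg)
  sub <- gen_submission(ann$reference, cfg)
  cat <- build_catalog(ann$reference)

  # partition: every query gets exactly one category
  cats <- vapply(sub$models, function(q) classify(q, cat)$category, "")
  expect_length(cats, length(sub$models))
  expect_true(all(cats %in% c("FSM", "ISM", "NIC", "NNC", "other")))

  # closure: adding a query's own model to the catalog makes it FSM with a
  # perfect reference match at window 0
  for (q in sub$models[cats %in% c("NIC", "NNC")][1:3]) {
    cat2 <- build_catalog(c(ann$reference, stats::setNames(list(q), q$transcript_id)))
    call2 <- classify(q, cat2)
    expect_equal(call2$category, "FSM")
    mr <- match_reference(call2, q, cat2, window = 0)
    expect_true(mr$reference_match)
  }

  # end-jitter invariance: perturbing ends inside terminal exons keeps the
  # category
  set.seed(99)
  for (q in sub$models[1:30]) {
    ex <- q$exons
    n <- nrow(ex)
    ex[1, 1] <- ex[1, 1] + sample(-20:min(20, ex[1, 2] - ex[1, 1] - 1), 1)
    ex[n, 2] <- ex[n, 2] + sample(max(-20, 1 + ex[n, 1] - ex[n, 2]):20, 1)
    qj <- transcript_model(q$transcript_id, q$gene_id, q$chrom, q$strand, ex)
    expect_equal(classify(qj, cat)$category, classify(q, cat)$category)
  }
})

test_that("classification agrees with a brute-force enumerator on tiny catalogs", {
  for (seed in 1:4) {
    cfg <- sim_config(seed = seed, n_genes = 2, n_models = 40,
                      isoforms_per_gene = c(2, 3))
    ann <- gen_annotation(cfg)
    sub <- gen_submission(ann$reference, cfg)
    cat <- build_catalog(ann$reference)
    for (q in sub$models) {
      expect_equal(classify(q, cat)$category,
                   oracle_classify(q, ann$reference),
                   info = q$transcript_id)
    }
  }
})

test_that("classify_submission assembles a coherent per-transcript table", {
  cfg <- sim_config(seed = 31, n_models = 80)
  ann <- gen_annotation(cfg)
  sub <- gen_submission(ann$reference, cfg)
  cat <- build_catalog(ann$reference)
  tab <- classify_submission(sub$models, cat)
  expect_equal(nrow(tab), 80L)
  expect_equal(sum(table(tab$category)), 80L)
  expect_true(all(!is.na(tab$matched_reference_id[tab$category %in% c("FSM", "ISM")])))
  expect_true(all(is.na(tab$matched_reference_id[tab$category %in% c("NIC", "NNC")])))
  expect_true(all(tab$nic_reason[tab$category == "NIC"] != "none"))
  expect_true(all(tab$nic_reason[tab$category != "NIC"] == "none"))
})
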