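#' Simulation configuration
#'
#' Bundles every knob of the synthetic benchmark generator with the default
#' study conditions used throughout the package's tests: a 20-gene
#' multi-isoform annotation, submissions of 500 models drawn from a
#' realistic structural-category mixture, and replicate TPM matrices with
#' log-normal noise.
#'
#' @param seed Integer seed (mandatory; every generator call is a
#'   deterministic function of it).
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Range (min, max) of isoforms per gene.
#' @param exons_per_gene Range of exons in the gene skeleton (>= 5 so that
#'   truncation, exon-skipping and retention constructions are feasible).
#' @param exon_len,intron_len,intergenic_len Length ranges in nt.
#' @param category_mix Named proportions over
#'   `c(FSM, ISM, NIC, NNC, other)`; must sum to 1.
#' @param n_models Submission size.
#' @param end_jitter_sd S.d. (nt) of the Gaussian jitter applied to
#'   transcript ends (never crossing a splice junction).
#' @param noise_sd Log-scale s.d. of the multiplicative replicate noise.
#' @param dropout_rate Per-(transcript, sample) probability of a zeroed
#'   estimate.
#' @param groups,replicates Replicate design (G groups x R replicates).
#' @param mixing_w Mixing proportion of component A in the two-component
#'   design.
#' @param noncanonical_fraction Fraction of introns stamped with a
#'   non-canonical splice motif in the toy genome.
#' @param meanlog,sdlog Log-normal parameters of the ground-truth TPM.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 20L,
                       isoforms_per_gene = c(2L, 4L),
                       exons_per_gene = c(5L, 9L),
                       exon_len = c(100L, 300L),
                       intron_len = c(200L, 500L),
                       intergenic_len = c(1000L, 3000L),
                       category_mix = c(FSM = 0.5, ISM = 0.2, NIC = 0.15,
                                        NNC = 0.1, other = 0.05),
                       n_models = 500L,
                       end_jitter_sd = 0,
                       noise_sd = 0.25,
                       dropout_rate = 0.05,
                       groups = 2L,
                       replicates = 3L,
                       mixing_w = 0.5,
                       noncanonical_fraction = 0,
                       meanlog = 3,
                       sdlog = 1.5) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop("category_mix proportions must sum to 1")
  if (exons_per_gene[1L] < 5L)
    stop("exons_per_gene minimum must be >= 5 for category constructions")
  stopifnot(n_genes >= 1L, isoforms_per_gene[1L] >= 1L,
            groups >= 1L, replicates >= 1L,
            dropout_rate >= 0, dropout_rate <= 1,
            mixing_w >= 0, mixing_w <= 1)
  structure(as.list(environment()), class = "sim_config")
}

r_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate a synthetic reference annotation and toy genome
#'
#' Lays out `n_genes` non-overlapping genes on one chromosome.  Each gene
#' has a skeleton of exons; its first isoform uses all of them and further
#' isoforms each skip one distinct internal exon, so all splice sites in
#' the annotation derive from the skeleton.  A random-sequence genome is
#' emitted with canonical GT-AG dinucleotides stamped at every distinct
#' intron except a configurable fraction stamped CT-AC (non-canonical).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `reference` (list of [transcript_model]), `genome`
#'   (`DNAStringSet`, one chromosome `"chrS"`).
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom <- "chrS"
  models <- list()
  skeletons <- list()
  pos <- r_int(1L, cfg$intergenic_len)
  for (g in seq_len(cfg$n_genes)) {
    ne <- r_int(1L, cfg$exons_per_gene)
    elens <- r_int(ne, cfg$exon_len)
    ilens <- r_int(ne - 1L, cfg$intron_len)
    starts <- pos + cumsum(c(0, elens[-ne] + ilens))
    exons <- cbind(start = starts, end = starts + elens)
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%03d", g)
    n_iso <- min(r_int(1L, cfg$isoforms_per_gene), ne - 1L)
    internal <- 2:(ne - 1L)
    skips <- sample(internal, min(n_iso - 1L, length(internal)))
    iso_exons <- c(list(seq_len(ne)),
                   lapply(skips, function(s) setdiff(seq_len(ne), s)))
    for (k in seq_along(iso_exons)) {
      tid <- sprintf("%s.t%d", gid, k)
      models[[tid]] <- transcript_model(tid, gid, chrom, strand,
                                        exons[iso_exons[[k]], , drop = FALSE],
                                        source_label = "reference")
    }
    skeletons[[gid]] <- list(exons = exons, strand = strand)
    pos <- max(exons[, 2L]) + r_int(1L, cfg$intergenic_len)
  }
  genome_len <- pos + r_int(1L, cfg$intergenic_len)
  bases <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

  # stamp splice motifs at every distinct annotated intron
  introns <- unique(do.call(rbind, lapply(models, function(t) {
    ch <- junction_chain(t)
    if (nrow(ch$introns) == 0L) return(NULL)
    cbind(ch$introns, strand = ifelse(t$strand == "+", 1, -1))
  })))
  # introns sharing a splice site (e.g. a skip junction reusing the donor of
  # the skeleton intron) must agree on their motif class, so the
  # canonical/non-canonical draw is made once per connected component of the
  # site-sharing graph
  nin <- nrow(introns)
  parent <- seq_len(nin)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (col in 1:2) {
    for (grp in split(seq_len(nin), introns[, col])) {
      if (length(grp) > 1L) {
        for (j in grp[-1L]) {
          rj <- find(j); r1 <- find(grp[1L])
          if (rj != r1) parent[rj] <- r1
        }
      }
    }
  }
  roots <- vapply(seq_len(nin), find, integer(1))
  comp_noncan <- stats::runif(nin) < cfg$noncanonical_fraction  # one draw/root
  noncan <- comp_noncan[roots]
  for (i in seq_len(nrow(introns))) {
    s <- introns[i, 1L]; e <- introns[i, 2L]
    donor <- if (noncan[i]) c("C", "T") else c("G", "T")
    accep <- if (noncan[i]) c("A", "C") else c("A", "G")
    if (introns[i, 3L] > 0) {       # + strand
      bases[(s + 1):(s + 2)] <- donor
      bases[(e - 1):e] <- accep
    } else {                        # - strand: genomic revcomp
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      bases[(s + 1):(s + 2)] <- comp[rev(accep)]
      bases[(e - 1):e] <- comp[rev(donor)]
    }
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- chrom
  list(reference = models, genome = genome)
}

#' Generate a category-labeled synthetic submission
#'
#' Draws `cfg$n_models` query models from `cfg$category_mix` and constructs
#' each to receive its intended structural category when classified against
#' the reference: FSM as a copy with (bounded) end jitter; ISM as a
#' consecutive truncation of the intron chain; NIC as a skip of two
#' adjacent internal exons (novel junction between known sites), a skip of
#' two non-adjacent internal exons (novel junction combination) or an
#' internal intron retention; NNC by shifting one internal splice site off
#' every annotated coordinate; "other" as an intergenic mono-exon model.
#' Every construction is verified by classification and re-drawn on the
#' rare topological collision (error after 50 failed attempts).
#'
#' @param reference List of reference [transcript_model] from
#'   [gen_annotation()].
#' @param cfg A [sim_config()].
#' @return List: `models` (the submission), `labels` (data frame
#'   `query_id`, `category`, `source_reference`).
#' @export
gen_submission <- function(reference, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  catalog <- build_catalog(reference)
  set.seed(cfg$seed + 1L)
  cats <- sample(names(cfg$category_mix), cfg$n_models, replace = TRUE,
                 prob = cfg$category_mix)
  multi_ids <- names(reference)[vapply(reference, function(t)
    nrow(t$exons) >= 5L, logical(1))]   # full-skeleton isoforms
  span_lo <- min(vapply(reference, function(t) t$exons[1L, 1L], numeric(1)))
  span_hi <- max(vapply(reference, function(t)
    t$exons[nrow(t$exons), 2L], numeric(1)))

  models <- vector("list", cfg$n_models)
  src <- character(cfg$n_models)
  for (k in seq_len(cfg$n_models)) {
    want <- cats[k]
    tid <- sprintf("q%04d_%s", k, want)
    for (try in 1:50) {
      ref_id <- sample(multi_ids, 1L)
      ref <- reference[[ref_id]]
      q <- switch(want,
        FSM = construct_fsm(tid, ref, cfg),
        ISM = construct_ism(tid, ref, cfg),
        NIC = construct_nic(tid, ref, cfg, catalog),
        NNC = construct_nnc(tid, ref, cfg, catalog),
        other = construct_intergenic(tid, ref$chrom, span_hi, cfg))
      if (is.null(q)) next
      got <- classify(q, catalog)$category
      if (got == want) break
      q <- NULL
    }
    if (is.null(q))
      stop("could not construct a '", want,
           "' model from the reference topology")
    models[[k]] <- q
    names(models)[k] <- tid
    src[k] <- if (want == "other") NA_character_ else ref_id
  }
  list(models = models,
       labels = data.frame(query_id = names(models), category = cats,
                           source_reference = src,
                           stringsAsFactors = FALSE))
}

# jitter outer ends without crossing a junction: the 5'/3' terminal exon
# keeps >= 1 base
jitter_ends <- function(exons, sd) {
  if (sd <= 0) return(exons)
  n <- nrow(exons)
  d1 <- round(stats::rnorm(1L, 0, sd))
  d2 <- round(stats::rnorm(1L, 0, sd))
  exons[1L, 1L] <- max(0, min(exons[1L, 1L] + d1, exons[1L, 2L] - 1L))
  exons[n, 2L] <- max(exons[n, 1L] + 1L, exons[n, 2L] + d2)
  exons
}

construct_fsm <- function(tid, ref, cfg) {
  transcript_model(tid, ref$gene_id, ref$chrom, ref$strand,
                   jitter_ends(ref$exons, cfg$end_jitter_sd),
                   source_label = "submission")
}

construct_ism <- function(tid, ref, cfg) {
  ne <- nrow(ref$exons)
  nin <- ne - 1L
  if (nin < 2L) return(NULL)
  # consecutive intron run i..j, proper
  i <- sample(seq_len(nin), 1L)
  j <- if (i == nin) nin else sample(i:nin, 1L)
  if (i == 1L && j == nin) {
    if (i + 1L <= nin) i <- i + 1L else j <- j - 1L
  }
  transcript_model(tid, ref$gene_id, ref$chrom, ref$strand,
                   jitter_ends(ref$exons[i:(j + 1L), , drop = FALSE],
                               cfg$end_jitter_sd),
                   source_label = "submission")
}

construct_nic <- function(tid, ref, cfg, catalog) {
  ne <- nrow(ref$exons)
  internal <- 2:(ne - 1L)
  variant <- sample(c("bigskip", "retention", "combo"), 1L)
  ex <- ref$exons
  if (variant == "bigskip" && length(internal) >= 2L) {
    # skip two adjacent internal exons -> novel junction, known sites
    i <- sample(internal[-length(internal)], 1L)
    keep <- setdiff(seq_len(ne), c(i, i + 1L))
    ex <- ex[keep, , drop = FALSE]
  } else if (variant == "combo" && length(internal) >= 3L) {
    # skip two non-adjacent internal exons -> novel combination of
    # annotated (skip-isoform) junctions
    i <- internal[1L]
    cand <- internal[internal >= i + 2L]
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    ex <- ex[setdiff(seq_len(ne), c(i, j)), , drop = FALSE]
  } else {
    # retain an internal intron: merge exons i and i+1
    i <- sample(internal[-length(internal)], 1L)
    ex[i, 2L] <- ex[i + 1L, 2L]
    ex <- ex[-(i + 1L), , drop = FALSE]
  }
  transcript_model(tid, ref$gene_id, ref$chrom, ref$strand,
                   jitter_ends(ex, cfg$end_jitter_sd),
                   source_label = "submission")
}

construct_nnc <- function(tid, ref, cfg, catalog) {
  ne <- nrow(ref$exons)
  ex <- ref$exons
  i <- sample(2:(ne - 1L), 1L)  # internal exon; shift its start (acceptor side)
  shift <- sample(c(-10:-3, 3:10), 1L)
  new_start <- ex[i, 1L] + shift
  if (new_start <= ex[i - 1L, 2L] || new_start >= ex[i, 2L]) return(NULL)
  key <- paste0(ref$chrom, "|", ref$strand, "|", new_start)
  if (key %in% catalog$donor_set || key %in% catalog$acceptor_set) return(NULL)
  ex[i, 1L] <- new_start
  transcript_model(tid, ref$gene_id, ref$chrom, ref$strand,
                   jitter_ends(ex, cfg$end_jitter_sd),
                   source_label = "submission")
}

construct_intergenic <- function(tid, chrom, span_hi, cfg) {
  start <- span_hi + r_int(1L, cfg$intergenic_len %/% 2L) + 200L
  len <- r_int(1L, cfg$exon_len)
  transcript_model(tid, "novel_gene", chrom, sample(c("+", "-"), 1L),
                   cbind(start, start + len), source_label = "submission")
}

#' Generate a replicate TPM matrix with known ground truth
#'
#' Ground-truth abundances are drawn log-normal and normalized to TPM
#' (sum 1e6).  Each replicate estimate is the truth under multiplicative
#' log-normal noise (`exp(noise_sd * z)`, `z ~ N(0,1)` drawn once per
#' transcript x sample, independent of `noise_sd` so noise ladders at a
#' fixed seed share their randomness), with Bernoulli dropout zeroing, and
#' is re-normalized to sum 1e6.  Deterministic given `cfg$seed`.
#'
#' @param truth_ids Character vector of transcript ids.
#' @param cfg A [sim_config()].
#' @param truth Optional pre-specified ground-truth TPM (named); drawn if
#'   `NULL`.
#' @return List: `quant` (a [quant_matrix]), `truth` (named TPM vector).
#' @export
gen_quant <- function(truth_ids, cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(truth_ids)
  set.seed(cfg$seed + 2L)
  if (is.null(truth)) {
    truth <- stats::rlnorm(n, cfg$meanlog, cfg$sdlog)
    truth <- truth * 1e6 / sum(truth)
    names(truth) <- truth_ids
  } else {
    truth <- truth[truth_ids]
  }
  G <- cfg$groups; R <- cfg$replicates
  vals <- matrix(0, n, G * R, dimnames = list(truth_ids, NULL))
  col <- 0L
  for (g in seq_len(G)) for (r in seq_len(R)) {
    col <- col + 1L
    z <- stats::rnorm(n)
    est <- truth * exp(cfg$noise_sd * z)
    drop <- stats::runif(n) < cfg$dropout_rate
    est[drop] <- 0
    if (sum(est) > 0) est <- est * 1e6 / sum(est)
    vals[, col] <- est
  }
  q <- quant_matrix(vals,
                    col_groups = rep(paste0("group", seq_len(G)), each = R),
                    col_reps = rep(paste0("rep", seq_len(R)), times = G))
  list(quant = q, truth = truth)
}

#' Generate a two-component mixing scenario
#'
#' The mixed ground truth is `w * a + (1 - w) * b` re-normalized to TPM;
#' the observed mixed sample is that truth under the same noise model as
#' [gen_quant()] (single group).
#'
#' @param truth_a,truth_b Named component TPM vectors (aligned by name).
#' @param w Mixing proportion of component A.
#' @param cfg A [sim_config()].
#' @return List: `observed` (a one-group [quant_matrix]), `mixed_truth`,
#'   `w`.
#' @export
gen_mixing <- function(truth_a, truth_b, w, cfg) {
  mixed <- mixing_expected(truth_a, truth_b, w)
  cfg2 <- cfg
  cfg2$groups <- 1L
  cfg2$seed <- cfg$seed + 3L
  obs <- gen_quant(names(mixed), cfg2, truth = mixed)
  list(observed = obs$quant, mixed_truth = mixed, w = w)
}

#' Materialize a complete miniature benchmark directory
#'
#' Writes every fixture the evaluation commands consume: reference and
#' submission GTFs, the toy genome FASTA, the submission label table, wide
#' replicate TPM tables with ground truth, and the mixing scenario.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
write_fixtures <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- gen_annotation(cfg)
  sub <- gen_submission(ann$reference, cfg)
  qt <- gen_quant(names(ann$reference), cfg)
  cfg_b <- cfg; cfg_b$seed <- cfg$seed + 101L
  qt_b <- gen_quant(names(ann$reference), cfg_b)
  mix <- gen_mixing(qt$truth, qt_b$truth, cfg$mixing_w, cfg)
  p <- list(
    reference_gtf = file.path(dir, "reference.gtf"),
    submission_gtf = file.path(dir, "submission.gtf"),
    genome_fa = file.path(dir, "genome.fa"),
    labels_tsv = file.path(dir, "labels.tsv"),
    quant_tsv = file.path(dir, "quant.tsv"),
    truth_tsv = file.path(dir, "truth.tsv"),
    mixed_tsv = file.path(dir, "mixed.tsv"),
    comp_a_tsv = file.path(dir, "component_a.tsv"),
    comp_b_tsv = file.path(dir, "component_b.tsv"))
  write_gtf(ann$reference, p$reference_gtf)
  write_gtf(sub$models, p$submission_gtf)
  Biostrings::writeXStringSet(ann$genome, p$genome_fa)
  utils::write.table(sub$labels, p$labels_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_quant_tsv(qt$quant, p$quant_tsv)
  write_truth_tsv(qt$truth, p$truth_tsv)
  write_quant_tsv(mix$observed, p$mixed_tsv)
  write_truth_tsv(qt$truth, p$comp_a_tsv)
  write_truth_tsv(qt_b$truth, p$comp_b_tsv)
  invisible(p)
}
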