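# Command-line orchestration and machine-readable reporting.

#' Render evaluation results as JSON and TSV reports
#'
#' Writes `<prefix>.json` (all result sections under a versioned schema,
#' floats at 6 significant digits) and one `<prefix>_<section>.tsv` per
#' tabular section.
#'
#' @param results Named list of result sections; scalars and flat lists go
#'   to JSON, data frames additionally to TSV.
#' @param prefix Output path prefix.
#' @return Named list of written paths, invisibly.
#' @export
render_report <- function(results, prefix) {
  round_sig <- function(x) {
    if (is.numeric(x)) signif(x, 6) else x
  }
  prep <- function(x) {
    if (is.data.frame(x)) return(lapply(x, round_sig))
    if (is.list(x)) return(lapply(x, prep))
    round_sig(x)
  }
  payload <- c(list(schema_version = "1.0"), prep(results))
  paths <- list(json = paste0(prefix, ".json"))
  jsonlite::write_json(payload, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      p <- paste0(prefix, "_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv")
      utils::write.table(results[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[nm]] <- p
    }
  }
  invisible(paths)
}

parse_flags <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("usage error: expected --flag, got '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- argv[i + 1L]; i <- i + 2L
    }
  }
  out
}

req <- function(flags, name) {
  if (is.null(flags[[name]]))
    stop("usage error: missing required --", name)
  flags[[name]]
}

#' Run the command-line interface
#'
#' Subcommands: `classify` (structural classification of a submission GTF
#' against a reference GTF, with optional CAGE/3'-peak/junction/genome
#' evidence), `eval-detect` (detection scoring against a ground-truth GTF),
#' `eval-quant` (replicate and, with `--truth`, ground-truth quantification
#' metrics), `eval-mixing` (cell-mixing evaluation), and `simulate`
#' (materialize a synthetic benchmark directory).  A YAML `--config` file
#' supplies default flag values; explicit command-line flags win.
#' Reports are written under `--out` (default `"."`, prefix per
#' subcommand).
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("classify", "--queries", "q.gtf", "--reference", "r.gtf")`.
#' @return Exit code (0 on success), invisibly.  Validation problems raise
#'   errors; the shell wrapper maps them to a nonzero exit.
#' @export
run_cli <- function(argv) {
  if (length(argv) == 0L)
    stop("usage: txbench-cli <classify|eval-detect|eval-quant|eval-mixing|",
         "simulate> [--flags]")
  cmd <- argv[1L]
  flags <- parse_flags(argv[-1L])
  if (!is.null(flags$config)) {
    cfgf <- yaml_flags(flags$config)
    for (nm in names(cfgf)) if (is.null(flags[[nm]])) flags[[nm]] <- cfgf[[nm]]
  }
  out_dir <- flags$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  window <- as.numeric(flags$window %||% 50)
  seed <- as.integer(flags$seed %||% 1)

  results <- switch(cmd,
    "classify" = {
      catalog <- build_catalog(read_gtf(req(flags, "reference")))
      queries <- read_gtf(req(flags, "queries"))
      ev <- support_evidence(
        cage_peaks = if (!is.null(flags$cage)) read_bed_peaks(flags$cage),
        tts_peaks = if (!is.null(flags$tts)) read_bed_peaks(flags$tts),
        junction_counts = if (!is.null(flags$junctions))
          read_junction_counts(flags$junctions),
        genome = flags$genome)
      tab <- classify_submission(queries, catalog, evidence = ev,
                                 window = window)
      list(classification = tab,
           category_counts = as.list(table(tab$category)),
           junction_profile = junction_profile(queries, catalog, ev))
    },
    "eval-detect" = {
      truth <- build_catalog(read_gtf(req(flags, "truth")))
      preds <- read_gtf(req(flags, "predictions"))
      r <- evaluate_detection(preds, truth, window = window)
      list(detection = list(TP = r$tp, PTP = r$ptp, FN = r$fn, FP = r$fp,
                            Sen = r$sensitivity, Pre = r$precision,
                            F1 = r$f1, PDR = r$pdr,
                            redundancy = r$redundancy,
                            inv_redundancy = r$inv_redundancy))
    },
    "eval-quant" = {
      q <- read_quant_tsv(req(flags, "estimates"))
      rep_metrics <- if (q$R >= 2L) {
        ir <- irreproducibility(q)
        cm <- consistency(q)
        list(IM = ir$IM, ACVC = ir$ACVC, CM = cm$CM, ACC = cm$ACC)
      } else list()
      re_per_sample <- apply(q$values, 2L, resolution_entropy)
      out <- c(rep_metrics, list(RE = mean(re_per_sample)))
      if (!is.null(flags$truth)) {
        truth <- read_truth_tsv(flags$truth)
        missing <- setdiff(names(truth), rownames(q$values))
        est <- rowMeans(q$values)
        out <- c(out, list(SCC = scc(est, truth), MRD = mrd(est, truth),
                           NRMSE = nrmse(est, truth),
                           PET = pet(est, names(truth)[truth > 0])))
      }
      list(quant = out)
    },
    "eval-mixing" = {
      obs <- read_truth_tsv(req(flags, "mixed"))
      a <- read_truth_tsv(req(flags, "a"))
      b <- read_truth_tsv(req(flags, "b"))
      w <- as.numeric(req(flags, "ratio"))
      list(mixing = evaluate_mixing(obs, a, b, w))
    },
    "simulate" = {
      cfg <- sim_config(seed = seed)
      paths <- write_fixtures(cfg, out_dir)
      list(simulate = lapply(paths, normalizePath))
    },
    stop("usage error: unknown subcommand '", cmd, "'"))

  results$run <- list(subcommand = cmd, seed = seed, window = window,
                      config_hash = digest_flags(flags))
  render_report(results, file.path(out_dir, paste0("txbench_", gsub("-", "_", cmd))))
  invisible(0L)
}

yaml_flags <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("--config requires the yaml package")
  yaml::read_yaml(path)
}

# stable fingerprint of the effective configuration (order-independent)
digest_flags <- function(flags) {
  flags <- flags[order(names(flags))]
  txt <- paste(names(flags), vapply(flags, function(x)
    paste(as.character(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% .Machine$integer.max)
}
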