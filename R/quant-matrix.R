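#' Construct a replicate quantification matrix
#'
#' Holds per-transcript abundance estimates (TPM) across a group x replicate
#' design: `values` is an I x (G*R) matrix whose columns are labeled by
#' group and replicate.  Missing estimates should be encoded as 0 before
#' construction; negative values are rejected.
#'
#' @param values Numeric matrix, rows = transcripts (rownames = ids),
#'   columns = samples.
#' @param col_groups Character/factor of length `ncol(values)`, the group of
#'   each column.
#' @param col_reps Vector of length `ncol(values)`, the replicate label of
#'   each column within its group.  Every group must have the same number of
#'   replicates (complete grid).
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, col_groups, col_reps) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1L, is.numeric(values),
            length(col_groups) == ncol(values),
            length(col_reps) == ncol(values))
  if (any(values < 0)) stop("TPM values must be >= 0")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("tx", seq_len(nrow(values)))
  col_groups <- as.character(col_groups)
  per_group <- table(col_groups)
  if (length(unique(per_group)) != 1L)
    stop("incomplete design: every group must have the same replicate count")
  colnames(values) <- paste0(col_groups, "_", col_reps)
  structure(list(values = values, col_groups = col_groups,
                 col_reps = as.character(col_reps),
                 groups = unique(col_groups),
                 R = unname(per_group[1L])),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d transcripts x %d groups x %d replicates\n",
              nrow(x$values), length(x$groups), x$R))
  invisible(x)
}

#' Read a quantification TSV (long or wide format)
#'
#' Long format has columns `transcript_id  group  replicate  TPM`; wide
#' format has a `transcript_id` column followed by `<group>_<replicate>`
#' sample columns.  The format is auto-detected from the header.
#'
#' @param path TSV path.
#' @return A [quant_matrix].
#' @export
read_quant_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (all(c("transcript_id", "group", "replicate", "TPM") %in% names(df))) {
    ids <- unique(df$transcript_id)
    key <- paste0(df$group, "_", df$replicate)
    cols <- unique(key)
    m <- matrix(0, length(ids), length(cols),
                dimnames = list(ids, cols))
    m[cbind(match(df$transcript_id, ids), match(key, cols))] <- df$TPM
    parts <- strsplit(cols, "_(?=[^_]+$)", perl = TRUE)
    quant_matrix(m, vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  } else if (names(df)[1L] == "transcript_id") {
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$transcript_id
    parts <- strsplit(colnames(m), "_(?=[^_]+$)", perl = TRUE)
    quant_matrix(m, vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  } else {
    stop("unrecognized quantification table format in ", path,
         " (need long transcript_id/group/replicate/TPM or wide",
         " transcript_id + <group>_<rep> columns)")
  }
}

#' Write a quant_matrix as a wide TSV
#' @param q A [quant_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(q, path) {
  df <- data.frame(transcript_id = rownames(q$values), q$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth abundance TSV (`transcript_id  TPM`)
#' @param path TSV path.
#' @return Named numeric vector of TPM.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "TPM") %in% names(df)))
    stop("ground-truth table must have columns transcript_id and TPM")
  stats::setNames(as.numeric(df$TPM), df$transcript_id)
}

#' Write an abundance vector as a ground-truth TSV
#' @param v Named numeric vector of TPM.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(v, path) {
  utils::write.table(data.frame(transcript_id = names(v), TPM = unname(v)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align an estimate vector to the ground-truth id set: the evaluation set is
# all truth transcripts; ids the estimate does not report count as 0.
align_to_truth <- function(est, truth) {
  stopifnot(!is.null(names(truth)))
  if (is.null(names(est)) && length(est) == length(truth)) {
    names(est) <- names(truth)
  }
  e <- est[names(truth)]
  e[is.na(e)] <- 0
  names(e) <- names(truth)
  list(est = unname(e), truth = unname(truth), ids = names(truth))
}
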