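#' @import data.table
#' @importFrom stats cor sd quantile runif setNames rnorm rlnorm rpois
#'   complete.cases coef optim hclust cutree as.dist lm resid predict
#' @importFrom utils head tail write.table read.table
NULL

#' Construct an elution-trace matrix
#'
#' The central data container: quantitative elution profiles of analytes
#' (peptides or proteins) over an ordered, contiguous SEC fraction axis.
#' Intensities are stored dense, with missing observations as explicit
#' zeros; the 81-fraction axes typical of SEC-SWATH experiments are small
#' enough that sparsity buys nothing.
#'
#' @param intensity numeric matrix, analytes in rows (rownames = analyte
#'   ids), fractions in columns; all values finite and >= 0.
#' @param level `"peptide"` or `"protein"`.
#' @param parent_ids character vector, parent protein id per analyte. At
#'   protein level this must equal the analyte ids.
#' @param fractions integer vector of fraction indices; must be contiguous
#'   and strictly increasing (1-based, closed).
#' @param is_decoy logical vector per analyte, decoy flag carried over from
#'   the upstream peptide-centric search.
#' @param annotations optional `data.frame` with columns `analyte_id`,
#'   `protein_mw_kda`, `gene_name` (one row per analyte).
#' @param fraction_mw optional numeric vector of apparent molecular weight
#'   (kDa) per fraction; must be strictly decreasing.
#' @return An object of class `sec_traces`.
#' @export
sec_traces <- function(intensity, level = c("peptide", "protein"),
                       parent_ids, fractions = seq_len(ncol(intensity)),
                       is_decoy = rep(FALSE, nrow(intensity)),
                       annotations = NULL, fraction_mw = NULL) {
  level <- match.arg(level)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(rownames(intensity)))
    stop("intensity matrix must carry analyte ids as rownames")
  if (anyDuplicated(rownames(intensity)))
    stop("duplicate analyte ids")
  if (any(!is.finite(intensity)))
    stop("intensities must be finite")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  fractions <- as.integer(fractions)
  if (length(fractions) != ncol(intensity))
    stop("length(fractions) must equal ncol(intensity)")
  if (length(fractions) > 1L && any(diff(fractions) != 1L))
    stop("fraction indices must be contiguous and strictly increasing")
  parent_ids <- as.character(parent_ids)
  if (length(parent_ids) != nrow(intensity))
    stop("parent_ids must have one entry per analyte")
  if (level == "protein" && !identical(parent_ids, rownames(intensity)))
    stop("at protein level parent_ids must equal analyte ids")
  is_decoy <- as.logical(is_decoy)
  if (length(is_decoy) != nrow(intensity))
    stop("is_decoy must have one entry per analyte")
  if (!is.null(fraction_mw)) {
    if (length(fraction_mw) != length(fractions))
      stop("fraction_mw must have one entry per fraction")
    if (any(diff(fraction_mw) >= 0))
      stop("fraction_mw must be strictly decreasing with fraction index")
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (!all(c("analyte_id", "protein_mw_kda", "gene_name") %in%
             names(annotations)))
      stop("annotations need columns analyte_id, protein_mw_kda, gene_name")
  }
  colnames(intensity) <- as.character(fractions)
  structure(list(intensity = intensity, level = level,
                 parent_ids = parent_ids, fractions = fractions,
                 is_decoy = is_decoy, annotations = annotations,
                 fraction_mw = fraction_mw),
            class = "sec_traces")
}

#' @export
print.sec_traces <- function(x, ...) {
  cat(sprintf("<sec_traces> %s-level: %d analytes x %d fractions (%d-%d)\n",
              x$level, nrow(x$intensity), length(x$fractions),
              min(x$fractions), max(x$fractions)))
  cat(sprintf("  decoys: %d; annotated: %s; fraction MW: %s\n",
              sum(x$is_decoy),
              if (is.null(x$annotations)) "no" else "yes",
              if (is.null(x$fraction_mw)) "no" else "yes"))
  invisible(x)
}

#' @export
dim.sec_traces <- function(x) dim(x$intensity)

analyte_ids <- function(tm) rownames(tm$intensity)

#' Subset a trace matrix to a set of analytes
#'
#' @param tm a `sec_traces` object.
#' @param ids analyte ids to keep (order preserved as given).
#' @return A `sec_traces` with only the requested analytes.
#' @export
subset_traces <- function(tm, ids) {
  stopifnot(inherits(tm, "sec_traces"))
  ids <- as.character(ids)
  missing <- setdiff(ids, analyte_ids(tm))
  if (length(missing))
    stop("unknown analyte ids: ", paste(missing, collapse = ", "))
  idx <- match(ids, analyte_ids(tm))
  ann <- tm$annotations
  if (!is.null(ann)) {
    ann <- ann[match(ids, ann$analyte_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  sec_traces(tm$intensity[idx, , drop = FALSE], level = tm$level,
             parent_ids = tm$parent_ids[idx], fractions = tm$fractions,
             is_decoy = tm$is_decoy[idx], annotations = ann,
             fraction_mw = tm$fraction_mw)
}

#' Import a long-format peptide quantification table
#'
#' Converts the long table produced by peptide-centric DIA analysis (one
#' row per precursor x run) into a dense peptide-level trace matrix.
#' Multiple precursor rows of the same peptide in the same fraction are
#' summed to peptide level. Non-proteotypic rows, i.e. rows whose protein
#' id names more than one protein (contains any of the configured
#' separators), are removed. Missing (peptide, fraction) observations
#' become explicit zeros.
#'
#' Decoy rows from the upstream search are retained by default because the
#' downstream sibling-peptide-correlation filter estimates protein-level
#' FDR from them.
#'
#' @param rows `data.frame` with columns `peptide_id`, `protein_id`,
#'   `run_id`, `intensity`, `decoy` (logical or 0/1).
#' @param fraction_map `data.frame` with columns `run_id`,
#'   `fraction_number` mapping each run to one SEC fraction; fractions must
#'   form a contiguous range.
#' @param keep_decoys keep decoy-flagged peptides? Default `TRUE`.
#' @param separators characters in `protein_id` that mark multi-protein
#'   groups (non-proteotypic evidence).
#' @return A peptide-level `sec_traces`.
#' @export
import_long_table <- function(rows, fraction_map, keep_decoys = TRUE,
                              separators = c(";", "/")) {
  rows <- as.data.table(as.data.frame(rows))
  need <- c("peptide_id", "protein_id", "run_id", "intensity", "decoy")
  if (!all(need %in% names(rows)))
    stop("rows must have columns: ", paste(need, collapse = ", "))
  fraction_map <- as.data.frame(fraction_map)
  if (!all(c("run_id", "fraction_number") %in% names(fraction_map)))
    stop("fraction_map needs columns run_id, fraction_number")
  if (any(!is.finite(rows$intensity)))
    stop("non-finite intensity in input rows")
  if (any(rows$intensity < 0))
    stop("negative intensity in input rows")
  unknown <- setdiff(unique(rows$run_id), fraction_map$run_id)
  if (length(unknown))
    stop("run id(s) missing from fraction annotation: ",
         paste(unknown, collapse = ", "))
  fr_all <- sort(unique(as.integer(fraction_map$fraction_number)))
  if (length(fr_all) > 1L && any(diff(fr_all) != 1L))
    stop("fraction annotation does not form a contiguous range")

  # proteotypic rule: protein_id naming >1 protein is dropped
  sep_re <- paste0("[", paste(gsub("([][\\^-])", "\\\\\\1", separators),
                              collapse = ""), "]")
  rows <- rows[!grepl(sep_re, rows$protein_id)]
  rows$decoy <- as.logical(rows$decoy)
  if (!keep_decoys) rows <- rows[!rows$decoy]
  if (nrow(rows) == 0L) stop("no rows left after filtering")

  fraction <- NULL # NSE binding
  rows$fraction <- fraction_map$fraction_number[
    match(rows$run_id, fraction_map$run_id)]
  agg <- rows[, list(intensity = sum(intensity)),
              by = c("peptide_id", "protein_id", "decoy", "fraction")]
  setorder(agg, peptide_id, fraction)
  peps <- agg[, list(protein_id = protein_id[1L], decoy = decoy[1L]),
              by = "peptide_id"]
  setorder(peps, peptide_id)
  mat <- matrix(0, nrow(peps), length(fr_all),
                dimnames = list(peps$peptide_id, as.character(fr_all)))
  mat[cbind(match(agg$peptide_id, peps$peptide_id),
            match(agg$fraction, fr_all))] <- agg$intensity
  sec_traces(mat, level = "peptide", parent_ids = peps$protein_id,
             fractions = fr_all, is_decoy = peps$decoy)
}

#' Attach analyte annotations (monomer mass, gene name)
#'
#' Matches annotation rows to analytes via the parent protein id. Analytes
#' without a matching row keep an empty annotation; their count is
#' reported via a warning and the `n_unmatched` attribute.
#'
#' @param tm a `sec_traces` object.
#' @param table `data.frame` with columns `protein_id`, `protein_mw_kda`,
#'   optionally `gene_name`.
#' @return `tm` with the `annotations` slot filled.
#' @export
annotate_traces <- function(tm, table) {
  stopifnot(inherits(tm, "sec_traces"))
  table <- as.data.frame(table)
  if (!all(c("protein_id", "protein_mw_kda") %in% names(table)))
    stop("annotation table needs columns protein_id, protein_mw_kda")
  if (!"gene_name" %in% names(table)) table$gene_name <- NA_character_
  if (anyDuplicated(table$protein_id)) {
    dup <- table[table$protein_id %in%
                   table$protein_id[duplicated(table$protein_id)], ]
    conflict <- tapply(dup$protein_mw_kda, dup$protein_id,
                       function(v) length(unique(v)) > 1L)
    if (any(conflict))
      stop("conflicting monomer masses for: ",
           paste(names(conflict)[conflict], collapse = ", "))
    table <- table[!duplicated(table$protein_id), ]
  }
  idx <- match(tm$parent_ids, table$protein_id)
  ann <- data.frame(analyte_id = analyte_ids(tm),
                    protein_mw_kda = table$protein_mw_kda[idx],
                    gene_name = table$gene_name[idx],
                    stringsAsFactors = FALSE)
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched > 0L)
    warning(n_unmatched, " analyte(s) without annotation")
  tm$annotations <- ann
  attr(tm, "n_unmatched") <- n_unmatched
  tm
}

#' Read / write a wide trace TSV
#'
#' Wide format: first column the analyte id, remaining columns the
#' intensity per fraction with the fraction index as column header.
#' `write_traces` followed by `read_traces` reproduces the matrix up to
#' 12-significant-digit float formatting. Parent ids and decoy flags
#' travel in optional `parent_id` / `is_decoy` columns placed after the
#' analyte id.
#'
#' @param path TSV file path.
#' @param level trace level of the file being read.
#' @return `read_traces` returns a `sec_traces`; `write_traces` returns
#'   `path` invisibly.
#' @export
read_traces <- function(path, level = c("peptide", "protein")) {
  level <- match.arg(level)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no analytes in ", path)
  meta_cols <- intersect(c("parent_id", "is_decoy"), names(df))
  frac_cols <- setdiff(names(df)[-1L], meta_cols)
  fr <- suppressWarnings(as.integer(frac_cols))
  if (any(is.na(fr))) stop("non-numeric fraction header in ", path)
  if (length(fr) > 1L && any(diff(fr) != 1L))
    stop("fraction headers are not contiguous in ", path)
  vals <- as.matrix(df[, frac_cols, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                 bad[1L], frac_cols[bad[2L]], path))
  }
  rownames(num) <- df[[1L]]
  parent <- if ("parent_id" %in% meta_cols) df$parent_id else df[[1L]]
  decoy <- if ("is_decoy" %in% meta_cols)
    as.logical(as.integer(df$is_decoy)) else rep(FALSE, nrow(num))
  sec_traces(num, level = level, parent_ids = parent, fractions = fr,
             is_decoy = decoy)
}

#' @rdname read_traces
#' @param tm a `sec_traces` object to write.
#' @export
write_traces <- function(tm, path) {
  stopifnot(inherits(tm, "sec_traces"))
  df <- data.frame(analyte_id = analyte_ids(tm),
                   parent_id = tm$parent_ids,
                   is_decoy = as.integer(tm$is_decoy),
                   signif(tm$intensity, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
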