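#' Read a gene expression matrix from delimited text
#'
#' Reads a dense expression matrix from TSV (or CSV, chosen by file
#' extension) and returns it oriented samples x genes regardless of the
#' on-disk orientation. The canonical on-disk layout is the transcriptomics
#' convention: genes as rows with a first column of ENTREZ gene IDs (header
#' `entrez_id`) and samples as columns.
#'
#' Missing or non-numeric cells are rejected outright — the pipeline does
#' no expression imputation — with an error naming the offending row and
#' column. Duplicate gene IDs are permitted (they are merged later by
#' [aggregate_duplicates()]); duplicate sample IDs are an error.
#'
#' @param path Path to a delimited text file. `.csv` is read as
#'   comma-separated, anything else as tab-separated.
#' @param orientation Orientation of the file on disk:
#'   `"genes_x_samples"` (default, canonical) or `"samples_x_genes"`.
#' @param region Optional region label attached to the returned matrix.
#' @return A numeric matrix, rows = samples, columns = genes, with the
#'   region label (if any) stored in `attr(, "region")`.
#' @seealso [write_expression_matrix()], [align_region()]
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_x_samples",
                                                   "samples_x_genes"),
                                   region = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(sprintf("Empty or malformed expression file: %s", path))
  }
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(col_ids))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    abort(sprintf(
      "Non-numeric or missing expression value at row '%s', column '%s' in %s.",
      row_ids[b[1L]], col_ids[b[2L]], path))
  }
  dimnames(vals) <- list(row_ids, col_ids)
  m <- if (orientation == "genes_x_samples") t(vals) else vals
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    abort(sprintf("Duplicated sample IDs: %s",
                  paste(dups, collapse = ", ")))
  }
  if (!is.null(region)) region_of(m) <- region
  m
}

#' Write an expression matrix in the canonical on-disk layout
#'
#' Writes genes as rows (first column `entrez_id`) and samples as columns,
#' tab-separated, at full double precision so a write/read round trip
#' reproduces the values bit-identically.
#'
#' @param m Numeric samples x genes matrix.
#' @param path Output path (`.csv` switches to comma separation).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  assert_expression_matrix(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  g <- t(m)  # genes x samples on disk
  lines <- c(
    paste(c("entrez_id", colnames(g)), collapse = sep),
    vapply(seq_len(nrow(g)), function(i) {
      paste(c(rownames(g)[i], sprintf("%.17g", g[i, ])), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical metadata table
#'
#' Reads a CSV of per-subject clinical metadata. The columns `subject_id`
#' and `braak` are required; `age`, `sex`, `pmi` (post-mortem interval,
#' minutes) and `ph` are carried through when present, and extra columns
#' are retained untouched. Braak scores are accepted as integers 0-6 or
#' Roman numerals (`0`, `I`..`VI`); unparseable or out-of-range values
#' become missing (`NA`) and are dropped later, at alignment, not here.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with `subject_id` (character) and `braak` (integer,
#'   possibly `NA`) plus any further columns.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(tab)) {
    abort("Clinical table must contain a 'subject_id' column.")
  }
  if (!"braak" %in% names(tab)) {
    abort("Clinical table must contain a 'braak' column.")
  }
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) {
    dups <- unique(tab$subject_id[duplicated(tab$subject_id)])
    abort(sprintf("Duplicated subject IDs in clinical table: %s",
                  paste(dups, collapse = ", ")))
  }
  tab$braak <- parse_braak(tab$braak)
  tibble::as_tibble(tab)
}

# Braak scores arrive as integers or Roman numerals; anything else (or
# values outside 0-6) maps to NA so the alignment step can drop the sample.
parse_braak <- function(x) {
  x <- toupper(trimws(as.character(x)))
  roman <- c("0" = 0L, "I" = 1L, "II" = 2L, "III" = 3L,
             "IV" = 4L, "V" = 5L, "VI" = 6L)
  out <- unname(roman[x])
  numeric_in <- suppressWarnings(as.integer(x))
  out[is.na(out)] <- numeric_in[is.na(out)]
  out[!is.na(out) & (out < 0L | out > 6L)] <- NA_integer_
  out
}

#' Read a pathway gene panel
#'
#' Panels are plain text, one gene ID per line; blank lines and `#`
#' comments are ignored. The panel name defaults to the file name without
#' extension.
#'
#' @param path Path to the panel file.
#' @param panel_name Panel label (e.g. `"GABAergic"`, `"mitochondrial"`).
#' @return A `pathway_panel`: a list with `panel_name` and `gene_ids`.
#' @export
read_pathway_panel <- function(path, panel_name = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (is.null(panel_name)) {
    panel_name <- sub("\\.[^.]*$", "", basename(path))
  }
  pathway_panel(panel_name, ids)
}

#' Construct a pathway panel
#'
#' @param panel_name Panel label.
#' @param gene_ids Character vector of gene IDs; must be non-empty and
#'   unique within the panel.
#' @return A `pathway_panel` object.
#' @export
pathway_panel <- function(panel_name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) abort("A pathway panel cannot be empty.")
  if (anyDuplicated(gene_ids)) {
    abort("Gene IDs must be unique within a pathway panel.")
  }
  structure(list(panel_name = panel_name, gene_ids = gene_ids),
            class = "pathway_panel")
}

#' Align a region's expression matrix with clinical stage labels
#'
#' Links every sample of a region's expression matrix to its subject's
#' Braak score, converts scores to the three-class stage label via
#' [braak_to_stage()], and drops samples whose subject has a missing or
#' ambiguous score (the drop count is reported as a message). Gene order is
#' never changed; sample order is the expression matrix's order restricted
#' to retained samples.
#'
#' @param expr Numeric samples x genes matrix.
#' @param clinical Clinical tibble from [read_clinical_table()].
#' @param sample_to_subject Named character vector mapping sample IDs
#'   (names) to subject IDs (values). Samples whose subject is absent from
#'   `clinical` are an error.
#' @return A `region_dataset`: list with `region`, `expression`, `labels`
#'   (named integer vector in 0/1/2) and `subject_map`.
#' @export
align_region <- function(expr, clinical, sample_to_subject) {
  assert_expression_matrix(expr, "expr")
  samples <- rownames(expr)
  if (is.null(samples)) abort("`expr` must carry sample IDs as row names.")
  missing_map <- setdiff(samples, names(sample_to_subject))
  if (length(missing_map) > 0L) {
    abort(sprintf("Samples without a subject mapping: %s",
                  paste(missing_map, collapse = ", ")))
  }
  subjects <- sample_to_subject[samples]
  unknown <- setdiff(subjects, clinical$subject_id)
  if (length(unknown) > 0L) {
    abort(sprintf("Samples map to subjects absent from the clinical table: %s",
                  paste(unknown, collapse = ", ")))
  }
  braak <- clinical$braak[match(subjects, clinical$subject_id)]
  stage <- braak_to_stage(braak)
  keep <- !is.na(stage)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(sprintf("align_region: dropped %d sample(s) with missing Braak score.",
                   n_dropped))
  }
  kept <- expr[keep, , drop = FALSE]
  region_of(kept) <- region_of(expr)
  structure(
    list(region = region_of(expr),
         expression = kept,
         labels = setNames(stage[keep], samples[keep]),
         subject_map = sample_to_subject[samples[keep]]),
    class = "region_dataset")
}

#' @export
print.region_dataset <- function(x, ...) {
  cat(sprintf("<region_dataset> %s: %d samples x %d genes\n",
              x$region, nrow(x$expression), ncol(x$expression)))
  cat("  stage counts:",
      paste(sprintf("%s=%d", STAGE_LEVELS, tabulate(x$labels + 1L, 3L)),
            collapse = ", "), "\n")
  invisible(x)
}
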