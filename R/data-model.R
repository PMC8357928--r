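# Typed containers and TSV readers/writers for the five input table kinds,
# sample alignment, and the abundance transforms used by the models.
#
# All files are UTF-8 tab-separated with a header row, '.' decimals, and
# '#'-prefixed comment lines ignored.

#' Construct an abundance table
#'
#' Samples x taxa relative abundances (fractions of the community). Per-sample
#' totals may be below 1 (sub-communities are allowed) but not meaningfully
#' above it. Inputs whose rows sum to ~100 are detected as percentages and
#' rescaled to fractions with a message.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns; rownames are
#'   sample IDs, colnames taxon IDs.
#' @param group Optional character/factor of per-sample group labels
#'   (e.g. rural / urban / external).
#' @return Object of class `abundance_table`.
#' @export
abundance_table <- function(values, group = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("abundance matrix needs sample rownames and taxon colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop(sprintf("duplicate sample ID: '%s'", dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate taxon IDs", call. = FALSE)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  }
  rs <- rowSums(values)
  if (length(rs) > 0 && all(rs > 50) && all(abs(rs - 100) < 5)) {
    message("abundance rows sum to ~100; interpreting as percentages and rescaling to fractions")
    values <- values / 100
    rs <- rs / 100
  }
  if (any(rs > 1 + 1e-6)) {
    stop(sprintf("sample '%s' has total abundance %.4f > 1",
                 rownames(values)[which.max(rs)], max(rs)), call. = FALSE)
  }
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != nrow(values)) stop("group labels must match sample count", call. = FALSE)
    names(group) <- rownames(values)
  }
  structure(list(values = values, group = group), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$group)) "" else
                sprintf("; groups: %s", paste(names(table(x$group)), table(x$group),
                                              sep = "=", collapse = ", "))))
  invisible(x)
}

#' @export
sample_ids <- function(x, ...) UseMethod("sample_ids")
#' @export
sample_ids.abundance_table <- function(x, ...) rownames(x$values)
#' @export
sample_ids.metabolite_table <- function(x, ...) rownames(x$intensities)
#' @export
sample_ids.data.frame <- function(x, ...) {
  key <- intersect(c("subject_id", "sample_id"), names(x))[1L]
  if (is.na(key)) stop("data frame has neither subject_id nor sample_id", call. = FALSE)
  unique(as.character(x[[key]]))
}

#' Construct a subject metadata table
#'
#' @param df Data frame with columns `subject_id`, `age` (> 0 years),
#'   `sex` (binary), `residency`, plus any extra categorical/ordinal survey
#'   variables.
#' @return Validated data frame of class `subject_metadata`.
#' @export
subject_metadata <- function(df) {
  req <- c("subject_id", "age", "sex", "residency")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$subject_id)) {
    stop(sprintf("duplicate subject ID: '%s'", df$subject_id[duplicated(df$subject_id)][1L]), call. = FALSE)
  }
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("ages must be positive", call. = FALSE)
  if (length(unique(df$sex)) > 2L) stop("sex must be binary", call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("subject_metadata", "data.frame")
  df
}

#' Construct a long-format cytokine measurement table
#'
#' One row per (subject, cytokine, stimulus) with the measured supernatant
#' concentration in pg/mL. Rows with missing or nonpositive concentrations are
#' dropped (they cannot enter a log-linear model); the number dropped is
#' reported via a message and recorded in the `n_dropped` attribute.
#'
#' @param df Data frame with columns subject_id, cytokine, stimulus, concentration.
#' @return Validated data frame of class `cytokine_measurements`.
#' @export
cytokine_measurements <- function(df) {
  req <- c("subject_id", "cytokine", "stimulus", "concentration")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("cytokine table missing column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  bad <- !is.finite(df$concentration) | df$concentration <= 0
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    message(sprintf("dropping %d cytokine record(s) with missing or nonpositive concentration", n_dropped))
    df <- df[!bad, , drop = FALSE]
  }
  key <- paste(df$subject_id, df$cytokine, df$stimulus, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, cytokine, stimulus) record", call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  class(df) <- c("cytokine_measurements", "data.frame")
  df
}

#' Construct a metabolite intensity table with per-peak annotation
#'
#' @param intensities Nonnegative numeric matrix, samples x peaks, with
#'   rownames (sample IDs) and colnames (peak IDs).
#' @param annotation Data frame with columns `peak_id`, `molecular_class`, and
#'   optionally `pathway_ids` and `compound_ids` (comma-separated sets). All
#'   annotated peak IDs must exist in the intensity matrix.
#' @return Object of class `metabolite_table`.
#' @export
metabolite_table <- function(intensities, annotation = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensity matrix needs sample rownames and peak colnames", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (anyDuplicated(rownames(intensities))) stop("duplicate sample IDs", call. = FALSE)
  if (!is.null(annotation)) {
    if (!"peak_id" %in% names(annotation)) stop("annotation needs a peak_id column", call. = FALSE)
    unknown <- setdiff(annotation$peak_id, colnames(intensities))
    if (length(unknown)) {
      stop(sprintf("annotation refers to unknown peak(s): %s",
                   paste(utils::head(unknown, 3L), collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(intensities = intensities, annotation = annotation),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("<metabolite_table> %d samples x %d peaks (%d annotated)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (is.null(x$annotation)) 0L else nrow(x$annotation)))
  invisible(x)
}

#' Construct a species-stratified pathway copy-number table
#'
#' Long format: one row per (sample, species, pathway) with the number of
#' complete pathway copies encoded by that species in that sample, normalized
#' by pathway length. Per-sample total read depth rides along as a named
#' vector.
#'
#' @param df Data frame with columns sample_id, species_id, pathway_id, copies.
#' @param read_depth Named positive numeric vector of per-sample read counts,
#'   covering every sample in `df`.
#' @return Object of class `pathway_copy_table`.
#' @export
pathway_copy_table <- function(df, read_depth) {
  req <- c("sample_id", "species_id", "pathway_id", "copies")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("pathway table missing column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  if (any(df$copies < 0)) stop("copies must be nonnegative", call. = FALSE)
  if (is.null(names(read_depth))) stop("read_depth must be named by sample", call. = FALSE)
  if (any(read_depth <= 0)) stop("read depths must be positive", call. = FALSE)
  missing_depth <- setdiff(unique(df$sample_id), names(read_depth))
  if (length(missing_depth)) {
    stop(sprintf("no read depth for sample(s): %s",
                 paste(utils::head(missing_depth, 3L), collapse = ", ")), call. = FALSE)
  }
  structure(list(records = df, read_depth = read_depth), class = "pathway_copy_table")
}

#' Construct pathway annotation maps
#'
#' @param enzymes Named list: pathway_id -> character set of enzyme IDs.
#' @param compounds Named list: pathway_id -> character set of compound IDs.
#' @return Object of class `pathway_annotation`.
#' @export
pathway_annotation <- function(enzymes, compounds) {
  structure(list(enzymes = enzymes, compounds = compounds),
            class = "pathway_annotation")
}

# ---- TSV I/O ---------------------------------------------------------------

read_tsv_raw <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read one of the five table kinds from TSV
#'
#' Formats:
#' \describe{
#'   \item{abundance}{First column `sample_id`, remaining columns one per
#'     taxon; optional `group` column. With
#'     `orientation = "taxa_by_samples"` (MetaPhlAn-style merged table) the
#'     first column is the taxon ID and the remaining columns are samples.}
#'   \item{metadata}{Columns subject_id, age, sex, residency, plus extras.}
#'   \item{cytokine}{Columns subject_id, cytokine, stimulus, concentration.}
#'   \item{metabolite}{First column `sample_id`, one column per peak;
#'     `annotation_path` optionally points to a TSV with peak_id,
#'     molecular_class, pathway_ids, compound_ids.}
#'   \item{pathway}{Columns sample_id, species_id, pathway_id, copies,
#'     read_depth (repeated per sample, must be consistent).}
#' }
#'
#' @param path TSV file path.
#' @param kind One of "abundance", "metadata", "cytokine", "metabolite", "pathway".
#' @param orientation For abundance tables: "samples_by_taxa" (default) or
#'   "taxa_by_samples".
#' @param annotation_path Optional annotation TSV for metabolite tables.
#' @return A validated typed container (see constructors).
#' @export
read_table <- function(path, kind = c("abundance", "metadata", "cytokine",
                                      "metabolite", "pathway"),
                       orientation = c("samples_by_taxa", "taxa_by_samples"),
                       annotation_path = NULL) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read_tsv_raw(path)
  switch(kind,
    abundance = {
      if (orientation == "taxa_by_samples") {
        taxa <- df[[1L]]
        m <- t(as.matrix(df[, -1L, drop = FALSE]))
        colnames(m) <- taxa
        abundance_table(m)
      } else {
        if (!"sample_id" %in% names(df)) stop("abundance TSV needs a sample_id column", call. = FALSE)
        group <- df$group
        value_cols <- setdiff(names(df), c("sample_id", "group"))
        m <- as.matrix(df[, value_cols, drop = FALSE])
        rownames(m) <- df$sample_id
        abundance_table(m, group = group)
      }
    },
    metadata = subject_metadata(df),
    cytokine = cytokine_measurements(df),
    metabolite = {
      if (!"sample_id" %in% names(df)) stop("metabolite TSV needs a sample_id column", call. = FALSE)
      m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
      rownames(m) <- df$sample_id
      ann <- if (!is.null(annotation_path)) read_tsv_raw(annotation_path) else NULL
      metabolite_table(m, annotation = ann)
    },
    pathway = {
      if (!"read_depth" %in% names(df)) stop("pathway TSV needs a read_depth column", call. = FALSE)
      depth <- tapply(df$read_depth, df$sample_id, function(v) {
        if (length(unique(v)) > 1L) stop("inconsistent read_depth within a sample", call. = FALSE)
        v[1L]
      })
      pathway_copy_table(df[, c("sample_id", "species_id", "pathway_id", "copies")],
                         read_depth = stats::setNames(as.numeric(depth), names(depth)))
    }
  )
}

#' Write a typed table to TSV (inverse of [read_table])
#'
#' @param x A typed container.
#' @param path Output file path.
#' @param header_comment Optional character vector written as leading
#'   '#'-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, header_comment = NULL) {
  emit <- function(df) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header_comment)) {
      writeLines(paste0("# ", header_comment), con)
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (inherits(x, "abundance_table")) {
    df <- data.frame(sample_id = rownames(x$values), check.names = FALSE)
    if (!is.null(x$group)) df$group <- unname(x$group)
    df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
    emit(df)
  } else if (inherits(x, "metabolite_table")) {
    df <- cbind(data.frame(sample_id = rownames(x$intensities)),
                as.data.frame(x$intensities, check.names = FALSE))
    emit(df)
  } else if (inherits(x, "pathway_copy_table")) {
    df <- x$records
    df$read_depth <- unname(x$read_depth[as.character(df$sample_id)])
    emit(df)
  } else if (is.data.frame(x)) {
    emit(as.data.frame(x))
  } else {
    stop("unsupported table type", call. = FALSE)
  }
  invisible(path)
}

# ---- alignment and transforms ---------------------------------------------

#' Align a set of tables on their common samples/subjects
#'
#' Takes the intersection of sample/subject IDs across all supplied tables,
#' subsets every table to that intersection in a single consistent order, and
#' reports how many IDs each table lost. Sample and subject IDs live in one
#' namespace (one stool sample per subject).
#'
#' @param ... Named typed tables (abundance_table, metabolite_table,
#'   subject_metadata, cytokine_measurements, pathway_copy_table).
#' @return List with the aligned tables (same names), `ids` (the common IDs in
#'   final order) and `dropped` (named integer vector of per-table drop counts).
#' @export
align_cohort <- function(...) {
  tables <- list(...)
  if (length(tables) < 1L) stop("need at least one table", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("all tables must be named", call. = FALSE)
  }
  ids_of <- function(x) {
    if (inherits(x, "abundance_table")) rownames(x$values)
    else if (inherits(x, "metabolite_table")) rownames(x$intensities)
    else if (inherits(x, "pathway_copy_table")) unique(as.character(x$records$sample_id))
    else if (is.data.frame(x)) sample_ids(x)
    else stop("unsupported table type in align_cohort", call. = FALSE)
  }
  all_ids <- lapply(tables, ids_of)
  common <- Reduce(intersect, all_ids)
  if (length(common) == 0L) stop("no samples shared by all tables", call. = FALSE)
  common <- all_ids[[1L]][all_ids[[1L]] %in% common]  # stable order from first table
  dropped <- vapply(all_ids, function(v) length(v) - length(common), 1L)

  subset_to <- function(x) {
    if (inherits(x, "abundance_table")) {
      abundance_table(x$values[common, , drop = FALSE],
                      group = if (is.null(x$group)) NULL else x$group[common])
    } else if (inherits(x, "metabolite_table")) {
      metabolite_table(x$intensities[common, , drop = FALSE], annotation = x$annotation)
    } else if (inherits(x, "pathway_copy_table")) {
      keep <- as.character(x$records$sample_id) %in% common
      pathway_copy_table(x$records[keep, , drop = FALSE],
                         read_depth = x$read_depth[names(x$read_depth) %in% common])
    } else {
      key <- intersect(c("subject_id", "sample_id"), names(x))[1L]
      out <- x[as.character(x[[key]]) %in% common, , drop = FALSE]
      if (inherits(x, "subject_metadata")) {
        out <- out[match(common, out[[key]]), , drop = FALSE]
        rownames(out) <- NULL
      }
      out
    }
  }
  out <- lapply(tables, subset_to)
  out$ids <- common
  out$dropped <- dropped
  out
}

#' Prevalence of a taxon
#'
#' Fraction of samples in which the taxon is detected (abundance strictly > 0).
#'
#' @param table An [abundance_table].
#' @param taxon Taxon ID (must exist in the table).
#' @return Fraction in \[0, 1\].
#' @export
prevalence <- function(table, taxon) {
  stopifnot(inherits(table, "abundance_table"))
  if (!taxon %in% colnames(table$values)) {
    stop(sprintf("unknown taxon: '%s'", taxon), call. = FALSE)
  }
  mean(table$values[, taxon] > 0)
}

#' Zero-anchored rank transform of abundances
#'
#' Converts a vector of relative abundances to ranks where every zero maps to
#' rank 0 and the nonzero values receive ranks n_zero, n_zero + 1, ..., n - 1
#' in ascending abundance order (mid-ranks for ties among nonzeros), so a
#' unique maximum in a vector of length n receives rank n - 1.
#'
#' @param values Nonnegative numeric vector.
#' @return Numeric rank vector of the same length (mid-ranks may be .5).
#' @export
rank_transform_abundance <- function(values) {
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("abundances must be finite and nonnegative", call. = FALSE)
  }
  out <- numeric(length(values))
  nz <- values > 0
  n_zero <- sum(!nz)
  if (any(nz)) {
    out[nz] <- n_zero - 1 + rank(values[nz])  # ranks n_zero .. n-1
  }
  out
}

#' Fold change between two nonnegative quantities
#'
#' @param a Numerator (nonnegative).
#' @param b Denominator (strictly positive).
#' @return a / b.
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(a < 0)) stop("numerator must be nonnegative", call. = FALSE)
  a / b
}
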