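#' @title Sample, protein, and abundance containers
#' @description Validated plain data frames are the package's containers:
#'   a sample table (one row per woman/CVL with VMB group, vaginal pH and
#'   per-taxon 16S signal/background columns), a protein table (one row per
#'   identified protein with peptide-evidence fields), and a numeric
#'   protein x sample matrix of normalized total ion intensities
#'   ("relative abundance").
#' @name containers
NULL

#' List the taxa carried by a sample table
#'
#' @param samples A validated sample table.
#' @return Character vector of taxon names (e.g. `"L_iners"`).
#' @export
sample_taxa <- function(samples) {
  nm <- names(samples)
  sub("^sb_", "", nm[startsWith(nm, "sb_")])
}

#' Per-taxon S/B ratios and 16S positivity
#'
#' Accessors for the normalized signal/background ratio and the 16S
#' detection call of one taxon across a sample table.
#'
#' @param samples A validated sample table.
#' @param taxon Taxon name, e.g. `"L_iners"`.
#' @return `sample_sb()`: numeric vector named by sample id;
#'   `sample_positive()`: logical vector named by sample id.
#' @export
sample_sb <- function(samples, taxon) {
  col <- paste0("sb_", taxon)
  if (!col %in% names(samples)) {
    stop("no S/B column for taxon '", taxon, "'", call. = FALSE)
  }
  stats::setNames(samples[[col]], samples$sample_id)
}

#' @rdname sample_sb
#' @export
sample_positive <- function(samples, taxon) {
  col <- paste0("pos_", taxon)
  if (!col %in% names(samples)) {
    stop("no positivity column for taxon '", taxon, "'", call. = FALSE)
  }
  stats::setNames(samples[[col]], samples$sample_id)
}

#' Validate a sample table
#'
#' Checks the invariants of the sample container: unique sample ids, VMB
#' group labels drawn from [VMB_GROUPS], vaginal pH on the 0.5 grid within
#' 2-9, nonnegative S/B ratios, and a positivity column for every taxon.
#' When a `pos_<taxon>` column is absent it is defaulted from `sb > 0`
#' (a microarray S/B of zero means no hybridization signal).
#'
#' @param samples Data frame with columns `sample_id`, `vmb_group`,
#'   `vaginal_ph`, `sb_<taxon>` and optionally `pos_<taxon>`.
#' @return The validated data frame (with positivity columns filled in),
#'   invisibly classed `"lacto_samples"`.
#' @export
validate_samples <- function(samples) {
  req <- c("sample_id", "vmb_group", "vaginal_ph")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id", call. = FALSE)
  }
  bad_grp <- !samples$vmb_group %in% VMB_GROUPS
  if (any(bad_grp)) {
    stop("unknown vmb_group label in row(s) ",
         paste(which(bad_grp), collapse = ", "), ": ",
         paste(unique(samples$vmb_group[bad_grp]), collapse = ", "),
         call. = FALSE)
  }
  bad_ph <- !on_ph_grid(samples$vaginal_ph)
  if (any(bad_ph)) {
    stop("vaginal_ph off the 0.5 grid in [2, 9] in row(s) ",
         paste(which(bad_ph), collapse = ", "), call. = FALSE)
  }
  taxa <- sample_taxa(samples)
  if (length(taxa) == 0) {
    stop("sample table has no sb_<taxon> column", call. = FALSE)
  }
  for (t in taxa) {
    sb <- samples[[paste0("sb_", t)]]
    if (!is.numeric(sb) || any(!is.finite(sb)) || any(sb < 0)) {
      stop("S/B ratios for taxon '", t, "' must be finite and >= 0",
           call. = FALSE)
    }
    pcol <- paste0("pos_", t)
    if (!pcol %in% names(samples)) {
      samples[[pcol]] <- sb > 0
    }
    samples[[pcol]] <- as.logical(samples[[pcol]])
    if (any(is.na(samples[[pcol]]))) {
      stop("positivity for taxon '", t, "' contains NA", call. = FALSE)
    }
  }
  class(samples) <- unique(c("lacto_samples", class(samples)))
  samples
}

#' Validate a protein table
#'
#' Checks accession uniqueness, `best_match` labels, nonnegative integer
#' peptide counts with `unique_peptides <= peptide_count`, and p-values in
#' [0, 1]. Records with a single unique peptide and missing ANOVA p or
#' fragment-series flag are legal here but will fail the evidence filter;
#' a warning lists them.
#'
#' @param proteins Data frame with columns `accession`, `best_match`,
#'   `peptide_count`, `unique_peptides`; optional `confidence_score`,
#'   `anova_p`, `fragment_series_ok`.
#' @return The validated data frame, classed `"lacto_proteins"`.
#' @export
validate_proteins <- function(proteins) {
  req <- c("accession", "best_match", "peptide_count", "unique_peptides")
  miss <- setdiff(req, names(proteins))
  if (length(miss)) {
    stop("protein table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  proteins$accession <- as.character(proteins$accession)
  if (anyDuplicated(proteins$accession)) {
    stop("duplicated accession", call. = FALSE)
  }
  if (nrow(proteins) == 0) {
    # a header-only file reads every column as logical; fix the types
    proteins$best_match <- character(0)
    proteins$peptide_count <- integer(0)
    proteins$unique_peptides <- integer(0)
    proteins$confidence_score <- numeric(0)
    proteins$anova_p <- numeric(0)
    proteins$fragment_series_ok <- logical(0)
    class(proteins) <- unique(c("lacto_proteins", class(proteins)))
    return(proteins)
  }
  bad_bm <- !proteins$best_match %in% BEST_MATCH_LEVELS
  if (any(bad_bm)) {
    stop("unknown best_match label in row(s) ",
         paste(which(bad_bm), collapse = ", "), call. = FALSE)
  }
  for (col in c("peptide_count", "unique_peptides")) {
    v <- proteins[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != round(v))) {
      stop(col, " must be nonnegative integers", call. = FALSE)
    }
    proteins[[col]] <- as.integer(v)
  }
  bad <- proteins$unique_peptides > proteins$peptide_count
  if (any(bad)) {
    stop("unique_peptides > peptide_count in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (!"confidence_score" %in% names(proteins)) {
    proteins$confidence_score <- NA_real_
  }
  if (!"anova_p" %in% names(proteins)) proteins$anova_p <- NA_real_
  if (!"fragment_series_ok" %in% names(proteins)) {
    proteins$fragment_series_ok <- NA
  }
  proteins$anova_p <- as.numeric(proteins$anova_p)
  pv <- proteins$anova_p
  if (any(!is.na(pv) & (pv < 0 | pv > 1))) {
    stop("anova_p outside [0, 1]", call. = FALSE)
  }
  proteins$fragment_series_ok <- as.logical(proteins$fragment_series_ok)
  needs_meta <- proteins$unique_peptides == 1 &
    (is.na(proteins$anova_p) | is.na(proteins$fragment_series_ok))
  if (any(needs_meta)) {
    warning("protein(s) with a single unique peptide lack anova_p or ",
            "fragment_series_ok and will fail the inclusion filter: ",
            paste(proteins$accession[needs_meta], collapse = ", "),
            call. = FALSE)
  }
  class(proteins) <- unique(c("lacto_proteins", class(proteins)))
  proteins
}

#' Validate an abundance matrix
#'
#' A numeric protein x sample matrix of normalized total ion intensities.
#' Missing measurements are represented as explicit zeros (a protein not
#' detected in a run), so all entries must be finite and nonnegative.
#'
#' @param m Numeric matrix with accessions as row names and sample ids as
#'   column names.
#' @return The matrix, invisibly, after validation.
#' @export
validate_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("abundance matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("abundance matrix needs accession row names and sample id ",
         "column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicated row or column names in abundance matrix", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("abundance values must be finite and >= 0 (missing measurements ",
         "are explicit zeros)", call. = FALSE)
  }
  invisible(m)
}

# ---- readers / writers ----------------------------------------------------

read_delim_auto <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `vmb_group`, `vaginal_ph`, per-taxon S/B
#' columns named `sb:<taxon>`, and optional positivity columns
#' `pos:<taxon>`. When positivity columns are absent, positivity defaults
#' to `S/B > 0`. Files are UTF-8 with a decimal point; tab-separated is the
#' primary dialect, comma-separated is accepted.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A validated sample table.
#' @export
read_sample_table <- function(path, format = c("tsv", "csv")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read_delim_auto(path, match.arg(format))
  names(raw) <- sub("^sb:", "sb_", names(raw))
  names(raw) <- sub("^pos:", "pos_", names(raw))
  out <- validate_samples(raw)
  message(nrow(out), " sample record(s) read from ", path)
  out
}

#' Write a sample table
#'
#' Inverse of [read_sample_table()]; internal `sb_`/`pos_` columns are
#' written with the `sb:`/`pos:` header convention.
#'
#' @param samples A validated sample table.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  out <- as.data.frame(samples)
  names(out) <- sub("^sb_", "sb:", names(out))
  names(out) <- sub("^pos_", "pos:", names(out))
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein metadata table
#'
#' Expects columns `accession`, `best_match`, `peptide_count`,
#' `unique_peptides`; optional `confidence_score`, `anova_p`,
#' `fragment_series_ok`.
#'
#' @inheritParams read_sample_table
#' @return A validated protein table.
#' @export
read_protein_table <- function(path, format = c("tsv", "csv")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read_delim_auto(path, match.arg(format))
  out <- validate_proteins(raw)
  message(nrow(out), " protein record(s) read from ", path)
  out
}

#' Write a protein table
#'
#' @param proteins A validated protein table.
#' @inheritParams write_sample_table
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteins, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  utils::write.table(as.data.frame(proteins), path,
                     sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an abundance matrix
#'
#' Tab-separated with accessions in the first column (`accession`) and one
#' column per sample id.
#'
#' @param path Path to the file.
#' @return `read_abundance_matrix()`: a validated numeric matrix.
#' @export
read_abundance_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  validate_matrix(m)
  message(nrow(m), " x ", ncol(m), " abundance matrix read from ", path)
  m
}

#' @rdname read_abundance_matrix
#' @param m Numeric matrix (proteins x samples).
#' @return `write_abundance_matrix()`: `path`, invisibly.
#' @export
write_abundance_matrix <- function(m, path) {
  validate_matrix(m)
  out <- data.frame(accession = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
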