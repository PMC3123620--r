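#' Validate a Ct matrix
#'
#' A Ct matrix is a plain numeric matrix of cycle-threshold values with
#' miRNA (feature) rownames and sample colnames. Missing wells
#' ("Undetermined" reactions) are `NA`. All non-missing values must be
#' finite and strictly positive; feature and sample identifiers must be
#' unique and non-empty.
#'
#' @param m numeric matrix, features x samples.
#' @return `m`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validate_ct_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("Ct matrix must be a numeric matrix (features x samples)")
  }
  fid <- rownames(m)
  sid <- colnames(m)
  if (is.null(fid) || anyNA(fid) || any(!nzchar(fid))) {
    stop("Ct matrix must have non-empty feature rownames")
  }
  if (is.null(sid) || anyNA(sid) || any(!nzchar(sid))) {
    stop("Ct matrix must have non-empty sample colnames")
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  v <- m[!is.na(m)]
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all non-missing Ct values must be finite and > 0")
  }
  invisible(m)
}

.ct_missing_tokens <- c("", "NA", "Undetermined", "undetermined")

#' Read a Ct matrix from delimited text
#'
#' Expected layout: header row of sample identifiers, first column of
#' feature identifiers, one Ct value per cell. Cells equal to
#' `"Undetermined"`, `"NA"` or empty are read as missing wells. Row and
#' column order are preserved.
#'
#' TaqMan array cards can carry the same miRNA on both card A and card B;
#' by default duplicated feature rows are rejected (the file is ambiguous),
#' and `collapse_duplicates = TRUE` merges them by per-feature mean Ct
#' before entry into the pipeline.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma).
#' @param collapse_duplicates merge duplicated feature rows by mean Ct
#'   instead of rejecting them.
#' @return a validated Ct matrix (see [validate_ct_matrix()]).
#' @seealso [write_ct_table()] for the lossless inverse.
#' @export
read_ct_table <- function(path, sep = ",", collapse_duplicates = FALSE) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    stop("Ct table needs a feature-id column plus at least one sample column")
  }
  feature_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  miss <- matrix(cells %in% .ct_missing_tokens | is.na(cells),
                 nrow = nrow(cells))
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!miss & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric Ct value '%s' at feature '%s', sample '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]],
                 feature_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  num[miss] <- NA_real_
  dimnames(num) <- list(feature_ids, sample_ids)
  if (anyDuplicated(feature_ids)) {
    if (!collapse_duplicates) {
      stop("duplicate feature id(s): ",
           paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
           " (set collapse_duplicates = TRUE to merge by mean Ct)")
    }
    num <- collapse_duplicate_features(num)
  }
  validate_ct_matrix(num)
  num
}

#' Merge duplicated feature rows by per-feature mean Ct
#'
#' Duplicated assays for the same miRNA are collapsed to their mean Ct per
#' sample, ignoring missing wells (all wells missing stays missing). First
#' occurrence order is kept.
#'
#' @param m numeric matrix whose rownames may repeat.
#' @return matrix with unique feature rownames.
#' @export
collapse_duplicate_features <- function(m) {
  ids <- rownames(m)
  if (is.null(ids)) stop("matrix must have feature rownames")
  uniq <- unique(ids)
  out <- matrix(NA_real_, nrow = length(uniq), ncol = ncol(m),
                dimnames = list(uniq, colnames(m)))
  for (f in uniq) {
    rows <- m[ids == f, , drop = FALSE]
    v <- colMeans(rows, na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    out[f, ] <- v
  }
  out
}

#' Write a Ct matrix to delimited text
#'
#' Missing wells are written as empty cells. Values are serialized at full
#' double precision so that `read_ct_table(write_ct_table(m))` round-trips
#' exactly.
#'
#' @param m Ct matrix.
#' @param path output file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(m, path, sep = ",") {
  validate_ct_matrix(m)
  chr <- apply(m, 2L, function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- ""
    out
  })
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(m))
  df <- data.frame(feature_id = rownames(m), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(m))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Validate a sample annotation table
#'
#' Required columns: `sample_id`, `case_id`, `tissue_class`
#' (`"normal"`/`"malignant"`). Optional clinical columns: `gleason_score`
#' (integer 6-10), `tumor_pct` (0-100), `who_grade` (1-3); absent values
#' are `NA`.
#'
#' @param a data.frame of per-sample metadata.
#' @return `a` with optional columns filled in, invisibly-validated.
#' @export
validate_sample_annotation <- function(a) {
  need <- c("sample_id", "case_id", "tissue_class")
  missing_cols <- setdiff(need, colnames(a))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(a$sample_id)) {
    stop("duplicate sample id(s) in annotation: ",
         paste(unique(a$sample_id[duplicated(a$sample_id)]), collapse = ", "))
  }
  if (!all(a$tissue_class %in% c("normal", "malignant"))) {
    stop("tissue_class must be 'normal' or 'malignant'")
  }
  for (col in c("gleason_score", "tumor_pct", "who_grade")) {
    if (is.null(a[[col]])) a[[col]] <- NA_real_
  }
  gs <- a$gleason_score[!is.na(a$gleason_score)]
  if (length(gs) > 0L && (any(gs < 6) || any(gs > 10))) {
    stop("gleason_score must lie in [6, 10]")
  }
  tp <- a$tumor_pct[!is.na(a$tumor_pct)]
  if (length(tp) > 0L && (any(tp < 0) || any(tp > 100))) {
    stop("tumor_pct must lie in [0, 100]")
  }
  wg <- a$who_grade[!is.na(a$who_grade)]
  if (length(wg) > 0L && !all(wg %in% 1:3)) {
    stop("who_grade must be 1, 2 or 3")
  }
  a
}

#' Read / write sample annotation tables
#'
#' Delimited text with header
#' `sample_id,case_id,tissue_class,gleason_score,tumor_pct,who_grade`.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return `read_sample_annotation`: a validated annotation data.frame.
#' @export
read_sample_annotation <- function(path, sep = ",") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  a <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         na.strings = c("", "NA"), stringsAsFactors = FALSE)
  validate_sample_annotation(a)
}

#' @rdname read_sample_annotation
#' @param a annotation data.frame.
#' @export
write_sample_annotation <- function(a, path, sep = ",") {
  a <- validate_sample_annotation(a)
  utils::write.table(a, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = "")
  invisible(path)
}

#' Exclude samples and update pairing status
#'
#' Removes the named samples from matrix and annotation. If an exclusion
#' breaks a normal/malignant pair, the orphaned partner is flagged
#' (`in_paired_analysis = FALSE`) so paired statistics skip it, but it is
#' retained in the matrix: clustering and PCA operate on samples, not
#' pairs.
#'
#' @param m Ct matrix.
#' @param a sample annotation.
#' @param sample_ids samples to drop.
#' @return list with elements `ct` and `annotation`; the annotation gains a
#'   logical `in_paired_analysis` column.
#' @export
exclude_samples <- function(m, a, sample_ids = character()) {
  a <- validate_sample_annotation(a)
  unknown <- setdiff(sample_ids, a$sample_id)
  if (length(unknown) > 0L) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(colnames(m), sample_ids)
  m2 <- m[, keep, drop = FALSE]
  a2 <- a[a$sample_id %in% keep, , drop = FALSE]
  complete <- vapply(split(a2$tissue_class, a2$case_id),
                     function(tc) sum(tc == "normal") == 1L &&
                                  sum(tc == "malignant") == 1L,
                     logical(1L))
  a2$in_paired_analysis <- a2$case_id %in% names(complete)[complete]
  orphans <- a2$sample_id[!a2$in_paired_analysis]
  if (length(orphans) > 0L) {
    message("orphaned pair partner(s) excluded from paired analyses: ",
            paste(orphans, collapse = ", "))
  }
  rownames(a2) <- NULL
  list(ct = m2, annotation = a2)
}

#' Complete normal/malignant pairs
#'
#' Cases contributing exactly one normal and one malignant sample (and not
#' flagged out of paired analysis by [exclude_samples()]).
#'
#' @param a sample annotation.
#' @return data.frame with columns `case_id`, `normal`, `malignant`.
#' @export
complete_pairs <- function(a) {
  a <- validate_sample_annotation(a)
  if (!is.null(a$in_paired_analysis)) {
    a <- a[a$in_paired_analysis, , drop = FALSE]
  }
  out <- lapply(split(a, a$case_id), function(g) {
    n <- g$sample_id[g$tissue_class == "normal"]
    m <- g$sample_id[g$tissue_class == "malignant"]
    if (length(n) == 1L && length(m) == 1L) {
      data.frame(case_id = g$case_id[1L], normal = n, malignant = m,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(case_id = character(), normal = character(),
                      malignant = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(match(out$case_id, unique(a$case_id))), , drop = FALSE]
}

#' Drop control assays from a Ct matrix
#'
#' @param m Ct matrix.
#' @param roles data.frame with columns `feature_id` and `role`
#'   (`"target"` or `"control"`). Features not listed are treated as
#'   targets.
#' @return the matrix restricted to target features (possibly 0 rows).
#' @export
drop_controls <- function(m, roles) {
  if (!all(c("feature_id", "role") %in% colnames(roles))) {
    stop("roles must have columns 'feature_id' and 'role'")
  }
  if (!all(roles$role %in% c("target", "control"))) {
    stop("role must be 'target' or 'control'")
  }
  ctrl <- roles$feature_id[roles$role == "control"]
  m[!(rownames(m) %in% ctrl), , drop = FALSE]
}
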