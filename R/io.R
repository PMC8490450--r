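# Readers and writers for every table the pipeline touches.
#
# Coordinate convention: 1-based inclusive throughout (MAF/SEG style), for
# variant positions and for segment start/end.

#' Read a genes-by-samples expression matrix
#'
#' Tab-separated file, gene identifiers in the first column, a header row of
#' sample identifiers. Values must be numeric and complete: missing cells are
#' an error, never imputed. Duplicate gene rows are collapsed by keeping the
#' row with the highest mean expression (deterministic; ties broken by file
#' order). Duplicate sample columns are an error.
#'
#' @param path file path.
#' @param log_transform if `TRUE`, apply `log2(x + 1)` to the values as read.
#' @return numeric matrix (genes x samples) with attribute `is_centered`
#'   set to `FALSE`.
#' @export
read_expression <- function(path, log_transform = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus samples: ", path)
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    stop("non-numeric expression values in column(s): ",
         paste(samples[bad], collapse = ", "))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing expression value at gene '", genes[idx[1L]],
         "', sample '", samples[idx[2L]], "'")
  }
  rownames(m) <- NULL
  if (log_transform) m <- log2(m + 1)
  if (anyDuplicated(genes)) {
    keep <- order(rowMeans(m), decreasing = TRUE)
    keep <- keep[!duplicated(genes[keep])]
    keep <- sort(keep)
    message("collapsed ", length(genes) - length(keep),
            " duplicate gene row(s) by maximum mean expression")
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(m) <- genes
  expression_matrix(m, is_centered = FALSE)
}

#' Construct/validate an expression matrix
#'
#' @param values numeric genes x samples matrix with unique dimnames and
#'   finite values, log2 scale.
#' @param is_centered whether every gene row has median 0 (checked to 1e-9).
#' @return the matrix with attribute `is_centered`.
#' @export
expression_matrix <- function(values, is_centered = FALSE) {
  check_named_matrix(values, "expression matrix")
  if (is_centered) {
    med <- apply(values, 1L, stats::median)
    if (any(abs(med) > 1e-9)) stop("is_centered = TRUE but gene medians are not 0")
  }
  attr(values, "is_centered") <- is_centered
  values
}

is_centered <- function(expr) isTRUE(attr(expr, "is_centered"))

#' Write an expression matrix as TSV
#' @param expr genes x samples matrix.
#' @param path output path.
#' @param id_column header for the gene-identifier column.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

maf_required <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2")

#' Read a somatic variant table (MAF-compatible)
#'
#' Required columns: `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`
#' (1-based), `Reference_Allele`, `Tumor_Seq_Allele2`. Optional:
#' `Hugo_Symbol`, `HGVSp_Short`, `CONTEXT` (3-mer centered on the mutated
#' base). Rows violating the single-nucleotide contract (ref == alt, alleles
#' outside A/C/G/T, context whose middle base differs from the reference
#' allele) are rejected with a per-row report.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `protein_change`, `context`; attribute `rejected` holds the
#'   report of dropped rows.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(maf_required, colnames(df))
  if (length(missing))
    stop("missing mandatory MAF column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(
    sample_id = df$Tumor_Sample_Barcode,
    chrom = df$Chromosome,
    pos = as.integer(df$Start_Position),
    ref = toupper(df$Reference_Allele),
    alt = toupper(df$Tumor_Seq_Allele2),
    gene = if ("Hugo_Symbol" %in% colnames(df)) df$Hugo_Symbol else NA_character_,
    protein_change = if ("HGVSp_Short" %in% colnames(df)) df$HGVSp_Short else NA_character_,
    context = if ("CONTEXT" %in% colnames(df)) toupper(df$CONTEXT) else NA_character_,
    stringsAsFactors = FALSE)
  validate_variants(out)
}

#' Validate a variant table, rejecting malformed rows
#' @param vt data.frame in the `read_variants()` layout.
#' @return the valid rows, with a `rejected` attribute describing the rest.
#' @export
validate_variants <- function(vt) {
  bases <- c("A", "C", "G", "T")
  reason <- character(nrow(vt))
  bad_allele <- !(vt$ref %in% bases) | !(vt$alt %in% bases)
  reason[bad_allele] <- "allele not a single A/C/G/T base"
  same <- !bad_allele & vt$ref == vt$alt
  reason[same] <- "ref equals alt"
  has_ctx <- !is.na(vt$context) & vt$context != ""
  bad_ctx <- has_ctx & !bad_allele & !same &
    (nchar(vt$context) != 3L | substr(vt$context, 2L, 2L) != vt$ref)
  reason[bad_ctx] <- "context middle base does not match ref"
  drop <- reason != ""
  if (any(drop)) {
    rep <- data.frame(row = which(drop), reason = reason[drop])
    warning("rejected ", sum(drop), " variant row(s): ",
            paste(unique(reason[drop]), collapse = "; "))
  } else rep <- data.frame(row = integer(), reason = character())
  out <- vt[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rep
  out
}

#' Write a variant table as MAF-compatible TSV
#' @param vt variant table (see [read_variants()]).
#' @param path output path.
#' @export
write_variants <- function(vt, path) {
  df <- data.frame(Tumor_Sample_Barcode = vt$sample_id,
                   Chromosome = vt$chrom,
                   Start_Position = vt$pos,
                   Reference_Allele = vt$ref,
                   Tumor_Seq_Allele2 = vt$alt,
                   Hugo_Symbol = vt$gene,
                   HGVSp_Short = vt$protein_change,
                   CONTEXT = vt$context,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct/validate a copy-number table
#'
#' @param features data.frame with `feature_id` plus optional `chrom`,
#'   `start`, `end` (1-based inclusive; `start <= end`).
#' @param values numeric features x samples matrix of continuous copy-number
#'   values.
#' @param calls optional integer matrix of discretized calls in
#'   \{-2, -1, 0, 1, 2\}, same dimensions as `values`.
#' @return list of class `cn_table`.
#' @export
cn_table <- function(features, values, calls = NULL) {
  stopifnot(is.data.frame(features), "feature_id" %in% colnames(features))
  if (anyDuplicated(features$feature_id)) stop("duplicate feature identifiers")
  if (nrow(features) != nrow(values)) stop("features and values disagree on rows")
  rownames(values) <- features$feature_id
  check_named_matrix(values, "copy-number values")
  if (all(c("start", "end") %in% colnames(features)) &&
      any(features$start > features$end, na.rm = TRUE))
    stop("segment start > end")
  if (!is.null(calls)) {
    if (!all(dim(calls) == dim(values))) stop("calls and values grids differ in dimension")
    if (!all(calls %in% -2:2)) stop("calls outside {-2,...,2}")
    dimnames(calls) <- dimnames(values)
  }
  structure(list(features = features, values = values, calls = calls),
            class = "cn_table")
}

#' Read gene/segment-level copy number (matrix TSVs)
#'
#' @param values_path features x samples TSV of continuous values (first
#'   column feature id).
#' @param calls_path optional TSV of discretized calls, same layout.
#' @param features_path optional TSV with `feature_id`, `chrom`, `start`,
#'   `end` giving 1-based inclusive coordinates.
#' @return `cn_table`.
#' @export
read_copy_number <- function(values_path, calls_path = NULL, features_path = NULL) {
  vals <- read_expression(values_path)
  attr(vals, "is_centered") <- NULL
  calls <- NULL
  if (!is.null(calls_path)) {
    calls <- read_expression(calls_path)
    attr(calls, "is_centered") <- NULL
    calls <- calls[rownames(vals), colnames(vals), drop = FALSE]
    storage.mode(calls) <- "integer"
  }
  if (!is.null(features_path)) {
    feats <- utils::read.delim(features_path, stringsAsFactors = FALSE)
    feats <- feats[match(rownames(vals), feats$feature_id), , drop = FALSE]
  } else {
    feats <- data.frame(feature_id = rownames(vals), stringsAsFactors = FALSE)
  }
  cn_table(feats, vals, calls)
}

#' Write a copy-number table (values, calls, features TSVs)
#' @param cn `cn_table`.
#' @param values_path,calls_path,features_path output paths (`NULL` to skip).
#' @export
write_copy_number <- function(cn, values_path, calls_path = NULL,
                              features_path = NULL) {
  write_expression(cn$values, values_path, id_column = "feature_id")
  if (!is.null(calls_path) && !is.null(cn$calls))
    write_expression(cn$calls, calls_path, id_column = "feature_id")
  if (!is.null(features_path))
    utils::write.table(cn$features, features_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(values_path)
}

#' Read a SEG-format segment file
#'
#' Columns `Sample`, `Chromosome`, `Start`, `End`, `Segment_Mean` (1-based
#' inclusive coordinates). Rows with `Start > End` or non-finite means are
#' rejected with a report.
#' @param path file path.
#' @return long data.frame `sample_id`, `chrom`, `start`, `end`, `seg_mean`
#'   with a `rejected` attribute.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) stop("missing SEG column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$Sample),
                    chrom = as.character(df$Chromosome),
                    start = as.integer(df$Start), end = as.integer(df$End),
                    seg_mean = as.numeric(df$Segment_Mean),
                    stringsAsFactors = FALSE)
  bad <- out$start > out$end | !is.finite(out$seg_mean)
  if (any(bad)) {
    warning("rejected ", sum(bad), " SEG row(s) (start > end or non-finite mean)")
    rep <- data.frame(row = which(bad),
                      reason = ifelse(out$start[bad] > out$end[bad],
                                      "start > end", "non-finite segment mean"))
  } else rep <- data.frame(row = integer(), reason = character())
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rep
  out
}

#' Read a clinical table
#'
#' Required columns: `sample_id`, `time_days` (nonnegative), `event` (0/1).
#' Any further columns are carried as covariates. Rows with negative times or
#' non-binary events are rejected with a report.
#' @param path file path.
#' @return data.frame with a `rejected` attribute.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) stop("missing clinical column(s): ", paste(missing, collapse = ", "))
  df$time_days <- as.numeric(df$time_days)
  df$event <- as.integer(df$event)
  bad <- !is.finite(df$time_days) | df$time_days < 0 | !(df$event %in% c(0L, 1L))
  if (any(bad)) {
    warning("rejected ", sum(bad), " clinical row(s) (negative time or non-binary event)")
    rep <- data.frame(row = which(bad), reason = "negative time or non-binary event")
  } else rep <- data.frame(row = integer(), reason = character())
  if (anyDuplicated(df$sample_id[!bad])) stop("duplicate sample identifiers in clinical table")
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rep
  out
}

#' Write a clinical table as TSV
#' @param clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 96-motif signature catalog
#'
#' TSV with one row per trinucleotide substitution motif labeled like
#' `"A[C>T]G"` (first column) and one column per signature. Rows are aligned
#' to the canonical motif order by label, never by position. Each signature
#' column must be nonnegative; columns whose sum deviates from 1 by more than
#' `tol` but less than 0.5 are renormalized with a warning, larger deviations
#' are an error.
#'
#' @param path file path.
#' @param tol column-sum tolerance before renormalization kicks in.
#' @return 96 x K numeric matrix, rows in `motif_labels()` order, columns
#'   summing to 1.
#' @export
read_catalog <- function(path, tol = 1e-6) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- labels
  signature_catalog(m, tol = tol)
}

#' Construct/validate a signature catalog
#' @param m numeric matrix with the 96 motif labels as rownames.
#' @param tol column-sum tolerance (see [read_catalog()]).
#' @return validated, label-ordered, column-normalized matrix.
#' @export
signature_catalog <- function(m, tol = 1e-6) {
  canon <- motif_labels()
  if (nrow(m) != 96L || !setequal(rownames(m), canon))
    stop("catalog must have exactly the 96 canonical motif rows")
  m <- m[canon, , drop = FALSE]
  if (any(m < 0)) stop("catalog weights must be nonnegative")
  cs <- colSums(m)
  off <- abs(cs - 1) > tol
  if (any(abs(cs - 1) >= 0.5))
    stop("catalog column(s) ", paste(colnames(m)[abs(cs - 1) >= 0.5], collapse = ", "),
         " deviate from sum 1 by 0.5 or more")
  if (any(off)) {
    warning("renormalized ", sum(off), " catalog column(s) whose sums deviated from 1")
    m[, off] <- sweep(m[, off, drop = FALSE], 2L, cs[off], "/")
  }
  m
}

#' Write a signature catalog as TSV
#' @param catalog 96 x K matrix with motif-label rownames.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  write_expression(catalog, path, id_column = "motif")
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) in GMT")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default analysis configuration
#'
#' Every tunable threshold of the pipeline in one list; [read_config()]
#' overlays a YAML file on these defaults.
#' @return nested list of settings.
#' @export
default_config <- function() {
  list(
    classification = list(
      min_expr = 1, min_expr_fraction = 0.7, top_n_variable = 4035,
      tertile_population = "non_cca_tumors"),
    scores = list(method = "median"),
    signatures = list(k = 6L, n_restarts = 20L, max_iter = 2000L,
                      tol = 1e-8, input = "frequency"),
    cnv = list(alpha = 0.05, fdr_cutoff = 0.05, direction = "loss",
               call_thresholds = c(0.3, 1.0)),
    survival = list(horizon_days = 1826, ties = "efron")
  )
}

#' Read a YAML run configuration
#'
#' Settings present in the file override [default_config()]; everything else
#' keeps its default.
#' @param path YAML file path (`NULL` for pure defaults).
#' @return nested list of settings.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}
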