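#' @keywords internal
"_PACKAGE"

# Typed condition helper: all validation/parse failures raise a classed error
# so callers (and tests) can distinguish them from programming errors.
abort_icb <- function(message, class) {
  stop(structure(
    class = c(class, "icbstrat_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

warn_icb <- function(message, class = "icbstrat_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# ---------------------------------------------------------------------------
# ExpressionMatrix

#' Construct a validated expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix on the
#' log2(x + 1) scale (FPKM/TPM-like units), with unique gene row names and
#' unique sample column names. Missing values are allowed as explicit `NA`;
#' all non-missing values must be finite.
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @return the matrix with class `"expr_matrix"` prepended.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_icb("expression values must be a numeric matrix", "icb_validation_error")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    abort_icb("expression matrix needs gene rownames and sample colnames",
              "icb_validation_error")
  }
  if (anyDuplicated(gid)) {
    abort_icb(sprintf("duplicate gene ids: %s",
                      paste(unique(gid[duplicated(gid)]), collapse = ", ")),
              "icb_validation_error")
  }
  if (anyDuplicated(sid)) {
    abort_icb(sprintf("duplicate sample ids: %s",
                      paste(unique(sid[duplicated(sid)]), collapse = ", ")),
              "icb_validation_error")
  }
  if (nrow(values) < 1L || ncol(values) < 2L) {
    abort_icb("expression matrix needs at least 1 gene and 2 samples",
              "icb_validation_error")
  }
  if (any(!is.na(values) & !is.finite(values))) {
    abort_icb("expression matrix contains non-finite values", "icb_validation_error")
  }
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path file path.
#' @param linear if `TRUE` the file holds linear-scale values and
#'   `log2(x + 1)` is applied on load.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, linear = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    abort_icb("expression TSV needs a gene-id column plus >= 2 sample columns",
              "icb_parse_error")
  }
  gid <- as.character(df[[1L]])
  num <- df[-1L]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "NA" & is.na(conv))
      if (length(bad)) {
        abort_icb(sprintf("non-numeric expression value '%s' at row %d, column '%s'",
                          v[bad[1L]], bad[1L], names(num)[j]),
                  "icb_parse_error")
      }
      num[[j]] <- conv
    }
  }
  m <- as.matrix(num)
  rownames(m) <- gid
  if (linear) {
    if (any(m < 0, na.rm = TRUE)) {
      abort_icb("negative values are not valid linear-scale expression",
                "icb_parse_error")
    }
    m <- log2(m + 1)
  }
  expression_matrix(m)
}

#' Write an expression matrix to TSV
#' @param x an [expression_matrix()].
#' @param path destination path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CopyCallTable

#' Construct a validated copy-call table
#'
#' Gene-level thresholded copy-number calls (GISTIC-style): one integer call
#' in -2..+2 per (sample, gene) pair. -2 homozygous deletion, -1 hemizygous
#' loss, 0 diploid, +1/+2 gain/amplification.
#'
#' @param sample_id,gene_id,call parallel vectors.
#' @return data.frame with class `"copy_calls"`.
#' @export
copy_call_table <- function(sample_id, gene_id, call) {
  sample_id <- as.character(sample_id)
  gene_id <- as.character(gene_id)
  if (length(sample_id) != length(gene_id) || length(gene_id) != length(call)) {
    abort_icb("sample_id, gene_id and call must have equal length",
              "icb_validation_error")
  }
  calln <- suppressWarnings(as.numeric(call))
  bad <- which(is.na(calln) | calln != round(calln) | calln < -2 | calln > 2)
  if (length(bad)) {
    abort_icb(sprintf("copy call out of range {-2..+2}: '%s' (sample %s, gene %s)",
                      as.character(call[bad[1L]]), sample_id[bad[1L]], gene_id[bad[1L]]),
              "icb_validation_error")
  }
  key <- paste(sample_id, gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    abort_icb(sprintf("duplicate call for sample x gene pair: %s",
                      sub("\r", " / ", d, fixed = TRUE)),
              "icb_validation_error")
  }
  out <- data.frame(sample_id = sample_id, gene_id = gene_id,
                    call = as.integer(calln), stringsAsFactors = FALSE)
  class(out) <- c("copy_calls", "data.frame")
  out
}

#' Read gene-level copy calls from TSV
#'
#' Two dialects are auto-detected from the header: long format with columns
#' `sample_id`, `gene_id`, `call` (any order, case-insensitive, `sample`/
#' `gene` accepted), or wide format with gene ids in the first column and
#' one column per sample.
#'
#' @param path file path.
#' @return a [copy_call_table()].
#' @export
read_copy_calls <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  s_col <- match(TRUE, nm %in% c("sample_id", "sample"))
  g_col <- match(TRUE, nm %in% c("gene_id", "gene"))
  c_col <- match(TRUE, nm %in% c("call", "copy_call"))
  if (!is.na(s_col) && !is.na(g_col) && !is.na(c_col)) {
    return(copy_call_table(df[[s_col]], df[[g_col]], df[[c_col]]))
  }
  # wide: first column gene ids, remaining columns samples
  if (ncol(df) < 2L) abort_icb("copy-call TSV has no sample columns", "icb_parse_error")
  gid <- as.character(df[[1L]])
  samples <- names(df)[-1L]
  long <- expand.grid(gene_id = gid, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$call <- unlist(df[-1L], use.names = FALSE)
  copy_call_table(long$sample_id, long$gene_id, long$call)
}

#' Write copy calls to TSV
#' @param x a [copy_call_table()].
#' @param path destination path.
#' @param format `"long"` (sample_id, gene_id, call) or `"wide"`.
#' @export
write_copy_calls <- function(x, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    wide <- stats::reshape(as.data.frame(x), idvar = "gene_id",
                           timevar = "sample_id", direction = "wide")
    names(wide) <- sub("^call\\.", "", names(wide))
    utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# ClinicalTable

.response_vocab <- c("CR", "PR", "SD", "PD", "NE")
.pdl1_ic_vocab <- c("IC0", "IC1", "IC2+")

#' Construct a validated clinical table
#'
#' Recognised columns: `sample_id` (required), `response` (RECIST best
#' response: CR/PR/SD/PD/NE), `dcb` (durable clinical benefit flag),
#' `os_time`/`pfs_time`/`dss_time` in months with matching `*_event` flags,
#' `tmb` (non-negative, unit treated as opaque since only median splits are
#' used), `pdl1_ic` (IC0/IC1/IC2+), `pdl1_tc`, `therapy`, `cancer_type`,
#' `subtype`. Unknown columns are preserved untouched.
#'
#' @param df data.frame with at least a `sample_id` column.
#' @return the data.frame with class `"clinical_table"`.
#' @export
clinical_table <- function(df) {
  if (!"sample_id" %in% names(df)) {
    abort_icb("clinical table requires a sample_id column", "icb_validation_error")
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort_icb("duplicate sample_id in clinical table", "icb_validation_error")
  }
  if ("response" %in% names(df)) {
    bad <- !is.na(df$response) & !(df$response %in% .response_vocab)
    if (any(bad)) {
      abort_icb(sprintf("response outside vocabulary {%s}: '%s'",
                        paste(.response_vocab, collapse = ", "),
                        df$response[bad][1L]),
                "icb_validation_error")
    }
  }
  if ("pdl1_ic" %in% names(df)) {
    bad <- !is.na(df$pdl1_ic) & !(df$pdl1_ic %in% .pdl1_ic_vocab)
    if (any(bad)) {
      abort_icb(sprintf("pdl1_ic outside vocabulary {%s}: '%s'",
                        paste(.pdl1_ic_vocab, collapse = ", "),
                        df$pdl1_ic[bad][1L]),
                "icb_validation_error")
    }
  }
  for (ep in c("os", "pfs", "dss")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (tcol %in% names(df)) {
      if (any(df[[tcol]] < 0, na.rm = TRUE)) {
        abort_icb(sprintf("negative %s", tcol), "icb_validation_error")
      }
    }
    if (ecol %in% names(df)) {
      ev <- df[[ecol]]
      if (!all(is.na(ev) | ev %in% c(0, 1, TRUE, FALSE))) {
        abort_icb(sprintf("%s must be boolean (0/1)", ecol), "icb_validation_error")
      }
      df[[ecol]] <- as.logical(ev)
      if (tcol %in% names(df)) {
        if (any(!is.na(df[[ecol]]) & is.na(df[[tcol]]))) {
          abort_icb(sprintf("%s present without %s", ecol, tcol),
                    "icb_validation_error")
        }
      } else {
        abort_icb(sprintf("%s present without %s column", ecol, tcol),
                  "icb_validation_error")
      }
    }
  }
  if ("tmb" %in% names(df) && any(df$tmb < 0, na.rm = TRUE)) {
    abort_icb("negative tmb", "icb_validation_error")
  }
  if ("dcb" %in% names(df)) df$dcb <- as.logical(df$dcb)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from TSV
#' @param path file path.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  clinical_table(df)
}

#' Write a clinical table to TSV
#' @param x a [clinical_table()].
#' @param path destination path.
#' @export
write_clinical <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeneSetCollection

#' Construct a validated gene-set collection
#'
#' @param sets named list of character vectors (unique set names, non-empty
#'   member lists; duplicate members within a set are removed with a warning).
#' @param category optional tag, e.g. "immune pathway", "cell-type markers",
#'   "target list".
#' @return named list with class `"gene_sets"`.
#' @export
gene_set_collection <- function(sets, category = NA_character_) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort_icb("gene sets must be a named list", "icb_validation_error")
  }
  if (anyDuplicated(names(sets))) {
    abort_icb("duplicate gene-set names", "icb_validation_error")
  }
  for (nm in names(sets)) {
    g <- as.character(sets[[nm]])
    if (length(g) == 0L) {
      abort_icb(sprintf("gene set '%s' is empty", nm), "icb_validation_error")
    }
    if (anyDuplicated(g)) {
      warn_icb(sprintf("gene set '%s' has duplicate members; deduplicated", nm))
      g <- unique(g)
    }
    sets[[nm]] <- g
  }
  structure(sets, category = category, class = c("gene_sets", "list"))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids.
#'
#' @param path file path.
#' @param category optional collection tag.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(path, category = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort_icb("empty GMT file", "icb_parse_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  for (p in parts) {
    if (length(p) < 3L) {
      abort_icb(sprintf("GMT line for set '%s' has no members", p[1L]),
                "icb_parse_error")
    }
    sets[[p[1L]]] <- p[-(1:2)]
  }
  gene_set_collection(sets, category = category)
}

#' Write gene sets to a GMT file
#' @param x a [gene_set_collection()].
#' @param path destination path.
#' @export
write_gene_sets <- function(x, path) {
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, nm, x[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result writer

#' Write a result table with a JSON metadata sidecar
#'
#' Writes `path` as TSV and `path.json` containing run metadata: seed,
#' package version, R version, a hash of the supplied configuration, and the
#' md5 of the TSV payload.
#'
#' @param results data.frame (any module's result table).
#' @param path destination TSV path.
#' @param seed integer seed used for the run (recorded, not applied).
#' @param config optional list of run parameters; hashed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NA_integer_, config = list()) {
  results <- as.data.frame(results)
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  meta <- list(
    seed = seed,
    package = "icbstrat",
    package_version = as.character(utils::packageVersion("icbstrat")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = unname(tools::md5sum(tmp)),
    payload_md5 = unname(tools::md5sum(path)),
    n_rows = nrow(results)
  )
  unlink(tmp)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
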