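# CSV readers/writers for the package's table dialects. All files are
# RFC-4180 CSV, UTF-8, "." decimal. Numbers are written with 17 significant
# digits so writer -> reader round-trips are exact.

.fmtNum <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  out
}

.readValidated <- function(path, required, numeric_cols) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    .warnf("%s: ignoring unknown column(s): %s", path,
           paste(extra, collapse = ", "))
  df <- df[required]
  for (col in numeric_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & !(raw %in% c("", "NA")))
    if (length(bad))
      .stopf("%s:%d: non-numeric value '%s' in column '%s'",
             path, bad[1] + 1L, raw[bad[1]], col)  # +1 for the header line
    df[[col]] <- val
  }
  df
}

#' Read and write the qPCR Cq table dialect
#'
#' Columns: `cultivar,lot,time_h,rep,gene,role,cq`. Malformed numeric cells
#' raise an error naming the file and line; unknown columns are dropped
#' with a warning; an empty file with a valid header yields an empty table.
#'
#' @param path CSV file path.
#' @return `readCqTable()` a [CqTable]; the writer returns `path`
#'   invisibly.
#' @export
readCqTable <- function(path) {
  df <- .readValidated(path, .cq_cols, c("time_h", "rep", "cq"))
  CqTable(df)
}

#' @rdname readCqTable
#' @param x the object to write.
#' @export
writeCqTable <- function(x, path) {
  stopifnot(is(x, "CqTable"))
  df <- x@records
  df$cq <- .fmtNum(df$cq)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write the germination time-course dialect
#'
#' Columns: `condition,replicate,time_h,cumulative,total`, optionally
#' preceded by `cultivar,lot`.
#'
#' @inheritParams readCqTable
#' @return `readGerminationCourses()` a [GerminationCourses].
#' @export
readGerminationCourses <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  header <- names(read.csv(path, nrows = 0))
  cols <- c(intersect(c("cultivar", "lot"), header), .germ_cols)
  df <- .readValidated(path, cols,
                       c("replicate", "time_h", "cumulative", "total"))
  GerminationCourses(df)
}

#' @rdname readGerminationCourses
#' @param x the object to write.
#' @export
writeGerminationCourses <- function(x, path) {
  stopifnot(is(x, "GerminationCourses"))
  write.csv(x@records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write the trait replicate dialect
#'
#' Columns: `cultivar,lot,trait,replicate,value` with an optional `units`
#' column.
#'
#' @inheritParams readCqTable
#' @return `readTraitReplicates()` a [TraitReplicateTable].
#' @export
readTraitReplicates <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  header <- names(read.csv(path, nrows = 0))
  cols <- c(.trait_cols, intersect("units", header))
  df <- .readValidated(path, cols, c("replicate", "value"))
  TraitReplicateTable(df)
}

#' @rdname readTraitReplicates
#' @param x the object to write.
#' @export
writeTraitReplicates <- function(x, path) {
  stopifnot(is(x, "TraitReplicateTable"))
  df <- x@records
  df$value <- .fmtNum(df$value)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write the lot-level trait matrix
#'
#' Stored long: `cultivar,lot,trait,value,orientation`, one row per cell,
#' with full-precision values so the round-trip is exact.
#'
#' @inheritParams readCqTable
#' @return `readTraitMatrix()` a [TraitMatrix].
#' @export
readTraitMatrix <- function(path) {
  df <- .readValidated(path, c("cultivar", "lot", "trait", "value",
                               "orientation"), "value")
  traits <- unique(df$trait)
  lots <- unique(df[c("cultivar", "lot")])
  rownames(lots) <- NULL
  values <- matrix(NA_real_, nrow(lots), length(traits),
                   dimnames = list(paste(lots$cultivar, lots$lot, sep = "."),
                                   traits))
  idx <- cbind(match(paste(df$cultivar, df$lot),
                     paste(lots$cultivar, lots$lot)),
               match(df$trait, traits))
  values[idx] <- df$value
  orient <- setNames(df$orientation[!duplicated(df$trait)], traits)
  new("TraitMatrix", values = values, keys = lots, orientation = orient)
}

#' @rdname readTraitMatrix
#' @param x the object to write.
#' @export
writeTraitMatrix <- function(x, path) {
  stopifnot(is(x, "TraitMatrix"))
  long <- expand.grid(row = seq_len(nrow(x@values)),
                      trait = colnames(x@values), stringsAsFactors = FALSE)
  df <- data.frame(cultivar = x@keys$cultivar[long$row],
                   lot = x@keys$lot[long$row],
                   trait = long$trait,
                   value = .fmtNum(x@values[cbind(long$row,
                                                  match(long$trait,
                                                        colnames(x@values)))]),
                   orientation = unname(x@orientation[long$trait]))
  df <- df[order(match(df$trait, colnames(x@values)), df$cultivar, df$lot), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an expression matrix as long-format CSV
#'
#' Columns: `cultivar,lot,time_h,rep,gene,rq,log2rq`.
#'
#' @inheritParams readCqTable
#' @param x an [ExpressionMatrix].
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  info <- sampleInfo(x)
  genes <- rownames(x)
  long <- data.frame(info[rep(seq_len(nrow(info)), each = length(genes)),
                          c("cultivar", "lot", "time_h", "rep")],
                     gene = rep(genes, nrow(info)),
                     rq = .fmtNum(as.vector(rq(x))),
                     log2rq = .fmtNum(as.vector(log2rq(x))),
                     row.names = NULL)
  write.csv(long, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
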