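## Stream readers and writers.  JSON-lines is the canonical format (a header
## object on the first line, one record object per subsequent line); CSV is
## supported with a JSON sidecar (<path>.meta.json) or, failing that, with
## the column-name convention id, y, x.*, z.*.

.streamFormat <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("jsonl", "csv")))
  if (grepl("\\.csv$", path)) "csv" else "jsonl"
}

#' Write a data stream to disk
#'
#' @param stream a [DataStream-class].
#' @param path output file; extension .csv selects CSV (with a
#'   \code{<path>.meta.json} sidecar), anything else JSON-lines.
#' @param format "jsonl" or "csv"; inferred from the extension when NULL.
#' @return \code{path}, invisibly.
#' @export
writeStream <- function(stream, path, format = NULL) {
  format <- .streamFormat(path, format)
  h <- stream@header
  df <- stream@data
  covCols <- union(h$xCols, h$zCols)
  if (format == "jsonl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(c(list(type = "header"), h),
                                auto_unbox = TRUE, digits = NA), con)
    extraZ <- setdiff(h$zCols, h$xCols)
    xm <- as.matrix(df[, h$xCols, drop = FALSE])
    zm <- if (length(extraZ)) as.matrix(df[, extraZ, drop = FALSE])
    lines <- vapply(seq_len(nrow(df)), function(i) {
      rec <- list(id = df$id[i], y = df$y[i], x = xm[i, ])
      if (length(extraZ)) rec$z <- zm[i, ]
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, con)
  } else {
    utils::write.csv(df[, c("id", "y", covCols)], path, row.names = FALSE)
    jsonlite::write_json(h, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

.headerFromColumns <- function(cols) {
  xCols <- grep("^x\\.", cols, value = TRUE)
  zCols <- grep("^z\\.", cols, value = TRUE)
  if (!length(xCols))
    stop("no sidecar header and no x.* columns to infer a schema from")
  list(p = length(xCols), r = length(zCols), xCols = xCols, zCols = zCols)
}

#' Open a data stream for lazy reading
#'
#' Reads the header, then yields records in file order in chunks of
#' \code{chunkSize} rows so that memory stays constant in the stream length.
#'
#' @param path a JSON-lines or CSV stream file.
#' @param format "jsonl" or "csv"; inferred from the extension when NULL.
#' @param chunkSize rows per chunk (default 1000).
#' @return list with \code{header}, a \code{nextChunk()} function returning a
#'   data.frame (or NULL at end of stream), and \code{close()}.
#' @export
openStream <- function(path, format = NULL, chunkSize = 1000L) {
  format <- .streamFormat(path, format)
  skipped <- 0L
  lineNo <- 0L
  if (format == "jsonl") {
    con <- file(path, "r")
    first <- readLines(con, n = 1L)
    lineNo <- 1L
    if (!length(first)) {
      close(con)
      stop("empty stream file (no header line)")
    }
    header <- tryCatch(jsonlite::fromJSON(first), error = function(e) {
      close(con)
      stop("malformed header on line 1: ", conditionMessage(e))
    })
    if (!identical(header$type, "header")) {
      close(con)
      stop("line 1 is not a header record")
    }
    header$type <- NULL
    covCols <- union(header$xCols, header$zCols)
    extraZ <- setdiff(header$zCols, header$xCols)
    nextChunk <- function() {
      lines <- readLines(con, n = chunkSize)
      if (!length(lines)) return(NULL)
      out <- vector("list", length(lines))
      for (i in seq_along(lines)) {
        lineNo <<- lineNo + 1L
        rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
          stop("malformed record on line ", lineNo, ": ",
               conditionMessage(e)))
        if (is.null(rec$id) || is.null(rec$y) ||
            length(rec$x) != header$p ||
            (length(extraZ) && length(rec$z) != length(extraZ)))
          stop("schema violation on line ", lineNo)
        vals <- c(rec$y, rec$x, if (length(extraZ)) rec$z)
        if (!all(is.finite(vals))) {
          skipped <<- skipped + 1L
          out[i] <- list(NULL)
          next
        }
        row <- c(list(id = as.character(rec$id), y = rec$y),
                 as.list(stats::setNames(rec$x, header$xCols)))
        if (length(extraZ)) row <- c(row, as.list(stats::setNames(rec$z,
                                                                  extraZ)))
        out[[i]] <- as.data.frame(row, check.names = FALSE)
      }
      out <- out[!vapply(out, is.null, logical(1))]
      if (!length(out)) return(data.frame())
      do.call(rbind, out)
    }
    closeFn <- function() close(con)
  } else {
    sidecar <- paste0(path, ".meta.json")
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(id = "character"))
    header <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar)
              else .headerFromColumns(names(df))
    covCols <- union(header$xCols, header$zCols)
    miss <- setdiff(c("id", "y", covCols), names(df))
    if (length(miss))
      stop("CSV stream is missing columns: ", paste(miss, collapse = ", "))
    ok <- is.finite(df$y) &
      rowSums(!is.finite(as.matrix(df[, covCols, drop = FALSE]))) == 0
    skipped <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    pos <- 0L
    nextChunk <- function() {
      if (pos >= nrow(df)) return(NULL)
      take <- seq(pos + 1L, min(pos + chunkSize, nrow(df)))
      pos <<- pos + length(take)
      df[take, , drop = FALSE]
    }
    closeFn <- function() invisible(NULL)
  }
  list(header = header, nextChunk = nextChunk, close = closeFn,
       skipped = function() skipped)
}

#' Read a whole stream file
#'
#' @param path a JSON-lines or CSV stream file.
#' @param format "jsonl" or "csv"; inferred from the extension when NULL.
#' @return A [DataStream-class].  Records with non-finite fields are skipped
#'   with a warning reporting the count.
#' @export
readStream <- function(path, format = NULL) {
  src <- openStream(path, format = format, chunkSize = 100000L)
  on.exit(src$close())
  chunks <- list()
  repeat {
    ch <- src$nextChunk()
    if (is.null(ch)) break
    if (nrow(ch)) chunks[[length(chunks) + 1L]] <- ch
  }
  if (src$skipped() > 0L)
    warning("skipped ", src$skipped(), " record(s) with non-finite fields")
  df <- if (length(chunks)) do.call(rbind, chunks)
        else {
          h <- src$header
          cols <- c("id", "y", union(h$xCols, h$zCols))
          stats::setNames(as.data.frame(
            c(list(character(0), numeric(0)),
              rep(list(numeric(0)), length(cols) - 2L))), cols)
        }
  rownames(df) <- NULL
  h <- src$header
  h <- h[c("p", "r", "xCols", "zCols",
           intersect(names(h), c("condition", "seed", "shiftAt")))]
  h$p <- as.integer(h$p)
  h$r <- as.integer(h$r)
  names(h)[1:4] <- c("p", "r", "xCols", "zCols")
  new("DataStream", header = h, data = df)
}
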