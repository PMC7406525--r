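#' Write annotations as a delimited file for ELAN/ANVIL import
#'
#' Writes a header plus one row per annotation with columns
#' `tier, begin, end, duration, value`, timestamps in `hh:mm:ss.ms`. The
#' duration column is recomputed from begin and end. Output is
#' byte-deterministic for identical input.
#'
#' @param annotations Annotation data frame (`tier`, `begin`, `end`, `value`).
#' @param path Output file path.
#' @param delim Field delimiter: `","` (default) or `"\t"` for tools that
#'   expect tab-separated import.
#' @return Invisibly, `path`.
#' @export
write_annotation_csv <- function(annotations, path, delim = ",") {
  stopifnot(delim %in% c(",", "\t"))
  ann <- .validate_annotations(annotations)
  dur <- .format_ms(timestamp_to_ms(ann$end) - timestamp_to_ms(ann$begin))
  header <- paste(c("tier", "begin", "end", "duration", "value"),
                  collapse = delim)
  rows <- if (nrow(ann) == 0L) character(0) else
    paste(ann$tier, ann$begin, ann$end, dur, ann$value, sep = delim)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

.validate_annotations <- function(annotations) {
  need <- c("begin", "end")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("annotations must be a data frame with begin and end columns",
         call. = FALSE)
  if (is.null(annotations$tier)) annotations$tier <- "movement"
  if (is.null(annotations$value)) annotations$value <- "movement"
  if (nrow(annotations) > 0L) {
    b <- timestamp_to_ms(annotations$begin)
    e <- timestamp_to_ms(annotations$end)
    bad <- which(b >= e)
    if (length(bad))
      stop("annotation ", bad[[1L]], " has begin >= end", call. = FALSE)
    o <- order(b)
    annotations <- annotations[o, , drop = FALSE]
    rownames(annotations) <- NULL
  }
  annotations[, c("tier", "begin", "end", "value")]
}

#' Read an annotation file
#'
#' Accepts the dialect written by [write_annotation_csv()] (comma- or
#' tab-separated, columns `tier, begin, end, duration, value`) or a minimal
#' two-column `begin, end` variant. Rows are validated (begin < end) and
#' returned sorted by begin time.
#'
#' @param path Path to the annotation file.
#' @return Annotation data frame (`tier`, `begin`, `end`, `value`).
#' @export
read_annotation_csv <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("begin", "end") %in% names(df)))
    stop("annotation file must have 'begin' and 'end' columns", call. = FALSE)
  if (is.null(df$tier)) df$tier <- "movement"
  if (is.null(df$value)) df$value <- "movement"
  for (i in seq_len(nrow(df))) {
    b <- tryCatch(timestamp_to_ms(df$begin[i]), error = function(e) NA)
    e <- tryCatch(timestamp_to_ms(df$end[i]), error = function(e) NA)
    if (is.na(b) || is.na(e))
      stop("row ", i, ": unparseable timestamp", call. = FALSE)
    if (b >= e)
      stop("row ", i, ": begin must precede end", call. = FALSE)
  }
  ann <- df[, c("tier", "begin", "end", "value")]
  ann <- ann[order(timestamp_to_ms(ann$begin)), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write annotations as a minimal ELAN .eaf document
#'
#' Convenience writer for the ELAN native XML format: one alignable tier with
#' millisecond time slots. The delimited-text writer
#' ([write_annotation_csv()]) remains the primary export.
#'
#' @param annotations Annotation data frame.
#' @param path Output `.eaf` path.
#' @param media_url Optional media descriptor URL recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_eaf <- function(annotations, path, media_url = NULL) {
  ann <- .validate_annotations(annotations)
  doc <- xml2::xml_new_root(
    "ANNOTATION_DOCUMENT", AUTHOR = "handmotion",
    DATE = "2026-01-01T00:00:00+00:00",
    FORMAT = "3.0", VERSION = "3.0"
  )
  header <- xml2::xml_add_child(doc, "HEADER", TIME_UNITS = "milliseconds")
  if (!is.null(media_url))
    xml2::xml_add_child(header, "MEDIA_DESCRIPTOR", MEDIA_URL = media_url,
                        MIME_TYPE = "video/*")
  time_order <- xml2::xml_add_child(doc, "TIME_ORDER")
  n <- nrow(ann)
  b_ms <- if (n) timestamp_to_ms(ann$begin) else numeric(0)
  e_ms <- if (n) timestamp_to_ms(ann$end) else numeric(0)
  for (i in seq_len(n)) {
    xml2::xml_add_child(time_order, "TIME_SLOT",
                        TIME_SLOT_ID = sprintf("ts%db", i),
                        TIME_VALUE = sprintf("%.0f", b_ms[i]))
    xml2::xml_add_child(time_order, "TIME_SLOT",
                        TIME_SLOT_ID = sprintf("ts%de", i),
                        TIME_VALUE = sprintf("%.0f", e_ms[i]))
  }
  tier_name <- if (n) ann$tier[[1L]] else "movement"
  tier <- xml2::xml_add_child(doc, "TIER", TIER_ID = tier_name,
                              LINGUISTIC_TYPE_REF = "default")
  for (i in seq_len(n)) {
    a <- xml2::xml_add_child(tier, "ANNOTATION")
    al <- xml2::xml_add_child(a, "ALIGNABLE_ANNOTATION",
                              ANNOTATION_ID = sprintf("a%d", i),
                              TIME_SLOT_REF1 = sprintf("ts%db", i),
                              TIME_SLOT_REF2 = sprintf("ts%de", i))
    xml2::xml_add_child(al, "ANNOTATION_VALUE", ann$value[[i]])
  }
  xml2::xml_add_child(doc, "LINGUISTIC_TYPE",
                      LINGUISTIC_TYPE_ID = "default",
                      TIME_ALIGNABLE = "true")
  xml2::write_xml(doc, path)
  invisible(path)
}
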