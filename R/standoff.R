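#' Parse brat standoff annotations
#'
#' Reads a document in the brat standoff convention: the raw text plus an
#' `.ann` side-file of tab-separated records. Text-bound entities (`T`
#' lines, possibly with discontinuous spans joined by `";"`) and attributes
#' (`A` lines) are supported; all offsets are 0-based half-open. Every
#' entity's surface text is checked against the corresponding text slice
#' (discontinuous pieces joined with a single space, as brat writes them).
#'
#' @param txt full document text (single string).
#' @param ann contents of the `.ann` file (single string or character vector
#'   of lines).
#' @return an object of class `standoff_document`: `text`, `entities` (list
#'   of `id`, `type`, `spans` (list of `c(start, end)`), `text`), and
#'   `attributes` (data frame `id`, `name`, `target`, `value`).
#' @examples
#' doc <- parse_standoff("Shown in [5] here.", "T1\tCitation 9 12\t[5]")
#' doc$entities[[1]]$spans
#' @export
parse_standoff <- function(txt, ann) {
  stopifnot(is.character(txt), length(txt) == 1)
  lines <- if (length(ann) == 1) strsplit(ann, "\n", fixed = TRUE)[[1]] else ann
  lines <- lines[nzchar(trimws(lines))]
  entities <- list()
  attrs <- data.frame(id = character(), name = character(),
                      target = character(), value = character(),
                      stringsAsFactors = FALSE)
  seen <- character()

  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- fields[1]
    if (id %in% seen) stop("duplicate annotation id in line: ", ln, call. = FALSE)
    seen <- c(seen, id)
    kind <- substr(id, 1, 1)
    if (kind == "T") {
      if (length(fields) < 3) stop("malformed entity line: ", ln, call. = FALSE)
      head <- fields[2]
      surface <- fields[3]
      type <- sub("^(\\S+).*", "\\1", head)
      span_part <- sub("^\\S+\\s+", "", head)
      spans <- lapply(strsplit(span_part, ";", fixed = TRUE)[[1]], function(s) {
        nums <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
        if (length(nums) != 2 || anyNA(nums))
          stop("malformed span in line: ", ln, call. = FALSE)
        nums
      })
      for (sp in spans) {
        if (sp[1] < 0 || sp[2] > nchar(txt) || sp[1] >= sp[2])
          stop("offset outside text in line: ", ln, call. = FALSE)
      }
      slice <- paste(vapply(spans, function(sp)
        substr(txt, sp[1] + 1, sp[2]), character(1)), collapse = " ")
      if (slice != surface)
        stop("surface text mismatch in line: ", ln,
             " (text slice is '", slice, "')", call. = FALSE)
      entities[[length(entities) + 1L]] <-
        list(id = id, type = type, spans = spans, text = surface)
    } else if (kind == "A") {
      if (length(fields) < 2) stop("malformed attribute line: ", ln, call. = FALSE)
      parts <- strsplit(fields[2], "\\s+")[[1]]
      if (length(parts) < 2) stop("malformed attribute line: ", ln, call. = FALSE)
      attrs <- rbind(attrs, data.frame(
        id = id, name = parts[1], target = parts[2],
        value = if (length(parts) >= 3) paste(parts[-(1:2)], collapse = " ")
                else NA_character_,
        stringsAsFactors = FALSE))
    }
    # other record kinds (R/E/N/#) are outside this corpus dialect: skipped
  }
  structure(list(text = txt, entities = entities, attributes = attrs),
            class = "standoff_document")
}

#' Serialize a standoff document back to brat format
#'
#' Inverse of [parse_standoff()]: `parse_standoff(txt, write_standoff(doc))`
#' reproduces the same entities and attributes.
#'
#' @param doc a `standoff_document`.
#' @return single string with one annotation record per line.
#' @export
write_standoff <- function(doc) {
  stopifnot(inherits(doc, "standoff_document"))
  e_lines <- vapply(doc$entities, function(e) {
    span_part <- paste(vapply(e$spans, function(sp)
      paste(sp[1], sp[2]), character(1)), collapse = ";")
    paste0(e$id, "\t", e$type, " ", span_part, "\t", e$text)
  }, character(1))
  a_lines <- if (nrow(doc$attributes)) {
    vapply(seq_len(nrow(doc$attributes)), function(i) {
      a <- doc$attributes[i, ]
      val <- if (is.na(a$value)) "" else paste0(" ", a$value)
      paste0(a$id, "\t", a$name, " ", a$target, val)
    }, character(1))
  } else character()
  paste(c(e_lines, a_lines), collapse = "\n")
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document: %d chars, %d entities, %d attributes>\n",
              nchar(x$text), length(x$entities), nrow(x$attributes)))
  invisible(x)
}
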