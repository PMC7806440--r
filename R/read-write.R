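#' Read a labelled corpus from a delimited or JSON-lines file
#'
#' Expects columns/keys `id`, `title`, `abstract` and optionally `label`.
#' Files are read as UTF-8; invalid bytes are a hard error rather than being
#' silently replaced, since replacement characters would corrupt tokens.
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"tsv"`, `"jsonl"`; the default guesses from
#'   the file extension.
#' @return A [screening corpus][as_corpus], preserving input order.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "citescreen_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", tab = "tsv",
      jsonl = "jsonl", ndjson = "jsonl",
      abort(paste0("cannot guess corpus format from extension '", ext,
                   "'; pass `format`"), class = "citescreen_format_error")
    )
  }
  df <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE),
    jsonl = read_jsonl(path)
  )
  as_corpus(df)
}

read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble::tibble(
      id = rec$id %||% NA_character_,
      title = rec$title %||% "",
      abstract = rec$abstract %||% "",
      label = rec$label %||% NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus to CSV or JSON lines
#'
#' @param corpus A screening corpus.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  corpus <- as_corpus(corpus)
  if (format == "csv") {
    readr::write_csv(corpus[c("id", "title", "abstract", "label")], path,
                     progress = FALSE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      writeLines(jsonlite::toJSON(
        list(id = corpus$id[i], title = corpus$title[i],
             abstract = corpus$abstract[i], label = corpus$label[i]),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

# -- MEDLINE / nbib ----------------------------------------------------------

#' Read a PubMed MEDLINE (nbib) export
#'
#' Parses the tagged MEDLINE text format produced by PubMed's "save as
#' PubMed format" export. Each record becomes one article: `PMID` is the id,
#' `TI` the title, `AB` the abstract (empty when absent). Continuation lines
#' (leading whitespace) are joined with single spaces. All labels are
#' `unknown` until [attach_labels()] is applied.
#'
#' @param path Path to the nbib file.
#' @return A [screening corpus][as_corpus].
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "citescreen_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(!validUTF8(lines))) {
    abort("file contains bytes that are not valid UTF-8",
          class = "citescreen_validation_error")
  }
  # records are separated by blank lines
  blank <- !nzchar(trimws(lines))
  groups <- split(lines, cumsum(blank))
  groups <- purrr::map(groups, function(g) g[nzchar(trimws(g))])
  groups <- groups[purrr::map_int(groups, length) > 0]

  rows <- purrr::imap(groups, function(g, idx) {
    fields <- parse_tagged(g, tag_width = 4)
    pmid <- fields[["PMID"]]
    if (is.null(pmid)) {
      abort(paste0("MEDLINE record ", idx, " has no PMID tag"),
            class = "citescreen_parse_error")
    }
    tibble::tibble(
      id = pmid[1],
      title = (fields[["TI"]] %||% "")[1],
      abstract = (fields[["AB"]] %||% "")[1]
    )
  })
  as_corpus(dplyr::bind_rows(rows))
}

# Parses one tagged record (MEDLINE: "TAG - value" with 4-char tag field;
# continuation lines start with whitespace). Returns a named list of
# character vectors; repeated tags accumulate.
parse_tagged <- function(lines, tag_width) {
  fields <- list()
  tag <- NULL
  for (l in lines) {
    if (grepl("^\\s", l) && !is.null(tag)) {
      n <- length(fields[[tag]])
      fields[[tag]][n] <- paste(fields[[tag]][n], trimws(l))
      next
    }
    m <- regmatches(l, regexec("^([A-Z0-9]{1,4})\\s*- ?(.*)$", l))[[1]]
    if (length(m) == 3) {
      tag <- m[2]
      fields[[tag]] <- c(fields[[tag]], trimws(m[3]))
    } else {
      tag <- NULL
    }
  }
  fields
}

# -- RIS ---------------------------------------------------------------------

#' Read an RIS reference export
#'
#' Records run from a `TY` tag to `ER`. The id is taken from `AN` then `ID`
#' (falling back to a record index when neither is present), the title from
#' `TI` then `T1`, and the abstract from `AB` with `N2` as fallback.
#'
#' @param path Path to the RIS file.
#' @return A [screening corpus][as_corpus] with all labels `unknown`.
#' @export
read_ris <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "citescreen_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(!validUTF8(lines))) {
    abort("file contains bytes that are not valid UTF-8",
          class = "citescreen_validation_error")
  }
  rows <- list()
  fields <- NULL
  tag <- NULL
  n_rec <- 0L
  for (l in lines) {
    m <- regmatches(l, regexec("^([A-Z][A-Z0-9])  - ?(.*)$", l))[[1]]
    if (length(m) == 3) {
      tag <- m[2]
      val <- trimws(m[3])
      if (tag == "TY") {
        if (!is.null(fields)) {
          abort("malformed RIS: new record starts before ER tag",
                class = "citescreen_parse_error")
        }
        fields <- list()
      } else if (tag == "ER") {
        if (is.null(fields)) {
          abort("malformed RIS: ER tag outside a record",
                class = "citescreen_parse_error")
        }
        n_rec <- n_rec + 1L
        rows[[n_rec]] <- tibble::tibble(
          id = first_of(fields, c("AN", "ID")) %||% sprintf("ris%05d", n_rec),
          title = first_of(fields, c("TI", "T1")) %||% "",
          abstract = first_of(fields, c("AB", "N2")) %||% ""
        )
        fields <- NULL
      } else if (!is.null(fields)) {
        fields[[tag]] <- c(fields[[tag]], val)
      }
    } else if (nzchar(trimws(l)) && !is.null(fields) && !is.null(tag)) {
      n <- length(fields[[tag]])
      if (n > 0) fields[[tag]][n] <- paste(fields[[tag]][n], trimws(l))
    }
  }
  if (!is.null(fields)) {
    abort("malformed RIS: file ends inside a record (missing ER)",
          class = "citescreen_parse_error")
  }
  if (n_rec == 0L) {
    abort("no RIS records found", class = "citescreen_parse_error")
  }
  as_corpus(dplyr::bind_rows(rows))
}

first_of <- function(fields, tags) {
  for (t in tags) if (!is.null(fields[[t]])) return(fields[[t]][1])
  NULL
}
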