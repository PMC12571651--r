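#' Default report section headers
#'
#' Canonical section names mapped to the header spellings that introduce
#' them in free-text radiology reports. "Impression" is accepted as a
#' synonym for the diagnosis section.
#'
#' @return Named list: canonical section -> accepted header words.
#' @export
default_section_headers <- function() {
  list(findings = c("findings"),
       diagnosis = c("diagnosis", "impression", "conclusion"))
}

#' Extract Findings/Diagnosis sections from a raw report
#'
#' Splits a report on case-insensitive `HEADER:` markers and keeps only
#' the findings and diagnosis sections, dropping history, requests and
#' other non-diagnostic text. If a canonical section appears under several
#' headers, the first occurrence wins. A report with neither section is
#' returned flagged invalid rather than raising an error.
#'
#' @param raw nonempty report text.
#' @param section_headers header map as in [default_section_headers()].
#' @param record_id optional identifier carried through.
#' @return Object of class `report_document` with fields `findings`,
#'   `diagnosis`, `raw`, `record_id`, `valid`.
#' @export
#' @examples
#' doc <- extract_sections(
#'   "HISTORY: cough. FINDINGS: opacity. IMPRESSION: pneumonia.")
#' doc$findings; doc$diagnosis
extract_sections <- function(raw, section_headers = default_section_headers(),
                             record_id = NA_character_) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("raw report must be a nonempty string", call. = FALSE)
  all_headers <- unlist(section_headers, use.names = FALSE)
  # locate every HEADER: marker (any word followed by a colon)
  pat <- "(?i)\\b([A-Za-z][A-Za-z ]*?)\\s*:"
  m <- gregexpr(pat, raw, perl = TRUE)[[1]]
  out <- list(findings = "", diagnosis = "")
  if (m[1] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    ends <- starts + lens - 1L
    words <- tolower(trimws(sub(":\\s*$", "",
                                regmatches(raw, list(m))[[1]])))
    n <- length(starts)
    for (k in seq_len(n)) {
      canon <- NULL
      for (nm in names(section_headers))
        if (words[k] %in% section_headers[[nm]]) canon <- nm
      if (is.null(canon) || nzchar(out[[canon]])) next  # first occurrence wins
      body_start <- ends[k] + 1L
      body_end <- if (k < n) starts[k + 1L] - 1L else nchar(raw)
      out[[canon]] <- trimws(substr(raw, body_start, body_end))
    }
  }
  valid <- nzchar(out$findings) || nzchar(out$diagnosis)
  structure(list(findings = out$findings, diagnosis = out$diagnosis,
                 raw = raw, record_id = record_id, valid = valid),
            class = "report_document")
}

#' Deterministic whitespace + punctuation tokenizer
#'
#' Lowercases, splits on whitespace, detaches sentence punctuation
#' (`.`, `;`, `,`, `:`) as separate tokens, and assigns each token a
#' stable id by a platform-independent string hash into a fixed-size
#' vocabulary. No external vocabulary is needed; a wordpiece tokenizer can
#' be plugged in by supplying any function with the same return contract.
#'
#' Reserved ids: 0 = `[PAD]`.
#'
#' @param text input string.
#' @param vocab_size hash vocabulary size (ids occupy `1..vocab_size-1`).
#' @return List with `tokens` (character), `ids` (integer) and
#'   `sentence_ends` (1-based positions of `.`/`;` tokens).
#' @export
simple_tokenize <- function(text, vocab_size = 512L) {
  text <- tolower(text)
  text <- gsub("([.;,:])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  ids <- vapply(toks, function(t) as.integer(str_hash(t) %% (vocab_size - 1L) + 1L),
                integer(1), USE.NAMES = FALSE)
  list(tokens = toks, ids = ids,
       sentence_ends = which(toks %in% c(".", ";")))
}

#' Pad or truncate a token sequence to a fixed length
#'
#' Short sequences are right-padded with `pad_id` to `max_len`. Long
#' sequences are truncated at the largest sentence boundary at or before
#' `max_len` so that only complete diagnostic sentences survive; if no
#' sentence end fits, a hard cut at `max_len` is the fallback. The output
#' length is always exactly `max_len`.
#'
#' @param ids integer token ids.
#' @param max_len target length (default 128).
#' @param pad_id padding id (default 0).
#' @param sentence_ends 1-based positions in `ids` that end a sentence.
#' @return Object of class `token_sequence` with fields `ids` (length
#'   `max_len`), `length` (content length), `pad_id`, `truncated`.
#' @export
#' @examples
#' ts <- pad_or_truncate(rep(7L, 150), max_len = 128,
#'                       sentence_ends = c(60, 120, 150))
#' ts$length  # 120: cut at the last sentence end that fits
pad_or_truncate <- function(ids, max_len = 128L, pad_id = 0L,
                            sentence_ends = integer()) {
  max_len <- as.integer(max_len)
  if (max_len < 1L) stop("max_len must be >= 1", call. = FALSE)
  ids <- as.integer(ids)
  n <- length(ids)
  if (n <= max_len) {
    content <- n
    out <- c(ids, rep(as.integer(pad_id), max_len - n))
    truncated <- FALSE
  } else {
    fit <- sentence_ends[sentence_ends <= max_len]
    content <- if (length(fit)) max(fit) else max_len
    out <- c(ids[seq_len(content)],
             rep(as.integer(pad_id), max_len - content))
    truncated <- TRUE
  }
  structure(list(ids = out, length = as.integer(content),
                 pad_id = as.integer(pad_id), truncated = truncated),
            class = "token_sequence")
}

#' Full report preparation: extract, tokenize, pad/truncate
#'
#' @param raw raw report text.
#' @param record_id identifier carried through.
#' @param max_len target token length (default 128).
#' @param vocab_size tokenizer vocabulary size.
#' @param tokenizer tokenizing function with the [simple_tokenize()]
#'   contract.
#' @return List with the `report_document`, the `token_sequence` and the
#'   tokens; `valid = FALSE` documents with no recognized section yield a
#'   fully padded sequence.
#' @export
prepare_report <- function(raw, record_id = NA_character_, max_len = 128L,
                           vocab_size = 512L, tokenizer = simple_tokenize) {
  doc <- extract_sections(raw, record_id = record_id)
  text <- trimws(paste(doc$findings, doc$diagnosis))
  if (!doc$valid || !nzchar(text)) {
    seq <- pad_or_truncate(integer(), max_len = max_len)
    return(list(document = doc, sequence = seq, tokens = character()))
  }
  tk <- tokenizer(text, vocab_size = vocab_size)
  seq <- pad_or_truncate(tk$ids, max_len = max_len,
                         sentence_ends = tk$sentence_ends)
  list(document = doc, sequence = seq, tokens = tk$tokens)
}
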