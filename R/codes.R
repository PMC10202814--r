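#' Truncate diagnosis codes to the three-character ICD category
#'
#' Disease vocabularies are built at the level-3 ("three-character category")
#' resolution of the ICD hierarchy: `"C25.1"` (malignant neoplasm of body of
#' pancreas) collapses to `"C25"` (malignant neoplasm of pancreas). Punctuation
#' and whitespace are stripped before truncation, so `"K85.90"`, `"K85 90"`
#' and `"K8590"` all map to `"K85"`.
#'
#' @param raw_code character vector of raw diagnosis codes.
#' @param system optional code-system tag (e.g. `"icd10"`); returned unchanged
#'   alongside the truncated codes when supplied, purely for convenience.
#' @return if `system` is `NULL`, a character vector of level-3 codes;
#'   otherwise a `data.table` with columns `code` and `system`.
#' @examples
#' truncate_code(c("C25.1", "C25", "K85.90"))
#' @export
truncate_code <- function(raw_code, system = NULL) {
  raw_code <- as.character(raw_code)
  if (any(is.na(raw_code) | !nzchar(raw_code))) {
    stop("truncate_code: empty or missing codes at positions ",
         paste(utils::head(which(is.na(raw_code) | !nzchar(raw_code)), 5L),
               collapse = ", "))
  }
  cleaned <- gsub("[^A-Za-z0-9]", "", raw_code)
  bad <- nchar(cleaned) < 3L
  if (any(bad)) {
    stop("truncate_code: codes with fewer than 3 significant characters: ",
         paste(unique(utils::head(raw_code[bad], 10L)), collapse = ", "))
  }
  out <- toupper(substr(cleaned, 1L, 3L))
  if (is.null(system)) return(out)
  data.table(code = out, system = rep_len(as.character(system), length(out)))
}

#' Build a token vocabulary over (system, level-3 code) pairs
#'
#' Codes from different coding systems are kept as distinct tokens (no
#' semantic merging between e.g. ICD-8 and ICD-10), so a token is the pair
#' `system:code`. Indices are contiguous `1..n_tokens`; an extra padding index
#' `n_tokens + 1` is reserved for sequence padding and is excluded from
#' attribution aggregation and embeds to the zero vector.
#'
#' @param events a `data.table`/data.frame with columns `code` and `system`
#'   (codes already at level 3), or a `trajrisk_cohort`.
#' @return an object of class `trajrisk_vocab` with elements `tokens`
#'   (character, in sorted order), `index` (named integer lookup) and
#'   `pad_index`.
#' @export
build_vocabulary <- function(events) {
  if (inherits(events, "trajrisk_cohort")) events <- events$events
  stopifnot(all(c("code", "system") %in% names(events)))
  tokens <- sort(unique(paste(events$system, events$code, sep = ":")))
  if (length(tokens) == 0L) stop("build_vocabulary: no events supplied")
  index <- seq_along(tokens)
  names(index) <- tokens
  structure(
    list(tokens = tokens, index = index, pad_index = length(tokens) + 1L),
    class = "trajrisk_vocab"
  )
}

#' @export
print.trajrisk_vocab <- function(x, ...) {
  cat("<trajrisk_vocab> ", length(x$tokens), " tokens + padding index ",
      x$pad_index, "\n", sep = "")
  invisible(x)
}

vocab_lookup <- function(vocab, system, code) {
  idx <- unname(vocab$index[paste(system, code, sep = ":")])
  if (anyNA(idx)) {
    missing <- unique(paste(system, code, sep = ":")[is.na(idx)])
    stop("tokens absent from vocabulary: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  idx
}

#' Map events between coding systems via a user-supplied equivalence table
#'
#' For cross-application of a model trained in one registry to data coded in
#' another system, ICD-9 events are rewritten to level-3 ICD-10 tokens through
#' a caller-provided mapping table, and a registry-specific prefix (e.g. `"D"`
#' for Danish-style codes) is prepended. No general-equivalence table is
#' bundled; mappings are registry policy, not package policy.
#'
#' @param events `data.table` with columns `code`, `system` (and any others,
#'   preserved).
#' @param mapping_table data.frame with columns `from` (source code) and `to`
#'   (target code, truncated to level 3 on ingestion).
#' @param target_prefix string prepended to every mapped code (default `"D"`).
#' @param source_system,target_system system tags selecting which rows are
#'   rewritten and how the result is tagged.
#' @param unmapped `"drop"` (default) removes events whose code has no mapping
#'   entry; `"keep"` leaves them untouched. Either way the tally of unmapped
#'   codes is attached as attribute `"unmapped"`.
#' @return the rewritten events `data.table` with attribute `"unmapped"` (a
#'   named integer tally, possibly empty).
#' @export
map_code_system <- function(events, mapping_table, target_prefix = "D",
                            source_system = "icd9", target_system = "icd10",
                            unmapped = c("drop", "keep")) {
  unmapped <- match.arg(unmapped)
  if (is.null(mapping_table) || nrow(mapping_table) == 0L) {
    stop("map_code_system: empty mapping table")
  }
  stopifnot(all(c("from", "to") %in% names(mapping_table)))
  events <- as.data.table(events)
  map <- truncate_code(mapping_table$to)
  names(map) <- as.character(mapping_table$from)

  is_src <- events$system == source_system
  hit <- map[events$code]
  ok <- is_src & !is.na(hit)
  miss <- is_src & is.na(hit)
  tally <- if (any(miss)) table(events$code[miss]) else table(character(0))

  out <- copy(events)
  out[ok, `:=`(code = paste0(target_prefix, hit[ok]), system = target_system)]
  if (unmapped == "drop" && any(miss)) out <- out[!miss]
  setattr(out, "unmapped", c(tally))
  out[]
}
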