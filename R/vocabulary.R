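#' Build an event vocabulary with rare-event pooling and dictionary caps
#'
#' The number of event series M is controlled by two heuristics: codes
#' occurring fewer than `min_count` times are pooled into a per-class rare
#' pseudo-code, and at most `max_size` codes are retained per entity class
#' (the most frequent ones; ties at the cut are broken lexicographically so
#' the result is deterministic).
#'
#' @param events Events tibble; to avoid leakage, pass only events from the
#'   derivation period.
#' @param min_count Minimum database-wide occurrence count for a code to be
#'   retained (default 50; codes with exactly `min_count` occurrences are
#'   kept).
#' @param max_size Maximum dictionary size per entity class (default 2000).
#' @return An `ehr_vocabulary`: a tibble `class, code, rank, count, retained`
#'   with attributes `min_count`, `max_size`.
#' @export
build_vocabulary <- function(events, min_count = 50, max_size = 2000) {
  stopifnot(min_count >= 1, max_size >= 1)
  counts <- dplyr::count(events, .data$class, .data$code, name = "count")
  vocab <- counts |>
    dplyr::arrange(.data$class, dplyr::desc(.data$count), .data$code) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      retained = as.integer(.data$count >= min_count & .data$rank <= max_size)
    ) |>
    dplyr::ungroup()
  structure(vocab, min_count = min_count, max_size = max_size,
            class = c("ehr_vocabulary", class(vocab)))
}

# reserved pooled pseudo-code for a class; guaranteed not to collide with a
# real code by extending with underscores
rare_code_for <- function(class, existing_codes = character(0)) {
  rc <- paste0("__rare_", class, "__")
  while (rc %in% existing_codes) rc <- paste0(rc, "_")
  rc
}

#' Pooled rare pseudo-codes of a vocabulary
#'
#' @param vocab An `ehr_vocabulary`.
#' @return Named character vector, one rare code per entity class.
#' @export
rare_codes <- function(vocab) {
  cls <- unique(vocab$class)
  stats::setNames(
    vapply(cls, function(cl)
      rare_code_for(cl, vocab$code[vocab$class == cl]), character(1)),
    cls
  )
}

#' Retained codes plus the rare pseudo-code, per class
#'
#' Defines the ordered series universe (the M event series): per class, the
#' retained codes in rank order followed by the class's rare pseudo-code.
#'
#' @param vocab An `ehr_vocabulary`.
#' @return Tibble `class, code` in deterministic order.
#' @export
vocabulary_codes <- function(vocab) {
  rc <- rare_codes(vocab)
  kept <- vocab |>
    dplyr::filter(.data$retained == 1L) |>
    dplyr::arrange(.data$class, .data$rank) |>
    dplyr::select("class", "code")
  pooled <- tibble::tibble(class = names(rc), code = unname(rc))
  dplyr::bind_rows(kept, pooled) |>
    dplyr::arrange(.data$class)
}

#' Rewrite rare codes to their class's pooled pseudo-code
#'
#' Record counts are conserved: every record maps to exactly one output code.
#' Codes never seen when the vocabulary was built are treated as rare.
#'
#' @param events Events tibble.
#' @param vocab An `ehr_vocabulary` from [build_vocabulary()].
#' @return Events tibble with non-retained codes rewritten.
#' @export
apply_vocabulary <- function(events, vocab) {
  if (nrow(events) == 0L) return(events)
  rc <- rare_codes(vocab)
  kept <- vocab[vocab$retained == 1L, c("class", "code")]
  kept$.keep <- TRUE
  out <- dplyr::left_join(events, kept, by = c("class", "code"))
  is_rare <- is.na(out$.keep)
  # classes absent from the vocabulary still get a deterministic pool code
  need <- setdiff(unique(out$class[is_rare]), names(rc))
  if (length(need))
    rc <- c(rc, stats::setNames(vapply(need, rare_code_for, character(1)), need))
  out$code[is_rare] <- rc[out$class[is_rare]]
  out$.keep <- NULL
  out
}

#' Write / read a vocabulary as CSV
#'
#' @param vocab An `ehr_vocabulary`.
#' @param path Output CSV path (`class, code, rank, count, retained`).
#' @return `path`, invisibly (write); an `ehr_vocabulary` (read).
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_csv(tibble::as_tibble(vocab), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @param min_count,max_size Thresholds to re-attach on read.
#' @export
read_vocabulary <- function(path, min_count = 50, max_size = 2000) {
  v <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         class = readr::col_character(),
                         code = readr::col_character(),
                         rank = readr::col_integer(),
                         count = readr::col_integer(),
                         retained = readr::col_integer()
                       ))
  structure(v, min_count = min_count, max_size = max_size,
            class = c("ehr_vocabulary", class(v)))
}
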