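# Reading and filtering syntenic paralog pair lists (the shape of a
# trimmed SynMap self-comparison export: gene_a, gene_b, percent
# similarity, tab-separated, '#' comments).

#' Read a syntenic paralog pair list
#'
#' Reads tab-separated rows `gene_a  gene_b  similarity_percent` (extra
#' columns ignored, `#` comment lines skipped).  Pairs are canonicalized
#' (lexically smaller gene first) and deduplicated; a duplicate unordered
#' pair with differing similarity keeps the maximum with a warning.
#' Self-pairs are dropped and counted.
#'
#' @param source File path, or a character vector of lines.
#' @return A tibble `gene_a`, `gene_b`, `similarity`, with attributes
#'   `n_self_removed` and `n_duplicates_collapsed`.
#' @export
read_pairs <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\t", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    rlang::abort("no data rows in pair list")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    rlang::abort(sprintf("%d row(s) have fewer than 3 tab-separated columns", sum(nf < 3)))
  }
  gene_a <- vapply(fields, `[[`, character(1), 1)
  gene_b <- vapply(fields, `[[`, character(1), 2)
  sim <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (any(is.na(sim))) {
    rlang::abort(sprintf("%d row(s) have an unparseable similarity", sum(is.na(sim))))
  }
  if (any(sim <= 0 | sim > 100)) {
    rlang::abort(sprintf("%d row(s) have similarity outside (0, 100]", sum(sim <= 0 | sim > 100)))
  }
  self <- gene_a == gene_b
  n_self <- sum(self)
  if (n_self > 0) {
    rlang::inform(sprintf("removed %d self-pair row(s)", n_self))
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]; sim <- sim[!self]
  }
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  pairs <- tibble::tibble(gene_a = a, gene_b = b, similarity = sim)
  key <- paste(a, b, sep = "\r")
  ndup <- 0L
  if (anyDuplicated(key)) {
    dup_groups <- pairs |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(
        n = dplyr::n(),
        spread = max(.data$similarity) - min(.data$similarity),
        similarity = max(.data$similarity),
        .groups = "drop"
      )
    ndup <- sum(dup_groups$n > 1)
    if (any(dup_groups$n > 1 & dup_groups$spread > 0)) {
      rlang::warn(sprintf(
        "%d duplicate pair(s) had differing similarities; kept the maximum",
        sum(dup_groups$n > 1 & dup_groups$spread > 0)
      ))
    }
    pairs <- dup_groups[, c("gene_a", "gene_b", "similarity")]
  }
  pairs <- dplyr::arrange(pairs, .data$gene_a, .data$gene_b)
  attr(pairs, "n_self_removed") <- n_self
  attr(pairs, "n_duplicates_collapsed") <- ndup
  pairs
}

#' Write a pair list in the canonical tab-separated format
#'
#' @param pairs Pair tibble (`gene_a`, `gene_b`, `similarity`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("gene_a", "gene_b", "similarity")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Filter pairs to an exclusion window
#'
#' Keeps pairs with `exclude_below < similarity <= exclude_above`.  The low
#' cutoff removes pairs too diverged to have a polyploid origin (or, set
#' higher, restricts to the recent events); the high cutoff removes
#' near-identical pairs that are tandem or allelic rather than
#' polyploidy-derived.
#'
#' @param pairs Pair tibble.
#' @param exclude_below,exclude_above Percent cutoffs,
#'   `0 <= exclude_below < exclude_above <= 100`.
#' @return Filtered tibble with attributes `n_removed_low`,
#'   `n_removed_high`.
#' @export
filter_pairs <- function(pairs, exclude_below = 0, exclude_above = 100) {
  if (!(exclude_below >= 0 && exclude_below < exclude_above && exclude_above <= 100)) {
    rlang::abort("need 0 <= exclude_below < exclude_above <= 100")
  }
  low <- pairs$similarity <= exclude_below
  high <- pairs$similarity > exclude_above
  out <- pairs[!(low | high), , drop = FALSE]
  attr(out, "n_removed_low") <- sum(low)
  attr(out, "n_removed_high") <- sum(high)
  out
}
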