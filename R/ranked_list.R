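#' Ranked SNP-pair lists
#'
#' A `ranked_pair_list` is the unit of every stability comparison: the top-k
#' scored pairs of a scan, most significant first. Entries are a data frame
#' with columns `rank`, `snp_id_1`, `snp_id_2` (the canonical pair, lower
#' variant index first), `score` and `p_value`. The ranking key is score
#' descending with ties broken by ascending pair index, so repeated runs
#' produce byte-identical lists.
#'
#' @param entries data frame with at least `snp_id_1`, `snp_id_2`, `score`,
#'   `p_value`, already sorted most significant first.
#' @param statistic name of the statistic that produced the scores.
#' @param k_requested the k that was asked for.
#' @param total_pairs_scanned number of pairs evaluated.
#' @return a `ranked_pair_list`.
#' @export
ranked_pair_list <- function(entries, statistic = NA_character_,
                             k_requested = nrow(entries),
                             total_pairs_scanned = NA_integer_) {
  stopifnot(is.data.frame(entries),
            all(c("snp_id_1", "snp_id_2", "score", "p_value") %in%
                  names(entries)))
  key <- paste(entries$snp_id_1, entries$snp_id_2, sep = "\t")
  if (anyDuplicated(key)) stop("duplicate pairs in ranked list")
  entries$rank <- seq_len(nrow(entries))
  rownames(entries) <- NULL
  structure(entries[, c("rank", "snp_id_1", "snp_id_2", "score", "p_value")],
            statistic = statistic, k_requested = k_requested,
            total_pairs_scanned = total_pairs_scanned,
            class = c("ranked_pair_list", "data.frame"))
}

#' @rdname ranked_pair_list
#' @param x a `ranked_pair_list` (or a character vector of keys, returned
#'   unchanged).
#' @return `pair_keys()`: character vector identifying each pair, in rank
#'   order.
#' @export
pair_keys <- function(x) {
  if (is.character(x)) return(x)
  stopifnot(is.data.frame(x))
  paste(x$snp_id_1, x$snp_id_2, sep = "\t")
}

#' Write / read a ranked pair list as TSV
#'
#' Columns: `rank`, `snp_id_1`, `snp_id_2`, `score`, `p_value`. Scores are
#' written with full precision so that a round trip preserves the ordering
#' key exactly. Reading validates that ranks are `1..n`, scores are
#' non-increasing, and no pair appears twice.
#'
#' @param x a `ranked_pair_list`.
#' @param path file path.
#' @export
write_ranked_list <- function(x, path) {
  stopifnot(inherits(x, "ranked_pair_list"))
  df <- as.data.frame(x)
  df$score <- sprintf("%.17g", df$score)
  df$p_value <- sprintf("%.17g", df$p_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character",
                                         "numeric", "numeric"))
  if (!identical(names(df),
                 c("rank", "snp_id_1", "snp_id_2", "score", "p_value")))
    stop("unexpected ranked-list columns in ", path)
  if (nrow(df) > 0L) {
    if (!identical(df$rank, seq_len(nrow(df))))
      stop("ranked list is not sorted: ranks must be 1..n")
    if (any(diff(df$score) > 0))
      stop("ranked list is not sorted: scores must be non-increasing")
    ukey <- paste(pmin(df$snp_id_1, df$snp_id_2),
                  pmax(df$snp_id_1, df$snp_id_2))
    if (anyDuplicated(ukey)) stop("duplicate pair in ranked list")
  }
  ranked_pair_list(df)
}
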