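#' Cohort frequency store
#'
#' Tracks, per unordered gene pair, the set of cohort samples in which the
#' pair was called, so that recurrent artifactual fusions can be filtered
#' by their detection frequency. The store is an in-memory object with a
#' single-file JSON persistence format ([save_cohort_store()] /
#' [load_cohort_store()]); it replaces a client-server database with an
#' embedded, self-contained equivalent.
#'
#' Frequencies are per sample, not per call: several isoforms of a pair in
#' one sample count once, and re-registering a sample replaces its previous
#' observations rather than double-counting them.
#'
#' @param samples Character vector of registered sample identifiers.
#' @param observations Named list mapping pair key (see [pair_key()]) to a
#'   character vector of sample identifiers.
#' @return A `cohort_store` object.
#' @export
cohort_store <- function(samples = character(), observations = list()) {
  structure(list(samples = unique(samples), observations = observations),
            class = "cohort_store")
}

#' Register one sample's called gene pairs
#'
#' Adds `sample_id` to the cohort and records each pair as observed in that
#' sample. Registering the same sample again replaces its observations.
#' Idempotent per (sample, pair).
#'
#' @param store A [cohort_store()].
#' @param sample_id Non-empty sample identifier.
#' @param pairs Character vector of pair keys, or a two-column data.frame
#'   of gene symbols.
#' @return The updated store.
#' @export
register_sample <- function(store, sample_id, pairs) {
  if (!nzchar(sample_id)) stop("sample_id must be non-empty", call. = FALSE)
  if (is.data.frame(pairs)) {
    pairs <- pair_key(pairs[[1]], pairs[[2]])
  }
  pairs <- unique(pairs)
  # Replacement semantics: drop any previous observation of this sample.
  store$observations <- lapply(store$observations, setdiff, sample_id)
  for (p in pairs) {
    store$observations[[p]] <- union(store$observations[[p]], sample_id)
  }
  store$observations <-
    store$observations[lengths(store$observations) > 0]
  store$samples <- union(store$samples, sample_id)
  store
}

#' Cohort detection frequency of gene pairs
#'
#' Fraction of registered samples in which the unordered pair was called;
#' 0 for unseen pairs or an empty store. Symmetric in the two genes.
#'
#' @param store A [cohort_store()].
#' @param a,b Gene symbol vectors, or `b = NULL` with `a` a vector of pair
#'   keys.
#' @return Numeric vector of frequencies in \[0, 1\].
#' @export
cohort_frequency <- function(store, a, b = NULL) {
  keys <- if (is.null(b)) a else pair_key(a, b)
  n <- length(store$samples)
  if (n == 0) return(rep(0, length(keys)))
  vapply(keys, function(k) {
    length(store$observations[[k]]) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Persist a cohort store to a single JSON file
#'
#' @param store A [cohort_store()].
#' @param path Output path.
#' @export
save_cohort_store <- function(store, path) {
  jsonlite::write_json(
    list(samples = store$samples,
         observations = store$observations),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' Load a cohort store saved by [save_cohort_store()]
#'
#' @param path Path to the JSON store file.
#' @return A `cohort_store` object; frequencies round-trip exactly.
#' @export
load_cohort_store <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  obs <- lapply(x$observations, as.character)
  cohort_store(samples = as.character(unlist(x$samples)),
               observations = obs)
}

#' Dump per-pair cohort frequencies as a table
#'
#' @param store A [cohort_store()].
#' @return data.frame with columns pair, n_samples_observed,
#'   n_samples_total, frequency.
#' @export
dump_frequencies <- function(store) {
  pairs <- names(store$observations)
  data.frame(
    pair = pairs,
    n_samples_observed = unname(lengths(store$observations)),
    n_samples_total = length(store$samples),
    frequency = cohort_frequency(store, pairs),
    stringsAsFactors = FALSE
  )
}
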