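#' Embedding specification for 5'UTR sequences
#'
#' Two providers are supported: `"onehot"` (4 channels per position, the
#' built-in default) and `"file"` (precomputed language-model embeddings,
#' e.g. 640-dimensional per-position vectors, consumed from an
#' [embedding_store()]; the embedding model itself is never run here).
#' Sequences shorter than `max_length` are padded on the right with
#' `pad_value` rows.
#'
#' @param provider `"onehot"` or `"file"`.
#' @param dimension Channels per position (4 for onehot; declared dimension
#'   for file stores).
#' @param max_length Padding target (positions).
#' @param pad_value Fill value for padded positions (default 0).
#' @param store An [embedding_store()]; required when `provider = "file"`.
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(provider = c("onehot", "file"), dimension = 4L,
                           max_length = 50L, pad_value = 0,
                           store = NULL) {
  provider <- match.arg(provider)
  stopifnot(dimension >= 1, max_length >= 1)
  if (provider == "onehot" && dimension != 4L)
    stop("onehot embeddings have dimension 4", call. = FALSE)
  if (provider == "file" && is.null(store))
    stop("file provider requires an embedding store", call. = FALSE)
  structure(list(provider = provider, dimension = as.integer(dimension),
                 max_length = as.integer(max_length), pad_value = pad_value,
                 store = store),
            class = "embedding_spec")
}

#' An id-indexed store of precomputed per-position embeddings
#'
#' The on-disk layout is a directory holding one CSV matrix per sequence id
#' (rows = positions, columns = channels, no header) plus an `index.json`
#' mapping ids to file names and declaring the common channel dimension.
#' An in-memory store can be built directly from a named list of matrices.
#'
#' @param matrices Named list of position-by-channel matrices, or `NULL`
#'   when loading from `dir`.
#' @param dir Directory containing `index.json`, for file-backed stores.
#' @return An object of class `embedding_store`.
#' @export
embedding_store <- function(matrices = NULL, dir = NULL) {
  if (!is.null(matrices)) {
    stopifnot(length(names(matrices)) == length(matrices))
    dims <- unique(vapply(matrices, ncol, integer(1)))
    if (length(dims) != 1L)
      stop("all matrices in a store must share one channel dimension",
           call. = FALSE)
    return(structure(list(matrices = matrices, dimension = dims,
                          dir = NULL), class = "embedding_store"))
  }
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path))
    stop("no index.json in embedding store directory ", dir, call. = FALSE)
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  structure(list(matrices = NULL, dimension = as.integer(idx$dimension),
                 index = idx$files, dir = dir), class = "embedding_store")
}

#' @rdname embedding_store
#' @param store A store to write.
#' @export
write_embedding_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- setNames(paste0(names(store$matrices), ".csv"),
                    names(store$matrices))
  for (id in names(store$matrices))
    utils::write.table(store$matrices[[id]], file.path(dir, files[[id]]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(dimension = store$dimension,
                            files = as.list(files)),
                       file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

store_fetch <- function(store, id) {
  if (!is.null(store$matrices)) {
    if (is.null(store$matrices[[id]]))
      stop("id '", id, "' missing from embedding store", call. = FALSE)
    return(as.matrix(store$matrices[[id]]))
  }
  f <- store$index[[id]]
  if (is.null(f))
    stop("id '", id, "' missing from embedding store", call. = FALSE)
  as.matrix(utils::read.table(file.path(store$dir, f), sep = ","))
}

#' Embed one UTR record as a position-by-channel matrix
#'
#' @param sequence Nucleotide string (onehot provider) — ignored for file
#'   stores.
#' @param spec An [embedding_spec()].
#' @param id Record id (required for file stores).
#' @return Matrix of shape `(max_length, dimension)`; onehot rows sum to 1
#'   on real positions and 0 on padding.
#' @export
embed_utr <- function(sequence = NULL, spec = embedding_spec(), id = NULL) {
  if (spec$provider == "onehot") {
    s <- norm_dna(sequence, "UTR sequence")
    n <- nchar(s)
    if (n > spec$max_length)
      stop("sequence longer (", n, ") than max_length (", spec$max_length,
           ")", call. = FALSE)
    m <- matrix(spec$pad_value * 1.0, nrow = spec$max_length, ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    if (n > 0) {
      ch <- str_chars(s)
      m[seq_len(n), ] <- 0
      m[cbind(seq_len(n), match(ch, c("A", "C", "G", "T")))] <- 1
    }
    return(m)
  }
  mat <- store_fetch(spec$store, id)
  if (ncol(mat) != spec$dimension)
    stop("dimension mismatch for id '", id, "': store has ", ncol(mat),
         " channels, spec declares ", spec$dimension, call. = FALSE)
  if (nrow(mat) > spec$max_length)
    stop("embedding for id '", id, "' longer than max_length", call. = FALSE)
  out <- matrix(spec$pad_value * 1.0, nrow = spec$max_length,
                ncol = spec$dimension)
  out[seq_len(nrow(mat)), ] <- mat
  out
}

#' Assign train/validation splits to an MRL dataset
#'
#' Seeded uniform shuffle; the first `round(n * ratio[1])` records become the
#' training set and the rest the validation set, so the two are disjoint and
#' exhaustive and the counts are within one record of `n * fraction`.
#'
#' @param dataset MRL data frame (see [gen_mrl_library()]).
#' @param ratio Two fractions summing to 1 (default `c(0.8, 0.2)`).
#' @param seed Integer seed.
#' @return The dataset with its `split` column set to "train"/"validation".
#' @export
split_mrl_dataset <- function(dataset, ratio = c(0.8, 0.2), seed = 1L) {
  stopifnot(abs(sum(ratio) - 1) < 1e-9, length(ratio) == 2L)
  n <- nrow(dataset)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- round(n * ratio[1L])
  split <- rep("validation", n)
  split[ord[seq_len(n_train)]] <- "train"
  dataset$split <- split
  dataset
}

#' Regression metrics for predicted vs measured MRL
#'
#' @param measured,predicted Equal-length numeric vectors (length >= 2).
#' @return List of class `regression_metrics`: `r2` (1 - SSres/SStot),
#'   `mse`, `mae`, `rmse` (= sqrt(mse)). With zero variance in `measured`,
#'   `r2` is `NA` and the result carries `attr(, "degenerate") = TRUE`.
#' @export
regression_metrics <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2L)
  res <- measured - predicted
  mse <- mean(res^2)
  sstot <- sum((measured - mean(measured))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(res^2) / sstot
  out <- structure(list(r2 = r2, mse = mse, mae = mean(abs(res)),
                        rmse = sqrt(mse)),
                   class = "regression_metrics")
  if (sstot == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Build a candidate 5'UTR pool from multiple sources
#'
#' Concatenates several sequence sources (CSV with `id`,`sequence` columns,
#' FASTA files, or in-memory data frames) into one screening pool. Ids must
#' be unique across sources; duplicates are an error because downstream
#' predictions are keyed by id.
#'
#' @param sources List of file paths or data frames.
#' @return Data frame `id`, `sequence`, `length`, `source`.
#' @export
build_candidate_pool <- function(sources) {
  if (is.null(names(sources)))
    names(sources) <- sprintf("source%d", seq_along(sources))
  parts <- lapply(names(sources), function(nm) {
    src <- sources[[nm]]
    df <- if (is.data.frame(src)) {
      src[, c("id", "sequence")]
    } else if (grepl("\\.(fa|fasta|fna)$", src, ignore.case = TRUE)) {
      x <- Biostrings::readDNAStringSet(src)
      data.frame(id = names(x), sequence = as.character(x),
                 stringsAsFactors = FALSE)
    } else {
      utils::read.csv(src, stringsAsFactors = FALSE)[, c("id", "sequence")]
    }
    df$source <- nm
    df
  })
  pool <- do.call(rbind, parts)
  dup <- unique(pool$id[duplicated(pool$id)])
  if (length(dup))
    stop("duplicate ids across sources: ", paste(dup, collapse = ", "),
         call. = FALSE)
  pool$length <- nchar(pool$sequence)
  rownames(pool) <- NULL
  pool[, c("id", "sequence", "length", "source")]
}

#' Rank screened candidates by predicted mean ribosome load
#'
#' @param records Data frame with `sequence` and `predicted_mrl` (and
#'   optionally `id`, used as the documented tie-break).
#' @param k Number of rows to return (>= 1).
#' @return Top-k data frame `(id, sequence, length, predicted_mrl)` in
#'   descending predicted MRL, ties broken by id.
#' @export
rank_candidates <- function(records, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  stopifnot("predicted_mrl" %in% names(records))
  if (any(is.na(records$predicted_mrl)))
    stop("predictions missing for some records", call. = FALSE)
  if (is.null(records$id)) records$id <- as.character(seq_len(nrow(records)))
  ord <- order(-records$predicted_mrl, records$id)
  out <- records[ord[seq_len(min(k, nrow(records)))], , drop = FALSE]
  out$length <- nchar(out$sequence)
  rownames(out) <- NULL
  out[, c("id", "sequence", "length", "predicted_mrl")]
}
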