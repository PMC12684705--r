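# Deterministic transformation of sequence text into encoded chunks, packed
# reads, and SIMD-batched stride vectors, with exact coordinate bookkeeping.
#
# Alphabet convention (fixed throughout the protocol): A,C,G,T (case-folded)
# map to 0,1,2,3; every other character -- IUPAC ambiguity codes, gaps, and
# all padding -- maps to the non-nucleotide symbol 4. Queries are restricted
# to {0..3}, so any window touching a pad symbol differs from every query in
# at least one slot and can never produce a zero sum of squared differences.

PAD_SYMBOL <- 4L

#' Encode sequence text as protocol symbols
#'
#' @param text A single character string (may be empty).
#' @return Integer vector over `{0,1,2,3,4}`, same length as `nchar(text)`.
#' @examples
#' encode_symbols("ACGT")   # 0 1 2 3
#' encode_symbols("acgtN-") # 0 1 2 3 4 4
#' @export
encode_symbols <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (nchar(text) == 0) return(integer(0))
  codes <- utf8ToInt(toupper(text))
  lut <- rep(PAD_SYMBOL, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  codes[codes > 255L] <- 0L  # any non-latin byte is "unknown"
  lut[codes + 1L]
}

#' Decode protocol symbols back to text
#'
#' Pad/unknown symbols render as `"N"`.
#' @param symbols Integer vector over `{0..4}`.
#' @return A single character string.
#' @export
decode_symbols <- function(symbols) {
  if (length(symbols) == 0) return("")
  paste(c("A", "C", "G", "T", "N")[symbols + 1L], collapse = "")
}

#' Plan overlapping chunks over a linear coordinate space
#'
#' Consecutive chunks overlap by `k_max - 1` symbols, the minimum overlap
#' guaranteeing that every window of length at most `k_max` lies wholly
#' inside at least one chunk.
#'
#' @param total_length Length of the concatenated source, in symbols.
#' @param chunk_size Maximum chunk length (default 262144 = 256 KB).
#' @param k_max Maximum queryable k-mer length.
#' @return A tibble with columns `chunk_index` (0-based), `start` (0-based
#'   offset), `length`, `overlap`.
#' @export
chunk_plan <- function(total_length, chunk_size = 262144L, k_max = 16L) {
  if (chunk_size <= k_max) {
    stop("configuration error: chunk_size must exceed k_max", call. = FALSE)
  }
  step <- chunk_size - (k_max - 1L)
  starts <- 0L
  while (utils::tail(starts, 1) + chunk_size < total_length) {
    starts <- c(starts, utils::tail(starts, 1) + step)
  }
  tibble::tibble(
    chunk_index = seq_along(starts) - 1L,
    start = as.integer(starts),
    length = as.integer(pmin(chunk_size, total_length - starts)),
    overlap = k_max - 1L
  )
}

#' Split an encoded sequence into overlapping chunks
#'
#' The final chunk is right-padded with `k_max - 1` pad symbols so that
#' trailing windows for every `k < k_max` exist in the stride layout.
#'
#' @param symbols Encoded symbol vector (see [encode_symbols()]).
#' @param chunk_size,k_max As in [chunk_plan()].
#' @return A list of chunks, each a list with fields `chunk_index`, `start`,
#'   `length` (un-padded length) and `symbols` (possibly padded).
#' @export
chunk_symbols <- function(symbols, chunk_size = 262144L, k_max = 16L) {
  plan <- chunk_plan(length(symbols), chunk_size, k_max)
  n_chunks <- nrow(plan)
  lapply(seq_len(n_chunks), function(i) {
    row <- plan[i, ]
    syms <- symbols[(row$start + 1L):(row$start + row$length)]
    if (i == n_chunks && k_max > 1L) {
      syms <- c(syms, rep(PAD_SYMBOL, k_max - 1L))
    }
    list(chunk_index = row$chunk_index, start = row$start,
         length = row$length, symbols = syms)
  })
}

#' Pack FASTQ reads into one symbol vector with read-boundary guards
#'
#' Reads are concatenated with a run of `k_max - 1` pad symbols between
#' consecutive reads and after the last read, so no window of length at
#' most `k_max` consisting only of nucleotide symbols can span two reads.
#' Qualities are carried along aligned to packed positions; pad positions
#' get quality 0.
#'
#' @param reads A data frame with columns `read_id`, `sequence`, and
#'   optionally `quality` (Phred+33 strings, same length as `sequence`).
#' @param k_max Maximum queryable k-mer length.
#' @return A list with `symbols` (packed vector), `layout` (tibble:
#'   `read_id`, `packed_start` 0-based, `read_length`), and `quality`
#'   (integer Phred vector aligned to `symbols`).
#' @export
pack_fastq <- function(reads, k_max = 16L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in%
                                        names(reads)))
  has_qual <- "quality" %in% names(reads) && !all(is.na(reads$quality))
  if (has_qual &&
      any(nchar(reads$quality) != nchar(reads$sequence))) {
    stop("format error: quality string length differs from sequence length",
         call. = FALSE)
  }
  pad <- rep(PAD_SYMBOL, k_max - 1L)
  lens <- nchar(reads$sequence)
  packed_start <- cumsum(c(0L, utils::head(lens + (k_max - 1L), -1)))
  symbols <- integer(0)
  quality <- integer(0)
  for (i in seq_len(nrow(reads))) {
    symbols <- c(symbols, encode_symbols(reads$sequence[i]), pad)
    q <- if (has_qual) utf8ToInt(reads$quality[i]) - 33L else
      rep(0L, lens[i])
    quality <- c(quality, q, rep(0L, k_max - 1L))
  }
  list(
    symbols = symbols,
    layout = tibble::tibble(read_id = reads$read_id,
                            packed_start = as.integer(packed_start),
                            read_length = as.integer(lens)),
    quality = quality
  )
}

#' Transpose a chunk into SIMD window batches of stride vectors
#'
#' Stride vector `j` of a batch holds the `j`-th character of every sliding
#' window in that batch: `strides[j + 1, i] = symbols[offset + i + j]`
#' (0-based `i`, `j`). A chunk with `L` symbols yields `L - k_max + 1`
#' windows, segmented into batches of at most `slot_count` windows; slots
#' beyond the final valid window hold the pad symbol, so they can never
#' match a nucleotide query.
#'
#' @param symbols Encoded chunk symbols.
#' @param k_max Maximum queryable k-mer length.
#' @param slot_count SIMD slot count of the ciphertext context.
#' @param chunk_index,chunk_start Bookkeeping copied into each batch.
#' @param pad_value Fill value for slots beyond the final valid window
#'   (the pad symbol for sequence strides, 0 for quality strides).
#' @return A list of window batches: `chunk_index`, `batch_index`,
#'   `window_start` (absolute 0-based coordinate of slot 0's window),
#'   `n_windows`, and `strides` (a `k_max` x `slot_count` integer matrix).
#' @export
build_strides <- function(symbols, k_max, slot_count,
                          chunk_index = 0L, chunk_start = 0L,
                          pad_value = PAD_SYMBOL) {
  L <- length(symbols)
  if (L < k_max) {
    warning("chunk shorter than k_max; skipped")
    return(list())
  }
  n_windows <- L - k_max + 1L
  offsets <- seq(0L, n_windows - 1L, by = slot_count)
  padded <- c(symbols, rep(pad_value, slot_count + k_max))
  lapply(seq_along(offsets), function(b) {
    off <- as.integer(offsets[b])
    nw <- as.integer(min(slot_count, n_windows - off))
    strides <- matrix(pad_value, nrow = k_max, ncol = slot_count)
    for (j in seq_len(k_max) - 1L) {
      strides[j + 1L, ] <- padded[off + j + seq_len(slot_count)]
    }
    if (nw < slot_count) {
      strides[, (nw + 1L):slot_count] <- pad_value
    }
    list(chunk_index = chunk_index, batch_index = b - 1L,
         window_start = chunk_start + off, n_windows = nw,
         strides = strides)
  })
}

#' Map a ciphertext slot back to an absolute coordinate
#'
#' Inverse of the chunk/batch geometry: slot `i` of batch `b` of chunk `c`
#' addresses the window starting at `window_start + i` in the concatenated
#' source. Windows seen through two overlapping chunks resolve to the same
#' canonical absolute coordinate, so deduplication on the coordinate leaves
#' one record.
#'
#' @param manifest A deployment manifest (see [encrypt_input()]), or any
#'   list with a `batches` tibble holding `chunk_index`, `batch_index`,
#'   `window_start`, `n_windows`.
#' @param chunk_index,batch_index,slot 0-based identifiers of the slot.
#' @return Absolute 0-based position in the concatenated source.
#' @export
map_slot_to_coordinate <- function(manifest, chunk_index, batch_index, slot) {
  b <- manifest$batches
  row <- b[b$chunk_index == chunk_index & b$batch_index == batch_index, ]
  if (nrow(row) != 1) {
    stop("out-of-range error: unknown (chunk, batch)", call. = FALSE)
  }
  if (slot < 0 || slot >= row$n_windows) {
    stop("out-of-range error: slot ", slot, " >= n_windows ", row$n_windows,
         call. = FALSE)
  }
  row$window_start + slot
}

#' Resolve an absolute coordinate to its source record or read
#'
#' A window is attributable to a record/read only when its full `k`-symbol
#' span lies inside that record; windows landing in a pad run (between
#' records or reads) resolve to `NA` and are never reported, since pads
#' cannot yield a zero SSD.
#'
#' @param manifest A deployment manifest with a `records` tibble
#'   (`name`, `concat_start`, `length`).
#' @param position Absolute 0-based position in the concatenated source.
#' @param k Window length.
#' @return A one-row tibble `record`, `offset` (0-based within the record),
#'   with `NA`s when the window spans a boundary or pad run.
#' @export
map_coordinate_to_source <- function(manifest, position, k) {
  r <- manifest$records
  hit <- r[r$concat_start <= position &
             position + k <= r$concat_start + r$length, ]
  if (nrow(hit) == 0) {
    return(tibble::tibble(record = NA_character_, offset = NA_integer_))
  }
  tibble::tibble(record = hit$name[1],
                 offset = as.integer(position - hit$concat_start[1]))
}
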