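# Reproducible synthetic inputs: random genomes and read sets with planted
# k-mer occurrences, controlled GC content, and a truncated-normal per-base
# quality model -- enough structure to exercise every protocol path
# (chunking, read packing, quality filters) with exact ground truth.

#' Generate a synthetic genome with planted k-mer occurrences
#'
#' Background bases are drawn i.i.d. at the stated GC content; planted
#' sequences overwrite the background at their (given or drawn) positions.
#' The returned ground truth lists each planted `(query, position)` pair;
#' additional chance occurrences of a planted sequence may exist in the
#' background and are found by any correct search, so tests compare against
#' a full plaintext scan rather than the plant list alone.
#'
#' @param genome_length Total length in bases.
#' @param gc_content Probability of G or C per background base.
#' @param plants Optional tibble/data frame with columns `seq` and
#'   optionally `position` (0-based); missing positions are drawn uniformly
#'   without overlap between plants.
#' @param name Record name for the FASTA header.
#' @param path Optional path; when given, a FASTA file is written.
#' @param seed Optional integer seed (fixed seed gives byte-identical
#'   output).
#' @return List with `sequence` (character), `truth` (tibble `query`,
#'   `position`), and `path` (or `NA`).
#' @export
make_genome <- function(genome_length, gc_content = 0.5, plants = NULL,
                        name = "synthetic_genome", path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  bases <- sample(names(p), genome_length, replace = TRUE, prob = p)
  truth <- tibble::tibble(query = character(0), position = integer(0))
  if (!is.null(plants) && nrow(plants) > 0) {
    plants <- tibble::as_tibble(plants)
    if (!"position" %in% names(plants)) plants$position <- NA_integer_
    occupied <- integer(0)
    for (i in seq_len(nrow(plants))) {
      len <- nchar(plants$seq[i])
      pos <- plants$position[i]
      if (is.na(pos)) {
        for (try in 1:1000) {
          cand <- sample.int(genome_length - len + 1L, 1L) - 1L
          if (!any((cand:(cand + len - 1L)) %in% occupied)) {
            pos <- cand
            break
          }
        }
        if (is.na(pos)) {
          stop("generation error: could not place plant ", i,
               " without overlap", call. = FALSE)
        }
      }
      if (pos < 0 || pos + len > genome_length) {
        stop("generation error: plant ", i, " does not fit in the genome",
             call. = FALSE)
      }
      bases[(pos + 1L):(pos + len)] <- strsplit(plants$seq[i], "")[[1]]
      occupied <- c(occupied, pos:(pos + len - 1L))
      truth <- dplyr::bind_rows(truth,
                                tibble::tibble(query = plants$seq[i],
                                               position = as.integer(pos)))
    }
  }
  sequence <- paste(bases, collapse = "")
  if (!is.null(path)) {
    writeLines(c(paste0(">", name), .wrap_fasta(sequence)), path)
  }
  invisible(list(sequence = stats::setNames(sequence, name), truth = truth,
                 path = path %||% NA_character_))
}

.wrap_fasta <- function(s, width = 70L) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Generate synthetic FASTQ reads with planted k-mers and modelled qualities
#'
#' Per-base qualities are drawn from a truncated normal (`round(rnorm)`,
#' clamped to `[quality_floor, 41]`) and encoded Phred+33. Plants are placed
#' wholly inside single reads, so the within-read ground truth never
#' contains a boundary-spanning occurrence by construction.
#'
#' @param n_reads,read_length Read set geometry.
#' @param plants Optional tibble with columns `seq` and optionally `read`
#'   (1-based read index) and `offset` (0-based within the read).
#' @param quality_mean,quality_sd,quality_floor Per-base quality model.
#' @param gc_content Background GC content.
#' @param path Optional path; when given, a FASTQ file is written.
#' @param seed Optional integer seed.
#' @return List with `reads` (tibble `read_id`, `sequence`, `quality`),
#'   `truth` (tibble `query`, `read_id`, `offset`), and `path`.
#' @export
make_reads <- function(n_reads, read_length, plants = NULL,
                       quality_mean = 30, quality_sd = 5, quality_floor = 2,
                       gc_content = 0.5, path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- vapply(seq_len(n_reads), function(i) {
    paste(sample(names(p), read_length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  quals <- vapply(seq_len(n_reads), function(i) {
    q <- round(stats::rnorm(read_length, quality_mean, quality_sd))
    q <- pmin(pmax(q, quality_floor), 41L)
    intToUtf8(q + 33L)
  }, character(1))
  truth <- tibble::tibble(query = character(0), read_id = character(0),
                          offset = integer(0))
  if (!is.null(plants) && nrow(plants) > 0) {
    plants <- tibble::as_tibble(plants)
    for (i in seq_len(nrow(plants))) {
      len <- nchar(plants$seq[i])
      if (len > read_length) {
        stop("generation error: plant longer than read_length", call. = FALSE)
      }
      rd <- if ("read" %in% names(plants) && !is.na(plants$read[i])) {
        plants$read[i]
      } else {
        sample.int(n_reads, 1L)
      }
      off <- if ("offset" %in% names(plants) && !is.na(plants$offset[i])) {
        plants$offset[i]
      } else {
        sample.int(read_length - len + 1L, 1L) - 1L
      }
      substr(seqs[rd], off + 1L, off + len) <- plants$seq[i]
      truth <- dplyr::bind_rows(
        truth, tibble::tibble(query = plants$seq[i],
                              read_id = paste0("read", rd),
                              offset = as.integer(off)))
    }
  }
  reads <- tibble::tibble(read_id = paste0("read", seq_len(n_reads)),
                          sequence = seqs, quality = quals)
  if (!is.null(path)) write_fastq(reads, path)
  invisible(list(reads = reads, truth = truth,
                 path = path %||% NA_character_))
}

#' Read and write sequence files
#'
#' Thin wrappers: FASTA/FASTQ parsing goes through Biostrings; the FASTQ
#' writer emits standard four-line records with Phred+33 qualities.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of record sequences.
#'   `read_fastq()`: a tibble `read_id`, `sequence`, `quality`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' @rdname read_fasta
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Exact plaintext k-mer search (reference oracle)
#'
#' Independent of the encrypted pipeline: exact matching is delegated to
#' `Biostrings::vmatchPattern` over the plain records. Used for ground-truth
#' verification and in tests as the oracle the homomorphic path must equal.
#'
#' @param seqs Named character vector of sequences (records or reads).
#' @param kmers Character vector of query k-mers over A/C/G/T.
#' @return Tibble `query_seq`, `record`, `position` (0-based).
#' @export
naive_kmer_search <- function(seqs, kmers) {
  subject <- Biostrings::DNAStringSet(toupper(seqs))
  out <- lapply(unique(kmers), function(km) {
    hits <- Biostrings::vmatchPattern(km, subject, fixed = TRUE)
    rows <- lapply(seq_along(hits), function(i) {
      st <- BiocGenerics::start(hits[[i]])
      if (length(st) == 0) return(NULL)
      tibble::tibble(query_seq = km, record = names(subject)[i],
                     position = as.integer(st - 1L))
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(query_seq = character(0), record = character(0),
                          position = integer(0)))
  }
  dplyr::arrange(res, .data$query_seq, .data$record, .data$position)
}
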