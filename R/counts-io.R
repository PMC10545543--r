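## I/O for sgRNA count matrices, sample metadata and raw FASTQ guide
## counting. Count tables use the common screen layout: a header line
## `sgRNA<TAB>gene` followed by one column per sample.

#' Read an sgRNA count table
#'
#' Expects tab-separated text whose first two columns are `sgRNA` and
#' `gene`, followed by sample count columns. Counts must be non-negative
#' integers; violations raise a parse error naming the offending cell.
#'
#' @param path Count TSV path.
#' @param manifest Optional `library_manifest`; sgRNAs absent from it are
#'   reported via a warning and kept (never silently dropped).
#' @return List with `counts` (integer matrix, sgRNA x sample) and `genes`
#'   (data.frame sgrna_id, target_id).
#' @export
read_counts <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop_io(paste("no such file:", path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop_format("count table needs sgRNA, gene and >= 1 sample column")
  if (!identical(tolower(names(raw)[1:2]), c("sgrna", "gene"))) {
    stop_format("count table header must start with 'sgRNA<TAB>gene'")
  }
  if (anyDuplicated(raw[[1L]])) {
    stop_format(paste("duplicated sgrna_id:",
                      paste(unique(raw[[1L]][duplicated(raw[[1L]])]), collapse = ", ")))
  }
  samp <- names(raw)[-(1:2)]
  mat <- matrix(NA_integer_, nrow(raw), length(samp),
                dimnames = list(raw[[1L]], samp))
  for (j in seq_along(samp)) {
    v <- raw[[j + 2L]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad)) {
      stop_parse(sprintf(
        "non-integer count '%s' at row %d (sgRNA %s), column '%s'",
        v[bad[1L]], bad[1L], raw[[1L]][bad[1L]], samp[j]))
    }
    mat[, j] <- as.integer(num)
  }
  if (!is.null(manifest)) {
    unknown <- setdiff(rownames(mat), manifest$sgrna_id)
    if (length(unknown)) {
      warning(sprintf("%d sgRNA id(s) not in manifest (e.g. %s)",
                      length(unknown), unknown[1L]))
    }
  }
  list(counts = mat,
       genes = data.frame(sgrna_id = raw[[1L]], target_id = raw[[2L]],
                          stringsAsFactors = FALSE))
}

#' Write an sgRNA count table
#'
#' @param counts Integer matrix (sgRNA x sample).
#' @param genes Mapping of sgrna_id to target_id: a data.frame with those
#'   columns or a `library_manifest`.
#' @param path Output TSV path.
#' @export
write_counts <- function(counts, genes, path) {
  if (is.null(colnames(counts)) || ncol(counts) < 1L) {
    stop_format("count matrix must have at least one named sample column")
  }
  map <- setNames(genes$target_id, genes$sgrna_id)
  missing <- setdiff(rownames(counts), names(map))
  if (length(missing)) stop_format(paste("no target mapping for", missing[1L]))
  out <- data.frame(sgRNA = rownames(counts), gene = unname(map[rownames(counts)]),
                    counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' TSV with columns `sample_id`, `tissue`, `replicate`; (tissue, replicate)
#' pairs must be unique.
#' @param path File path.
#' @param meta Metadata data.frame.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop_io(paste("no such file:", path))
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "replicate")
  if (!all(need %in% names(meta))) {
    stop_format("sample metadata needs sample_id, tissue, replicate")
  }
  if (anyDuplicated(meta[, c("tissue", "replicate")])) {
    stop_format("duplicated (tissue, replicate) pair in sample metadata")
  }
  meta
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count guides in a FASTQ file by anchored extraction
#'
#' Screen amplicons place the 20-nt guide directly after a constant vector
#' anchor (`CACCG` at the end of the U6 scaffold). For each read the first
#' anchor occurrence is located, the following 20 nt are extracted and
#' matched against the manifest's guide sequences (exactly, or within
#' `max_mismatch` Hamming distance when opted in). Anchor search makes the
#' extraction robust to staggered primer offsets.
#'
#' @param fastq_path FASTQ file, plain or gzipped.
#' @param manifest A `library_manifest`.
#' @param anchor Constant sequence preceding the guide.
#' @param max_mismatch Maximum Hamming distance for guide matching
#'   (default 0 = exact); a read is assigned only when a unique best guide
#'   exists at distance <= `max_mismatch`.
#' @return List with `counts` (named integer vector per sgrna_id) and
#'   `stats` (`n_reads`, `n_anchored`, `n_mapped`).
#' @export
count_guides <- function(fastq_path, manifest, anchor = "CACCG", max_mismatch = 0L) {
  validate_manifest(manifest)
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq_path, format = "fastq")),
    error = function(e) stop_io(paste("cannot read FASTQ:", conditionMessage(e)))
  )
  n_reads <- length(reads)
  counts <- setNames(integer(nrow(manifest)), manifest$sgrna_id)
  pos <- regexpr(anchor, reads, fixed = TRUE)
  start <- pos + nchar(anchor)
  ok <- pos > 0L & (start + 19L) <= nchar(reads)
  n_anchored <- sum(pos > 0L)
  cand <- substr(reads[ok], start[ok], start[ok] + 19L)
  hit <- match(cand, manifest$guide_seq)
  if (max_mismatch > 0L && anyNA(hit)) {
    un <- which(is.na(hit))
    for (i in un) {
      d <- hamming_to_all(cand[i], manifest$guide_seq)
      best <- min(d)
      if (best <= max_mismatch && sum(d == best) == 1L) hit[i] <- which.min(d)
    }
  }
  mapped <- hit[!is.na(hit)]
  if (length(mapped)) {
    tab <- tabulate(mapped, nbins = nrow(manifest))
    counts[] <- counts + tab
  }
  list(counts = counts,
       stats = list(n_reads = n_reads, n_anchored = n_anchored,
                    n_mapped = length(mapped)))
}

hamming_to_all <- function(q, refs) {
  qi <- utf8ToInt(q)
  vapply(refs, function(r) sum(utf8ToInt(r) != qi), integer(1), USE.NAMES = FALSE)
}

#' Write a FASTQ file (plain text)
#'
#' Minimal writer used by the simulator and tests; constant quality.
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param ids Optional read ids.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), path)
  invisible(path)
}
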