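#' Read a text SAM file
#'
#' Minimal record-level reader: header lines (`@`-prefixed) are passed
#' through untouched; each alignment line contributes a record with the
#' fields the supplementary filter and coverage accounting need, plus the
#' original line so that filtered output is byte-faithful.
#'
#' @param path Path to a text SAM file.
#' @return A list of class `sam_file` with `header` (character vector) and
#'   `records` (data frame: `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `line`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  body <- lines[!is_hdr]
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 11L)
    if (length(short)) {
      stop("SAM record with fewer than 11 fields at line ",
           which(!is_hdr)[short[1L]], " of ", path)
    }
    flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    if (anyNA(flag)) {
      bad <- which(is.na(flag))[1L]
      stop("unparseable FLAG for record '", vapply(fields, `[[`, "", 1L)[bad],
           "' in ", path)
    }
    records <- data.frame(
      qname = vapply(fields, `[[`, "", 1L),
      flag = flag,
      rname = vapply(fields, `[[`, "", 3L),
      pos = as.integer(vapply(fields, `[[`, "", 4L)),
      mapq = as.integer(vapply(fields, `[[`, "", 5L)),
      cigar = vapply(fields, `[[`, "", 6L),
      line = body,
      stringsAsFactors = FALSE)
  } else {
    records <- data.frame(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          line = character(), stringsAsFactors = FALSE)
  }
  structure(list(header = lines[is_hdr], records = records),
            class = "sam_file")
}

#' Write a text SAM file
#'
#' @param sam A `sam_file` (from [read_sam()] or after filtering).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(sam, path) {
  writeLines(c(sam$header, sam$records$line), path)
  invisible(path)
}

#' Remove supplementary alignments
#'
#' Drops records whose FLAG has bit 2048 set — the supplementary alignments
#' that double-count palindromic reads mapped twice at one locus — keeping
#' everything else in order (equivalent to `samtools view -F 2048`).
#'
#' @param records A record data frame (the `records` element of a
#'   `sam_file`) or a `sam_file`.
#' @return The same type as the input, with supplementary records removed.
#' @export
filter_supplementary <- function(records) {
  if (inherits(records, "sam_file")) {
    records$records <- filter_supplementary(records$records)
    return(records)
  }
  records[bitwAnd(records$flag, 2048L) == 0L, , drop = FALSE]
}

# Reference-consuming blocks of a CIGAR string, as a matrix of 1-based
# [start, end] intervals. D (deletion) blocks count as covered, N (intron)
# blocks advance without coverage; I/S/H consume no reference.
.cigar_ref_blocks <- function(cigar, pos) {
  if (cigar == "*") return(matrix(integer(), ncol = 2L))
  toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("invalid CIGAR string: ", cigar)
  }
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  if (any(!op %in% c("M", "=", "X", "I", "D", "N", "S", "H"))) {
    stop("unsupported CIGAR operation in: ", cigar)
  }
  blocks <- matrix(integer(), ncol = 2L)
  at <- pos
  run_start <- NA_integer_
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X", "D")) {
      if (is.na(run_start)) run_start <- at
      at <- at + len[k]
    } else if (op[k] == "N") {
      if (!is.na(run_start)) {
        blocks <- rbind(blocks, c(run_start, at - 1L))
        run_start <- NA_integer_
      }
      at <- at + len[k]
    }
    # I, S, H: no reference advance
  }
  if (!is.na(run_start)) blocks <- rbind(blocks, c(run_start, at - 1L))
  blocks
}

#' Per-base coverage depth over a region
#'
#' Depth at each reference base is the number of records whose aligned
#' (`M`/`=`/`X`/`D`) blocks cover it; `N` introns and soft/hard clips add no
#' depth. Filtering supplementary alignments of a palindromic read halves
#' the depth wherever the read mapped twice.
#'
#' @param records A SAM record data frame or `sam_file`.
#' @param chrom Reference name.
#' @param start,end 1-based inclusive region bounds.
#' @return Integer vector of depths, one per base of `[start, end]`.
#' @export
coverage_profile <- function(records, chrom, start, end) {
  if (inherits(records, "sam_file")) records <- records$records
  stopifnot(start <= end)
  depth <- integer(end - start + 1L)
  hit <- which(records$rname == chrom)
  for (i in hit) {
    blocks <- .cigar_ref_blocks(records$cigar[i], records$pos[i])
    for (b in seq_len(nrow(blocks))) {
      lo <- max(blocks[b, 1L], start)
      hi <- min(blocks[b, 2L], end)
      if (lo <= hi) {
        idx <- (lo - start + 1L):(hi - start + 1L)
        depth[idx] <- depth[idx] + 1L
      }
    }
  }
  depth
}
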