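#' Write alignment records as coordinate-sorted SAM
#'
#' Plain-text SAM with `@SQ` header lines, 1-based positions, CIGAR of the
#' form `<S><M><S>`, and the tags the pipeline consumes: `NM:i` (edit
#' distance), `SA:Z` (mapped position of the soft-clipped segment) and `XA:Z`
#' (alternative hits as `contig,pos,strand,NM;` with 1-based positions).
#' SEQ/QUAL are `*` — no downstream stage consumes base-level sequence.
#'
#' @param alignments alignment data.frame (see [simulate_alignments()]).
#' @param path output path.
#' @param contig_lengths named integer vector for the `@SQ` header.
#' @return invisibly, `path`.
#' @export
write_sam <- function(alignments, path, contig_lengths) {
  a <- alignments
  miss <- setdiff(unique(a$contig), names(contig_lengths))
  if (length(miss)) stop("no @SQ length for contig: ", paste(miss, collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- ifelse(a$strand == "-", 16L, 0L)
  paired <- !is.na(a$mate_contig)
  flag <- flag + ifelse(paired, 1L, 0L) +
    ifelse(paired & !is.na(a$mate_strand) & a$mate_strand == "-", 32L, 0L) +
    ifelse(a$secondary, 256L, 0L)
  cigar <- paste0(ifelse(a$clip_left > 0L, paste0(a$clip_left, "S"), ""),
                  a$aln_len, "M",
                  ifelse(a$clip_right > 0L, paste0(a$clip_right, "S"), ""))
  rnext <- ifelse(paired, ifelse(a$mate_contig == a$contig, "=", a$mate_contig), "*")
  pnext <- ifelse(paired, a$mate_pos + 1L, 0L)
  tags <- sprintf("NM:i:%d", a$nm)
  has_sa <- !is.na(a$sa_pos)
  tags <- ifelse(has_sa,
                 paste0(tags, sprintf("\tSA:Z:%s,%d,%s,*,60,0;",
                                      a$sa_contig, a$sa_pos + 1L, a$sa_strand)),
                 tags)
  has_xa <- !is.na(a$xa)
  xa_sam <- rep(NA_character_, nrow(a))
  if (any(has_xa)) xa_sam[has_xa] <- vapply(a$xa[has_xa], xa_to_sam, character(1))
  tags <- ifelse(has_xa, paste0(tags, "\tXA:Z:", xa_sam), tags)
  body <- paste(a$qname, flag, a$contig, a$start + 1L, a$mapq, cigar,
                rnext, pnext, 0L, "*", "*", tags, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# internal xa strings are 0-based "contig,pos,strand,nm;..."; SAM is 1-based
# "contig,<strand><pos>,nm;..."
xa_to_sam <- function(x) {
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  paste0(vapply(parts, function(p)
    sprintf("%s,%s%d,%s", p[1], p[3], as.integer(p[2]) + 1L, p[4]),
    character(1)), ";", collapse = "")
}

xa_from_sam <- function(x) {
  entries <- strsplit(x, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  parts <- strsplit(entries, ",", fixed = TRUE)
  paste(vapply(parts, function(p) {
    strand <- substr(p[2], 1, 1)
    pos <- as.integer(substr(p[2], 2, nchar(p[2]))) - 1L
    sprintf("%s,%d,%s,%s", p[1], pos, strand, p[3])
  }, character(1)), collapse = ";")
}

#' Read a SAM file into the package's alignment representation
#'
#' Accepts the subset of SAM this pipeline consumes: `<S>M<S>` CIGARs (any
#' other operator raises an error with its line number), NM/SA/XA tags.
#' Positions are converted to 0-based half-open.
#'
#' @param path SAM file path.
#' @return alignment data.frame plus a `contig_lengths` attribute.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  sq_name <- sub(".*SN:([^\t]+).*", "\\1", sq)
  sq_len <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
  body <- lines[!is_hdr]
  if (!length(body)) {
    out <- empty_alignments()
    attr(out, "contig_lengths") <- stats::setNames(sq_len, sq_name)
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("malformed SAM record at line ",
                          which(!is_hdr)[which(nf < 11L)[1]])
  get <- function(i) vapply(f, `[[`, character(1), i)
  contig <- get(3)
  miss <- setdiff(unique(contig), c(sq_name, "*"))
  if (length(miss)) stop("contig missing from @SQ header: ",
                         paste(miss, collapse = ", "))
  flag <- as.integer(get(2))
  cigar <- get(6)
  ok <- grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", cigar)
  if (any(!ok)) stop("unsupported CIGAR at line ", which(!is_hdr)[which(!ok)[1]])
  cl <- integer(length(cigar))
  has_l <- grepl("^[0-9]+S", cigar)
  cl[has_l] <- as.integer(sub("^([0-9]+)S.*", "\\1", cigar[has_l]))
  cr <- integer(length(cigar))
  has_r <- grepl("M[0-9]+S$", cigar)
  cr[has_r] <- as.integer(sub(".*M([0-9]+)S$", "\\1", cigar[has_r]))
  m <- as.integer(sub("^(?:[0-9]+S)?([0-9]+)M.*", "\\1", cigar))
  tagf <- function(re) {
    out <- rep(NA_character_, length(f))
    for (i in seq_along(f)) {
      hit <- grep(re, f[[i]][-(1:11)], value = TRUE)
      if (length(hit)) out[i] <- sub(re, "\\1", hit[1])
    }
    out
  }
  nm <- tagf("^NM:i:(.*)$")
  sa <- tagf("^SA:Z:(.*)$")
  xa <- tagf("^XA:Z:(.*)$")
  sa_parts <- strsplit(ifelse(is.na(sa), "NA,0,NA", sa), ",", fixed = TRUE)
  rnext <- get(7)
  paired <- bitwAnd(flag, 1L) > 0L
  out <- data.frame(
    qname = get(1), contig = contig, start = as.integer(get(4)) - 1L,
    aln_len = m, strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(get(5)), clip_left = cl, clip_right = cr,
    sa_contig = vapply(sa_parts, `[[`, character(1), 1),
    sa_pos = suppressWarnings(as.integer(vapply(sa_parts, `[[`, character(1), 2)) - 1L),
    sa_strand = vapply(sa_parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                       character(1)),
    mate_contig = ifelse(paired, ifelse(rnext == "=", contig, rnext), NA_character_),
    mate_pos = ifelse(paired, as.integer(get(8)) - 1L, NA_integer_),
    mate_strand = ifelse(paired, ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
                         NA_character_),
    nm = ifelse(is.na(nm), 0L, as.integer(nm)),
    xa = ifelse(is.na(xa), NA_character_,
                vapply(ifelse(is.na(xa), "", xa), xa_from_sam, character(1))),
    secondary = bitwAnd(flag, 256L) > 0L,
    stringsAsFactors = FALSE)
  out$sa_pos[is.na(sa)] <- NA_integer_
  out$sa_contig[is.na(sa)] <- NA_character_
  out$sa_strand[is.na(sa)] <- NA_character_
  attr(out, "contig_lengths") <- stats::setNames(sq_len, sq_name)
  out
}

empty_alignments <- function() {
  data.frame(qname = character(0), contig = character(0), start = integer(0),
             aln_len = integer(0), strand = character(0), mapq = integer(0),
             clip_left = integer(0), clip_right = integer(0),
             sa_contig = character(0), sa_pos = integer(0),
             sa_strand = character(0), mate_contig = character(0),
             mate_pos = integer(0), mate_strand = character(0),
             nm = integer(0), xa = character(0), secondary = logical(0),
             stringsAsFactors = FALSE)
}

#' Write and read circle-call tables
#'
#' BED-like TSV: contig, start, end, name, support, mode, coverage_fraction,
#' sample. Round-trips all fields the pipeline consumes.
#'
#' @param calls call data.frame from the detectors.
#' @param path file path.
#' @return `read_calls_tsv` returns the call data.frame.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("call with start >= end")
  df
}

#' Write a generic TSV table
#' @param df data.frame. @param path file path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
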