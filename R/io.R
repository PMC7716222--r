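# Readers and writers for the interchange formats: EMPOP-style haplotype
# tables, SAM alignments, and the per-position per-strand pileup TSV dialect.

range_to_string <- function(range) {
  paste(apply(range, 1L, paste, collapse = "-"), collapse = ";")
}

string_to_range <- function(s) {
  parts <- strsplit(trimws(s), "[;,]")[[1L]]
  m <- do.call(rbind, lapply(parts, function(p) {
    ab <- as.integer(strsplit(p, "-")[[1L]])
    if (length(ab) != 2L || any(is.na(ab))) stop("malformed range '", p, "'")
    ab
  }))
  colnames(m) <- c("start", "end")
  m
}

#' Read an EMPOP-style haplotype table
#'
#' Tab-separated columns \code{SampleID}, \code{Haplogroup}, \code{Range}
#' (semicolon-separated inclusive intervals, e.g. \code{"16024-16569;1-576"}),
#' and \code{Variants} (space-separated forensic variant strings).
#'
#' @param path Input path.
#' @param reference Optional \code{mito_reference} used to validate stated
#'   reference bases.
#' @return List of \code{mito_profile} objects.
#' @export
read_profile_table <- function(path, reference = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("SampleID", "Haplogroup", "Range", "Variants")
  if (!all(need %in% names(d))) {
    stop("profile table must have columns ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(d)), function(i) {
    toks <- strsplit(trimws(d$Variants[i]), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    hg <- d$Haplogroup[i]
    profile_from_strings(
      d$SampleID[i], toks, reference = reference,
      range = string_to_range(d$Range[i]),
      haplogroup = if (is.na(hg) || !nzchar(hg)) NA_character_ else hg,
      population = if ("Population" %in% names(d)) d$Population[i]
                   else NA_character_
    )
  })
}

#' Write profiles as an EMPOP-style haplotype table
#'
#' Rows are emitted in sample-id order and variants in coordinate order, so
#' output is deterministic for a given set of profiles.
#'
#' @param profiles List of \code{mito_profile} objects.
#' @param path Output path.
#' @param deletion_style Passed to \code{\link{format_variant}}.
#' @export
write_profile_table <- function(profiles, path,
                                deletion_style = c("DEL", "dash")) {
  deletion_style <- match.arg(deletion_style)
  profiles <- profiles[order(vapply(profiles, `[[`, "", "sample_id"))]
  d <- data.frame(
    SampleID = vapply(profiles, `[[`, "", "sample_id"),
    Haplogroup = vapply(profiles, `[[`, "", "haplogroup"),
    Range = vapply(profiles, function(p) range_to_string(p$range), ""),
    Variants = vapply(profiles, function(p) {
      paste(format_variant(p$variants, deletion_style), collapse = " ")
    }, ""),
    Population = vapply(profiles, `[[`, "", "population"),
    stringsAsFactors = FALSE
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import aligned reads from a SAM file
#'
#' Reads a mapped, single-contig SAM file and applies the alignment
#' admission contract: unmapped reads, clipped reads (length fraction below
#' 1.0) and reads whose edit distance implies identity below
#' \code{min_identity} are dropped.
#'
#' @param path SAM file path.
#' @param min_identity Minimum (length - NM)/length, applied when the NM tag
#'   is present.
#' @return A read stack (see \code{\link{read_stack}}).
#' @export
read_sam <- function(path, min_identity = 0.8) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq", "qual"), tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- x$flag
  keep <- !bitwAnd(flag, 4L)
  cig <- x$cigar
  keep <- keep & !grepl("[SH]", cig)
  nm <- x$tag$NM
  len <- nchar(as.character(x$seq))
  if (!is.null(nm)) {
    ident <- (len - ifelse(is.na(nm), 0L, nm)) / pmax(len, 1L)
    keep <- keep & ident >= min_identity
  }
  read_stack(data.frame(
    read_id = x$qname[keep],
    start = x$pos[keep],
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
    paired = bitwAnd(flag[keep], 1L) > 0L,
    seq = as.character(x$seq)[keep],
    qual = as.character(x$qual)[keep],
    cigar = cig[keep],
    stringsAsFactors = FALSE
  ))
}

#' Write a read stack to SAM
#'
#' Reads that wrap the circular origin cannot be expressed as a single linear
#' SAM record and are skipped with a warning.
#'
#' @param reads A read stack.
#' @param path Output path.
#' @param reference A \code{mito_reference} (for the header).
#' @export
write_sam <- function(reads, path, reference) {
  ends <- reads$start + cigar_ref_span(reads$cigar) - 1L
  wrap <- ends > reference$length
  if (any(wrap)) {
    warning(sum(wrap), " origin-wrapping read(s) skipped in SAM output")
    reads <- reads[!wrap, , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", reference$name, "\tLN:", reference$length)
  ), con)
  flag <- ifelse(reads$strand == "-", 16L, 0L) + ifelse(reads$paired, 1L, 0L)
  writeLines(paste(reads$read_id, flag, reference$name, reads$start, 60L,
                   reads$cigar, "*", 0L, 0L, reads$seq, reads$qual,
                   sep = "\t"), con)
  invisible(path)
}

#' Write a pileup to the TSV dialect
#'
#' Columns: position, refbase, per-base and deletion counts split by strand
#' (\code{A_f}, \code{A_r}, ..., \code{del_f}, \code{del_r}) and
#' \code{ins_json}, a JSON object mapping each insertion motif anchored at
#' the position to its [forward, reverse] counts.
#'
#' @param pileup A \code{mito_pileup}.
#' @param path Output path.
#' @param reference A \code{mito_reference}.
#' @export
write_pileup_tsv <- function(pileup, path, reference) {
  cm <- pileup$counts
  covered <- which(rowSums(cm) > 0L)
  ins <- pileup$insertions
  ins_json <- rep("{}", length(covered))
  if (nrow(ins)) {
    byp <- split(ins, ins$position)
    idx <- match(as.integer(names(byp)), covered)
    ins_json[idx[!is.na(idx)]] <- vapply(byp[!is.na(idx)], function(g) {
      obj <- stats::setNames(
        lapply(seq_len(nrow(g)), function(i) c(g$fwd[i], g$rev[i])), g$motif)
      as.character(jsonlite::toJSON(obj))
    }, "")
  }
  d <- data.frame(
    position = covered,
    refbase = ref_base(reference, covered),
    A_f = cm[covered, "A_f"], A_r = cm[covered, "A_r"],
    C_f = cm[covered, "C_f"], C_r = cm[covered, "C_r"],
    G_f = cm[covered, "G_f"], G_r = cm[covered, "G_r"],
    T_f = cm[covered, "T_f"], T_r = cm[covered, "T_r"],
    del_f = cm[covered, "D_f"], del_r = cm[covered, "D_r"],
    ins_json = ins_json, stringsAsFactors = FALSE
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the pileup TSV dialect
#'
#' @param path Input path.
#' @param reference A \code{mito_reference} (fixes the genome length).
#' @return A \code{mito_pileup}.
#' @export
read_pileup_tsv <- function(path, reference) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  cm <- matrix(0L, nrow = reference$length, ncol = 10L,
               dimnames = list(NULL, PILEUP_COLS))
  cm[d$position, ] <- as.matrix(
    d[, c("A_f", "C_f", "G_f", "T_f", "del_f",
          "A_r", "C_r", "G_r", "T_r", "del_r")])
  ins <- empty_insertions()
  has_ins <- which(!is.na(d$ins_json) & d$ins_json != "{}" & nzchar(d$ins_json))
  for (i in has_ins) {
    obj <- jsonlite::fromJSON(d$ins_json[i])
    ins <- rbind(ins, data.frame(
      position = d$position[i], motif = names(obj),
      fwd = vapply(obj, `[`, 0L, 1L), rev = vapply(obj, `[`, 0L, 2L),
      stringsAsFactors = FALSE, row.names = NULL
    ))
  }
  new_pileup(cm, ins, reference)
}
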