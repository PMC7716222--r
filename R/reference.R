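# Circular reference model and the fixed coordinate sets used throughout
# forensic mitogenome interpretation.

RCRS_LENGTH <- 16569L
BASES <- c("A", "C", "G", "T")
# two-base ambiguity codes only; three/four-base codes are rejected on input
IUPAC_PAIRS <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Mitochondrial reference genome
#'
#' Holds a single circular reference sequence with 1-based coordinates.
#' Coordinate arithmetic wraps around the origin: the position after the last
#' base is position 1.
#'
#' @param sequence Character scalar over A, C, G, T, N (case-insensitive).
#' @param name Sequence name, used when writing SAM/FASTA.
#' @return An object of class \code{mito_reference} with fields \code{name},
#'   \code{sequence} and \code{length}.
#' @export
mito_reference <- function(sequence, name = "chrM") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence may only contain A, C, G, T, N")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$name, ": ", x$length, " bp (circular)\n", sep = "")
  invisible(x)
}

#' Read a single-record reference FASTA
#'
#' Circularity is a property of the model, not of the file; the sequence is
#' treated as circular regardless of the FASTA content.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A \code{mito_reference}.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop("expected a single FASTA record, found ", length(x))
  mito_reference(as.character(x[[1L]]), name = sub("\\s.*$", "", names(x)[1L]))
}

#' Write a reference to FASTA
#'
#' @param reference A \code{mito_reference}.
#' @param path Output path.
#' @export
write_reference_fasta <- function(reference, path) {
  s <- Biostrings::DNAStringSet(reference$sequence)
  names(s) <- reference$name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

# vectorized base lookup, 1-based
ref_base <- function(reference, positions) {
  substring(reference$sequence, positions, positions)
}

#' Wrap a position onto the circular genome
#'
#' @param pos Integer vector (may exceed the genome length or be < 1).
#' @param length Genome length.
#' @return Positions mapped into 1..length.
#' @export
circular_position <- function(pos, length = RCRS_LENGTH) {
  ((as.integer(pos) - 1L) %% as.integer(length)) + 1L
}

#' Fixed region catalogue for the mitogenome
#'
#' Returns the coordinate sets used by the caller, the length-heteroplasmy
#' module and the haplotype comparison rules: the control region (spanning the
#' origin), the nine regions that commonly exhibit length heteroplasmy, the
#' ten insertion positions ignored in haplotype comparisons, the coding
#' region, and the amplicon interval screened for nuclear-insert (NUMT)
#' interference.
#'
#' @return A list of class \code{region_catalog}.
#' @export
region_catalog <- function() {
  lh <- list(
    "303-315"     = c(303L, 315L),
    "452-463"     = c(452L, 463L),
    "513-524"     = c(513L, 524L),
    "565-573"     = c(565L, 573L),
    "956-966"     = c(956L, 966L),
    "5891-5899"   = c(5891L, 5899L),
    "8270-8289"   = c(8270L, 8289L),
    "12418-12425" = c(12418L, 12425L),
    "16180-16193" = c(16180L, 16193L)
  )
  structure(list(
    genome_length = RCRS_LENGTH,
    control_region = rbind(c(16024L, 16569L), c(1L, 576L)),
    cds = rbind(c(577L, 16023L)),
    whole_mitogenome = rbind(c(1L, RCRS_LENGTH)),
    length_het_regions = lh,
    ignored_insertion_positions =
      c(16193L, 309L, 315L, 455L, 463L, 573L, 960L, 5899L, 8276L, 8285L),
    numt_screen_region = rbind(c(6636L, 11428L))
  ), class = "region_catalog")
}

# interval matrix (cols start, end) membership, vectorized over positions
in_intervals <- function(positions, intervals) {
  hit <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (positions >= intervals[i, 1L] & positions <= intervals[i, 2L])
  }
  hit
}

length_het_intervals <- function(catalog) {
  do.call(rbind, unname(catalog$length_het_regions))
}

#' Test membership of positions in a named catalogue region
#'
#' @param position Integer vector of 1-based positions.
#' @param region One of \code{"control_region"}, \code{"cds"},
#'   \code{"whole_mitogenome"}, \code{"numt_screen_region"},
#'   \code{"length_het"} (any of the nine regions), or the name of a single
#'   length-heteroplasmy region such as \code{"303-315"}.
#' @param catalog A \code{region_catalog}.
#' @return Logical vector.
#' @export
in_region <- function(position, region, catalog = region_catalog()) {
  if (any(position < 1L | position > catalog$genome_length)) {
    stop("position out of 1-", catalog$genome_length)
  }
  iv <- if (region %in% c("control_region", "cds", "whole_mitogenome",
                          "numt_screen_region")) {
    catalog[[region]]
  } else if (identical(region, "length_het")) {
    length_het_intervals(catalog)
  } else if (region %in% names(catalog$length_het_regions)) {
    matrix(catalog$length_het_regions[[region]], ncol = 2L)
  } else {
    stop("unknown region name: ", region)
  }
  in_intervals(position, iv)
}

# resolve a region argument (name or c(start,end)) to an interval
resolve_region <- function(region, catalog = region_catalog()) {
  if (is.character(region)) {
    if (!region %in% names(catalog$length_het_regions)) {
      stop("region not in length-heteroplasmy catalogue: ", region)
    }
    iv <- catalog$length_het_regions[[region]]
    return(list(name = region, start = iv[1L], end = iv[2L]))
  }
  stopifnot(is.numeric(region), length(region) == 2L)
  list(name = paste0(region[1L], "-", region[2L]),
       start = as.integer(region[1L]), end = as.integer(region[2L]))
}
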