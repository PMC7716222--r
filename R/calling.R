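# Variant and point-heteroplasmy calling from aligned reads or pileups:
# read trimming, neighborhood base-quality masking, strand-resolved pileup
# construction, and threshold-based column calling with a secondary
# low-threshold screen for nuclear-insert (NUMT) interference.

PILEUP_COLS <- c("A_f", "C_f", "G_f", "T_f", "D_f",
                 "A_r", "C_r", "G_r", "T_r", "D_r")

empty_insertions <- function() {
  data.frame(position = integer(), motif = character(),
             fwd = integer(), rev = integer(), stringsAsFactors = FALSE)
}

#' Calling parameters
#'
#' Defaults follow the analysis contract of the workflow: a 100x minimum
#' read depth, a 5\% variant frequency (VF) threshold with a secondary 2\%
#' screen for NUMT interference, a base-quality filter with neighborhood
#' radius 5 and minimum central/neighborhood quality 30, a 1\% per-allele
#' forward/reverse balance filter, 20 nt trimmed from the 5' end of every
#' read (and from the 3' end of paired reads) and a 40 bp minimum read
#' length after trimming.
#'
#' @param min_depth Minimum filtered depth for any call.
#' @param vf_threshold Variant frequency threshold for reporting.
#' @param numt_screen_vf Lower VF threshold of the NUMT screen.
#' @param bq_radius,bq_central,bq_neighborhood Base-quality filter settings.
#' @param strand_balance_min Minimum fraction of an allele's reads required
#'   on each strand.
#' @param trim_5p,trim_3p_paired,min_read_length Read trimming settings.
#' @return List of class \code{call_params}.
#' @export
call_params <- function(min_depth = 100L, vf_threshold = 0.05,
                        numt_screen_vf = 0.02, bq_radius = 5L,
                        bq_central = 30L, bq_neighborhood = 30L,
                        strand_balance_min = 0.01, trim_5p = 20L,
                        trim_3p_paired = 20L, min_read_length = 40L) {
  stopifnot(min_depth >= 1L, numt_screen_vf > 0, numt_screen_vf < vf_threshold,
            vf_threshold < 0.5)
  structure(list(
    min_depth = as.integer(min_depth), vf_threshold = vf_threshold,
    numt_screen_vf = numt_screen_vf, bq_radius = as.integer(bq_radius),
    bq_central = as.integer(bq_central),
    bq_neighborhood = as.integer(bq_neighborhood),
    strand_balance_min = strand_balance_min, trim_5p = as.integer(trim_5p),
    trim_3p_paired = as.integer(trim_3p_paired),
    min_read_length = as.integer(min_read_length)
  ), class = "call_params")
}

#' Aligned read stack
#'
#' The in-memory representation of aligned reads: one row per read with
#' columns \code{read_id}, \code{start} (1-based position of the first
#' aligned base), \code{strand} (\code{"+"}/\code{"-"}), \code{paired},
#' \code{seq}, \code{qual} (Phred+33 string, same length as \code{seq}) and
#' \code{cigar} (M/I/D operations only). Alignments may wrap the circular
#' origin.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class \code{read_stack}.
#' @export
read_stack <- function(df) {
  need <- c("read_id", "start", "strand", "paired", "seq", "qual", "cigar")
  stopifnot(all(need %in% names(df)))
  if (nrow(df)) {
    stopifnot(all(df$strand %in% c("+", "-")),
              all(nchar(df$seq) == nchar(df$qual)))
  }
  df$start <- as.integer(df$start)
  class(df) <- c("read_stack", "data.frame")
  df
}

# ---- CIGAR helpers --------------------------------------------------------

cigar_ops <- function(cigar) {
  list(len = as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]]),
       op = regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]])
}

cigar_ref_span <- function(cigars) {
  u <- unique(cigars)
  span <- vapply(u, function(cg) {
    o <- cigar_ops(cg)
    sum(o$len[o$op %in% c("M", "D", "N", "=", "X")])
  }, 0L)
  unname(span[match(cigars, u)])
}

cigar_query_len <- function(cigars) {
  u <- unique(cigars)
  n <- vapply(u, function(cg) {
    o <- cigar_ops(cg)
    sum(o$len[o$op %in% c("M", "I", "S", "=", "X")])
  }, 0L)
  unname(n[match(cigars, u)])
}

# remove k query bases from the left of an alignment; boundary deletions are
# dropped and the start advanced accordingly
trim_alignment_left <- function(start, cigar, k) {
  if (k == 0L) return(list(start = start, cigar = cigar, drop = 0L))
  o <- cigar_ops(cigar)
  left <- k
  shift <- 0L
  i <- 1L
  while (i <= length(o$op) && left > 0L) {
    if (o$op[i] %in% c("M", "=", "X")) {
      take <- min(left, o$len[i])
      o$len[i] <- o$len[i] - take
      shift <- shift + take
      left <- left - take
    } else if (o$op[i] == "I") {
      take <- min(left, o$len[i])
      o$len[i] <- o$len[i] - take
      left <- left - take
    } else if (o$op[i] == "D") {
      shift <- shift + o$len[i]
      o$len[i] <- 0L
    }
    if (o$len[i] == 0L) i <- i + 1L else if (left == 0L) break
  }
  # drop a deletion left dangling at the new alignment start
  while (i <= length(o$op) && o$op[i] == "D") {
    shift <- shift + o$len[i]
    o$len[i] <- 0L
    i <- i + 1L
  }
  keep <- o$len > 0L
  list(start = start + shift,
       cigar = paste0(o$len[keep], o$op[keep], collapse = ""),
       drop = k)
}

trim_alignment_right <- function(cigar, k) {
  if (k == 0L) return(cigar)
  o <- cigar_ops(cigar)
  right <- k
  i <- length(o$op)
  while (i >= 1L && right > 0L) {
    if (o$op[i] %in% c("M", "I", "=", "X")) {
      take <- min(right, o$len[i])
      o$len[i] <- o$len[i] - take
      right <- right - take
    } else if (o$op[i] == "D") {
      o$len[i] <- 0L
    }
    if (o$len[i] == 0L) i <- i - 1L else if (right == 0L) break
  }
  while (i >= 1L && o$op[i] == "D") {
    o$len[i] <- 0L
    i <- i - 1L
  }
  keep <- o$len > 0L
  paste0(o$len[keep], o$op[keep], collapse = "")
}

# ---- Trimming and quality masking ----------------------------------------

#' Trim reads
#'
#' Removes \code{trim_5p} bases from the 5' end of every read and
#' \code{trim_3p_paired} bases from the 3' end of paired reads, then drops
#' reads shorter than \code{min_read_length}. Reads are stored in aligned
#' orientation, so the 5' end of a reverse-strand read is the right-hand end
#' of its alignment.
#'
#' @param reads A \code{read_stack}.
#' @param params A \code{call_params}.
#' @return The trimmed read stack.
#' @export
trim_reads <- function(reads, params = call_params()) {
  if (!nrow(reads)) return(reads)
  left <- ifelse(reads$strand == "+", params$trim_5p,
                 ifelse(reads$paired, params$trim_3p_paired, 0L))
  right <- ifelse(reads$strand == "-", params$trim_5p,
                  ifelse(reads$paired, params$trim_3p_paired, 0L))
  qlen <- cigar_query_len(reads$cigar)
  keep <- qlen - left - right >= params$min_read_length
  reads <- reads[keep, , drop = FALSE]
  left <- left[keep]; right <- right[keep]
  qlen <- qlen[keep]
  if (!nrow(reads)) return(read_stack(reads))
  simple <- grepl("^[0-9]+M$", reads$cigar)
  newlen <- qlen - left - right
  reads$seq <- substr(reads$seq, left + 1L, left + newlen)
  reads$qual <- substr(reads$qual, left + 1L, left + newlen)
  reads$start[simple] <- reads$start[simple] + left[simple]
  reads$cigar[simple] <- paste0(newlen[simple], "M")
  for (i in which(!simple)) {
    tl <- trim_alignment_left(reads$start[i], reads$cigar[i], left[i])
    reads$start[i] <- tl$start
    reads$cigar[i] <- trim_alignment_right(tl$cigar, right[i])
  }
  read_stack(reads)
}

# OR-dilate a logical vector by `radius` positions in both directions
dilate_logical <- function(x, radius) {
  out <- x
  n <- length(x)
  for (s in seq_len(radius)) {
    out[seq_len(n - s)] <- out[seq_len(n - s)] | x[(s + 1L):n]
    out[(s + 1L):n] <- out[(s + 1L):n] | x[seq_len(n - s)]
  }
  out
}

#' Apply the neighborhood base-quality filter
#'
#' A base is masked (excluded from every pileup column) when its own quality
#' is below the central minimum or when any base within the neighborhood
#' radius has quality below the neighborhood minimum. Masked bases are
#' replaced by \code{N} in the read sequence.
#'
#' @param reads A \code{read_stack} (trimmed).
#' @param params A \code{call_params}.
#' @return The masked read stack.
#' @export
quality_mask <- function(reads, params = call_params()) {
  if (!nrow(reads)) return(reads)
  lens <- nchar(reads$seq)
  r <- params$bq_radius
  q <- utf8ToInt(paste0(reads$qual, collapse = "")) - 33L
  # place reads in a padded vector so dilation cannot leak across reads
  pad_starts <- cumsum(c(1L, lens[-length(lens)] + r))
  idx <- sequence(lens) + rep(pad_starts, lens) - 1L
  plen <- max(idx)
  low_n <- logical(plen)
  low_n[idx] <- q < params$bq_neighborhood
  mask <- dilate_logical(low_n, r)[idx] | (q < params$bq_central)
  if (any(mask)) {
    chars <- strsplit(paste0(reads$seq, collapse = ""), "")[[1L]]
    chars[mask] <- "N"
    joined <- paste0(chars, collapse = "")
    ends <- cumsum(lens)
    reads$seq <- substring(joined, ends - lens + 1L, ends)
  }
  reads
}

# ---- Pileup construction --------------------------------------------------

new_pileup <- function(counts, insertions, reference) {
  colnames(counts) <- PILEUP_COLS
  structure(list(counts = counts, insertions = insertions,
                 genome_length = reference$length,
                 reference_name = reference$name),
            class = "mito_pileup")
}

#' @export
print.mito_pileup <- function(x, ...) {
  cov <- sum(rowSums(x$counts) > 0L)
  cat("<mito_pileup> ", cov, "/", x$genome_length, " positions covered\n",
      sep = "")
  invisible(x)
}

#' Build a strand-resolved pileup from masked reads
#'
#' One column per covered position with per-base and deletion counts split
#' by strand; insertion motifs are counted on their 3' anchor position.
#' Alignments wrap the circular origin. Masked (\code{N}) bases contribute
#' nothing.
#'
#' @param reads A trimmed, quality-masked \code{read_stack}.
#' @param reference A \code{mito_reference}.
#' @return A \code{mito_pileup}.
#' @export
build_pileup <- function(reads, reference) {
  L <- reference$length
  if (nrow(reads) && any(cigar_ref_span(reads$cigar) > 2L * L)) {
    stop("read alignment spans more than twice the genome length")
  }
  pos_acc <- integer(0); base_acc <- integer(0); strand_acc <- integer(0)
  ins_pos <- integer(0); ins_motif <- character(0); ins_strand <- integer(0)
  if (nrow(reads)) {
    simple <- grepl("^[0-9]+M$", reads$cigar)
    if (any(simple)) {
      rs <- reads[simple, , drop = FALSE]
      lens <- nchar(rs$seq)
      pos <- rep(rs$start, lens) + sequence(lens) - 1L
      chars <- strsplit(paste0(rs$seq, collapse = ""), "")[[1L]]
      b <- match(chars, BASES)
      st <- rep(ifelse(rs$strand == "-", 2L, 1L), lens)
      keep <- !is.na(b)
      pos_acc <- pos[keep]; base_acc <- b[keep]; strand_acc <- st[keep]
    }
    for (i in which(!simple)) {
      o <- cigar_ops(reads$cigar[i])
      chars <- strsplit(reads$seq[i], "")[[1L]]
      st <- if (reads$strand[i] == "-") 2L else 1L
      rp <- reads$start[i]   # next reference position
      qp <- 1L               # next query position
      for (j in seq_along(o$op)) {
        len <- o$len[j]
        if (o$op[j] %in% c("M", "=", "X")) {
          b <- match(chars[qp:(qp + len - 1L)], BASES)
          keep <- !is.na(b)
          pos_acc <- c(pos_acc, (rp:(rp + len - 1L))[keep])
          base_acc <- c(base_acc, b[keep])
          strand_acc <- c(strand_acc, rep(st, sum(keep)))
          rp <- rp + len; qp <- qp + len
        } else if (o$op[j] == "I") {
          motif <- substr(reads$seq[i], qp, qp + len - 1L)
          ins_pos <- c(ins_pos, rp - 1L)
          ins_motif <- c(ins_motif, motif)
          ins_strand <- c(ins_strand, st)
          qp <- qp + len
        } else if (o$op[j] == "D") {
          pos_acc <- c(pos_acc, rp:(rp + len - 1L))
          base_acc <- c(base_acc, rep(5L, len))
          strand_acc <- c(strand_acc, rep(st, len))
          rp <- rp + len
        } else {
          stop("unsupported CIGAR op '", o$op[j], "'")
        }
      }
    }
  }
  pos_acc <- circular_position(pos_acc, L)
  idx <- (strand_acc - 1L) * 5L * L + (base_acc - 1L) * L + pos_acc
  counts <- matrix(tabulate(idx, nbins = 10L * L), nrow = L)
  ins <- empty_insertions()
  if (length(ins_pos)) {
    ins_pos <- circular_position(ins_pos, L)
    key <- paste(ins_pos, ins_motif, sep = "\r")
    fwd <- tapply(ins_strand == 1L, key, sum)
    rev <- tapply(ins_strand == 2L, key, sum)
    parts <- strsplit(names(fwd), "\r", fixed = TRUE)
    ins <- data.frame(
      position = as.integer(vapply(parts, `[`, "", 1L)),
      motif = vapply(parts, `[`, "", 2L),
      fwd = as.integer(fwd), rev = as.integer(rev),
      stringsAsFactors = FALSE, row.names = NULL
    )
    ins <- ins[order(ins$position, ins$motif), , drop = FALSE]
  }
  new_pileup(counts, ins, reference)
}

# ---- Column classification ------------------------------------------------

# shared per-column decision rule; fwd/rev are counts over (A,C,G,T,del)
classify_column <- function(fwd, rev, refb, params) {
  tot <- fwd + rev
  depth <- sum(tot)
  if (depth < params$min_depth) return(list(status = "no_call_depth"))
  f <- tot / depth
  bal_ok <- tot > 0 & fwd / pmax(tot, 1L) >= params$strand_balance_min &
    rev / pmax(tot, 1L) >= params$strand_balance_min
  ret <- which(f >= params$vf_threshold & bal_ok)
  refi <- match(refb, BASES)
  if (length(ret) == 0L) return(list(status = "reference"))
  if (length(ret) == 1L) {
    if (!is.na(refi) && ret == refi) return(list(status = "reference"))
    if (is.na(refi)) return(list(status = "reference"))  # N site: no naming
    if (ret == 5L) {
      return(list(status = "deletion", major_freq = f[5L]))
    }
    return(list(status = "substitution", call = BASES[ret],
                major_freq = f[ret]))
  }
  if (length(ret) > 2L) return(list(status = "mixture_suspect"))
  if (5L %in% ret) {
    # base/deletion mixture: report the major allele, flag length variation
    maj <- ret[which.max(tot[ret])]
    if (maj == 5L) {
      return(list(status = "deletion", major_freq = f[5L], del_het = TRUE))
    }
    st <- if (is.na(refi) || maj == refi) "reference" else "substitution"
    out <- list(status = st, major_freq = f[maj], del_het = TRUE)
    if (st == "substitution") out$call <- BASES[maj]
    return(out)
  }
  b <- BASES[ret]
  maj <- which.max(tot[ret])  # ties resolve to the earlier base, A<C<G<T
  list(status = "php", call = iupac_code_for(b[1L], b[2L]),
       major_base = b[maj], major_freq = f[ret[maj]])
}

#' Call a single pileup column
#'
#' Applies the depth, variant-frequency and strand-balance rules to one
#' position. Useful for inspecting individual sites; \code{\link{call_profile}}
#' applies the same rule to every column.
#'
#' @param counts Numeric vector of length 10 in the column order
#'   \code{A_f, C_f, G_f, T_f, D_f, A_r, C_r, G_r, T_r, D_r}, or a 2x5
#'   matrix (rows forward, reverse).
#' @param ref_base Reference base at the position.
#' @param params A \code{call_params}.
#' @return List with \code{status} (one of \code{no_call_depth},
#'   \code{reference}, \code{substitution}, \code{php}, \code{deletion},
#'   \code{mixture_suspect}) and, where applicable, \code{call},
#'   \code{major_base} and \code{major_freq}.
#' @export
call_column <- function(counts, ref_base, params = call_params()) {
  if (is.matrix(counts)) counts <- c(t(counts))
  stopifnot(length(counts) == 10L)
  classify_column(counts[1:5], counts[6:10], toupper(ref_base), params)
}

# ---- Profile assembly -----------------------------------------------------

positions_in <- function(range) {
  if (is.null(dim(range))) range <- matrix(as.integer(range), ncol = 2L)
  unlist(lapply(seq_len(nrow(range)), function(i) {
    seq.int(range[i, 1L], range[i, 2L])
  }), use.names = FALSE)
}

intervals_from_positions <- function(pos) {
  pos <- sort(unique(as.integer(pos)))
  if (!length(pos)) return(matrix(integer(), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end"))))
  brk <- which(diff(pos) != 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))]
  cbind(start = starts, end = ends)
}

# pick the major insertion motif at an anchor; ties prefer the shorter then
# lexicographically smaller motif
select_major_motif <- function(motifs, totals) {
  o <- order(-totals, nchar(motifs), motifs)
  motifs[o[1L]]
}

#' Call a haplotype profile and coverage metrics
#'
#' Assembles per-column calls over the interpretation range into a
#' \code{mito_profile}. Positions below the minimum depth are excluded from
#' the reported range and listed in the metrics. Insertions and deletions
#' falling inside the nine catalogued length-heteroplasmy regions are
#' withheld from the profile (recorded in \code{attr(profile,
#' "withheld_indels")}) pending the spanning-read motif analysis; see
#' \code{\link{length_het_calls}}.
#'
#' @param x A \code{read_stack} (quality masking is applied) or a
#'   \code{mito_pileup}.
#' @param reference A \code{mito_reference}.
#' @param params A \code{call_params}.
#' @param range Requested interpretation range (interval matrix or length-2
#'   vector); defaults to the covered positions.
#' @param sample_id Sample identifier for the resulting profile.
#' @param catalog A \code{region_catalog}.
#' @return List with elements \code{profile} and \code{metrics}.
#' @export
call_profile <- function(x, reference, params = call_params(), range = NULL,
                         sample_id = "sample", catalog = region_catalog()) {
  UseMethod("call_profile")
}

#' @export
call_profile.read_stack <- function(x, reference, params = call_params(),
                                    range = NULL, sample_id = "sample",
                                    catalog = region_catalog()) {
  pl <- build_pileup(quality_mask(x, params), reference)
  call_profile(pl, reference, params, range, sample_id, catalog)
}

#' @export
call_profile.mito_pileup <- function(x, reference, params = call_params(),
                                     range = NULL, sample_id = "sample",
                                     catalog = region_catalog()) {
  depth_all <- rowSums(x$counts)
  if (is.null(range)) {
    range <- intervals_from_positions(which(depth_all > 0L))
    if (!nrow(range)) stop("pileup has no covered positions")
  }
  if (is.null(dim(range))) range <- matrix(as.integer(range), ncol = 2L)
  pos <- positions_in(range)
  if (!length(pos) || all(depth_all[pos] == 0L)) {
    stop("no covered positions in the requested range")
  }
  fwd <- x$counts[pos, 1:5, drop = FALSE]
  rev <- x$counts[pos, 6:10, drop = FALSE]
  tot <- fwd + rev
  depth <- rowSums(tot)
  ok <- depth >= params$min_depth
  below <- pos[!ok]
  f <- tot / pmax(depth, 1L)
  fshare <- fwd / pmax(tot, 1L)
  rshare <- rev / pmax(tot, 1L)
  ret <- (f >= params$vf_threshold & fshare >= params$strand_balance_min &
            rshare >= params$strand_balance_min & tot > 0) & ok
  refb <- ref_base(reference, pos)
  refi <- match(refb, BASES)
  nret <- rowSums(ret)
  ref_ret <- !is.na(refi) &
    ret[cbind(seq_along(pos), ifelse(is.na(refi), 1L, refi))]
  interesting <- which((nret > 1L | (nret == 1L & !ref_ret)) & !is.na(refi))

  variants <- empty_variants()
  suspect <- integer(0)
  del_het <- integer(0)
  for (i in interesting) {
    cl <- classify_column(fwd[i, ], rev[i, ], refb[i], params)
    p <- pos[i]
    if (cl$status == "mixture_suspect") {
      suspect <- c(suspect, p)
    } else if (cl$status == "substitution") {
      variants <- rbind(variants, new_variant(
        p, "substitution", ref = refb[i], call = cl$call,
        major_freq = cl$major_freq, major_base = cl$call))
      if (isTRUE(cl$del_het)) del_het <- c(del_het, p)
    } else if (cl$status == "php") {
      variants <- rbind(variants, new_variant(
        p, "substitution", ref = refb[i], call = cl$call,
        major_freq = cl$major_freq, major_base = cl$major_base))
    } else if (cl$status == "deletion") {
      variants <- rbind(variants, new_variant(p, "deletion", ref = refb[i]))
      if (isTRUE(cl$del_het)) del_het <- c(del_het, p)
    } else if (isTRUE(cl$del_het)) {
      del_het <- c(del_het, p)
    }
  }

  # insertion alleles, anchored 3', same depth/VF/strand rules
  ins <- x$insertions
  if (nrow(ins)) {
    ins <- ins[ins$position %in% pos[ok], , drop = FALSE]
  }
  if (nrow(ins)) {
    d_anchor <- depth_all[ins$position]
    itot <- ins$fwd + ins$rev
    ifreq <- itot / pmax(d_anchor, 1L)
    ins_ok <- ifreq >= params$vf_threshold &
      ins$fwd / pmax(itot, 1L) >= params$strand_balance_min &
      ins$rev / pmax(itot, 1L) >= params$strand_balance_min
    ins <- ins[ins_ok, , drop = FALSE]
    itot <- itot[ins_ok]
    for (p in unique(ins$position)) {
      g <- ins$position == p
      motif <- select_major_motif(ins$motif[g], itot[g])
      chars <- strsplit(motif, "")[[1L]]
      if (any(!chars %in% BASES)) next  # masked bases inside the motif
      for (k in seq_along(chars)) {
        variants <- rbind(variants, new_variant(
          p, "insertion", call = chars[k], insert_index = k))
      }
    }
  }

  final_range <- intervals_from_positions(setdiff(pos, below))
  if (!nrow(final_range)) stop("all positions fall below the depth threshold")
  profile <- mito_profile(sample_id, variants, range = final_range)
  profile <- normalize_indels(profile, reference)

  # withhold indels inside catalogued length-heteroplasmy regions
  lh_iv <- length_het_intervals(catalog)
  v <- profile$variants
  wh <- v$kind != "substitution" & in_intervals(v$position, lh_iv)
  withheld <- v[wh, , drop = FALSE]
  if (any(wh)) {
    profile <- edit_variants(profile, remove = withheld,
                             reason = "indel withheld pending length-heteroplasmy read-count analysis")
  }
  attr(profile, "withheld_indels") <- withheld
  profile$flags$mixture_suspect <- length(suspect) > 0L
  profile$flags$suspect_positions <- suspect
  profile$flags$deletion_het_positions <- del_het

  covered <- depth > 0L
  maxf <- pmax(f[, 1L], f[, 2L], f[, 3L], f[, 4L], f[, 5L])
  php_pos <- variants$position[variants$is_php]
  lh_mask <- in_intervals(pos, lh_iv)
  excl <- covered & !lh_mask & !(pos %in% php_pos)
  vpos <- unique(profile$variants$position)
  metrics <- structure(list(
    average_read_depth = mean(depth),
    average_major_base_frequency = mean(maxf[covered]),
    average_major_base_frequency_excl_het =
      if (any(excl)) mean(maxf[excl]) else NA_real_,
    variant_position_depth =
      if (length(vpos)) mean(depth_all[vpos]) else NA_real_,
    positions_below_min_depth = below,
    n_positions = length(pos)
  ), class = "call_metrics")
  list(profile = profile, metrics = metrics)
}

#' @export
print.call_metrics <- function(x, ...) {
  cat("<call_metrics>\n")
  cat(sprintf("  average read depth:            %.1f\n", x$average_read_depth))
  cat(sprintf("  avg major base freq:           %.4f\n",
              x$average_major_base_frequency))
  cat(sprintf("  avg major base freq (excl het):%.4f\n",
              x$average_major_base_frequency_excl_het))
  cat("  positions below min depth:", length(x$positions_below_min_depth), "\n")
  invisible(x)
}

#' Screen for NUMT interference at a lowered variant-frequency threshold
#'
#' Reports minor alleles that pass every filter at the secondary screen
#' threshold (default 2\%) but fall below the reporting threshold (default
#' 5\%); nuclear-insert co-amplification typically presents in this band.
#' Each hit is annotated with whether it falls in the screened amplicon
#' interval (nps 6,636-11,428).
#'
#' @param x A \code{read_stack} or \code{mito_pileup}.
#' @param reference A \code{mito_reference}.
#' @param params A \code{call_params}.
#' @param range Optional range restriction.
#' @param catalog A \code{region_catalog}.
#' @return Data frame with columns \code{position}, \code{base},
#'   \code{frequency}, \code{in_numt_region}.
#' @export
numt_screen <- function(x, reference, params = call_params(), range = NULL,
                        catalog = region_catalog()) {
  if (inherits(x, "read_stack")) {
    x <- build_pileup(quality_mask(x, params), reference)
  }
  depth_all <- rowSums(x$counts)
  if (is.null(range)) range <- intervals_from_positions(which(depth_all > 0L))
  if (is.null(dim(range))) range <- matrix(as.integer(range), ncol = 2L)
  pos <- positions_in(range)
  fwd <- x$counts[pos, 1:5, drop = FALSE]
  rev <- x$counts[pos, 6:10, drop = FALSE]
  tot <- fwd + rev
  depth <- rowSums(tot)
  ok <- depth >= params$min_depth
  f <- tot / pmax(depth, 1L)
  bal <- fwd / pmax(tot, 1L) >= params$strand_balance_min &
    rev / pmax(tot, 1L) >= params$strand_balance_min & tot > 0
  refi <- match(ref_base(reference, pos), BASES)
  hit <- which(
    (f >= params$numt_screen_vf & f < params$vf_threshold & bal & ok)[, 1:4] &
      outer(seq_along(pos), 1:4, function(i, b) {
        !is.na(refi[i]) & refi[i] != b
      }),
    arr.ind = TRUE
  )
  if (!length(hit)) {
    return(data.frame(position = integer(), base = character(),
                      frequency = numeric(), in_numt_region = logical(),
                      stringsAsFactors = FALSE))
  }
  p <- pos[hit[, 1L]]
  out <- data.frame(
    position = p, base = BASES[hit[, 2L]],
    frequency = f[hit], in_numt_region = in_intervals(p, catalog$numt_screen_region),
    stringsAsFactors = FALSE
  )
  out[order(out$position), , drop = FALSE]
}
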