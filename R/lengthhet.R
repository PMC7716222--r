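# Length-heteroplasmy read-count analysis: spanning-read motif counting per
# catalogued region, major-molecule selection, point-heteroplasmy detection
# inside motifs, and profile rewriting with the major molecule's variants.

# per-read offsets of a run of reference positions, via a CIGAR walk;
# returns list(map = query offsets aligned to refpos a..b (NA if deleted),
# ins = data.frame(anchor refpos, query start, len) for insertions)
walk_alignment <- function(start, cigar) {
  o <- cigar_ops(cigar)
  n_ops <- length(o$op)
  ref_from <- integer(n_ops); ref_to <- integer(n_ops)
  q_from <- integer(n_ops)
  rp <- start; qp <- 1L
  for (j in seq_len(n_ops)) {
    ref_from[j] <- rp; q_from[j] <- qp
    len <- o$len[j]
    if (o$op[j] %in% c("M", "=", "X")) {
      rp <- rp + len; qp <- qp + len
    } else if (o$op[j] == "I") {
      qp <- qp + len
    } else if (o$op[j] == "D") {
      rp <- rp + len
    } else {
      stop("unsupported CIGAR op '", o$op[j], "'")
    }
    ref_to[j] <- rp - 1L
  }
  list(op = o$op, len = o$len, ref_from = ref_from, ref_to = ref_to,
       q_from = q_from, ref_end = rp - 1L)
}

# extract the read subsequence aligned strictly between anchor positions a
# and b (exclusive); returns NA unless the read has an aligned base at both
# anchors
extract_between <- function(seq, start, cigar, a, b) {
  w <- walk_alignment(start, cigar)
  anchored <- function(p) {
    any(w$op %in% c("M", "=", "X") & w$ref_from <= p & w$ref_to >= p)
  }
  if (start > a || w$ref_end < b || !anchored(a) || !anchored(b)) {
    return(NA_character_)
  }
  pieces <- character(0)
  for (j in seq_along(w$op)) {
    if (w$op[j] %in% c("M", "=", "X")) {
      lo <- max(w$ref_from[j], a + 1L)
      hi <- min(w$ref_to[j], b - 1L)
      if (lo <= hi) {
        qs <- w$q_from[j] + (lo - w$ref_from[j])
        pieces <- c(pieces, substr(seq, qs, qs + (hi - lo)))
      }
    } else if (w$op[j] == "I") {
      anchor <- w$ref_from[j] - 1L
      if (anchor >= a && anchor <= b - 1L) {
        pieces <- c(pieces, substr(seq, w$q_from[j],
                                   w$q_from[j] + w$len[j] - 1L))
      }
    }
  }
  paste0(pieces, collapse = "")
}

#' Count spanning-read motifs over a length-heteroplasmy region
#'
#' A read contributes when it covers the full region plus one aligned anchor
#' base on each side; its motif is the read subsequence aligned strictly
#' between the anchors (so insertions lengthen and deletions shorten the
#' motif). Motifs carried by fewer than \code{min_count} reads are omitted
#' from the listing but still counted in \code{total_spanning}.
#'
#' @param reads A trimmed, quality-masked \code{read_stack}.
#' @param region Region name from the catalogue (e.g. \code{"303-315"}) or a
#'   length-2 interval.
#' @param catalog A \code{region_catalog}.
#' @param min_count Motif listing floor (an absolute read count).
#' @return List of class \code{motif_table} with \code{region},
#'   \code{interval}, \code{motifs} (named counts, decreasing) and
#'   \code{total_spanning}.
#' @export
spanning_motifs <- function(reads, region, catalog = region_catalog(),
                            min_count = 5L) {
  rg <- resolve_region(region, catalog)
  a <- rg$start - 1L
  b <- rg$end + 1L
  motifs <- character(0)
  if (nrow(reads)) {
    # candidate reads must at least span [a, b]
    span <- cigar_ref_span(reads$cigar)
    cand <- which(reads$start <= a & reads$start + span - 1L >= b)
    if (length(cand)) {
      grp <- paste(reads$start[cand], reads$cigar[cand])
      motifs <- unlist(lapply(split(cand, grp), function(ii) {
        # identical alignment geometry: extract once, substring for all
        first <- ii[1L]
        m1 <- extract_between(reads$seq[first], reads$start[first],
                              reads$cigar[first], a, b)
        if (is.na(m1)) return(character(0))
        if (length(ii) == 1L) return(m1)
        vapply(ii, function(i) {
          extract_between(reads$seq[i], reads$start[i], reads$cigar[i], a, b)
        }, "")
      }), use.names = FALSE)
    }
  }
  tab <- sort(table(motifs), decreasing = TRUE)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  listed <- counts[counts >= min_count]
  # deterministic ordering: count desc, then length, then lexicographic
  if (length(listed)) {
    o <- order(-listed, nchar(names(listed)), names(listed))
    listed <- listed[o]
  }
  structure(list(region = rg$name, interval = c(rg$start, rg$end),
                 motifs = listed, total_spanning = length(motifs)),
            class = "motif_table")
}

#' @export
print.motif_table <- function(x, ...) {
  cat("<motif_table> region ", x$region, ", ", x$total_spanning,
      " spanning reads\n", sep = "")
  for (i in seq_along(x$motifs)) {
    cat(sprintf("  %-24s %d\n", names(x$motifs)[i], x$motifs[i]))
  }
  invisible(x)
}

# align a motif to the reference segment. Returns list(map = reference
# segment offset (1-based) for each motif character or NA if inserted,
# deleted = segment offsets absent from the motif). Clean prefix/suffix
# cases are handled directly; anything else falls back to a global pairwise
# alignment.
align_motif <- function(motif, segment) {
  nm <- nchar(motif); ns <- nchar(segment)
  mc <- strsplit(motif, "")[[1L]]
  sc <- strsplit(segment, "")[[1L]]
  lcp <- 0L
  while (lcp < min(nm, ns) && mc[lcp + 1L] == sc[lcp + 1L]) lcp <- lcp + 1L
  lcs <- 0L
  while (lcs < min(nm, ns) - lcp && mc[nm - lcs] == sc[ns - lcs]) lcs <- lcs + 1L
  mid_m <- nm - lcp - lcs
  mid_s <- ns - lcp - lcs
  map <- rep(NA_integer_, nm)
  if (lcp) map[seq_len(lcp)] <- seq_len(lcp)
  if (lcs) map[(nm - lcs + 1L):nm] <- (ns - lcs + 1L):ns
  if (mid_m == mid_s) {
    # same-length middle: positional substitutions
    if (mid_m) map[(lcp + 1L):(lcp + mid_m)] <- (lcp + 1L):(lcp + mid_s)
    return(list(map = map, deleted = integer(0)))
  }
  if (mid_m == 0L) {
    return(list(map = map, deleted = (lcp + 1L):(lcp + mid_s)))
  }
  if (mid_s == 0L) {
    return(list(map = map, deleted = integer(0)))
  }
  # mixed indel + substitution middle: defer to a global alignment
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(motif), Biostrings::DNAString(segment),
    type = "global", gapOpening = 4, gapExtension = 1
  )
  pg <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sg <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  map <- integer(0)
  deleted <- integer(0)
  qi <- 0L; si <- 0L
  for (k in seq_along(pg)) {
    if (pg[k] != "-" && sg[k] != "-") {
      qi <- qi + 1L; si <- si + 1L
      map[qi] <- si
    } else if (pg[k] != "-") {
      qi <- qi + 1L
      map[qi] <- NA_integer_
    } else {
      si <- si + 1L
      deleted <- c(deleted, si)
    }
  }
  list(map = map, deleted = deleted)
}

# variants implied by a motif relative to the reference segment starting at
# `start`, 3'-justified against the full reference
motif_variants <- function(motif, start, end, reference) {
  segment <- substr(reference$sequence, start, end)
  if (identical(motif, segment)) return(empty_variants())
  al <- align_motif(motif, segment)
  mc <- strsplit(motif, "")[[1L]]
  sc <- strsplit(segment, "")[[1L]]
  v <- empty_variants()
  aligned <- which(!is.na(al$map))
  for (i in aligned) {
    so <- al$map[i]
    if (mc[i] != sc[so] && mc[i] %in% BASES) {
      v <- rbind(v, new_variant(start + so - 1L, "substitution",
                                ref = sc[so], call = mc[i],
                                major_freq = NA_real_, major_base = mc[i]))
    }
  }
  for (so in al$deleted) {
    v <- rbind(v, new_variant(start + so - 1L, "deletion", ref = sc[so]))
  }
  ins_runs <- which(is.na(al$map))
  if (length(ins_runs)) {
    run <- cumsum(c(1L, diff(ins_runs) != 1L))
    for (rr in split(ins_runs, run)) {
      prev_aligned <- aligned[aligned < rr[1L]]
      anchor_off <- if (length(prev_aligned)) al$map[max(prev_aligned)] else 0L
      anchor <- start + anchor_off - 1L
      for (k in seq_along(rr)) {
        v <- rbind(v, new_variant(anchor, "insertion", call = mc[rr[k]],
                                  insert_index = k))
      }
    }
  }
  if (!nrow(v)) return(v)
  tmp <- mito_profile("motif", v)
  normalize_indels(tmp, reference)$variants
}

#' Determine the major length molecule for a region
#'
#' Selects the motif with the most spanning reads; ties are broken in favor
#' of the motif whose length is closest to the reference segment, then
#' lexicographically. The variants implied by the major motif (relative to
#' the reference) are derived and 3'-justified. Length heteroplasmy is
#' declared when at least two listed motifs differ in length.
#'
#' @param table A \code{motif_table}.
#' @param reference A \code{mito_reference}.
#' @return List of class \code{major_molecule_call} with \code{region},
#'   \code{major_motif}, \code{major_count}, \code{minor_motifs},
#'   \code{derived_variants} and \code{length_het}; \code{NULL} when the
#'   table lists no motifs (no-call for the region).
#' @export
major_molecule <- function(table, reference) {
  m <- table$motifs
  if (!length(m)) return(NULL)
  start <- table$interval[1L]; end <- table$interval[2L]
  ref_len <- end - start + 1L
  o <- order(-m, abs(nchar(names(m)) - ref_len), names(m))
  major <- names(m)[o[1L]]
  structure(list(
    region = table$region,
    interval = table$interval,
    major_motif = major,
    major_count = unname(m[o[1L]]),
    minor_motifs = m[names(m) != major],
    derived_variants = motif_variants(major, start, end, reference),
    length_het = length(unique(nchar(names(m)))) > 1L
  ), class = "major_molecule_call")
}

#' Detect point heteroplasmy inside a length-heteroplasmy region
#'
#' Among listed motifs of equal length, positional base disagreements whose
#' minor base is carried by at least \code{vf_threshold} of all spanning
#' reads are reported as PHPs. Motifs that differ only in length never
#' produce a PHP. Positions are mapped to reference coordinates through the
#' length group's most-read motif.
#'
#' @param table A \code{motif_table}.
#' @param reference A \code{mito_reference}.
#' @param params A \code{call_params} (for \code{vf_threshold}).
#' @return Variant data frame of PHP calls (possibly empty).
#' @export
php_in_region <- function(table, reference, params = call_params()) {
  m <- table$motifs
  out <- empty_variants()
  if (length(m) < 2L || table$total_spanning == 0L) return(out)
  start <- table$interval[1L]; end <- table$interval[2L]
  segment <- substr(reference$sequence, start, end)
  for (len in unique(nchar(names(m)))) {
    g <- m[nchar(names(m)) == len]
    if (length(g) < 2L) next
    rep_motif <- names(g)[which.max(g)]
    al <- align_motif(rep_motif, segment)
    chars <- do.call(rbind, strsplit(names(g), ""))
    for (col in seq_len(len)) {
      so <- al$map[col]
      if (is.na(so)) next
      cnt <- tapply(g, chars[, col], sum)
      cnt <- sort(cnt[names(cnt) %in% BASES], decreasing = TRUE)
      if (length(cnt) < 2L) next
      minor_frac <- cnt[2L] / table$total_spanning
      if (minor_frac < params$vf_threshold) next
      b <- names(cnt)[1:2]
      pos <- start + so - 1L
      out <- rbind(out, new_variant(
        pos, "substitution", ref = ref_base(reference, pos),
        call = iupac_code_for(b[1L], b[2L]),
        major_freq = unname(cnt[1L] / sum(cnt[1:2])),
        major_base = names(cnt)[1L]
      ))
    }
  }
  out
}

#' Rewrite a profile with major-molecule calls
#'
#' Inserts the variants implied by each region's major length molecule (and
#' any PHPs detected inside the region) into a profile whose region indels
#' were withheld by the caller. Each edit is written to the audit trail and
#' the region's length-heteroplasmy status is annotated on the profile.
#'
#' @param profile A \code{mito_profile} from \code{\link{call_profile}}.
#' @param calls List of \code{major_molecule_call} objects (NULL entries,
#'   from regions without spanning coverage, are skipped).
#' @param php Optional list of PHP variant data frames parallel to
#'   \code{calls}, as from \code{\link{php_in_region}}.
#' @return The updated profile.
#' @export
apply_length_calls <- function(profile, calls, php = NULL) {
  for (k in seq_along(calls)) {
    cl <- calls[[k]]
    if (is.null(cl)) next
    add <- cl$derived_variants
    if (!is.null(php) && !is.null(php[[k]]) && nrow(php[[k]])) {
      add <- rbind(add, php[[k]])
    }
    if (nrow(add)) {
      existing <- profile$variants
      inside <- existing$position >= cl$interval[1L] &
        existing$position <= cl$interval[2L] &
        existing$kind == "substitution"
      if (any(inside)) {
        ek <- variant_keys(existing[inside, , drop = FALSE])
        ak <- variant_keys(add)
        clash <- intersect(ek, ak)
        same <- existing[inside, , drop = FALSE]
        for (key in clash) {
          if (same$call[ek == key] != add$call[ak == key]) {
            stop("region ", cl$region, ": substitution already present at ",
                 key, " conflicts with the major-molecule call ",
                 "(region indels were not withheld upstream)")
          }
        }
        add <- add[!ak %in% ek, , drop = FALSE]
      }
      if (nrow(add)) {
        profile <- edit_variants(
          profile, add = add,
          reason = paste0("major length molecule, region ", cl$region))
      }
    }
    profile$length_het[[cl$region]] <- cl$length_het
  }
  profile
}

#' Run the length-heteroplasmy analysis over all catalogued regions
#'
#' Convenience wrapper: spanning-read motif tables, major-molecule calls and
#' in-region PHP detection for each of the nine regions.
#'
#' @param reads A trimmed, quality-masked \code{read_stack}.
#' @param reference A \code{mito_reference}.
#' @param params A \code{call_params}.
#' @param catalog A \code{region_catalog}.
#' @return List with \code{tables}, \code{calls} and \code{php}, each named
#'   by region.
#' @export
length_het_calls <- function(reads, reference, params = call_params(),
                             catalog = region_catalog()) {
  regions <- names(catalog$length_het_regions)
  tables <- lapply(regions, function(r) {
    spanning_motifs(reads, r, catalog)
  })
  names(tables) <- regions
  calls <- lapply(tables, major_molecule, reference = reference)
  php <- lapply(tables, php_in_region, reference = reference, params = params)
  list(tables = tables, calls = calls, php = php)
}
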