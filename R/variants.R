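# Forensic variant notation and haplotype profiles.
#
# A variant set is represented as a data frame with one row per named
# difference from the reference:
#   position     1-based reference coordinate (anchor base for insertions)
#   kind         "substitution", "insertion" or "deletion"
#   ref          reference base ("" for insertions)
#   call         called base, two-base IUPAC code for point heteroplasmy
#                (PHP), or "" for deletions
#   insert_index the ".k" of an insertion (NA otherwise)
#   major_freq   frequency of the major base at a PHP site (NA if unknown)
#   major_base   the major base at a PHP site (NA if unknown)
#   is_php       TRUE iff call is a two-base ambiguity code

empty_variants <- function() {
  data.frame(
    position = integer(), kind = character(), ref = character(),
    call = character(), insert_index = integer(),
    major_freq = numeric(), major_base = character(), is_php = logical(),
    stringsAsFactors = FALSE
  )
}

iupac_code_for <- function(b1, b2) {
  pair <- paste(sort(c(b1, b2)), collapse = "")
  code <- names(IUPAC_PAIRS)[match(pair, IUPAC_PAIRS)]
  if (is.na(code)) stop("no two-base IUPAC code for pair ", pair)
  code
}

iupac_bases <- function(code) strsplit(IUPAC_PAIRS[[code]], "")[[1L]]

#' Construct a single variant record
#'
#' @param position 1-based reference position.
#' @param kind One of "substitution", "insertion", "deletion".
#' @param ref Reference base (ignored for insertions).
#' @param call Called base or two-base IUPAC code; empty for deletions.
#' @param insert_index Insertion index (the .k of 315.1C); NA otherwise.
#' @param major_freq Major-base frequency at a PHP site.
#' @param major_base Major base at a PHP site.
#' @return One-row variant data frame.
#' @export
new_variant <- function(position, kind, ref = "", call = "",
                        insert_index = NA_integer_, major_freq = NA_real_,
                        major_base = NA_character_) {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  position <- as.integer(position)
  call <- toupper(call)
  is_php <- call %in% names(IUPAC_PAIRS)
  if (kind == "insertion") {
    if (is.na(insert_index) || insert_index < 1L) {
      stop("insertions require a positive insert_index")
    }
    if (!call %in% BASES) stop("insertion call must be a single base")
    ref <- ""
  } else {
    insert_index <- NA_integer_
  }
  if (kind == "deletion" && nzchar(call)) stop("deletions carry an empty call")
  if (kind == "substitution" && !(call %in% BASES || is_php)) {
    stop("substitution call must be a base or two-base IUPAC code: ", call)
  }
  data.frame(
    position = position, kind = kind, ref = toupper(ref), call = call,
    insert_index = as.integer(insert_index), major_freq = major_freq,
    major_base = major_base, is_php = is_php, stringsAsFactors = FALSE
  )
}

#' Parse a forensic variant string
#'
#' Accepted forms: \code{A263G} (substitution; the call may be a two-base
#' IUPAC ambiguity code, e.g. \code{C16192Y} for a point heteroplasmy),
#' \code{315.1C} (insertion), and \code{249DEL} or \code{249-} (deletion).
#'
#' @param text Variant string.
#' @param reference Optional \code{mito_reference}; when supplied the stated
#'   reference base is checked against it.
#' @return One-row variant data frame (see \code{\link{new_variant}}).
#' @export
parse_variant <- function(text, reference = NULL) {
  t <- toupper(trimws(text))
  L <- if (is.null(reference)) RCRS_LENGTH else reference$length
  check_pos <- function(p) {
    if (is.na(p) || p < 1L || p > L) {
      stop("variant position out of 1-", L, " in token '", text, "'")
    }
    p
  }
  if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", t)) {
    pos <- check_pos(as.integer(sub("^([0-9]+)\\..*$", "\\1", t)))
    idx <- as.integer(sub("^[0-9]+\\.([0-9]+)[ACGT]$", "\\1", t))
    if (idx < 1L) stop("insertion index must be >= 1 in token '", text, "'")
    base <- substr(t, nchar(t), nchar(t))
    return(new_variant(pos, "insertion", call = base, insert_index = idx))
  }
  if (grepl("^[0-9]+(DEL|-)$", t)) {
    pos <- check_pos(as.integer(sub("^([0-9]+).*$", "\\1", t)))
    rb <- if (is.null(reference)) "" else ref_base(reference, pos)
    return(new_variant(pos, "deletion", ref = rb))
  }
  if (grepl("^[ACGT][0-9]+[A-Z]$", t)) {
    rb <- substr(t, 1L, 1L)
    pos <- check_pos(as.integer(substr(t, 2L, nchar(t) - 1L)))
    alt <- substr(t, nchar(t), nchar(t))
    if (!(alt %in% BASES || alt %in% names(IUPAC_PAIRS))) {
      stop("call '", alt, "' in token '", text,
           "' is neither a base nor a two-base IUPAC code")
    }
    if (!is.null(reference)) {
      actual <- ref_base(reference, pos)
      if (actual != rb) {
        stop("token '", text, "' states reference base ", rb,
             " but the reference has ", actual, " at ", pos)
      }
    }
    return(new_variant(pos, "substitution", ref = rb, call = alt))
  }
  stop("malformed variant token '", text, "'")
}

#' Format variants as forensic strings
#'
#' Inverse of \code{\link{parse_variant}} for canonical strings.
#'
#' @param variants Variant data frame.
#' @param deletion_style \code{"DEL"} (emit \code{249DEL}) or \code{"dash"}
#'   (emit \code{249-}).
#' @return Character vector, one string per row.
#' @export
format_variant <- function(variants, deletion_style = c("DEL", "dash")) {
  deletion_style <- match.arg(deletion_style)
  if (!nrow(variants)) return(character())
  out <- character(nrow(variants))
  sub <- variants$kind == "substitution"
  out[sub] <- paste0(variants$ref[sub], variants$position[sub],
                     variants$call[sub])
  ins <- variants$kind == "insertion"
  out[ins] <- paste0(variants$position[ins], ".", variants$insert_index[ins],
                     variants$call[ins])
  del <- variants$kind == "deletion"
  out[del] <- paste0(variants$position[del],
                     if (deletion_style == "DEL") "DEL" else "-")
  out
}

order_variants <- function(v) {
  v[order(v$position, ifelse(is.na(v$insert_index), 0L, v$insert_index),
          v$kind), , drop = FALSE]
}

variant_keys <- function(v) {
  paste(v$position, v$kind, ifelse(is.na(v$insert_index), 0L, v$insert_index),
        sep = ":")
}

#' Construct a haplotype profile
#'
#' A profile is a sample's haplotype expressed as named differences from the
#' reference plus the interpretation range over which calls were made.
#'
#' @param sample_id Sample identifier.
#' @param variants Variant data frame (rows as from
#'   \code{\link{parse_variant}}); rbind rows to combine.
#' @param range Interpretation range: a 2-column matrix of inclusive 1-based
#'   intervals, or a length-2 vector. Defaults to the whole mitogenome.
#' @param haplogroup Optional haplogroup label (user-supplied; the package
#'   never infers haplogroups).
#' @param population,source Optional metadata labels.
#' @return Object of class \code{mito_profile}.
#' @export
mito_profile <- function(sample_id, variants = empty_variants(),
                         range = c(1L, RCRS_LENGTH), haplogroup = NA_character_,
                         population = NA_character_, source = NA_character_) {
  if (is.null(dim(range))) range <- matrix(as.integer(range), ncol = 2L)
  storage.mode(range) <- "integer"
  colnames(range) <- c("start", "end")
  variants <- order_variants(variants)
  k <- variant_keys(variants)
  if (anyDuplicated(k)) {
    stop("duplicate variant at ", paste(k[duplicated(k)], collapse = ", "))
  }
  if (nrow(variants) && !all(in_intervals(variants$position, range))) {
    bad <- variants$position[!in_intervals(variants$position, range)]
    stop("variant position(s) outside interpretation range: ",
         paste(bad, collapse = ", "))
  }
  structure(list(
    sample_id = sample_id, variants = variants, range = range,
    haplogroup = haplogroup, population = population, source = source,
    length_het = list(), flags = list(mixture_suspect = FALSE,
                                      suspect_positions = integer()),
    audit = list()
  ), class = "mito_profile")
}

#' Build a profile from forensic variant strings
#'
#' @param sample_id Sample identifier.
#' @param strings Character vector of variant tokens (e.g.
#'   \code{c("A263G", "315.1C")}).
#' @param reference Optional reference for validation.
#' @param ... Passed to \code{\link{mito_profile}}.
#' @return A \code{mito_profile}.
#' @export
profile_from_strings <- function(sample_id, strings, reference = NULL, ...) {
  v <- if (length(strings)) {
    do.call(rbind, lapply(strings, parse_variant, reference = reference))
  } else {
    empty_variants()
  }
  mito_profile(sample_id, v, ...)
}

#' @export
print.mito_profile <- function(x, ...) {
  cat("<mito_profile> ", x$sample_id, "\n", sep = "")
  cat("  range: ", paste(apply(x$range, 1L, paste, collapse = "-"),
                         collapse = "; "), "\n", sep = "")
  cat("  variants (", nrow(x$variants), "): ",
      paste(format_variant(x$variants), collapse = " "), "\n", sep = "")
  if (!is.na(x$haplogroup)) cat("  haplogroup:", x$haplogroup, "\n")
  if (isTRUE(x$flags$mixture_suspect)) cat("  ** mixture suspect **\n")
  invisible(x)
}

add_audit <- function(profile, action, before = NA_character_,
                      after = NA_character_, reason = "") {
  profile$audit[[length(profile$audit) + 1L]] <- list(
    action = action, before = before, after = after, reason = reason,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  profile
}

#' Replay an audit trail against a starting profile
#'
#' Every profile edit made by the package is recorded as an audit entry
#' holding the variant string before and after the edit. Reapplying the
#' trail to the pre-edit profile must reproduce the final variant set; this
#' function performs that replay.
#'
#' @param profile The starting (pre-edit) \code{mito_profile}.
#' @param audit An audit list, as found in \code{profile$audit} of the edited
#'   profile.
#' @return The profile with all recorded edits applied.
#' @export
replay_audit <- function(profile, audit) {
  v <- profile$variants
  for (e in audit) {
    if (!e$action %in% c("add_variant", "remove_variant", "replace_variant")) next
    if (!is.na(e$before)) {
      for (tok in strsplit(e$before, "[[:space:]]+")[[1L]]) {
        old <- parse_variant(tok)
        k <- variant_keys(v) == variant_keys(old) & v$call == old$call
        v <- v[!k, , drop = FALSE]
      }
    }
    if (!is.na(e$after)) {
      for (tok in strsplit(e$after, "[[:space:]]+")[[1L]]) {
        v <- rbind(v, parse_variant(tok))
      }
    }
  }
  profile$variants <- order_variants(v)
  profile
}

# record an edit of the variant table plus its audit entry
edit_variants <- function(profile, remove = NULL, add = NULL, reason = "") {
  v <- profile$variants
  if (!is.null(remove) && nrow(remove)) {
    for (i in seq_len(nrow(remove))) {
      k <- variant_keys(v) == variant_keys(remove[i, , drop = FALSE])
      v <- v[!k, , drop = FALSE]
      profile <- add_audit(profile, "remove_variant",
                           before = format_variant(remove[i, , drop = FALSE]),
                           reason = reason)
    }
  }
  if (!is.null(add) && nrow(add)) {
    for (i in seq_len(nrow(add))) {
      profile <- add_audit(profile, "add_variant",
                           after = format_variant(add[i, , drop = FALSE]),
                           reason = reason)
    }
    v <- rbind(v, add)
  }
  profile$variants <- order_variants(v)
  profile
}

#' Re-express indels at their 3'-most equivalent placement
#'
#' Forensic nomenclature places insertions and deletions inside homopolymeric
#' or repeated stretches at the 3'-most position (relative to the light
#' strand) at which the alternative sequence is unchanged. Substitutions are
#' untouched. Every relocation is recorded in the profile's audit trail.
#'
#' @param profile A \code{mito_profile}.
#' @param reference A \code{mito_reference}.
#' @return The profile with indels 3'-justified.
#' @export
normalize_indels <- function(profile, reference) {
  v <- profile$variants
  if (!nrow(v) || !any(v$kind != "substitution")) return(profile)
  seqc <- reference$sequence
  base_at <- function(p) substr(seqc, p, p)
  out <- v[v$kind == "substitution", , drop = FALSE]
  moved_from <- list()
  moved_to <- list()

  dels <- v[v$kind == "deletion", , drop = FALSE]
  if (nrow(dels)) {
    dels <- dels[order(dels$position), , drop = FALSE]
    run <- cumsum(c(1L, diff(dels$position) != 1L))
    for (idx in split(seq_len(nrow(dels)), run)) {
      p0 <- dels$position[idx[1L]]
      k <- length(idx)
      p <- p0
      while (p + k <= reference$length && base_at(p) == base_at(p + k)) {
        p <- p + 1L
      }
      newd <- do.call(rbind, lapply(seq_len(k) - 1L, function(o) {
        new_variant(p + o, "deletion", ref = base_at(p + o))
      }))
      if (p != p0) {
        if (!all(in_intervals(newd$position, profile$range))) {
          stop("3'-justified deletion leaves the interpretation range")
        }
        moved_from <- c(moved_from, list(dels[idx, , drop = FALSE]))
        moved_to <- c(moved_to, list(newd))
      }
      out <- rbind(out, newd)
    }
  }

  ins <- v[v$kind == "insertion", , drop = FALSE]
  if (nrow(ins)) {
    for (p0 in unique(ins$position)) {
      g <- ins[ins$position == p0, , drop = FALSE]
      g <- g[order(g$insert_index), , drop = FALSE]
      b <- g$call
      p <- as.integer(p0)
      while (p + 1L <= reference$length && b[1L] == base_at(p + 1L)) {
        b <- c(b[-1L], b[1L])
        p <- p + 1L
      }
      newi <- do.call(rbind, lapply(seq_along(b), function(i) {
        new_variant(p, "insertion", call = b[i], insert_index = i)
      }))
      if (p != p0) {
        if (!all(in_intervals(newi$position, profile$range))) {
          stop("3'-justified insertion leaves the interpretation range")
        }
        moved_from <- c(moved_from, list(g))
        moved_to <- c(moved_to, list(newi))
      }
      out <- rbind(out, newi)
    }
  }

  for (i in seq_along(moved_from)) {
    profile <- add_audit(
      profile, "replace_variant",
      before = paste(format_variant(moved_from[[i]]), collapse = " "),
      after = paste(format_variant(moved_to[[i]]), collapse = " "),
      reason = "3'-most indel placement"
    )
  }
  profile$variants <- order_variants(out)
  profile
}

#' Realize a profile as a base string
#'
#' Applies the profile's differences to the reference over an interval:
#' substitutions replace the reference base, insertions are spliced in after
#' their anchor, deletions are removed. Point heteroplasmies are rendered as
#' the major base (\code{php_resolution = "major"}) or kept as their IUPAC
#' ambiguity code (\code{"ambiguity"}).
#'
#' @param profile A \code{mito_profile}.
#' @param reference A \code{mito_reference}.
#' @param interval Length-2 vector (start, end), inside the profile range;
#'   defaults to the whole genome.
#' @param php_resolution \code{"ambiguity"} or \code{"major"}.
#' @return Base string.
#' @export
profile_to_sequence <- function(profile, reference,
                                interval = c(1L, reference$length),
                                php_resolution = c("ambiguity", "major")) {
  php_resolution <- match.arg(php_resolution)
  start <- as.integer(interval[1L]); end <- as.integer(interval[2L])
  stopifnot(start >= 1L, end <= reference$length, start <= end)
  n <- end - start + 1L
  bases <- strsplit(substr(reference$sequence, start, end), "")[[1L]]
  ins_after <- character(n)
  v <- profile$variants
  v <- v[v$position >= start & v$position <= end, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    off <- v$position[i] - start + 1L
    if (v$kind[i] == "substitution") {
      if (v$is_php[i]) {
        if (php_resolution == "ambiguity") {
          bases[off] <- v$call[i]
        } else {
          if (is.na(v$major_base[i])) {
            stop("PHP at ", v$position[i],
                 " has no recorded major base; cannot resolve to major")
          }
          bases[off] <- v$major_base[i]
        }
      } else {
        bases[off] <- v$call[i]
      }
    } else if (v$kind[i] == "deletion") {
      bases[off] <- ""
    } else {
      ins_after[off] <- paste0(ins_after[off], v$call[i])
    }
  }
  paste0(paste0(bases, ins_after), collapse = "")
}
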