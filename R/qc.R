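# Replicate-based PHP confirmation, mixture flagging, shared-haplotype
# detection, dual-analyst comparison and Sanger concordance checks.

php_rows <- function(profile) {
  profile$variants[profile$variants$is_php, , drop = FALSE]
}

minor_frequency <- function(v) {
  ifelse(is.na(v$major_freq), NA_real_, 1 - v$major_freq)
}

#' Confirm low-level point heteroplasmies against a replicate
#'
#' Every PHP whose minor base frequency is below \code{threshold} must be
#' observed (same position, same base pair) in an independently amplified
#' replicate. Unconfirmed PHPs revert to the major base; PHPs at positions
#' the replicate does not cover are removed as unresolvable rather than
#' silently confirmed. PHPs with minor frequency at or above the threshold
#' pass without replication. All edits are audited.
#'
#' @param primary The reported \code{mito_profile} (calls carry
#'   \code{major_freq}/\code{major_base}).
#' @param replicate The replicate profile.
#' @param threshold Minor-frequency cutoff below which replication is
#'   required.
#' @return List with \code{profile} (edited primary), \code{confirmed},
#'   \code{removed} and \code{unresolvable} variant data frames.
#' @export
confirm_php <- function(primary, replicate, threshold = 0.10) {
  php <- php_rows(primary)
  confirmed <- empty_variants()
  removed <- empty_variants()
  unresolvable <- empty_variants()
  for (i in seq_len(nrow(php))) {
    v <- php[i, , drop = FALSE]
    minor <- minor_frequency(v)
    if (is.na(minor)) {
      stop("PHP at ", v$position, " has no recorded major frequency")
    }
    if (minor >= threshold) {
      confirmed <- rbind(confirmed, v)
      next
    }
    if (!any(in_intervals(v$position, replicate$range))) {
      unresolvable <- rbind(unresolvable, v)
      primary <- revert_php(primary, v,
                            reason = "PHP unresolvable: no replicate coverage")
      next
    }
    rv <- replicate$variants
    hit <- rv$is_php & rv$position == v$position & rv$call == v$call
    if (any(hit)) {
      confirmed <- rbind(confirmed, v)
    } else {
      removed <- rbind(removed, v)
      primary <- revert_php(primary, v,
                            reason = "PHP not reproduced in replicate amplification")
    }
  }
  list(profile = primary, confirmed = confirmed, removed = removed,
       unresolvable = unresolvable)
}

# replace a PHP call by its major base (drop the variant when the major base
# is the reference)
revert_php <- function(profile, v, reason) {
  if (is.na(v$major_base)) {
    return(edit_variants(profile, remove = v, reason = reason))
  }
  if (v$major_base == v$ref) {
    edit_variants(profile, remove = v, reason = reason)
  } else {
    fixed <- new_variant(v$position, "substitution", ref = v$ref,
                         call = v$major_base, major_freq = v$major_freq,
                         major_base = v$major_base)
    profile <- add_audit(profile, "replace_variant",
                         before = format_variant(v),
                         after = format_variant(fixed), reason = reason)
    vv <- profile$variants
    k <- variant_keys(vv) == variant_keys(v)
    vv <- vv[!k, , drop = FALSE]
    profile$variants <- order_variants(rbind(vv, fixed))
    profile
  }
}

#' Flag a profile as a possible two-donor mixture
#'
#' A mixture is indicated by reduced major-base frequency together with
#' multiple PHPs, by a PHP sitting on a haplogroup-diagnostic site, or by
#' any pileup column that retained more than two alleles.
#'
#' @param profile A \code{mito_profile} (its \code{mixture_suspect} flag from
#'   calling is consulted).
#' @param metrics The \code{call_metrics} computed on the same range.
#' @param diagnostic_sites Optional integer vector of haplogroup-diagnostic
#'   positions.
#' @param php_count_min Minimum PHP count for the frequency trigger.
#' @param major_freq_max Major-base frequency (excluding heteroplasmy) below
#'   which overall variant frequency counts as reduced.
#' @return List with \code{flag} (logical) and \code{reasons} (character).
#' @export
flag_mixture <- function(profile, metrics, diagnostic_sites = NULL,
                         php_count_min = 3L, major_freq_max = 0.98) {
  reasons <- character(0)
  php <- php_rows(profile)
  avg <- metrics$average_major_base_frequency_excl_het
  if (!is.na(avg) && avg < major_freq_max && nrow(php) >= php_count_min) {
    reasons <- c(reasons, sprintf(
      "reduced overall major base frequency (%.4f) with %d PHPs",
      avg, nrow(php)))
  }
  if (!is.null(diagnostic_sites) && nrow(php)) {
    on_diag <- php$position[php$position %in% diagnostic_sites]
    if (length(on_diag)) {
      reasons <- c(reasons, paste0("diagnostic-site PHP at ",
                                   paste(on_diag, collapse = ", ")))
    }
  }
  if (length(profile$flags$suspect_positions)) {
    reasons <- c(reasons, paste0(
      ">2 alleles above threshold at ",
      paste(profile$flags$suspect_positions, collapse = ", ")))
  }
  list(flag = length(reasons) > 0L, reasons = reasons)
}

#' Group samples sharing a mitogenome haplotype
#'
#' Haplotypes are keyed with PHPs excluded and insertions at the common
#' length-heteroplasmy positions ignored, mirroring how candidates for
#' kinship (STR) testing are selected. An exclusion list supports dropping
#' samples already identified as duplicates or relatives.
#'
#' @param profiles List of \code{mito_profile} objects.
#' @param options A \code{comparison_options}; defaults to whole-mitogenome
#'   range with PHPs ignored.
#' @param exclude Character vector of sample ids to drop before grouping.
#' @return List of character vectors (sample-id groups of size >= 2).
#' @export
find_shared_haplotypes <- function(profiles,
                                   options = comparison_options(
                                     php_mode = "ignored"),
                                   exclude = character(0)) {
  profiles <- profiles[!vapply(profiles, `[[`, "", "sample_id") %in% exclude]
  keys <- vapply(profiles, haplotype_key, "", options = options)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  groups <- split(ids, keys)
  unname(groups[lengths(groups) >= 2L])
}

#' Compare two analysts' profiles for the same sample
#'
#' Returns the symmetric difference of the two variant sets with
#' position-wise detail; an empty result means the analyses are concordant.
#'
#' @param a,b \code{mito_profile} objects with identical sample ids.
#' @return Data frame with columns \code{position}, \code{kind},
#'   \code{insert_index}, \code{call_a}, \code{call_b} (NA where a side
#'   lacks the variant).
#' @export
compare_analyst_profiles <- function(a, b) {
  if (!identical(a$sample_id, b$sample_id)) {
    stop("profiles are for different samples: ", a$sample_id, " vs ",
         b$sample_id)
  }
  profile_diff(a, b)
}

profile_diff <- function(a, b) {
  va <- a$variants; vb <- b$variants
  ka <- variant_keys(va); kb <- variant_keys(vb)
  keys <- union(ka, kb)
  out <- data.frame(position = integer(), kind = character(),
                    insert_index = integer(), call_a = character(),
                    call_b = character(), stringsAsFactors = FALSE)
  for (k in keys) {
    ia <- match(k, ka); ib <- match(k, kb)
    ca <- if (is.na(ia)) NA_character_ else va$call[ia]
    cb <- if (is.na(ib)) NA_character_ else vb$call[ib]
    if (!is.na(ia) && !is.na(ib) && identical(ca, cb)) next
    src <- if (is.na(ia)) vb[ib, ] else va[ia, ]
    out <- rbind(out, data.frame(
      position = src$position, kind = src$kind,
      insert_index = src$insert_index, call_a = ca, call_b = cb,
      stringsAsFactors = FALSE))
  }
  out[order(out$position), , drop = FALSE]
}

#' Check NGS haplotypes against Sanger control-region data
#'
#' Restricts both profiles to the control region and reports discordances.
#' With \code{ignore_low_level_php}, differences in which one side's PHP
#' contains the other side's fixed (or reference) base are suppressed —
#' low-level heteroplasmy below the Sanger detection limit is expected to be
#' missed by the chemistry, not a processing error.
#'
#' @param ngs,sanger \code{mito_profile} objects for the same sample.
#' @param catalog A \code{region_catalog}.
#' @param ignore_low_level_php Suppress PHP-vs-major-base differences.
#' @return Data frame of discordances in the format of
#'   \code{\link{compare_analyst_profiles}}.
#' @export
sanger_concordance <- function(ngs, sanger, catalog = region_catalog(),
                               ignore_low_level_php = TRUE) {
  restrict <- function(p) {
    keep <- in_intervals(p$variants$position, catalog$control_region)
    p$variants <- p$variants[keep, , drop = FALSE]
    p
  }
  a <- restrict(ngs); b <- restrict(sanger)
  d <- profile_diff(a, b)
  if (!nrow(d) || !ignore_low_level_php) return(d)
  refb <- vapply(seq_len(nrow(d)), function(i) {
    for (p in list(a, b)) {
      v <- p$variants[p$variants$position == d$position[i] &
                        p$variants$kind == d$kind[i], , drop = FALSE]
      if (nrow(v)) return(v$ref[1L])
    }
    NA_character_
  }, "")
  suppress <- vapply(seq_len(nrow(d)), function(i) {
    ca <- d$call_a[i]; cb <- d$call_b[i]
    one_php_covers <- function(php, other) {
      if (is.na(php) || !php %in% names(IUPAC_PAIRS)) return(FALSE)
      other_base <- if (is.na(other)) refb[i] else other
      !is.na(other_base) && other_base %in% iupac_bases(php)
    }
    one_php_covers(ca, cb) || one_php_covers(cb, ca)
  }, TRUE)
  d[!suppress, , drop = FALSE]
}
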