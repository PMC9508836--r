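## Deterministic rule-based de novo caller and hard-filter QC, built on
## per-member depth / alt-read / VAF evidence at a site. Boundary
## semantics are implemented exactly as quoted thresholds (>=, <=, <, >).

#' Variant allele fraction
#'
#' @param alt_reads alt-supporting read count.
#' @param depth total read depth (`0 <= alt_reads <= depth`).
#' @return `alt_reads / depth`, and 0 when depth is 0 (vectorized).
#' @export
compute_vaf <- function(alt_reads, depth) {
  if (any(alt_reads < 0) || any(depth < 0) || any(alt_reads > depth)) {
    stop2("need 0 <= alt_reads <= depth")
  }
  ifelse(depth == 0, 0, alt_reads / depth)
}

#' Per-member read evidence at a site
#'
#' @param depth,alt_reads read counts per member.
#' @param population_af optional population (e.g. gnomAD) allele
#'   frequency of the variant; `NA`/missing is treated as 0 (novel).
#' @param caller_quality optional upstream caller quality score.
#' @return a `trio_evidence` object with per-role depth, alt_reads, vaf.
#' @export
trio_evidence <- function(depth, alt_reads, population_af = NA_real_,
                          caller_quality = NA_real_) {
  stopifnot(all(TRIO_ROLES %in% names(depth)),
            all(TRIO_ROLES %in% names(alt_reads)))
  depth <- depth[TRIO_ROLES]; alt_reads <- alt_reads[TRIO_ROLES]
  structure(list(depth = depth, alt_reads = alt_reads,
                 vaf = compute_vaf(alt_reads, depth),
                 population_af = population_af,
                 caller_quality = caller_quality),
            class = "trio_evidence")
}

## CIGAR-consistent alt support of one read slice at the variant.
read_supports_alt <- function(slice, variant_position, ref, alt, type) {
  cols <- slice$columns
  at <- function(p) which(!is.na(cols$ref_pos) & cols$ref_pos == p)
  a0 <- at(variant_position)
  if (!length(a0)) return(NA)   # not spanning
  a0 <- a0[1]
  if (type == "substitution") {
    k <- nchar(alt)
    want <- strsplit(alt, "")[[1]]
    got <- vapply(seq_len(k) - 1L, function(d) {
      i <- at(variant_position + d)
      if (length(i)) cols$base[i[1]] else NA_character_
    }, character(1))
    return(all(!is.na(got) & got == want))
  }
  if (type == "insertion") {
    ins <- substr(alt, 2L, nchar(alt))
    idx <- a0 + seq_len(nchar(ins))
    if (max(idx) > length(cols$base)) return(FALSE)
    return(all(is.na(cols$ref_pos[idx])) &&
             paste(cols$base[idx], collapse = "") == ins)
  }
  ## deletion: the deleted reference positions must be gap columns
  dpos <- variant_position + seq_len(nchar(ref) - nchar(alt))
  del <- vapply(dpos, function(p) {
    i <- at(p)
    length(i) > 0L && cols$base[i[1]] == GAP
  }, logical(1))
  all(del)
}

#' Summarize a trio window into filter evidence
#'
#' Depth counts spanning reads with mapping quality > 0; alt reads are the
#' spanning reads whose aligned bases support the alt allele
#' (CIGAR-consistent for indels), mirroring pileup conventions.
#'
#' @param window a `trio_window`.
#' @param population_af,caller_quality optional annotations.
#' @return a [trio_evidence()] object.
#' @export
genotype_evidence <- function(window, population_af = NA_real_,
                              caller_quality = NA_real_) {
  stopifnot(inherits(window, "trio_window"))
  type <- window$variant_type
  depth <- alt <- stats::setNames(integer(3), TRIO_ROLES)
  for (role in TRIO_ROLES) {
    for (s in window$reads[[role]]) {
      if (s$mapping_quality <= 0L) next
      sup <- read_supports_alt(s, window$variant_position,
                               window$ref, window$alt, type)
      if (is.na(sup)) next    # read does not span the site
      depth[role] <- depth[role] + 1L
      if (sup) alt[role] <- alt[role] + 1L
    }
  }
  trio_evidence(depth, alt, population_af, caller_quality)
}

#' Rule-based de novo caller
#'
#' Passes iff both parents have coverage >= 10 and either carry no
#' alternative reads at all, or both have VAF <= 15% with fewer than 3
#' alternative reads. Failures report the first violated clause.
#'
#' @param evidence a [trio_evidence()].
#' @return list with `pass` (logical) and `reason` (`"ok"` or the violated
#'   clause).
#' @export
inhouse_denovo_filter <- function(evidence) {
  stopifnot(inherits(evidence, "trio_evidence"))
  d <- evidence$depth; a <- evidence$alt_reads; v <- evidence$vaf
  if (any(is.na(d[c("father", "mother")]))) {
    stop2("missing parental evidence")
  }
  if (d[["father"]] < 10 || d[["mother"]] < 10) {
    return(list(pass = FALSE, reason = "parental_coverage"))
  }
  if (a[["father"]] == 0 && a[["mother"]] == 0) {
    return(list(pass = TRUE, reason = "ok"))
  }
  if (v[["father"]] > 0.15 || v[["mother"]] > 0.15) {
    return(list(pass = FALSE, reason = "parental_vaf"))
  }
  if (a[["father"]] >= 3 || a[["mother"]] >= 3) {
    return(list(pass = FALSE, reason = "parental_alt_reads"))
  }
  list(pass = TRUE, reason = "ok")
}

#' Population allele-frequency pre-filter
#'
#' WES mode passes variants with population AF < 1%; WGS mode requires
#' AF < 0.1% and an upstream caller quality score > 15. A missing AF is
#' treated as 0 (novel variant).
#'
#' @param evidence a [trio_evidence()].
#' @param mode `"WES"` or `"WGS"`.
#' @return list with `pass` and `reason`.
#' @export
population_af_prefilter <- function(evidence, mode = c("WES", "WGS")) {
  mode <- match.arg(mode)
  af <- evidence$population_af
  if (is.na(af)) af <- 0
  if (mode == "WES") {
    if (af < 0.01) return(list(pass = TRUE, reason = "ok"))
    return(list(pass = FALSE, reason = "population_af"))
  }
  if (af >= 0.001) return(list(pass = FALSE, reason = "population_af"))
  q <- evidence$caller_quality
  if (is.na(q) || q <= 15) return(list(pass = FALSE, reason = "caller_quality"))
  list(pass = TRUE, reason = "ok")
}

#' High-quality DNM post-filter
#'
#' Passes iff all three members have >= 10 reads, the child VAF is
#' >= 20%, and the population allele frequency is < 0.01% (strict).
#'
#' @param evidence a [trio_evidence()].
#' @return list with `pass` and `reason`.
#' @export
high_quality_filter <- function(evidence) {
  stopifnot(inherits(evidence, "trio_evidence"))
  if (any(is.na(evidence$depth))) stop2("missing member evidence")
  if (min(evidence$depth) < 10) {
    return(list(pass = FALSE, reason = "trio_coverage"))
  }
  if (evidence$vaf[["child"]] < 0.20) {
    return(list(pass = FALSE, reason = "child_vaf"))
  }
  af <- evidence$population_af
  if (is.na(af)) af <- 0
  if (af >= 0.0001) return(list(pass = FALSE, reason = "population_af"))
  list(pass = TRUE, reason = "ok")
}

#' Training-data selection preset
#'
#' Thresholds historically used to assemble high-confidence DNM training
#' examples from cohort calls (child coverage >= 20x, child VAF > 30%,
#' plus caller-quality cutoffs upstream). Exposed for dataset curation;
#' deliberately not part of the calling path.
#'
#' @return named list of thresholds.
#' @export
training_data_preset <- function() {
  list(min_child_depth = 20L, min_child_vaf = 0.30)
}
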