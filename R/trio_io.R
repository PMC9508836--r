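## Trio alignment/variant input and windowed read extraction.
##
## Internal coordinates are 0-based half-open; positions in user-facing
## tables and VCF records are 1-based and converted on read.

#' Describe one trio sample
#'
#' @param role one of `"child"`, `"father"`, `"mother"`.
#' @param alignment_path path to an indexed BAM (or CRAM) file.
#' @param variants_path path to a VCF file (plain or bgzipped).
#' @return a `trio_sample` handle.
#' @export
trio_sample <- function(role, alignment_path, variants_path) {
  role <- match.arg(role, TRIO_ROLES)
  structure(
    list(role = role, alignment_path = alignment_path,
         variants_path = variants_path),
    class = "trio_sample"
  )
}

#' Load and validate a sequencing trio
#'
#' Checks that all six files exist, that each alignment has an index, that
#' each VCF is parseable, and that the three members use a consistent contig
#' naming dialect (`chr`-prefixed or bare). A dialect mismatch raises a
#' warning and is harmonized automatically by recording a per-member prefix
#' mapping used during extraction.
#'
#' @param child,father,mother `trio_sample` objects (or 2-element character
#'   vectors `c(bam, vcf)`).
#' @param reference optional path to the reference FASTA (required for CRAM).
#' @return a `trio` object with one validated handle per role.
#' @export
load_trio <- function(child, father, mother, reference = NULL) {
  as_sample <- function(x, role) {
    if (inherits(x, "trio_sample")) {
      if (x$role != role) stop2("sample given for role '", role,
                                "' is labelled '", x$role, "'")
      return(x)
    }
    trio_sample(role, x[[1]], x[[2]])
  }
  samples <- list(
    child = as_sample(child, "child"),
    father = as_sample(father, "father"),
    mother = as_sample(mother, "mother")
  )
  for (s in samples) {
    for (p in c(s$alignment_path, s$variants_path)) {
      if (!file.exists(p)) stop2("missing file for ", s$role, ": ", p)
    }
    idx <- paste0(s$alignment_path, c(".bai", ".crai"))
    idx2 <- sub("\\.(bam|cram)$", ".\\1.bai", s$alignment_path)
    if (!any(file.exists(c(idx, idx2)))) {
      stop2("missing alignment index for ", s$role, ": ", s$alignment_path)
    }
  }
  ## contig dialect per member, from the BAM header
  contigs <- lapply(samples, function(s) {
    hdr <- Rsamtools::scanBamHeader(s$alignment_path)[[1]]$targets
    if (is.null(hdr) || !length(hdr)) {
      stop2("alignment header of ", s$role, " declares no contigs")
    }
    names(hdr)
  })
  dialect <- vapply(contigs, function(x) any(startsWith(x, "chr")), logical(1))
  if (length(unique(dialect)) > 1L) {
    warning("contig naming dialect differs between trio members; ",
            "harmonizing automatically", call. = FALSE)
  }
  stripped <- lapply(contigs, function(x) sub("^chr", "", x))
  common <- Reduce(intersect, stripped)
  if (!length(common)) {
    stop2("trio members share no contigs after dialect harmonization")
  }
  structure(
    list(samples = samples, reference = reference,
         dialect = dialect, contigs = contigs),
    class = "trio"
  )
}

## Map a harmonized contig name to the member's own dialect.
member_contig <- function(trio, role, contig) {
  own <- trio$contigs[[role]]
  bare <- sub("^chr", "", contig)
  hit <- own[sub("^chr", "", own) == bare]
  if (!length(hit)) {
    stop2("contig '", contig, "' absent from the ", role, " alignment")
  }
  hit[[1]]
}

## Convert one aligned read into alignment columns.
## Returns parallel vectors: ref_pos (0-based; NA for inserted bases),
## base (A/C/T/G or "-"), qual (Phred; 0 for deletion gaps).
## Soft/hard clips are consumed but never rendered.
cigar_columns <- function(pos0, cigar, seq, quals) {
  ## fast path: fully aligned read (no indels/clips)
  if (grepl("^[0-9]+M$", cigar)) {
    base <- strsplit(seq, "", fixed = TRUE)[[1]]
    base[!(base %in% BASES)] <- GAP
    return(list(ref_pos = pos0 + seq_along(base) - 1L, base = base,
                qual = as.integer(quals)))
  }
  cg <- parse_cigar(cigar)
  n <- sum(cg$len[cg$op %in% c("M", "=", "X", "I", "D")])
  ref_pos <- integer(n); base <- character(n); qual <- integer(n)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  ri <- pos0   # next reference position
  qi <- 1L     # next query base (1-based)
  k <- 0L
  for (j in seq_along(cg$op)) {
    op <- cg$op[j]; len <- cg$len[j]
    if (op %in% c("M", "=", "X")) {
      idx <- k + seq_len(len)
      ref_pos[idx] <- ri + 0:(len - 1L)
      base[idx] <- bases[qi + 0:(len - 1L)]
      qual[idx] <- quals[qi + 0:(len - 1L)]
      ri <- ri + len; qi <- qi + len; k <- k + len
    } else if (op == "I") {
      idx <- k + seq_len(len)
      ref_pos[idx] <- NA_integer_
      base[idx] <- bases[qi + 0:(len - 1L)]
      qual[idx] <- quals[qi + 0:(len - 1L)]
      qi <- qi + len; k <- k + len
    } else if (op == "D" || op == "N") {
      if (op == "D") {
        idx <- k + seq_len(len)
        ref_pos[idx] <- ri + 0:(len - 1L)
        base[idx] <- GAP
        qual[idx] <- 0L
        k <- k + len
      }
      ri <- ri + len
    } else if (op == "S") {
      qi <- qi + len
    } # H, P consume nothing rendered
  }
  base[!(base %in% BASES) & base != GAP] <- GAP   # N and ambiguity codes
  list(ref_pos = ref_pos[seq_len(k)], base = base[seq_len(k)],
       qual = qual[seq_len(k)])
}

## Trim alignment columns to the window [wstart, wstart + WINDOW_LEN).
## Keeps the contiguous run between the first and last in-window aligned
## column so that interior insertions survive; NULL if no overlap.
trim_columns <- function(cols, wstart) {
  inw <- !is.na(cols$ref_pos) &
    cols$ref_pos >= wstart & cols$ref_pos < wstart + WINDOW_LEN
  if (!any(inw)) return(NULL)
  idx <- seq(which(inw)[1], max(which(inw)))
  list(ref_pos = cols$ref_pos[idx], base = cols$base[idx],
       qual = cols$qual[idx])
}

new_read_slice <- function(read_id, mapping_quality, leftmost, cols) {
  structure(
    list(read_id = read_id, mapping_quality = as.integer(mapping_quality),
         leftmost = as.integer(leftmost), columns = cols),
    class = "read_slice"
  )
}

## Assemble a trio_window from per-member lists of full read records
## (each: id, pos0, cigar, seq, qual, mapq). Shared by extraction and the
## simulator so that BAM round-trips are exact by construction.
build_trio_window <- function(reads_by_role, contig, variant_position,
                              ref, alt) {
  wstart <- variant_position - WINDOW_FLANK
  slices <- lapply(reads_by_role, function(reads) {
    out <- list()
    for (r in reads) {
      cols <- trim_columns(
        cigar_columns(r$pos0, r$cigar, r$seq, r$qual), wstart
      )
      if (is.null(cols)) next
      out[[length(out) + 1L]] <- new_read_slice(r$id, r$mapq, r$pos0, cols)
    }
    if (length(out)) {
      ord <- order(vapply(out, `[[`, integer(1), "leftmost"),
                   vapply(out, `[[`, character(1), "read_id"))
      out <- out[ord]
    }
    out
  })
  names(slices) <- TRIO_ROLES
  structure(
    list(contig = contig, variant_position = as.integer(variant_position),
         window_start = as.integer(wstart), window_length = WINDOW_LEN,
         ref = ref, alt = alt,
         variant_type = classify_variant_type(ref, alt),
         reads = slices),
    class = "trio_window"
  )
}

#' @export
print.trio_window <- function(x, ...) {
  cat(sprintf(
    "<trio_window> %s:%d %s>%s (%s)\n  reads: child %d, father %d, mother %d\n",
    x$contig, x$variant_position + 1L, x$ref, x$alt, x$variant_type,
    length(x$reads$child), length(x$reads$father), length(x$reads$mother)
  ))
  invisible(x)
}

#' Extract the trio read window around a candidate site
#'
#' Collects every primary, non-duplicate, QC-pass read overlapping the
#' 41-position window centred on the variant, for each trio member, with
#' per-base and mapping qualities preserved. Slices are ordered by
#' (leftmost position, read id) so that downstream encoding is
#' deterministic.
#'
#' @param trio a `trio` from [load_trio()].
#' @param contig contig name (either dialect).
#' @param position 1-based position of the variant's first reference base.
#' @param ref,alt normalized alleles.
#' @return a `trio_window`.
#' @export
extract_trio_window <- function(trio, contig, position, ref, alt) {
  stopifnot(inherits(trio, "trio"))
  pos0 <- as.integer(position) - 1L
  wstart <- pos0 - WINDOW_FLANK
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE
  )
  reads_by_role <- lapply(TRIO_ROLES, function(role) {
    ctg <- member_contig(trio, role, contig)
    which <- GenomicRanges::GRanges(
      ctg, IRanges::IRanges(max(1L, wstart + 1L), wstart + WINDOW_LEN)
    )
    param <- Rsamtools::ScanBamParam(
      flag = flags, which = which,
      what = c("qname", "pos", "mapq", "cigar", "seq", "qual")
    )
    res <- Rsamtools::scanBam(trio$samples[[role]]$alignment_path,
                              param = param)[[1]]
    n <- length(res$qname)
    if (!n) return(list())
    seqs <- as.character(res$seq)
    quals <- as(res$qual, "IntegerList")
    out <- vector("list", n)
    for (i in seq_len(n)) {
      if (is.na(res$cigar[i]) || nchar(seqs[i]) == 0L) next
      out[[i]] <- list(
        id = res$qname[i], pos0 = res$pos[i] - 1L, cigar = res$cigar[i],
        seq = seqs[i], qual = as.integer(quals[[i]]),
        mapq = ifelse(is.na(res$mapq[i]), 0L, res$mapq[i])
      )
    }
    out[!vapply(out, is.null, logical(1))]
  })
  names(reads_by_role) <- TRIO_ROLES
  build_trio_window(reads_by_role, contig, pos0, ref, alt)
}
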