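## Candidate DNM generation: allele-aware subtraction of parental variants
## from the child's call set, plus variant-type routing.

#' Classify a normalized variant into substitution / insertion / deletion
#'
#' Length-preserving multi-nucleotide changes count as substitutions;
#' complex length-changing events are routed by net length change so the
#' three-way routing is total.
#'
#' @param ref,alt normalized allele strings over A/C/G/T.
#' @return `"substitution"`, `"insertion"` or `"deletion"` (vectorized).
#' @export
classify_variant_type <- function(ref, alt) {
  ok <- nzchar(ref) & nzchar(alt) &
    !grepl("[^ACGT]", ref) & !grepl("[^ACGT]", alt)
  if (!all(ok)) stop2("alleles must be non-empty strings over A/C/G/T")
  if (any(ref == alt)) stop2("ref and alt alleles must differ")
  d <- nchar(alt) - nchar(ref)
  ifelse(d == 0L, "substitution", ifelse(d > 0L, "insertion", "deletion"))
}

#' Parsimony-normalize one biallelic variant
#'
#' Trims the shared allele suffix, then the shared prefix (keeping at least
#' one base on each side and advancing the position across trimmed prefix
#' bases). Full left-alignment against the reference is expected upstream
#' (e.g. `bcftools norm`); simulated fixtures are emitted pre-normalized.
#'
#' @param position 1-based position.
#' @param ref,alt allele strings.
#' @return list with `position`, `ref`, `alt`.
#' @export
normalize_variant <- function(position, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    position <- position + 1L
  }
  list(position = as.integer(position), ref = ref, alt = alt)
}

#' Read, split and normalize the records of one VCF
#'
#' Multiallelic records are split into biallelic ones; each is
#' parsimony-trimmed. Records with symbolic, missing or non-ACGT alleles
#' are skipped with a warning counter (attribute `n_skipped`).
#'
#' @param path VCF path (plain or bgzipped).
#' @return data.frame with columns contig, position, ref, alt.
#' @export
read_vcf_records <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  keep <- !is.na(alt) & nzchar(ref) & nzchar(alt) &
    !grepl("[^ACGT]", ref) & !grepl("[^ACGT]", alt) & ref != alt
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " unparseable/symbolic record(s) skipped in ",
            basename(path), call. = FALSE)
  }
  contig <- contig[keep]; pos <- pos[keep]
  ref <- ref[keep]; alt <- alt[keep]
  if (length(pos)) {
    norm <- mapply(normalize_variant, pos, ref, alt, SIMPLIFY = FALSE)
    pos <- vapply(norm, `[[`, integer(1), "position")
    ref <- vapply(norm, `[[`, character(1), "ref")
    alt <- vapply(norm, `[[`, character(1), "alt")
  }
  out <- data.frame(contig = contig, position = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

variant_key <- function(df) {
  paste(sub("^chr", "", df$contig), df$position, df$ref, df$alt, sep = ":")
}

#' Subtract inherited variants from the child's call set
#'
#' Stage one of DNM calling: keeps the child records whose
#' (contig, position, ref, alt) key — after multiallelic splitting and
#' parsimony normalization — appears in neither parent's VCF. Matching is
#' allele-aware (a parental A>T does not mask a child A>G at the same
#' position), mirroring `bcftools isec -C`.
#'
#' @param child_vcf,father_vcf,mother_vcf VCF paths, or a `trio` object as
#'   first argument.
#' @return data.frame of candidates (contig, position, ref, alt,
#'   variant_type), sorted by (contig, position).
#' @export
subtract_inherited <- function(child_vcf, father_vcf = NULL,
                               mother_vcf = NULL) {
  if (inherits(child_vcf, "trio")) {
    trio <- child_vcf
    child_vcf <- trio$samples$child$variants_path
    father_vcf <- trio$samples$father$variants_path
    mother_vcf <- trio$samples$mother$variants_path
  }
  child <- read_vcf_records(child_vcf)
  father <- read_vcf_records(father_vcf)
  mother <- read_vcf_records(mother_vcf)
  parental <- unique(c(variant_key(father), variant_key(mother)))
  keep <- !(variant_key(child) %in% parental)
  out <- child[keep, , drop = FALSE]
  out <- out[order(out$contig, out$position, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out$variant_type <- if (nrow(out)) {
    classify_variant_type(out$ref, out$alt)
  } else {
    character(0)
  }
  out
}

#' Write a candidate table as TSV
#'
#' @param candidates data.frame from [subtract_inherited()] or [dnm_call()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
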