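## Seeded trio read simulator. Generates windowed pileups with known
## inheritance status (and hence truth labels) and can write them out as
## valid FASTA / BAM / VCF fixtures so that every other module is testable
## without external data.

#' Simulation parameters for one variant site
#'
#' Defaults emulate a modern short-read trio experiment: ~30x member
#' coverage, 80 bp reads, per-base error rate 1e-3 (~Q30 instrument), base
#' qualities centred at 35 (capped at 40), mapping qualities centred at 55
#' (capped at 60). A germline de novo or inherited variant is heterozygous
#' (VAF 0.5); `child_vaf < 0.5` models mosaicism. Artifact sites scatter
#' low-quality alt bases across all three members at low VAF.
#'
#' @param depth_mean mean coverage per member (scalar, or named vector with
#'   entries child/father/mother).
#' @param read_length read length in bases.
#' @param base_error_rate per-base miscall probability.
#' @param bq_mean,bq_sd base quality distribution (truncated to `[2, 40]`).
#' @param mq_mean,mq_sd mapping quality distribution (truncated to `[0, 60]`).
#' @param child_vaf child variant allele fraction (0.5 = germline het).
#' @param inheritance one of `"denovo"`, `"inherited_father"`,
#'   `"inherited_mother"`, `"inherited_both"`, `"artifact"`.
#' @param variant list with `type` (substitution/insertion/deletion) and
#'   `len` (allele-length change; substitution `len` > 1 gives an MNV).
#' @param artifact_vaf,artifact_bq_mean VAF and base-quality centre of
#'   artifact alt evidence.
#' @return a `sim_params` list.
#' @export
sim_params <- function(depth_mean = 30, read_length = 80,
                       base_error_rate = 0.001,
                       bq_mean = 35, bq_sd = 4,
                       mq_mean = 55, mq_sd = 5,
                       child_vaf = 0.5,
                       inheritance = c("denovo", "inherited_father",
                                       "inherited_mother", "inherited_both",
                                       "artifact"),
                       variant = list(type = "substitution", len = 1L),
                       artifact_vaf = 0.08, artifact_bq_mean = 10) {
  inheritance <- match.arg(inheritance)
  if (length(depth_mean) == 1L) {
    depth_mean <- stats::setNames(rep(depth_mean, 3), TRIO_ROLES)
  }
  stopifnot(all(TRIO_ROLES %in% names(depth_mean)), all(depth_mean >= 0),
            base_error_rate >= 0, base_error_rate <= 1,
            child_vaf >= 0, child_vaf <= 1, read_length > WINDOW_LEN)
  variant$type <- match.arg(variant$type,
                            c("substitution", "insertion", "deletion"))
  variant$len <- as.integer(variant$len %||% 1L)
  structure(list(
    depth_mean = depth_mean[TRIO_ROLES], read_length = as.integer(read_length),
    base_error_rate = base_error_rate, bq_mean = bq_mean, bq_sd = bq_sd,
    mq_mean = mq_mean, mq_sd = mq_sd, child_vaf = child_vaf,
    inheritance = inheritance, variant = variant,
    artifact_vaf = artifact_vaf, artifact_bq_mean = artifact_bq_mean
  ), class = "sim_params")
}

#' Seeded random reference sequence
#'
#' @param length contig length in bases.
#' @param seed optional RNG seed.
#' @param contig contig name.
#' @return character string of A/C/G/T, with attribute `contig`.
#' @export
synth_reference <- function(length = 10000L, seed = NULL, contig = "ref1") {
  if (!is.null(seed)) set.seed(seed)
  structure(paste(sample(BASES, length, replace = TRUE), collapse = ""),
            contig = contig)
}

trunc_norm_int <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, as.integer(round(stats::rnorm(n, mean, sd)))))
}

random_other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

## Derive ref/alt allele strings at pos0 from the reference.
make_alleles <- function(reference, pos0, variant) {
  refseq <- unclass(reference)
  base_at <- function(i) substr(refseq, i + 1L, i + 1L)   # 0-based
  type <- variant$type; len <- max(1L, variant$len)
  if (type == "substitution") {
    ref <- substr(refseq, pos0 + 1L, pos0 + len)
    alt <- paste(random_other_base(strsplit(ref, "")[[1]]), collapse = "")
  } else if (type == "insertion") {
    ref <- base_at(pos0)
    alt <- paste0(ref, paste(sample(BASES, len, replace = TRUE),
                             collapse = ""))
  } else {
    ref <- substr(refseq, pos0 + 1L, pos0 + 1L + len)
    alt <- base_at(pos0)
  }
  list(ref = ref, alt = alt)
}

## One simulated read (full record usable for SAM writing).
sim_read <- function(id, member, reference, pos0_variant, ref, alt,
                     carries_alt, params, artifact = FALSE,
                     type = classify_variant_type(ref, alt)) {
  refseq <- unclass(reference)
  rl <- params$read_length
  vlen_ref <- nchar(ref)
  ## read must contain the whole variant event in its interior
  max_left <- rl - max(nchar(ref), nchar(alt)) - 2L
  offset <- sample.int(max_left, 1L)
  start0 <- max(0L, pos0_variant - offset)
  if (!carries_alt || type == "substitution") {
    ref_span <- rl
  } else if (type == "insertion") {
    ref_span <- rl - (nchar(alt) - nchar(ref))
  } else {
    ref_span <- rl + (nchar(ref) - nchar(alt))
  }
  ref_span <- min(ref_span, nchar(refseq) - start0)
  tmpl <- strsplit(substr(refseq, start0 + 1L, start0 + ref_span), "")[[1]]
  rel <- pos0_variant - start0           # 0-based index of variant in tmpl
  if (carries_alt) {
    if (type == "substitution") {
      seqb <- tmpl
      seqb[rel + seq_len(nchar(ref))] <- strsplit(alt, "")[[1]]
      cigar <- paste0(length(seqb), "M")
      alt_q_idx <- rel + seq_len(nchar(ref))
    } else if (type == "insertion") {
      ins <- substr(alt, 2L, nchar(alt))
      seqb <- c(tmpl[seq_len(rel + 1L)], strsplit(ins, "")[[1]],
                tmpl[(rel + 2L):length(tmpl)])
      cigar <- paste0(rel + 1L, "M", nchar(ins), "I",
                      length(tmpl) - rel - 1L, "M")
      alt_q_idx <- rel + 1L + seq_len(nchar(ins))
    } else {
      dlen <- nchar(ref) - nchar(alt)
      keep <- setdiff(seq_along(tmpl), rel + 1L + seq_len(dlen))
      seqb <- tmpl[keep]
      cigar <- paste0(rel + 1L, "M", dlen, "D",
                      length(tmpl) - rel - 1L - dlen, "M")
      alt_q_idx <- integer(0)
    }
  } else {
    seqb <- tmpl
    cigar <- paste0(length(seqb), "M")
    alt_q_idx <- integer(0)
  }
  ## sequencing errors on the final base sequence
  err <- stats::runif(length(seqb)) < params$base_error_rate
  if (any(err)) seqb[err] <- random_other_base(seqb[err])
  qual <- trunc_norm_int(length(seqb), params$bq_mean, params$bq_sd, 2L, 40L)
  if (artifact && length(alt_q_idx)) {
    qual[alt_q_idx] <- trunc_norm_int(length(alt_q_idx),
                                      params$artifact_bq_mean, 3, 2L, 40L)
  }
  mapq <- trunc_norm_int(1L, params$mq_mean, params$mq_sd, 0L, 60L)
  list(id = id, member = member, pos0 = start0, cigar = cigar,
       seq = paste(seqb, collapse = ""), qual = qual, mapq = mapq)
}

#' Simulate the trio read evidence around one variant site
#'
#' Per member, `Poisson(depth_mean)` reads are drawn spanning the site; the
#' alt allele is injected at the member's VAF (child at `child_vaf`;
#' carrier parents at 0.5 for inherited modes; all members at
#' `artifact_vaf` with low base qualities in artifact mode). The truth
#' label is `"DNM"` iff `inheritance == "denovo"`.
#'
#' @param params a [sim_params()] object.
#' @param position 1-based variant position (defaults to the reference
#'   midpoint).
#' @param reference reference sequence from [synth_reference()] (one is
#'   generated when omitted).
#' @param seed optional RNG seed.
#' @return a `trio_sim`: list with `window` (a `trio_window`), `reads`
#'   (full per-member read records), `truth` (`"DNM"`/`"IV"`), `site`
#'   metadata, and the member VAFs used.
#' @export
simulate_site <- function(params = sim_params(), position = NULL,
                          reference = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) reference <- synth_reference(2000L)
  contig <- attr(reference, "contig") %||% "ref1"
  pos0 <- if (is.null(position)) nchar(reference) %/% 2L else
    as.integer(position) - 1L
  al <- make_alleles(reference, pos0, params$variant)
  vafs <- c(child = 0, father = 0, mother = 0)
  if (params$inheritance == "artifact") {
    vafs[] <- params$artifact_vaf
  } else {
    vafs["child"] <- params$child_vaf
    if (params$inheritance %in% c("inherited_father", "inherited_both")) {
      vafs["father"] <- 0.5
    }
    if (params$inheritance %in% c("inherited_mother", "inherited_both")) {
      vafs["mother"] <- 0.5
    }
  }
  artifact <- params$inheritance == "artifact"
  vtype <- classify_variant_type(al$ref, al$alt)
  reads <- lapply(TRIO_ROLES, function(member) {
    n <- stats::rpois(1L, params$depth_mean[[member]])
    if (n == 0L) return(list())
    n_alt <- stats::rbinom(1L, n, vafs[[member]])
    carries <- sample(c(rep(TRUE, n_alt), rep(FALSE, n - n_alt)))
    lapply(seq_len(n), function(i) {
      sim_read(sprintf("%s_p%d_%03d", member, pos0 + 1L, i), member,
               reference, pos0, al$ref, al$alt, carries[i], params,
               artifact = artifact, type = vtype)
    })
  })
  names(reads) <- TRIO_ROLES
  window <- build_trio_window(reads, contig, pos0, al$ref, al$alt)
  structure(list(
    window = window, reads = reads,
    truth = if (params$inheritance == "denovo") "DNM" else "IV",
    site = list(contig = contig, position = pos0 + 1L, ref = al$ref,
                alt = al$alt, variant_type = window$variant_type,
                inheritance = params$inheritance),
    vafs = vafs
  ), class = "trio_sim")
}

#' Simulate a labeled set of variant sites
#'
#' Sites are laid out along a single synthetic contig with enough spacing
#' that their read windows never overlap, so the set can be written as one
#' BAM/VCF fixture per member.
#'
#' @param n_sites number of sites (> 0).
#' @param class_mix named fractions over inheritance modes (must sum to 1).
#' @param type_mix named fractions over variant types (must sum to 1).
#' @param params template [sim_params()]; its `inheritance`/`variant`
#'   fields are overridden per site.
#' @param seed RNG seed (full determinism given the seed).
#' @return a `trio_simset`: list of `trio_sim` (`$sims`), the `reference`,
#'   and a `manifest` data.frame (contig, position, ref, alt, variant_type,
#'   inheritance, truth).
#' @export
simulate_dataset <- function(n_sites,
                             class_mix = c(denovo = 0.5,
                                           inherited_father = 0.2,
                                           inherited_mother = 0.2,
                                           artifact = 0.1),
                             type_mix = c(substitution = 0.8,
                                          insertion = 0.1, deletion = 0.1),
                             params = sim_params(), seed = 1L) {
  stopifnot(n_sites > 0, abs(sum(class_mix) - 1) < 1e-8,
            abs(sum(type_mix) - 1) < 1e-8)
  set.seed(seed)
  spacing <- 2L * params$read_length + 20L
  ref_len <- (n_sites + 1L) * spacing + 200L
  reference <- synth_reference(ref_len)
  ## deterministic per-class counts: floor + largest-remainder
  alloc <- function(mix, n) {
    raw <- mix * n
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
    }
    cnt
  }
  classes <- rep(names(class_mix), alloc(class_mix, n_sites))
  types <- rep(names(type_mix), alloc(type_mix, n_sites))
  classes <- sample(classes); types <- sample(types)
  sims <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    p <- params
    p$inheritance <- classes[i]
    p$variant <- list(type = types[i],
                      len = if (types[i] == "substitution") 1L else
                        sample(1:3, 1L))
    sims[[i]] <- simulate_site(p, position = i * spacing,
                               reference = reference)
  }
  manifest <- do.call(rbind, lapply(sims, function(s) {
    data.frame(contig = s$site$contig, position = s$site$position,
               ref = s$site$ref, alt = s$site$alt,
               variant_type = s$site$variant_type,
               inheritance = s$site$inheritance, truth = s$truth,
               stringsAsFactors = FALSE)
  }))
  structure(list(sims = sims, reference = reference, manifest = manifest),
            class = "trio_simset")
}

#' Encode a simulated dataset as an image stack
#'
#' @param simset a `trio_simset` (or list of `trio_sim`).
#' @param model an [intensity_model()].
#' @return list with `x` (integer array `160 x 164 x 3 x n`), `y` (1 for
#'   DNM, 0 for IV), `variant_type` (character vector).
#' @export
encode_dataset <- function(simset, model = intensity_model()) {
  sims <- if (inherits(simset, "trio_simset")) simset$sims else simset
  n <- length(sims)
  x <- array(0L, dim = c(IMAGE_ROWS, IMAGE_COLS, 3L, n))
  y <- integer(n)
  vt <- character(n)
  for (i in seq_len(n)) {
    x[, , , i] <- encode_trio(sims[[i]]$window, model)
    y[i] <- as.integer(sims[[i]]$truth == "DNM")
    vt[i] <- sims[[i]]$site$variant_type
  }
  list(x = x, y = y, variant_type = vt)
}

phred_string <- function(q) {
  intToUtf8(pmin(q, 93L) + 33L)
}

## Which members' VCFs carry the site's variant.
vcf_carriers <- function(inheritance) {
  switch(inheritance,
    denovo = "child",
    artifact = "child",                       # false call enters child VCF
    inherited_father = c("child", "father"),
    inherited_mother = c("child", "mother"),
    inherited_both = c("child", "father", "mother")
  )
}

#' Write a simulated dataset as FASTA + BAM + VCF fixtures
#'
#' Emits the synthetic reference (FASTA + index), one coordinate-sorted and
#' indexed BAM per member, and one bgzipped + tabix-indexed VCF per member
#' containing the variants that member's genome carries (artifact sites are
#' emitted as child calls, emulating an upstream false positive). A
#' manifest TSV with truth labels is written alongside.
#'
#' @param simset a `trio_simset`.
#' @param dir output directory (created if needed).
#' @return named list of paths (`reference`, `bam`, `vcf`, `manifest`),
#'   usable directly with [load_trio()].
#' @export
write_fixture <- function(simset, dir) {
  stopifnot(inherits(simset, "trio_simset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contig <- attr(simset$reference, "contig") %||% "ref1"
  ref_len <- nchar(simset$reference)

  ref_fa <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(unclass(simset$reference))
  names(dna) <- contig
  Biostrings::writeXStringSet(dna, ref_fa)
  Rsamtools::indexFa(ref_fa)

  bam_paths <- character(0)
  vcf_paths <- character(0)
  for (member in TRIO_ROLES) {
    reads <- unlist(lapply(simset$sims, function(s) s$reads[[member]]),
                    recursive = FALSE)
    sam <- file.path(dir, paste0(member, ".sam"))
    con <- file(sam, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", contig, ref_len)), con)
    for (r in reads) {
      writeLines(paste(r$id, 0L, contig, r$pos0 + 1L, r$mapq, r$cigar,
                       "*", 0L, 0L, r$seq, phred_string(r$qual),
                       sep = "\t"), con)
    }
    close(con)
    bam <- Rsamtools::asBam(sam, file.path(dir, member),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    bam_paths[member] <- bam

    rows <- simset$manifest[
      vapply(simset$manifest$inheritance,
             function(m) member %in% vcf_carriers(m), logical(1)), ,
      drop = FALSE]
    vcf <- file.path(dir, paste0(member, ".vcf"))
    con <- file(vcf, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s,length=%d>", contig, ref_len),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", sep = "\t")), con)
    if (nrow(rows)) {
      rows <- rows[order(rows$position), , drop = FALSE]
      writeLines(paste(rows$contig, rows$position, ".", rows$ref, rows$alt,
                       100L, "PASS", ".", sep = "\t"), con)
    }
    close(con)
    vgz <- Rsamtools::bgzip(vcf, overwrite = TRUE)
    Rsamtools::indexTabix(vgz, format = "vcf")
    unlink(vcf)
    vcf_paths[member] <- vgz
  }

  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(simset$manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(reference = ref_fa, bam = bam_paths, vcf = vcf_paths,
       manifest = manifest_path)
}
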