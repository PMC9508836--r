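# Shared fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

# A small simulated trio written out as BAM/VCF/FASTA, reused across files.
small_fixture <- function() {
  if (is.null(fixture_cache$small)) {
    dir <- file.path(tempdir(), "trioDNM-small-fixture")
    simset <- simulate_dataset(
      12,
      class_mix = c(denovo = 0.5, inherited_father = 0.25,
                    inherited_mother = 0.25),
      type_mix = c(substitution = 0.6, insertion = 0.2, deletion = 0.2),
      seed = 101
    )
    paths <- write_fixture(simset, dir)
    fixture_cache$small <- list(simset = simset, paths = paths)
  }
  fixture_cache$small
}

load_small_trio <- function() {
  fx <- small_fixture()
  p <- fx$paths
  load_trio(c(p$bam[["child"]], p$vcf[["child"]]),
            c(p$bam[["father"]], p$vcf[["father"]]),
            c(p$bam[["mother"]], p$vcf[["mother"]]))
}

# Hand-built window: one member with explicitly chosen reads.
manual_window <- function(child_reads = list(), father_reads = list(),
                          mother_reads = list(), pos0 = 100L,
                          ref = "A", alt = "G") {
  trioDNM:::build_trio_window(
    list(child = child_reads, father = father_reads, mother = mother_reads),
    "ref1", pos0, ref, alt
  )
}

# A simple ungapped read record.
manual_read <- function(id, pos0, seq, qual = 35L, mapq = 60L) {
  if (length(qual) == 1L) qual <- rep(qual, nchar(seq))
  list(id = id, pos0 = as.integer(pos0), cigar = paste0(nchar(seq), "M"),
       seq = seq, qual = as.integer(qual), mapq = as.integer(mapq))
}

random_base_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
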