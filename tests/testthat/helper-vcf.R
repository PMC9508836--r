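# VCF helpers: write small VCFs and run the bcftools isec oracle.

write_test_vcf <- function(records, path, contig = "ref1",
                           contig_len = 100000L) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", sep = "\t")), con)
  if (nrow(records)) {
    records <- records[order(records$position), , drop = FALSE]
    writeLines(paste(contig, records$position, ".", records$ref,
                     records$alt, 100L, "PASS", ".", sep = "\t"), con)
  }
  close(con)
  gz <- Rsamtools::bgzip(path, overwrite = TRUE)
  Rsamtools::indexTabix(gz, format = "vcf")
  unlink(path)
  gz
}

random_vcf_records <- function(n, positions = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(positions)) positions <- sort(sample(1000:9999, n))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  # mix in some indels
  ind <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
  for (i in which(ind)) {
    if (runif(1) < 0.5) {
      alt[i] <- paste0(ref[i], paste(sample(bases, sample(1:2, 1),
                                            replace = TRUE), collapse = ""))
    } else {
      ref[i] <- paste0(ref[i], paste(sample(bases, sample(1:2, 1),
                                            replace = TRUE), collapse = ""))
      alt[i] <- substr(ref[i], 1, 1)
    }
  }
  unique(data.frame(position = positions, ref = ref, alt = alt,
                    stringsAsFactors = FALSE))
}

have_bcftools <- function() nzchar(Sys.which("bcftools"))

# records private to the child according to bcftools isec -C
bcftools_isec_C <- function(child_gz, father_gz, mother_gz) {
  out <- system2("bcftools",
                 c("isec", "-C", child_gz, father_gz, mother_gz),
                 stdout = TRUE, stderr = FALSE)
  if (!length(out)) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character()))
  }
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[[`, "", 2)),
             ref = vapply(parts, `[[`, "", 3),
             alt = vapply(parts, `[[`, "", 4),
             stringsAsFactors = FALSE)
}
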