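# Trio loading, validation and windowed read extraction.

test_that("load_trio validates files, indexes and roles", {
  fx <- small_fixture()
  p <- fx$paths
  trio <- load_small_trio()
  expect_s3_class(trio, "trio")
  expect_identical(names(trio$samples), c("child", "father", "mother"))
  expect_identical(trio$samples$father$role, "father")

  expect_error(
    load_trio(c(p$bam[["child"]], p$vcf[["child"]]),
              c("/nonexistent/father.bam", p$vcf[["father"]]),
              c(p$bam[["mother"]], p$vcf[["mother"]])),
    "missing file for father"
  )

  # role mislabelling is rejected
  s <- trio_sample("mother", p$bam[["father"]], p$vcf[["father"]])
  expect_error(
    load_trio(c(p$bam[["child"]], p$vcf[["child"]]), s,
              c(p$bam[["mother"]], p$vcf[["mother"]])),
    "labelled"
  )

  # missing index
  noidx <- file.path(tempdir(), "noindex.bam")
  file.copy(p$bam[["child"]], noidx, overwrite = TRUE)
  expect_error(
    load_trio(c(noidx, p$vcf[["child"]]),
              c(p$bam[["father"]], p$vcf[["father"]]),
              c(p$bam[["mother"]], p$vcf[["mother"]])),
    "index"
  )
})

test_that("contig dialect mismatch warns and is harmonized", {
  fx <- small_fixture()
  p <- fx$paths
  # rewrite the child BAM with a chr-prefixed contig
  dir <- file.path(tempdir(), "dialect")
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "child.sam")
  lines <- system2("samtools", c("view", "-h", p$bam[["child"]]),
                   stdout = TRUE)
  lines <- sub("\tSN:ref1", "\tSN:chrref1", lines, fixed = TRUE)
  body <- !startsWith(lines, "@")
  lines[body] <- sub("\tref1\t", "\tchrref1\t", lines[body], fixed = TRUE)
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "child"), overwrite = TRUE)
  expect_warning(
    trio <- load_trio(c(bam, p$vcf[["child"]]),
                      c(p$bam[["father"]], p$vcf[["father"]]),
                      c(p$bam[["mother"]], p$vcf[["mother"]])),
    "dialect"
  )
  # harmonized lookup maps shared names onto each member's own dialect
  expect_identical(trioDNM:::member_contig(trio, "child", "ref1"), "chrref1")
  expect_identical(trioDNM:::member_contig(trio, "father", "chrref1"), "ref1")
})

test_that("extraction windows are exact and deterministic", {
  fx <- small_fixture()
  trio <- load_small_trio()
  site <- fx$simset$manifest[1, ]
  w1 <- extract_trio_window(trio, site$contig, site$position,
                            site$ref, site$alt)
  w2 <- extract_trio_window(trio, site$contig, site$position,
                            site$ref, site$alt)
  expect_identical(w1, w2)
  expect_identical(w1$window_length, 41L)
  expect_identical(w1$window_start + 20L, w1$variant_position)
  # every slice overlaps the window and offsets strictly increase
  for (role in c("child", "father", "mother")) {
    for (s in w1$reads[[role]]) {
      rp <- s$columns$ref_pos[!is.na(s$columns$ref_pos)]
      expect_true(all(diff(rp) > 0))
      expect_true(any(rp >= w1$window_start &
                        rp < w1$window_start + 41L))
    }
  }
  expect_error(extract_trio_window(trio, "ref99", 100, "A", "G"),
               "child")
})

test_that("BAM round-trip preserves bases, offsets and qualities", {
  fx <- small_fixture()
  trio <- load_small_trio()
  for (i in seq_len(nrow(fx$simset$manifest))) {
    site <- fx$simset$manifest[i, ]
    sim_w <- fx$simset$sims[[i]]$window
    bam_w <- extract_trio_window(trio, site$contig, site$position,
                                 site$ref, site$alt)
    for (role in c("child", "father", "mother")) {
      sim_r <- sim_w$reads[[role]]
      bam_r <- bam_w$reads[[role]]
      expect_identical(length(bam_r), length(sim_r))
      for (j in seq_along(sim_r)) {
        expect_identical(bam_r[[j]]$columns, sim_r[[j]]$columns)
        expect_identical(bam_r[[j]]$mapping_quality,
                         sim_r[[j]]$mapping_quality)
      }
    }
  }
})

test_that("the CIGAR walk renders indels and clips correctly", {
  # read: 5M 2D 3M 2I 2M with soft clips on both ends, vs an
  # independently hand-walked alignment
  cols <- trioDNM:::cigar_columns(
    100L, "2S5M2D3M2I2M1S", "NNACGTTGCAGGTAN",
    c(2L, 2L, 30L, 31L, 32L, 33L, 34L, 35L, 36L, 37L, 38L, 39L, 40L, 30L,
      2L)
  )
  expect_identical(cols$ref_pos,
                   c(100:104, 105:106, 107:109, NA, NA, 110:111))
  expect_identical(cols$base,
                   c("A", "C", "G", "T", "T", "-", "-", "G", "C", "A",
                     "G", "G", "T", "A"))
  expect_identical(cols$qual[6:7], c(0L, 0L))      # deletion gap
  expect_identical(cols$qual[1:5], c(30:34))       # clips consumed
})

test_that("reads outside the window and depth-0 members are handled", {
  far <- manual_read("r_far", 10L, random_base_string(30))
  near <- manual_read("r_near", 90L, random_base_string(30))
  w <- manual_window(child_reads = list(far, near), pos0 = 100L)
  expect_identical(length(w$reads$child), 1L)
  expect_identical(w$reads$child[[1]]$read_id, "r_near")
  expect_identical(length(w$reads$father), 0L)
})
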